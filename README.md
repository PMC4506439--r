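# cciNeuroimmune

Rats given a chronic constriction injury (CCI) of the sciatic nerve all
develop mechanical allodynia, but only some develop lasting *behavioural
disability* — a persistent collapse of dominance behaviour in
resident-intruder encounters. `cciNeuroimmune` implements the computational
workflow for studies of this phenomenon: it classifies animals into
disability phenotypes from coded behaviour time series, quantifies immune
readouts (stained-cell densities, densitometry, multiplex cytokine panels
with detection-limit censoring), and applies the study-style statistical
layer. A seeded synthetic-cohort generator reproduces the statistical
structure of such a study so that every stage is testable with known ground
truth.

## The core rules and models

**Phenotype classification.** Each resident's baseline is its mean dominance
duration on the three days before injury (pre days 4–6). With per-day
percent change `100·(post_d − baseline)/baseline`, the ordered rule is:

1. **Pain and disability** — reduction ≥ 30 % on at least 5 of 6 post-injury
   days;
2. **Pain and transient disability** — reduction ≥ 30 % on each of days 1–3
   and recovery (reduction < 30 %) on days 5 and 6 (day 4 unconstrained);
3. **Pain alone** — otherwise.

**Image quantification.** Automated counting of stained cells
(8-connectivity components above an intensity floor, filtered by equivalent
radius), pooled as `cells / (n_fields · field_area_mm²)`; percent
immunoreactive area by Otsu auto-thresholding; the S100 injury/proximal
ratio; the ATF3 nuclear fraction with a 300-neuron floor; electron
microscopy measurement aggregation.

**Statistics.** Censoring-aware group summaries (mean ± SEM), the
sample-size-weighted combined-CCI column `Σnᵢmᵢ/Σnᵢ`, one- and two-way
fixed-effects ANOVA with pooled-variance Bonferroni post hoc contrasts,
ordinary least-squares regression, and Benjamini–Hochberg step-up FDR
control applied within families of tests sharing the same biological
material (one family per tissue panel).

## Worked example

```r
library(cciNeuroimmune)

cfg <- cohort_config(seed = 20151)   # 5/5/4/5 animals, study-style defaults
report <- run_pipeline(cfg, include_images = FALSE)
print(report)
#> run_report (seed 20151)
#>   label recovery: 84.2 %
#>   combined-CCI reproduction: 15 of 23 uncensored rows match
```

At the default day-to-day behavioural jitter (8 s) the 30 % rule recovers
84 % of the generating phenotypes — disability labels sit 40 % below
baseline, so most animals classify correctly, but borderline days flip a
few; at `behaviour_noise_sd = 0` recovery is 100 %. The reproduction line
says that of the 23 uncensored analyte × tissue cells in the reference
cytokine tables, 15 combined-CCI cells are exactly the weighted mean of
their subgroup cells at 1-decimal rounding (the remainder differ only
through rounding of the printed subgroup means, e.g.:

```r
subset(reproduce_tables(), tissue == "nerve" & analyte == "IL6")
#>   tissue analyte censored recomputed printed match
#> 2  nerve     IL6    FALSE   101.2214   101.2  TRUE
```

The numbered scripts under `analysis/` run the same workflow as a
stepwise narrative — simulate (`01`), classify (`02`), quantify the field
images (`03`), statistics (`04`), table reproduction (`05`) — writing
their tables under `results/`.

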