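---
title: "Phenotyping disability and neuro-immune signatures after sciatic nerve constriction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping disability and neuro-immune signatures after sciatic nerve constriction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cciNeuroimmune)
```

## The problem

Chronic constriction injury (CCI) of the rat sciatic nerve is a standard
model of neuropathic pain. All injured animals develop allodynia, yet only a
subgroup develops lasting *behavioural disability*: a persistent loss of
dominance behaviour towards an intruder in daily 6-minute resident-intruder
tests. Studies of this phenomenon classify animals into phenotypes from
their behaviour time series and then ask whether immune readouts — cell
infiltration at the injury site and in the dorsal root ganglia (DRG),
densitometry of Schwann-cell staining, multiplex cytokine panels in nerve,
DRG and spinal cord — differ between phenotypes. This package implements
that computational chain, together with a synthetic cohort generator that
supplies ground truth for every stage: no raw data from such studies are
publicly deposited, so all validation is against generated data with known
structure.

## The classification rule

Behaviour in each 6-minute test is coded into four mutually exclusive
categories (dominance, social, non-social, submissive; daily sums are at
most 360 s). Because stable resident-intruder interactions need several
days of intruder exposure, the baseline is the mean dominance duration over
pre-injury days 4–6, a single scalar. The ordered rule in
`classify_phenotype()`, at the default 30 % threshold, is:

1. reduction ≥ 30 % on ≥ 5 of 6 post-injury days → *Pain and disability*;
2. otherwise, reduction ≥ 30 % on each of days 1–3 and reduction < 30 % on
   both days 5 and 6 → *Pain and transient disability*;
3. otherwise → *Pain alone*.

Sham-operated animals are labelled at surgery and bypass the rule.

Three choices here were genuinely open and are package decisions:

* **The transient window.** Transient disability is described as a drop on
  "the first 3–4 days" followed by recovery. We require days 1–3 below
  threshold and leave day 4 unconstrained, so both 3- and 4-day transients
  are accepted without double-counting against the persistent rule.
* **"Return to pre-injury levels"** is operationalised as reduction < 30 %
  on days 5 and 6, not exact equality with baseline, since day-to-day noise
  makes an exact return unobservable.
* **Zero baseline is an error**, not *Pain alone*: an animal that never
  displayed dominance cannot exhibit a 30 % reduction. `classify_cohort()`
  surfaces the offending animal id.

Each post-injury day is compared against the scalar baseline rather than a
day-matched pre-injury day; whether the original analyses did the same is
not documented, and the per-day-matched variant would behave differently
only when the pre-injury series is unstable.

The scalar effect size used in regressions, `dominance_change_scalar()`, is
the percent change from the pre-injury day 4–6 mean to the post-injury day
4–6 mean.

## The synthetic cohort

`cohort_config()` fixes the study conditions; `generate_cohort()` draws a
cohort bit-reproducibly from the seed. Defaults:

* **Group sizes** (5, 5, 4, 5) for (Sham, PainDisability,
  PainTransientDisability, PainAlone) — the sizes of the reference cytokine
  panels. The reference behavioural cohort was larger (16–24 per group);
  tests that need more animals set `n_per_group` explicitly.
* **Behaviour**: 100 s baseline dominance (the remaining test time is
  split over the other categories with 20 % headroom). Disabled animals
  drop to 60 % of baseline — a 40 % effect, deliberately above the 30 %
  rule threshold so that moderate noise rarely flips labels; transient
  animals recover through day 4 (80 %) to baseline on days 5–6. Dominance
  lost to injury is reallocated to non-social behaviour, mirroring the
  reciprocal dominance/non-social pattern in injured residents; daily
  totals are preserved. Day-to-day jitter is Gaussian per category
  (default SD 8 s, truncated at 0, days rescaled in the rare case a sum
  exceeds 360 s). At that default about 84 % of labels are recovered; at
  zero noise, 100 % (a tested invariant), and recovery is non-increasing
  in the noise SD. The imperfect recovery at realistic noise is a feature
  of rule-based phenotyping worth keeping visible, not a defect.
* **Withdrawal thresholds**: 40 g baseline dropping 15 g after injury
  (shams are forced to no drop), each session the mean of five trials with
  2 g trial SD. These magnitudes are typical for dynamic plantar
  aesthesiometry in adult rats; the reference work reports reductions, not
  absolute thresholds, so the absolute scale is a config choice.
* **Cytokines**: per-animal concentrations are Normal(mean, SEM·√n) using
  the printed group summaries shipped in
  `inst/extdata/cytokine_group_params.csv`, truncated at zero by
  resampling (clipping would create a point mass at 0). Values outside the
  assay range are stored at the limit and flagged. Only two detection
  limits are identifiable from the reference tables — IL-1β upper limit
  3860 pg/mL, IFN-γ lower limit 5 pg/mL — all other analytes get a wide
  default range (1–100 000 pg/mL) so censoring never triggers for them.
  Parameter rows that are themselves censored (nerve IL-1β in every CCI
  group; sham nerve IFN-γ) have no printable distribution, so the
  generator emits deterministically censored measurements at the limit.
* **Fields**: 12 images per animal of 512 × 512 px at 0.5 µm/px (0.0655
  mm² per field — the reference work never states its ×40 field
  dimensions, so this is configurable). Spot counts per field are Poisson
  with group-specific T-lymphocyte densities (1.4, 41.6, 24.6, 21.1
  cells/mm², the reference group means). Spots are Gaussian profiles
  (σ = radius/2, radius 3 µm, peak 30 000 counts) on Gaussian background
  (2000 ± 300), centres at least one diameter apart and fully inside the
  field. Real stained fields contain overlapping cells, uneven
  illumination and debris; non-overlap is enforced so the ground-truth
  count is unambiguous. Passing the recovery tests therefore shows the
  detector is correct on well-separated spots, not that it matches manual
  counts on real tissue.

Within a group, behaviour severity and cytokine level are drawn
independently; no within-animal correlation between the two is asserted,
because none is documented. Regression checks on synthetic data therefore
exercise the between-group signal only.

## Image quantification

* `count_cells()` thresholds at an intensity floor (default 10 000, far
  above the background tail yet below half the spot peak), labels
  8-connected components, and keeps components whose equivalent radius is
  1–8 µm. 8-connectivity and the keep-border-spots rule are package
  decisions; the labelling is a pixel-adjacency graph solved with igraph.
  Automated detection replaces manual counting, which is not reproducible
  in software; its acceptance is defined against the generator's ground
  truth.
* `percent_ir_area()` uses Otsu's method on a 256-bin histogram as the
  auto-threshold (with a fixed-threshold mode for exactness in tests). The
  between-class variance criterion plateaus across empty histogram
  regions; we take the plateau midpoint. A constant image has no Otsu
  threshold and is reported as 0 % with a degenerate flag and a warning.
  Background standardisation via brightness/contrast adjustment, as done
  interactively in image software, is qualitative and not reproduced; only
  the thresholding step is.
* `s100_ratio()`, `atf3_fraction()` (with its 300-neuron reporting floor)
  and `summarize_em()` are deterministic aggregations; electron-microscopy
  tracing itself is out of scope — the package consumes measurement lists.

## Statistics

* `group_summary()` reports mean ± SEM (sample SD, n−1 denominator). A
  single measurement has undefined SEM, reported as 0 with a flag.
* `censored_summary()`: any above-range value makes a group's summary
  "> limit" (the assay only bounds those concentrations from below);
  all-below-range gives "< limit"; such groups are excluded from ANOVA
  rather than imputed — no statistics are reportable for them. Mixed
  high/low censoring within one group is an inconsistent panel and errors.
* `combined_cci_mean()` is the sample-size-weighted subgroup mean. The
  combined SEM is computed from pooled raw values when available and
  otherwise omitted: how a printed combined SEM was derived is not
  recoverable from subgroup summaries, so means are asserted and SEMs are
  not.
* ANOVA and regression wrap `stats::lm`; the degenerate all-identical case
  returns F = 0, p = 1 by convention. Post hoc contrasts use the classic
  pooled-variance t on the omnibus error degrees of freedom with
  Bonferroni multiplication capped at 1; a Welch mode exists but is not
  the default. Contrasts default to each CCI subgroup versus sham, the
  reported comparison set; arbitrary pairs can be requested.
* `two_way_anova()` is fixed-effects with interaction, treating day as a
  crossed factor. A repeated-measures covariance structure over days may
  be more faithful to daily testing of the same animals, but none is
  documented; this is a known divergence risk for p-values (not for the
  sums-of-squares decomposition that the tests pin down).
* `bh_adjust()` implements the Benjamini–Hochberg step-up rule directly and
  is cross-checked in the tests against `stats::p.adjust` and against
  exhaustive evaluation of the definition. Families follow the
  same-biological-material principle: one family per tissue for the
  8-analyte panel, one for the nerve IHC measures; family membership is
  visible in every result row (`family_id`).

## Numerical and testing choices

Problem sizes were chosen to make the stochastic checks sharp but quick:
10 000 random families for the FDR cross-check, 2000 replicate panels for
null calibration (the family-wise rejection rate under a global null must
stay at or below q up to three binomial standard errors), 1000 replicate
cohorts for group-mean recovery (each estimate within two per-animal SDs of
truth at least 95 % of the time), and 50 fields of 5–50 cells for count
recovery (within ±1 in at least 95 % of fields). Determinism is enforced
end to end: every generator takes an explicit seed, `generate_cohort()`
derives sub-seeds from the config seed, and generators restore the caller's
RNG state.

Of the 23 uncensored analyte × tissue cells in the reference tables, 15
combined-CCI cells equal the weighted subgroup mean at 1-decimal rounding.
Seven of the remaining eight differ by at most ~1.6 pg/mL, consistent with
the subgroup means themselves being printed at 1 decimal; the nerve IL-10
combined cell differs by ~9 pg/mL and cannot be produced by any rounding of
its printed subgroups — an apparent typographical inconsistency, documented
here and excluded from the numeric claims.

## Limitations

Animal-level findings from real cohorts (regression r², specific group
p-values) are not reproducible from printed summaries and are deliberately
not asserted; the property suites validate the machinery, not those
numbers. The generator emulates group structure, censoring and field
geometry, not resident-intruder interaction dynamics, bead-assay
fluorescence, or electron micrograph pixels. The cell detector presumes
separable spots; dense infiltrates belong to the densitometry path, which
is why both are implemented.
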