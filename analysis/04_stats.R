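#!/usr/bin/env Rscript
# Statistical layer: censoring-aware cytokine summaries per tissue with the
# combined-CCI column, omnibus one-way ANOVAs with Bonferroni sham contrasts,
# per-tissue Benjamini-Hochberg correction (q < 0.05), T-cell density ANOVA,
# and the regression of density on the dominance-change scalar. Writes
# results/tables_1_2_3.csv, results/stats.csv, results/regression.csv.

library(cciNeuroimmune)

cytokines <- read.csv("results/cohort/cytokines.csv")
labels <- read.csv("results/labels.csv")
quant <- read.csv("results/quant.csv")
behaviour <- read.csv("results/cohort/behaviour.csv")

# analyse by the *assigned* phenotype, as the study would
cytokines$group_truth <- labels$label[match(cytokines$animal_id,
                                            labels$animal_id)]

summary_tab <- summarize_cytokines(cytokines)
write.csv(summary_tab, "results/tables_1_2_3.csv", row.names = FALSE)

st <- cytokine_stats(cytokines)
stats_tbl <- rbind(
  data.frame(measure = "omnibus_anova", tissue = st$omnibus$tissue,
             analyte = st$omnibus$analyte, statistic = st$omnibus$statistic,
             p_raw = st$omnibus$p_raw, family = st$omnibus$family_id,
             significant_q05 = st$omnibus$significant_fdr),
  data.frame(measure = "sham_vs_cci", tissue = st$sham_vs_cci$tissue,
             analyte = st$sham_vs_cci$analyte,
             statistic = st$sham_vs_cci$statistic,
             p_raw = st$sham_vs_cci$p_raw, family = st$sham_vs_cci$family_id,
             significant_q05 = st$sham_vs_cci$significant_fdr))
write.csv(stats_tbl, "results/stats.csv", row.names = FALSE)
cat("Cytokine tests significant after per-tissue BH (q < 0.05):\n")
sig <- stats_tbl[stats_tbl$significant_q05, c("measure", "tissue", "analyte")]
print(sig, row.names = FALSE)

# T-cell density: omnibus + sham contrasts within the nerve IHC family
glist <- split(quant$density_mm2,
               factor(quant$group_truth, levels = phenotype_levels()))
om <- one_way_anova(glist)
ph <- bonferroni_posthoc(glist,
                         comparisons = lapply(cci_levels(),
                                              function(g) c("Sham", g)))
cat(sprintf("\nT-cell density omnibus ANOVA: F = %.2f, p = %.2g\n",
            om$statistic, om$p_raw))
print(ph[, c("group1", "group2", "statistic", "p_raw", "p_bonferroni")],
      row.names = FALSE)

# per-animal regression: density vs dominance change, injured animals only
cci <- labels[labels$label != "Sham", ]
dom_change <- vapply(cci$animal_id, function(id) {
  sub <- behaviour[behaviour$animal_id == id, ]
  dominance_change_scalar(trajectory_from_table(sub))
}, numeric(1))
dens <- quant$density_mm2[match(cci$animal_id, quant$animal_id)]
fit <- linear_regression(dens, dom_change)
reg <- data.frame(x = "tcell_density_mm2", y = "dominance_change_pct",
                  slope = fit$slope, intercept = fit$intercept,
                  r_squared = fit$r_squared, p_raw = fit$p_raw, n = fit$n)
write.csv(reg, "results/regression.csv", row.names = FALSE)
cat(sprintf("\nDensity vs dominance change: slope %.3f, r2 = %.2f, p = %.3g (n = %d)\n",
            fit$slope, fit$r_squared, fit$p_raw, fit$n))
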