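#' Group x analyte cytokine summary table for one cohort
#'
#' Builds, per tissue and analyte, the censoring-aware summaries of the
#' four phenotype groups plus the sample-size-weighted combined-CCI column
#' (with SEM pooled from the raw per-animal values).
#'
#' @param cytokines Long-format cytokine table (schema of
#'   [generate_cohort()]'s `cytokines` element, using the true or assigned
#'   group in `group_truth`).
#' @param assay_range Detection-limit table as [default_assay_range()].
#' @return Data frame: `tissue`, `analyte`, `group`, `n`, `mean`, `sem`,
#'   `censor_state`, with `group` covering the four phenotypes and
#'   `CombinedCCI`.
#' @export
summarize_cytokines <- function(cytokines, assay_range = default_assay_range()) {
  rows <- list(); k <- 0L
  for (tissue in unique(cytokines$tissue)) {
    for (a in unique(cytokines$analyte)) {
      lim <- assay_range[assay_range$analyte == a, ]
      sub <- cytokines[cytokines$tissue == tissue & cytokines$analyte == a, ]
      summaries <- lapply(phenotype_levels(), function(g) {
        censored_summary(sub[sub$group_truth == g, ], lim, group = g)
      })
      names(summaries) <- phenotype_levels()
      cci <- summaries[cci_levels()]
      raw <- sub[sub$group_truth != "Sham" & sub$censor == "none", ]
      combined <- combined_cci_mean(
        cci,
        raw_values = if (all(vapply(cci, function(s) s$censor_state,
                                    character(1)) == "none"))
          raw$conc_pg_ml else NULL)
      for (s in c(summaries, list(combined))) {
        k <- k + 1L
        rows[[k]] <- data.frame(tissue = tissue, analyte = a,
                                group = s$group, n = s$n, mean = s$mean,
                                sem = s$sem, censor_state = s$censor_state)
      }
    }
  }
  do.call(rbind, rows)
}

#' Cytokine statistics for one cohort
#'
#' Per tissue and analyte: (i) sham vs combined-CCI one-way ANOVA, (ii) the
#' omnibus one-way ANOVA across the four groups with Bonferroni post hoc
#' contrasts of each CCI subgroup against sham. Analytes censored in any
#' group are excluded (the assay carries no usable numbers for them).
#' Benjamini-Hochberg correction is applied within one family per tissue —
#' the panel's eight analytes share the same homogenate — separately for
#' the sham-vs-CCI and omnibus test sets.
#'
#' @inheritParams summarize_cytokines
#' @param q FDR level for the family correction.
#' @return List with data frames `omnibus` (tissue, analyte, F, p_raw,
#'   family_id, significant_fdr), `sham_vs_cci` (same layout), and
#'   `posthoc` (per-contrast Bonferroni results).
#' @export
cytokine_stats <- function(cytokines, assay_range = default_assay_range(),
                           q = 0.05) {
  omnibus <- list(); svc <- list(); posthoc <- list(); k <- 0L
  for (tissue in unique(cytokines$tissue)) {
    fam <- paste0("cytokine_", tissue)
    for (a in unique(cytokines$analyte)) {
      sub <- cytokines[cytokines$tissue == tissue & cytokines$analyte == a, ]
      if (any(sub$censor != "none")) next
      k <- k + 1L
      glist <- split(sub$conc_pg_ml,
                     factor(sub$group_truth, levels = phenotype_levels()))
      om <- one_way_anova(glist, family_id = fam)
      omnibus[[k]] <- data.frame(tissue = tissue, analyte = a,
                                 statistic = om$statistic,
                                 p_raw = om$p_raw, family_id = fam)
      two <- one_way_anova(list(Sham = glist$Sham,
                                CCI = unlist(glist[cci_levels()],
                                             use.names = FALSE)),
                           family_id = paste0(fam, "_shamCCI"))
      svc[[k]] <- data.frame(tissue = tissue, analyte = a,
                             statistic = two$statistic, p_raw = two$p_raw,
                             family_id = paste0(fam, "_shamCCI"))
      ph <- bonferroni_posthoc(glist,
                               comparisons = lapply(cci_levels(),
                                                    function(g) c("Sham", g)),
                               family_id = fam)
      ph$tissue <- tissue; ph$analyte <- a
      posthoc[[k]] <- ph
    }
  }
  list(omnibus = adjust_families(do.call(rbind, omnibus), q),
       sham_vs_cci = adjust_families(do.call(rbind, svc), q),
       posthoc = do.call(rbind, posthoc))
}

#' Check the combined-CCI column against its printed values
#'
#' For every tissue x analyte with numeric subgroup summaries, recomputes
#' the sample-size-weighted mean of the three CCI subgroup means and
#' compares it with the printed combined-CCI cell at 1-decimal rounding.
#' Rows censored in any subgroup are reported as censored with no numeric
#' comparison. A handful of rows fail the identity because the printed
#' subgroup means are themselves rounded to 1 decimal; `match` records the
#' outcome row by row.
#'
#' @param params Subgroup parameter table as [cytokine_group_params()].
#' @param printed Printed combined column as [combined_cci_printed()].
#' @return Data frame: `tissue`, `analyte`, `censored`, `recomputed`,
#'   `printed`, `match` (NA for censored rows).
#' @export
reproduce_tables <- function(params = cytokine_group_params(),
                             printed = combined_cci_printed()) {
  rows <- list(); k <- 0L
  for (i in seq_len(nrow(printed))) {
    tissue <- printed$tissue[i]; a <- printed$analyte[i]
    sub <- params[params$tissue == tissue & params$analyte == a &
                    params$group %in% cci_levels(), ]
    k <- k + 1L
    if (any(sub$censor != "none") || printed$censor[i] != "none") {
      rows[[k]] <- data.frame(tissue = tissue, analyte = a, censored = TRUE,
                              recomputed = NA_real_, printed = NA_real_,
                              match = NA)
      next
    }
    summaries <- lapply(seq_len(nrow(sub)), function(j) {
      s <- group_summary(sub$mean[j], group = sub$group[j])
      s$n <- sub$n[j]
      s
    })
    w <- combined_cci_mean(summaries)
    rows[[k]] <- data.frame(
      tissue = tissue, analyte = a, censored = FALSE,
      recomputed = w$mean, printed = printed$mean[i],
      match = abs(round(w$mean, 1) - round(printed$mean[i], 1)) < 1e-9)
  }
  do.call(rbind, rows)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates a cohort from the configuration, classifies every injured
#' animal from its behaviour, quantifies the per-animal T-lymphocyte field
#' sets, computes withdrawal-threshold reductions, runs the cytokine and
#' cell-density statistics with family-wise BH correction, regresses cell
#' density on the dominance-change scalar, and recomputes the combined-CCI
#' reproduction table. Deterministic under the configuration seed.
#'
#' @param config A [cohort_config()].
#' @param out_dir Optional directory; when given, the cohort CSVs, result
#'   tables and a JSON report are written there.
#' @param include_images Generate and quantify microscope fields (default
#'   TRUE).
#' @param threshold_pct Classification threshold passed to
#'   [classify_cohort()].
#' @param q FDR level.
#' @return List of class `run_report`: `labels`, `label_recovery`,
#'   `withdrawal_reduction`, `cytokine_summary`, `cytokine_stats`,
#'   `cell_density` and `density_stats` (when images are on), `regression`,
#'   `reproduction`, `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL, include_images = TRUE,
                         threshold_pct = 30, q = 0.05) {
  stopifnot(inherits(config, "cohort_config"))
  cohort <- generate_cohort(config, include_images = include_images)

  labels <- classify_cohort(cohort$behaviour, threshold_pct)
  truth <- cohort$animals$group_truth[match(labels$animal_id,
                                            cohort$animals$animal_id)]
  label_recovery <- mean(labels$label == truth)

  wd <- do.call(rbind, lapply(split(cohort$withdrawal,
                                    cohort$withdrawal$animal_id),
    function(sub) {
      ws <- withdrawal_series(
        sub$threshold_g[match(paste0("baseline", 1:3), sub$session)],
        sub$threshold_g[match(c("post_d2_3", "post_d4_5"), sub$session)])
      data.frame(animal_id = sub$animal_id[1],
                 group_truth = sub$group_truth[1],
                 timepoint = c("d2_3", "d4_5"),
                 reduction_g = withdrawal_reduction(ws))
    }))
  rownames(wd) <- NULL

  cyto_summary <- summarize_cytokines(cohort$cytokines, config$assay_range)
  cyto_stats <- cytokine_stats(cohort$cytokines, config$assay_range, q)

  density <- NULL; density_stats <- NULL; regression <- NULL
  if (include_images) {
    density <- quantify_cohort_fields(cohort)
    glist <- split(density$density_mm2,
                   factor(density$group_truth, levels = phenotype_levels()))
    om <- one_way_anova(glist, family_id = "ihc_nerve")
    ph <- bonferroni_posthoc(glist,
                             comparisons = lapply(cci_levels(),
                                                  function(g) c("Sham", g)),
                             family_id = "ihc_nerve")
    density_stats <- list(
      omnibus = adjust_families(
        data.frame(measure = "tcell_density_mm2", statistic = om$statistic,
                   p_raw = om$p_raw, family_id = "ihc_nerve"), q),
      posthoc = ph)

    cci_ids <- labels$animal_id[labels$label != "Sham"]
    dom_change <- vapply(cci_ids, function(id) {
      dominance_change_scalar(trajectory_from_table(
        cohort$behaviour[cohort$behaviour$animal_id == id, ]))
    }, numeric(1))
    dens_cci <- density$density_mm2[match(cci_ids, density$animal_id)]
    if (length(cci_ids) >= 3L && stats::var(dens_cci) > 0) {
      regression <- linear_regression(dens_cci, dom_change,
                                      family_id = "ihc_nerve")
    }
  }

  reproduction <- reproduce_tables(config$group_cytokine_params)

  report <- structure(
    list(labels = labels, label_recovery = label_recovery,
         withdrawal_reduction = wd,
         cytokine_summary = cyto_summary, cytokine_stats = cyto_stats,
         cell_density = density, density_stats = density_stats,
         regression = regression, reproduction = reproduction,
         provenance = list(seed = config$seed,
                           n_per_group = as.list(config$n_per_group),
                           threshold_pct = threshold_pct, q = q,
                           package_version =
                             as.character(utils::packageVersion("cciNeuroimmune")))),
    class = "run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    utils::write.csv(labels, file.path(out_dir, "labels.csv"),
                     row.names = FALSE)
    utils::write.csv(cyto_summary, file.path(out_dir, "tables_1_2_3.csv"),
                     row.names = FALSE)
    utils::write.csv(reproduction, file.path(out_dir, "reproduction.csv"),
                     row.names = FALSE)
    stats_tbl <- rbind(
      data.frame(measure = paste(cyto_stats$omnibus$analyte, "omnibus"),
                 tissue = cyto_stats$omnibus$tissue,
                 statistic = cyto_stats$omnibus$statistic,
                 p_raw = cyto_stats$omnibus$p_raw,
                 family = cyto_stats$omnibus$family_id,
                 significant_q05 = cyto_stats$omnibus$significant_fdr),
      data.frame(measure = paste(cyto_stats$sham_vs_cci$analyte,
                                 "sham_vs_cci"),
                 tissue = cyto_stats$sham_vs_cci$tissue,
                 statistic = cyto_stats$sham_vs_cci$statistic,
                 p_raw = cyto_stats$sham_vs_cci$p_raw,
                 family = cyto_stats$sham_vs_cci$family_id,
                 significant_q05 = cyto_stats$sham_vs_cci$significant_fdr))
    utils::write.csv(stats_tbl, file.path(out_dir, "stats.csv"),
                     row.names = FALSE)
    json_report <- list(
      label_recovery = label_recovery,
      reproduction_matches = sum(reproduction$match, na.rm = TRUE),
      reproduction_checked = sum(!is.na(reproduction$match)),
      provenance = report$provenance)
    jsonlite::write_json(json_report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (seed ", x$provenance$seed, ")\n", sep = "")
  cat(sprintf("  label recovery: %.1f %%\n", 100 * x$label_recovery))
  cat(sprintf("  combined-CCI reproduction: %d of %d uncensored rows match\n",
              sum(x$reproduction$match, na.rm = TRUE),
              sum(!is.na(x$reproduction$match))))
  if (!is.null(x$regression)) {
    cat(sprintf("  density ~ dominance change: slope %.3f, r2 %.3f\n",
                x$regression$slope, x$regression$r_squared))
  }
  invisible(x)
}
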