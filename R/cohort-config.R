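#' Reference cytokine group parameters
#'
#' Group-level summaries (mean, SEM, group size) of the 8-plex cytokine panel
#' (IL-1b, IL-6, IL-10, IL-17A, IL-18, TNF, IFN-g, MCP-1) measured in the
#' ipsilateral sciatic nerve, L4-L5 DRG and L4-L5 spinal cord seven days
#' after chronic constriction injury, per phenotype group. Rows whose
#' concentration fell outside the assay's detection range carry a censor flag
#' (`above_range` for nerve IL-1b in all CCI groups, `below_range` for sham
#' nerve IFN-g) and no numeric mean. These parameters drive the synthetic
#' cohort generator and are the targets of the combined-CCI reproduction
#' check.
#'
#' @return Data frame with columns `tissue`, `analyte`, `group`, `n`,
#'   `mean`, `sem`, `censor`.
#' @export
cytokine_group_params <- function() {
  path <- system.file("extdata", "cytokine_group_params.csv",
                      package = "cciNeuroimmune", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published combined-CCI column
#'
#' The printed combined-CCI (n = 14) cytokine summaries corresponding to
#' [cytokine_group_params()], used by [reproduce_tables()] to check that the
#' combined column is the sample-size-weighted mean of the three CCI
#' subgroup columns.
#'
#' @return Data frame with columns `tissue`, `analyte`, `mean`, `sem`,
#'   `censor`.
#' @export
combined_cci_printed <- function() {
  path <- system.file("extdata", "combined_cci_printed.csv",
                      package = "cciNeuroimmune", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Default assay detection ranges
#'
#' Detection limits (pg/mL) for the multiplex panel. Only two limits are
#' identified by the reference data: the IL-1b upper limit of 3860 pg/mL
#' (exceeded in the injured nerve of every CCI group) and the IFN-g lower
#' limit of 5 pg/mL (sham nerve below detection). The remaining analytes get
#' a deliberately wide range so censoring never triggers for them.
#'
#' @return Data frame with columns `analyte`, `lower`, `upper`.
#' @export
default_assay_range <- function() {
  analytes <- c("IL1b", "IL6", "IL10", "IL17A", "IL18", "TNF", "IFNg", "MCP1")
  out <- data.frame(analyte = analytes, lower = 1, upper = 1e5)
  out$upper[out$analyte == "IL1b"] <- 3860
  out$lower[out$analyte == "IFNg"] <- 5
  out
}

#' Default synthetic microscope-field geometry
#'
#' @return Named list: `width_px`, `height_px` (field size), `pixel_size_um`
#'   (physical pixel pitch), `cell_radius_um` (nominal stained-cell radius),
#'   `cell_peak` (spot peak intensity, 16-bit counts), `background_mean` and
#'   `background_sd` (additive Gaussian background). The default 512 x 512
#'   field at 0.5 um/px covers 0.0655 mm2.
#' @export
default_image_params <- function() {
  list(width_px = 512L, height_px = 512L, pixel_size_um = 0.5,
       cell_radius_um = 3, cell_peak = 30000,
       background_mean = 2000, background_sd = 300)
}

#' Area of one microscope field in mm2
#'
#' @param params Image-parameter list as in [default_image_params()].
#' @return Field area in mm2.
#' @export
field_area_mm2 <- function(params = default_image_params()) {
  params$width_px * params$height_px * (params$pixel_size_um / 1000)^2
}

#' Cohort configuration
#'
#' Bundles every parameter the synthetic-cohort generator needs. Defaults
#' reproduce the reference study conditions: group sizes (5, 5, 4, 5) for
#' (Sham, PainDisability, PainTransientDisability, PainAlone) as in the
#' cytokine panels, a 100 s pre-injury dominance baseline with a 40 %
#' post-injury reduction in disabled animals, von Frey thresholds around
#' 40 g dropping by 15 g after injury, cytokine distributions parameterised
#' by the printed group means/SEMs, and nerve T-lymphocyte densities of
#' (1.4, 41.6, 24.6, 21.1) cells/mm2 for (Sham, PainDisability,
#' PainTransientDisability, PainAlone).
#'
#' @param n_per_group Single integer, or named integer vector over the four
#'   phenotype groups.
#' @param seed Integer RNG seed; identical configurations with identical
#'   seeds generate bit-identical cohorts.
#' @param baseline_dominance_s Pre-injury dominance duration (seconds).
#' @param disability_drop Fractional post-injury dominance reduction in
#'   disabled animals (default 0.4, i.e. 40 %, a margin above the 30 %
#'   classification threshold so moderate noise does not flip labels).
#' @param behaviour_noise_sd Day-to-day jitter SD of category durations (s).
#' @param withdrawal_baseline_g,withdrawal_drop_g,withdrawal_trial_sd Von
#'   Frey baseline (grams), post-injury drop (grams; forced to 0 for shams)
#'   and per-trial SD.
#' @param group_cytokine_params Parameter table as
#'   [cytokine_group_params()].
#' @param assay_range Detection-limit table as [default_assay_range()].
#' @param image_params Field geometry as [default_image_params()].
#' @param tcell_density_mm2 Named vector of true nerve T-lymphocyte
#'   densities (cells/mm2) per group.
#' @param n_fields Fields imaged per animal (default 12).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(Sham = 5L, PainDisability = 5L,
                                          PainTransientDisability = 4L,
                                          PainAlone = 5L),
                          seed = 1L,
                          baseline_dominance_s = 100,
                          disability_drop = 0.4,
                          behaviour_noise_sd = 8,
                          withdrawal_baseline_g = 40,
                          withdrawal_drop_g = 15,
                          withdrawal_trial_sd = 2,
                          group_cytokine_params = cytokine_group_params(),
                          assay_range = default_assay_range(),
                          image_params = default_image_params(),
                          tcell_density_mm2 = c(Sham = 1.4,
                                                PainDisability = 41.6,
                                                PainTransientDisability = 24.6,
                                                PainAlone = 21.1),
                          n_fields = 12L) {
  if (length(n_per_group) == 1L && is.null(names(n_per_group))) {
    n_per_group <- setNames(rep(as.integer(n_per_group), 4L),
                            phenotype_levels())
  }
  if (!all(phenotype_levels() %in% names(n_per_group))) {
    stop("n_per_group must name all four phenotype groups", call. = FALSE)
  }
  n_per_group <- as.integer(n_per_group[phenotype_levels()])
  names(n_per_group) <- phenotype_levels()
  stopifnot(all(n_per_group >= 1L),
            baseline_dominance_s > 0, baseline_dominance_s <= 360,
            disability_drop > 0, disability_drop < 1,
            behaviour_noise_sd >= 0,
            withdrawal_baseline_g > 0,
            withdrawal_drop_g >= 0,
            withdrawal_drop_g < withdrawal_baseline_g,
            withdrawal_trial_sd >= 0,
            all(assay_range$lower < assay_range$upper),
            all(is.na(group_cytokine_params$sem) |
                  group_cytokine_params$sem >= 0),
            image_params$cell_radius_um > 0,
            n_fields >= 1L)
  structure(
    list(n_per_group = n_per_group, seed = as.integer(seed),
         baseline_dominance_s = baseline_dominance_s,
         disability_drop = disability_drop,
         behaviour_noise_sd = behaviour_noise_sd,
         withdrawal_baseline_g = withdrawal_baseline_g,
         withdrawal_drop_g = withdrawal_drop_g,
         withdrawal_trial_sd = withdrawal_trial_sd,
         group_cytokine_params = group_cytokine_params,
         assay_range = assay_range,
         image_params = image_params,
         tcell_density_mm2 = tcell_density_mm2,
         n_fields = as.integer(n_fields)),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("cohort_config: n per group =",
      paste(names(x$n_per_group), x$n_per_group, sep = ":", collapse = ", "),
      "\n  seed", x$seed,
      "| dominance baseline", x$baseline_dominance_s, "s, drop",
      100 * x$disability_drop, "%, noise sd", x$behaviour_noise_sd, "s\n")
  invisible(x)
}
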