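# Synthetic-cohort generators. Each generator takes an explicit seed and is
# bit-reproducible; generate_cohort() derives sub-seeds from the config seed
# so components stay independent of evaluation order.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate one behaviour trajectory with a known phenotype
#'
#' Builds the deterministic phenotype structure first, then adds day-to-day
#' noise. Before noise: `PainDisability` animals sit at
#' `(1 - disability_drop)` of baseline dominance on all six post-injury days;
#' `PainTransientDisability` animals on days 1-3, with partial recovery
#' (80 % of baseline) on day 4 and full recovery on days 5-6; `PainAlone`
#' and `Sham` stay at baseline. Dominance lost to the injury is reallocated
#' to non-social behaviour, so the daily total is preserved, mirroring the
#' reciprocal dominance/non-social pattern seen in injured residents.
#'
#' @param phenotype One of [phenotype_levels()].
#' @param baseline_dominance Pre-injury dominance duration in seconds
#'   (0 < x <= 360).
#' @param noise_sd Day-to-day jitter SD (seconds) applied to every category.
#' @param seed Integer seed.
#' @param disability_drop Fractional dominance reduction in disabled
#'   animals; the default 0.4 leaves a margin above the 30 % rule threshold.
#' @param animal_id Identifier stored in the trajectory.
#' @return A [behaviour_trajectory()].
#' @export
generate_behaviour_trajectory <- function(phenotype, baseline_dominance,
                                          noise_sd, seed,
                                          disability_drop = 0.4,
                                          animal_id = "synthetic") {
  assert_phenotype(phenotype)
  if (!is.numeric(baseline_dominance) || baseline_dominance <= 0 ||
      baseline_dominance > 360) {
    stop("baseline_dominance must be in (0, 360] seconds", call. = FALSE)
  }
  stopifnot(noise_sd >= 0, disability_drop > 0, disability_drop < 1)

  # Split the time not spent dominating over the other three categories,
  # leaving 20 % of the 6-min test unused so jitter cannot overflow the test
  # length in typical configurations.
  rest <- 0.8 * (360 - baseline_dominance)
  base_profile <- c(dominance_s = baseline_dominance,
                    social_s = 0.4 * rest,
                    nonsocial_s = 0.5 * rest,
                    submissive_s = 0.1 * rest)

  post_factor <- switch(phenotype,
    PainDisability = rep(1 - disability_drop, 6),
    PainTransientDisability = c(rep(1 - disability_drop, 3), 0.8, 1, 1),
    PainAlone = rep(1, 6),
    Sham = rep(1, 6)
  )

  day_profile <- function(factor) {
    dom <- base_profile[["dominance_s"]] * factor
    lost <- base_profile[["dominance_s"]] - dom
    c(dominance_s = dom,
      social_s = base_profile[["social_s"]],
      nonsocial_s = base_profile[["nonsocial_s"]] + lost,
      submissive_s = base_profile[["submissive_s"]])
  }

  with_seed(seed, {
    make_phase <- function(factors) {
      days <- t(vapply(factors, day_profile, numeric(4)))
      if (noise_sd > 0) {
        days <- days + matrix(stats::rnorm(length(days), 0, noise_sd),
                              nrow = nrow(days))
        days[days < 0] <- 0
        over <- rowSums(days) > 360
        days[over, ] <- days[over, , drop = FALSE] *
          (360 / rowSums(days)[over])
      }
      as.data.frame(days)
    }
    pre <- make_phase(rep(1, 6))
    post <- make_phase(post_factor)
    behaviour_trajectory(animal_id, pre, post)
  })
}

#' Generate a von Frey withdrawal-threshold series
#'
#' Three pre-injury baseline sessions and two post-injury sessions (days 2/3
#' and 4/5), each session the mean of five simulated trials drawn from a
#' normal distribution around the session's true threshold. Sham animals
#' keep the baseline threshold after surgery regardless of `injury_drop_g`.
#'
#' @param group One of [phenotype_levels()].
#' @param baseline_g True pre-injury threshold (grams, > 0).
#' @param injury_drop_g True post-injury threshold drop (grams,
#'   0 <= drop < baseline).
#' @param seed Integer seed.
#' @param trial_sd Per-trial SD in grams.
#' @return A [withdrawal_series()].
#' @export
generate_withdrawal_series <- function(group, baseline_g, injury_drop_g,
                                       seed, trial_sd = 2) {
  assert_phenotype(group)
  if (baseline_g <= 0 || injury_drop_g < 0 || trial_sd < 0) {
    stop("baseline_g must be positive; injury_drop_g and trial_sd non-negative",
         call. = FALSE)
  }
  if (injury_drop_g >= baseline_g) {
    stop("injury_drop_g must be smaller than baseline_g", call. = FALSE)
  }
  if (group == "Sham") injury_drop_g <- 0
  with_seed(seed, {
    session_mean <- function(true_g) {
      trials <- stats::rnorm(5, true_g, trial_sd)
      while (any(trials <= 0)) {  # thresholds are physical weights
        trials[trials <= 0] <- stats::rnorm(sum(trials <= 0), true_g, trial_sd)
      }
      mean(trials)
    }
    withdrawal_series(
      baseline_g = vapply(rep(baseline_g, 3), session_mean, numeric(1)),
      post_g = vapply(rep(baseline_g - injury_drop_g, 2), session_mean,
                      numeric(1))
    )
  })
}

#' Generate a per-animal cytokine panel for one tissue and group
#'
#' For each analyte with a numeric parameter row, per-animal concentrations
#' are drawn from Normal(mean, SEM * sqrt(n)) — the per-animal SD
#' reconstructed from the printed group summary — truncated at zero by
#' resampling (not clipping, which would pile mass at zero). Draws outside
#' the assay detection range are stored at the limit with a censor flag.
#' Parameter rows that are themselves censored (nerve IL-1b after injury,
#' sham nerve IFN-g) have no printable distribution, so every animal is
#' emitted censored at the corresponding limit.
#'
#' @param tissue One of `"nerve"`, `"drg"`, `"spinal"`.
#' @param group One of [phenotype_levels()].
#' @param config A [cohort_config()]; supplies parameters, assay ranges and
#'   the number of animals.
#' @param seed Integer seed.
#' @return Data frame: `animal`, `tissue`, `analyte`, `conc_pg_ml`,
#'   `censor` (`"none"`, `"high"`, `"low"`).
#' @export
generate_cytokine_panel <- function(tissue, group, config, seed) {
  assert_phenotype(group)
  params <- config$group_cytokine_params
  rows <- params[params$tissue == tissue & params$group == group, ,
                 drop = FALSE]
  analytes <- default_assay_range()$analyte
  if (!setequal(rows$analyte, analytes)) {
    stop("missing cytokine parameters for (", tissue, ", ", group, ")",
         call. = FALSE)
  }
  n <- config$n_per_group[[group]]
  with_seed(seed, {
    out <- lapply(analytes, function(a) {
      p <- rows[rows$analyte == a, ]
      lim <- config$assay_range[config$assay_range$analyte == a, ]
      if (p$censor == "above_range") {
        data.frame(animal = seq_len(n), tissue = tissue, analyte = a,
                   conc_pg_ml = lim$upper, censor = "high")
      } else if (p$censor == "below_range") {
        data.frame(animal = seq_len(n), tissue = tissue, analyte = a,
                   conc_pg_ml = lim$lower, censor = "low")
      } else {
        sd_animal <- p$sem * sqrt(p$n)
        x <- stats::rnorm(n, p$mean, sd_animal)
        while (any(x < 0)) {
          x[x < 0] <- stats::rnorm(sum(x < 0), p$mean, sd_animal)
        }
        censor <- ifelse(x > lim$upper, "high",
                         ifelse(x < lim$lower, "low", "none"))
        x[censor == "high"] <- lim$upper
        x[censor == "low"] <- lim$lower
        data.frame(animal = seq_len(n), tissue = tissue, analyte = a,
                   conc_pg_ml = x, censor = censor)
      }
    })
    do.call(rbind, out)
  })
}

#' Generate one synthetic microscope field with ground truth
#'
#' Places `n_cells` Gaussian-profile spots (sigma = radius / 2 in pixels) on
#' a Gaussian background, with centres at least `2 * radius` apart and at
#' least one radius from the border so every spot lies fully inside the
#' field. Real stained fields contain overlapping cells; non-overlap is
#' enforced here so the ground-truth count is unambiguous for validating
#' automated detection. Returns the noisy image together with the true spot
#' centres and the noise-free half-peak coverage mask used as densitometry
#' ground truth.
#'
#' @param n_cells Number of cells to place (>= 0).
#' @param params Field geometry, as [default_image_params()].
#' @param seed Integer seed.
#' @return A list of class `ground_truth_field`: `image` (a `field_image`),
#'   `true_positions` (n x 2 matrix of x/y pixel centres), `true_count`,
#'   `true_mask` (logical matrix, signal >= half peak before noise).
#' @export
generate_field_image <- function(n_cells, params = default_image_params(),
                                 seed = 1L) {
  stopifnot(n_cells >= 0, params$cell_radius_um > 0)
  w <- params$width_px; h <- params$height_px
  r_px <- params$cell_radius_um / params$pixel_size_um
  # conservative packing bound for rejection sampling
  capacity <- floor((w - 2 * r_px) * (h - 2 * r_px) / (4 * r_px)^2)
  if (n_cells > capacity) {
    stop("n_cells = ", n_cells, " cannot be placed without overlap ",
         "(capacity ~", capacity, ")", call. = FALSE)
  }
  with_seed(seed, {
    pos <- matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("x_px", "y_px")))
    tries <- 0L
    while (nrow(pos) < n_cells) {
      cand <- c(stats::runif(1, r_px + 1, w - r_px),
                stats::runif(1, r_px + 1, h - r_px))
      ok <- nrow(pos) == 0L ||
        all((pos[, 1] - cand[1])^2 + (pos[, 2] - cand[2])^2 >= (2 * r_px)^2)
      if (ok) pos <- rbind(pos, cand)
      tries <- tries + 1L
      if (tries > 200L * max(n_cells, 1L) + 1000L) {
        stop("failed to place ", n_cells, " non-overlapping cells",
             call. = FALSE)
      }
    }
    rownames(pos) <- NULL

    signal <- matrix(0, nrow = h, ncol = w)  # row = y, col = x
    sigma <- r_px / 2
    half <- ceiling(3 * sigma)
    for (i in seq_len(nrow(pos))) {
      cx <- pos[i, 1]; cy <- pos[i, 2]
      xs <- max(1, floor(cx - half)):min(w, ceiling(cx + half))
      ys <- max(1, floor(cy - half)):min(h, ceiling(cy + half))
      d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
      signal[ys, xs] <- signal[ys, xs] +
        params$cell_peak * exp(-d2 / (2 * sigma^2))
    }
    noise <- matrix(stats::rnorm(w * h, params$background_mean,
                                 params$background_sd), nrow = h)
    pixels <- pmin(pmax(round(signal + noise), 0), 65535)
    list_out <- list(
      image = field_image(pixels, params$pixel_size_um, channel = "TCRab"),
      true_positions = pos,
      true_count = nrow(pos),
      true_mask = signal >= params$cell_peak / 2
    )
    class(list_out) <- "ground_truth_field"
    list_out
  })
}

#' Generate a complete synthetic cohort
#'
#' One record per animal linking the true phenotype label, a behaviour
#' trajectory, a withdrawal series, cytokine panels for all three tissues,
#' and (optionally) a set of nerve T-lymphocyte fields whose expected cell
#' count per field follows the group's configured density. All randomness
#' derives from `config$seed`, so identical configurations generate
#' bit-identical cohorts.
#'
#' @param config A [cohort_config()].
#' @param include_images Generate per-animal ground-truth field sets
#'   (default TRUE; disable for lightweight statistical simulations).
#' @return A list of class `synthetic_cohort`: `animals` (data frame of
#'   `animal_id`, `group_truth`), `behaviour`, `withdrawal`, `cytokines`
#'   (long-format data frames), `fields` (named list per animal of
#'   `ground_truth_field` lists, or NULL), `config`.
#' @export
generate_cohort <- function(config, include_images = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- rep(phenotype_levels(), times = config$n_per_group)
  ids <- sprintf("%s_%02d", c(Sham = "SH", PainAlone = "PA",
                              PainTransientDisability = "PT",
                              PainDisability = "PD")[groups],
                 unlist(lapply(config$n_per_group, seq_len)))
  n_animals <- length(ids)
  sub_seeds <- with_seed(config$seed,
                         sample.int(.Machine$integer.max,
                                    3L * n_animals + 12L + n_animals))

  behaviour <- list(); withdrawal <- list(); fields <- NULL
  if (include_images) fields <- setNames(vector("list", n_animals), ids)
  area <- field_area_mm2(config$image_params)

  for (i in seq_len(n_animals)) {
    traj <- generate_behaviour_trajectory(
      groups[i], config$baseline_dominance_s, config$behaviour_noise_sd,
      seed = sub_seeds[i], disability_drop = config$disability_drop,
      animal_id = ids[i])
    behaviour[[i]] <- data.frame(
      animal_id = ids[i], group_truth = groups[i],
      phase = rep(c("pre", "post"), each = 6), day = rep(1:6, 2),
      rbind(traj$pre, traj$post))

    ws <- generate_withdrawal_series(
      groups[i], config$withdrawal_baseline_g, config$withdrawal_drop_g,
      seed = sub_seeds[n_animals + i], trial_sd = config$withdrawal_trial_sd)
    withdrawal[[i]] <- data.frame(
      animal_id = ids[i], group_truth = groups[i],
      session = c("baseline1", "baseline2", "baseline3", "post_d2_3",
                  "post_d4_5"),
      threshold_g = c(ws$baseline_g, ws$post_g))

    if (include_images) {
      img_seed <- sub_seeds[3L * n_animals + 12L + i]
      density <- config$tcell_density_mm2[[groups[i]]]
      fields[[ids[i]]] <- with_seed(img_seed, {
        n_cells <- stats::rpois(config$n_fields, density * area)
        fseeds <- sample.int(.Machine$integer.max, config$n_fields)
        lapply(seq_len(config$n_fields), function(j) {
          generate_field_image(n_cells[j], config$image_params, fseeds[j])
        })
      })
    }
  }

  cytokines <- list(); k <- 0L
  for (tissue in c("nerve", "drg", "spinal")) {
    for (g in phenotype_levels()) {
      k <- k + 1L
      panel <- generate_cytokine_panel(tissue, g, config,
                                       seed = sub_seeds[2L * n_animals + k])
      idx <- ids[groups == g][panel$animal]
      panel$animal_id <- idx
      panel$group_truth <- g
      cytokines[[k]] <- panel[, c("animal_id", "group_truth", "tissue",
                                  "analyte", "conc_pg_ml", "censor")]
    }
  }

  structure(
    list(animals = data.frame(animal_id = ids, group_truth = groups),
         behaviour = do.call(rbind, behaviour),
         withdrawal = do.call(rbind, withdrawal),
         cytokines = do.call(rbind, cytokines),
         fields = fields,
         config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$animals), "animals (",
      paste(names(table(x$animals$group_truth)),
            table(x$animals$group_truth), sep = "=", collapse = ", "),
      ")\n", sep = " ")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes `behaviour.csv`, `withdrawal.csv`, `cytokines.csv`, a JSON config
#' snapshot, and (when fields are present) one 16-bit grayscale TIFF per
#' field plus a `truth.json` sidecar of true counts and positions.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$behaviour, file.path(dir, "behaviour.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$withdrawal, file.path(dir, "withdrawal.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$cytokines, file.path(dir, "cytokines.csv"),
                   row.names = FALSE)
  cfg <- cohort$config
  cfg$group_cytokine_params <- NULL  # shipped with the package
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  if (!is.null(cohort$fields)) {
    img_dir <- file.path(dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    truth <- list()
    for (id in names(cohort$fields)) {
      for (j in seq_along(cohort$fields[[id]])) {
        f <- cohort$fields[[id]][[j]]
        fname <- sprintf("%s_field%02d.tif", id, j)
        tiff::writeTIFF(f$image$pixels / 65535,
                        file.path(img_dir, fname), bits.per.sample = 16L)
        truth[[fname]] <- list(true_count = f$true_count,
                               true_positions = f$true_positions)
      }
    }
    jsonlite::write_json(truth, file.path(img_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
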