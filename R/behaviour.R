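#' Baseline dominance duration
#'
#' Stable resident-intruder interactions only develop after repeated intruder
#' exposure, so the behavioural baseline is the mean dominance duration over
#' the last three pre-injury test days (pre days 4-6), not all six.
#'
#' @param trajectory A [behaviour_trajectory()].
#' @return Baseline dominance duration in seconds.
#' @export
baseline_dominance <- function(trajectory) {
  stopifnot(inherits(trajectory, "behaviour_trajectory"))
  mean(trajectory$pre$dominance_s[4:6])
}

#' Per-day percent change in dominance
#'
#' Percent change of each post-injury day's dominance duration relative to
#' the scalar pre-injury baseline ([baseline_dominance()]). Negative values
#' are reductions.
#'
#' @inheritParams baseline_dominance
#' @return Numeric length 6; `100 * (post_d - baseline) / baseline`.
#' @export
percent_change_series <- function(trajectory) {
  base <- baseline_dominance(trajectory)
  if (base <= 0) {
    stop("zero baseline dominance: percent change undefined for animal ",
         trajectory$animal_id, call. = FALSE)
  }
  100 * (trajectory$post$dominance_s - base) / base
}

#' Classify an injured animal's disability phenotype
#'
#' Applies the dominance-reduction rule to a post-injury behaviour
#' trajectory. With the default 30 % threshold:
#' \enumerate{
#'   \item a reduction of at least `threshold_pct` on at least 5 of the 6
#'     post-injury days gives `PainDisability` (persistent disability);
#'   \item otherwise, a reduction of at least `threshold_pct` on each of post
#'     days 1-3 together with recovery (reduction below threshold) on both
#'     days 5 and 6 gives `PainTransientDisability`; day 4 is unconstrained,
#'     so both 3- and 4-day transients are accepted;
#'   \item otherwise `PainAlone`.
#' }
#' Rules are evaluated in that order, so a trajectory satisfying both
#' day-count patterns is persistent. Sham animals are labelled at surgery and
#' never pass through this rule. A zero baseline is an error: an animal that
#' never displayed dominance cannot exhibit a 30 % reduction.
#'
#' @inheritParams baseline_dominance
#' @param threshold_pct Reduction threshold in percent (default 30).
#' @return One of `"PainDisability"`, `"PainTransientDisability"`,
#'   `"PainAlone"`.
#' @export
classify_phenotype <- function(trajectory, threshold_pct = 30) {
  stopifnot(is.numeric(threshold_pct), length(threshold_pct) == 1L,
            threshold_pct > 0, threshold_pct < 100)
  pct <- percent_change_series(trajectory)  # errors on zero baseline
  reduced <- pct <= -threshold_pct
  if (sum(reduced) >= 5L) {
    return("PainDisability")
  }
  if (all(reduced[1:3]) && !reduced[5] && !reduced[6]) {
    return("PainTransientDisability")
  }
  "PainAlone"
}

#' Scalar dominance change used for regressions
#'
#' The single per-animal effect size regressed against immune measures:
#' percent change in mean dominance from pre-injury days 4-6 to post-injury
#' days 4-6.
#'
#' @inheritParams baseline_dominance
#' @return Percent change (negative = reduction).
#' @export
dominance_change_scalar <- function(trajectory) {
  base <- baseline_dominance(trajectory)
  if (base <= 0) {
    stop("zero baseline dominance: change undefined for animal ",
         trajectory$animal_id, call. = FALSE)
  }
  100 * (mean(trajectory$post$dominance_s[4:6]) - base) / base
}

#' Withdrawal-threshold reduction relative to baseline
#'
#' @param series A [withdrawal_series()].
#' @return Numeric length 2: mean baseline minus each post-injury session
#'   mean, in grams. Positive values indicate a threshold drop (allodynia).
#' @export
withdrawal_reduction <- function(series) {
  stopifnot(inherits(series, "withdrawal_series"))
  mean(series$baseline_g) - series$post_g
}

#' Classify every injured animal in a behaviour table
#'
#' Applies [classify_phenotype()] to each CCI animal in a long-format
#' behaviour table (schema of [write_cohort()]'s `behaviour.csv`); sham
#' animals keep their preassigned label.
#'
#' @param behaviour Data frame with columns `animal_id`, `group_truth`,
#'   `phase` (`"pre"`/`"post"`), `day`, and the four category duration
#'   columns.
#' @param threshold_pct Passed to [classify_phenotype()].
#' @return Data frame: `animal_id`, `label`, `baseline_s`, `pct_change_d1`
#'   ... `pct_change_d6`.
#' @export
classify_cohort <- function(behaviour, threshold_pct = 30) {
  ids <- unique(behaviour$animal_id)
  rows <- lapply(ids, function(id) {
    sub <- behaviour[behaviour$animal_id == id, , drop = FALSE]
    traj <- trajectory_from_table(sub)
    truth <- unique(sub$group_truth)
    if (identical(truth, "Sham")) {
      data.frame(animal_id = id, label = "Sham",
                 baseline_s = baseline_dominance(traj),
                 t(setNames(rep(NA_real_, 6), paste0("pct_change_d", 1:6))))
    } else {
      data.frame(animal_id = id,
                 label = classify_phenotype(traj, threshold_pct),
                 baseline_s = baseline_dominance(traj),
                 t(setNames(percent_change_series(traj),
                            paste0("pct_change_d", 1:6))))
    }
  })
  do.call(rbind, rows)
}

#' Rebuild a behaviour trajectory from one animal's long-format rows
#'
#' @param sub Rows of a behaviour table (see [classify_cohort()]) belonging
#'   to a single animal.
#' @return A [behaviour_trajectory()].
#' @export
trajectory_from_table <- function(sub) {
  phase_df <- function(phase) {
    p <- sub[sub$phase == phase, , drop = FALSE]
    p <- p[order(p$day), behaviour_categories(), drop = FALSE]
    rownames(p) <- NULL
    p
  }
  behaviour_trajectory(unique(sub$animal_id), phase_df("pre"), phase_df("post"))
}
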