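#' Group summary (mean and SEM)
#'
#' @param values Numeric measurements (>= 1 value).
#' @param group Optional group label carried in the result.
#' @return List of class `group_summary`: `group`, `n`, `mean`, `sem`
#'   (sample SD / sqrt(n); 0 with `sem_defined = FALSE` for a single
#'   value), `censor_state = "none"`.
#' @export
group_summary <- function(values, group = NA_character_) {
  if (!length(values)) stop("empty measurement list", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite measurements", call. = FALSE)
  n <- length(values)
  structure(list(group = group, n = n, mean = mean(values),
                 sem = if (n > 1L) stats::sd(values) / sqrt(n) else 0,
                 sem_defined = n > 1L, censor_state = "none"),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  if (x$censor_state == "above_range") {
    cat(sprintf("%s: >%g (n = %d, above assay range)\n",
                x$group, x$mean, x$n))
  } else if (x$censor_state == "below_range") {
    cat(sprintf("%s: <%g (n = %d, below assay range)\n",
                x$group, x$mean, x$n))
  } else {
    cat(sprintf("%s: %.1f +/- %.1f (n = %d)\n", x$group, x$mean, x$sem, x$n))
  }
  invisible(x)
}

#' Censoring-aware group summary of cytokine measurements
#'
#' A group with any above-range value cannot be summarised numerically: the
#' assay only bounds those concentrations from below, so the group is
#' reported as "> upper limit" and excluded from ANOVA. A group in which
#' every animal fell below the detection limit is reported as
#' "< lower limit". Groups containing both high- and low-censored values
#' indicate an inconsistent panel and raise an error. Otherwise the
#' uncensored values are summarised as in [group_summary()].
#'
#' @param measurements Data frame with columns `conc_pg_ml` and `censor`
#'   (`"none"`, `"high"`, `"low"`), as produced by
#'   [generate_cytokine_panel()].
#' @param limits One row of an assay-range table (`lower`, `upper`).
#' @param group Optional group label.
#' @return A `group_summary`; `censor_state` is one of `"none"`,
#'   `"above_range"`, `"below_range"`.
#' @export
censored_summary <- function(measurements, limits, group = NA_character_) {
  stopifnot(all(c("conc_pg_ml", "censor") %in% names(measurements)))
  cens <- measurements$censor
  if (any(cens == "high") && any(cens == "low")) {
    stop("inconsistent panel: group censored in both directions",
         call. = FALSE)
  }
  n <- nrow(measurements)
  if (any(cens == "high")) {
    return(structure(list(group = group, n = n, mean = limits$upper,
                          sem = NA_real_, sem_defined = FALSE,
                          censor_state = "above_range"),
                     class = "group_summary"))
  }
  if (all(cens == "low")) {
    return(structure(list(group = group, n = n, mean = limits$lower,
                          sem = NA_real_, sem_defined = FALSE,
                          censor_state = "below_range"),
                     class = "group_summary"))
  }
  out <- group_summary(measurements$conc_pg_ml[cens == "none"], group)
  out$n <- sum(cens == "none")
  out
}

#' Sample-size-weighted combined-CCI summary
#'
#' The combined-CCI column of a group x analyte table is the
#' sample-size-weighted mean of the three injury-subgroup means,
#' `sum(n_i * mean_i) / sum(n_i)` with `n = sum(n_i)`. If per-animal raw
#' values are supplied the combined SEM is computed from the pooled raw
#' values; from printed summaries alone it is not recoverable and is
#' reported as NA. Any censored subgroup makes the combined cell censored.
#'
#' @param subgroups List of three `group_summary` objects (the CCI
#'   subgroups).
#' @param raw_values Optional numeric vector of all per-animal values
#'   pooled across the subgroups.
#' @return A `group_summary` for the combined-CCI column.
#' @export
combined_cci_mean <- function(subgroups, raw_values = NULL) {
  stopifnot(length(subgroups) == 3L,
            all(vapply(subgroups, inherits, logical(1), "group_summary")))
  states <- vapply(subgroups, function(s) s$censor_state, character(1))
  n_total <- sum(vapply(subgroups, function(s) s$n, numeric(1)))
  if (any(states != "none")) {
    state <- if (any(states == "above_range")) "above_range" else "below_range"
    lim <- subgroups[[which(states != "none")[1]]]$mean
    return(structure(list(group = "CombinedCCI", n = n_total, mean = lim,
                          sem = NA_real_, sem_defined = FALSE,
                          censor_state = state),
                     class = "group_summary"))
  }
  ns <- vapply(subgroups, function(s) s$n, numeric(1))
  means <- vapply(subgroups, function(s) s$mean, numeric(1))
  if (!is.null(raw_values)) {
    if (length(raw_values) != n_total) {
      stop("raw_values length does not match the pooled subgroup n",
           call. = FALSE)
    }
    sem <- stats::sd(raw_values) / sqrt(n_total)
  } else {
    sem <- NA_real_
  }
  structure(list(group = "CombinedCCI", n = n_total,
                 mean = sum(ns * means) / sum(ns),
                 sem = sem, sem_defined = !is.null(raw_values),
                 censor_state = "none"),
            class = "group_summary")
}

stat_result <- function(statistic, p_raw, family_id = NA_character_,
                        extra = list()) {
  stopifnot(p_raw >= 0, p_raw <= 1)
  c(list(statistic = statistic, p_raw = p_raw, family_id = family_id,
         significant_fdr = NA), extra)
}

#' Omnibus one-way ANOVA
#'
#' Fixed-effects one-way analysis of variance across k groups. Degenerate
#' case: when both between- and within-group variance are zero (all values
#' identical) the test carries no information and F = 0, p = 1 by
#' convention.
#'
#' @param groups Named list of >= 2 numeric vectors, each of length >= 2.
#' @param family_id Correction-family label carried into the result.
#' @return List: `statistic` (F), `p_raw`, `df_between`, `df_within`,
#'   `family_id`, `significant_fdr` (NA until family adjustment).
#' @export
one_way_anova <- function(groups, family_id = NA_character_) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  value <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), times = vapply(groups, length, integer(1))))
  k <- nlevels(g); N <- length(value)
  if (stats::var(value) == 0) {
    return(stat_result(0, 1, family_id,
                       list(df_between = k - 1L, df_within = N - k)))
  }
  tab <- stats::anova(stats::lm(value ~ g))
  stat_result(tab[["F value"]][1], tab[["Pr(>F)"]][1], family_id,
              list(df_between = tab$Df[1], df_within = tab$Df[2]))
}

#' Bonferroni post hoc pairwise comparisons after one-way ANOVA
#'
#' Classic Bonferroni-after-ANOVA contrasts: each pair is tested with a
#' two-sample t statistic using the pooled within-group variance (the
#' omnibus mean-square error) on N - k degrees of freedom, and raw p-values
#' are multiplied by the number of comparisons, capped at 1. A Welch mode
#' (per-pair variances, Satterthwaite df) is available but not the default.
#'
#' @param groups Named list of numeric vectors (the omnibus groups).
#' @param comparisons List of length-2 character vectors naming the pairs
#'   to test; default every group against the first (the sham-vs-each
#'   layout).
#' @param family_id Correction-family label.
#' @param welch Use Welch per-pair variances instead of the pooled MSE.
#' @return Data frame: `group1`, `group2`, `statistic` (t), `df`, `p_raw`,
#'   `p_bonferroni`, `family_id`.
#' @export
bonferroni_posthoc <- function(groups, comparisons = NULL,
                               family_id = NA_character_, welch = FALSE) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  if (is.null(comparisons)) {
    comparisons <- lapply(names(groups)[-1],
                          function(g) c(names(groups)[1], g))
  }
  stopifnot(length(comparisons) >= 1L)
  k_cmp <- length(comparisons)
  ns <- vapply(groups, length, integer(1))
  mse <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1))) /
    (sum(ns) - length(groups))
  rows <- lapply(comparisons, function(pair) {
    if (!all(pair %in% names(groups))) {
      stop("comparison references unknown group: ",
           paste(pair, collapse = " vs "), call. = FALSE)
    }
    x <- groups[[pair[1]]]; y <- groups[[pair[2]]]
    if (welch) {
      tt <- stats::t.test(x, y)
      tstat <- unname(tt$statistic); df <- unname(tt$parameter)
      p <- tt$p.value
    } else {
      se <- sqrt(mse * (1 / length(x) + 1 / length(y)))
      tstat <- (mean(x) - mean(y)) / se
      df <- sum(ns) - length(groups)
      p <- 2 * stats::pt(-abs(tstat), df)
    }
    data.frame(group1 = pair[1], group2 = pair[2], statistic = tstat,
               df = df, p_raw = p,
               p_bonferroni = min(1, k_cmp * p), family_id = family_id)
  })
  do.call(rbind, rows)
}

#' Two-way fixed-effects ANOVA with interaction
#'
#' Analyses the effects of phenotype group and test day (and their
#' interaction) on a behavioural duration. Days are treated as a fixed
#' crossed factor without a repeated-measures covariance structure.
#'
#' @param values Numeric response vector.
#' @param factor_group,factor_day Factors (or coercible) of the same
#'   length as `values`.
#' @param family_id Correction-family label.
#' @return Data frame with rows `group`, `day`, `group:day`: `effect`,
#'   `df`, `statistic` (F), `p_raw`, `family_id`.
#' @export
two_way_anova <- function(values, factor_group, factor_day,
                          family_id = NA_character_) {
  g <- factor(factor_group); d <- factor(factor_day)
  stopifnot(length(values) == length(g), length(values) == length(d))
  if (nlevels(g) < 2L || nlevels(d) < 2L) {
    stop("both factors need at least two levels", call. = FALSE)
  }
  tab <- stats::anova(stats::lm(values ~ g * d))
  data.frame(effect = c("group", "day", "group:day"),
             df = tab$Df[1:3],
             statistic = tab[["F value"]][1:3],
             p_raw = tab[["Pr(>F)"]][1:3],
             family_id = family_id)
}

#' Per-day Bonferroni group contrasts for a two-factor behaviour layout
#'
#' The post hoc layout that accompanies [two_way_anova()] for daily
#' behaviour trajectories: within each day, every requested group pair is
#' tested with a pooled-variance t statistic, and the Bonferroni factor is
#' the total number of (day x pair) comparisons.
#'
#' @inheritParams two_way_anova
#' @param comparisons List of length-2 character vectors of group names;
#'   default all pairs.
#' @return Data frame: `day`, `group1`, `group2`, `statistic`, `df`,
#'   `p_raw`, `p_bonferroni`.
#' @export
per_day_posthoc <- function(values, factor_group, factor_day,
                            comparisons = NULL) {
  g <- factor(factor_group); d <- factor(factor_day)
  if (is.null(comparisons)) {
    comparisons <- utils::combn(levels(g), 2, simplify = FALSE)
  }
  k_cmp <- length(comparisons) * nlevels(d)
  rows <- list()
  for (day in levels(d)) {
    sub_v <- values[d == day]; sub_g <- g[d == day]
    glist <- split(sub_v, droplevels(sub_g))
    ph <- bonferroni_posthoc(glist,
                             comparisons[vapply(comparisons, function(p)
                               all(p %in% names(glist)), logical(1))])
    ph$p_bonferroni <- pmin(1, k_cmp * ph$p_raw)
    ph$day <- day
    rows[[day]] <- ph
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("day", "group1", "group2", "statistic", "df", "p_raw",
          "p_bonferroni")]
}

#' Ordinary least-squares regression of one measure on another
#'
#' Used for per-animal relationships such as nerve T-lymphocyte density
#' against the percent change in dominance behaviour.
#'
#' @param x,y Numeric vectors of equal length >= 3; `x` must not be
#'   constant.
#' @param family_id Correction-family label.
#' @return List: `slope`, `intercept`, `r_squared`, `statistic` (t for the
#'   slope), `p_raw`, `n`, `family_id`.
#' @export
linear_regression <- function(x, y, family_id = NA_character_) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::var(x) == 0) stop("constant x: slope undefined", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       statistic = sm$coefficients[2, "t value"],
       p_raw = sm$coefficients[2, "Pr(>|t|)"],
       n = length(x), family_id = family_id)
}

#' Benjamini-Hochberg step-up rejection flags for one family
#'
#' Implements the step-up rule on one correction family (tests sharing the
#' same biological material): sort the m raw p-values ascending, find the
#' largest i with `p(i) <= (i / m) * q`, and reject hypotheses 1..i. False
#' discovery rate is controlled at level `q`.
#'
#' @param p_values Raw p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return Logical vector in the original order: TRUE = rejected
#'   (significant after correction).
#' @export
bh_adjust <- function(p_values, q = 0.05) {
  if (!length(p_values)) stop("empty p-value family", call. = FALSE)
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(q > 0, q < 1)
  m <- length(p_values)
  ord <- order(p_values)
  sorted <- p_values[ord]
  passing <- which(sorted <= (seq_len(m) / m) * q)
  reject <- logical(m)
  if (length(passing)) reject[ord[seq_len(max(passing))]] <- TRUE
  reject
}

#' Apply BH correction family-wise to a results table
#'
#' @param results Data frame with columns `p_raw` and `family_id`.
#' @param q FDR level.
#' @return `results` with a logical `significant_fdr` column, corrected
#'   within each family.
#' @export
adjust_families <- function(results, q = 0.05) {
  stopifnot(all(c("p_raw", "family_id") %in% names(results)))
  results$significant_fdr <- NA
  for (fam in unique(results$family_id)) {
    idx <- which(results$family_id == fam & !is.na(results$p_raw))
    if (length(idx)) {
      results$significant_fdr[idx] <- bh_adjust(results$p_raw[idx], q)
    }
  }
  results
}
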