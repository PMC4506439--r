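#' Phenotype labels
#'
#' The four post-surgery phenotype labels used throughout the package. Sham
#' animals are labelled at surgery and bypass behavioural classification; the
#' three constriction-injury (CCI) phenotypes are assigned from the
#' dominance-behaviour rule in [classify_phenotype()].
#'
#' @return Character vector of the four valid labels.
#' @export
phenotype_levels <- function() {
  c("Sham", "PainAlone", "PainTransientDisability", "PainDisability")
}

#' @rdname phenotype_levels
#' @export
cci_levels <- function() {
  c("PainAlone", "PainTransientDisability", "PainDisability")
}

assert_phenotype <- function(label, allow_sham = TRUE) {
  levels <- if (allow_sham) phenotype_levels() else cci_levels()
  if (!(is.character(label) && length(label) == 1L && label %in% levels)) {
    stop("invalid phenotype label: ", paste(label, collapse = ", "),
         " (expected one of ", paste(levels, collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(label)
}

behaviour_categories <- function() {
  c("dominance_s", "social_s", "nonsocial_s", "submissive_s")
}

#' Construct a behaviour trajectory
#'
#' A behaviour trajectory holds the per-day durations (seconds) of the four
#' mutually exclusive resident-intruder behaviour categories over six
#' pre-injury and six post-injury test days. Each daily test lasts 6 minutes,
#' so category durations must sum to at most 360 s on any day.
#'
#' @param animal_id Identifier for the animal.
#' @param pre,post Data frames with 6 rows (days 1-6) and columns
#'   `dominance_s`, `social_s`, `nonsocial_s`, `submissive_s`.
#' @return An object of class `behaviour_trajectory`.
#' @export
behaviour_trajectory <- function(animal_id, pre, post) {
  for (phase in list(pre = pre, post = post)) NULL
  check_phase <- function(df, what) {
    if (!is.data.frame(df) || nrow(df) != 6L) {
      stop(what, " phase must contain exactly 6 days", call. = FALSE)
    }
    missing <- setdiff(behaviour_categories(), names(df))
    if (length(missing)) {
      stop(what, " phase missing categories: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    m <- as.matrix(df[behaviour_categories()])
    if (any(!is.finite(m)) || any(m < 0)) {
      stop(what, " phase durations must be finite and non-negative",
           call. = FALSE)
    }
    if (any(rowSums(m) > 360 + 1e-9)) {
      stop(what, " phase daily durations exceed the 360 s test length",
           call. = FALSE)
    }
    df[behaviour_categories()]
  }
  structure(
    list(animal_id = animal_id,
         pre = check_phase(pre, "pre"),
         post = check_phase(post, "post")),
    class = "behaviour_trajectory"
  )
}

#' @export
print.behaviour_trajectory <- function(x, ...) {
  cat("behaviour_trajectory for animal", x$animal_id, "\n")
  cat("  pre  dominance (s):", round(x$pre$dominance_s, 1), "\n")
  cat("  post dominance (s):", round(x$post$dominance_s, 1), "\n")
  invisible(x)
}

#' Construct a withdrawal-threshold series
#'
#' Mechanical (von Frey) withdrawal thresholds in grams: three pre-injury
#' baseline session means and two post-injury session means (days 2/3 and
#' 4/5), each the mean of five trials.
#'
#' @param baseline_g Numeric length 3, baseline session means (grams).
#' @param post_g Numeric length 2, post-injury session means (grams).
#' @return An object of class `withdrawal_series`.
#' @export
withdrawal_series <- function(baseline_g, post_g) {
  if (length(baseline_g) != 3L || length(post_g) != 2L) {
    stop("need 3 baseline and 2 post-injury threshold means", call. = FALSE)
  }
  if (any(!is.finite(c(baseline_g, post_g))) || any(c(baseline_g, post_g) <= 0)) {
    stop("withdrawal thresholds must be positive", call. = FALSE)
  }
  structure(list(baseline_g = as.numeric(baseline_g),
                 post_g = as.numeric(post_g)),
            class = "withdrawal_series")
}
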