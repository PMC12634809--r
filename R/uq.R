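#' Ensemble mean prediction
#'
#' The patient-level AI prediction is the arithmetic mean of the submodel
#' likelihoods.
#'
#' @param scores Numeric vector of submodel likelihoods in \[0, 1\].
#' @return The mean prediction, in \[0, 1\].
#' @export
ensemble_mean <- function(scores) {
  check_scores(scores, min_n = 1L)
  mean(scores)
}

#' meanUQ: certainty as distance of the mean prediction from 0.5
#'
#' `meanUQ = |mean(scores) - 0.5|`. Mean predictions near 0 or 1 are certain
#' (benign / csPCa respectively) and mean predictions near 0.5 are uncertain,
#' so *higher* meanUQ means *more* certain.
#'
#' @inheritParams ensemble_mean
#' @return meanUQ in \[0, 0.5\].
#' @export
mean_uq <- function(scores) {
  abs(ensemble_mean(scores) - 0.5)
}

#' varUQ: certainty as ensemble dispersion
#'
#' `varUQ` is the standard deviation of the submodel likelihoods; disagreeing
#' submodels produce a high varUQ, so *lower* varUQ means *more* certain. The
#' population divisor (n) is the default because the submodels are the entire
#' ensemble, not a sample from a larger one; the sample divisor (n - 1) is
#' available for comparison.
#'
#' @inheritParams ensemble_mean
#' @param divisor `"population"` (divide by n, default) or `"sample"`
#'   (divide by n - 1).
#' @return varUQ, a non-negative number (at most 0.5 for scores in \[0, 1\]
#'   under the population divisor).
#' @export
var_uq <- function(scores, divisor = c("population", "sample")) {
  divisor <- match.arg(divisor)
  check_scores(scores, min_n = 2L)
  n <- length(scores)
  ss <- sum((scores - mean(scores))^2)
  sqrt(ss / if (divisor == "population") n else n - 1L)
}

check_scores <- function(scores, min_n) {
  if (!is.numeric(scores) || length(scores) < min_n) {
    stop(sprintf("scores must be a numeric vector of length >= %d", min_n),
         call. = FALSE)
  }
  if (anyNA(scores) || any(scores < 0 | scores > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  invisible(scores)
}

#' Summarize the ensemble of every visit in a cohort
#'
#' Appends the per-visit ensemble summary columns `mean_pred`, `mean_uq` and
#' `var_uq` to a cohort data frame.
#'
#' @param cohort A cohort data frame (see [generate_cohort()]).
#' @param divisor Passed to [var_uq()].
#' @return The cohort with the three summary columns added.
#' @export
add_ensemble_summary <- function(cohort, divisor = "population") {
  sc <- cohort_score_cols(cohort)
  if (length(sc) < 2L) stop("cohort must have at least 2 score columns", call. = FALSE)
  m <- as.matrix(cohort[, sc, drop = FALSE])
  if (nrow(m) > 0 && (anyNA(m) || any(m < 0 | m > 1))) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  mu <- rowMeans(m)
  n <- ncol(m)
  ss <- rowSums((m - mu)^2)
  cohort$mean_pred <- mu
  cohort$mean_uq <- abs(mu - 0.5)
  cohort$var_uq <- sqrt(ss / if (divisor == "population") n else n - 1L)
  cohort
}

#' Orientation-aware certainty comparison
#'
#' Both uncertainty metrics are compared to a threshold through this single
#' comparator so the orientation (meanUQ: higher = more certain; varUQ: lower =
#' more certain) lives in one place. Certainty is inclusive of the threshold.
#'
#' @param uq Numeric vector of metric values.
#' @param metric `"meanUQ"` or `"varUQ"`.
#' @param tau Threshold.
#' @return Logical vector: `TRUE` where the case is certain at `tau`.
#' @export
is_certain <- function(uq, metric = c("meanUQ", "varUQ"), tau) {
  metric <- match.arg(metric)
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau)) {
    stop("tau must be a single finite number", call. = FALSE)
  }
  if (metric == "meanUQ") uq >= tau else uq <= tau
}

# Certainty key: a vector that is larger for more certain cases, whatever the
# metric, used for ranking.
certainty_key <- function(uq, metric) {
  if (metric == "meanUQ") uq else -uq
}

uq_column <- function(metric) {
  switch(metric, meanUQ = "mean_uq", varUQ = "var_uq",
         stop("unknown metric: ", metric, call. = FALSE))
}
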