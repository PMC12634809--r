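#' Triage visits by an uncertainty threshold
#'
#' Flags as certain every visit whose uncertainty metric is on the certain side
#' of `tau` (meanUQ: `>= tau`; varUQ: `<= tau`). Certain visits are read
#' autonomously by the AI; uncertain visits are referred to the radiologist.
#'
#' @param cohort A cohort data frame carrying ensemble summaries (see
#'   [add_ensemble_summary()]).
#' @param metric `"meanUQ"` or `"varUQ"`.
#' @param tau Finite threshold on the metric.
#' @return Logical vector of certainty flags, aligned with `cohort` rows.
#' @export
triage_by_threshold <- function(cohort, metric = c("meanUQ", "varUQ"), tau) {
  metric <- match.arg(metric)
  is_certain(cohort[[uq_column(metric)]], metric, tau)
}

#' Triage a fixed fraction of visits to autonomous AI reading
#'
#' Ranks visits from most to least certain under the metric and flags the top
#' `floor(fraction * n)` as certain, so the autonomous share never exceeds the
#' requested fraction. Ties in the metric are broken by `visit_id` (stable,
#' platform-independent). Returns the implied metric threshold alongside the
#' flags.
#'
#' @inheritParams triage_by_threshold
#' @param fraction Fraction of visits to rule out, in \[0, 1\].
#' @return A list with `tau` (the metric value of the least certain flagged
#'   visit; `NA` when no visit is flagged) and `certain` (logical flags aligned
#'   with `cohort`).
#' @export
triage_by_fraction <- function(cohort, metric = c("meanUQ", "varUQ"), fraction) {
  metric <- match.arg(metric)
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction > 1) {
    stop("fraction must be a number in [0, 1]", call. = FALSE)
  }
  n <- nrow(cohort)
  k <- floor(fraction * n)
  uq <- cohort[[uq_column(metric)]]
  ord <- order(-certainty_key(uq, metric), cohort$visit_id)
  certain <- logical(n)
  if (k > 0) certain[ord[seq_len(k)]] <- TRUE
  tau <- if (k > 0) uq[ord[k]] else NA_real_
  list(tau = tau, certain = certain)
}

#' Combined pathway diagnosis
#'
#' Certain visits receive the autonomous AI diagnosis (mean ensemble prediction
#' at or above `ai_threshold`); uncertain visits receive the radiologist's
#' clinical-practice call (PI-RADS >= 4).
#'
#' @inheritParams triage_by_threshold
#' @param certain Logical certainty flags aligned with `cohort` rows.
#' @param ai_threshold Operating threshold on the mean ensemble prediction for
#'   the autonomous AI call.
#' @return A data frame with one row per visit: `visit_id`, `certain`,
#'   `reader` (`"AI"` or `"radiologist"`) and `diagnosis` (0/1).
#' @export
combined_diagnosis <- function(cohort, certain, ai_threshold) {
  if (!is.logical(certain) || length(certain) != nrow(cohort) || anyNA(certain)) {
    stop("certain must be a complete logical vector aligned with the cohort",
         call. = FALSE)
  }
  diagnosis <- ifelse(certain, as.integer(cohort$mean_pred >= ai_threshold),
                      as.integer(cohort$pirads >= 4))
  data.frame(
    visit_id = cohort$visit_id,
    certain = certain,
    reader = ifelse(certain, "AI", "radiologist"),
    diagnosis = as.integer(diagnosis),
    stringsAsFactors = FALSE
  )
}

#' Pathway confusion counts, accuracy and workload
#'
#' Confusion counts are taken over all visits regardless of reader; the
#' radiologist workload is the fraction of visits the radiologist still reads.
#' A rate whose denominator is empty (no positives, or no negatives) is
#' reported as `NA`, never coerced to 0.
#'
#' @param diagnosis Integer/logical vector of final pathway diagnoses (1 =
#'   csPCa call).
#' @param truth Ground-truth labels aligned with `diagnosis`.
#' @param certain Logical certainty flags (used for the workload accounting).
#' @return A one-row data frame: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `n_certain`, `n_total`, `workload_radiologist`.
#' @export
pathway_metrics <- function(diagnosis, truth, certain = logical(length(truth))) {
  if (length(diagnosis) == 0L) stop("empty pathway", call. = FALSE)
  if (length(truth) != length(diagnosis) || length(certain) != length(diagnosis)) {
    stop("diagnosis, truth and certain must be aligned", call. = FALSE)
  }
  d <- as.integer(diagnosis)
  t <- as.integer(truth)
  tp <- sum(d == 1L & t == 1L)
  fp <- sum(d == 1L & t == 0L)
  tn <- sum(d == 0L & t == 0L)
  fn <- sum(d == 0L & t == 1L)
  n <- length(d)
  data.frame(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    n_certain = sum(certain),
    n_total = n,
    workload_radiologist = 1 - sum(certain) / n
  )
}

#' Calibrate the autonomous AI threshold to a specificity target
#'
#' The combined-pathway specificity (AI on certain visits, radiologist on
#' uncertain visits) is a non-decreasing step function of the AI threshold.
#' The calibrator scans every achievable operating point — midpoints between
#' sorted unique mean predictions of the certain visits, with -Inf/+Inf
#' sentinels — and returns the smallest threshold whose combined specificity
#' reaches the target; being the smallest such threshold, it maximizes
#' sensitivity subject to the specificity constraint. The target is typically
#' the radiologist's specificity minus a non-inferiority margin (0.05 or 0.10).
#'
#' @inheritParams combined_diagnosis
#' @param target_specificity Required combined specificity, in (0, 1).
#' @return A list: `ai_threshold`, `achieved_specificity`, `sensitivity`,
#'   `attainable` (logical). When the target is unattainable even with the AI
#'   calling every certain visit negative, `attainable` is `FALSE` and
#'   `achieved_specificity` is the maximum achievable value.
#' @export
calibrate_ai_threshold <- function(cohort, certain, target_specificity) {
  if (!is.numeric(target_specificity) || length(target_specificity) != 1L ||
      target_specificity <= 0 || target_specificity >= 1) {
    stop("target_specificity must be in (0, 1)", call. = FALSE)
  }
  if (sum(cohort$truth == 0L) == 0L) {
    stop("cohort has no negative cases; specificity undefined", call. = FALSE)
  }
  cand <- threshold_candidates(cohort$mean_pred[certain])
  best <- NULL
  for (tau in cand) {
    res <- combined_diagnosis(cohort, certain, tau)
    pm <- pathway_metrics(res$diagnosis, cohort$truth, certain)
    if (is.null(best) || pm$specificity > best$achieved_specificity) {
      best <- list(ai_threshold = tau, achieved_specificity = pm$specificity,
                   sensitivity = pm$sensitivity, attainable = FALSE)
    }
    if (pm$specificity >= target_specificity) {
      return(list(ai_threshold = tau, achieved_specificity = pm$specificity,
                  sensitivity = pm$sensitivity, attainable = TRUE))
    }
  }
  best
}

# Candidate cut points visiting every achievable confusion table exactly once:
# midpoints between adjacent sorted unique values, with sentinels below and
# above the data. Mean predictions live in [0, 1], so 0 serves as the lower
# sentinel (every case called positive).
threshold_candidates <- function(values) {
  u <- sort(unique(values))
  if (length(u) == 0L) return(c(0, Inf))
  c(0, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2, Inf)
}
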