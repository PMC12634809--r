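#' Area under the ROC curve
#'
#' Mann-Whitney estimator with half credit for ties: the probability that a
#' random positive case scores above a random negative case, counting ties as
#' 1/2. Equals the trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param truth 0/1 labels aligned with `scores`.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, truth) {
  check_two_classes(truth)
  t <- as.integer(truth)
  r <- rank(scores)
  n1 <- sum(t == 1L)
  n0 <- sum(t == 0L)
  (sum(r[t == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' One operating point per achievable confusion table (candidate thresholds at
#' midpoints of sorted unique scores plus infinite sentinels, positive call at
#' `score >= threshold`), ordered by descending threshold.
#'
#' @inheritParams auroc
#' @return A list with `thresholds` (descending), `sensitivities`,
#'   `specificities` and `auroc`.
#' @export
roc_curve <- function(scores, truth) {
  check_two_classes(truth)
  t <- as.integer(truth)
  cand <- rev(score_candidates(scores))
  n1 <- sum(t == 1L)
  n0 <- sum(t == 0L)
  sens <- vapply(cand, function(tau) sum(scores >= tau & t == 1L) / n1, numeric(1))
  spec <- vapply(cand, function(tau) sum(scores < tau & t == 0L) / n0, numeric(1))
  list(thresholds = cand, sensitivities = sens, specificities = spec,
       auroc = auroc(scores, truth))
}

score_candidates <- function(scores) {
  u <- sort(unique(scores))
  c(-Inf, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2, Inf)
}

check_two_classes <- function(truth) {
  t <- as.integer(truth)
  if (anyNA(t) || !all(t %in% c(0L, 1L))) {
    stop("truth must be 0/1 with no missing values", call. = FALSE)
  }
  if (sum(t == 1L) == 0L || sum(t == 0L) == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  invisible(t)
}

#' Youden-index threshold
#'
#' Scans every achievable cut point (midpoints of sorted unique scores with
#' infinite sentinels; positive call at `score >= tau`) and returns the
#' threshold maximizing Youden's J = sensitivity + specificity - 1. Ties in J
#' are broken toward higher specificity (the larger threshold); exact ties in
#' both go to the first such candidate.
#'
#' @inheritParams auroc
#' @return A list with `tau` and `J`.
#' @export
youden_threshold <- function(scores, truth) {
  t <- check_two_classes(truth)
  n1 <- sum(t == 1L)
  n0 <- sum(t == 0L)
  cand <- score_candidates(scores)
  # cumulative class counts strictly below each candidate, in candidate order
  idx <- order(scores)
  s <- scores[idx]
  tt <- t[idx]
  last <- which(c(diff(s) != 0, TRUE))  # last index of each unique value
  cpos <- cumsum(tt == 1L)[last]
  below_pos <- c(0, cpos)
  below_neg <- c(0, last - cpos)
  sens <- (n1 - below_pos) / n1
  spec <- below_neg / n0
  J <- sens + spec - 1
  top <- which(J >= max(J) - 1e-12)
  best_spec <- max(spec[top])
  i <- top[spec[top] >= best_spec - 1e-12][1L]
  list(tau = cand[i], J = J[i])
}

#' Youden-style rule-out threshold on an uncertainty metric
#'
#' Selects the rule-out threshold on an uncertainty metric by Youden's index.
#' An uncertainty threshold is not itself a classifier, so Youden's J does not
#' apply to it directly; which classifier's sensitivity and specificity enter
#' J is a genuine design choice, and two concretizations are provided behind
#' a strategy switch:
#'
#' * `"subset_youden"` (default): for each observed metric value taken as a
#'   candidate threshold (inclusive, orientation per the metric), the mean
#'   ensemble prediction is evaluated on the resulting certain subset at its
#'   own Youden-optimal cut, and the candidate maximizing that subset's J is
#'   returned — the threshold whose ruled-out cases the AI discriminates best.
#'   Ties in J are broken toward the larger certain subset (more autonomous
#'   reading). Candidates whose certain subset lacks a class are skipped; if
#'   no candidate subset contains both classes, an error is raised.
#' * `"error_youden"`: the metric's certainty score is treated as a predictor
#'   of whether the AI's own diagnosis (mean prediction at its full-cohort
#'   Youden cut) is correct, and the rule-out threshold is the Youden-optimal
#'   cut of that correctness ROC — certain cases are those the AI is predicted
#'   to get right.
#'
#' @inheritParams triage_by_threshold
#' @param strategy Concretization of the Youden rule (see Details).
#' @return A list with `tau`, `J` (the Youden index the strategy maximized)
#'   and `n_certain` (certain cases at `tau`).
#' @export
youden_uq_threshold <- function(cohort, metric = c("meanUQ", "varUQ"),
                                strategy = c("subset_youden", "error_youden")) {
  metric <- match.arg(metric)
  strategy <- match.arg(strategy)
  uq <- cohort[[uq_column(metric)]]
  if (strategy == "error_youden") {
    ai_cut <- youden_threshold(cohort$mean_pred, cohort$truth)$tau
    correct <- as.integer((cohort$mean_pred >= ai_cut) == (cohort$truth == 1L))
    if (all(correct == 1L)) {  # AI never errs: every case is certain
      return(list(tau = if (metric == "meanUQ") 0 else max(uq),
                  J = 0, n_certain = nrow(cohort)))
    }
    if (all(correct == 0L)) {
      stop("AI diagnosis incorrect on every case; no certain subset", call. = FALSE)
    }
    key <- certainty_key(uq, metric)
    yt <- youden_threshold(key, correct)
    tau <- if (metric == "meanUQ") yt$tau else -yt$tau
    certain <- is_certain(uq, metric, tau)
    return(list(tau = tau, J = yt$J, n_certain = sum(certain)))
  }
  cand <- sort(unique(uq))
  best <- NULL
  for (tau in cand) {
    certain <- is_certain(uq, metric, tau)
    t_sub <- cohort$truth[certain]
    if (sum(t_sub == 1L) == 0L || sum(t_sub == 0L) == 0L) next
    J <- youden_threshold(cohort$mean_pred[certain], t_sub)$J
    n_c <- sum(certain)
    if (is.null(best) || J > best$J + 1e-12 ||
        (abs(J - best$J) <= 1e-12 && n_c > best$n_certain)) {
      best <- list(tau = tau, J = J, n_certain = n_c)
    }
  }
  if (is.null(best)) {
    stop("no uncertainty threshold yields a certain subset with both classes",
         call. = FALSE)
  }
  best
}

# DeLong structural components via midranks. For positives X (m) and negatives
# Y (n), V10_i = mean_j psi(X_i, Y_j) and V01_j = mean_i psi(X_i, Y_j) with
# psi = 1, 1/2, 0 for X > Y, X == Y, X < Y.
delong_components <- function(scores, truth) {
  t <- as.integer(truth)
  x <- scores[t == 1L]
  y <- scores[t == 0L]
  m <- length(x)
  n <- length(y)
  r_all <- rank(c(x, y))
  r_x <- rank(x)
  r_y <- rank(y)
  v10 <- (r_all[seq_len(m)] - r_x) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m
  list(v10 = v10, v01 = v01, theta = mean(v10), m = m, n = n)
}

#' DeLong test comparing two AUROCs
#'
#' Nonparametric comparison of two AUROC estimates using the DeLong (1988)
#' structural-components estimator of their variances and covariance, with a
#' two-sided normal test on the AUROC difference. In paired mode both score
#' vectors are evaluated on the same cases and the covariance between the
#' curves is estimated from the components; in unpaired mode (e.g., two
#' different certain-case subsets) each AUROC has its own case set and the
#' covariance term is zero.
#'
#' @param scores_a,scores_b Score vectors for the two classifiers.
#' @param truth 0/1 labels for `scores_a` (and for `scores_b` when paired).
#' @param truth_b Labels for `scores_b` in unpaired mode; defaults to `truth`.
#' @param paired Logical; paired mode requires `scores_a` and `scores_b` on an
#'   identical case set.
#' @return A list of class `uqtriage_test`: `statistic` (z), `p_value`,
#'   `estimate` (AUROC difference a - b), `auroc_a`, `auroc_b`, `method`.
#' @references DeLong ER, DeLong DM, Clarke-Pearson DL (1988). Comparing the
#'   areas under two or more correlated receiver operating characteristic
#'   curves: a nonparametric approach. Biometrics 44:837-845.
#' @export
delong_test <- function(scores_a, scores_b, truth, truth_b = NULL,
                        paired = TRUE) {
  check_two_classes(truth)
  if (paired) {
    if (!is.null(truth_b) && !identical(as.integer(truth_b), as.integer(truth))) {
      stop("paired mode requires identical case sets", call. = FALSE)
    }
    if (length(scores_a) != length(scores_b) ||
        length(scores_a) != length(truth)) {
      stop("paired mode requires identical case sets", call. = FALSE)
    }
    ca <- delong_components(scores_a, truth)
    cb <- delong_components(scores_b, truth)
    s10 <- cov0(cbind(ca$v10, cb$v10))
    s01 <- cov0(cbind(ca$v01, cb$v01))
    var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / ca$m +
      (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / ca$n
  } else {
    if (is.null(truth_b)) truth_b <- truth
    check_two_classes(truth_b)
    if (length(scores_b) != length(truth_b)) {
      stop("scores_b and truth_b must be aligned", call. = FALSE)
    }
    ca <- delong_components(scores_a, truth)
    cb <- delong_components(scores_b, truth_b)
    var_diff <- var0(ca$v10) / ca$m + var0(ca$v01) / ca$n +
      var0(cb$v10) / cb$m + var0(cb$v01) / cb$n
  }
  diff <- ca$theta - cb$theta
  if (var_diff <= 0) {
    z <- if (abs(diff) < 1e-15) 0 else sign(diff) * Inf
  } else {
    z <- diff / sqrt(var_diff)
  }
  p <- 2 * stats::pnorm(-abs(z))
  structure(
    list(statistic = z, p_value = p, estimate = diff,
         auroc_a = ca$theta, auroc_b = cb$theta,
         method = if (paired) "DeLong (paired)" else "DeLong (unpaired)",
         n_resamples = NA_integer_),
    class = "uqtriage_test"
  )
}

# Sample variance/covariance with the convention that a single observation
# contributes no variance (a degenerate, not missing, component).
var0 <- function(x) if (length(x) < 2L) 0 else stats::var(x)
cov0 <- function(m) if (nrow(m) < 2L) matrix(0, 2, 2) else stats::cov(m)

#' Variance of a single AUROC by DeLong's estimator
#'
#' @inheritParams auroc
#' @return The estimated variance of the Mann-Whitney AUROC.
#' @export
delong_variance <- function(scores, truth) {
  check_two_classes(truth)
  cc <- delong_components(scores, truth)
  var0(cc$v10) / cc$m + var0(cc$v01) / cc$n
}

#' Patient-level permutation test for a sensitivity difference
#'
#' Tests whether the rule-out pathway's sensitivity differs from the
#' radiologist's, with the patient as the resampling unit: under the null the
#' two diagnosis sources are exchangeable within a patient, so each null
#' replicate swaps, per patient (all of that patient's visits together), the
#' pathway and radiologist diagnoses with probability 1/2 and recomputes the
#' sensitivity difference. The p-value uses the add-one estimator
#' `(1 + #extreme) / (1 + n_perm)`, so it is never exactly zero. The default
#' alternative is one-sided (`pathway sensitivity greater`), matching a
#' superiority question at a non-inferior specificity; a two-sided p-value is
#' available.
#'
#' @param pathway_diag,radiologist_diag 0/1 diagnosis vectors, aligned per
#'   visit.
#' @param truth 0/1 ground truth per visit.
#' @param patient_ids Patient identifier per visit; visits sharing an id are
#'   permuted together.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed for the permutation stream.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A list of class `uqtriage_test`: `statistic` (observed sensitivity
#'   difference, pathway - radiologist), `p_value`, `method`, `n_resamples`.
#' @export
permutation_sensitivity_test <- function(pathway_diag, radiologist_diag, truth,
                                         patient_ids, n_perm = 10000L,
                                         seed = 1L,
                                         alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- length(truth)
  if (length(pathway_diag) != n || length(radiologist_diag) != n ||
      length(patient_ids) != n) {
    stop("all inputs must be aligned per visit", call. = FALSE)
  }
  if (!is.numeric(n_perm) || n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  pos <- as.integer(truth) == 1L
  n_pos <- sum(pos)
  if (n_pos == 0L) stop("no positive cases; sensitivity undefined", call. = FALSE)

  # Only positive visits contribute to sensitivity; aggregate the per-visit
  # difference by patient, since all of a patient's visits swap together.
  delta <- (as.integer(pathway_diag) - as.integer(radiologist_diag))[pos]
  pat <- as.character(patient_ids)[pos]
  delta_pat <- tapply(delta, pat, sum)
  observed <- sum(delta_pat) / n_pos

  n_pat <- length(delta_pat)
  null_stats <- with_local_seed(seed, {
    signs <- matrix(ifelse(stats::runif(n_pat * n_perm) < 0.5, 1, -1),
                    nrow = n_pat, ncol = n_perm)
    as.numeric(crossprod(signs, as.numeric(delta_pat))) / n_pos
  })
  eps <- 1e-12
  p <- if (alternative == "greater") {
    (1 + sum(null_stats >= observed - eps)) / (1 + n_perm)
  } else {
    (1 + sum(abs(null_stats) >= abs(observed) - eps)) / (1 + n_perm)
  }
  structure(
    list(statistic = observed, p_value = p,
         method = sprintf("patient-level permutation (%s)", alternative),
         n_resamples = as.integer(n_perm)),
    class = "uqtriage_test"
  )
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Share of varUQ-certain cases also certain under meanUQ
#'
#' @param flags_var,flags_mean Aligned logical certainty flags for the two
#'   metrics.
#' @return `|varUQ-certain and meanUQ-certain| / |varUQ-certain|`.
#' @export
overlap_share <- function(flags_var, flags_mean) {
  if (length(flags_var) != length(flags_mean)) {
    stop("flag vectors must be aligned", call. = FALSE)
  }
  if (sum(flags_var) == 0L) {
    stop("no varUQ-certain cases; overlap undefined", call. = FALSE)
  }
  sum(flags_var & flags_mean) / sum(flags_var)
}

#' @export
print.uqtriage_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.4g, p = %.4g\n", x$statistic, x$p_value))
  if (!is.na(x$n_resamples)) cat("  resamples =", x$n_resamples, "\n")
  invisible(x)
}
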