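# Builders for small in-memory cohorts used across the test files.

# A cohort data frame with ensemble summary columns set directly; the score
# columns are filled with a constant vector per row reproducing mean_pred so
# the frame still passes the schema.
make_summary_cohort <- function(mean_pred, var_uq, truth, pirads,
                                center_id = "X",
                                visit_id = sprintf("V%03d", seq_along(mean_pred)),
                                patient_id = sprintf("P%03d", seq_along(mean_pred))) {
  n <- length(mean_pred)
  df <- data.frame(
    patient_id = patient_id, visit_id = visit_id, center_id = center_id,
    truth = as.integer(truth), pirads = as.integer(pirads),
    score_01 = mean_pred, score_02 = mean_pred,
    stringsAsFactors = FALSE
  )
  df$mean_pred <- mean_pred
  df$mean_uq <- abs(mean_pred - 0.5)
  df$var_uq <- var_uq
  df
}

# Independent two-pass population standard deviation (oracle for var_uq).
oracle_pop_sd <- function(x) {
  m <- 0
  for (v in x) m <- m + v
  m <- m / length(x)
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  sqrt(ss / length(x))
}

# O(n^2) pairwise Mann-Whitney AUROC oracle with half credit for ties.
oracle_auroc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  total <- 0
  for (x in pos) {
    for (y in neg) {
      total <- total + if (x > y) 1 else if (x == y) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Exhaustive Youden oracle: evaluates J on a dense grid of cut points built
# from the data (all midpoints plus sentinels), independent of the package's
# candidate machinery.
oracle_youden <- function(scores, truth) {
  u <- sort(unique(scores))
  cand <- c(min(u) - 1, if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2,
            max(u) + 1)
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  best <- list(J = -Inf, spec = -Inf, tau = NA)
  for (tau in cand) {
    sens <- sum(scores >= tau & truth == 1) / n1
    spec <- sum(scores < tau & truth == 0) / n0
    J <- sens + spec - 1
    if (J > best$J + 1e-12 || (abs(J - best$J) <= 1e-12 && spec > best$spec + 1e-12)) {
      best <- list(J = J, spec = spec, tau = tau)
    }
  }
  best
}

# Direct (double-loop) DeLong structural components.
oracle_delong_components <- function(scores, truth) {
  x <- scores[truth == 1]
  y <- scores[truth == 0]
  m <- length(x)
  n <- length(y)
  psi <- function(a, b) if (a > b) 1 else if (a == b) 0.5 else 0
  v10 <- numeric(m)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) v10[i] <- v10[i] + psi(x[i], y[j])
  }
  v10 <- v10 / n
  v01 <- numeric(n)
  for (j in seq_len(n)) {
    for (i in seq_len(m)) v01[j] <- v01[j] + psi(x[i], y[j])
  }
  v01 <- v01 / m
  list(v10 = v10, v01 = v01, m = m, n = n)
}

# 99% binomial CI check: is the empirical proportion consistent with p?
within_binom_ci99 <- function(k, n, p) {
  half <- stats::qnorm(0.995) * sqrt(p * (1 - p) / n)
  abs(k / n - p) <= half
}
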