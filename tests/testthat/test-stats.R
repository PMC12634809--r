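test_that("AUROC matches the pairwise Mann-Whitney oracle, ties included", {
  expect_equal(auroc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(auroc(rep(0.4, 8), rep(c(0, 1), 4)), 0.5)
  expect_error(auroc(1:4, rep(1, 4)), "both classes")
  set.seed(7)
  for (i in 1:10) {
    n <- 20
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    t <- c(rep(1, 8), rep(0, 12))
    expect_equal(auroc(s, t), oracle_auroc(s, t), tolerance = 1e-12)
  }
  # complement invariant for tie-free scores
  set.seed(8)
  s <- runif(30)
  t <- rbinom(30, 1, 0.5)
  if (length(unique(t)) == 2) expect_equal(auroc(s, t) + auroc(-s, t), 1)
})

test_that("roc_curve is a proper staircase whose area is the AUROC", {
  set.seed(12)
  s <- runif(40)
  t <- rbinom(40, 1, 0.4)
  rc <- roc_curve(s, t)
  expect_true(all(diff(rc$thresholds) <= 0))
  expect_true(all(diff(rc$sensitivities) >= 0))
  # trapezoidal area over (1 - specificity, sensitivity) equals the estimate
  fpr <- 1 - rc$specificities
  area <- sum(diff(fpr) * (head(rc$sensitivities, -1) + tail(rc$sensitivities, -1)) / 2)
  expect_equal(area, rc$auroc, tolerance = 1e-12)
})

test_that("Youden threshold matches the exhaustive cut-point oracle", {
  # separable scores: J = 1 at the gap midpoint
  yt <- youden_threshold(c(1, 2, 3, 7, 8, 9), c(0, 0, 0, 1, 1, 1))
  expect_equal(yt$J, 1)
  expect_equal(yt$tau, 5)
  # uninformative scores: J = 0
  expect_equal(youden_threshold(rep(2, 6), c(0, 0, 0, 1, 1, 1))$J, 0)
  set.seed(30)
  for (i in 1:10) {
    n <- 30
    s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
    t <- c(rep(1, 10), rep(0, 20))
    got <- youden_threshold(s, t)
    want <- oracle_youden(s, t)
    expect_equal(got$J, want$J, tolerance = 1e-12)
    # same confusion table, even if the representative tau differs
    expect_equal(sum(s >= got$tau & t == 1), sum(s >= want$tau & t == 1))
    expect_equal(sum(s >= got$tau & t == 0), sum(s >= want$tau & t == 0))
  }
})

test_that("Youden J is invariant to strictly monotone score transforms", {
  set.seed(31)
  s <- runif(50)
  t <- rbinom(50, 1, 0.4)
  J0 <- youden_threshold(s, t)$J
  expect_equal(youden_threshold(qlogis(s), t)$J, J0)
  expect_equal(youden_threshold(s^3, t)$J, J0)
})

test_that("the rule-out Youden threshold excludes an uninformative high-dispersion block", {
  set.seed(42)
  # low-dispersion block: separable mean predictions; high-dispersion block:
  # label-independent scores, led by a case any inclusion of which breaks
  # perfect separation (a confident false positive)
  n1 <- 40; n2 <- 40
  truth1 <- rbinom(n1, 1, 0.5)
  mp2 <- runif(n2, 0.3, 0.9)
  truth2 <- rbinom(n2, 1, 0.5)
  mp2[1] <- 0.9; truth2[1] <- 0
  co <- make_summary_cohort(
    mean_pred = c(ifelse(truth1 == 1, 0.9, 0.1), mp2),
    var_uq = c(runif(n1, 0, 0.05), 0.2, runif(n2 - 1, 0.25, 0.45)),
    truth = c(truth1, truth2),
    pirads = 3
  )
  th <- youden_uq_threshold(co, "varUQ")
  expect_lt(th$tau, 0.2)                     # cuts below the noisy block
  certain <- is_certain(co$var_uq, "varUQ", th$tau)
  expect_true(all(which(certain) <= n1))
  expect_equal(th$J, 1)
  # zero-dispersion cohort: everything certain at tau = 0
  coz <- make_summary_cohort(mean_pred = c(0.1, 0.9, 0.2, 0.8),
                             var_uq = rep(0, 4),
                             truth = c(0, 1, 0, 1), pirads = c(1, 5, 2, 4))
  thz <- youden_uq_threshold(coz, "varUQ")
  expect_equal(thz$tau, 0)
  expect_equal(thz$n_certain, 4)
  # meanUQ on bimodal mean predictions isolates the extreme modes; values are
  # chosen exactly representable so symmetric pairs share one meanUQ value
  cob <- make_summary_cohort(
    mean_pred = c(0.0625, 0.9375, 0.125, 0.875, 0.25, 0.75),
    var_uq = rep(0.1, 6),
    truth = c(0, 1, 0, 1, 1, 0), pirads = 3)
  thb <- youden_uq_threshold(cob, "meanUQ")
  certain <- is_certain(cob$mean_uq, "meanUQ", thb$tau)
  expect_true(all(certain[1:4]))
  expect_false(any(certain[5:6]))
})

test_that("both Youden strategies return thresholds with both classes certain", {
  spec <- cohort_spec(center_spec("A", 200, 0.3, 0.8, 0.6), seed = 99)
  co <- add_ensemble_summary(generate_cohort(spec))
  for (strategy in c("subset_youden", "error_youden")) {
    for (metric in c("meanUQ", "varUQ")) {
      th <- youden_uq_threshold(co, metric, strategy = strategy)
      expect_gt(th$n_certain, 0)
    }
  }
})

test_that("DeLong variance matches the direct structural-components computation", {
  set.seed(55)
  s <- runif(20)
  t <- c(rep(1, 8), rep(0, 12))
  oc <- oracle_delong_components(s, t)
  var_direct <- var(oc$v10) / oc$m + var(oc$v01) / oc$n
  expect_equal(delong_variance(s, t), var_direct, tolerance = 1e-10)
  # paired difference variance against the same oracle
  s2 <- runif(20)
  oc2 <- oracle_delong_components(s2, t)
  s10 <- cov(cbind(oc$v10, oc2$v10))
  s01 <- cov(cbind(oc$v01, oc2$v01))
  var_pair <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / oc$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / oc$n
  dl <- delong_test(s, s2, t, paired = TRUE)
  z_direct <- (mean(oc$v10) - mean(oc2$v10)) / sqrt(var_pair)
  expect_equal(dl$statistic, z_direct, tolerance = 1e-10)
})

test_that("DeLong test agrees with the reference implementation in pROC", {
  set.seed(56)
  t <- c(rep(1, 30), rep(0, 40))
  s1 <- rnorm(70, t)
  s2 <- rnorm(70, 0.8 * t)
  dl <- delong_test(s1, s2, t, paired = TRUE)
  ref <- pROC::roc.test(pROC::roc(t, s1, quiet = TRUE),
                        pROC::roc(t, s2, quiet = TRUE),
                        method = "delong", paired = TRUE)
  expect_equal(abs(dl$statistic), abs(as.numeric(ref$statistic)), tolerance = 1e-8)
  expect_equal(dl$p_value, as.numeric(ref$p.value), tolerance = 1e-8)
  # unpaired mode on disjoint case sets
  t_b <- c(rep(1, 25), rep(0, 35))
  s_b <- rnorm(60, 0.8 * t_b)
  dlu <- delong_test(s1, s_b, t, truth_b = t_b, paired = FALSE)
  refu <- pROC::roc.test(pROC::roc(t, s1, quiet = TRUE),
                         pROC::roc(t_b, s_b, quiet = TRUE),
                         method = "delong", paired = FALSE)
  expect_equal(abs(dlu$statistic), abs(as.numeric(refu$statistic)), tolerance = 1e-8)
})

test_that("identical score vectors give a null DeLong result", {
  set.seed(57)
  s <- runif(40)
  t <- rep(c(1, 0), 20)
  dl <- delong_test(s, s, t, paired = TRUE)
  expect_equal(dl$statistic, 0)
  expect_equal(dl$p_value, 1)
  expect_error(delong_test(s, s[-1], t, paired = TRUE), "identical case sets")
})

test_that("DeLong variance shrinks roughly as 1/n", {
  set.seed(58)
  mean_var <- function(n, reps = 150) {
    mean(replicate(reps, {
      t <- c(rep(1, n / 2), rep(0, n / 2))
      delong_variance(rnorm(n, t), t)
    }))
  }
  v1 <- mean_var(60)
  v4 <- mean_var(240)
  expect_lt(abs(v1 / v4 - 4) / 4, 0.3)
})

test_that("the permutation test is exact-null-safe and reproducible", {
  truth <- rep(1, 12)
  ids <- sprintf("P%02d", c(1:10, 1, 2))
  d <- rbinom(12, 1, 0.7)
  pt <- permutation_sensitivity_test(d, d, truth, ids, n_perm = 200, seed = 4)
  expect_equal(pt$statistic, 0)
  expect_equal(pt$p_value, 1)
  expect_error(permutation_sensitivity_test(d, d, rep(0, 12), ids, 10, 1),
               "positive")
  # same seed, same p; different seed may differ
  d2 <- rbinom(12, 1, 0.5)
  p_a <- permutation_sensitivity_test(d, d2, truth, ids, n_perm = 500, seed = 9)
  p_b <- permutation_sensitivity_test(d, d2, truth, ids, n_perm = 500, seed = 9)
  expect_identical(p_a$p_value, p_b$p_value)
})

test_that("the permutation test detects a pathway that recovers false negatives", {
  # 60 positive visits; the pathway flips 10 radiologist false negatives to
  # true positives and changes nothing else
  n <- 60
  truth <- rep(1, n)
  ids <- sprintf("P%02d", seq_len(n))
  rad <- c(rep(1, 40), rep(0, 20))
  path <- rad
  path[41:50] <- 1
  pt <- permutation_sensitivity_test(path, rad, truth, ids,
                                     n_perm = 10000, seed = 11)
  expect_equal(pt$statistic, 10 / 60)
  expect_lt(pt$p_value, 0.05)
})

test_that("overlap share is the varUQ-certain fraction also meanUQ-certain", {
  f <- c(TRUE, TRUE, FALSE, TRUE)
  expect_equal(overlap_share(f, f), 1)
  expect_equal(overlap_share(f, !f), 0)
  expect_error(overlap_share(rep(FALSE, 4), f), "varUQ")
  # published-scale arithmetic: 207 of 224 varUQ-certain also meanUQ-certain
  fv <- c(rep(TRUE, 224), rep(FALSE, 465))
  fm <- c(rep(TRUE, 207), rep(FALSE, 17), rep(TRUE, 235), rep(FALSE, 230))
  expect_equal(round(100 * overlap_share(fv, fm), 2), 92.41)
})
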