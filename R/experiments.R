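#' Radiologist operating point of a cohort
#'
#' Sensitivity and specificity of the clinical-practice call (PI-RADS >= 4)
#' against the biopsy ground truth.
#'
#' @param cohort A cohort data frame.
#' @return A one-row data frame as from [pathway_metrics()] (all visits read by
#'   the radiologist).
#' @export
radiologist_metrics <- function(cohort) {
  pathway_metrics(as.integer(cohort$pirads >= 4), cohort$truth,
                  certain = logical(nrow(cohort)))
}

round2 <- function(x) round(x, 2)  # round-half-even, the package's reporting convention

#' Compare meanUQ and varUQ rule-out per center
#'
#' For each center and each uncertainty metric: selects the Youden rule-out
#' threshold ([youden_uq_threshold()]), counts the certain cases, computes the
#' AUROC of the mean ensemble prediction on the certain subset, compares the
#' two subsets' AUROCs with an unpaired DeLong test (the certain sets differ
#' between metrics), and reports the share of varUQ-certain cases that are
#' also meanUQ-certain.
#'
#' @param cohort A cohort data frame; ensemble summaries are added if absent.
#' @param strategy Youden concretization passed to [youden_uq_threshold()].
#' @param verbose Emit per-center progress messages.
#' @return A data frame with one row per center x metric: `center_id`,
#'   `metric`, `tau`, `n_certain`, `pct_certain` (rounded to 2 decimals),
#'   `auroc_certain`, `delong_p` (the metric pair's test, repeated on both
#'   rows), `overlap_pct`.
#' @export
run_experiment1 <- function(cohort, strategy = "subset_youden", verbose = FALSE) {
  cohort <- ensure_summary(cohort)
  rows <- list()
  for (cid in unique(cohort$center_id)) {
    cc <- cohort[cohort$center_id == cid, , drop = FALSE]
    if (length(unique(cc$truth)) < 2L) {
      warning("center ", cid, " lacks both classes; skipped", call. = FALSE)
      next
    }
    per_metric <- lapply(c("meanUQ", "varUQ"), function(metric) {
      th <- youden_uq_threshold(cc, metric, strategy = strategy)
      certain <- triage_by_threshold(cc, metric, th$tau)
      list(metric = metric, tau = th$tau, certain = certain,
           auc = auroc(cc$mean_pred[certain], cc$truth[certain]))
    })
    names(per_metric) <- c("meanUQ", "varUQ")
    dl <- delong_test(cc$mean_pred[per_metric$varUQ$certain],
                      cc$mean_pred[per_metric$meanUQ$certain],
                      truth = cc$truth[per_metric$varUQ$certain],
                      truth_b = cc$truth[per_metric$meanUQ$certain],
                      paired = FALSE)
    ov <- overlap_share(per_metric$varUQ$certain, per_metric$meanUQ$certain)
    if (verbose) {
      message(sprintf(
        "center %s: meanUQ tau=%.3f (%d certain), varUQ tau=%.3f (%d certain), DeLong p=%.3g",
        cid, per_metric$meanUQ$tau, sum(per_metric$meanUQ$certain),
        per_metric$varUQ$tau, sum(per_metric$varUQ$certain), dl$p_value))
    }
    for (pm in per_metric) {
      rows[[length(rows) + 1L]] <- data.frame(
        center_id = cid, metric = pm$metric, tau = pm$tau,
        n_certain = sum(pm$certain),
        pct_certain = round2(100 * sum(pm$certain) / nrow(cc)),
        auroc_certain = pm$auc,
        delong_p = dl$p_value,
        overlap_pct = round2(100 * ov),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) stop("no center had both classes", call. = FALSE)
  do.call(rbind, rows)
}

#' Workload-reduction sweep at non-inferior specificity
#'
#' For each center, non-inferiority margin and autonomous-reading fraction:
#' rules out the requested fraction of most-certain visits
#' ([triage_by_fraction()]), calibrates the autonomous AI threshold to the
#' non-inferior specificity target (the center's radiologist specificity minus
#' the margin, [calibrate_ai_threshold()]), forms the combined pathway
#' diagnosis, and tests the pathway's sensitivity against the radiologist's
#' with the patient-level permutation test. Also reports the share of
#' PI-RADS >= 3 reads (biopsy-triggering under clinical rules) among the
#' ruled-out visits.
#'
#' @inheritParams run_experiment1
#' @param metric Uncertainty metric used for ranking (default `"varUQ"`).
#' @param margins Non-inferiority specificity margins (default 0.05 and 0.10).
#' @param fractions Autonomous-reading fractions (default 0, 0.1, ..., 1).
#' @param n_perm Permutations for the sensitivity test.
#' @param seed Seed for the permutation streams; each center x margin x
#'   fraction cell uses a distinct derived stream, so every p-value is
#'   reproducible in isolation.
#' @param alternative Sidedness of the permutation test (default one-sided
#'   `"greater"`).
#' @return A data frame with one row per center x margin x fraction:
#'   calibrated threshold, achieved specificity, pathway and radiologist
#'   sensitivity, permutation p-value, workload, attainability flag and the
#'   PI-RADS >= 3 share among ruled-out visits.
#' @export
run_experiment2 <- function(cohort, metric = "varUQ",
                            margins = c(0.05, 0.10),
                            fractions = seq(0, 1, by = 0.1),
                            n_perm = 10000L, seed = 1L,
                            alternative = "greater",
                            verbose = FALSE) {
  if (any(margins <= 0 | margins >= 1)) stop("margins must be in (0, 1)", call. = FALSE)
  if (is.unsorted(fractions)) stop("fractions must be sorted", call. = FALSE)
  cohort <- ensure_summary(cohort)
  rows <- list()
  cell <- 0L
  for (cid in unique(cohort$center_id)) {
    cc <- cohort[cohort$center_id == cid, , drop = FALSE]
    rad <- radiologist_metrics(cc)
    rad_diag <- as.integer(cc$pirads >= 4)
    for (margin in margins) {
      target <- rad$specificity - margin
      for (fraction in fractions) {
        cell <- cell + 1L
        tri <- triage_by_fraction(cc, metric, fraction)
        cal <- calibrate_ai_threshold(cc, tri$certain, target)
        res <- combined_diagnosis(cc, tri$certain, cal$ai_threshold)
        pm <- pathway_metrics(res$diagnosis, cc$truth, tri$certain)
        pt <- permutation_sensitivity_test(
          res$diagnosis, rad_diag, cc$truth, cc$patient_id,
          n_perm = n_perm, seed = derive_seed(seed, cell),
          alternative = alternative)
        ruled_out <- tri$certain
        p3_share <- if (any(ruled_out)) {
          mean(cc$pirads[ruled_out] >= 3)
        } else NA_real_
        if (verbose) {
          message(sprintf(
            "center %s margin %.2f fraction %.1f: ai_threshold=%.4f spec=%.3f sens=%.3f p=%.3g",
            cid, margin, fraction, cal$ai_threshold, pm$specificity,
            pm$sensitivity, pt$p_value))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          center_id = cid, metric = metric, margin = margin,
          fraction_ai = fraction, tau_uq = tri$tau,
          ai_threshold = cal$ai_threshold,
          target_specificity = target,
          achieved_specificity = pm$specificity,
          attainable = cal$attainable,
          pathway_sensitivity = pm$sensitivity,
          radiologist_sensitivity = rad$sensitivity,
          radiologist_specificity = rad$specificity,
          p_value = pt$p_value,
          n_certain = pm$n_certain,
          workload_radiologist = pm$workload_radiologist,
          pirads3plus_share_ruled_out = p3_share,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

# Distinct permutation stream per experiment cell, kept inside 32-bit range.
derive_seed <- function(seed, counter) {
  (abs(seed) + 7919L * counter) %% 2147483587L
}

ensure_summary <- function(cohort) {
  if (!all(c("mean_pred", "mean_uq", "var_uq") %in% colnames(cohort))) {
    cohort <- add_ensemble_summary(cohort)
  }
  cohort
}

#' Write experiment tables and sensitivity-versus-fraction figures
#'
#' Writes the result rows as a comma-separated table and, for workload-sweep
#' rows, one figure per center plotting the combined pathway sensitivity
#' against the autonomous-reading fraction with the radiologist's sensitivity
#' as a dashed reference line. File names are deterministic
#' (`experiment1.csv`, `experiment2.csv`, `sensitivity_<center>.pdf`).
#'
#' @param rows Result rows from [run_experiment1()] or [run_experiment2()].
#' @param outdir Output directory, created if needed.
#' @return Character vector of files written, invisibly.
#' @export
render_reports <- function(rows, outdir) {
  if (!is.data.frame(rows) || nrow(rows) == 0L) {
    stop("rows must be a non-empty data frame", call. = FALSE)
  }
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  is_exp2 <- "fraction_ai" %in% colnames(rows)
  table_file <- file.path(outdir, if (is_exp2) "experiment2.csv" else "experiment1.csv")
  utils::write.csv(rows, table_file, row.names = FALSE, quote = FALSE)
  files <- table_file
  if (is_exp2) {
    for (cid in unique(rows$center_id)) {
      sub <- rows[rows$center_id == cid, , drop = FALSE]
      p <- ggplot2::ggplot(sub, ggplot2::aes(x = .data$fraction_ai,
                                             y = .data$pathway_sensitivity,
                                             colour = factor(.data$margin))) +
        ggplot2::geom_line() +
        ggplot2::geom_point(size = 1) +
        ggplot2::geom_hline(ggplot2::aes(yintercept = .data$radiologist_sensitivity),
                            linetype = "dashed") +
        ggplot2::scale_x_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
        ggplot2::labs(x = "Autonomous AI reading (fraction of visits)",
                      y = "Combined pathway sensitivity",
                      colour = "Specificity margin",
                      title = paste("Center", cid)) +
        ggplot2::theme_minimal()
      f <- file.path(outdir, sprintf("sensitivity_%s.pdf", cid))
      ggplot2::ggsave(f, p, width = 6, height = 4)
      files <- c(files, f)
    }
  }
  invisible(files)
}
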