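#' Specify one center of a multicenter diagnostic cohort
#'
#' A center is characterised by its size, its csPCa prevalence, the operating
#' point of its radiologists at the PI-RADS >= 4 cut, and the behaviour of the
#' AI ensemble on its cases. The AI score model is a logit-normal mixture: each
#' case carries a latent class signal of magnitude `ai_separation / 2` (positive
#' for csPCa, negative otherwise) plus case-level Gaussian noise, and each of
#' the ensemble's submodels perturbs that latent value with its own Gaussian
#' noise before the logistic transform maps it into \[0, 1\]. A fraction
#' `uncertain_mix` of cases is drawn from a high-dispersion regime
#' (`ensemble_sd_uncertain`), the rest from a low-dispersion regime
#' (`ensemble_sd_certain`); the two regimes produce the concordant (certain)
#' and discordant (uncertain) ensembles that uncertainty-based rule-out acts on.
#'
#' @param center_id Character label for the center.
#' @param n_visits Number of MRI visits to generate.
#' @param prevalence Fraction of visits with csPCa (Gleason Grade Group >= 2),
#'   in \[0, 1\].
#' @param rad_sensitivity,rad_specificity Radiologist operating point at the
#'   PI-RADS >= 4 positive call, each strictly inside (0, 1).
#' @param pirads3_rate_neg Probability that a radiologist-negative,
#'   biopsy-negative case is scored PI-RADS 3 (biopsy-triggering) rather than
#'   PI-RADS 1-2.
#' @param ai_separation Distance, on the logit scale, between the latent class
#'   means; controls the AUROC of the mean ensemble prediction.
#' @param latent_sd Standard deviation of the case-level latent noise shared by
#'   all submodels.
#' @param ensemble_sd_certain,ensemble_sd_uncertain Submodel noise standard
#'   deviations in the low- and high-dispersion regimes;
#'   `ensemble_sd_uncertain >= ensemble_sd_certain` is required.
#' @param uncertain_mix Fraction of visits drawn from the high-dispersion
#'   regime, in \[0, 1\].
#' @param repeat_visit_rate Fraction of visits that are repeat visits of an
#'   earlier patient of the same center (default 0, one visit per patient).
#'
#' @return An object of class `center_spec` (a named list of the validated
#'   parameters).
#' @seealso [cohort_spec()], [generate_cohort()]
#' @export
center_spec <- function(center_id,
                        n_visits,
                        prevalence,
                        rad_sensitivity,
                        rad_specificity,
                        pirads3_rate_neg = 0.3,
                        ai_separation = 1.5,
                        latent_sd = 1,
                        ensemble_sd_certain = 0.15,
                        ensemble_sd_uncertain = 1,
                        uncertain_mix = 0.35,
                        repeat_visit_rate = 0) {
  stop_cfg <- function(field, msg) {
    stop(sprintf("invalid center_spec field '%s': %s", field, msg), call. = FALSE)
  }
  if (!is.character(center_id) || length(center_id) != 1L || is.na(center_id) ||
      !nzchar(center_id)) {
    stop_cfg("center_id", "must be a non-empty string")
  }
  if (!is.numeric(n_visits) || length(n_visits) != 1L || is.na(n_visits) ||
      n_visits < 1 || n_visits != floor(n_visits)) {
    stop_cfg("n_visits", "must be a positive integer")
  }
  chk_frac <- function(x, field, open = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x)) stop_cfg(field, "must be a number")
    if (open && (x <= 0 || x >= 1)) stop_cfg(field, "must be strictly between 0 and 1")
    if (!open && (x < 0 || x > 1)) stop_cfg(field, "must be in [0, 1]")
    x
  }
  chk_frac(prevalence, "prevalence")
  chk_frac(rad_sensitivity, "rad_sensitivity", open = TRUE)
  chk_frac(rad_specificity, "rad_specificity", open = TRUE)
  chk_frac(pirads3_rate_neg, "pirads3_rate_neg")
  chk_frac(uncertain_mix, "uncertain_mix")
  chk_frac(repeat_visit_rate, "repeat_visit_rate")
  if (!is.numeric(ai_separation) || ai_separation <= 0) {
    stop_cfg("ai_separation", "must be > 0")
  }
  if (!is.numeric(latent_sd) || latent_sd < 0) stop_cfg("latent_sd", "must be >= 0")
  if (!is.numeric(ensemble_sd_certain) || ensemble_sd_certain < 0) {
    stop_cfg("ensemble_sd_certain", "must be >= 0")
  }
  if (!is.numeric(ensemble_sd_uncertain) || ensemble_sd_uncertain < ensemble_sd_certain) {
    stop_cfg("ensemble_sd_uncertain", "must be >= ensemble_sd_certain")
  }
  structure(
    list(center_id = center_id, n_visits = as.integer(n_visits),
         prevalence = prevalence, rad_sensitivity = rad_sensitivity,
         rad_specificity = rad_specificity, pirads3_rate_neg = pirads3_rate_neg,
         ai_separation = ai_separation, latent_sd = latent_sd,
         ensemble_sd_certain = ensemble_sd_certain,
         ensemble_sd_uncertain = ensemble_sd_uncertain,
         uncertain_mix = uncertain_mix, repeat_visit_rate = repeat_visit_rate),
    class = "center_spec"
  )
}

#' Specify a multicenter cohort
#'
#' @param centers A list of [center_spec()] objects.
#' @param n_submodels Number of ensemble submodels (default 15). At least 2,
#'   since the ensemble standard deviation is undefined for a single submodel.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   spec and seed. Each center draws from its own substream derived from
#'   `seed` by a fixed per-center offset, so a center's records do not depend
#'   on the other centers in the spec.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(centers, n_submodels = 15L, seed = 1L) {
  if (inherits(centers, "center_spec")) centers <- list(centers)
  if (!is.list(centers) || length(centers) == 0L ||
      !all(vapply(centers, inherits, logical(1), "center_spec"))) {
    stop("invalid cohort_spec field 'centers': must be a list of center_spec objects",
         call. = FALSE)
  }
  ids <- vapply(centers, `[[`, character(1), "center_id")
  if (anyDuplicated(ids)) {
    stop("invalid cohort_spec field 'centers': duplicated center_id", call. = FALSE)
  }
  if (!is.numeric(n_submodels) || length(n_submodels) != 1L || is.na(n_submodels) ||
      n_submodels < 2 || n_submodels != floor(n_submodels)) {
    stop("invalid cohort_spec field 'n_submodels': must be an integer >= 2",
         call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != floor(seed)) {
    stop("invalid cohort_spec field 'seed': must be an integer", call. = FALSE)
  }
  structure(list(centers = centers, n_submodels = as.integer(n_submodels),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default three-center cohort specification
#'
#' Reproduces the structure of the multicenter csPCa cohort the pipeline is
#' designed around: three centers of 689, 723 and 200 visits with csPCa
#' prevalences of 25%, 25% and 27.5% and radiologist operating points of
#' 83%/58%, 86%/54% and 95%/78% sensitivity/specificity at PI-RADS >= 4.
#' AI score-model parameters take the package defaults (see [center_spec()]).
#'
#' @param seed Integer seed passed to [cohort_spec()].
#' @param n_scale Multiplier applied to the per-center visit counts (useful for
#'   large-sample parameter-recovery checks).
#' @return A `cohort_spec`.
#' @export
default_cohort_spec <- function(seed = 1L, n_scale = 1) {
  cohort_spec(
    centers = list(
      center_spec("A", n_visits = round(689 * n_scale), prevalence = 0.25,
                  rad_sensitivity = 0.83, rad_specificity = 0.58),
      center_spec("B", n_visits = round(723 * n_scale), prevalence = 0.25,
                  rad_sensitivity = 0.86, rad_specificity = 0.54),
      center_spec("C", n_visits = round(200 * n_scale), prevalence = 0.275,
                  rad_sensitivity = 0.95, rad_specificity = 0.78)
    ),
    n_submodels = 15L,
    seed = seed
  )
}

logistic <- function(x) 1 / (1 + exp(-x))

# Per-center RNG substream: fixed offset from the cohort seed, independent of
# center order. Kept well below .Machine$integer.max.
center_seed <- function(seed, center_index) {
  (abs(seed) + 10007L * center_index) %% 2147483587L
}

generate_center <- function(cs, n_submodels, seed, center_index) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(center_seed(seed, center_index))

  n <- cs$n_visits
  truth <- stats::rbinom(n, 1L, cs$prevalence)

  # Latent logit signal shared by all submodels of a case.
  z <- ifelse(truth == 1L, cs$ai_separation / 2, -cs$ai_separation / 2) +
    stats::rnorm(n, 0, cs$latent_sd)
  uncertain <- stats::rbinom(n, 1L, cs$uncertain_mix) == 1L
  sub_sd <- ifelse(uncertain, cs$ensemble_sd_uncertain, cs$ensemble_sd_certain)
  scores <- logistic(z + matrix(stats::rnorm(n * n_submodels), n, n_submodels) * sub_sd)

  # PI-RADS read. A radiologist-negative csPCa case must be PI-RADS 3: PI-RADS
  # 1-2 cases are never biopsied and so cannot carry a positive ground truth.
  # Assigning 3 directly is the fixed point of redrawing the negative branch
  # until valid and leaves the empirical sensitivity at rad_sensitivity.
  u_call <- stats::runif(n)
  u_high <- stats::runif(n)   # 4 vs 5 split
  u_p3 <- stats::runif(n)
  u_low <- stats::runif(n)    # 1 vs 2 split
  pirads <- integer(n)
  pos_call <- ifelse(truth == 1L, u_call < cs$rad_sensitivity,
                     u_call < 1 - cs$rad_specificity)
  pirads[pos_call] <- ifelse(u_high[pos_call] < 0.5, 4L, 5L)
  neg <- !pos_call
  pirads[neg & truth == 1L] <- 3L
  neg0 <- neg & truth == 0L
  pirads[neg0] <- ifelse(u_p3[neg0] < cs$pirads3_rate_neg, 3L,
                         ifelse(u_low[neg0] < 0.5, 1L, 2L))

  # Repeat visits: a chosen fraction of visits reuses an earlier patient id.
  patient_idx <- seq_len(n)
  if (cs$repeat_visit_rate > 0 && n > 1) {
    repeats <- which(stats::runif(n) < cs$repeat_visit_rate & patient_idx > 1)
    for (i in repeats) {
      patient_idx[i] <- patient_idx[sample.int(i - 1L, 1L)]
    }
  }

  df <- data.frame(
    patient_id = sprintf("%s-P%04d", cs$center_id, patient_idx),
    visit_id = sprintf("%s-V%04d", cs$center_id, seq_len(n)),
    center_id = cs$center_id,
    truth = truth,
    pirads = pirads,
    stringsAsFactors = FALSE
  )
  colnames(scores) <- score_cols(n_submodels)
  cbind(df, as.data.frame(scores))
}

score_cols <- function(k) sprintf("score_%02d", seq_len(k))

#' Generate a synthetic multicenter cohort
#'
#' Draws one record per MRI visit: ground-truth csPCa label, radiologist
#' PI-RADS score, and the ensemble submodel likelihoods, according to the score
#' model described in [center_spec()]. Deterministic given the spec (which
#' includes the seed).
#'
#' @param spec A [cohort_spec()].
#' @return A data frame with columns `patient_id`, `visit_id`, `center_id`,
#'   `truth` (0/1), `pirads` (1-5) and `score_01` ... `score_NN`, one row per
#'   visit.
#' @examples
#' spec <- cohort_spec(center_spec("A", 50, 0.25, 0.83, 0.58), seed = 7)
#' cohort <- generate_cohort(spec)
#' table(cohort$truth, cohort$pirads >= 4)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    stop("spec must be a cohort_spec object", call. = FALSE)
  }
  parts <- lapply(seq_along(spec$centers), function(i) {
    generate_center(spec$centers[[i]], spec$n_submodels, spec$seed, i)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Write / read a cohort file
#'
#' The on-disk format is plain comma-separated text with a header row and
#' columns `patient_id`, `visit_id`, `center_id`, `truth`, `pirads`,
#' `score_01` ... `score_NN` (UTF-8, `.` decimal separator). `read_cohort()`
#' validates the schema and value ranges and reports the offending row on
#' failure; `write_cohort()` then `read_cohort()` is a field-for-field
#' identity.
#'
#' @param cohort A cohort data frame as produced by [generate_cohort()].
#' @param path File path.
#' @return `read_cohort()` returns the validated cohort data frame;
#'   `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                        colClasses = c(patient_id = "character",
                                       visit_id = "character",
                                       center_id = "character"))
  validate_cohort(df)
}

validate_cohort <- function(df) {
  fixed <- c("patient_id", "visit_id", "center_id", "truth", "pirads")
  missing <- setdiff(fixed, colnames(df))
  if (length(missing)) {
    stop("cohort schema violation: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sc <- grep("^score_[0-9]+$", colnames(df), value = TRUE)
  if (length(sc) < 2L) {
    stop("cohort schema violation: need at least 2 score_* columns", call. = FALSE)
  }
  bad_row <- function(ok, what) {
    if (!all(ok)) {
      stop(sprintf("cohort parse error at row %d: %s", which(!ok)[1L], what),
           call. = FALSE)
    }
  }
  if (nrow(df) > 0) {
    bad_row(df$truth %in% c(0L, 1L), "truth must be 0 or 1")
    bad_row(df$pirads %in% 1:5, "pirads must be in 1..5")
    for (col in sc) {
      v <- df[[col]]
      bad_row(is.finite(v) & v >= 0 & v <= 1,
              sprintf("%s must be in [0, 1]", col))
    }
    bad_row(!(df$pirads <= 2 & df$truth == 1),
            "PI-RADS <= 2 implies truth 0 (no biopsy follow-up)")
  }
  df[, c(fixed, sort(sc))]
}

#' Names of the submodel score columns of a cohort
#'
#' @param cohort A cohort data frame.
#' @return Character vector of `score_*` column names, in submodel order.
#' @export
cohort_score_cols <- function(cohort) {
  sort(grep("^score_[0-9]+$", colnames(cohort), value = TRUE))
}
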