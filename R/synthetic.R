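default_densities <- function() {
  tibble::tribble(
    ~biomarker, ~mu_nonevent, ~sd_nonevent, ~mu_event, ~sd_event,
    "HIP_FCI",    0.20,  0.20,   0.60,  0.20,
    "PCC_FCI",    2.80,  0.50,   1.80,  0.50,
    "FG_FCI",     9.50,  1.50,  12.50,  1.50,
    "HIP_GMI",    0.55,  0.10,   0.35,  0.10,
    "FG_GMI",     0.62,  0.07,   0.48,  0.07,
    "ABETA",    192.00, 25.00, 142.00, 25.00,
    "PTAU",      23.00, 11.00,  45.00, 11.00,
    "MMSE",      28.00,  2.00,  24.00,  2.00,
    "ADAS_COG",   9.00,  4.00,  17.00,  4.00,
    "AVLT",      38.00,  6.00,  26.00,  6.00
  )
}

#' Configuration for the synthetic two-cohort generator
#'
#' Describes the generative process the event-based analysis assumes: a
#' ground-truth event ordering, per-biomarker event/non-event Gaussian
#' densities, a stage distribution, a stage-threshold converter rule with
#' label noise, per-cohort structured missingness, and a between-cohort
#' location shift. Defaults emulate the published study design: a
#' 46-subject discovery cohort and a 56-subject validation cohort, a
#' uniform stage distribution over 0..10 with converter threshold at stage
#' 8 (so roughly 27% converters, matching the reported 26-29% three-year
#' conversion rates), a standardized event/non-event separation of 2.0 SD
#' per biomarker, three biomarkers (CSF A-beta, p-tau, ADAS-Cog) absent
#' from the validation cohort, and a 0.2 SD location shift in the
#' validation cohort.
#'
#' @param panel Panel tibble.
#' @param true_sequence Ground-truth event ordering (permutation of the
#'   panel).
#' @param densities Tibble `biomarker`, `mu_nonevent`, `sd_nonevent`,
#'   `mu_event`, `sd_event`.
#' @param stage_probs Probability vector over stages 0..N (sums to 1).
#' @param n_discovery,n_validation Cohort sizes.
#' @param converter_stage Stage threshold tau: a subject converts when
#'   `true_stage >= tau` (before label noise).
#' @param label_noise Probability of flipping the converter label,
#'   in `[0, 0.5)`.
#' @param validation_missing Biomarkers deleted entirely from the
#'   validation cohort.
#' @param missing_rate Random per-cell missingness rate for the remaining
#'   biomarkers.
#' @param validation_shift Named numeric: additive location shift applied
#'   to the validation cohort; default 0.2 SD per biomarker.
#' @param seed Integer seed; generation is byte-identical given the seed.
#' @return A `care_synthetic_config` list.
#' @export
synthetic_config <- function(panel = default_panel(),
                             true_sequence = c("HIP_FCI", "PCC_FCI", "ABETA",
                                               "PTAU", "MMSE", "ADAS_COG",
                                               "HIP_GMI", "AVLT", "FG_GMI",
                                               "FG_FCI"),
                             densities = default_densities(),
                             stage_probs = NULL,
                             n_discovery = 46L, n_validation = 56L,
                             converter_stage = 8L, label_noise = 0.05,
                             validation_missing = c("ABETA", "PTAU",
                                                    "ADAS_COG"),
                             missing_rate = 0,
                             validation_shift = NULL,
                             seed = 1L) {
  check_permutation(true_sequence, panel$name)
  densities <- densities[match(panel$name, densities$biomarker), ]
  if (anyNA(densities$biomarker)) {
    stop("densities must cover every panel biomarker", call. = FALSE)
  }
  n_bm <- nrow(panel)
  if (is.null(stage_probs)) stage_probs <- rep(1 / (n_bm + 1), n_bm + 1)
  if (length(stage_probs) != n_bm + 1 || any(stage_probs < 0) ||
      abs(sum(stage_probs) - 1) > 1e-8) {
    stop("stage_probs must be a length N+1 probability vector summing to 1",
         call. = FALSE)
  }
  if (n_discovery < 1L || n_validation < 1L) {
    stop("cohort sizes must be >= 1", call. = FALSE)
  }
  if (label_noise < 0 || label_noise >= 0.5) {
    stop("label_noise must be in [0, 0.5)", call. = FALSE)
  }
  if (is.null(validation_shift)) {
    validation_shift <- stats::setNames(0.2 * densities$sd_nonevent,
                                        densities$biomarker)
  }
  structure(
    list(panel = panel, true_sequence = true_sequence,
         densities = densities, stage_probs = stage_probs,
         n_discovery = as.integer(n_discovery),
         n_validation = as.integer(n_validation),
         converter_stage = as.integer(converter_stage),
         label_noise = label_noise,
         validation_missing = validation_missing,
         missing_rate = missing_rate,
         validation_shift = validation_shift,
         seed = as.integer(seed)),
    class = "care_synthetic_config"
  )
}

draw_biomarker_values <- function(config, stages, shift = NULL) {
  n <- length(stages)
  seq_pos <- match(config$true_sequence, config$densities$biomarker)
  out <- matrix(NA_real_, n, nrow(config$densities),
                dimnames = list(NULL, config$densities$biomarker))
  for (i in seq_along(config$true_sequence)) {
    bm <- config$true_sequence[i]
    d <- config$densities[seq_pos[i], ]
    occurred <- stages >= i
    vals <- numeric(n)
    vals[occurred] <- stats::rnorm(sum(occurred), d$mu_event, d$sd_event)
    vals[!occurred] <- stats::rnorm(sum(!occurred), d$mu_nonevent,
                                    d$sd_nonevent)
    if (!is.null(shift) && bm %in% names(shift)) vals <- vals + shift[[bm]]
    out[, bm] <- vals
  }
  out
}

#' Generate one synthetic cohort
#'
#' Each subject draws a true stage from the configured stage distribution;
#' biomarkers at positions up to the stage in the true sequence come from
#' their event density, the rest from the non-event density. The converter
#' label is `true_stage >= converter_stage`, flipped with probability
#' `label_noise`. Configured missing biomarkers are deleted entirely
#' (their columns dropped); remaining cells go missing at `missing_rate`.
#'
#' @param config A [synthetic_config()] object.
#' @param cohort_id Cohort label.
#' @param n Cohort size (default `config$n_discovery`).
#' @param shift Optional named location-shift vector to apply.
#' @param missing_cols Biomarker columns to delete entirely.
#' @param seed Seed (default `config$seed`); generation is reproducible.
#' @return A list: `cohort` (tibble with subject_id, cohort, group,
#'   demographics, biomarkers) and `truth` (tibble with `true_stage`,
#'   `converter_rule` — the pre-noise label — and `label_flipped`).
#' @export
generate_cohort <- function(config, cohort_id = "discovery",
                            n = config$n_discovery, shift = NULL,
                            missing_cols = character(),
                            seed = config$seed) {
  set.seed(seed)
  n_bm <- nrow(config$panel)
  stages <- sample(0:n_bm, n, replace = TRUE, prob = config$stage_probs)
  values <- draw_biomarker_values(config, stages, shift)
  rule <- stages >= config$converter_stage
  flipped <- stats::runif(n) < config$label_noise
  converter <- xor(rule, flipped)
  cohort <- tibble::tibble(
    subject_id = sprintf("%s_%03d", cohort_id, seq_len(n)),
    cohort = cohort_id,
    group = ifelse(converter, "P-MCI", "N-MCI"),
    age = round(stats::rnorm(n, 70 + 0.4 * stages, 6), 1),
    sex = sample(c("M", "F"), n, replace = TRUE),
    education = pmax(6, round(stats::rnorm(n, 14, 3)))
  )
  keep_bm <- setdiff(colnames(values), missing_cols)
  for (bm in keep_bm) {
    x <- values[, bm]
    if (config$missing_rate > 0) {
      x[stats::runif(n) < config$missing_rate] <- NA_real_
    }
    cohort[[bm]] <- x
  }
  truth <- tibble::tibble(
    subject_id = cohort$subject_id, group = cohort$group,
    cohort = cohort_id, true_stage = stages, converter_rule = rule,
    label_flipped = flipped
  )
  list(cohort = cohort, truth = truth)
}

#' Generate a discovery/validation cohort pair
#'
#' The discovery cohort carries the full panel; the validation cohort
#' shares the true event sequence but loses the configured biomarkers
#' entirely and is location-shifted, emulating an independent cohort from
#' a different site with a reduced assay battery.
#'
#' @param config A [synthetic_config()] object.
#' @return A list: `discovery`, `validation` (cohort tibbles), `truth`
#'   (both cohorts' truth records stacked), and `config`.
#' @export
generate_pair <- function(config) {
  disc <- generate_cohort(config, "discovery", n = config$n_discovery,
                          seed = config$seed)
  val <- generate_cohort(config, "validation", n = config$n_validation,
                         shift = config$validation_shift,
                         missing_cols = config$validation_missing,
                         seed = config$seed + 1L)
  list(discovery = disc$cohort, validation = val$cohort,
       truth = dplyr::bind_rows(disc$truth, val$truth), config = config)
}

#' Generate a follow-up wave for an existing synthetic cohort
#'
#' Advances each subject's true stage by a Poisson number of new events
#' (capped at N), redraws the biomarkers at the new stage, and optionally
#' drops a fraction of subjects to emulate attrition between baseline and
#' follow-up.
#'
#' @param config A [synthetic_config()] object.
#' @param truth Truth tibble of the baseline wave (one cohort).
#' @param progression_rate Mean number of new events over the follow-up
#'   interval.
#' @param dropout Fraction of subjects lost to follow-up.
#' @param shift,missing_cols As in [generate_cohort()].
#' @param seed Seed.
#' @return A list: `cohort` (follow-up wave) and `truth`.
#' @export
generate_followup <- function(config, truth, progression_rate = 1.5,
                              dropout = 0, shift = NULL,
                              missing_cols = character(), seed = config$seed + 2L) {
  set.seed(seed)
  keep <- stats::runif(nrow(truth)) >= dropout
  truth <- truth[keep, , drop = FALSE]
  n <- nrow(truth)
  n_bm <- nrow(config$panel)
  stages <- pmin(truth$true_stage + stats::rpois(n, progression_rate), n_bm)
  values <- draw_biomarker_values(config, stages, shift)
  cohort <- tibble::tibble(
    subject_id = truth$subject_id, cohort = truth$cohort,
    group = truth$group
  )
  for (bm in setdiff(colnames(values), missing_cols)) {
    cohort[[bm]] <- values[, bm]
  }
  new_truth <- truth
  new_truth$true_stage <- stages
  list(cohort = cohort, truth = new_truth)
}
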