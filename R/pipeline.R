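run_metadata <- function(seed, n_subjects, extra = list()) {
  c(list(
    seed = seed,
    n_subjects = n_subjects,
    package_version = as.character(utils::packageVersion("careindex")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  ), extra)
}

#' Fit the full discovery model and write its artifacts
#'
#' Runs the discovery-side pipeline — the joint event-density and
#' event-sequence estimation of [fit_care_model()] — and serializes the
#' results: `event_models.yaml`, `sequence.json`, `loglik_trajectory.csv`
#' (the greedy ascent trajectory of every start of the final search), and
#' `fit_log.json` recording the seed, a hash of the inputs, row counts
#' and versions. Outputs are deterministic given the seed, so re-running
#' writes identical files.
#'
#' @param data Discovery cohort tibble.
#' @param panel Panel tibble; all biomarkers must be columns of `data`.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param seed Integer seed for the sequence search.
#' @param n_starts Random restarts for the greedy search.
#' @param mcmc_iter Metropolis iterations for positional uncertainty
#'   (0 disables).
#' @return Invisibly, a list with `models`, `sequence_fit`, and `paths`.
#' @export
run_fit <- function(data, panel = default_panel(), out_dir = NULL,
                    seed = 1L, n_starts = 10L, mcmc_iter = 0L) {
  joint <- fit_care_model(data, panel, n_starts = n_starts, seed = seed,
                          mcmc_iter = mcmc_iter)
  models <- joint$models
  fit <- joint$sequence_fit
  paths <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      models = file.path(out_dir, "event_models.yaml"),
      sequence = file.path(out_dir, "sequence.json"),
      trajectory = file.path(out_dir, "loglik_trajectory.csv"),
      log = file.path(out_dir, "fit_log.json")
    )
    write_event_models(models, paths[["models"]])
    write_sequence_fit(fit, paths[["sequence"]])
    traj <- purrr::imap_dfr(fit$trajectories, function(tr, s) {
      tibble::tibble(start = s, iteration = seq_along(tr), loglik = tr)
    })
    readr::write_csv(traj, paths[["trajectory"]])
    meta <- run_metadata(seed, nrow(data), list(
      n_starts = n_starts,
      panel = panel$name,
      input_hash = rlang::hash(list(data, panel)),
      best_loglik = as.numeric(fit$loglik)
    ))
    jsonlite::write_json(meta, paths[["log"]], auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(list(models = models, sequence_fit = fit, paths = paths))
}

score_direction <- function(panel, biomarker) {
  d <- panel$direction[match(biomarker, panel$name)]
  ifelse(d == "decrease", -1, 1)
}

#' Evaluate and transfer the staging classifier across cohorts
#'
#' Stages both cohorts under the fitted models and sequence, learns (or
#' accepts) a threshold on the discovery cohort's continuous stage score,
#' transfers it unchanged to the validation cohort, and emits the
#' diagnostic-metric and ranking reports:
#'
#' * `table2` — one row per cohort with the 2x2 counts, sensitivity,
#'   specificity, accuracy, balanced accuracy, OR and RR with 95% CIs at
#'   the (transferred) threshold;
#' * `ranking` — the staging score and each requested single-biomarker
#'   predictor, with per-cohort AUC, optimal-threshold metrics and ranks
#'   (thresholds always learned on discovery and transferred);
#' * the two ROC point lists.
#'
#' @param discovery,validation Cohort tibbles (must contain `group`).
#' @param models A `care_event_models` object.
#' @param sequence Event-sequence character vector.
#' @param threshold `"optimize"` (Youden on discovery) or a finite number
#'   to transfer as-is.
#' @param predictors Single-biomarker columns to rank against the staging
#'   score; default: model biomarkers present in both cohorts. Biomarkers
#'   whose abnormal direction is a decrease are sign-flipped so that a
#'   higher predictor score always means higher risk.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @param positive Group label of converters.
#' @return Invisibly, a list with `threshold`, `stages_discovery`,
#'   `stages_validation`, `roc_discovery`, `roc_validation`, `table2`,
#'   `ranking`, `paths`.
#' @export
run_evaluate <- function(discovery, validation, models, sequence,
                         threshold = "optimize", predictors = NULL,
                         out_dir = NULL, positive = "P-MCI") {
  if (nrow(validation) == 0L) stop("validation cohort is empty", call. = FALSE)
  if (nrow(discovery) == 0L) stop("discovery cohort is empty", call. = FALSE)
  for (nm in c("discovery", "validation")) {
    g <- get(nm)$group
    if (length(unique(g[!is.na(g)])) < 2L) {
      stop(nm, " cohort has a single outcome class", call. = FALSE)
    }
  }
  st_d <- stage_cohort(discovery, models, sequence)
  st_v <- stage_cohort(validation, models, sequence)
  roc_d <- roc_curve(st_d, .data$expected_stage, .data$group,
                     positive = positive)
  roc_v <- roc_curve(st_v, .data$expected_stage, .data$group,
                     positive = positive)
  thr <- if (identical(threshold, "optimize")) {
    roc_d$optimal_threshold
  } else {
    stopifnot(is.numeric(threshold), is.finite(threshold))
    threshold
  }
  table2 <- dplyr::bind_rows(
    dplyr::bind_cols(
      tibble::tibble(cohort = first_or(discovery$cohort, "discovery")),
      transfer_threshold(st_d, .data$expected_stage, .data$group, thr,
                         positive = positive)
    ),
    dplyr::bind_cols(
      tibble::tibble(cohort = first_or(validation$cohort, "validation")),
      transfer_threshold(st_v, .data$expected_stage, .data$group, thr,
                         positive = positive)
    )
  )
  if (is.null(predictors)) {
    predictors <- intersect(models$panel$name,
                            intersect(names(discovery), names(validation)))
  }
  ranking <- NULL
  if (length(predictors) >= 1L) {
    score_tbls <- list(
      discovery = dplyr::mutate(discovery,
                                CARE = st_d$expected_stage),
      validation = dplyr::mutate(validation,
                                 CARE = st_v$expected_stage)
    )
    rows <- purrr::map_dfr(c("CARE", predictors), function(pr) {
      sgn <- if (pr == "CARE") 1 else score_direction(models$panel, pr)
      sc_d <- sgn * score_tbls$discovery[[pr]]
      sc_v <- sgn * score_tbls$validation[[pr]]
      rd <- roc_curve(tibble::tibble(s = sc_d,
                                     g = score_tbls$discovery$group),
                      .data$s, .data$g, positive = positive)
      rv <- roc_curve(tibble::tibble(s = sc_v,
                                     g = score_tbls$validation$group),
                      .data$s, .data$g, positive = positive)
      thr_pr <- rd$optimal_threshold
      purrr::map2_dfr(
        list(discovery = score_tbls$discovery,
             validation = score_tbls$validation),
        list(rd, rv),
        function(tb, rc) {
          m <- transfer_threshold(
            tibble::tibble(s = if (pr == "CARE") tb$CARE else sgn * tb[[pr]],
                           g = tb$group),
            .data$s, .data$g, thr_pr, positive = positive)
          tibble::tibble(
            cohort = first_or(tb$cohort, "unknown"), predictor = pr,
            auc = rc$auc, sensitivity = m$sensitivity,
            specificity = m$specificity, accuracy = m$accuracy,
            balanced_accuracy = m$balanced_accuracy,
            threshold = sgn * thr_pr
          )
        }
      )
    })
    ranking <- ranking_table(
      dplyr::select(rows, -"threshold"), by = "cohort") |>
      dplyr::left_join(dplyr::select(rows, "cohort", "predictor",
                                     "threshold"),
                       by = c("cohort", "predictor"))
  }
  paths <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      table2 = file.path(out_dir, "table2_metrics.csv"),
      ranking = file.path(out_dir, "ranking.csv"),
      roc_discovery = file.path(out_dir, "roc_discovery.csv"),
      roc_validation = file.path(out_dir, "roc_validation.csv"),
      log = file.path(out_dir, "evaluate_log.json")
    )
    readr::write_csv(table2, paths[["table2"]])
    if (!is.null(ranking)) readr::write_csv(ranking, paths[["ranking"]])
    readr::write_csv(roc_d$curve, paths[["roc_discovery"]])
    readr::write_csv(roc_v$curve, paths[["roc_validation"]])
    meta <- run_metadata(NA_integer_, nrow(discovery) + nrow(validation),
                         list(threshold = thr,
                              input_hash = rlang::hash(list(discovery,
                                                            validation,
                                                            sequence))))
    jsonlite::write_json(meta, paths[["log"]], auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(list(threshold = thr, stages_discovery = st_d,
                 stages_validation = st_v, roc_discovery = roc_d,
                 roc_validation = roc_v, table2 = table2,
                 ranking = ranking, paths = paths))
}

first_or <- function(x, default) {
  if (is.null(x) || length(x) == 0L) default else x[[1]]
}
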