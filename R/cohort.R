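#' Read a cohort table from CSV
#'
#' Reads a per-subject cohort table: one row per subject, columns
#' `subject_id`, `group` (`"N-MCI"` for stable subjects, `"P-MCI"` for
#' three-year converters), `cohort`, and one column per panel biomarker.
#' Missing values are written as empty cells or `NA` (any case) and are
#' preserved as `NA`, never imputed or zeroed. Rows whose group label is
#' not `N-MCI`/`P-MCI` are dropped with a warning.
#'
#' @param path Path to a comma-delimited UTF-8 file with a header row.
#' @param panel A panel tibble (see [care_panel()]); its names must be a
#'   subset of the file's columns.
#' @param required_cols Columns that must be present.
#' @return A tibble with biomarker columns coerced to numeric. The number
#'   of rejected rows is attached as attribute `n_rejected`.
#' @export
read_cohort <- function(path, panel = default_panel(),
                        required_cols = c("subject_id", "group", "cohort")) {
  raw <- tibble::as_tibble(utils::read.csv(
    path, na.strings = c("", "NA", "na", "Na", "nA"),
    check.names = FALSE, stringsAsFactors = FALSE))
  missing_req <- setdiff(required_cols, names(raw))
  if (length(missing_req) > 0L) {
    stop("cohort file ", path, " lacks required column(s): ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  }
  missing_bm <- setdiff(panel$name, names(raw))
  if (length(missing_bm) > 0L) {
    stop("cohort file ", path, " lacks panel biomarker column(s): ",
         paste(missing_bm, collapse = ", "), call. = FALSE)
  }
  raw <- dplyr::mutate(
    raw,
    subject_id = as.character(.data$subject_id),
    group = as.character(.data$group),
    dplyr::across(dplyr::all_of(panel$name), as.numeric)
  )
  ok <- !is.na(raw$group) & raw$group %in% c("N-MCI", "P-MCI")
  n_rejected <- sum(!ok)
  if (n_rejected > 0L) {
    warning(n_rejected, " row(s) with unparseable group label rejected",
            call. = FALSE)
    raw <- raw[ok, , drop = FALSE]
  }
  if (anyDuplicated(raw$subject_id)) {
    stop("duplicate subject_id: ",
         paste(unique(raw$subject_id[duplicated(raw$subject_id)]),
               collapse = ", "), call. = FALSE)
  }
  attr(raw, "n_rejected") <- n_rejected
  raw
}

#' Write a cohort table to CSV
#'
#' Missing values are written as `NA`; numeric values are written with 17
#' significant digits so a write/read cycle preserves every value and
#' missingness flag bit-exactly.
#'
#' @param data A cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  out <- dplyr::mutate(data, dplyr::across(
    dplyr::where(is.double),
    ~ ifelse(is.na(.x), NA_character_, sprintf("%.17g", .x))
  ))
  readr::write_csv(out, path, na = "NA")
  invisible(path)
}

#' Default cognitive domain map
#'
#' Maps neuropsychological tests to cognitive domains (episodic memory,
#' information processing speed, executive function, visuospatial function)
#' for composite z-scoring. Timed tests (trail making, Stroop) are flagged
#' `higher_better = FALSE` so longer completion times standardize to lower
#' (worse) z. The assignment is a configurable default: batteries differ
#' between studies, so callers with a different battery should supply their
#' own map with the same three columns.
#'
#' @return A tibble with columns `domain`, `test`, `higher_better`.
#' @export
default_domain_map <- function() {
  tibble::tribble(
    ~domain,                        ~test,              ~higher_better,
    "episodic_memory",              "AVLT_IR",          TRUE,
    "episodic_memory",              "AVLT_DR5",         TRUE,
    "episodic_memory",              "AVLT_DR20",        TRUE,
    "episodic_memory",              "LMT_IR",           TRUE,
    "episodic_memory",              "LMT_DR20",         TRUE,
    "episodic_memory",              "ROCFT_DR20",       TRUE,
    "information_processing_speed", "TMT_A",            FALSE,
    "information_processing_speed", "DSST",             TRUE,
    "information_processing_speed", "STROOP_A",         FALSE,
    "information_processing_speed", "STROOP_B",         FALSE,
    "executive_function",           "TMT_B",            FALSE,
    "executive_function",           "STROOP_C",         FALSE,
    "executive_function",           "VFT",              TRUE,
    "executive_function",           "DST_BACKWARD",     TRUE,
    "executive_function",           "SIMILARITY",       TRUE,
    "visuospatial_function",        "ROCFT_COPY",       TRUE,
    "visuospatial_function",        "CDT",              TRUE
  )
}

validate_domain_map <- function(map) {
  stopifnot(all(c("domain", "test", "higher_better") %in% names(map)))
  if (anyDuplicated(map$test)) {
    stop("each test may appear in at most one domain; duplicated: ",
         paste(unique(map$test[duplicated(map$test)]), collapse = ", "),
         call. = FALSE)
  }
  invisible(map)
}

#' Composite cognitive-domain z-scores
#'
#' Standardizes each test against reference moments, sign-flips tests where
#' a higher raw score means worse performance, and averages the available
#' standardized tests within each domain. After standardization a higher
#' composite always means better performance. The default reference is the
#' combined baseline sample of the table being analyzed (both outcome
#' groups pooled), appropriate when no separate healthy-control sample
#' exists.
#'
#' @param data Cohort tibble containing the test columns.
#' @param map Domain map tibble (see [default_domain_map()]).
#' @param reference Optional tibble with columns `test`, `mean`, `sd`
#'   giving the standardization moments; defaults to moments of `data`.
#' @return A tibble with `subject_id` and one z-score column per domain;
#'   a subject with no available test in a domain gets `NA` there.
#' @export
composite_z <- function(data, map = default_domain_map(), reference = NULL) {
  validate_domain_map(map)
  tests <- intersect(map$test, names(data))
  if (length(tests) == 0L) stop("no mapped test columns found in data", call. = FALSE)
  if (is.null(reference)) {
    # a test with no observed values cannot be standardized in-sample;
    # it is simply unavailable for every subject
    tests <- tests[vapply(tests, function(t) any(!is.na(data[[t]])),
                          logical(1))]
    if (length(tests) == 0L) {
      stop("no mapped test column has observed values", call. = FALSE)
    }
  }
  map <- dplyr::filter(map, .data$test %in% tests)
  if (is.null(reference)) {
    reference <- tibble::tibble(
      test = tests,
      mean = vapply(tests, function(t) mean(data[[t]], na.rm = TRUE), numeric(1)),
      sd   = vapply(tests, function(t) stats::sd(data[[t]], na.rm = TRUE), numeric(1))
    )
  }
  ref <- dplyr::filter(reference, .data$test %in% tests)
  bad_sd <- !is.finite(ref$sd) | ref$sd <= 0
  if (any(bad_sd)) {
    stop("degenerate reference (sd <= 0) for test(s): ",
         paste(ref$test[bad_sd], collapse = ", "), call. = FALSE)
  }
  long <- data |>
    dplyr::select("subject_id", dplyr::all_of(tests)) |>
    tidyr::pivot_longer(-"subject_id", names_to = "test", values_to = "raw") |>
    dplyr::left_join(ref, by = "test") |>
    dplyr::left_join(dplyr::select(map, "test", "domain", "higher_better"),
                     by = "test") |>
    dplyr::mutate(z = (.data$raw - .data$mean) / .data$sd,
                  z = ifelse(.data$higher_better, .data$z, -.data$z))
  long |>
    dplyr::group_by(.data$subject_id, .data$domain) |>
    dplyr::summarise(
      z = if (all(is.na(.data$z))) NA_real_ else mean(.data$z, na.rm = TRUE),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "domain", values_from = "z") |>
    dplyr::arrange(match(.data$subject_id, data$subject_id))
}

#' Follow-up minus baseline change scores
#'
#' Joins two waves on `subject_id` and returns per-subject differences
#' (follow-up minus baseline) for the named variables. Subjects absent at
#' either wave are dropped; the number dropped is attached as attribute
#' `n_dropped`.
#'
#' @param baseline,followup Cohort tibbles sharing `subject_id`.
#' @param variables Character vector of columns to difference.
#' @return A tibble with `subject_id` and one `delta_<variable>` column per
#'   variable.
#' @export
change_scores <- function(baseline, followup, variables) {
  miss_b <- setdiff(variables, names(baseline))
  miss_f <- setdiff(variables, names(followup))
  if (length(miss_b) || length(miss_f)) {
    stop("variables absent from input table(s): ",
         paste(unique(c(miss_b, miss_f)), collapse = ", "), call. = FALSE)
  }
  ids <- intersect(baseline$subject_id, followup$subject_id)
  if (length(ids) == 0L) stop("no subjects shared between waves", call. = FALSE)
  n_dropped <- length(union(baseline$subject_id, followup$subject_id)) -
    length(ids)
  b <- dplyr::filter(baseline, .data$subject_id %in% ids)
  f <- dplyr::filter(followup, .data$subject_id %in% ids)
  f <- f[match(b$subject_id, f$subject_id), , drop = FALSE]
  out <- tibble::tibble(subject_id = b$subject_id)
  for (v in variables) out[[paste0("delta_", v)]] <- f[[v]] - b[[v]]
  attr(out, "n_dropped") <- n_dropped
  out
}
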