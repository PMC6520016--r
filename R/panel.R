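#' Build a biomarker panel specification
#'
#' A panel is a tibble with one row per biomarker, recording its name, the
#' direction in which the measurement moves when the biomarker becomes
#' abnormal in Alzheimer's disease (its "event"), and free-text units.
#' Every downstream step (mixture fitting, event-sequence search, staging)
#' needs the direction to orient the event component of the density.
#'
#' @param name Character vector of unique biomarker names.
#' @param direction Character vector, each `"increase"` or `"decrease"`:
#'   the direction of change toward abnormality.
#' @param units Optional character vector of measurement units.
#' @return A tibble with columns `name`, `direction`, `units`.
#' @export
#' @examples
#' care_panel(c("MMSE", "PTAU"), c("decrease", "increase"))
care_panel <- function(name, direction, units = NA_character_) {
  name <- as.character(name)
  direction <- as.character(direction)
  if (length(direction) == 1L) direction <- rep(direction, length(name))
  if (length(units) == 1L) units <- rep(units, length(name))
  if (anyDuplicated(name)) {
    stop("biomarker names must be unique within a panel: ",
         paste(unique(name[duplicated(name)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- !direction %in% c("increase", "decrease")
  if (any(bad)) {
    stop("direction must be 'increase' or 'decrease' for every biomarker; ",
         "offending: ", paste(name[bad], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(name = name, direction = direction,
                 units = as.character(units))
}

#' The canonical ten-biomarker AD panel
#'
#' The ten biomarkers used to stage MCI subjects: three functional
#' connectivity indices (hippocampus, posterior cingulate, fusiform), two
#' gray-matter concentration indices (hippocampus, fusiform), two CSF
#' analytes (A-beta 1-42, p-tau), and three cognitive scores (MMSE,
#' ADAS-Cog, AVLT). Directions encode the abnormal direction in AD, e.g.
#' hippocampal FCI rises while PCC FCI falls.
#'
#' @return A panel tibble (see [care_panel()]).
#' @export
default_panel <- function() {
  care_panel(
    name = c("HIP_FCI", "PCC_FCI", "FG_FCI",
             "HIP_GMI", "FG_GMI",
             "ABETA", "PTAU",
             "MMSE", "ADAS_COG", "AVLT"),
    direction = c("increase", "decrease", "increase",
                  "decrease", "decrease",
                  "decrease", "increase",
                  "decrease", "increase", "decrease"),
    units = c("z", "z", "z", "fraction", "fraction",
              "pg/mL", "pg/mL", "points", "points", "words")
  )
}

#' The harmonized seven-biomarker panel
#'
#' Cohorts without CSF assays or the ADAS-Cog (e.g. a validation cohort
#' missing A-beta, p-tau and ADAS-Cog entirely) are staged on the shared
#' seven-biomarker subset. Restricting both cohorts to the shared panel
#' before model fitting, sequence search and staging is the supported
#' cross-cohort harmonization.
#'
#' @return A panel tibble with the CSF and ADAS-Cog rows removed.
#' @export
harmonized_panel <- function() {
  dplyr::filter(default_panel(),
                !.data$name %in% c("ABETA", "PTAU", "ADAS_COG"))
}

#' Restrict a panel to the columns shared by several cohort tables
#'
#' @param panel A panel tibble.
#' @param ... Cohort tibbles; the panel is restricted to biomarkers present
#'   as columns in all of them.
#' @return The restricted panel tibble.
#' @export
harmonize_panel <- function(panel, ...) {
  tables <- list(...)
  keep <- panel$name
  for (tb in tables) keep <- intersect(keep, names(tb))
  out <- dplyr::filter(panel, .data$name %in% keep)
  if (nrow(out) == 0L) stop("no shared biomarkers across cohorts", call. = FALSE)
  out
}

#' Read or write a panel as YAML
#'
#' @param path File path.
#' @param panel A panel tibble.
#' @return `read_panel()` returns a panel tibble; `write_panel()` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path) {
  spec <- yaml::read_yaml(path)
  care_panel(
    name = vapply(spec, function(b) b$name, character(1)),
    direction = vapply(spec, function(b) b$direction, character(1)),
    units = vapply(spec, function(b) b$units %||% NA_character_, character(1))
  )
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  yaml::write_yaml(purrr::pmap(panel, function(name, direction, units) {
    list(name = name, direction = direction, units = units)
  }), path)
  invisible(path)
}
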