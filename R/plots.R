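#' Plot a ROC curve
#'
#' @param object A `care_roc` object.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.care_roc <- function(object, ...) {
  tb <- object$curve
  opt <- tb[which.min(abs(tb$threshold - object$optimal_threshold)), ]
  ggplot2::ggplot(tb, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(data = opt, colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc),
      subtitle = sprintf("Optimal threshold %.2f: sens %.2f, spec %.2f",
                         object$optimal_threshold, opt$sensitivity,
                         opt$specificity)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the stage histogram by outcome group
#'
#' Counts of subjects at each maximum-likelihood stage (CARE index),
#' split by converter status.
#'
#' @param object A `care_stages` tibble from [stage_cohort()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.care_stages <- function(object, ...) {
  hist <- stage_histogram(object)
  ggplot2::ggplot(hist, ggplot2::aes(x = factor(.data$ml_stage),
                                     y = .data$n, fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(preserve = "single")) +
    ggplot2::labs(x = "CARE index stage", y = "Number of subjects",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot positional uncertainty of the event sequence
#'
#' Heatmap of the Metropolis positional-frequency matrix: how often each
#' biomarker occupied each sequence position. Rows are ordered by the
#' optimal sequence; a crisp diagonal means a well-identified ordering.
#'
#' @param object A `care_sequence_fit` with a sampled `position_freq`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.care_sequence_fit <- function(object, ...) {
  if (is.null(object$position_freq)) {
    stop("no positional-frequency matrix; rerun with mcmc_iter > 0",
         call. = FALSE)
  }
  freq <- object$position_freq
  tb <- tibble::as_tibble(freq, rownames = "biomarker") |>
    tidyr::pivot_longer(-"biomarker", names_to = "position",
                        values_to = "frequency") |>
    dplyr::mutate(position = as.integer(gsub("\\D", "", .data$position)),
                  biomarker = factor(.data$biomarker,
                                     levels = rev(object$sequence)))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$position, y = .data$biomarker,
                                   fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "Sequence position", y = NULL,
                  fill = "Frequency") +
    ggplot2::theme_minimal()
}

#' Plot fitted event/non-event densities
#'
#' Overlays the fitted non-event and event Gaussian components for each
#' biomarker, spanning both component means plus three scales on either
#' side.
#'
#' @param object A `care_event_models` object.
#' @param ... Ignored.
#' @return A ggplot facetted by biomarker.
#' @export
autoplot.care_event_models <- function(object, ...) {
  tb <- purrr::map_dfr(object$models, function(m) {
    lo <- min(m$mu_nonevent - 3 * m$sd_nonevent,
              m$mu_event - 3 * m$sd_event)
    hi <- max(m$mu_nonevent + 3 * m$sd_nonevent,
              m$mu_event + 3 * m$sd_event)
    x <- seq(lo, hi, length.out = 200)
    tibble::tibble(
      biomarker = m$name,
      x = rep(x, 2),
      density = c(stats::dnorm(x, m$mu_nonevent, m$sd_nonevent),
                  stats::dnorm(x, m$mu_event, m$sd_event)),
      component = rep(c("non-event", "event"), each = length(x))
    )
  })
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$x, y = .data$density,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~biomarker, scales = "free") +
    ggplot2::labs(x = NULL, y = "Density", colour = NULL) +
    ggplot2::theme_minimal()
}
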