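#' Fit event/non-event densities for each biomarker
#'
#' For each panel biomarker, fits a two-component Gaussian mixture to all
#' non-missing values by EM: one component models measurements before the
#' biomarker's abnormality event ("non-event"), the other after it
#' ("event"). The event component is constrained to lie on the abnormal
#' side of the non-event component in the biomarker's declared direction.
#' All subjects are pooled; with a purely MCI sample there are no healthy
#' or AD anchors, and the mixture itself separates the two regimes.
#'
#' Initialization places the component means at the 25th/75th percentiles
#' (ordered by abnormality direction) and both scales at half the sample
#' SD; the EM is restarted over a small grid of initial event weights and
#' initial mean quantiles, keeping the restart with the best final
#' log-likelihood. In a staging sample the fraction of subjects past a
#' given event can be far from one half (early events have occurred in
#' almost everyone, late events in almost no one), and a single
#' equal-weight start is prone to splitting the dominant component instead
#' of finding the minority one; the restart grid recovers those skewed
#' mixtures. By default the two components share one scale
#' (`shared_scale = TRUE`), which suppresses the same pathology.
#'
#' Variances are floored at `var_floor_frac` times the sample variance (a
#' floored fit is flagged and warned about). Convergence is declared when
#' the log-likelihood improves by less than `tol`, or at `max_iter`.
#'
#' @param data Cohort tibble with one column per panel biomarker.
#' @param panel Panel tibble; all its biomarkers must be columns of `data`.
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param var_floor_frac Variance floor as a fraction of sample variance.
#' @param shared_scale Constrain both components to one common scale.
#' @param init_weights Grid of initial event weights for EM restarts.
#' @return A `care_event_models` object: per-biomarker location/scale for
#'   both components, event mixing weight, and fit diagnostics. Inspect
#'   with [tidy()][generics::tidy] / [glance()][generics::glance].
#' @export
fit_event_models <- function(data, panel = default_panel(), tol = 1e-6,
                             max_iter = 500L, var_floor_frac = 1e-3,
                             shared_scale = TRUE,
                             init_weights = c(0.15, 0.3, 0.5, 0.7, 0.85)) {
  missing_bm <- setdiff(panel$name, names(data))
  if (length(missing_bm) > 0L) {
    stop("data lacks panel biomarker column(s): ",
         paste(missing_bm, collapse = ", "),
         "; harmonize the panel first (see harmonize_panel())", call. = FALSE)
  }
  models <- purrr::pmap(panel, function(name, direction, units) {
    cands <- list()
    for (w0 in init_weights) {
      cands[[length(cands) + 1L]] <- fit_gaussian_event_mixture(
        data[[name]], name, direction, tol = tol, max_iter = max_iter,
        var_floor_frac = var_floor_frac, shared_scale = shared_scale,
        init_weight = w0, init_quantiles = c(0.25, 0.75))
    }
    for (w0 in intersect(c(0.3, 0.7), init_weights)) {
      cands[[length(cands) + 1L]] <- fit_gaussian_event_mixture(
        data[[name]], name, direction, tol = tol, max_iter = max_iter,
        var_floor_frac = var_floor_frac, shared_scale = shared_scale,
        init_weight = w0, init_quantiles = c(0.10, 0.90))
    }
    best <- cands[[which.max(vapply(cands, function(m) m$loglik,
                                    numeric(1)))]]
    if (best$floored) {
      warning("biomarker ", name, ": variance floor applied during EM",
              call. = FALSE)
    }
    best
  })
  names(models) <- panel$name
  structure(list(family = "gaussian", panel = panel, models = models),
            class = "care_event_models")
}

# Constrained two-component Gaussian EM for one biomarker. The event
# component must sit on the abnormal side of the non-event component;
# a violating M-step is repaired by relabeling (which leaves the mixture
# density, hence the log-likelihood, unchanged).
fit_gaussian_event_mixture <- function(x, name, direction, tol = 1e-6,
                                       max_iter = 500L,
                                       var_floor_frac = 1e-3,
                                       shared_scale = TRUE,
                                       init_weight = 0.5,
                                       init_quantiles = c(0.25, 0.75)) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 10L) {
    stop("biomarker ", name, ": ", n,
         " non-missing observation(s); at least 10 required", call. = FALSE)
  }
  v <- stats::var(x)
  if (!is.finite(v) || v < .Machine$double.eps) {
    stop("biomarker ", name, ": degenerate values (zero variance)",
         call. = FALSE)
  }
  floor_v <- var_floor_frac * v
  q <- stats::quantile(x, init_quantiles, names = FALSE)
  if (direction == "increase") {
    mu_n <- q[1]; mu_e <- q[2]
  } else {
    mu_n <- q[2]; mu_e <- q[1]
  }
  sd_n <- sd_e <- sqrt(v) / 2
  w <- init_weight
  floored <- FALSE
  converged <- FALSE
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    de <- w * stats::dnorm(x, mu_e, sd_e)
    dn <- (1 - w) * stats::dnorm(x, mu_n, sd_n)
    tot <- pmax(de + dn, 1e-300)
    r <- de / tot
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    se <- sum(r); sn <- n - se
    w <- min(max(se / n, 1e-6), 1 - 1e-6)
    if (se > 0) mu_e <- sum(r * x) / se
    if (sn > 0) mu_n <- sum((1 - r) * x) / sn
    if (shared_scale) {
      vv <- (sum(r * (x - mu_e)^2) + sum((1 - r) * (x - mu_n)^2)) / n
      if (vv < floor_v) { vv <- floor_v; floored <- TRUE }
      ve <- vn <- vv
    } else {
      ve <- if (se > 0) sum(r * (x - mu_e)^2) / se else floor_v
      vn <- if (sn > 0) sum((1 - r) * (x - mu_n)^2) / sn else floor_v
      if (ve < floor_v) { ve <- floor_v; floored <- TRUE }
      if (vn < floor_v) { vn <- floor_v; floored <- TRUE }
    }
    sd_e <- sqrt(ve); sd_n <- sqrt(vn)
    violated <- (direction == "increase" && mu_e < mu_n) ||
      (direction == "decrease" && mu_e > mu_n)
    if (violated) {
      tmp <- mu_e; mu_e <- mu_n; mu_n <- tmp
      tmp <- sd_e; sd_e <- sd_n; sd_n <- tmp
      w <- 1 - w
    }
  }
  list(name = name, direction = direction,
       mu_nonevent = mu_n, sd_nonevent = sd_n,
       mu_event = mu_e, sd_event = sd_e,
       w_event = w, n = n, loglik = ll_trace[length(ll_trace)],
       iterations = length(ll_trace), converged = converged,
       floored = floored, ll_trace = ll_trace)
}

#' Construct an event-model set from explicit parameters
#'
#' Builds a `care_event_models` object from known component parameters
#' instead of fitting them — e.g. the generating densities of a synthetic
#' cohort, or parameters published elsewhere.
#'
#' @param panel Panel tibble.
#' @param params Tibble with columns `biomarker`, `mu_nonevent`,
#'   `sd_nonevent`, `mu_event`, `sd_event` and optionally `w_event`,
#'   covering every panel biomarker.
#' @return A `care_event_models` object.
#' @export
event_models <- function(panel, params) {
  params <- params[match(panel$name, params$biomarker), ]
  if (anyNA(params$biomarker)) {
    stop("params must cover every panel biomarker", call. = FALSE)
  }
  if (any(params$sd_nonevent <= 0) || any(params$sd_event <= 0)) {
    stop("scales must be positive", call. = FALSE)
  }
  models <- purrr::pmap(
    list(panel$name, panel$direction, params$mu_nonevent,
         params$sd_nonevent, params$mu_event, params$sd_event,
         if ("w_event" %in% names(params)) params$w_event else
           rep(0.5, nrow(params))),
    function(nm, dir, mn, sn, me, se, w) {
      list(name = nm, direction = dir, mu_nonevent = mn, sd_nonevent = sn,
           mu_event = me, sd_event = se, w_event = w, n = NA_integer_,
           loglik = NA_real_, iterations = NA_integer_, converged = NA,
           floored = NA, ll_trace = numeric(0))
    })
  names(models) <- panel$name
  structure(list(family = "gaussian", panel = panel, models = models),
            class = "care_event_models")
}

#' Event and non-event density of a measurement
#'
#' Evaluates the fitted densities `p(x | event occurred)` and
#' `p(x | event not occurred)` for one biomarker. A missing measurement
#' returns the neutral factor `(1, 1)`: in the staging likelihood a
#' missing biomarker is marginalized out, which amounts to dropping its
#' factor.
#'
#' @param models A `care_event_models` object.
#' @param x Numeric measurement(s); may contain `NA`.
#' @param biomarker Biomarker name.
#' @return A tibble with columns `p_event`, `p_nonevent` (one row per
#'   element of `x`).
#' @export
event_likelihoods <- function(models, x, biomarker) {
  m <- models$models[[biomarker]]
  if (is.null(m)) stop("unknown biomarker: ", biomarker, call. = FALSE)
  p_e <- ifelse(is.na(x), 1, stats::dnorm(x, m$mu_event, m$sd_event))
  p_n <- ifelse(is.na(x), 1, stats::dnorm(x, m$mu_nonevent, m$sd_nonevent))
  tibble::tibble(p_event = p_e, p_nonevent = p_n)
}

#' @export
tidy.care_event_models <- function(x, ...) {
  purrr::map_dfr(x$models, function(m) {
    tibble::tibble(
      biomarker = m$name, direction = m$direction,
      mu_nonevent = m$mu_nonevent, sd_nonevent = m$sd_nonevent,
      mu_event = m$mu_event, sd_event = m$sd_event,
      w_event = m$w_event, n = m$n, loglik = m$loglik,
      iterations = m$iterations, converged = m$converged,
      floored = m$floored
    )
  })
}

#' @export
glance.care_event_models <- function(x, ...) {
  tb <- tidy.care_event_models(x)
  tibble::tibble(
    family = x$family,
    n_biomarkers = nrow(tb),
    total_loglik = sum(tb$loglik),
    all_converged = all(tb$converged),
    any_floored = any(tb$floored)
  )
}

#' @export
print.care_event_models <- function(x, ...) {
  cat("Event/non-event density models (", x$family, "), ",
      length(x$models), " biomarkers\n", sep = "")
  print(tidy.care_event_models(x))
  invisible(x)
}

#' Serialize fitted event models to/from YAML
#'
#' Writes family and per-biomarker parameters so a model set fitted on a
#' discovery cohort can be reused to stage another cohort.
#'
#' @param models A `care_event_models` object.
#' @param path File path.
#' @return `read_event_models()` returns a `care_event_models` object;
#'   `write_event_models()` returns `path` invisibly.
#' @export
write_event_models <- function(models, path) {
  num <- function(x) sprintf("%.17g", x)  # full-precision round trip
  payload <- list(
    family = models$family,
    biomarkers = purrr::map(models$models, function(m) {
      list(name = m$name, direction = m$direction,
           mu_nonevent = num(m$mu_nonevent), sd_nonevent = num(m$sd_nonevent),
           mu_event = num(m$mu_event), sd_event = num(m$sd_event),
           w_event = num(m$w_event), n = m$n)
    })
  )
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' @rdname write_event_models
#' @export
read_event_models <- function(path) {
  payload <- yaml::read_yaml(path)
  models <- purrr::map(payload$biomarkers, function(m) {
    list(name = m$name, direction = m$direction,
         mu_nonevent = as.numeric(m$mu_nonevent),
         sd_nonevent = as.numeric(m$sd_nonevent),
         mu_event = as.numeric(m$mu_event),
         sd_event = as.numeric(m$sd_event),
         w_event = as.numeric(m$w_event), n = m$n, loglik = NA_real_,
         iterations = NA_integer_, converged = NA, floored = NA,
         ll_trace = numeric(0))
  })
  names(models) <- vapply(models, function(m) m$name, character(1))
  panel <- care_panel(
    name = names(models),
    direction = vapply(models, function(m) m$direction, character(1))
  )
  structure(list(family = payload$family, panel = panel, models = models),
            class = "care_event_models")
}
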