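# Per-subject log-density matrices under the fitted event models, in panel
# order. Missing measurements contribute log(1) = 0 in both matrices, which
# marginalizes them out of every stage term.
loglik_matrices <- function(data, models) {
  panel <- models$panel$name
  missing_bm <- setdiff(panel, names(data))
  if (length(missing_bm) > 0L) {
    stop("data lacks model biomarker column(s): ",
         paste(missing_bm, collapse = ", "), call. = FALSE)
  }
  n <- nrow(data)
  log_e <- log_n <- matrix(0, nrow = n, ncol = length(panel),
                           dimnames = list(NULL, panel))
  for (bm in panel) {
    x <- data[[bm]]
    obs <- !is.na(x)
    m <- models$models[[bm]]
    log_e[obs, bm] <- stats::dnorm(x[obs], m$mu_event, m$sd_event, log = TRUE)
    log_n[obs, bm] <- stats::dnorm(x[obs], m$mu_nonevent, m$sd_nonevent,
                                   log = TRUE)
  }
  list(log_event = log_e, log_nonevent = log_n,
       all_missing = rowSums(is.na(data[, panel, drop = FALSE])) ==
         length(panel))
}

# Stage-wise subject log-likelihoods for a permutation given precomputed
# matrices: column k is log L(k) = sum_{i<=k} log p(x_i|E) +
# sum_{i>k} log p(x_i|not E), k = 0..N.
stage_loglik_matrix <- function(log_e, log_n, perm) {
  n_bm <- length(perm)
  d <- (log_e - log_n)[, perm, drop = FALSE]
  base <- rowSums(log_n[, perm, drop = FALSE])
  cum <- d %*% upper.tri(diag(n_bm), diag = TRUE)
  cbind(base, base + cum, deparse.level = 0)
}

logsumexp_rows <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mx + log(rowSums(exp(m - mx)))
}

check_permutation <- function(sequence, panel) {
  if (length(sequence) != length(panel) ||
      !setequal(sequence, panel) || anyDuplicated(sequence)) {
    stop("sequence must be a permutation of the panel biomarkers (",
         paste(panel, collapse = ", "), ")", call. = FALSE)
  }
  invisible(sequence)
}

#' Event-based model log-likelihood of an event ordering
#'
#' Computes the data log-likelihood of an ordering of biomarker abnormality
#' events. Each subject's unknown stage k (the number of events that have
#' occurred) is marginalized under a uniform prior over 0..N: the subject
#' likelihood is `(1/(N+1)) * sum_k prod_{i<=k} p(x_i|E) * prod_{i>k}
#' p(x_i|not E)`, with missing biomarkers contributing a factor of 1.
#' Computed in log space with log-sum-exp for stability.
#'
#' @param data Cohort tibble with the model biomarker columns.
#' @param models A `care_event_models` object.
#' @param sequence Character vector: a permutation of the panel biomarkers.
#' @return The total log-likelihood (sum over subjects). Subjects with all
#'   biomarkers missing contribute exactly 0; their count is attached as
#'   attribute `n_all_missing`.
#' @export
sequence_loglik <- function(data, models, sequence) {
  check_permutation(sequence, models$panel$name)
  mats <- loglik_matrices(data, models)
  perm <- match(sequence, colnames(mats$log_event))
  m <- stage_loglik_matrix(mats$log_event, mats$log_nonevent, perm)
  ll <- sum(logsumexp_rows(m) - log(ncol(m)))
  attr(ll, "n_all_missing") <- sum(mats$all_missing)
  ll
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  idx <- 1L
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[idx]] <- append(p, n, after = pos - 1L)
      idx <- idx + 1L
    }
  }
  out
}

# Greedy ascent from one starting permutation over the swap + insertion
# neighborhood; deterministic first-encountered tie-breaking (a move is
# taken only if it strictly improves on the current best).
greedy_ascent <- function(log_e, log_n, start_perm) {
  perm <- start_perm
  n_bm <- length(perm)
  eval_perm <- function(p) {
    sum(logsumexp_rows(stage_loglik_matrix(log_e, log_n, p))) -
      nrow(log_e) * log(n_bm + 1)
  }
  cur <- eval_perm(perm)
  trajectory <- cur
  repeat {
    best_ll <- cur
    best_perm <- NULL
    for (i in seq_len(n_bm - 1L)) {        # pairwise swaps
      for (j in seq(i + 1L, n_bm)) {
        cand <- perm
        cand[c(i, j)] <- cand[c(j, i)]
        ll <- eval_perm(cand)
        if (ll > best_ll) { best_ll <- ll; best_perm <- cand }
      }
    }
    for (i in seq_len(n_bm)) {             # single-element insertions
      for (j in seq_len(n_bm)) {
        if (i == j) next
        cand <- append(perm[-i], perm[i], after = j - 1L)
        ll <- eval_perm(cand)
        if (ll > best_ll) { best_ll <- ll; best_perm <- cand }
      }
    }
    if (is.null(best_perm)) break
    perm <- best_perm
    cur <- best_ll
    trajectory <- c(trajectory, cur)
  }
  list(perm = perm, loglik = cur, trajectory = trajectory)
}

#' Estimate the optimal event sequence
#'
#' Searches for the maximum-likelihood ordering of biomarker abnormality
#' events by multi-start greedy ascent: each start is a random permutation,
#' and the search repeatedly takes the best strictly-improving pairwise
#' swap or single-element insertion until a local optimum is reached. The
#' best sequence across starts is returned. Optionally, a Metropolis
#' sampler over permutations (random-swap proposals at the data likelihood)
#' summarizes positional uncertainty as an N-by-N frequency matrix; the
#' sampler is diagnostic only and never redefines the optimum.
#'
#' @param data Cohort tibble.
#' @param models A `care_event_models` object.
#' @param n_starts Number of random restarts.
#' @param seed Optional integer seed; the result is deterministic given the
#'   seed and data.
#' @param initial_sequences Optional list of sequences (character
#'   permutations) used as additional warm starts before the random ones.
#' @param mcmc_iter Metropolis iterations (0 disables the sampler).
#' @param mcmc_burnin Burn-in iterations discarded from the frequency
#'   matrix.
#' @return A `care_sequence_fit` object: `sequence`, `loglik`, per-start
#'   `trajectories`, and (if sampled) `position_freq` whose rows (one per
#'   biomarker) sum to 1.
#' @export
find_optimal_sequence <- function(data, models, n_starts = 25L, seed = NULL,
                                  initial_sequences = NULL,
                                  mcmc_iter = 0L, mcmc_burnin = NULL) {
  panel <- models$panel$name
  n_bm <- length(panel)
  if (!is.null(seed)) set.seed(seed)
  mats <- loglik_matrices(data, models)
  log_e <- mats$log_event
  log_n <- mats$log_nonevent
  warm <- lapply(initial_sequences, function(sq) {
    check_permutation(sq, panel)
    match(sq, panel)
  })
  starts <- c(warm, lapply(seq_len(n_starts), function(s) {
    if (n_bm == 1L) 1L else sample.int(n_bm)
  }))
  best <- NULL
  trajectories <- vector("list", length(starts))
  for (s in seq_along(starts)) {
    res <- greedy_ascent(log_e, log_n, starts[[s]])
    trajectories[[s]] <- res$trajectory
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  position_freq <- NULL
  if (mcmc_iter > 0L && n_bm > 1L) {
    if (is.null(mcmc_burnin)) mcmc_burnin <- ceiling(mcmc_iter / 5)
    eval_perm <- function(p) {
      sum(logsumexp_rows(stage_loglik_matrix(log_e, log_n, p))) -
        nrow(log_e) * log(n_bm + 1)
    }
    perm <- best$perm
    cur <- best$loglik
    counts <- matrix(0, n_bm, n_bm, dimnames = list(panel, NULL))
    for (it in seq_len(mcmc_iter)) {
      ij <- sample.int(n_bm, 2L)
      cand <- perm
      cand[ij] <- cand[rev(ij)]
      ll <- eval_perm(cand)
      if (log(stats::runif(1)) < ll - cur) {
        perm <- cand
        cur <- ll
      }
      if (it > mcmc_burnin) {
        counts[cbind(perm, seq_len(n_bm))] <- counts[cbind(perm, seq_len(n_bm))] + 1
      }
    }
    position_freq <- counts / rowSums(counts)
  }
  structure(
    list(sequence = panel[best$perm], loglik = best$loglik,
         trajectories = trajectories, position_freq = position_freq,
         n_starts = n_starts, seed = seed, n_subjects = nrow(data),
         n_all_missing = sum(mats$all_missing)),
    class = "care_sequence_fit"
  )
}

#' Exhaustive event-sequence search
#'
#' Enumerates all N! orderings and returns the maximum-likelihood one.
#' Feasible only for small panels; used as the ground-truth optimum when
#' validating the greedy search.
#'
#' @inheritParams find_optimal_sequence
#' @param max_n Refuse panels larger than this (N! blow-up guard).
#' @return A `care_sequence_fit` object.
#' @export
exhaustive_sequence_search <- function(data, models, max_n = 8L) {
  panel <- models$panel$name
  n_bm <- length(panel)
  if (n_bm > max_n) {
    stop("exhaustive search over ", n_bm, "! permutations refused; ",
         "raise max_n deliberately if you mean it", call. = FALSE)
  }
  mats <- loglik_matrices(data, models)
  best_ll <- -Inf
  best_perm <- seq_len(n_bm)
  for (p in all_permutations(n_bm)) {
    ll <- sum(logsumexp_rows(
      stage_loglik_matrix(mats$log_event, mats$log_nonevent, p))) -
      nrow(data) * log(n_bm + 1)
    if (ll > best_ll) {
      best_ll <- ll
      best_perm <- p
    }
  }
  structure(
    list(sequence = panel[best_perm], loglik = best_ll,
         trajectories = list(), position_freq = NULL,
         n_starts = NA_integer_, seed = NULL, n_subjects = nrow(data),
         n_all_missing = sum(mats$all_missing)),
    class = "care_sequence_fit"
  )
}

#' @export
tidy.care_sequence_fit <- function(x, ...) {
  tibble::tibble(position = seq_along(x$sequence), biomarker = x$sequence)
}

#' @export
glance.care_sequence_fit <- function(x, ...) {
  tibble::tibble(
    loglik = as.numeric(x$loglik),
    n_biomarkers = length(x$sequence),
    n_starts = x$n_starts,
    n_subjects = x$n_subjects,
    n_all_missing = x$n_all_missing
  )
}

#' @export
print.care_sequence_fit <- function(x, ...) {
  cat("Optimal event sequence (log-likelihood ",
      format(x$loglik, digits = 8), "):\n", sep = "")
  cat(paste0("  ", seq_along(x$sequence), ") ", x$sequence, collapse = "\n"),
      "\n")
  invisible(x)
}

#' Save / load a sequence fit as JSON
#'
#' @param fit A `care_sequence_fit` object.
#' @param path File path.
#' @return `read_sequence_fit()` returns a `care_sequence_fit`;
#'   `write_sequence_fit()` returns `path` invisibly.
#' @export
write_sequence_fit <- function(fit, path) {
  payload <- list(sequence = fit$sequence, loglik = as.numeric(fit$loglik),
                  n_starts = fit$n_starts, seed = fit$seed,
                  n_subjects = fit$n_subjects)
  if (!is.null(fit$position_freq)) {
    payload$position_freq <- as.data.frame(fit$position_freq)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sequence_fit
#' @export
read_sequence_fit <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(sequence = payload$sequence, loglik = payload$loglik,
         trajectories = list(),
         position_freq = if (!is.null(payload$position_freq))
           as.matrix(payload$position_freq),
         n_starts = payload$n_starts, seed = payload$seed,
         n_subjects = payload$n_subjects, n_all_missing = NA_integer_),
    class = "care_sequence_fit"
  )
}
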