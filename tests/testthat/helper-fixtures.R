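# Hand-specified event-model sets and independent oracles used across the
# suite. The oracles enumerate stages / pairs directly with plain loops so
# they share no code path with the package internals they check.

toy_models <- function(names, directions, mu_n, sd_n, mu_e, sd_e,
                       w = 0.5) {
  panel <- care_panel(names, directions)
  models <- purrr::pmap(
    list(names, directions, mu_n, sd_n, mu_e, sd_e),
    function(nm, dir, mn, sn, me, se) {
      list(name = nm, direction = dir,
           mu_nonevent = mn, sd_nonevent = sn,
           mu_event = me, sd_event = se,
           w_event = w, n = NA_integer_, loglik = NA_real_,
           iterations = NA_integer_, converged = TRUE, floored = FALSE,
           ll_trace = numeric(0))
    })
  names(models) <- names
  structure(list(family = "gaussian", panel = panel, models = models),
            class = "care_event_models")
}

# three biomarkers with distinct hand-picked densities
toy3 <- function() {
  toy_models(c("A", "B", "C"), c("increase", "decrease", "increase"),
             mu_n = c(0, 5, 10), sd_n = c(1, 2, 1.5),
             mu_e = c(3, 1, 14), sd_e = c(1, 2, 1.5))
}

# stage likelihoods by direct enumeration: L(k) = prod_{i<=k} p(x|E) *
# prod_{i>k} p(x|nonE); missing values contribute 1
oracle_stage_lik <- function(values, models, sequence) {
  n_bm <- length(sequence)
  l <- numeric(n_bm + 1)
  for (k in 0:n_bm) {
    term <- 1
    for (i in seq_len(n_bm)) {
      m <- models$models[[sequence[i]]]
      x <- values[[sequence[i]]]
      if (is.na(x)) next
      term <- term * if (i <= k) {
        dnorm(x, m$mu_event, m$sd_event)
      } else {
        dnorm(x, m$mu_nonevent, m$sd_nonevent)
      }
    }
    l[k + 1] <- term
  }
  l
}

oracle_sequence_loglik <- function(data, models, sequence) {
  total <- 0
  for (s in seq_len(nrow(data))) {
    l <- oracle_stage_lik(data[s, ], models, sequence)
    total <- total + log(mean(l))
  }
  total
}

# AUC by exhaustive pair counting with half credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

kendall_tau_seq <- function(found, truth) {
  cor(match(found, truth), seq_along(found), method = "kendall")
}

# event-model set carrying the generator's true densities for a panel
true_models_from_config <- function(cfg, panel = cfg$panel) {
  d <- cfg$densities[match(panel$name, cfg$densities$biomarker), ]
  toy_models(panel$name, panel$direction,
             mu_n = d$mu_nonevent, sd_n = d$sd_nonevent,
             mu_e = d$mu_event, sd_e = d$sd_event)
}
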