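resolve_binary_labels <- function(truth, positive) {
  if (is.logical(truth)) return(truth)
  truth == positive
}

#' ROC curve of a continuous score against a binary outcome
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' sorted scores plus one sentinel below and one above all scores; a
#' subject is called positive when `score >= threshold`. The AUC is the
#' trapezoidal area, which equals the Mann-Whitney concordance probability
#' with ties counted half.
#'
#' @param data Tibble containing the score and outcome columns.
#' @param score Unquoted column with the continuous score (e.g. the
#'   expected CARE stage).
#' @param truth Unquoted column with the outcome; either logical or
#'   compared against `positive`.
#' @param positive Value of `truth` labelling the positive class.
#' @return A `care_roc` object with the per-threshold curve, the AUC, and
#'   the Youden-optimal threshold (see [optimal_threshold()]).
#' @export
roc_curve <- function(data, score, truth, positive = "P-MCI") {
  s <- dplyr::pull(data, {{ score }})
  y <- resolve_binary_labels(dplyr::pull(data, {{ truth }}), positive)
  keep <- !is.na(s) & !is.na(y)
  s <- s[keep]; y <- y[keep]
  if (!any(y) || all(y)) {
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  }
  su <- sort(unique(s))
  thresholds <- if (length(su) == 1L) {
    c(su - 1, su + 1)
  } else {
    c(su[1] - diff(range(su)) / 2,
      (su[-1] + su[-length(su)]) / 2,
      su[length(su)] + diff(range(su)) / 2)
  }
  pos <- s[y]; neg <- s[!y]
  sens <- vapply(thresholds, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(neg < t), numeric(1))
  curve <- tibble::tibble(threshold = thresholds, sensitivity = sens,
                          specificity = spec,
                          youden = sens + spec - 1)
  fpr <- 1 - curve$specificity
  ord <- order(fpr, curve$sensitivity)
  x <- c(0, fpr[ord], 1)
  yy <- c(0, curve$sensitivity[ord], 1)
  auc <- sum(diff(x) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
  out <- structure(
    list(curve = curve, auc = auc, n_pos = length(pos), n_neg = length(neg),
         positive = positive),
    class = "care_roc"
  )
  out$optimal_threshold <- optimal_threshold(out)
  out
}

#' Youden-optimal threshold of a ROC curve
#'
#' Returns the candidate threshold maximizing Youden's
#' J = sensitivity + specificity - 1. Ties are broken toward higher
#' specificity (fewer false alarms), then toward the lower threshold.
#'
#' @param curve A `care_roc` object.
#' @return The optimal threshold (numeric scalar).
#' @export
optimal_threshold <- function(curve) {
  tb <- curve$curve
  eps <- 1e-12
  best_j <- max(tb$youden)
  cand <- tb[tb$youden >= best_j - eps, , drop = FALSE]
  cand <- cand[cand$specificity >= max(cand$specificity) - eps, ,
               drop = FALSE]
  min(cand$threshold)
}

#' @export
tidy.care_roc <- function(x, ...) x$curve

#' @export
glance.care_roc <- function(x, ...) {
  at <- x$curve[which.min(abs(x$curve$threshold - x$optimal_threshold)), ]
  tibble::tibble(
    auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg,
    optimal_threshold = x$optimal_threshold,
    sensitivity = at$sensitivity, specificity = at$specificity,
    youden = at$youden
  )
}

#' @export
print.care_roc <- function(x, ...) {
  g <- glance.care_roc(x)
  cat("ROC curve: AUC ", format(g$auc, digits = 4),
      " (", x$n_pos, " positive / ", x$n_neg, " negative)\n",
      "Optimal threshold ", format(g$optimal_threshold, digits = 4),
      ": sensitivity ", format(g$sensitivity, digits = 4),
      ", specificity ", format(g$specificity, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Diagnostic metrics of a 2x2 threshold-by-outcome table
#'
#' From the counts a (called positive, converter), b (called positive,
#' non-converter), c (called negative, converter), d (called negative,
#' non-converter) computes sensitivity `a/(a+c)`, specificity `d/(b+d)`,
#' accuracy, balanced accuracy `(sens+spec)/2`, the diagnostic odds ratio
#' `ad/(bc)` with Woolf's log-method 95% CI, and the relative risk
#' `[a/(a+b)]/[c/(c+d)]` with Katz's log-method 95% CI. When a zero cell
#' occurs, Haldane's 0.5 correction is applied to the OR/RR and CIs and the
#' result is flagged.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @param conf_level Confidence level for the Woolf/Katz intervals.
#' @return A one-row tibble with the counts, metrics, CI bounds, and a
#'   `haldane` flag.
#' @export
contingency_metrics <- function(a, b, c, d, conf_level = 0.95) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  sens <- if (a + c > 0) a / (a + c) else NA_real_
  spec <- if (b + d > 0) d / (b + d) else NA_real_
  acc <- (a + d) / sum(counts)
  bal <- (sens + spec) / 2
  haldane <- any(counts == 0)
  if (haldane) {
    warning("zero cell: Haldane 0.5 correction applied to OR/RR",
            call. = FALSE)
  }
  k <- counts + if (haldane) 0.5 else 0
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  or <- (k["a"] * k["d"]) / (k["b"] * k["c"])
  se_or <- sqrt(sum(1 / k))
  rr <- (k["a"] / (k["a"] + k["b"])) / (k["c"] / (k["c"] + k["d"]))
  se_rr <- sqrt(1 / k["a"] - 1 / (k["a"] + k["b"]) +
                  1 / k["c"] - 1 / (k["c"] + k["d"]))
  tibble::tibble(
    a = a, b = b, c = c, d = d,
    sensitivity = sens, specificity = spec,
    accuracy = acc, balanced_accuracy = bal,
    or = unname(or),
    or_low = unname(exp(log(or) - z * se_or)),
    or_high = unname(exp(log(or) + z * se_or)),
    rr = unname(rr),
    rr_low = unname(exp(log(rr) - z * se_rr)),
    rr_high = unname(exp(log(rr) + z * se_rr)),
    haldane = haldane
  )
}

#' Apply a fixed threshold to a cohort's scores
#'
#' Classifies `score >= threshold` as a predicted converter and returns
#' the full diagnostic-metric table. This is the external-validation
#' operation: a cutoff learned on a discovery cohort is applied unchanged
#' to an independent cohort.
#'
#' @inheritParams roc_curve
#' @param threshold Finite numeric cutoff.
#' @return A one-row tibble: `threshold` plus all [contingency_metrics()]
#'   columns.
#' @export
transfer_threshold <- function(data, score, truth, threshold,
                               positive = "P-MCI") {
  stopifnot(is.finite(threshold))
  s <- dplyr::pull(data, {{ score }})
  y <- resolve_binary_labels(dplyr::pull(data, {{ truth }}), positive)
  keep <- !is.na(s) & !is.na(y)
  s <- s[keep]; y <- y[keep]
  pred <- s >= threshold
  out <- contingency_metrics(sum(pred & y), sum(pred & !y),
                             sum(!pred & y), sum(!pred & !y))
  dplyr::bind_cols(tibble::tibble(threshold = threshold), out)
}

delong_placements <- function(s, y) {
  pos <- s[y]; neg <- s[!y]
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)),
                numeric(1))
  v01 <- vapply(neg, function(x) mean((pos > x) + 0.5 * (pos == x)),
                numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Compare two correlated AUCs (DeLong test)
#'
#' Paired nonparametric comparison of the AUCs of two scores measured on
#' the same subjects, using the DeLong structural-components covariance.
#' Two-sided p-value from the normal reference.
#'
#' @param data Tibble containing both score columns and the outcome.
#' @param score_a,score_b Unquoted score columns.
#' @inheritParams roc_curve
#' @return A one-row tibble: `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
compare_aucs <- function(data, score_a, score_b, truth,
                         positive = "P-MCI") {
  sa <- dplyr::pull(data, {{ score_a }})
  sb <- dplyr::pull(data, {{ score_b }})
  y <- resolve_binary_labels(dplyr::pull(data, {{ truth }}), positive)
  keep <- !is.na(sa) & !is.na(sb) & !is.na(y)
  sa <- sa[keep]; sb <- sb[keep]; y <- y[keep]
  if (!any(y) || all(y)) stop("both classes required", call. = FALSE)
  pa <- delong_placements(sa, y)
  pb <- delong_placements(sb, y)
  m <- sum(y); n <- sum(!y)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (var_diff <= .Machine$double.eps) {
    z <- 0
  } else {
    z <- (pa$auc - pb$auc) / sqrt(var_diff)
  }
  tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)))
}

#' Rank predictors on each diagnostic metric
#'
#' Ranks every numeric metric column across predictors (1 = best, higher
#' metric better, ties sharing the lower rank number), optionally within
#' cohorts, producing the metric-plus-rank comparison layout used to set a
#' composite staging score against its single-biomarker components.
#'
#' @param metrics Tibble with a `predictor` column and numeric metric
#'   columns (e.g. `auc`, `sensitivity`, `specificity`, `accuracy`,
#'   `balanced_accuracy`).
#' @param by Optional grouping column name (e.g. `"cohort"`): ranks are
#'   computed within groups.
#' @return `metrics` with an added `rank_<metric>` column per metric.
#' @export
ranking_table <- function(metrics, by = NULL) {
  if (nrow(metrics) < 2L) {
    stop("ranking requires at least two predictors", call. = FALSE)
  }
  metric_cols <- setdiff(names(metrics)[vapply(metrics, is.numeric,
                                               logical(1))], by)
  grouped <- if (!is.null(by)) {
    dplyr::group_by(metrics, dplyr::across(dplyr::all_of(by)))
  } else {
    metrics
  }
  out <- dplyr::mutate(
    grouped,
    dplyr::across(dplyr::all_of(metric_cols),
                  ~ rank(-.x, ties.method = "min"),
                  .names = "rank_{.col}")
  )
  dplyr::ungroup(out)
}
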