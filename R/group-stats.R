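#' Two-sample t-test with a Levene-gated variance rule
#'
#' Compares a continuous variable between two groups. Under
#' `variance_rule = "auto"` Levene's test (centered at the group means) at
#' alpha = 0.05 selects the pooled-variance t-test when variances look
#' equal and Welch's otherwise — the gate common in clinical reporting
#' software, which is what makes published tables built from such software
#' reproducible. The statistic's sign follows `mean(first group) -
#' mean(second group)`, groups ordered by factor level or first appearance.
#'
#' @param data Tibble with value and group columns.
#' @param value Unquoted numeric column.
#' @param group Unquoted two-level grouping column.
#' @param variance_rule `"auto"`, `"pooled"`, or `"welch"`.
#' @return A one-row tibble: `variable`, `test` ("pooled-t" or "welch-t"),
#'   `statistic`, `df`, `p_value`, per-group mean/sd/n, and the Levene p
#'   when the gate ran.
#' @export
two_sample_t <- function(data, value, group,
                         variance_rule = c("auto", "pooled", "welch")) {
  variance_rule <- match.arg(variance_rule)
  v <- dplyr::pull(data, {{ value }})
  g <- dplyr::pull(data, {{ group }})
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  g <- if (is.factor(g)) droplevels(g) else factor(g, levels = unique(g))
  if (nlevels(g) != 2L) stop("group must have exactly two levels", call. = FALSE)
  x <- v[g == levels(g)[1]]
  y <- v[g == levels(g)[2]]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  levene_p <- NA_real_
  if (variance_rule == "auto") {
    absdev <- abs(v - stats::ave(v, g))
    levene_p <- stats::anova(stats::lm(absdev ~ g))[["Pr(>F)"]][1]
    variance_rule <- if (levene_p < 0.05) "welch" else "pooled"
  }
  ht <- stats::t.test(x, y, var.equal = variance_rule == "pooled")
  tibble::tibble(
    variable = rlang::as_name(rlang::enquo(value)),
    test = if (variance_rule == "pooled") "pooled-t" else "welch-t",
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_x = mean(x), sd_x = stats::sd(x), n_x = length(x),
    mean_y = mean(y), sd_y = stats::sd(y), n_y = length(y),
    levene_p = levene_p
  )
}

#' Two-sample t statistic from printed summary statistics
#'
#' Computes the pooled or Welch t-test from group means, SDs and sizes —
#' the only inputs available when working from a published demographics
#' table. The equal-variance gate cannot run on summaries, so the rule
#' must be chosen explicitly.
#'
#' @param mean_x,sd_x,n_x First group's summary statistics.
#' @param mean_y,sd_y,n_y Second group's summary statistics.
#' @param variance_rule `"pooled"` or `"welch"`.
#' @return A one-row tibble: `test`, `statistic`, `df`, `p_value`.
#' @export
t_from_summary <- function(mean_x, sd_x, n_x, mean_y, sd_y, n_y,
                           variance_rule = c("pooled", "welch")) {
  variance_rule <- match.arg(variance_rule)
  if (variance_rule == "pooled") {
    sp2 <- ((n_x - 1) * sd_x^2 + (n_y - 1) * sd_y^2) / (n_x + n_y - 2)
    se <- sqrt(sp2 * (1 / n_x + 1 / n_y))
    df <- n_x + n_y - 2
  } else {
    a <- sd_x^2 / n_x
    b <- sd_y^2 / n_y
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n_x - 1) + b^2 / (n_y - 1))
  }
  stat <- (mean_x - mean_y) / se
  tibble::tibble(
    test = if (variance_rule == "pooled") "pooled-t" else "welch-t",
    statistic = stat, df = df,
    p_value = 2 * stats::pt(-abs(stat), df)
  )
}

#' Pearson chi-square test of a 2x2 table
#'
#' Without continuity correction, as used for comparing conversion rates
#' or sex ratios between cohorts.
#'
#' @param a,b,c,d Cell counts, row-wise: the table is
#'   `rbind(c(a, b), c(c, d))`.
#' @return A one-row tibble: `test`, `statistic`, `df`, `p_value`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  m <- rbind(c(a, b), c(c, d))
  if (sum(m) <= 0) stop("table total must be positive", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero row or column margin", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble::tibble(test = "chi-square",
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of a continuous score (e.g. the CARE stage)
#' between two groups. Reports the U statistic for the first group. With
#' at most 8 subjects per group and no ties the exact two-sided p is used;
#' otherwise the tie-corrected normal approximation (no continuity
#' correction). When every pairing is tied the statistic carries no
#' information and p = 1.
#'
#' @inheritParams two_sample_t
#' @return A one-row tibble: `test`, `statistic` (U), `p_value`, `exact`,
#'   `n_x`, `n_y`.
#' @export
mann_whitney <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- dplyr::pull(data, {{ group }})
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  g <- if (is.factor(g)) droplevels(g) else factor(g, levels = unique(g))
  if (nlevels(g) != 2L) stop("group must have exactly two levels", call. = FALSE)
  x <- v[g == levels(g)[1]]
  y <- v[g == levels(g)[2]]
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !has_ties && nx <= 8L && ny <= 8L
  if (use_exact) {
    p <- 2 * min(stats::pwilcox(u, nx, ny),
                 1 - stats::pwilcox(u - 1, nx, ny))
    p <- min(p, 1)
  } else {
    n <- nx + ny
    ties <- table(c(x, y))
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= .Machine$double.eps) {
      p <- 1
    } else {
      z <- (u - nx * ny / 2) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  tibble::tibble(test = "mann-whitney", statistic = u, p_value = p,
                 exact = use_exact, n_x = nx, n_y = ny)
}

#' Change-score regressions with FDR correction
#'
#' Fits one linear model per outcome, regressing each outcome change score
#' on the change in CARE index (plus optional covariates), and adjusts the
#' CARE-slope p-values across outcomes by Benjamini-Hochberg. A negative
#' slope means a rising CARE index (worsening stage) accompanies declining
#' performance on that outcome.
#'
#' @param data Tibble with all columns.
#' @param dcare Unquoted column: change in CARE index.
#' @param outcomes Tidy-selection of outcome change-score columns.
#' @param covariates Optional tidy-selection of covariate columns
#'   (typically age, sex, education).
#' @return A tibble with one row per outcome: `outcome`, `estimate`
#'   (CARE slope), `std_error`, `statistic`, `p_value`, `q_value` (BH),
#'   `n`.
#' @export
change_regressions <- function(data, dcare, outcomes, covariates = NULL) {
  dc <- rlang::as_name(rlang::enquo(dcare))
  out_cols <- names(dplyr::select(data, {{ outcomes }}))
  cov_cols <- names(dplyr::select(data, {{ covariates }}))
  n_pred <- 1L + length(cov_cols)
  results <- purrr::map_dfr(out_cols, function(oc) {
    dat <- data[, c(oc, dc, cov_cols)]
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    if (nrow(dat) <= n_pred + 2L) {
      stop("outcome ", oc, ": n = ", nrow(dat),
           " too small for ", n_pred, " predictor(s)", call. = FALSE)
    }
    fml <- stats::reformulate(c(dc, cov_cols), response = oc)
    fit <- stats::lm(fml, data = dat)
    if (anyNA(stats::coef(fit))) {
      stop("rank-deficient design for outcome ", oc, "; collinear column(s): ",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                 collapse = ", "), call. = FALSE)
    }
    cf <- summary(fit)$coefficients[dc, ]
    tibble::tibble(outcome = oc, estimate = cf[["Estimate"]],
                   std_error = cf[["Std. Error"]],
                   statistic = cf[["t value"]],
                   p_value = cf[["Pr(>|t|)"]], n = nrow(dat))
  })
  results$q_value <- stats::p.adjust(results$p_value, method = "BH")
  results
}
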