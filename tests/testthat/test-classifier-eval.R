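roc_tbl <- function(scores, labels) {
  tibble::tibble(score = scores, truth = labels)
}

test_that("roc_curve handles separation, ties and the worked 4-point example", {
  perfect <- roc_tbl(c(1, 2, 3, 10, 11, 12),
                     c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  r <- roc_curve(perfect, score, truth)
  expect_equal(r$auc, 1)
  expect_true(any(r$curve$sensitivity == 1 & r$curve$specificity == 1))

  four <- roc_tbl(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE))
  r4 <- roc_curve(four, score, truth)
  expect_equal(r4$auc, 0.75)  # 3 concordant of 4 pairs

  ties <- roc_tbl(rep(2.2, 8), rep(c(TRUE, FALSE), 4))
  rt <- roc_curve(ties, score, truth)
  expect_equal(rt$auc, 0.5)

  expect_error(roc_curve(roc_tbl(1:4, rep(TRUE, 4)), score, truth),
               "both classes")
})

test_that("trapezoidal AUC equals exhaustive pair counting", {
  set.seed(23)
  for (rep in 1:40) {
    n <- sample(4:30, 1)
    scores <- round(rnorm(n), 1)  # rounding induces ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(labels) || !any(labels)) next
    r <- roc_curve(roc_tbl(scores, labels), score, truth)
    expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(29)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.4) == 1
  r <- roc_curve(roc_tbl(scores, labels), score, truth)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(r$auc, ref, tolerance = 1e-10)
})

test_that("optimal_threshold maximizes Youden with spec-then-low tie-breaks", {
  four <- roc_tbl(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE))
  r4 <- roc_curve(four, score, truth)
  thr <- optimal_threshold(r4)
  expect_gt(thr, 0.4)
  expect_lte(thr, 0.8)
  at <- r4$curve[r4$curve$threshold == thr, ]
  expect_equal(at$sensitivity, 0.5)
  expect_equal(at$specificity, 1)

  ties <- roc_tbl(rep(1, 6), rep(c(TRUE, FALSE), 3))
  rt <- roc_curve(ties, score, truth)
  expect_equal(max(rt$curve$youden), 0)

  perfect <- roc_tbl(c(1, 2, 8, 9), c(FALSE, FALSE, TRUE, TRUE))
  rp <- roc_curve(perfect, score, truth)
  at_p <- rp$curve[rp$curve$threshold == rp$optimal_threshold, ]
  expect_equal(at_p$youden, 1)
})

test_that("contingency_metrics satisfies its identities and edge rules", {
  flat <- contingency_metrics(1, 1, 1, 1)
  expect_equal(flat$or, 1)
  expect_equal(flat$rr, 1)
  expect_equal(flat$sensitivity, 0.5)
  expect_equal(flat$specificity, 0.5)
  expect_equal(flat$accuracy, 0.5)

  expect_error(contingency_metrics(-1, 2, 3, 4), "non-negative")

  expect_warning(z <- contingency_metrics(5, 0, 3, 7), "Haldane")
  expect_true(z$haldane)
  expect_true(is.finite(z$or_high))

  # OR invariant under simultaneous row and column swap; balanced accuracy
  set.seed(17)
  for (rep in 1:20) {
    k <- as.list(sample(1:30, 4, replace = TRUE))
    m1 <- contingency_metrics(k[[1]], k[[2]], k[[3]], k[[4]])
    m2 <- contingency_metrics(k[[4]], k[[3]], k[[2]], k[[1]])
    expect_equal(m1$or, m2$or, tolerance = 1e-12)
    expect_equal(m1$balanced_accuracy,
                 (m1$sensitivity + m1$specificity) / 2, tolerance = 1e-12)
  }
})

test_that("transfer_threshold classifies by score >= threshold", {
  dat <- roc_tbl(c(1, 2, 3, 4), c(TRUE, FALSE, TRUE, FALSE))
  lo <- suppressWarnings(transfer_threshold(dat, score, truth, 0))
  expect_equal(lo$sensitivity, 1)
  expect_equal(lo$specificity, 0)
  hi <- suppressWarnings(transfer_threshold(dat, score, truth, 100))
  expect_equal(hi$sensitivity, 0)
  expect_equal(hi$specificity, 1)

  # validation-style fixture engineered to the published count pattern
  scores <- c(seq(6.6, 7.8, length.out = 13), seq(5.0, 6.4, length.out = 3),
              seq(6.7, 7.1, length.out = 5), seq(3.0, 6.3, length.out = 35))
  labels <- rep(c(TRUE, FALSE), c(16, 40))
  tr <- transfer_threshold(roc_tbl(scores, labels), score, truth, 6.54)
  expect_equal(c(tr$a, tr$b, tr$c, tr$d), c(13, 5, 3, 35))
  expect_equal(round(tr$or, 2), 30.33)
  expect_equal(round(tr$rr, 2), 9.15)
})

test_that("the optimal threshold round-trips through transfer_threshold", {
  set.seed(37)
  for (rep in 1:10) {
    scores <- rnorm(40)
    labels <- rbinom(40, 1, 0.3) == 1
    if (all(labels) || !any(labels)) next
    r <- roc_curve(roc_tbl(scores, labels), score, truth)
    at <- r$curve[r$curve$threshold == r$optimal_threshold, ]
    tr <- suppressWarnings(
      transfer_threshold(roc_tbl(scores, labels), score, truth,
                         r$optimal_threshold))
    expect_equal(tr$sensitivity, at$sensitivity, tolerance = 1e-12)
    expect_equal(tr$specificity, at$specificity, tolerance = 1e-12)
  }
})

test_that("compare_aucs degenerates correctly and matches a brute-force oracle", {
  dat <- tibble::tibble(s1 = c(1, 2, 3, 4, 5, 6),
                        s2 = c(1, 2, 3, 4, 5, 6) + 10,
                        y = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE))
  same <- compare_aucs(dplyr::mutate(dat, s2 = s1), s1, s2, y)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)

  shifted <- compare_aucs(dat, s1, s2, y)  # rank-preserving shift
  expect_equal(shifted$z, 0)

  # 6-subject example: placement values computed directly
  d6 <- tibble::tibble(sa = c(0.9, 0.4, 0.7, 0.2, 0.5, 0.1),
                       sb = c(0.8, 0.3, 0.2, 0.6, 0.4, 0.5),
                       y = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  got <- compare_aucs(d6, sa, sb, y)
  v10 <- function(s) vapply(s[d6$y], function(x)
    mean((x > s[!d6$y]) + 0.5 * (x == s[!d6$y])), numeric(1))
  v01 <- function(s) vapply(s[!d6$y], function(x)
    mean((s[d6$y] > x) + 0.5 * (s[d6$y] == x)), numeric(1))
  a1 <- mean(v10(d6$sa)); a2 <- mean(v10(d6$sb))
  s10 <- cov(cbind(v10(d6$sa), v10(d6$sb)))
  s01 <- cov(cbind(v01(d6$sa), v01(d6$sb)))
  vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / 3 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / 3
  expect_equal(got$auc_a, a1, tolerance = 1e-12)
  expect_equal(got$auc_b, a2, tolerance = 1e-12)
  expect_equal(got$z, (a1 - a2) / sqrt(vd), tolerance = 1e-12)
})

test_that("compare_aucs agrees with an independent DeLong implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  dat <- tibble::tibble(sa = rnorm(50), sb = rnorm(50),
                        y = rbinom(50, 1, 0.5) == 1)
  dat$sa <- dat$sa + 2 * dat$y
  got <- compare_aucs(dat, sa, sb, y)
  ref <- pROC::roc.test(pROC::roc(dat$y, dat$sa, quiet = TRUE, direction = "<"),
                        pROC::roc(dat$y, dat$sb, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-8)
})

test_that("ranking_table ranks each metric with shared ranks on ties", {
  tb <- tibble::tibble(predictor = c("CARE", "MMSE", "AVLT"),
                       auc = c(0.9, 0.7, 0.7),
                       accuracy = c(0.8, 0.8, 0.6))
  r <- ranking_table(tb)
  expect_equal(r$rank_auc, c(1L, 2L, 2L))
  expect_equal(r$rank_accuracy, c(1L, 1L, 3L))
  expect_error(ranking_table(tb[1, ]), "at least two")
})
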