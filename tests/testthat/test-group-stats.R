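test_that("summary-statistic t-tests reproduce published demographic rows", {
  avlt <- t_from_summary(37.47, 10.20, 34, 29.25, 5.85, 12, "welch")
  expect_equal(avlt$statistic, 3.382, tolerance = 0.01)

  age <- t_from_summary(70.24, 7.20, 34, 73.90, 5.41, 12, "pooled")
  expect_equal(age$statistic, -1.605, tolerance = 0.01)

  adas <- t_from_summary(8.62, 3.23, 34, 13.08, 4.21, 12, "pooled")
  expect_equal(adas$statistic, -3.800, tolerance = 0.01)
})

test_that("two_sample_t gates pooled vs Welch on Levene's test", {
  set.seed(52)
  eq <- tibble::tibble(v = c(rnorm(40, 0, 1), rnorm(40, 0.3, 1)),
                       g = rep(c("a", "b"), each = 40))
  r_eq <- two_sample_t(eq, v, g)
  expect_equal(r_eq$test, "pooled-t")

  uneq <- tibble::tibble(v = c(rnorm(40, 0, 1), rnorm(40, 0.3, 6)),
                         g = rep(c("a", "b"), each = 40))
  r_uneq <- two_sample_t(uneq, v, g)
  expect_equal(r_uneq$test, "welch-t")

  same <- tibble::tibble(v = rep(rnorm(20), 2),
                         g = rep(c("a", "b"), each = 20))
  expect_equal(two_sample_t(same, v, g, "pooled")$statistic, 0)

  tiny <- tibble::tibble(v = c(1, 2, 3), g = c("a", "a", "b"))
  expect_error(two_sample_t(tiny, v, g), "at least 2")
})

test_that("Welch equals pooled under equal variances and sizes", {
  welch <- t_from_summary(5, 2, 30, 4, 2, 30, "welch")
  pooled <- t_from_summary(5, 2, 30, 4, 2, 30, "pooled")
  expect_equal(welch$statistic, pooled$statistic, tolerance = 1e-12)
  expect_equal(welch$df, pooled$df, tolerance = 1e-9)
})

test_that("chi_square_2x2 reproduces the conversion-rate and sex-ratio tests", {
  conv <- chi_square_2x2(12, 34, 16, 40)
  expect_lt(abs(conv$statistic - 0.078), 0.001)
  expect_lt(abs(conv$p_value - 0.78), 0.005)

  sex <- chi_square_2x2(17, 17, 6, 6)
  expect_equal(sex$statistic, 0, tolerance = 1e-12)

  prop <- chi_square_2x2(10, 20, 20, 40)
  expect_equal(prop$statistic, 0, tolerance = 1e-12)

  # transposition invariance
  expect_equal(chi_square_2x2(12, 16, 34, 40)$statistic, conv$statistic,
               tolerance = 1e-12)

  expect_error(chi_square_2x2(0, 0, 5, 7), "margin")
})

test_that("mann_whitney uses exact tails for small tie-free samples", {
  sep <- tibble::tibble(v = c(1, 2, 3, 10, 11, 12),
                        g = rep(c("a", "b"), each = 3))
  r <- mann_whitney(sep, v, g)
  expect_true(r$statistic %in% c(0, 9))
  expect_true(r$exact)
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)  # 2/20 orderings

  # one adjacent swap off full separation
  swap <- tibble::tibble(v = c(1, 2, 10, 3, 11, 12),
                         g = rep(c("a", "b"), each = 3))
  r2 <- mann_whitney(swap, v, g)
  expect_true(r2$statistic %in% c(1, 8))

  all_tied <- tibble::tibble(v = rep(5, 12), g = rep(c("a", "b"), 6))
  r3 <- mann_whitney(all_tied, v, g)
  expect_equal(r3$statistic, 18)  # n^2 / 2 for 6 vs 6
  expect_equal(r3$p_value, 1)
})

test_that("mann_whitney matches wilcox.test for larger samples", {
  set.seed(61)
  dat <- tibble::tibble(v = c(rnorm(15), rnorm(20, 0.8)),
                        g = rep(c("a", "b"), c(15, 20)))
  r <- mann_whitney(dat, v, g)
  ref <- wilcox.test(v ~ g, data = dat, exact = FALSE, correct = FALSE)
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("change_regressions recovers a planted slope and adjusts across outcomes", {
  set.seed(71)
  n <- 44
  dat <- tibble::tibble(
    dcare = rnorm(n, 0, 1),
    age = rnorm(n, 70, 6),
    sex = rbinom(n, 1, 0.5)
  )
  dat$dm1 <- -2 * dat$dcare + rnorm(n, 0, 0.1)
  dat$dm2 <- rnorm(n)
  res <- change_regressions(dat, dcare, c(dm1, dm2), c(age, sex))
  expect_equal(res$estimate[res$outcome == "dm1"], -2, tolerance = 0.1)
  expect_lt(res$q_value[res$outcome == "dm1"], 0.05)

  single <- change_regressions(dat, dcare, dm1)
  expect_equal(single$q_value, single$p_value)

  dat$age2 <- dat$age
  expect_error(change_regressions(dat, dcare, dm1, c(age, age2)),
               "rank-deficient|collinear")
})

test_that("the null change-score simulation behaves like a controlled FDR", {
  set.seed(81)
  n <- 44
  n_rep <- 200
  raw_hits <- numeric(n_rep)
  any_q <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    dat <- tibble::tibble(dcare = rnorm(n))
    for (j in 1:6) dat[[paste0("o", j)]] <- rnorm(n)
    res <- change_regressions(dat, dcare, dplyr::starts_with("o"))
    raw_hits[r] <- sum(res$p_value < 0.05)
    any_q[r] <- any(res$q_value < 0.05)
  }
  expect_equal(mean(raw_hits), 0.3, tolerance = 0.12)
  expect_lte(mean(any_q), 0.1)
})

test_that("BH q-values are monotone in p and bounded by one", {
  set.seed(91)
  dat <- tibble::tibble(dcare = rnorm(30))
  for (j in 1:8) dat[[paste0("o", j)]] <- rnorm(30)
  res <- change_regressions(dat, dcare, dplyr::starts_with("o"))
  ord <- order(res$p_value)
  expect_true(all(diff(res$q_value[ord]) > -1e-12))
  expect_true(all(res$q_value <= 1))
  expect_equal(res$q_value, p.adjust(res$p_value, "BH"))
})
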