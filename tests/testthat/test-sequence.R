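test_that("sequence_loglik matches the stage-enumeration oracle", {
  m <- toy3()
  dat <- tibble::tibble(A = c(2.5, -0.5), B = c(1.2, 4.8), C = c(13, 9.5))
  for (sq in list(c("A", "B", "C"), c("C", "A", "B"), c("B", "C", "A"))) {
    expect_equal(as.numeric(sequence_loglik(dat, m, sq)),
                 oracle_sequence_loglik(dat, m, sq), tolerance = 1e-12)
  }
})

test_that("sequence_loglik marginalizes missing values and flags all-missing", {
  m <- toy_models("A", "increase", 0, 1, 3, 1)
  ll <- sequence_loglik(tibble::tibble(A = NA_real_), m, "A")
  expect_equal(as.numeric(ll), 0)
  expect_equal(attr(ll, "n_all_missing"), 1)

  m3 <- toy3()
  dat <- tibble::tibble(A = c(1, NA), B = c(NA, 2), C = c(12, NA))
  expect_equal(as.numeric(sequence_loglik(dat, m3, c("A", "B", "C"))),
               oracle_sequence_loglik(dat, m3, c("A", "B", "C")),
               tolerance = 1e-12)
})

test_that("sequence_loglik is invariant to subject order and validates input", {
  m <- toy3()
  set.seed(2)
  dat <- tibble::tibble(A = rnorm(20, 1.5), B = rnorm(20, 3), C = rnorm(20, 12))
  ll1 <- sequence_loglik(dat, m, c("B", "A", "C"))
  ll2 <- sequence_loglik(dat[sample(20), ], m, c("B", "A", "C"))
  expect_equal(as.numeric(ll1), as.numeric(ll2), tolerance = 1e-10)

  expect_error(sequence_loglik(dat, m, c("A", "B")), "permutation")
  expect_error(sequence_loglik(dat, m, c("A", "B", "B")), "permutation")
})

test_that("single-biomarker panels give the only possible ordering", {
  m <- toy_models("A", "increase", 0, 1, 3, 1)
  dat <- tibble::tibble(A = rnorm(15, 1.5))
  fit <- find_optimal_sequence(dat, m, n_starts = 3, seed = 1)
  expect_equal(fit$sequence, "A")
  expect_equal(as.numeric(fit$loglik),
               as.numeric(sequence_loglik(dat, m, "A")))
})

test_that("greedy search attains the exhaustive optimum on a 4-event panel", {
  nm <- paste0("B", 1:4)
  cfg <- synthetic_config(
    panel = care_panel(nm, "increase"),
    true_sequence = nm,
    densities = tibble::tibble(biomarker = nm, mu_nonevent = 0,
                               sd_nonevent = 1, mu_event = 4, sd_event = 1),
    stage_probs = rep(1 / 5, 5),
    n_discovery = 200, converter_stage = 3,
    validation_missing = character(), seed = 8
  )
  gc0 <- generate_cohort(cfg, "d", seed = 8)
  m <- fit_event_models(gc0$cohort, cfg$panel)
  greedy <- find_optimal_sequence(gc0$cohort, m, n_starts = 5, seed = 4)
  exact <- exhaustive_sequence_search(gc0$cohort, m)
  expect_equal(greedy$sequence, exact$sequence)
  expect_equal(as.numeric(greedy$loglik), as.numeric(exact$loglik),
               tolerance = 1e-10)
})

test_that("greedy ascent trajectories never decrease", {
  m <- toy3()
  set.seed(6)
  dat <- tibble::tibble(A = rnorm(30, 1), B = rnorm(30, 3), C = rnorm(30, 12))
  fit <- find_optimal_sequence(dat, m, n_starts = 6, seed = 6)
  for (tr in fit$trajectories) {
    expect_true(all(diff(tr) > 0 | length(tr) == 1))
  }
})

test_that("relabeling biomarkers relabels the optimal sequence", {
  cfg <- synthetic_config(
    panel = care_panel(paste0("B", 1:4), "increase"),
    true_sequence = paste0("B", 1:4),
    densities = tibble::tibble(biomarker = paste0("B", 1:4),
                               mu_nonevent = 0, sd_nonevent = 1,
                               mu_event = 3, sd_event = 1),
    stage_probs = rep(1 / 5, 5), n_discovery = 100, converter_stage = 3,
    validation_missing = character(), seed = 12
  )
  gc0 <- generate_cohort(cfg, "d", seed = 12)
  m <- fit_event_models(gc0$cohort, cfg$panel)
  fit <- find_optimal_sequence(gc0$cohort, m, n_starts = 4, seed = 2)

  relab <- c(B1 = "X1", B2 = "X2", B3 = "X3", B4 = "X4")
  dat2 <- gc0$cohort
  names(dat2)[match(names(relab), names(dat2))] <- relab
  m2 <- m
  m2$panel$name <- unname(relab[m2$panel$name])
  names(m2$models) <- unname(relab[names(m2$models)])
  for (bm in names(m2$models)) m2$models[[bm]]$name <- bm
  fit2 <- find_optimal_sequence(dat2, m2, n_starts = 4, seed = 2)
  expect_equal(fit2$sequence, unname(relab[fit$sequence]))
  expect_equal(as.numeric(fit2$loglik), as.numeric(fit$loglik),
               tolerance = 1e-10)
})

test_that("warm starts are honored and MCMC frequencies are row-stochastic", {
  m <- toy3()
  set.seed(9)
  dat <- tibble::tibble(A = rnorm(40, 1.5), B = rnorm(40, 3), C = rnorm(40, 12))
  fit <- find_optimal_sequence(dat, m, n_starts = 0,
                               initial_sequences = list(c("C", "B", "A")),
                               seed = 1, mcmc_iter = 500)
  expect_length(fit$trajectories, 1)
  expect_equal(unname(rowSums(fit$position_freq)), rep(1, 3),
               tolerance = 1e-9)
  expect_error(
    find_optimal_sequence(dat, m, initial_sequences = list(c("A", "B"))),
    "permutation")
})

test_that("sequence fits serialize to JSON and back", {
  m <- toy3()
  set.seed(10)
  dat <- tibble::tibble(A = rnorm(25, 1.5), B = rnorm(25, 3), C = rnorm(25, 12))
  fit <- find_optimal_sequence(dat, m, n_starts = 3, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_sequence_fit(fit, path)
  fit2 <- read_sequence_fit(path)
  expect_equal(fit2$sequence, fit$sequence)
  expect_equal(fit2$loglik, as.numeric(fit$loglik))
})
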