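test_that("fluorescence normalization divides by the t = 0 value", {
  tc <- time_course(c(0, 1, 2), c(2, 3, 4))
  out <- normalize_fluorescence(tc)
  expect_equal(out$signal, c(1, 1.5, 2))
  expect_equal(normalize_fluorescence(out)$signal, out$signal)  # idempotent
  expect_equal(normalize_fluorescence(time_course(0:2, rep(3, 3)))$signal,
               rep(1, 3))
  expect_error(normalize_fluorescence(time_course(0:2, c(0, 1, 2))),
               "zero")
})

test_that("product normalization maps the range onto the unit interval", {
  tc <- time_course(0:2, c(0, 5, 10))
  expect_equal(normalize_product(tc)$signal, c(0, 0.5, 1))
  unit <- time_course(0:2, c(0, 0.4, 1))
  expect_equal(normalize_product(unit)$signal, unit$signal)
  expect_error(normalize_product(time_course(0:2, rep(2, 3))), "flat")
})

test_that("noiseless exponential courses are inverted exactly", {
  tg <- seq(0, 0.1, length.out = 100)
  tc <- simulate_exponential_course(70, 1, tg, noise_sd = 0)
  fit <- fit_exponential(tc, phases = 1)
  expect_lt(abs(fit$k_app - 70) / 70, 1e-6)
  expect_equal(fit$tau * fit$k_app, 1)
  # decaying form
  tc2 <- simulate_exponential_course(3, 1, seq(0, 2, length.out = 60),
                                     form = "decaying")
  expect_lt(abs(fit_exponential(tc2, phases = 1)$k_app - 3) / 3, 1e-6)
})

test_that("fitted rates are invariant to affine rescaling of the signal", {
  tg <- seq(0, 0.2, length.out = 120)
  tc <- simulate_exponential_course(25, 1, tg, noise_sd = 0.01, seed = 2)
  k1 <- fit_exponential(tc, phases = 1)$k_app
  tc$signal <- 5 + 3 * tc$signal
  k2 <- fit_exponential(tc, phases = 1)$k_app
  expect_equal(k1, k2, tolerance = 1e-6)
})

test_that("the major phase of a two-phase mixture is identified", {
  tg <- seq(0, 0.1, length.out = 400)
  tc <- simulate_exponential_course(c(60, 12), c(0.8, 0.2), tg,
                                    noise_sd = 0.005, seed = 14)
  fit <- fit_exponential(tc, phases = 2)
  expect_equal(fit$phases, 2L)
  expect_lt(abs(fit$k_app - 60) / 60, 0.1)
  expect_gt(fit$amplitude_fraction, 0.6)
})

test_that("a genuinely single-phase course falls back from a two-phase fit", {
  tg <- seq(0, 0.1, length.out = 300)
  tc <- simulate_exponential_course(40, 1, tg, noise_sd = 0.01, seed = 6)
  fit <- fit_exponential(tc, phases = 2)
  expect_equal(fit$phases, 1L)
  expect_match(fit$note, "fell back")
})

test_that("delays between constructs are differences in reaction time", {
  tg <- seq(0, 20, length.out = 40)
  fa <- fit_exponential(simulate_exponential_course(1 / 0.08, 1,
                          seq(0, 1, length.out = 40)), phases = 1)
  fb <- fit_exponential(simulate_exponential_course(1 / 3.3, 1, tg),
                        phases = 1)
  expect_equal(delay_between(fa, fb), 3.3 - 0.08, tolerance = 1e-4)
  expect_equal(delay_between(fa, fa), 0)
})

test_that("reaction-time comparisons match the closed-form t statistic", {
  a <- c(1.1, 1.3, 1.2)
  b <- c(2.0, 2.4, 2.1)
  out <- compare_tau(a, b, test = "student_unpaired")
  n <- 3
  sp2 <- (var(a) * (n - 1) + var(b) * (n - 1)) / (2 * n - 2)
  t_ref <- (mean(a) - mean(b)) / sqrt(sp2 * 2 / n)
  expect_equal(out$statistic, t_ref, tolerance = 1e-12)
  expect_lt(out$p_value, 0.05)
  same <- compare_tau(c(1, 1.05, 0.95), c(1.02, 0.98, 1), "welch")
  expect_gt(same$p_value, 0.5)
})

test_that("an 8-fold reaction-time difference is reliably significant", {
  set.seed(4)
  hits <- 0L
  for (s in 1:20) {
    a <- rnorm(3, 1, 0.12)     # tau with SEM roughly as printed
    b <- rnorm(3, 8, 0.9)
    if (compare_tau(a, b, "student_unpaired")$p_value < 0.05)
      hits <- hits + 1L
  }
  expect_gte(hits / 20, 0.95)
})

test_that("end level of product formation tracks the completion probability", {
  rs <- rs_simple(k1_app = 2, k_rev1 = 0, k_rev2 = 0, k2 = 20,
                  k_gtp = 5, k45 = 2, k7 = 1)
  sc <- build_scheme(rs, "wildtype")
  p_done <- absorption_probability(sc, "ACCOMMODATED_CLASSICAL")
  tg <- seq(0.05, 15, length.out = 60)
  tc <- generate_ensemble_timecourse(sc, c("ACCOMMODATED_CLASSICAL",
                                           "HYBRID_APstar"), tg,
                                     noise_sd = 0.005, n_replicates = 3,
                                     seed = 17)
  fit <- fit_exponential(tc, phases = 1)
  expect_equal(fit$end_level, p_done, tolerance = 0.05)
})
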