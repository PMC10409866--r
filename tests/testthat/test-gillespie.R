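test_that("stochastic paths are contiguous, reproducible, and horizon-bound", {
  sc <- build_scheme(rs_simple(), "wildtype")
  tr1 <- simulate_trajectory(sc, horizon = 10, seed = 99)
  tr2 <- simulate_trajectory(sc, horizon = 10, seed = 99)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
  expect_true(all(tr1$t_exit > tr1$t_enter))
  expect_equal(tr1$t_enter[-1], tr1$t_exit[-nrow(tr1)])
  expect_equal(tr1$t_exit[nrow(tr1)], 10)
  expect_equal(nrow(simulate_trajectory(sc, horizon = 0, seed = 1)), 0)
})

test_that("an absorbing start spans the horizon in one segment", {
  sc <- build_scheme(rs_simple(), "wildtype")
  tr <- simulate_trajectory(sc, horizon = 5, seed = 1, init = "DROPPED")
  expect_equal(nrow(tr), 1)
  expect_equal(tr$state, "DROPPED")
  expect_equal(tr$t_exit, 5)
})

test_that("first dwell times are exponential with the exit rate", {
  # single exit at 1.0 s^-1: mean hitting time 1.0 within 3 SE at n = 1e4
  sc <- build_scheme(rs_simple(k_hyb_fwd = 1, k_hyb_rev = 0), "hybrid_only")
  ht <- simulate_hitting(sc, "ACCOMMODATED_CLASSICAL", "HYBRID_APstar",
                         n = 1e4, seed = 7)
  expect_true(all(is.finite(ht)))
  expect_lt(abs(mean(ht) - 1), 3 / sqrt(1e4))
})

test_that("Gillespie agrees with the analytic first-passage solution", {
  # random small schemes: hitting-time means and absorption frequencies
  # within 3 standard errors at 1e4 paths
  set.seed(2024)
  for (i in 1:20) {
    rs <- rs_random()
    sc <- build_scheme(rs, "wildtype")
    target <- "ACCOMMODATED_CLASSICAL"
    m <- mean_first_passage(sc, "UNBOUND", target)
    p <- attr(m, "p_hit")
    ht <- simulate_hitting(sc, "UNBOUND", target, n = 1e4,
                           seed = 1000 + i)
    hit <- is.finite(ht)
    expect_lt(abs(mean(hit) - p), 3 * sqrt(p * (1 - p) / 1e4) + 1e-12)
    se <- stats::sd(ht[hit]) / sqrt(sum(hit))
    expect_lt(abs(mean(ht[hit]) - m), 3 * se)
  }
})

test_that("empirical occupancancy matches the master-equation solution", {
  sc <- build_scheme(rs_simple(k7 = 0.5), "wildtype")
  tg <- c(0.5, 2, 8)
  tc <- ensemble_timecourse(sc, c("ACCOMMODATED_CLASSICAL",
                                  "HYBRID_APstar"), tg)
  n <- 4000
  seeds <- derive_seeds(11, n)
  occ <- matrix(0, n, length(tg))
  for (j in seq_len(n)) {
    tr <- simulate_trajectory(sc, horizon = max(tg), seed = seeds[j])
    for (g in seq_along(tg)) {
      row <- tr[tr$t_enter <= tg[g] & tr$t_exit > tg[g], , drop = FALSE]
      if (nrow(row) == 0L) row <- tr[nrow(tr), , drop = FALSE]
      occ[j, g] <- row$state[1] %in% c("ACCOMMODATED_CLASSICAL",
                                       "HYBRID_APstar")
    }
  }
  for (g in seq_along(tg)) {
    p_hat <- mean(occ[, g])
    se <- sqrt(p_hat * (1 - p_hat) / n)
    expect_lt(abs(p_hat - tc$signal[g]), 3 * se + 1e-12)
  }
})

test_that("child seeds derive deterministically from the master seed", {
  expect_identical(derive_seeds(5, 10), derive_seeds(5, 10))
  expect_false(identical(derive_seeds(5, 10), derive_seeds(6, 10)))
  expect_true(all(derive_seeds(1, 1000) < .Machine$integer.max))
})
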