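test_that("noiseless two-level traces idealize to exact dwell boundaries", {
  E <- c(rep(0.8, 50), rep(0.6, 30), rep(0.8, 40), rep(0.6, 60))
  it <- idealize(fret_manual(E))
  expect_equal(it$n_states, 2L)
  expect_equal(nrow(it$segments), 4L)
  expect_equal(it$segments$start_frame, c(1, 51, 81, 121))
  expect_equal(sort(unique(round(it$segments$mu, 3))), c(0.6, 0.8))
})

test_that("a constant noisy trace selects a single state", {
  set.seed(9)
  it <- idealize(fret_manual(rnorm(400, 0.8, 0.05)))
  expect_equal(it$n_states, 1L)
  expect_equal(it$segments$mu, 0.8, tolerance = 0.02)
})

test_that("short traces are skipped with a message", {
  expect_message(res <- idealize(fret_manual(rep(0.5, 5))), "skipped")
  expect_null(res)
})

test_that("most true transitions are recovered within one frame", {
  # two-state fluctuations at the published classical/hybrid rates
  ts <- generate_dataset(decoding_rates("AAA"), fret_map(), camera_model(),
                         n_traces = 20,
                         scenario = "preformed_postdecoding",
                         n_replicates = 1, seed = 31, bleach_mode = "none")
  dt <- camera_model()$dt
  found <- 0L; total <- 0L
  for (tr in ts$traces) {
    ft <- compute_fret(correct_bleedthrough(tr, 0.13))
    it <- assign_levels(filter_transitions(idealize(ft)),
                        c(classical = 0.8, hybrid = 0.6))
    ideal_t <- it$segments$t_start[-1]
    truth <- attr(tr, "truth")$trajectory
    true_t <- truth$t_enter[-1]
    true_t <- true_t[true_t < 33 - dt]
    # only transitions bounded by resolvable dwells can be recovered
    dur <- diff(c(truth$t_enter, 33))
    keep <- dur[-1] >= dt & dur[-length(dur)] >= dt
    true_t <- truth$t_enter[-1][keep & truth$t_enter[-1] < 33 - dt]
    total <- total + length(true_t)
    for (tt in true_t)
      if (any(abs(ideal_t - tt) <= dt + 1e-9)) found <- found + 1L
  }
  expect_gt(found / total, 0.9)
})

test_that("transitions below the state width are merged like the oracle", {
  # independent brute-force merge: repeatedly merge the smallest
  # violating gap, duration-weighted mean, larger width kept
  oracle <- function(mu, sigma, dur) {
    repeat {
      if (length(mu) < 2) break
      gap <- abs(diff(mu))
      thr <- pmax(head(sigma, -1), tail(sigma, -1))
      bad <- which(gap < thr)
      if (!length(bad)) break
      i <- bad[which.min(gap[bad])]
      mu[i] <- (mu[i] * dur[i] + mu[i + 1] * dur[i + 1]) /
        (dur[i] + dur[i + 1])
      sigma[i] <- max(sigma[i], sigma[i + 1])
      dur[i] <- dur[i] + dur[i + 1]
      mu <- mu[-(i + 1)]; sigma <- sigma[-(i + 1)]; dur <- dur[-(i + 1)]
    }
    list(mu = mu, dur = dur)
  }
  set.seed(77)
  for (rep in 1:100) {
    n <- sample(2:10, 1)
    mu <- runif(n, 0, 1)
    sigma <- runif(n, 0.01, 0.2)
    dur <- sample(1:50, n, replace = TRUE)
    it <- itrace_manual(mu, dur, sigma = sigma)
    out <- filter_transitions(it)$segments
    ref <- oracle(mu, sigma, dur * it$dt)
    expect_equal(out$mu, ref$mu, tolerance = 1e-12)
    expect_equal(out$t_end - out$t_start, ref$dur, tolerance = 1e-12)
  }
})

test_that("clear transitions and sub-width splits behave as specified", {
  it <- itrace_manual(c(0.8, 0.6), c(20, 20), sigma = 0.05)
  expect_equal(nrow(filter_transitions(it)$segments), 2L)
  it2 <- itrace_manual(c(0.8, 0.83), c(20, 20), sigma = 0.05)
  expect_equal(nrow(filter_transitions(it2)$segments), 1L)
})

test_that("levels are assigned by nearest value with ties to the previous dwell", {
  it <- itrace_manual(c(0.0, 0.9, 0.45, 0.0), c(10, 10, 1, 10),
                      sigma = 0.01)
  # 0.45 is equidistant from dark (0) and high (0.9): it joins the
  # previous (high) dwell
  out <- assign_levels(it, c(dark = 0, high = 0.9))
  expect_equal(out$segments$level, c("dark", "high", "dark"))
  expect_equal(out$segments$end_frame[2], 21)
})
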