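test_that("datasets carry replicate structure and ground truth", {
  ts <- generate_dataset(decoding_rates("AAA"), fret_map(), camera_model(),
                         n_traces = 4, scenario = "injection",
                         n_replicates = 2, seed = 3)
  expect_length(ts$traces, 8)
  expect_equal(sort(unique(ts$manifest$replicate)), 1:2)
  expect_true(all(c("class", "bleach_time", "seed") %in%
                    names(ts$manifest)))
  expect_error(generate_dataset(decoding_rates("AAA"), fret_map(),
                                camera_model(), n_traces = 0, seed = 1),
               "n_traces")
})

test_that("no association rate means every injected trace stays dark", {
  rs <- rs_simple(k1_app = 0)
  ts <- generate_dataset(rs, fret_map(), camera_model(), n_traces = 5,
                         scenario = "injection", n_replicates = 1,
                         seed = 4, bleach_mode = "none")
  for (tr in ts$traces) {
    E <- correct_bleedthrough(tr, 0.13)
    E <- E$acceptor / (E$donor + E$acceptor)
    expect_lt(abs(mean(E)), 0.02)   # channel noise only, no FRET state
    expect_lt(max(abs(E)), 0.45)
  }
  expect_true(all(ts$manifest$class == "dark"))
})

test_that("preformed complexes fluctuate between the two post-decoding levels", {
  ts <- generate_dataset(decoding_rates("AAA"), fret_map(), camera_model(),
                         n_traces = 5,
                         scenario = "preformed_postdecoding",
                         n_replicates = 1, seed = 5, bleach_mode = "none")
  for (tr in ts$traces) {
    states <- attr(tr, "truth")$trajectory$state
    expect_true(all(states %in% c("ACCOMMODATED_CLASSICAL",
                                  "HYBRID_APstar")))
  }
  expect_true(all(ts$manifest$class == "post_decoding"))
})

test_that("datasets are reproducible from the master seed", {
  a <- generate_dataset(decoding_rates("AAA"), fret_map(), camera_model(),
                        n_traces = 3, scenario = "injection",
                        n_replicates = 1, seed = 11)
  b <- generate_dataset(decoding_rates("AAA"), fret_map(), camera_model(),
                        n_traces = 3, scenario = "injection",
                        n_replicates = 1, seed = 11)
  for (i in seq_along(a$traces))
    expect_identical(as.data.frame(a$traces[[i]]),
                     as.data.frame(b$traces[[i]]))
  expect_identical(a$manifest, b$manifest)
})

test_that("noise-free ensemble generation equals the analytic course", {
  sc <- build_scheme(rs_simple(), "wildtype")
  tg <- seq(0.2, 5, by = 0.2)
  tc <- generate_ensemble_timecourse(sc, "ACCOMMODATED_CLASSICAL", tg,
                                     noise_sd = 0, n_replicates = 2,
                                     seed = 1)
  ref <- ensemble_timecourse(sc, "ACCOMMODATED_CLASSICAL", tg)
  for (r in 1:2)
    expect_equal(tc$signal[tc$replicate == r], ref$signal)
})

test_that("a fast synthetic course returns its generating rate", {
  tc <- simulate_exponential_course(70, 1, seq(0, 0.1, length.out = 300),
                                    noise_sd = 0.01, n_replicates = 3,
                                    seed = 21)
  fit <- fit_exponential(tc, phases = 1)
  expect_lt(abs(fit$k_app - 70) / 70, 0.05)
})

test_that("parallel accommodation routes produce a detectably biphasic course", {
  fast <- build_scheme(rs_simple(k45 = 8, k7 = 0, k_rev1 = 0,
                                 k_rev2 = 0, k1_app = 50, k2 = 50,
                                 k_gtp = 8), "wildtype")
  slow <- build_scheme(rs_simple(k45 = 0.25, k7 = 0, k_rev1 = 0,
                                 k_rev2 = 0, k1_app = 50, k2 = 50,
                                 k_gtp = 8), "wildtype")
  tg <- seq(0.05, 12, length.out = 80)
  tc <- generate_ensemble_timecourse(list(fast, slow),
                                     c("ACCOMMODATED_CLASSICAL",
                                       "HYBRID_APstar"),
                                     tg, noise_sd = 0.01,
                                     n_replicates = 1, seed = 8,
                                     weights = c(0.6, 0.4))
  f1 <- fit_exponential(tc, phases = 1)
  f2 <- fit_exponential(tc, phases = 2)
  n <- length(tg)
  rss1 <- sum(f1$per_replicate$rss)
  rss2 <- sum(f2$per_replicate$rss)
  bic1 <- n * log(rss1 / n) + 3 * log(n)
  bic2 <- n * log(rss2 / n) + 5 * log(n)
  expect_lt(bic2, bic1)   # information criterion prefers two phases
  expect_equal(f2$phases, 2L)
})

test_that("the stalled-subpopulation injector produces stalled phenotypes", {
  ts <- generate_dataset(decoding_rates("AAA"), fret_map(),
                         camera_model(k_photobleach = 0), n_traces = 12,
                         protocol = "H84A", scenario = "injection",
                         n_replicates = 1, seed = 19,
                         stalled_fraction = 1, bleach_mode = "none")
  # every molecule that binds within the window stays in codon reading
  bound <- ts$manifest$class != "dark"
  expect_true(any(bound))
  expect_true(all(ts$manifest$class[bound] == "stalled"))
})
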