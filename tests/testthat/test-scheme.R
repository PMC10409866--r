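test_that("the generator encodes the branched pathway exactly", {
  rs <- rs_simple()
  sc <- build_scheme(rs, "wildtype")
  Q <- sc$generator
  expect_equal(Q["UNBOUND", "IB"], rs$k1_app)
  expect_equal(Q["IB", "UNBOUND"], rs$k_rev1)
  expect_equal(Q["IB", "CR"], rs$k2)
  expect_equal(Q["CR", "UNBOUND"], rs$k_rev2)
  expect_equal(Q["CR", "POST_GTP"], rs$k_gtp)
  expect_equal(Q["POST_GTP", "ACCOMMODATED_CLASSICAL"], rs$k45)
  expect_equal(Q["POST_GTP", "DROPPED"], rs$k7)
  expect_equal(Q["ACCOMMODATED_CLASSICAL", "HYBRID_APstar"], rs$k_hyb_fwd)
  expect_equal(Q["HYBRID_APstar", "ACCOMMODATED_CLASSICAL"], rs$k_hyb_rev)
  expect_equal(unname(rowSums(Q)), rep(0, nrow(Q)), tolerance = 1e-14)
})

test_that("no-rejection rates make DROPPED unreachable", {
  sc <- build_scheme(rs_simple(k_rev1 = 0, k_rev2 = 0, k7 = 0), "wildtype")
  m <- suppressWarnings(mean_first_passage(sc, "UNBOUND", "DROPPED"))
  expect_identical(as.numeric(m), Inf)
  expect_equal(absorption_probability(sc, "ACCOMMODATED_CLASSICAL"), 1)
})

test_that("the GTPase-deficient protocol stalls the chain at codon reading", {
  sc <- build_scheme(decoding_rates("m6AAA"), "H84A")
  expect_equal(sc$generator["CR", "POST_GTP"], 0)
  # probability of ever reaching the post-hydrolysis state is exactly 0
  m <- suppressWarnings(mean_first_passage(sc, "UNBOUND", "POST_GTP"))
  expect_identical(attr(m, "p_hit"), 0)
  # CR exits only by dissociation
  q_cr <- sc$generator["CR", ]
  expect_equal(sum(q_cr[q_cr > 0]), decoding_rates("m6AAA")$k_rev2)
})

test_that("hybrid_only restricts to the two-state fluctuation generator", {
  rs <- rs_simple(k_hyb_fwd = 2.9, k_hyb_rev = 4.4)
  sc <- build_scheme(rs, "hybrid_only")
  expect_equal(unname(sc$generator),
               matrix(c(-2.9, 4.4, 2.9, -4.4), 2, 2))
})

test_that("mean first-passage time matches closed forms", {
  # irreversible two-step chain: total time is the sum of the step times
  rs <- rs_simple(k1_app = 2, k_rev1 = 0, k2 = 5, k_rev2 = 0, k7 = 0)
  sc <- build_scheme(rs, "wildtype")
  expect_equal(as.numeric(mean_first_passage(sc, "UNBOUND", "CR")),
               1 / 2 + 1 / 5, tolerance = 1e-12)
  sc_h <- build_scheme(rs_simple(), "hybrid_only")
  expect_equal(as.numeric(mean_first_passage(sc_h, "ACCOMMODATED_CLASSICAL",
                                             "HYBRID_APstar")),
               1 / rs_simple()$k_hyb_fwd, tolerance = 1e-12)
})

test_that("absorption probabilities are a proper distribution", {
  # symmetric branching gives a coin flip
  sc <- build_scheme(rs_simple(k45 = 2, k7 = 2), "wildtype")
  expect_equal(absorption_probability(sc, "DROPPED"), 0.5,
               tolerance = 1e-12)
  # probabilities over terminal fates sum to one for arbitrary rates
  set.seed(42)
  for (i in 1:5) {
    sc <- build_scheme(rs_random(), "wildtype")
    p1 <- absorption_probability(sc, "DROPPED")
    p2 <- absorption_probability(sc, "ACCOMMODATED_CLASSICAL")
    expect_gte(p1, 0); expect_lte(p1, 1)
    expect_equal(p1 + p2, 1, tolerance = 1e-12)
  }
  expect_error(absorption_probability(build_scheme(rs_simple(), "wildtype"),
                                      "CR"), "closed")
})

test_that("occupancy time course solves the master equation", {
  # irreversible single step: occupancy is 1 - exp(-k t)
  rs <- rs_simple(k_hyb_fwd = 1.7, k_hyb_rev = 0)
  sc <- build_scheme(rs, "hybrid_only")
  tg <- seq(0.1, 3, by = 0.1)
  tc <- ensemble_timecourse(sc, "HYBRID_APstar", tg,
                            start = "ACCOMMODATED_CLASSICAL")
  expect_equal(tc$signal, 1 - exp(-1.7 * tg), tolerance = 1e-10)
  # product states carry no mass at t = 0
  tc0 <- ensemble_timecourse(build_scheme(rs_simple(), "wildtype"),
                             "ACCOMMODATED_CLASSICAL", c(0, 1))
  expect_equal(tc0$signal[1], 0)
  expect_equal(nrow(ensemble_timecourse(sc, "HYBRID_APstar", numeric(0))), 0)
})

test_that("chained cycles add their conditional passage times", {
  rs1 <- rs_simple(k7 = 0, label = "c1")
  rs2 <- rs_simple(k1_app = 0.8, k_rev2 = 1.1, k7 = 0, label = "c2")
  m1 <- mean_first_passage(build_scheme(rs1, "wildtype"), "UNBOUND",
                          "ACCOMMODATED_CLASSICAL")
  m2 <- mean_first_passage(build_scheme(rs2, "wildtype"), "UNBOUND",
                          "ACCOMMODATED_CLASSICAL")
  ch <- chain_cycles(list(rs1, rs2))
  mc <- mean_first_passage(ch, "UNBOUND.1", "ACCOMMODATED_CLASSICAL.2")
  expect_equal(unname(mc), unname(m1) + unname(m2), tolerance = 1e-9)
  # a single cycle is the plain scheme
  expect_equal(chain_cycles(list(rs1))$generator,
               build_scheme(rs1, "wildtype")$generator)
  expect_error(chain_cycles(list()), "at least one")
})

test_that("a slowed late codon delays the chain by its own extra time", {
  fast <- rs_simple(k7 = 0, label = "fast")
  slow <- rs_simple(k_gtp = 0.63, k45 = 0.29, k7 = 0, label = "slow")
  ch_fast <- chain_cycles(list(fast, fast, fast, fast))
  ch_slow <- chain_cycles(list(fast, fast, fast, slow))
  t_fast <- mean_first_passage(ch_fast, "UNBOUND.1",
                               "ACCOMMODATED_CLASSICAL.4")
  t_slow <- mean_first_passage(ch_slow, "UNBOUND.1",
                               "ACCOMMODATED_CLASSICAL.4")
  extra <- mean_first_passage(build_scheme(slow, "wildtype"), "UNBOUND",
                              "ACCOMMODATED_CLASSICAL") -
    mean_first_passage(build_scheme(fast, "wildtype"), "UNBOUND",
                       "ACCOMMODATED_CLASSICAL")
  expect_equal(unname(t_slow - t_fast), unname(extra), tolerance = 1e-9)
})
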