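cam0 <- camera_model()

test_that("noiseless rendering reproduces state FRET exactly", {
  dt <- cam0$dt
  tr <- traj_manual("CR", 0, 10 * dt, horizon = 10 * dt)
  cam <- camera_model(bleed_through = 0)
  it <- render_trace(tr, fret_map(), cam, bleach_mode = "none",
                     noiseless = TRUE)
  E <- it$acceptor / (it$donor + it$acceptor)
  expect_equal(E, rep(0.9, 10), tolerance = 1e-12)
})

test_that("a mid-frame state switch is occupancy-weighted", {
  dt <- cam0$dt
  tr <- traj_manual(c("CR", "HYBRID_APstar"), c(0, dt / 2), c(dt / 2, dt),
                    horizon = dt)
  cam <- camera_model(bleed_through = 0)
  it <- render_trace(tr, fret_map(), cam, bleach_mode = "none",
                     noiseless = TRUE)
  expect_equal(it$acceptor / (it$donor + it$acceptor), 0.75,
               tolerance = 1e-12)
})

test_that("bleed-through is algebraically invertible", {
  tr <- traj_manual("ACCOMMODATED_CLASSICAL", 0, 1, horizon = 1)
  it <- render_trace(tr, fret_map(), camera_model(bleed_through = 0),
                     seed = 3, bleach_mode = "none")
  with_bt <- add_bleedthrough(it, 0.13)
  back <- correct_bleedthrough(with_bt, 0.13)
  expect_equal(back$acceptor, it$acceptor, tolerance = 1e-12)
  expect_equal(back$donor, it$donor)
  # and the rendered bleed-through is removed by the same correction
  it2 <- render_trace(tr, fret_map(), camera_model(), seed = 3,
                      bleach_mode = "none", noiseless = TRUE)
  corrected <- correct_bleedthrough(it2, 0.13)
  E <- corrected$acceptor / (corrected$donor + corrected$acceptor)
  expect_equal(E, rep(0.8, nrow(it2)), tolerance = 1e-9)
  expect_error(correct_bleedthrough(it, 1), "beta")
})

test_that("photobleaching times are exponential with the stated rate", {
  expect_identical(sample_bleach_time(camera_model(k_photobleach = 0)), Inf)
  set.seed(1)
  draws <- replicate(1e4, sample_bleach_time(cam0))
  expect_lt(abs(mean(draws) - 1 / 0.03), 3 * (1 / 0.03) / sqrt(1e4))
  ks <- suppressWarnings(stats::ks.test(draws, "pexp", rate = 0.03))
  expect_gt(ks$p.value, 0.01)
})

test_that("a bleach at t = 0 darkens the whole trace", {
  tr <- traj_manual("CR", 0, 1, horizon = 1)
  it <- render_trace(tr, fret_map(), camera_model(k_photobleach = 1e9),
                     seed = 5, bleach_mode = "donor", noiseless = TRUE)
  expect_true(all(it$donor + it$acceptor < 1e-3))
})

test_that("ground-truth classes follow the first resolved phase", {
  dt <- cam0$dt
  # bind, stay high, dissociate: a rejection
  tr <- traj_manual(c("UNBOUND", "IB", "UNBOUND"),
                    c(0, 10 * dt, 20 * dt), c(10 * dt, 20 * dt, 33),
                    horizon = 33)
  expect_equal(ribodecode:::trajectory_class(tr, cam0), "rejected")
  # fluctuating from the first frame: post-decoding
  tr2 <- traj_manual(c("ACCOMMODATED_CLASSICAL", "HYBRID_APstar"),
                     c(0, 5), c(5, 33), horizon = 33)
  expect_equal(ribodecode:::trajectory_class(tr2, cam0), "post_decoding")
  # high phase then accommodation: decoding
  tr3 <- traj_manual(c("UNBOUND", "CR", "ACCOMMODATED_CLASSICAL"),
                     c(0, 1, 2), c(1, 2, 33), horizon = 33)
  expect_equal(ribodecode:::trajectory_class(tr3, cam0), "decoding")
  # high phase persisting to the end: stalled
  tr4 <- traj_manual(c("UNBOUND", "CR"), c(0, 1), c(1, 33), horizon = 33)
  expect_equal(ribodecode:::trajectory_class(tr4, cam0), "stalled")
})
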