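test_that("rate sets validate their inputs", {
  expect_s3_class(rs_simple(), "rate_set")
  expect_error(rs_simple(k_rev1 = -1), "negative")
  expect_error(rate_set(k1_app = NA, k_rev1 = 1, k2 = 1, k_rev2 = 1,
                        k_gtp = 1, k45 = 1, k7 = 0, k_hyb_fwd = 1,
                        k_hyb_rev = 1), "finite")
  expect_error(rs_simple(k2 = Inf), "finite")
})

test_that("shipped codon rate sets carry the published dissociation rates", {
  aaa <- decoding_rates("AAA")
  m6 <- decoding_rates("m6AAA")
  expect_equal(aaa$k_rev1, 8.1)
  expect_equal(aaa$k_rev2, 0.34)
  expect_equal(aaa$k_hyb_fwd, 2.9)
  expect_equal(aaa$k_hyb_rev, 4.4)
  expect_equal(m6$k_rev1, 15)
  expect_equal(m6$k_rev2, 1.1)
  # the modified codon destabilizes both binding intermediates
  expect_gt(m6$k_rev1, aaa$k_rev1)
  expect_gt(m6$k_rev2, aaa$k_rev2)
})

test_that("rate sets round-trip through the flat config format", {
  path <- withr::local_tempfile(fileext = ".yaml")
  orig <- list(decoding_rates("AAA"), decoding_rates("m6AAA"))
  write_rate_sets(orig, path)
  back <- read_rate_sets(path)
  expect_named(back, c("AAA", "m6AAA"))
  for (i in 1:2)
    expect_equal(unclass(back[[i]]), unclass(orig[[i]]))
})

test_that("missing rate keys are reported by name", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(AAA = list(k1_app = 1, k_rev1 = 2)), path)
  expect_error(read_rate_sets(path), "k_rev2")
})
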