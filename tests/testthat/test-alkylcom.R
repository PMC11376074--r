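# Fragment-mass model, theoretical transition list, and MRM screening.

test_that("product-ion masses match the instrument-reported values", {
  m <- fragment_mass_model()
  expect_identical(fragment_mz(m, "HSO3"), 80.9)
  expect_identical(fragment_mz(m, "C2H3SO3"), 106.9)
  # independent evaluation of the generalized formula for hexadecyl-sulfonate
  expect_identical(fragment_mz(m, "alkyl", 16),
                   round(12.00055 * 16 + 1.00837 * 33 + 79.9, 1))
  expect_identical(fragment_mz(m, "alkyl", 16), 305.2)
})

test_that("alkyl-sulfonate series is strictly increasing with CH2 spacing", {
  # spacing checked at formula precision; the instrument rounds to 0.1
  m5 <- fragment_mass_model(report_decimals = 5)
  mz <- fragment_mz(m5, "alkyl", 4:28)
  expect_true(all(diff(mz) > 0))
  expect_equal(unique(round(diff(mz), 3)), 14.017)
  expect_equal(round(12.00055 + 2 * 1.00837, 3), 14.017)
  expect_true(all(diff(fragment_mz(fragment_mass_model(),
                                   "alkyl", 4:28)) > 0))
  expect_error(fragment_mz(m5, "alkyl", 41), "1, 40")
})

test_that("theoretical transition list covers the series three ways", {
  expect_equal(nrow(build_transitions(n_min = 16, n_max = 16)), 3L)
  full <- build_transitions()
  expect_equal(nrow(full), 75L)
  expect_equal(length(unique(full$chain_length)), 25L)
  # precursors strictly increasing in chain length
  pre <- unique(full[, c("chain_length", "precursor_mz")])
  expect_true(all(diff(pre$precursor_mz[order(pre$chain_length)]) > 0))
  expect_error(build_transitions(n_min = 20, n_max = 10), "n_min")
  expect_error(build_transitions(n_min = 2), "4..28", fixed = TRUE)
})

test_that("detection threshold on the bisulfite pair is strict", {
  at <- function(i) screen_alkylcom(
    simulate_mrm_run(16, intensity = i))$variety$variety
  expect_equal(at(1999), 0L)
  expect_equal(at(2000), 0L)  # strictly greater than
  expect_equal(at(2001), 1L)
})

test_that("screening recovers exactly the planted chain lengths", {
  run <- simulate_mrm_run(13:20, intensity = 5000, decoy_count = 25,
                          seed = 11)
  res <- screen_alkylcom(run)
  expect_equal(res$variety$variety, 8L)
  expect_setequal(res$variety$detected_chain_lengths, 13:20)
  # corroborating product ions recorded for planted homologs
  expect_true(all(grepl("HSO3", res$hits$matched_ions)))
})

test_that("decoys at least 1 Da off never match at 0.3 Da tolerance", {
  run <- simulate_mrm_run(integer(0), decoy_count = 200, seed = 5)
  res <- screen_alkylcom(run, mz_tolerance = 0.3)
  expect_equal(res$variety$variety, 0L)
  expect_equal(nrow(res$hits), 0L)
})

test_that("empty observed table gives variety zero, not an error", {
  res <- screen_alkylcom(data.frame(precursor_mz = numeric(0),
                                    product_mz = numeric(0),
                                    intensity = numeric(0)))
  expect_equal(res$variety$variety, 0L)
})

test_that("screen is monotone in observations and in the threshold", {
  set.seed(42)
  for (rep in 1:5) {
    planted <- sort(sample(4:28, sample(3:12, 1)))
    run <- simulate_mrm_run(planted, intensity = runif(1, 2500, 9000),
                            decoy_count = 10, seed = rep)
    v_full <- screen_alkylcom(run)$variety$variety
    sub <- run[sample(nrow(run), nrow(run) %/% 2), ]
    expect_lte(screen_alkylcom(sub)$variety$variety, v_full)
    expect_lte(screen_alkylcom(run,
                               intensity_threshold = 6000)$variety$variety,
               v_full)
    expect_lte(v_full, 25L)
  }
})
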