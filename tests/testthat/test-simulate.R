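# Synthetic-data generator: determinism, construction guarantees, coupling.

test_that("identical seeds give bit-identical outputs", {
  p <- chromatogram_sim_params(noise_sd = 0.05)
  a <- simulate_chromatogram(2, p, seed = 123)
  b <- simulate_chromatogram(2, p, seed = 123)
  expect_identical(a$chromatogram$intensity, b$chromatogram$intensity)
  expect_identical(simulate_mrm_run(10:14, decoy_count = 20, seed = 4),
                   simulate_mrm_run(10:14, decoy_count = 20, seed = 4))
  expect_identical(simulate_expression(seed = 5),
                   simulate_expression(seed = 5))
  s1 <- simulate_study(12, seed = 6); s2 <- simulate_study(12, seed = 6)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$features, s2$features)
})

test_that("degree-4 noise-free traces carry no n-alkane signal", {
  p0 <- chromatogram_sim_params(noise_sd = 0)
  ch <- simulate_chromatogram(4, p0, seed = 1)$chromatogram
  cal <- alkane_calibration()
  # at every n-alkane retention time the trace equals the UCM hump alone
  ucm_only <- 0.30 * exp(-0.5 * ((ch$rt - 18) / 6)^2) * 1e5
  at_alkanes <- vapply(cal$rt[grepl("nC", cal$identity)], function(r)
    ch$intensity[which.min(abs(ch$rt - r))] -
      ucm_only[which.min(abs(ch$rt - r))], numeric(1))
  # nearest alkane slots sit 5 peak-sigmas from Pr/Ph, so tails are negligible
  expect_true(all(abs(at_alkanes) < 1e-3 * max(ch$intensity)))
  expect_error(simulate_chromatogram(5, p0), "degree")
  expect_error(chromatogram_sim_params(rt_grid = c(0, 10, -1)))
})

test_that("MRM simulation plants exactly the requested ion pairs", {
  run <- simulate_mrm_run(16, intensity = 5000)
  expect_equal(nrow(run), 3L)
  expect_equal(length(unique(run$precursor_mz)), 1L)
  expect_equal(unique(run$precursor_mz),
               alkylcom_precursor_mz(fragment_mass_model(), 16))
  only_decoys <- simulate_mrm_run(integer(0), decoy_count = 7, seed = 2)
  expect_equal(nrow(only_decoys), 7L)
  expect_error(simulate_mrm_run(3), "\\[4, 28\\]")
})

test_that("expression generator degenerates and couples as designed", {
  # no covariate effect, intercept at the degree-2 logit: all degree 2
  flat <- simulate_expression(true_beta = c(0, 0), intercept = 0,
                              n_samples = 50, noise_sd = 0, seed = 3)
  expect_true(all(flat$degrees == 2L))
  expect_error(simulate_expression(noise_sd = -1), "noise_sd")
  # acrA coefficient dominant: degrees increase with acrA FPKM
  sim <- simulate_expression(n_samples = 300, seed = 8)
  expect_gt(cor(log(sim$fpkm$fpkm_acrA + 0.01), sim$degrees), 0.7)
})

test_that("study generator is coherent with its ground truth", {
  expect_equal(nrow(simulate_study(0)$samples), 0L)
  expect_error(simulate_study(5, degree_mix = c(1, 1, 0, 0, 0)),
               "proportions")
  st <- simulate_study(15, seed = 21)
  expect_equal(length(st$chromatograms), 15L)
  expect_equal(length(st$mrm), 15L)
  expect_false(any(duplicated(st$samples$sample_id)))
  # every sample carries a ground truth consistent with the metadata
  for (i in seq_len(15)) {
    expect_s3_class(st$truth[[i]], "ground_truth")
    expect_equal(st$truth[[i]]$degradation_degree,
                 st$samples$degradation_degree[i])
    expect_equal(length(st$truth[[i]]$planted_alkylcom_chain_lengths) > 0,
                 st$samples$true_has_alkylcom[i])
  }
  # qPCR Cq defined exactly for the samples with 16S present
  expect_equal(is.na(st$qpcr$cq), !st$samples$true_has_16S)
})
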