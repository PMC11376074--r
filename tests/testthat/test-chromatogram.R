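# Peak detection, series assignment, UCM index, and the 0-4 rule set.

test_that("peak detection handles flat and single-peak traces", {
  rt <- seq(0, 40, by = 0.02)
  expect_equal(nrow(detect_peaks(chromatogram(rt, rep(0, length(rt))))), 0L)
  one <- chromatogram(rt, 100 * exp(-0.5 * ((rt - 20) / 0.1)^2))
  pk <- detect_peaks(one)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$apex_rt, 20, tolerance = 0.01)
  # area close to the Gaussian integral height * sd * sqrt(2*pi)
  expect_equal(pk$area, 100 * 0.1 * sqrt(2 * pi), tolerance = 0.1)
})

test_that("noise-free pristine chromatogram yields the full 28-peak series", {
  sim <- simulate_chromatogram(0, chromatogram_sim_params(noise_sd = 0),
                               seed = 1)
  pk <- detect_peaks(sim$chromatogram)
  expect_equal(nrow(pk), 28L)  # nC10..nC35 plus Pr and Ph
  prof <- assign_series(pk)
  expect_equal(prof$n_alkanes_present, 26L)
  expect_equal(sum(prof$peaks$assignment %in% c("Pr", "Ph")), 2L)
  expect_equal(sum(prof$peaks$assignment == "unassigned"), 0L)
})

test_that("series assignment computes ratios with the missing-member rule", {
  cal <- alkane_calibration()
  rts <- cal$rt[match(c("nC17", "nC18", "Pr", "Ph"), cal$identity)]
  pk <- data.frame(apex_rt = rts, height = c(200, 150, 100, 100),
                   area = 1, assignment = "unassigned")
  prof <- assign_series(pk, cal)
  expect_equal(prof$c17_pr_ratio, 2.0)
  expect_equal(prof$c18_ph_ratio, 1.5)
  # Pr absent -> nC17/Pr undefined
  prof2 <- assign_series(pk[-3, ], cal)
  expect_true(is.na(prof2$c17_pr_ratio))
  expect_false(is.na(prof2$c18_ph_ratio))
  bad <- cal; bad$rt[bad$identity == "nC20"] <- bad$rt[bad$identity == "nC25"]
  expect_error(assign_series(pk, bad), "monotone")
})

test_that("UCM index separates resolved peaks from a broad hump", {
  rt <- seq(0, 40, by = 0.02)
  narrow <- Reduce(`+`, lapply(seq(5, 35, by = 2), function(ctr)
    exp(-0.5 * ((rt - ctr) / 0.08)^2)))
  expect_lt(compute_ucm_index(chromatogram(rt, narrow)), 0.05)
  hump <- exp(-0.5 * ((rt - 20) / 7)^2)
  expect_gt(compute_ucm_index(chromatogram(rt, hump)), 0.95)
  # constructed 50/50 split, oracle = trapezoid areas of the two components
  resolved <- 2.2 * narrow
  a_res <- pracma::trapz(rt, resolved); a_hump <- pracma::trapz(rt, hump)
  mix <- chromatogram(rt, resolved * (a_hump / a_res) + hump)
  expect_equal(compute_ucm_index(mix), 0.5, tolerance = 0.05)
  expect_equal(compute_ucm_index(chromatogram(rt, rep(0, length(rt)))), 0)
})

test_that("rule set assigns each described profile its degree", {
  # non-degraded: straight baseline, full series, ratios above 1
  s0 <- score_degradation(make_profile(2.0, 1.8, dominance = 1,
                                       residual_alkanes = 24), 0.02)
  expect_equal(s0$degree, 0L)
  # light degradation: slight UCM, ratios still above 1
  s1 <- score_degradation(make_profile(1.3, 1.2, dominance = 1,
                                       residual_alkanes = 24), 0.2)
  expect_equal(s1$degree, 1L)
  # severe: no n-alkanes at all under a significant UCM
  s4 <- score_degradation(make_profile(include_c17_c18 = FALSE), 0.7)
  expect_equal(s4$degree, 4L)
  # moderate, split by surviving non-Pr/Ph alkane count
  s2 <- score_degradation(make_profile(0.5, 0.4, dominance = 5,
                                       residual_alkanes = 10), 0.6)
  expect_equal(s2$degree, 2L)
  s3 <- score_degradation(make_profile(0.5, 0.4, dominance = 5,
                                       residual_alkanes = 2), 0.6)
  expect_equal(s3$degree, 3L)
})

test_that("profiles outside the described rules resolve deterministically", {
  # ratios undefined while alkanes present falls through to degree 0
  s <- score_degradation(make_profile(NA, NA, residual_alkanes = 5), 0.05)
  expect_equal(s$degree, 0L)
  # nothing detected and no significant UCM: indeterminate, not 0-4
  si <- score_degradation(make_profile(include_c17_c18 = FALSE), 0.1)
  expect_true(si$indeterminate)
  expect_true(is.na(si$degree))
})

test_that("scoring is invariant to overall intensity scale", {
  sim <- simulate_chromatogram(2, chromatogram_sim_params(noise_sd = 0.02),
                               seed = 7)
  ch <- sim$chromatogram
  ch1000 <- chromatogram(ch$rt, ch$intensity * 1000)
  expect_equal(compute_ucm_index(ch), compute_ucm_index(ch1000),
               tolerance = 1e-10)
  expect_equal(score_chromatogram(ch)$degree,
               score_chromatogram(ch1000)$degree)
})

test_that("noise-free simulated chromatograms score their own degree", {
  p0 <- chromatogram_sim_params(noise_sd = 0)
  for (d in 0:4) {
    sc <- score_chromatogram(simulate_chromatogram(d, p0,
                                                   seed = 50 + d)$chromatogram)
    expect_equal(sc$degree, as.integer(d))
  }
})

test_that("degree is monotone in the generator's degradation parameter", {
  p0 <- chromatogram_sim_params(noise_sd = 0)
  degs <- vapply(0:4, function(d)
    score_chromatogram(simulate_chromatogram(d, p0,
                                             seed = 9)$chromatogram)$degree,
    integer(1))
  expect_true(all(diff(degs) >= 0))
})
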