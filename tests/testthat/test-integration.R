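# Evidence groups, stratified detection, transforms, ridge regression.

test_that("all eight marker combinations map to the declared labels", {
  g <- expand.grid(s16 = c(TRUE, FALSE), acrA = c(TRUE, FALSE),
                   com = c(TRUE, FALSE))
  lab <- classify_evidence(g$s16, g$acrA, g$com)
  key <- paste(g$s16, g$acrA, g$com)
  expected <- c("TRUE TRUE TRUE" = "1", "TRUE FALSE TRUE" = "2",
                "FALSE FALSE TRUE" = "3", "FALSE FALSE FALSE" = "4",
                "FALSE TRUE TRUE" = "other", "TRUE TRUE FALSE" = "other",
                "FALSE TRUE FALSE" = "other", "TRUE FALSE FALSE" = "other")
  expect_equal(lab, unname(expected[key]))
  expect_warning(out <- classify_evidence(NA, TRUE, TRUE), "not classified")
  expect_true(is.na(out))
})

test_that("group labels partition every simulated dataset", {
  st <- simulate_study(60, seed = 13)
  has_acrA <- st$samples$true_fpkm_acrA > 0
  lab <- classify_evidence(st$samples$true_has_16S, has_acrA,
                           st$samples$true_has_alkylcom)
  expect_false(any(is.na(lab)))
  expect_true(all(lab %in% c("1", "2", "3", "4", "other")))
})

test_that("stratified proportions are exact on small fixtures", {
  out <- detection_summary(detected = c(TRUE, TRUE, FALSE, FALSE),
                           degree = c(3, 3, 3, 3))
  expect_equal(out$proportion, 0.5)
  all_hit <- detection_summary(rep(TRUE, 6), c(0, 0, 1, 1, 4, 4))
  expect_true(all(all_hit$proportion == 1))
  # empty strata are absent rather than 0/0
  expect_false("2" %in% all_hit$stratum)
  # weighted stratum average equals the pooled proportion
  set.seed(3)
  det <- runif(100) < 0.4; deg <- sample(0:4, 100, replace = TRUE)
  s <- detection_summary(det, deg)
  expect_equal(sum(s$proportion * s$n_total) / sum(s$n_total), mean(det))
})

test_that("planted per-degree detection rates are recovered", {
  rates <- c(0.64, 0.33, 0.50, 1.00, 0.78)
  st <- simulate_study(200, seed = 17)
  s <- detection_summary(st$samples$true_has_alkylcom,
                         st$samples$degradation_degree)
  s <- s[s$stratum_type == "degree", ]
  for (i in seq_len(nrow(s))) {
    p <- rates[as.integer(s$stratum[i]) + 1]
    half <- 1.96 * sqrt(p * (1 - p) / s$n_total[i])
    expect_gte(s$proportion[i], p - half - 1e-9)
    expect_lte(s$proportion[i], p + half + 1e-9)
  }
})

test_that("degree transform is the declared monotone logit", {
  xy <- transform_xy(matrix(c(0, 1, 2, 3, 4), ncol = 1), 0:4,
                     pseudocount = 1)
  expect_equal(xy$Y[3], 0)                       # degree 2 at the midpoint
  expect_true(all(diff(xy$Y) > 0))
  expect_equal(xy$X[1, 1], 0)                    # fpkm 0, pseudocount 1
  expect_message(
    dropped <- transform_xy(matrix(1:4, ncol = 1), c(0, NA, 2, 3)),
    "dropped")
  expect_equal(dropped$n_dropped, 1L)
  expect_error(transform_xy(matrix(1), 0, pseudocount = 0), "positive")
})

test_that("ridge solution matches its closed form and least squares", {
  set.seed(11)
  n <- 80
  X <- cbind(b = rnorm(n, 2, 1), a = rnorm(n, 0, 1.3))
  Y <- 0.3 * X[, 1] + 0.9 * X[, 2] + 0.5 + rnorm(n, 0, 0.2)
  xy <- structure(list(X = X, Y = Y, pseudocount = 0.01, n_dropped = 0L),
                  class = "transformed_xy")
  # lambda = 0 equals ordinary least squares
  f0 <- fit_ridge(xy, lambda = 0)
  ls <- stats::lm(Y ~ X)
  expect_equal(unname(f0$beta), unname(stats::coef(ls)[2:3]),
               tolerance = 1e-10)
  expect_equal(f0$intercept, unname(stats::coef(ls)[1]), tolerance = 1e-10)
  # independent oracle: normal equations on centred data
  for (lam in c(0.5, 5, 50)) {
    f <- fit_ridge(xy, lambda = lam)
    Xc <- scale(X, scale = FALSE); Yc <- Y - mean(Y)
    beta_ne <- solve(crossprod(Xc) + diag(lam, 2), crossprod(Xc, Yc))
    expect_equal(unname(f$beta), as.numeric(beta_ne), tolerance = 1e-10)
  }
  # zero-intercept mode honours the constraint
  fz <- fit_ridge(xy, lambda = 1, fit_intercept = FALSE)
  expect_identical(fz$intercept, 0)
  beta_z <- solve(crossprod(X) + diag(1, 2), crossprod(X, Y))
  expect_equal(unname(fz$beta), as.numeric(beta_z), tolerance = 1e-10)
  expect_error(fit_ridge(xy, lambda = -1), "nonnegative")
})

test_that("coefficient norm shrinks monotonically with the penalty", {
  sim <- simulate_expression(n_samples = 120, seed = 19)
  xy <- transform_xy(sim$fpkm[, 2:3], sim$degrees)
  norms <- vapply(c(0, 0.1, 1, 10, 1e3, 1e5), function(l)
    sqrt(sum(fit_ridge(xy, lambda = l)$beta^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
  expect_lt(norms[6], 0.05 * norms[1])
})

test_that("leave-one-out selection prefers small penalties on strong signal", {
  sim <- simulate_expression(n_samples = 60, noise_sd = 0.05, seed = 23)
  xy <- transform_xy(sim$fpkm[, 2:3], sim$degrees)
  sel <- select_lambda_loocv(xy, lambda_grid = c(0.01, 1, 100))
  expect_equal(sel$lambda, 0.01)
  expect_equal(names(which.min(sel$cv_mse)), "0.01")
})

test_that("simulation truth is recovered by the ridge stage", {
  sim <- simulate_expression(true_beta = c(0.01, 0.86), intercept = 0.49,
                             n_samples = 200, noise_sd = 0.1, seed = 1)
  xy <- transform_xy(sim$fpkm[, c("fpkm_bacterial", "fpkm_acrA")],
                     sim$degrees)
  f <- fit_ridge(xy, lambda = 0.01)
  expect_lt(abs(f$beta[["fpkm_bacterial"]] - 0.01), 0.05)
  expect_lt(abs(f$beta[["fpkm_acrA"]] - 0.86), 0.05)
  expect_gt(f$beta[["fpkm_acrA"]], f$beta[["fpkm_bacterial"]])
})
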