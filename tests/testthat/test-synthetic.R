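test_that("cohorts are bit-for-bit reproducible under a fixed seed", {
  spec <- population_spec(n = 40, seed = 101)
  expect_identical(generate_profiles(spec), generate_profiles(spec))
  expect_identical(simulate_cohort(spec), simulate_cohort(spec))
  expect_equal(nrow(generate_profiles(population_spec(n = 0, seed = 1))), 0)
})

test_that("an identity copula yields near-zero sample correlations", {
  spec <- population_spec(n = 10000, seed = 202, correlation = diag(14))
  X <- moreba:::draw_factors(spec)
  off <- stats::cor(X)
  diag(off) <- 0
  expect_lt(max(abs(off)), 0.05)
})

test_that("marginal means and the posture correlation match their targets", {
  spec <- population_spec(n = 10000, seed = 303)
  profiles <- generate_profiles(spec)
  fm <- moreba:::factor_matrix(profiles)
  target <- default_marginals()
  expect_true(all(abs(colMeans(fm)[target$factor] - target$mean) < 0.1))
  expect_true(all(fm >= matrix(target$lo, nrow(fm), 14, byrow = TRUE)))
  expect_true(all(fm <= matrix(target$hi, nrow(fm), 14, byrow = TRUE)))
  expect_lt(abs(cor(profiles$posture_a, profiles$posture_b) - 0.843), 0.07)
})

test_that("correlation error shrinks as the cohort grows", {
  frob <- function(n, seed) {
    X <- moreba:::draw_factors(population_spec(n = n, seed = seed))
    norm(stats::cor(X) - default_correlation(), "F")
  }
  expect_lt(frob(10000, 404), frob(500, 404))
})

test_that("load/force decomposition reproduces the drawn factor values", {
  profiles <- generate_profiles(population_spec(n = 500, seed = 505))
  fm <- moreba:::factor_matrix(profiles)
  expect_equal(load_subscore(profiles$load_time, profiles$load_weight),
               unname(fm[, "load"]))
  expect_true(all(fm[, "load"] == floor(fm[, "load"])))
})

test_that("outcome noise calibration follows the closed form", {
  expect_equal(calibrate_outcome(1, 1), 0)
  expect_equal(calibrate_outcome(1, 0.5), 1)
  expect_equal(calibrate_outcome(1, 0.67), sqrt(0.33 / 0.67))
  expect_equal(calibrate_outcome(4, 0.5, slope = 3), 6)
  expect_error(calibrate_outcome(1, 0), "target_r2")
})

test_that("latent-strain outcomes hit the calibrated R-squared", {
  spec <- population_spec(n = 10000, seed = 606, floor_at_zero = FALSE)
  profiles <- generate_profiles(spec)
  # zero noise: deterministic affine outcome
  spec1 <- spec
  spec1$target_r2 <- 1
  y1 <- generate_cmdq(profiles, spec = spec1, seed = 1)
  expect_equal(r_squared(moreba_score(profiles), y1), 1)
  # severed link: slope 0 leaves only noise
  y0 <- generate_cmdq(profiles, spec = spec, seed = 2, slope = 0)
  expect_lt(r_squared(moreba_score(profiles), y0), 0.01)
  # calibrated default
  y <- generate_cmdq(profiles, spec = spec, seed = 3)
  expect_lt(abs(r_squared(moreba_score(profiles), y) - 0.67), 0.03)
  expect_true(all(simulate_cohort(population_spec(n = 2000, seed = 7))$cmdq_total >= 0))
})

test_that("non-PSD correlation matrices are repaired or rejected", {
  expect_identical(nearest_psd(default_correlation()), default_correlation())
  # mild indefiniteness from rounding gets clipped back to a correlation
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.7
  R[1, 3] <- R[3, 1] <- 0.7
  R[2, 3] <- R[3, 2] <- -0.05  # min eigenvalue ~ -0.015
  fixed <- nearest_psd(R)
  expect_gte(min(eigen(fixed, symmetric = TRUE)$values), 0)
  expect_equal(diag(fixed), rep(1, 3))
  # badly indefinite: rejected with the smallest eigenvalue reported
  bad <- diag(3)
  bad[1, 2] <- bad[2, 1] <- 0.9
  bad[1, 3] <- bad[3, 1] <- 0.9
  bad[2, 3] <- bad[3, 2] <- -0.9
  expect_error(nearest_psd(bad), "eigenvalue")
  expect_error(population_spec(correlation = matrix(0.5, 14, 14) + diag(14) * 0.5 + 1),
               "unit diagonal|symmetric|14 x 14")
})
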