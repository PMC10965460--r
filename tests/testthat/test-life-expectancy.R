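test_that("constant-intensity life expectancies match the closed form", {
  # time in state 1 = 1/(q12+q13); time in state 2 = q12/((q12+q13) q23)
  m <- constant_intensity_model(0.02, 0.05, 0.10)
  sle <- state_specific_life_expectancy(m, 65, grid_step = 0.1, max_age = 465)
  expect_equal(sle$hale, 1 / 0.07, tolerance = 1e-3)
  expect_equal(unname(sle$e[1, 2]), 0.02 / (0.07 * 0.10), tolerance = 1e-3)
  expect_equal(sle$le, 1 / 0.07 + 0.02 / (0.07 * 0.10), tolerance = 2e-3)
  expect_equal(unname(sle$e[2, 2]), 1 / 0.10, tolerance = 1e-3)
  expect_equal(unname(sle$e[2, 1]), 0) # no recovery
})

test_that("degenerate transition structures reduce to single exponentials", {
  no_onset <- constant_intensity_model(0, 0.05, 0.10)
  sle <- state_specific_life_expectancy(no_onset, 65, max_age = 565)
  expect_equal(unname(sle$e[1, 2]), 0)
  expect_equal(sle$le, 1 / 0.05, tolerance = 1e-3)
  expect_equal(unname(sle$total[["diseased"]]), 1 / 0.10, tolerance = 1e-3)
})

test_that("halving the grid step leaves life expectancies stable", {
  m <- default_cohort_intensities()
  a <- state_specific_life_expectancy(m, 65, grid_step = 0.1)
  b <- state_specific_life_expectancy(m, 65, grid_step = 0.05)
  expect_lt(abs(a$hale - b$hale), 1e-3)
  expect_lt(abs(a$le - b$le), 1e-3)
})

test_that("truncated survival mass triggers a warning", {
  slow <- constant_intensity_model(0.001, 0.002, 0.004)
  expect_warning(state_specific_life_expectancy(slow, 65, max_age = 110),
                 "survival mass")
})

test_that("marginal quantities interpolate between the start states", {
  m <- default_cohort_intensities()
  sle <- state_specific_life_expectancy(m, 65)
  m0 <- marginal_life_expectancy(sle, 0)
  expect_equal(m0$le, sle$le)
  expect_equal(m0$hale, sle$hale)
  m1 <- marginal_life_expectancy(sle, 1)
  expect_equal(m1$hale, 0)
  expect_equal(m1$le, unname(sle$e[2, 2]))
})

small_fit <- function(n = 1200, seed = 61) {
  cfg <- simulation_config(
    cohort_size = n,
    intensity_model = constant_intensity_model(0.02, 0.03, 0.06),
    loss_to_followup_prob = 0, seed = seed)
  fit_idd_model(simulate_cohort(cfg), age_trend = FALSE, sex_effect = FALSE)
}

test_that("bootstrap intervals are reproducible and degenerate at zero variance", {
  fit <- small_fit()
  ci1 <- life_expectancy_ci(fit, 65, n_boot = 100, seed = 7)
  ci2 <- life_expectancy_ci(fit, 65, n_boot = 100, seed = 7)
  expect_identical(ci1, ci2)
  ci3 <- life_expectancy_ci(fit, 65, n_boot = 100, seed = 8)
  expect_false(identical(ci1$lower, ci3$lower))
  expect_true(all(ci1$lower <= ci1$estimate & ci1$estimate <= ci1$upper))

  degenerate <- fit
  degenerate$cov[] <- 0
  ci0 <- life_expectancy_ci(degenerate, 65, n_boot = 50)
  expect_equal(ci0$lower, ci0$estimate)
  expect_equal(ci0$upper, ci0$estimate)
})

test_that("a non-positive-definite covariance is refused", {
  fit <- small_fit()
  fit$cov <- matrix(c(1, 0, 0, 0, -1, 0, 0, 0, 1), 3, 3,
                    dimnames = dimnames(fit$cov))
  expect_error(life_expectancy_ci(fit, 65), "positive semi-definite")
})

test_that("interval width shrinks as the cohort grows", {
  ci_small <- life_expectancy_ci(small_fit(1200, seed = 61), 65,
                                 n_boot = 200, seed = 3)
  ci_large <- life_expectancy_ci(small_fit(12000, seed = 62), 65,
                                 n_boot = 200, seed = 3)
  width <- function(ci) ci$upper[ci$quantity == "hale"] -
    ci$lower[ci$quantity == "hale"]
  expect_lt(width(ci_large), width(ci_small))
})
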