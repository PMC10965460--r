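test_that("prevalence estimates reproduce the published cohort proportions", {
  est <- estimate_prevalence(c(10318, 4671, 5647), c(1325, 481, 844))
  expect_equal(round(100 * est$prevalence, 2), c(12.84, 10.30, 14.95))
  # Wilson score interval for the women, frozen from an independent
  # evaluation of the score formula
  expect_equal(est$ci_low[3], 0.140399, tolerance = 1e-5)
  expect_equal(est$ci_high[3], 0.158997, tolerance = 1e-5)
})

test_that("boundary and Wald cases behave", {
  est0 <- estimate_prevalence(100, 0)
  expect_equal(est0$prevalence, 0)
  expect_equal(est0$ci_low, 0)
  w <- estimate_prevalence(5647, 844, method = "wald")
  p <- 844 / 5647
  half <- qnorm(0.975) * sqrt(p * (1 - p) / 5647)
  expect_equal(w$ci_low, p - half)
  expect_equal(w$ci_high, p + half)
  expect_error(estimate_prevalence(0, 0), "positive")
  expect_error(estimate_prevalence(10, 11), "\\[0, n\\]")
})

test_that("direct standardisation is a weighted mean", {
  prev <- data.frame(age_start = c(65, 70), prevalence = c(0.10, 0.20))
  expect_equal(age_standardize_prevalence(prev, c(3, 1)), 0.125)
  expect_equal(age_standardize_prevalence(prev, c(0, 7)), 0.20)
  uni <- data.frame(age_start = c(65, 70, 75), prevalence = rep(0.13, 3))
  expect_equal(age_standardize_prevalence(uni, c(5, 1, 9)), 0.13)
  wt <- data.frame(age_start = c(70, 65), weight = c(1, 3))
  expect_equal(age_standardize_prevalence(prev, wt), 0.125)
  expect_error(age_standardize_prevalence(prev, c(1, 2, 3)), "match")
  expect_error(age_standardize_prevalence(prev, c(0, 0)), "zero")
})

test_that("Sullivan weighting satisfies the boundary identities", {
  lt <- build_abridged_life_table(toy_counts())
  ages <- lt$age_start
  h0 <- sullivan_hale(lt, data.frame(age_start = ages, prevalence = 0))
  expect_equal(h0$hale, lt$e, tolerance = 1e-12)
  expect_equal(h0$ratio_pct, rep(100, 5))
  h1 <- sullivan_hale(lt, data.frame(age_start = ages, prevalence = 1))
  expect_equal(h1$hale, rep(0, 5))
  h5 <- sullivan_hale(lt, data.frame(age_start = ages, prevalence = 0.5))
  expect_equal(h5$hale, lt$e / 2, tolerance = 1e-12)
})

test_that("HALE is monotone in prevalence and bounded by LE", {
  lt <- build_abridged_life_table(toy_counts())
  ages <- lt$age_start
  set.seed(42)
  for (rep in 1:20) {
    pi_y <- runif(5)
    h <- sullivan_hale(lt, data.frame(age_start = ages, prevalence = pi_y))
    expect_true(all(h$hale >= 0 & h$hale <= h$le + 1e-12))
    j <- sample(5, 1)
    worse <- pi_y
    worse[j] <- min(1, worse[j] + 0.1)
    hw <- sullivan_hale(lt, data.frame(age_start = ages, prevalence = worse))
    expect_true(all(hw$hale <= h$hale + 1e-12))
    expect_lt(hw$hale[1], h$hale[1]) # strictly where L > 0
  }
})

test_that("prevalence is carried forward into unobserved old ages", {
  lt <- build_abridged_life_table(toy_counts())
  short <- data.frame(age_start = c(65, 70, 75), prevalence = c(0.1, 0.12, 0.15))
  full <- data.frame(age_start = c(65, 70, 75, 80, 85),
                     prevalence = c(0.1, 0.12, 0.15, 0.15, 0.15))
  expect_equal(sullivan_hale(lt, short, 65), sullivan_hale(lt, full, 65))
})

test_that("misaligned or invalid prevalence inputs are rejected", {
  lt <- build_abridged_life_table(toy_counts())
  expect_error(
    sullivan_hale(lt, data.frame(age_start = c(65, 71), prevalence = c(.1, .1))),
    "align")
  expect_error(
    sullivan_hale(lt, data.frame(age_start = 65, prevalence = 1.2)),
    "\\[0, 1\\]")
  expect_error(
    sullivan_hale(lt, data.frame(age_start = 65, prevalence = .1), 67),
    "interval start")
})

test_that("HALE/LE ratio matches printed-value arithmetic", {
  expect_equal(hale_le_ratio(20, 18), 90)
  expect_equal(hale_le_ratio(17.5, 17.5), 100)
  # Table-2-style division of printed LE and HALE for women aged 65-69
  expect_equal(round(hale_le_ratio(21.81, 18.73), 2), 85.88)
  expect_error(hale_le_ratio(0, 0), "positive")
  expect_error(hale_le_ratio(10, 11), "\\[0, le\\]")
})
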