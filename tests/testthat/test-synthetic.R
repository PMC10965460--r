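null_config <- function(n = 200, ...) {
  simulation_config(
    cohort_size = n,
    intensity_model = intensity_model(alpha = c(-Inf, -Inf, -Inf)),
    loss_to_followup_prob = 0, seed = 9, ...)
}

test_that("the null process produces only healthy survivors", {
  rec <- simulate_cohort(null_config())
  expect_true(all(rec$entry_state == 1L))
  expect_true(all(rec$exit_kind == "alive_observed"))
  expect_true(all(rec$exit_state == 1L))
  agg <- aggregate_counts(rec)
  expect_true(all(agg$counts$deaths == 0))
  expect_true(all(agg$prevalence$cases == 0))
})

test_that("without an onset pathway nobody is or becomes diseased", {
  cfg <- simulation_config(
    cohort_size = 400,
    intensity_model = intensity_model(alpha = c(-Inf, log(0.02), log(0.05))),
    loss_to_followup_prob = 0.1, seed = 10)
  rec <- simulate_cohort(cfg)
  expect_equal(sum(rec$entry_state == 2L), 0)
  expect_equal(sum(rec$exit_state == 2L, na.rm = TRUE), 0)
  expect_gt(sum(rec$exit_kind == "death_exact"), 0)
})

test_that("identical seed and config give bit-identical cohorts", {
  cfg <- simulation_config(cohort_size = 300, seed = 123)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  cfg2 <- simulation_config(cohort_size = 300, seed = 124)
  expect_false(identical(simulate_cohort(cfg), simulate_cohort(cfg2)))
})

test_that("no record implies recovery from the diseased state", {
  cfg <- simulation_config(cohort_size = 2000, seed = 5)
  rec <- simulate_cohort(cfg)
  expect_equal(sum(rec$entry_state == 2L & rec$exit_state == 1L,
                   na.rm = TRUE), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(cohort_size = 0), "positive")
  expect_error(simulation_config(burn_in_start_age = 70), "precede")
  expect_error(simulation_config(max_age = 75), "exceed")
  expect_error(simulation_config(loss_to_followup_prob = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(followup_gap_mean = 1,
                                 followup_gap_jitter = 2), "positive")
})

test_that("cohort margins match closed-form occupancy of the constant chain", {
  # constant onset 0.03, healthy death 0.02, diseased death 0.05,
  # burn-in from 50, enrolment 65-79, fixed 3-year follow-up gap
  cfg <- simulation_config(
    cohort_size = 50000,
    intensity_model = constant_intensity_model(0.03, 0.02, 0.05),
    followup_gap_mean = 3, followup_gap_jitter = 0,
    loss_to_followup_prob = 0, seed = 31)
  rec <- simulate_cohort(cfg)

  # Baseline prevalence: per-subject closed-form probability of being in
  # state 2 at the entry age, conditional on being alive (left truncation)
  t_i <- rec$entry_age - 50
  occ <- t(vapply(t_i, function(t) cc_occupancy(0.03, 0.02, 0.05, t),
                  numeric(3)))
  p_i <- occ[, "P12"] / (occ[, "P11"] + occ[, "P12"])
  obs <- sum(rec$entry_state == 2L)
  expect_lt(abs(obs - sum(p_i)), 3 * sqrt(sum(p_i * (1 - p_i))))

  # Outcomes at follow-up among those entering disease-free: multinomial
  # with closed-form constant-chain probabilities over the 3-year gap
  healthy <- rec[rec$entry_state == 1L, ]
  pr <- cc_occupancy(0.03, 0.02, 0.05, 3)
  n_h <- nrow(healthy)
  for (ev in c("P11", "P12", "P13")) {
    obs_n <- switch(ev,
      P11 = sum(healthy$exit_kind == "alive_observed" & healthy$exit_state == 1L),
      P12 = sum(healthy$exit_kind == "alive_observed" & healthy$exit_state == 2L),
      P13 = sum(healthy$exit_kind == "death_exact"))
    expect_lt(abs(obs_n - n_h * pr[ev]), 3 * sqrt(n_h * pr[ev] * (1 - pr[ev])))
  }
})

test_that("exposure and death aggregation is exact on hand-built records", {
  one <- data.frame(subject_id = 1, sex = "female", entry_age = 70,
                    entry_state = 1, exit_age = 75, exit_kind = "alive_observed",
                    exit_state = 1)
  agg <- aggregate_counts(one, age_breaks = c(65, 70, 75, 80))
  expect_equal(agg$counts$population, c(0, 5, 0, 0))
  expect_equal(agg$counts$deaths, c(0, 0, 0, 0))

  died <- data.frame(subject_id = 1, sex = "male", entry_age = 71,
                     entry_state = 2, exit_age = 77.5, exit_kind = "death_exact",
                     exit_state = NA)
  agg2 <- aggregate_counts(died, age_breaks = c(65, 70, 75, 80))
  expect_equal(agg2$counts$deaths, c(0, 0, 1, 0))
  expect_equal(agg2$counts$population, c(0, 4, 2.5, 0))
  expect_equal(agg2$prevalence$cases[agg2$prevalence$age_start == 70], 1)

  expect_error(aggregate_counts(one, age_breaks = c(71, 75, 80)),
               "below the first age break")
})

test_that("interval death rates recover a constant mortality hazard", {
  cfg <- simulation_config(
    cohort_size = 30000,
    intensity_model = constant_intensity_model(0, 0.04, 0),
    followup_gap_mean = 40, followup_gap_jitter = 1,
    loss_to_followup_prob = 0, seed = 77, max_age = 130)
  rec <- simulate_cohort(cfg)
  agg <- aggregate_counts(rec, age_breaks = seq(65, 90, 5))
  m_hat <- agg$counts$deaths / agg$counts$population
  se <- sqrt(agg$counts$deaths) / agg$counts$population
  expect_true(all(abs(m_hat - 0.04) < 3 * se))
})

test_that("published margin fixtures encode the cohort accounting", {
  mg <- henan_margins()
  expect_s3_class(mg$screening, "data.frame")
  expect_equal(mg$screening$n[mg$screening$stage == "analytic"], 10318L)
  expect_equal(mg$screening$n[1] - sum(mg$screening$n[2:4]), 10318L)
  expect_equal(sum(mg$by_sex$n), 10318L)
  expect_equal(mg$by_sex$baseline_t2dm, c(481L, 844L))
  expect_equal(sum(mg$by_sex$baseline_t2dm), 1325L)
  expect_equal(sum(mg$by_sex$incident_t2dm), 394L)
  expect_equal(mg$followup$n, c(10318L, 1185L, 9133L))
  expect_equal(mg$followup$n[1] - mg$followup$n[2], mg$followup$n[3])
})
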