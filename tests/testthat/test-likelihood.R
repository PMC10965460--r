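one_record <- function(entry_state = 1, exit_state = 1, entry = 65, exit = 72,
                       kind = "alive_observed", sex = "female", id = 1) {
  data.frame(subject_id = id, sex = sex, entry_age = entry,
             entry_state = entry_state, exit_age = exit, exit_kind = kind,
             exit_state = ifelse(kind == "alive_observed", exit_state, NA))
}

test_that("a healthy-to-healthy interval matches the closed form", {
  m <- constant_intensity_model(0.03, 0.02, 0.05)
  ll <- panel_log_likelihood(m, one_record(1, 1, 65, 72))
  expect_equal(ll, log(cc_occupancy(0.03, 0.02, 0.05, 7)[["P11"]]),
               tolerance = 1e-10)
})

test_that("an exact death sums over the unknown pre-death state", {
  m <- constant_intensity_model(0.03, 0.02, 0.05)
  ll <- panel_log_likelihood(m, one_record(1, NA, 65, 70, kind = "death_exact"))
  occ <- cc_occupancy(0.03, 0.02, 0.05, 5)
  expect_equal(ll, log(occ[["P11"]] * 0.02 + occ[["P12"]] * 0.05),
               tolerance = 1e-10)
  ll2 <- panel_log_likelihood(m, one_record(2, NA, 65, 70, kind = "death_exact"))
  expect_equal(ll2, log(exp(-0.05 * 5) * 0.05), tolerance = 1e-10)
})

test_that("an observed recovery is impossible and flagged", {
  m <- constant_intensity_model(0.03, 0.02, 0.05)
  expect_warning(ll <- panel_log_likelihood(m, one_record(2, 1, 65, 70, id = 99)),
                 "99")
  expect_identical(ll, -Inf)
})

test_that("panel likelihood equals a brute-force ODE computation", {
  skip_if_not_installed("deSolve")
  m <- intensity_model(alpha = log(c(0.02, 0.015, 0.04)),
                       xi = c(0.03, 0.08, 0.07), beta = c(-0.3, 0.4, 0.4))
  recs <- rbind(one_record(1, 1, 65.2, 68.9, id = 1),
                one_record(1, 2, 70.4, 73.3, id = 2, sex = "male"),
                one_record(2, 2, 75.0, 78.8, id = 3),
                one_record(1, NA, 66.5, 69.1, kind = "death_exact", id = 4),
                one_record(2, NA, 72.2, 74.0, kind = "death_exact",
                           sex = "male", id = 5))
  ll <- panel_log_likelihood(m, recs, grid_step = 0.01)
  expect_equal(ll, ode_panel_log_likelihood(m, recs), tolerance = 1e-6)
})

test_that("lost records contribute nothing under either handling", {
  m <- constant_intensity_model(0.03, 0.02, 0.05)
  recs <- rbind(one_record(1, 1, 65, 72, id = 1),
                one_record(1, NA, 66, 70, kind = "lost", id = 2))
  kept <- panel_log_likelihood(m, recs[1, ])
  expect_equal(panel_log_likelihood(m, recs), kept)
  expect_equal(panel_log_likelihood(m, recs, lost_action = "censor_at_entry"),
               kept)
})

test_that("the true model beats perturbed models on a large cohort", {
  cfg <- simulation_config(
    cohort_size = 4000,
    intensity_model = constant_intensity_model(0.02, 0.03, 0.06),
    loss_to_followup_prob = 0.1, seed = 21)
  rec <- simulate_cohort(cfg)
  ll_true <- panel_log_likelihood(cfg$intensity_model, rec)
  for (j in 1:3) for (f in c(0.5, 1.5)) {
    q <- c(0.02, 0.03, 0.06)
    q[j] <- q[j] * f
    ll_pert <- panel_log_likelihood(constant_intensity_model(q[1], q[2], q[3]),
                                    rec)
    expect_gt(ll_true, ll_pert)
  }
})
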