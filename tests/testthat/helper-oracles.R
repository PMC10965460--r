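# Independent oracles used across the suite. Everything here is written
# against the model definition directly (ODE solves, closed forms), not
# against the package's transition-probability code path.

# High-accuracy solve of the Kolmogorov forward equations dP/dt = P Q(t).
ode_transition_matrix <- function(model, a0, a1, z = 0) {
  rhs <- function(t, y, parms) {
    q <- transition_intensities(model, t, z)[1, ]
    Q <- rbind(c(-(q[1] + q[2]), q[1], q[2]),
               c(0, -q[3], q[3]),
               c(0, 0, 0))
    P <- matrix(y, 3, 3, byrow = TRUE)
    list(as.vector(t(P %*% Q)))
  }
  out <- deSolve::lsoda(as.vector(t(diag(3))), c(a0, a1), rhs,
                        rtol = 1e-12, atol = 1e-14)
  matrix(out[nrow(out), -1], 3, 3, byrow = TRUE)
}

# Brute-force panel log-likelihood from ODE-solved transition matrices.
ode_panel_log_likelihood <- function(model, records) {
  ll <- 0
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$exit_kind == "lost") next
    z <- as.numeric(r$sex == "male")
    P <- ode_transition_matrix(model, r$entry_age, r$exit_age, z)
    if (r$exit_kind == "alive_observed") {
      ll <- ll + log(P[r$entry_state, r$exit_state])
    } else {
      q <- transition_intensities(model, r$exit_age, z)[1, ]
      dens <- if (r$entry_state == 1L) P[1, 1] * q["q13"] + P[1, 2] * q["q23"]
      else P[2, 2] * q["q23"]
      ll <- ll + log(dens)
    }
  }
  unname(ll)
}

# Closed-form occupancy probabilities of the constant-rate illness-death
# chain started disease-free: P11, P12, P13 after time t.
cc_occupancy <- function(l12, l13, l23, t) {
  lam <- l12 + l13
  p11 <- exp(-lam * t)
  p12 <- if (abs(lam - l23) < 1e-12) l12 * t * exp(-lam * t)
  else l12 * (exp(-l23 * t) - exp(-lam * t)) / (lam - l23)
  c(P11 = p11, P12 = p12, P13 = 1 - p11 - p12)
}

# Random Gompertz intensity models under a fixed seed.
random_models <- function(n, seed, gompertz = TRUE) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    intensity_model(alpha = log(stats::runif(3, 0.005, 0.08)),
                    xi = if (gompertz) stats::runif(3, -0.02, 0.12) else c(0, 0, 0),
                    beta = stats::runif(3, -0.5, 0.5),
                    reference_age = 65)
  })
}

# Small mortality schedule for life-table and Sullivan unit tests.
toy_counts <- function() {
  data.frame(age_start = c(65, 70, 75, 80, 85),
             age_width = c(5, 5, 5, 5, NA),
             population = c(90000, 80000, 60000, 35000, 20000),
             deaths = c(900, 1300, 1500, 1700, 2400))
}
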