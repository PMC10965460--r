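# Transition probabilities of the illness-death process.
#
# For the upper-triangular generator of the progressive three-state model
# the matrix exponential has a closed two-exponential form obtained from
# its eigendecomposition (eigenvalues -(H12+H13), -H23, 0 for the
# integrated generator with entries H_rs). The 1->2 entry degenerates
# when the two non-zero eigenvalues collide; the stable series branch is
# taken through expm1.

# (1 - exp(-d)) / d, stable near d = 0.
phi_expm1 <- function(d) {
  out <- ifelse(abs(d) < 1e-12, 1 - d / 2, -expm1(-d) / d)
  out
}

# Exponential of the integrated generator with cumulative hazards
# H12, H13, H23 over one step. Exact when the generator is constant over
# the step. Vectorised; returns the five free entries of the stochastic
# matrix (the remainder are structural zeros/ones).
step_probs <- function(H12, H13, H23) {
  A <- H12 + H13
  E11 <- exp(-A)
  E22 <- exp(-H23)
  E12 <- H12 * E22 * phi_expm1(A - H23)
  E13 <- pmax(0, 1 - E11 - E12)
  list(E11 = E11, E12 = E12, E13 = E13, E22 = E22, E23 = 1 - E22)
}

# Core engine: free entries of P(t0, t1) for vectors of intervals.
# Age-constant models are handled in a single exact step; age-varying
# models by an ordered product of per-subinterval exponentials of the
# exactly-integrated generator on a grid of width <= grid_step.
tp_entries <- function(model, t0, t1, z = 0, grid_step = 0.25) {
  n <- max(length(t0), length(t1), length(z))
  t0 <- rep_len(as.numeric(t0), n)
  t1 <- rep_len(as.numeric(t1), n)
  z <- rep_len(as.numeric(z), n)
  if (any(t1 < t0)) stop("'t1' must be >= 't0'")
  if (!is.numeric(grid_step) || grid_step <= 0) stop("'grid_step' must be > 0")
  gap <- t1 - t0
  constant <- all(model$xi == 0)
  K <- if (constant) rep(1L, n) else pmax(1L, as.integer(ceiling(gap / grid_step)))
  h <- ifelse(K > 0, gap / K, 0)
  P11 <- rep(1, n); P12 <- numeric(n); P13 <- numeric(n)
  P22 <- rep(1, n); P23 <- numeric(n)
  if (n == 0L) {
    return(cbind(P11 = P11, P12 = P12, P13 = P13, P22 = P22, P23 = P23))
  }
  for (k in seq_len(max(K))) {
    act <- which(K >= k & gap > 0)
    if (!length(act)) break
    s0 <- t0[act] + (k - 1) * h[act]
    s1 <- s0 + h[act]
    H <- cumulative_hazards(model, s0, s1, z[act])
    E <- step_probs(H[, 1], H[, 2], H[, 3])
    p11 <- P11[act]; p12 <- P12[act]; p22 <- P22[act]
    P11[act] <- p11 * E$E11
    P12[act] <- p11 * E$E12 + p12 * E$E22
    P13[act] <- P13[act] + p11 * E$E13 + p12 * E$E23
    P22[act] <- p22 * E$E22
    P23[act] <- P23[act] + p22 * E$E23
  }
  cbind(P11 = P11, P12 = P12, P13 = P13, P22 = P22, P23 = P23)
}

#' Transition probability matrix between two ages
#'
#' Computes the 3x3 matrix \eqn{P(a_0, a_1)} whose entry \eqn{(r, s)} is
#' the probability of occupying state \eqn{s} at age \eqn{a_1} given
#' state \eqn{r} at age \eqn{a_0}, under an [intensity_model()]. For an
#' age-constant model this is the exact matrix exponential
#' \eqn{\exp\{Q (a_1 - a_0)\}}; for age-varying (Gompertz) intensities it
#' is the ordered product of per-subinterval exponentials of the exactly
#' integrated generator over a grid of width at most `grid_step`, which
#' is exact up to the (small) non-commutativity of the generator across
#' subintervals.
#'
#' Structural invariants of the progressive process hold by construction:
#' rows sum to one, the dead row is `(0, 0, 1)`, and the recovery entry
#' is zero.
#'
#' @inheritParams build_intensity_matrix
#' @param a0,a1 ages in years, `a1 >= a0`.
#' @param grid_step grid width (years) for age-varying intensities.
#' @return 3x3 stochastic matrix with dimnames
#'   `c("healthy", "diseased", "dead")`.
#' @examples
#' m <- constant_intensity_model(0.03, 0.02, 0.05)
#' transition_probability(m, 65, 75)
#' @export
transition_probability <- function(model, a0, a1, z = 0, grid_step = 0.25) {
  stopifnot(inherits(model, "intensity_model"),
            length(a0) == 1L, length(a1) == 1L, length(z) == 1L)
  if (a1 < a0) stop("'a1' must be >= 'a0'")
  p <- tp_entries(model, a0, a1, z, grid_step)[1, ]
  st <- c("healthy", "diseased", "dead")
  matrix(c(p[["P11"]], p[["P12"]], p[["P13"]],
           0, p[["P22"]], p[["P23"]],
           0, 0, 1),
         nrow = 3, byrow = TRUE, dimnames = list(st, st))
}
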