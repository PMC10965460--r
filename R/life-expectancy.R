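#' Total and state-specific life expectancy from an intensity model
#'
#' Integrates the transition probabilities of the illness-death model to
#' obtain the expected years spent in each living state from a starting
#' age and state:
#' \deqn{e_{rs}(a) = \int_0^{\omega - a} P_{rs}(a, a + u)\, du}
#' evaluated by the trapezoid rule on a grid of width `grid_step`, with
#' the upper limit `max_age` standing in for the maximum attainable age
#' \eqn{\omega}. For a subject disease-free at age `a`, total life
#' expectancy is \eqn{e_{11} + e_{12}} and health-adjusted life
#' expectancy (years lived disease-free) is \eqn{e_{11}}; for a subject
#' already diseased, \eqn{e_{21} = 0} (no recovery) and remaining life
#' expectancy is \eqn{e_{22}}.
#'
#' If the survival mass remaining at `max_age` is non-negligible the
#' integral is truncated; a warning reports the residual mass.
#'
#' @inheritParams transition_probability
#' @param start_age starting exact age (years).
#' @param grid_step integration grid width (years); default 0.1.
#' @param max_age upper integration limit (years); default 110.
#' @return object of class `state_life_expectancy`: matrix `e` of
#'   expected years by starting state (rows) and living state occupied
#'   (columns), `total` per starting state, and the convenience scalars
#'   `le` (total from the disease-free state) and `hale` (disease-free
#'   years from the disease-free state).
#' @examples
#' m <- constant_intensity_model(0.02, 0.05, 0.10)
#' state_specific_life_expectancy(m, start_age = 65)
#' @export
state_specific_life_expectancy <- function(model, start_age, z = 0,
                                           grid_step = 0.1, max_age = 110) {
  stopifnot(inherits(model, "intensity_model"),
            length(start_age) == 1L, length(z) == 1L)
  if (!(start_age < max_age)) stop("'start_age' must be below 'max_age'")
  if (grid_step <= 0) stop("'grid_step' must be > 0")
  horizon <- max_age - start_age
  K <- max(1L, as.integer(ceiling(horizon / grid_step)))
  h <- horizon / K
  # March the occupancy probabilities forward one subinterval at a time,
  # accumulating trapezoid weights as we go.
  P11 <- 1; P12 <- 0; P22 <- 1
  e11 <- 0.5 * P11; e12 <- 0.5 * P12; e22 <- 0.5 * P22
  for (k in seq_len(K)) {
    s0 <- start_age + (k - 1) * h
    H <- cumulative_hazards(model, s0, s0 + h, z)
    E <- step_probs(H[, 1], H[, 2], H[, 3])
    P12 <- P11 * E$E12 + P12 * E$E22
    P11 <- P11 * E$E11
    P22 <- P22 * E$E22
    w <- if (k < K) 1 else 0.5
    e11 <- e11 + w * P11
    e12 <- e12 + w * P12
    e22 <- e22 + w * P22
  }
  e11 <- e11 * h; e12 <- e12 * h; e22 <- e22 * h
  residual <- max(P11 + P12, P22)
  if (residual > 1e-3)
    warning(sprintf(
      "survival mass %.2e remains at max_age = %g; life expectancies are truncated",
      residual, max_age), call. = FALSE)
  e <- matrix(c(e11, e12, 0, e22), nrow = 2, byrow = TRUE,
              dimnames = list(start = c("healthy", "diseased"),
                              years_in = c("healthy", "diseased")))
  structure(
    list(start_age = start_age, z = z, e = e,
         total = rowSums(e),
         le = unname(e[1, 1] + e[1, 2]),
         hale = unname(e[1, 1]),
         grid_step = grid_step, max_age = max_age,
         residual_mass = residual),
    class = "state_life_expectancy")
}

#' @export
print.state_life_expectancy <- function(x, ...) {
  cat("State-specific life expectancy at age ", x$start_age,
      " (z = ", x$z, ")\n", sep = "")
  print(round(cbind(x$e, total = x$total), 3))
  cat(sprintf("LE (from healthy) %.3f y; HALE %.3f y; HALE/LE %.2f%%\n",
              x$le, x$hale, 100 * x$hale / x$le))
  invisible(x)
}

#' Parametric-bootstrap confidence intervals for life expectancies
#'
#' Draws parameter vectors from the asymptotic normal distribution of a
#' fitted illness-death model, recomputes the state-specific life
#' expectancies for each draw, and reports percentile intervals.
#' Reproducible for a fixed `seed`; a zero covariance matrix yields
#' degenerate intervals equal to the point estimates.
#'
#' @param fit an `idd_fit` from [fit_idd_model()].
#' @inheritParams state_specific_life_expectancy
#' @param n_boot number of parameter draws.
#' @param level confidence level.
#' @param seed integer seed for the draws.
#' @return data frame with one row per quantity (`hale` = disease-free
#'   years from healthy, `e12`, `le` = total from healthy, `e22`) giving
#'   the point estimate and percentile bounds.
#' @export
life_expectancy_ci <- function(fit, start_age, z = 0, grid_step = 0.1,
                               max_age = 110, n_boot = 500, level = 0.95,
                               seed = 1) {
  stopifnot(inherits(fit, "idd_fit"))
  V <- fit$cov
  if (any(!is.finite(V)))
    stop("fit has no usable covariance matrix")
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("covariance matrix is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")")
  point <- le_quantities(fit$model, start_age, z, grid_step, max_age)
  if (all(V == 0)) {
    draws <- matrix(rep(point, n_boot), nrow = n_boot, byrow = TRUE)
  } else {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
    s <- fit$settings
    theta <- MASS::mvrnorm(n_boot, mu = fit$coefficients, Sigma = V,
                           tol = 1e-6)
    draws <- t(apply(theta, 1, function(th) {
      m <- model_from_theta(th, s$age_trend, s$sex_effect, s$reference_age)
      le_quantities(m, start_age, z, grid_step, max_age)
    }))
  }
  a <- (1 - level) / 2
  data.frame(quantity = names(point),
             estimate = unname(point),
             lower = apply(draws, 2, stats::quantile, probs = a),
             upper = apply(draws, 2, stats::quantile, probs = 1 - a),
             row.names = NULL)
}

le_quantities <- function(model, start_age, z, grid_step, max_age) {
  sle <- suppressWarnings(
    state_specific_life_expectancy(model, start_age, z, grid_step, max_age))
  c(hale = sle$hale, e12 = unname(sle$e[1, 2]), le = sle$le,
    e22 = unname(sle$e[2, 2]))
}

#' Population-marginal life expectancy and HALE
#'
#' Averages the state-specific life expectancies over the baseline state
#' distribution: with prevalence \eqn{\pi} at the starting age, marginal
#' LE is \eqn{(1-\pi)(e_{11}+e_{12}) + \pi e_{22}} and marginal HALE is
#' \eqn{(1-\pi) e_{11}} (a subject already diseased accrues no further
#' disease-free years). This is the multistate quantity comparable to
#' Sullivan estimates, which are computed on the prevalence-mixed period
#' population rather than conditionally on starting disease-free.
#'
#' @param sle a [state_specific_life_expectancy()] result.
#' @param prevalence disease prevalence at the starting age, in `[0, 1]`.
#' @return data frame with `le`, `hale` and `ratio_pct`.
#' @export
marginal_life_expectancy <- function(sle, prevalence) {
  stopifnot(inherits(sle, "state_life_expectancy"),
            length(prevalence) == 1L, prevalence >= 0, prevalence <= 1)
  le <- (1 - prevalence) * sle$le + prevalence * unname(sle$e[2, 2])
  hale <- (1 - prevalence) * sle$hale
  data.frame(le = le, hale = hale, ratio_pct = hale_le_ratio(le, hale))
}
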