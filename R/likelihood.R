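#' Panel log-likelihood of the illness-death model
#'
#' Log-likelihood of two-wave panel records under an [intensity_model()],
#' with interval-censored living-state transitions and exactly observed
#' death times. Each subject contributes
#' \itemize{
#'   \item `alive_observed`: \eqn{\log P_{s_0 s_1}(a_0, a_1)} -- the
#'     transition probability from the entry state at the entry age to the
#'     exit state at the follow-up age; disease onset anywhere inside the
#'     interval is integrated out by the transition probability.
#'   \item `death_exact`: \eqn{\log \sum_{r \in \{1,2\}}
#'     P_{s_0 r}(a_0, a_d)\, q_{r3}(a_d)} -- the death age is known but
#'     the living state immediately before death is not, so both paths are
#'     summed (density, not probability).
#'   \item `lost`: excluded (default) or right-censored at entry, which
#'     contributes probability one; controlled by `lost_action`.
#' }
#'
#' An observation that is impossible under the progressive model (a
#' recorded 2 -> 1 recovery, or any zero-probability transition) makes the
#' log-likelihood `-Inf`; a warning identifies the offending subjects.
#'
#' @param model an [intensity_model()].
#' @param records panel-record data frame (see [simulate_cohort()] or
#'   [read_panel_csv()] for the layout).
#' @param grid_step grid width (years) used for age-varying transition
#'   probabilities.
#' @param lost_action `"exclude"` drops lost-to-follow-up records;
#'   `"censor_at_entry"` keeps them as observed only at entry (both give
#'   the same likelihood value; the flag exists to make the handling
#'   explicit).
#' @return the log-likelihood (scalar). `-Inf` if any record has zero
#'   probability under `model`.
#' @export
panel_log_likelihood <- function(model, records, grid_step = 0.25,
                                 lost_action = c("exclude", "censor_at_entry")) {
  stopifnot(inherits(model, "intensity_model"))
  lost_action <- match.arg(lost_action)
  records <- validate_panel(records)
  records <- records[records$exit_kind != "lost", , drop = FALSE]
  if (!nrow(records)) return(0)
  z <- as.numeric(records$sex == "male")
  P <- tp_entries(model, records$entry_age, records$exit_age, z, grid_step)
  contrib <- numeric(nrow(records))

  alive <- records$exit_kind == "alive_observed"
  s0 <- records$entry_state
  s1 <- records$exit_state
  p_alive <- rep(NA_real_, nrow(records))
  p_alive[alive & s0 == 1L & s1 == 1L] <- P[alive & s0 == 1L & s1 == 1L, "P11"]
  p_alive[alive & s0 == 1L & s1 == 2L] <- P[alive & s0 == 1L & s1 == 2L, "P12"]
  p_alive[alive & s0 == 2L & s1 == 2L] <- P[alive & s0 == 2L & s1 == 2L, "P22"]
  p_alive[alive & s0 == 2L & s1 == 1L] <- 0 # recovery: impossible
  contrib[alive] <- log(p_alive[alive])

  dead <- records$exit_kind == "death_exact"
  if (any(dead)) {
    q_at_death <- transition_intensities(model, records$exit_age[dead], z[dead])
    dens <- ifelse(s0[dead] == 1L,
                   P[dead, "P11"] * q_at_death[, "q13"] +
                     P[dead, "P12"] * q_at_death[, "q23"],
                   P[dead, "P22"] * q_at_death[, "q23"])
    contrib[dead] <- log(dens)
  }

  if (any(contrib == -Inf)) {
    offenders <- records$subject_id[contrib == -Inf]
    warning("zero-probability observation(s) for subject(s): ",
            paste(utils::head(offenders, 5L), collapse = ", "),
            if (length(offenders) > 5L)
              sprintf(" (and %d more)", length(offenders) - 5L),
            call. = FALSE)
    return(-Inf)
  }
  sum(contrib)
}

# Pack/unpack the free parameters of an intensity_model.
theta_from_model <- function(model, age_trend, sex_effect) {
  th <- model$alpha
  names(th) <- paste0("alpha", names(model$alpha))
  if (age_trend) th <- c(th, stats::setNames(model$xi, paste0("xi", names(model$xi))))
  if (sex_effect) th <- c(th, stats::setNames(model$beta, paste0("beta", names(model$beta))))
  th
}

model_from_theta <- function(theta, age_trend, sex_effect, reference_age) {
  alpha <- theta[1:3]
  i <- 3L
  xi <- c(0, 0, 0)
  if (age_trend) { xi <- theta[i + 1:3]; i <- i + 3L }
  beta <- c(0, 0, 0)
  if (sex_effect) beta <- theta[i + 1:3]
  intensity_model(alpha, xi, beta, reference_age)
}

#' Fit the illness-death model to panel data by maximum likelihood
#'
#' Maximises [panel_log_likelihood()] over the unconstrained
#' log-intensity parameterisation by quasi-Newton (BFGS) search. The
#' covariance of the estimates is the inverse of the numerically
#' differentiated observed information at the optimum.
#'
#' @inheritParams panel_log_likelihood
#' @param init optional [intensity_model()] holding starting values;
#'   by default crude occurrence/exposure rates on the observed panel.
#' @param age_trend fit log-linear age slopes (`xi`)? If `FALSE` the
#'   model is age-constant.
#' @param sex_effect fit additive log-intensity effects of male sex?
#' @param reference_age reference age of the fitted model (ignored when
#'   `init` is supplied).
#' @param control passed to [stats::optim()] (defaults: `maxit = 500`,
#'   `reltol = 1e-10`).
#' @return object of class `idd_fit`: the fitted `model`, `coefficients`,
#'   covariance matrix `cov`, standard errors `se`, `logLik`, and a
#'   `convergence` report (optim code, function/gradient evaluation
#'   counts, gradient norm at the optimum). Non-convergence sets
#'   `converged = FALSE` and raises a warning, never fails silently.
#' @export
fit_idd_model <- function(records, init = NULL, age_trend = TRUE,
                          sex_effect = TRUE, grid_step = 0.25,
                          lost_action = c("exclude", "censor_at_entry"),
                          reference_age = 65, control = list()) {
  lost_action <- match.arg(lost_action)
  records <- validate_panel(records)
  fitted_records <- records[records$exit_kind != "lost", , drop = FALSE]

  n_death <- sum(fitted_records$exit_kind == "death_exact")
  n_incident <- sum(fitted_records$exit_kind == "alive_observed" &
                      fitted_records$entry_state == 1L &
                      fitted_records$exit_state == 2L)
  n_prevalent <- sum(fitted_records$entry_state == 2L)
  if (n_death == 0L)
    warning("no deaths observed: mortality intensities are not identifiable",
            call. = FALSE)
  if (n_incident == 0L)
    warning("no incident disease observed: the onset intensity is not identifiable",
            call. = FALSE)

  if (is.null(init)) {
    py <- sum(fitted_records$exit_age - fitted_records$entry_age)
    crude <- function(events) max(events, 0.5) / max(py, 1)
    init <- intensity_model(
      alpha = log(c(crude(n_incident), crude(n_death) , 1.5 * crude(n_death))),
      xi = if (age_trend) c(0.02, 0.05, 0.05) else c(0, 0, 0),
      reference_age = reference_age)
  } else {
    stopifnot(inherits(init, "intensity_model"))
    reference_age <- init$reference_age
  }

  theta0 <- theta_from_model(init, age_trend, sex_effect)
  nll <- function(theta) {
    m <- model_from_theta(theta, age_trend, sex_effect, reference_age)
    ll <- suppressWarnings(
      panel_log_likelihood(m, fitted_records, grid_step, lost_action))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  control <- utils::modifyList(list(maxit = 500, reltol = 1e-10), control)
  opt <- stats::optim(theta0, nll, method = "BFGS", hessian = TRUE,
                      control = control)

  grad <- num_gradient(nll, opt$par)
  cov <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(cov)) || any(diag(cov) < 0)) {
    warning("observed information is not invertible/positive definite; ",
            "standard errors unavailable", call. = FALSE)
    cov <- matrix(NA_real_, length(opt$par), length(opt$par),
                  dimnames = list(names(opt$par), names(opt$par)))
  } else {
    dimnames(cov) <- list(names(opt$par), names(opt$par))
  }
  converged <- opt$convergence == 0L
  if (!converged)
    warning("optimiser did not converge (optim code ", opt$convergence, ")",
            call. = FALSE)

  structure(
    list(model = model_from_theta(opt$par, age_trend, sex_effect, reference_age),
         coefficients = opt$par,
         cov = cov,
         se = sqrt(diag(cov)),
         logLik = -opt$value,
         converged = converged,
         convergence = list(code = opt$convergence, counts = opt$counts,
                            gradient_norm = sqrt(sum(grad^2))),
         n = nrow(fitted_records),
         n_lost_excluded = sum(records$exit_kind == "lost"),
         events = c(deaths = n_death, incident = n_incident,
                    prevalent = n_prevalent),
         settings = list(age_trend = age_trend, sex_effect = sex_effect,
                         grid_step = grid_step, lost_action = lost_action,
                         reference_age = reference_age)),
    class = "idd_fit")
}

# Central-difference gradient (used for the convergence report).
num_gradient <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- eps * max(1, abs(x[i]))
    (f(x + e) - f(x - e)) / (2 * e[i])
  }, numeric(1))
}

#' @export
print.idd_fit <- function(x, ...) {
  cat("Illness-death model fit (", x$n, " panel records, ",
      x$n_lost_excluded, " lost excluded)\n", sep = "")
  cat("  events: ", x$events[["deaths"]], " deaths, ",
      x$events[["incident"]], " incident, ",
      x$events[["prevalent"]], " prevalent at entry\n", sep = "")
  cat("  log-likelihood:", format(x$logLik), "\n")
  cat("  converged:", x$converged,
      "(gradient norm", format(x$convergence$gradient_norm, digits = 3), ")\n")
  print(round(cbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}
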