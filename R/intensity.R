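#' Transition-intensity model for the illness-death process
#'
#' Parameterises the three transition intensities of the no-recovery
#' illness-death model -- state 1 (disease-free), state 2 (diseased),
#' state 3 (dead) -- as Gompertz hazards with proportional covariate
#' effects on the log scale:
#' \deqn{q_{rs}(a, z) = \exp\{\alpha_{rs} + \xi_{rs}(a - a_0) + \beta_{rs} z\}}
#' for the transitions 1->2 (disease onset), 1->3 (death while
#' disease-free) and 2->3 (death with disease), where \eqn{a} is age in
#' years, \eqn{a_0} is the reference age, and \eqn{z} is a scalar
#' covariate (by convention an indicator for male sex, with female as
#' reference). Setting \eqn{\xi_{rs} = 0} gives age-constant intensities,
#' useful for closed-form checks.
#'
#' Reverse transitions (recovery, resurrection) have intensity zero by
#' construction: the process is progressive and state 3 is absorbing.
#'
#' @param alpha numeric length 3: log baseline intensities at the
#'   reference age, in transition order 1->2, 1->3, 2->3. `-Inf` switches
#'   a transition off entirely.
#' @param xi numeric length 3: log-linear age slopes (per year), same
#'   order. All zero gives an age-constant model.
#' @param beta numeric length 3: additive log-intensity covariate
#'   effects, same order.
#' @param reference_age age (years) at which `alpha` applies. Default 65,
#'   the youngest enrolment age of the target elderly population.
#' @return an object of class `intensity_model`.
#' @seealso [constant_intensity_model()], [build_intensity_matrix()],
#'   [transition_probability()]
#' @examples
#' m <- intensity_model(alpha = log(c(0.01, 0.02, 0.04)),
#'                      xi = c(0.02, 0.09, 0.09), beta = c(-0.3, 0.4, 0.4))
#' transition_intensities(m, age = c(65, 75), z = 0)
#' @export
intensity_model <- function(alpha, xi = c(0, 0, 0), beta = c(0, 0, 0),
                            reference_age = 65) {
  trans <- c("12", "13", "23")
  alpha <- as.numeric(alpha)
  xi <- as.numeric(xi)
  beta <- as.numeric(beta)
  if (length(alpha) != 3L || length(xi) != 3L || length(beta) != 3L)
    stop("'alpha', 'xi' and 'beta' must each have length 3 (transitions 1->2, 1->3, 2->3)")
  if (any(is.na(alpha)) || any(alpha == Inf))
    stop("log intensities 'alpha' must be finite or -Inf (transition switched off)")
  if (any(!is.finite(xi)) || any(!is.finite(beta)))
    stop("'xi' and 'beta' must be finite")
  if (!is.numeric(reference_age) || length(reference_age) != 1L ||
      !is.finite(reference_age))
    stop("'reference_age' must be a single finite number")
  structure(
    list(alpha = stats::setNames(alpha, trans),
         xi = stats::setNames(xi, trans),
         beta = stats::setNames(beta, trans),
         reference_age = reference_age),
    class = "intensity_model")
}

#' Age-constant intensity model
#'
#' Convenience wrapper for an illness-death model with constant
#' transition rates, for which occupancy probabilities and life
#' expectancies have closed forms.
#'
#' @param q12,q13,q23 non-negative constant rates (per year) for disease
#'   onset, disease-free mortality and diseased mortality.
#' @param reference_age carried through to [intensity_model()]; has no
#'   effect on the rates.
#' @return an `intensity_model` with zero age slopes and covariate effects.
#' @export
constant_intensity_model <- function(q12, q13, q23, reference_age = 65) {
  q <- c(q12, q13, q23)
  if (any(q < 0) || any(!is.finite(q) & q != 0))
    stop("constant intensities must be finite and non-negative")
  intensity_model(alpha = log(q), reference_age = reference_age)
}

#' @export
print.intensity_model <- function(x, ...) {
  cat("Illness-death intensity model (Gompertz, log-linear in age)\n")
  cat("  reference age:", x$reference_age, "years\n")
  tab <- rbind(`log baseline (alpha)` = x$alpha,
               `age slope (xi, /yr)` = x$xi,
               `covariate effect (beta)` = x$beta)
  colnames(tab) <- c("1->2 onset", "1->3 death", "2->3 death")
  print(round(tab, 4))
  invisible(x)
}

#' Evaluate transition intensities
#'
#' @param model an [intensity_model()].
#' @param age vector of ages (years).
#' @param z covariate value(s), recycled against `age`.
#' @return matrix with one row per age and columns `q12`, `q13`, `q23`.
#' @export
transition_intensities <- function(model, age, z = 0) {
  stopifnot(inherits(model, "intensity_model"))
  n <- max(length(age), length(z))
  age <- rep_len(age, n)
  z <- rep_len(z, n)
  out <- vapply(1:3, function(j) {
    exp(model$alpha[j] + model$xi[j] * (age - model$reference_age) +
          model$beta[j] * z)
  }, numeric(n))
  out <- matrix(out, nrow = n, dimnames = list(NULL, c("q12", "q13", "q23")))
  out
}

#' Generator (intensity) matrix at a given age
#'
#' Builds the 3x3 generator `Q` of the illness-death process at one age
#' and covariate value. Off-diagonal entries are the transition
#' intensities; each row sums to zero; the death row is identically zero
#' (absorbing state); recovery entries are structurally zero.
#'
#' @inheritParams transition_intensities
#' @param age single age (years).
#' @return 3x3 numeric matrix with dimnames
#'   `c("healthy", "diseased", "dead")`.
#' @export
build_intensity_matrix <- function(model, age, z = 0) {
  stopifnot(length(age) == 1L, length(z) == 1L)
  q <- transition_intensities(model, age, z)[1, ]
  if (any(!is.finite(q)))
    stop("non-finite intensity at age ", age, ": ",
         paste(names(q)[!is.finite(q)], collapse = ", "))
  st <- c("healthy", "diseased", "dead")
  Q <- matrix(0, 3, 3, dimnames = list(st, st))
  Q[1, 2] <- q[["q12"]]
  Q[1, 3] <- q[["q13"]]
  Q[2, 3] <- q[["q23"]]
  diag(Q) <- -rowSums(Q)
  Q
}

# Integrated (cumulative) transition hazards over [t0, t1], vectorised.
# Closed form for the Gompertz intensity: H = q(t0..t1) integrates to
# exp(alpha + beta z)/xi * (exp(xi (t1 - a0)) - exp(xi (t0 - a0))).
# Returns an n x 3 matrix (columns 1->2, 1->3, 2->3).
cumulative_hazards <- function(model, t0, t1, z = 0) {
  n <- max(length(t0), length(t1), length(z))
  t0 <- rep_len(t0, n)
  t1 <- rep_len(t1, n)
  z <- rep_len(z, n)
  ref <- model$reference_age
  H <- matrix(0, n, 3, dimnames = list(NULL, c("12", "13", "23")))
  for (j in 1:3) {
    b <- exp(model$alpha[j] + model$beta[j] * z) # baseline rate at ref age
    if (model$xi[j] == 0) {
      H[, j] <- b * (t1 - t0)
    } else {
      xi <- model$xi[j]
      H[, j] <- b / xi * (exp(xi * (t1 - ref)) - exp(xi * (t0 - ref)))
    }
  }
  H
}
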