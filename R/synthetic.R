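#' Default cohort intensity model
#'
#' The true transition intensities used by the synthetic-cohort
#' generator's default configuration. Gompertz hazards referenced at age
#' 65, with male sex (`z = 1`) as the covariate; female is the
#' reference. Calibrated so that a cohort enrolled at ages 65-79 after
#' burn-in from age 50 shows a baseline disease prevalence near 12.8%
#' overall (higher in women), and remaining life expectancy at 65 of
#' roughly 20 years for women and 17 for men.
#'
#' @return an [intensity_model()].
#' @export
default_cohort_intensities <- function() {
  intensity_model(
    alpha = log(c(0.009, 0.009, 0.0144)), # onset, healthy death, diseased death at 65 (women)
    xi = c(0.02, 0.095, 0.095),
    beta = c(-0.37, 0.40, 0.40), # men: lower onset, higher mortality
    reference_age = 65)
}

#' Configuration for the synthetic-cohort generator
#'
#' Bundles and validates all knobs of [simulate_cohort()]. The defaults
#' emulate a rural elderly two-wave cohort: ~10,318 subjects enrolled at
#' ages 65-79, disease onset accumulated by burn-in from age 50 (so
#' onset ages are structurally interval-censored), one follow-up visit
#' about three years after baseline, deaths recorded with exact ages,
#' and roughly 12% of surviving subjects lost to follow-up at random.
#'
#' @param cohort_size number of subjects.
#' @param baseline_age_range numeric length 2: enrolment ages are drawn
#'   uniformly on this range (years).
#' @param burn_in_start_age age at which every subject starts
#'   disease-free; must precede the baseline range.
#' @param followup_gap_mean,followup_gap_jitter follow-up visit occurs
#'   `gap_mean + U(-jitter, jitter)` years after baseline.
#' @param loss_to_followup_prob probability that a subject alive at
#'   follow-up is lost (missing completely at random).
#' @param intensity_model true [intensity_model()] generating the data.
#' @param sex_ratio_male probability a subject is male.
#' @param seed master integer seed; per-subject substreams are derived
#'   deterministically from it and the subject index.
#' @param max_age cap on attainable age (years).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(cohort_size = 10318,
                              baseline_age_range = c(65, 79),
                              burn_in_start_age = 50,
                              followup_gap_mean = 3,
                              followup_gap_jitter = 1,
                              loss_to_followup_prob = 0.122,
                              intensity_model = default_cohort_intensities(),
                              sex_ratio_male = 0.4527,
                              seed = 1,
                              max_age = 110) {
  stopifnot(inherits(intensity_model, "intensity_model"))
  if (!is.numeric(cohort_size) || cohort_size < 1)
    stop("'cohort_size' must be positive")
  if (length(baseline_age_range) != 2L ||
      baseline_age_range[1] > baseline_age_range[2])
    stop("'baseline_age_range' must be (low, high) with low <= high")
  for (p in c(loss_to_followup_prob, sex_ratio_male))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (!(burn_in_start_age < baseline_age_range[1]))
    stop("'burn_in_start_age' must precede the baseline age range")
  if (!(max_age > baseline_age_range[2]))
    stop("'max_age' must exceed the upper baseline age")
  if (followup_gap_mean <= 0 || followup_gap_jitter < 0 ||
      followup_gap_jitter >= followup_gap_mean)
    stop("follow-up gap must be positive for every subject")
  structure(
    list(cohort_size = as.integer(cohort_size),
         baseline_age_range = baseline_age_range,
         burn_in_start_age = burn_in_start_age,
         followup_gap_mean = followup_gap_mean,
         followup_gap_jitter = followup_gap_jitter,
         loss_to_followup_prob = loss_to_followup_prob,
         intensity_model = intensity_model,
         sex_ratio_male = sex_ratio_male,
         seed = as.integer(seed),
         max_age = max_age),
    class = "simulation_config")
}

# Inverse-transform draw of the next event age for one Gompertz
# transition, starting at risk at age t0, given an Exp(1) deviate E:
# solve H(t0, t) = E. Returns Inf when the event never occurs.
gompertz_event_age <- function(model, trans, z, t0, E) {
  j <- match(trans, c("12", "13", "23"))
  b <- exp(model$alpha[j] + model$beta[j] * z)
  if (b == 0) return(Inf)
  xi <- model$xi[j]
  if (xi == 0) return(t0 + E / b)
  ref <- model$reference_age
  arg <- exp(xi * (t0 - ref)) + E * xi / b
  if (arg <= 0) return(Inf) # declining hazard: event escapes to infinity
  ref + log(arg) / xi
}

# Deterministic per-subject substream seed (Knuth multiplicative hash,
# kept inside the 32-bit signed range).
substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 * 31 + i * 2654435.0) %%
               2147483647)
}

#' Simulate a two-wave panel cohort from the illness-death process
#'
#' Each subject is simulated forward from `burn_in_start_age` in the
#' disease-free state under the true intensities: competing onset and
#' death hazards from state 1, a single death hazard from state 2, all
#' drawn by inverse transform on the closed-form Gompertz cumulative
#' hazards. Trajectories that die before the subject's drawn baseline
#' age are redrawn, so enrolment is left-truncated on survival exactly
#' as in a real cohort; the baseline state is the latent state at the
#' entry age, which makes onset ages interval-censored by construction.
#' Deaths before the follow-up visit are recorded with their exact ages;
#' a random fraction of subjects surviving to follow-up is marked lost.
#'
#' Reproducibility: the master seed spawns a deterministic substream per
#' subject, so identical configurations give bit-identical cohorts and
#' individual records do not depend on the rest of the cohort.
#'
#' @param config a [simulation_config()].
#' @return panel-record data frame (columns `subject_id`, `sex`,
#'   `entry_age`, `entry_state`, `exit_age`, `exit_kind`, `exit_state`).
#' @examples
#' cfg <- simulation_config(cohort_size = 100, seed = 42)
#' head(simulate_cohort(cfg))
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  m <- config$intensity_model
  n <- config$cohort_size
  lo <- config$baseline_age_range[1]
  hi <- config$baseline_age_range[2]
  sex <- character(n); entry_age <- numeric(n); entry_state <- integer(n)
  exit_age <- numeric(n); exit_kind <- character(n); exit_state <- integer(n)
  for (i in seq_len(n)) {
    set.seed(substream_seed(config$seed, i))
    sex_i <- if (stats::runif(1) < config$sex_ratio_male) "male" else "female"
    z <- as.numeric(sex_i == "male")
    baseline <- stats::runif(1, lo, hi)
    gap <- config$followup_gap_mean +
      stats::runif(1, -config$followup_gap_jitter, config$followup_gap_jitter)
    lost <- stats::runif(1) < config$loss_to_followup_prob
    onset <- Inf; death <- Inf
    ok <- FALSE
    for (try in 1:1000) {
      t_on <- gompertz_event_age(m, "12", z, config$burn_in_start_age,
                                 stats::rexp(1))
      t_d1 <- gompertz_event_age(m, "13", z, config$burn_in_start_age,
                                 stats::rexp(1))
      if (t_d1 <= t_on) {
        onset <- Inf; death <- t_d1
      } else {
        onset <- t_on
        death <- gompertz_event_age(m, "23", z, t_on, stats::rexp(1))
      }
      if (death > baseline) { ok <- TRUE; break }
    }
    if (!ok)
      stop("could not simulate survival to baseline age ",
           round(baseline, 1), " for subject ", i,
           " after 1000 attempts; check the intensity configuration")
    followup <- baseline + gap
    sex[i] <- sex_i
    entry_age[i] <- baseline
    entry_state[i] <- if (onset <= baseline) 2L else 1L
    if (death <= followup) {
      exit_age[i] <- death
      exit_kind[i] <- "death_exact"
      exit_state[i] <- NA_integer_
    } else if (lost) {
      exit_age[i] <- followup
      exit_kind[i] <- "lost"
      exit_state[i] <- NA_integer_
    } else {
      exit_age[i] <- followup
      exit_kind[i] <- "alive_observed"
      exit_state[i] <- if (onset <= followup) 2L else 1L
    }
  }
  data.frame(subject_id = seq_len(n), sex = sex, entry_age = entry_age,
             entry_state = entry_state, exit_age = exit_age,
             exit_kind = exit_kind, exit_state = exit_state)
}

#' Aggregate panel records into age-grouped counts and prevalence
#'
#' Produces the two aggregate inputs of the Sullivan pathway from
#' individual panel records: person-years of exposure and death counts
#' per age interval (exposure accrued between each subject's entry and
#' exit ages, deaths allocated to the interval containing the exact
#' death age), and baseline disease prevalence per interval from the
#' entry states.
#'
#' @param records panel-record data frame.
#' @param age_breaks increasing interval start ages; the last break
#'   opens the terminal open-ended interval. Default `c(65, 70, 75, 80,
#'   85)`, i.e. five-year bands from 65 with an 85+ tail.
#' @param conf_level confidence level for the prevalence intervals.
#' @return list with components `counts` (columns `age_start`,
#'   `age_width`, `population`, `deaths`; `population` is person-years)
#'   and `prevalence` (columns `age_start`, `age_width`, `n`, `cases`,
#'   `prevalence`, `ci_low`, `ci_high`).
#' @export
aggregate_counts <- function(records, age_breaks = c(65, 70, 75, 80, 85),
                             conf_level = 0.95) {
  records <- validate_panel(records)
  if (is.unsorted(age_breaks, strictly = TRUE))
    stop("'age_breaks' must be strictly increasing")
  if (any(records$entry_age < age_breaks[1]))
    stop("record(s) with entry_age below the first age break ",
         age_breaks[1])
  k <- length(age_breaks)
  lo <- age_breaks
  hi <- c(age_breaks[-1], Inf)
  py <- vapply(seq_len(k), function(g) {
    sum(pmax(0, pmin(records$exit_age, hi[g]) - pmax(records$entry_age, lo[g])))
  }, numeric(1))
  death_age <- records$exit_age[records$exit_kind == "death_exact"]
  deaths <- vapply(seq_len(k), function(g) {
    sum(death_age >= lo[g] & death_age < hi[g])
  }, numeric(1))
  grp <- findInterval(records$entry_age, age_breaks)
  n_g <- vapply(seq_len(k), function(g) sum(grp == g), numeric(1))
  cases_g <- vapply(seq_len(k), function(g) {
    sum(grp == g & records$entry_state == 2L)
  }, numeric(1))
  widths <- c(diff(age_breaks), NA_real_)
  counts <- data.frame(age_start = age_breaks, age_width = widths,
                       population = py, deaths = deaths)
  observed <- n_g > 0
  prev <- data.frame(age_start = age_breaks, age_width = widths,
                     n = n_g, cases = cases_g,
                     prevalence = NA_real_, ci_low = NA_real_,
                     ci_high = NA_real_)
  if (any(observed)) {
    est <- estimate_prevalence(n_g[observed], cases_g[observed],
                               conf_level = conf_level)
    prev$prevalence[observed] <- est$prevalence
    prev$ci_low[observed] <- est$ci_low
    prev$ci_high[observed] <- est$ci_high
  }
  list(counts = counts, prevalence = prev[observed, , drop = FALSE])
}

#' Published marginal counts of the reference elderly cohort
#'
#' Deterministic accounting tables encoding the published margins of the
#' Henan Rural Cohort elderly type-2-diabetes sub-study, used as fixed
#' fixtures: the screening/exclusion cascade, per-sex analytic and case
#' counts, and the follow-up attrition. These are reported counts, not
#' simulated data; they let the pipeline's bookkeeping be checked by
#' exact integer arithmetic.
#'
#' @return list of class `cohort_margins` with data frames `screening`
#'   (exclusion cascade down to the analytic sample), `by_sex` (analytic
#'   n, baseline cases and incident cases per sex), and `followup`
#'   (attrition from the analytic sample to the panel analysed
#'   longitudinally).
#' @export
henan_margins <- function() {
  structure(list(
    screening = data.frame(
      stage = c("screened_65_plus", "excluded_t1dm", "excluded_gdm",
                "excluded_missing_t2dm", "analytic"),
      n = c(10350L, 2L, 11L, 19L, 10318L)),
    by_sex = data.frame(
      sex = c("male", "female"),
      n = c(4671L, 5647L),
      baseline_t2dm = c(481L, 844L),
      incident_t2dm = c(163L, 231L)),
    followup = data.frame(
      stage = c("analytic", "lost_to_followup", "panel_analytic"),
      n = c(10318L, 1185L, 9133L))),
    class = "cohort_margins")
}
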