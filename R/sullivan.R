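#' Prevalence estimate with confidence interval
#'
#' Point estimate `cases / n` with a 95% (by default) Wilson score
#' interval; a Wald interval is available for comparison. Vectorised over
#' `n` and `cases`.
#'
#' @param n counts at risk (must be positive).
#' @param cases case counts, `0 <= cases <= n`.
#' @param conf_level confidence level (default 0.95).
#' @param method `"wilson"` (score interval, default) or `"wald"`.
#' @return data frame with columns `n`, `cases`, `prevalence`, `ci_low`,
#'   `ci_high` (all proportions).
#' @examples
#' estimate_prevalence(10318, 1325) # baseline T2DM prevalence, 12.84%
#' @export
estimate_prevalence <- function(n, cases, conf_level = 0.95,
                                method = c("wilson", "wald")) {
  method <- match.arg(method)
  k <- max(length(n), length(cases))
  n <- rep_len(n, k)
  cases <- rep_len(cases, k)
  if (any(n <= 0)) stop("'n' must be positive")
  if (any(cases < 0 | cases > n)) stop("'cases' must lie in [0, n]")
  p <- cases / n
  if (method == "wilson") {
    ci <- t(vapply(seq_len(k), function(i) {
      # suppress prop.test's chi-square-approximation warning: only the
      # score interval is used here, not the test
      suppressWarnings(
        stats::prop.test(cases[i], n[i], conf.level = conf_level,
                         correct = FALSE)$conf.int)
    }, numeric(2)))
  } else {
    zq <- stats::qnorm(1 - (1 - conf_level) / 2)
    half <- zq * sqrt(p * (1 - p) / n)
    ci <- cbind(pmax(0, p - half), pmin(1, p + half))
  }
  data.frame(n = n, cases = cases, prevalence = p,
             ci_low = ci[, 1], ci_high = ci[, 2])
}

#' Directly age-standardised prevalence
#'
#' Weighted mean of age-group-specific prevalences using a fixed
#' standard population's weights (the direct method):
#' \eqn{\sum_g w_g p_g / \sum_g w_g}.
#'
#' @param prev prevalence table: data frame with columns `age_start` and
#'   `prevalence` (as returned by [aggregate_counts()]).
#' @param standard_weights non-negative weights, either a numeric vector
#'   aligned with the rows of `prev` or a data frame with columns
#'   `age_start` and `weight` covering exactly the same intervals.
#' @return the standardised prevalence (proportion).
#' @export
age_standardize_prevalence <- function(prev, standard_weights) {
  if (!is.data.frame(prev) || !all(c("age_start", "prevalence") %in% names(prev)))
    stop("'prev' must have columns 'age_start' and 'prevalence'")
  if (is.data.frame(standard_weights)) {
    if (!all(c("age_start", "weight") %in% names(standard_weights)))
      stop("weight table must have columns 'age_start' and 'weight'")
    i <- match(prev$age_start, standard_weights$age_start)
    if (any(is.na(i)))
      stop("standard weights do not cover age group(s) starting at ",
           paste(prev$age_start[is.na(i)], collapse = ", "))
    w <- standard_weights$weight[i]
  } else {
    if (length(standard_weights) != nrow(prev))
      stop("weight vector length (", length(standard_weights),
           ") does not match the number of age groups (", nrow(prev), ")")
    w <- as.numeric(standard_weights)
  }
  if (any(w < 0)) stop("standard weights must be non-negative")
  if (sum(w) <= 0) stop("standard weights must not all be zero")
  sum(w * prev$prevalence) / sum(w)
}

#' Ratio of health-adjusted to total life expectancy
#'
#' @param le life expectancy (years), positive.
#' @param hale health-adjusted life expectancy (years),
#'   `0 <= hale <= le`.
#' @return the ratio as a percentage, `100 * hale / le`.
#' @export
hale_le_ratio <- function(le, hale) {
  k <- max(length(le), length(hale))
  le <- rep_len(le, k); hale <- rep_len(hale, k)
  if (any(le <= 0)) stop("'le' must be positive")
  if (any(hale < 0 | hale > le + 1e-9))
    stop("'hale' must lie in [0, le]")
  100 * hale / le
}

#' Sullivan health-adjusted life expectancy
#'
#' Combines an abridged life table with age-group disease prevalences by
#' the Sullivan method: person-years lived in each interval are
#' discounted by the proportion of the interval's population living with
#' the disease before summation,
#' \deqn{\mathrm{HALE}(x) = \frac{1}{l_x} \sum_{y \ge x}
#'   (1 - \pi_y)\, {}_nL_y,}
#' where \eqn{l_x} is the number of survivors at exact age \eqn{x},
#' \eqn{{}_nL_y} the person-years lived in the interval starting at
#' \eqn{y}, and \eqn{\pi_y} the disease prevalence in that interval. The
#' sum runs to the terminal open-ended interval (the maximum age of the
#' table).
#'
#' Prevalence must be supplied for each table interval from the first
#' requested starting age upward; if the prevalence table stops before
#' the life table's terminal interval, the last observed prevalence is
#' carried forward (the method needs a \eqn{\pi} on every remaining
#' interval and older ages are rarely observed directly).
#'
#' @param table an [build_abridged_life_table()] result.
#' @param prev data frame with columns `age_start` and `prevalence`
#'   (proportions in `[0, 1]`) on intervals matching the life table's.
#' @param start_age starting exact age(s); each must be an interval start.
#'   Defaults to every interval start of the table.
#' @return data frame of class `hale_result` with columns `age`, `le`,
#'   `hale`, `ratio_pct`.
#' @examples
#' counts <- data.frame(age_start = c(65, 70, 75, 80, 85),
#'                      age_width = c(5, 5, 5, 5, NA),
#'                      population = c(900, 800, 600, 350, 200) * 100,
#'                      deaths = c(900, 1300, 1500, 1700, 2400))
#' lt <- build_abridged_life_table(counts)
#' prev <- data.frame(age_start = c(65, 70, 75, 80, 85),
#'                    prevalence = c(0.13, 0.14, 0.15, 0.15, 0.15))
#' sullivan_hale(lt, prev, start_age = c(65, 70, 75))
#' @export
sullivan_hale <- function(table, prev, start_age = NULL) {
  stopifnot(inherits(table, "abridged_life_table"))
  if (!is.data.frame(prev) || !all(c("age_start", "prevalence") %in% names(prev)))
    stop("'prev' must have columns 'age_start' and 'prevalence'")
  if (any(prev$prevalence < 0 | prev$prevalence > 1, na.rm = TRUE) ||
      any(is.na(prev$prevalence)))
    stop("prevalences must lie in [0, 1]")
  if (is.null(start_age)) start_age <- table$age_start
  # Align prevalence onto the life-table intervals; carry the last
  # observed prevalence forward into older unobserved intervals.
  i <- match(table$age_start, prev$age_start)
  if (is.na(i[1]) && min(prev$age_start) > min(table$age_start) &&
      min(prev$age_start) <= max(table$age_start)) {
    # prevalence starting above the table's first interval is fine as
    # long as no requested start age precedes it
    if (any(start_age < min(prev$age_start)))
      stop("no prevalence available for intervals at or above start age ",
           min(start_age))
  }
  extra <- setdiff(prev$age_start, table$age_start)
  if (length(extra))
    stop("prevalence intervals do not align with the life table ",
         "(unmatched age_start: ", paste(extra, collapse = ", "), ")")
  pi_y <- prev$prevalence[i]
  # carry forward beyond the last observed group
  last_obs <- max(which(!is.na(pi_y)))
  if (last_obs < length(pi_y))
    pi_y[(last_obs + 1):length(pi_y)] <- pi_y[last_obs]
  healthy_L <- (1 - pi_y) * table$L
  res <- lapply(start_age, function(s) {
    idx <- which(table$age_start >= s - 1e-9)
    if (!length(idx) || abs(table$age_start[idx[1]] - s) > 1e-9)
      stop("start age ", s, " is not an interval start of this life table")
    if (any(is.na(pi_y[idx])))
      stop("no prevalence available for intervals at or above start age ", s)
    hale <- sum(healthy_L[idx]) / table$l[idx[1]]
    le <- table$e[idx[1]]
    data.frame(age = s, le = le, hale = hale,
               ratio_pct = hale_le_ratio(le, hale))
  })
  structure(do.call(rbind, res), class = c("hale_result", "data.frame"))
}
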