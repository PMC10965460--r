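#' Chiang abridged life table
#'
#' Builds a current (period) abridged life table from age-grouped
#' mid-period population and death counts using Chiang's method. For an
#' interior interval of width \eqn{n} with central death rate
#' \eqn{m = D / N} and mean fraction of the interval lived by decedents
#' \eqn{a}, the conditional probability of dying is
#' \deqn{q = \frac{n m}{1 + n (1 - a) m},}
#' capped at one. The terminal open-ended interval has \eqn{q = 1} and
#' person-years \eqn{L = l / m} (everyone alive at its start dies in it,
#' at the prevailing rate). Survivorship \eqn{l} cascades from the radix,
#' \eqn{d = l q}, interior \eqn{L = n\,l_{x+n} + a\,n\,d},
#' \eqn{T_x = \sum_{y \ge x} L_y}, and \eqn{e = T / l}.
#'
#' @param counts data frame with columns `age_start`, `age_width`
#'   (`NA` or `Inf` marks the single terminal open-ended interval, which
#'   must come last), `population` (mid-period count or person-years) and
#'   `deaths`. Intervals must be contiguous and non-overlapping.
#' @param radix survivors at the first age; any positive value gives the
#'   same `e` column (default 100000).
#' @param a mean fraction of the interval lived by those dying in it;
#'   a single value recycled or one value per interval. The default 0.5
#'   is standard for ages five and above; supply per-interval values for
#'   infant/child intervals in full tables.
#' @return data frame of class `abridged_life_table` with columns
#'   `age_start`, `age_width`, `m`, `q`, `a`, `l`, `d`, `L`, `T`, `e`.
#' @examples
#' counts <- data.frame(age_start = c(65, 70, 75, 80, 85),
#'                      age_width = c(5, 5, 5, 5, NA),
#'                      population = c(900, 800, 600, 350, 200) * 100,
#'                      deaths = c(900, 1300, 1500, 1700, 2400))
#' lt <- build_abridged_life_table(counts)
#' life_expectancy_at(lt, 65)
#' @export
build_abridged_life_table <- function(counts, radix = 1e5, a = 0.5) {
  counts <- validate_counts(counts)
  if (!is.numeric(radix) || length(radix) != 1L || radix <= 0)
    stop("'radix' must be a single positive number")
  k <- nrow(counts)
  a <- rep_len(a, k)
  if (any(a < 0 | a > 1)) stop("'a' fractions must lie in [0, 1]")
  n <- counts$age_width
  m <- ifelse(counts$population > 0, counts$deaths / counts$population, 0)
  if (m[k] <= 0)
    stop("terminal open-ended interval has zero mortality: ",
         "its person-years l/m are undefined")
  q <- pmin(1, n * m / (1 + n * (1 - a) * m))
  q[k] <- 1
  l <- radix * cumprod(c(1, 1 - q[-k]))
  d <- l * q
  L <- numeric(k)
  if (k > 1L)
    L[-k] <- n[-k] * (l[-1]) + a[-k] * n[-k] * d[-k]
  L[k] <- l[k] / m[k]
  Tx <- rev(cumsum(rev(L)))
  e <- ifelse(l > 0, Tx / l, 0)
  structure(
    data.frame(age_start = counts$age_start, age_width = counts$age_width,
               m = m, q = q, a = a, l = l, d = d, L = L, T = Tx, e = e),
    class = c("abridged_life_table", "data.frame"))
}

# Validate AgeGroupedCounts; terminal width normalised to NA.
validate_counts <- function(counts, where = "age-grouped counts") {
  if (!is.data.frame(counts))
    stop(where, ": expected a data frame")
  need <- c("age_start", "age_width", "population", "deaths")
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols))
    stop(where, ": missing columns: ", paste(missing_cols, collapse = ", "))
  counts <- counts[need]
  open <- is.na(counts$age_width) | is.infinite(counts$age_width)
  if (sum(open) != 1L || !open[nrow(counts)])
    stop(where, ": exactly one terminal open-ended interval ",
         "(age_width NA or Inf, in the last row) is required")
  counts$age_width[nrow(counts)] <- NA_real_
  k <- nrow(counts)
  if (k > 1L) {
    ends <- counts$age_start[-k] + counts$age_width[-k]
    if (any(abs(ends - counts$age_start[-1]) > 1e-9))
      stop(where, ": intervals must be contiguous and non-overlapping")
    if (any(counts$age_width[-k] <= 0))
      stop(where, ": interval widths must be positive")
  }
  if (any(counts$population < 0) || any(counts$deaths < 0))
    stop(where, ": negative population or death counts")
  if (any(counts$deaths > 0 & counts$population <= 0))
    stop(where, ": deaths recorded in an interval with no population")
  counts
}

#' Life expectancy at an exact age from an abridged life table
#'
#' @param table an `abridged_life_table`.
#' @param age exact age in years; must equal the start of one of the
#'   table's intervals.
#' @return expectation of life `e` (years) at that age.
#' @export
life_expectancy_at <- function(table, age) {
  stopifnot(inherits(table, "abridged_life_table"), length(age) == 1L)
  i <- which(abs(table$age_start - age) < 1e-9)
  if (!length(i))
    stop("age ", age, " is not an interval start of this life table ",
         "(starts: ", paste(table$age_start, collapse = ", "), ")")
  table$e[i]
}
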