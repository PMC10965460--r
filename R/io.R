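# Typed CSV readers/writers. CSV is the only tabular format used:
# UTF-8, mandatory header row, dot decimal separator. Readers validate
# and report offending data rows by file line number (header = line 1).

read_validated_csv <- function(path, need, where) {
  if (!file.exists(path)) stop(where, ": file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(where, " (", path, "): missing columns: ",
         paste(missing_cols, collapse = ", "))
  df
}

# wrap a row-indexed validator error so it reports file line numbers
with_line_numbers <- function(expr, path) {
  tryCatch(expr, error = function(e) {
    msg <- conditionMessage(e)
    m <- regmatches(msg, gregexpr("row\\(s\\) [0-9, ]+", msg))[[1]]
    if (length(m)) {
      rows <- as.integer(strsplit(sub("row\\(s\\) ", "", m[1]), ", ")[[1]])
      msg <- paste0(msg, " [file ", path, ", line(s) ",
                    paste(rows + 1L, collapse = ", "), "]")
    }
    stop(msg, call. = FALSE)
  })
}

#' Read and validate a panel-record CSV
#'
#' Columns: `subject_id, sex, entry_age, entry_state, exit_age,
#' exit_kind, exit_state`. Malformed rows (unknown state codes,
#' non-monotone ages, duplicate ids) are rejected with their file line
#' numbers.
#'
#' @param path CSV file path.
#' @return validated panel-record data frame.
#' @export
read_panel_csv <- function(path) {
  df <- read_validated_csv(path, PANEL_COLUMNS, "panel records")
  with_line_numbers(validate_panel(df, where = "panel records"), path)
}

#' @rdname read_panel_csv
#' @param records panel-record data frame to write.
#' @export
write_panel_csv <- function(records, path) {
  records <- validate_panel(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write age-grouped count and prevalence CSVs
#'
#' `read_counts_csv` expects columns `age_start, age_width, population,
#' deaths` (empty/`Inf` width marks the terminal open-ended interval);
#' `read_prevalence_csv` expects `age_start, age_width, n, cases` and
#' recomputes `prevalence` with its confidence interval.
#'
#' @param path CSV file path.
#' @return validated data frame.
#' @export
read_counts_csv <- function(path) {
  df <- read_validated_csv(path, c("age_start", "age_width", "population",
                                   "deaths"), "age-grouped counts")
  with_line_numbers(validate_counts(df), path)
}

#' @rdname read_counts_csv
#' @param counts counts data frame to write.
#' @export
write_counts_csv <- function(counts, path) {
  counts <- validate_counts(counts)
  utils::write.csv(counts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_counts_csv
#' @export
read_prevalence_csv <- function(path) {
  df <- read_validated_csv(path, c("age_start", "age_width", "n", "cases"),
                           "prevalence table")
  if (any(df$n <= 0))
    stop("prevalence table (", path, "): n must be positive")
  if (any(df$cases < 0 | df$cases > df$n))
    stop("prevalence table (", path, "): cases must lie in [0, n]")
  est <- estimate_prevalence(df$n, df$cases)
  df$prevalence <- est$prevalence
  df$ci_low <- est$ci_low
  df$ci_high <- est$ci_high
  df
}

#' @rdname read_counts_csv
#' @param prevalence prevalence data frame to write.
#' @export
write_prevalence_csv <- function(prevalence, path) {
  utils::write.csv(prevalence, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_counts_csv
#' @param table data frame (life table or HALE results) to write.
#' @export
write_results_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
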