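# Panel-record container: one row per subject covering a two-wave
# observation of the illness-death process. Columns:
#   subject_id  unique identifier
#   sex         "male" / "female"
#   entry_age   exact age at baseline (years)
#   entry_state 1 (disease-free) or 2 (diseased) at baseline
#   exit_age    age at follow-up visit, or exact age at death
#   exit_kind   "alive_observed", "death_exact", or "lost"
#   exit_state  1 or 2 when alive_observed, NA otherwise

PANEL_COLUMNS <- c("subject_id", "sex", "entry_age", "entry_state",
                   "exit_age", "exit_kind", "exit_state")
EXIT_KINDS <- c("alive_observed", "death_exact", "lost")

# Validate a data frame of panel records; returns the frame (with
# normalised column types) or stops with row-indexed messages.
validate_panel <- function(records, where = "panel records") {
  if (!is.data.frame(records))
    stop(where, ": expected a data frame")
  missing_cols <- setdiff(PANEL_COLUMNS, names(records))
  if (length(missing_cols))
    stop(where, ": missing columns: ", paste(missing_cols, collapse = ", "))
  records <- records[PANEL_COLUMNS]
  records$sex <- as.character(records$sex)
  records$exit_kind <- as.character(records$exit_kind)
  records$entry_state <- as.integer(records$entry_state)
  records$exit_state <- as.integer(records$exit_state)
  bad_row <- function(cond, what) {
    idx <- which(cond)
    if (length(idx))
      stop(where, ": ", what, " in row(s) ",
           paste(utils::head(idx, 5L), collapse = ", "),
           if (length(idx) > 5L) sprintf(" (and %d more)", length(idx) - 5L))
  }
  bad_row(duplicated(records$subject_id), "duplicate subject_id")
  bad_row(!records$sex %in% c("male", "female"), "unknown sex code")
  bad_row(!records$entry_state %in% c(1L, 2L), "unknown entry state code")
  bad_row(!records$exit_kind %in% EXIT_KINDS, "unknown exit_kind")
  alive <- records$exit_kind == "alive_observed"
  bad_row(alive & !records$exit_state %in% c(1L, 2L),
          "unknown exit state code")
  bad_row(!is.finite(records$entry_age) | records$entry_age < 0,
          "invalid entry_age")
  obs <- records$exit_kind %in% c("alive_observed", "death_exact")
  bad_row(obs & !(records$exit_age > records$entry_age),
          "exit_age not greater than entry_age")
  records
}
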