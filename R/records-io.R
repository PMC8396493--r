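# CSV dialect for individual rearing records: one row per individual, wide
# daily-egg columns eggs_day_1..eggs_day_K (K = longest adult life in the
# table; trailing/irrelevant cells empty). Writing then reading reproduces
# the record table exactly.

RECORD_COLUMNS <- c("individual_id", "diet", "tray", "age_hatch",
                    "age_larva_end", "age_proto_end", "age_deuto_end",
                    "died_in_stage", "sex", "adult_death_age")

#' Write rearing records to CSV
#'
#' @param records A `mite_records` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  k <- max(c(0L, vapply(records$daily_eggs, length, integer(1))))
  eggs <- matrix(NA_real_, nrow = nrow(records), ncol = k)
  for (i in seq_len(nrow(records))) {
    e <- records$daily_eggs[[i]]
    if (length(e)) eggs[i, seq_along(e)] <- e
  }
  flat <- records[RECORD_COLUMNS]
  class(flat) <- "data.frame"
  if (k > 0) {
    colnames(eggs) <- sprintf("eggs_day_%d", seq_len(k))
    flat <- cbind(flat, eggs)
  }
  utils::write.csv(flat, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read rearing records from CSV
#'
#' Parses the record CSV dialect written by [write_records()] and validates
#' every row: transition ages must be strictly increasing and present
#' exactly up to the first failed transition, `died_in_stage`/`sex`
#' consistency is enforced, and violations are reported with their row
#' numbers.
#'
#' @param path CSV file path.
#' @return A validated `mite_records` data frame.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("input error: file '%s' does not exist", path),
         call. = FALSE)
  }
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  missing_cols <- setdiff(RECORD_COLUMNS, header)
  if (length(missing_cols)) {
    stop("input error: missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  char_cols <- c("individual_id", "diet", "tray", "died_in_stage", "sex")
  classes <- ifelse(header %in% char_cols, "character", "numeric")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = classes)
  egg_cols <- grep("^eggs_day_\\d+$", names(raw), value = TRUE)
  egg_cols <- egg_cols[order(as.integer(sub("eggs_day_", "", egg_cols)))]

  out <- raw[RECORD_COLUMNS]
  eggs_mat <- as.matrix(raw[egg_cols])
  out$daily_eggs <- lapply(seq_len(nrow(out)), function(i) {
    e <- as.numeric(eggs_mat[i, ])
    e <- e[!is.na(e)]
    e
  })
  class(out) <- c("mite_records", "data.frame")
  validate_records(out)
  out
}

#' Validate a record table
#'
#' Checks the structural invariants of a `mite_records` table and stops
#' with a message listing the offending row numbers on violation.
#'
#' @param records A `mite_records` data frame.
#' @return `records`, invisibly.
#' @export
validate_records <- function(records) {
  trans <- cbind(records$age_hatch, records$age_larva_end,
                 records$age_proto_end, records$age_deuto_end)
  bad <- function(cond, msg) {
    rows <- which(cond)
    if (length(rows)) {
      stop(sprintf("validation error: %s (row%s %s)", msg,
                   if (length(rows) > 1) "s" else "",
                   paste(rows, collapse = ", ")), call. = FALSE)
    }
  }
  n_trans <- rowSums(!is.na(trans))
  # transitions present exactly up to the first NA
  first_na <- apply(trans, 1, function(a) {
    i <- which(is.na(a))
    if (length(i)) i[1] else 5L
  })
  bad(n_trans != first_na - 1L,
      "transition ages must be absent from the first failed transition onward")
  non_mono <- apply(trans, 1, function(a) {
    a <- a[!is.na(a)]
    length(a) > 1 && any(diff(a) <= 0)
  })
  bad(non_mono, "transition ages must be strictly increasing")
  bad(!records$died_in_stage %in% c(STAGES, "none"),
      "died_in_stage must be one of egg/larva/protonymph/deutonymph/none")
  expect_stage <- c(STAGES, "none")[pmin(first_na, 5L)]
  bad(records$died_in_stage != expect_stage,
      "died_in_stage inconsistent with recorded transitions")
  bad(!records$sex %in% c("female", "male", "unknown"),
      "sex must be female/male/unknown")
  bad((records$died_in_stage != "none") != (records$sex == "unknown"),
      "sex must be unknown exactly for immature deaths")
  is_f <- records$sex == "female"
  bad(is_f & is.na(records$adult_death_age),
      "females must carry an adult death age")
  bad(!is_f & !is.na(records$adult_death_age),
      "adult death age applies to females only")
  bad(is_f & !is.na(records$age_deuto_end) &
        records$adult_death_age <= records$age_deuto_end,
      "adult death age must exceed the age at adulthood")
  n_eggs_days <- vapply(records$daily_eggs, length, integer(1))
  bad(!is_f & n_eggs_days > 0, "daily egg counts apply to females only")
  bad(vapply(records$daily_eggs, function(e) any(e < 0), logical(1)),
      "daily egg counts must be nonnegative")
  invisible(records)
}
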