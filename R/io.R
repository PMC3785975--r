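# File interfaces: CSV for record tables, JSON for single records,
# YAML for norms and template banks.

CALENDAR_COLS <- paste0("cal_", WEEKDAYS)
PROBLEM_COLS <- sprintf("p%02d", 1:10)

#' Read screening records from CSV
#'
#' Expects one row per record with columns `person_id`, `class_id`,
#' `gender`, `age_years`, `education`, `migration`, `smoking_item`,
#' `activity_hours_week`, `rsod_category`, `cal_mon`..`cal_sun`,
#' `max_drinks_occasion`, `owns_mobile`. Localized categorical labels can be
#' translated to the canonical lowercase tokens through `label_map`, a named
#' list mapping column name to a named character vector
#' (`c("taeglich" = "daily", ...)`). Duplicate `person_id`s are a load error.
#'
#' @param path CSV file path.
#' @param label_map optional per-column label translation.
#' @return A tibble, one row per record, with a `valid` logical column and a
#'   `violations` list-column from [validate_screening()].
#' @export
read_screening_csv <- function(path, label_map = NULL) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(person_id = "character",
                                          class_id = "character")))
  need <- c("person_id", "class_id", "gender", "age_years", "education",
            "migration", "smoking_item", "activity_hours_week",
            "rsod_category", CALENDAR_COLS, "max_drinks_occasion",
            "owns_mobile")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    abort_input(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(df$person_id))
    abort_input("duplicate person_id values in screening file")
  for (col in names(label_map %||% list())) {
    m <- label_map[[col]]
    hit <- df[[col]] %in% names(m)
    df[[col]][hit] <- unname(m[df[[col]][hit]])
  }
  df$owns_mobile <- as.logical(df$owns_mobile)
  recs <- screening_from_df(df)
  df$violations <- lapply(recs, validate_screening)
  df$valid <- vapply(df$violations, nrow, 0L) == 0L
  df
}

# Rebuild screening_record objects from a wide data frame (without
# re-triggering per-record construction warnings for out-of-range ages).
screening_from_df <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    structure(list(
      person_id = row$person_id, class_id = row$class_id,
      gender = row$gender, age_years = as.integer(row$age_years),
      education = row$education, migration = row$migration,
      smoking_item = row$smoking_item,
      activity_hours_week = as.numeric(row$activity_hours_week),
      rsod_category = row$rsod_category,
      drinking_calendar = as.integer(unlist(row[CALENDAR_COLS])),
      max_drinks_occasion = as.integer(row$max_drinks_occasion),
      owns_mobile = isTRUE(row$owns_mobile)
    ), class = "screening_record")
  })
}

#' Write screening records to CSV
#'
#' @param df a screening tibble as returned by [read_screening_csv()] or
#'   [simulate_cohort()]; the `violations`/`valid` bookkeeping columns are
#'   dropped.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_screening_csv <- function(df, path) {
  drop <- intersect(c("violations", "valid"), names(df))
  write.csv(df[setdiff(names(df), drop)], path, row.names = FALSE)
  invisible(path)
}

#' JSON round-trip for single records
#'
#' Serialise a screening record, program baseline or follow-up record to
#' JSON and back; used by the command-line `classify` and `feedback`
#' subcommands.
#'
#' @param record a `screening_record`, `program_baseline` or
#'   `followup_record`.
#' @return JSON string.
#' @export
record_to_json <- function(record) {
  cls <- class(record)[1]
  payload <- unclass(record)
  if (cls == "program_baseline") payload$screening <- unclass(payload$screening)
  jsonlite::toJSON(c(list(.record_type = cls), payload),
                   auto_unbox = TRUE, null = "null", na = "null")
}

#' @rdname record_to_json
#' @param json a JSON string produced by [record_to_json()].
#' @export
record_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  cls <- x$.record_type
  x$.record_type <- NULL
  fix_na <- function(v) if (is.null(v)) NA else v
  if (cls == "program_baseline") {
    scr <- x$screening
    x$screening <- do.call(screening_record, scr)
    x$typical_drinking_day <- fix_na(x$typical_drinking_day)
    x$typical_drinking_time <- fix_na(x$typical_drinking_time)
    do.call(program_baseline, x)
  } else if (cls == "screening_record") {
    do.call(screening_record, x)
  } else if (cls == "followup_record") {
    vec_fields <- c("drinking_calendar", "problems")   # NULL-able vectors
    for (f in setdiff(names(formals(followup_record)), vec_fields)) {
      if (is.null(x[[f]])) x[f] <- list(NA)
    }
    do.call(followup_record, x)
  } else {
    abort_input(paste("unknown record type:", cls))
  }
}
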