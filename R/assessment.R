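# Assessment instruments: screening, program baseline, follow-up.
#
# All categorical answers are stored as canonical lowercase tokens; file
# readers translate localized labels through a configurable dictionary
# (see read_screening_csv). Identifiers are opaque strings.

GENDERS <- c("male", "female")
EDUCATION_LEVELS <- c("none", "secondary", "extended_secondary", "technical_or_high")
MIGRATION_LEVELS <- c("none", "one_parent", "both_parents")
SMOKING_LEVELS <- c("daily", "occasional", "former", "never")
IMPORTANCE_LEVELS <- c("very_unimportant", "rather_unimportant",
                       "rather_important", "very_important")
WEEKDAYS <- c("mon", "tue", "wed", "thu", "fri", "sat", "sun")

#' Response categories of the 30-day risky single-occasion drinking item
#'
#' The screening instrument asks how often the respondent had five (four for
#' women) or more drinks on one occasion in the last 30 days, with eight
#' ordered response categories from "never" to "more than 12 times".
#'
#' @return Character vector of the 8 canonical category tokens, in order.
#' @export
rsod_categories <- function() {
  c("never", "1-2", "3-4", "5-6", "7-8", "9-10", "11-12", ">12")
}

#' Alcohol-related problem items and their categories
#'
#' Ten yes/no problem items (last 3 months), positionally coded p01..p10 and
#' grouped into four categories: individual, relational, sexual, delinquency.
#' The grouping is configurable because only the category structure, not the
#' item wording, is fixed by the instrument.
#'
#' @return Named character vector: names p01..p10, values the category of
#'   each item.
#' @export
problem_item_categories <- function() {
  c(p01 = "individual", p02 = "individual", p03 = "individual",
    p04 = "relational", p05 = "relational", p06 = "relational",
    p07 = "sexual", p08 = "sexual",
    p09 = "delinquency", p10 = "delinquency")
}

#' Construct a screening record
#'
#' One student's screening answers: demographics, smoking, weekly physical
#' activity, the three alcohol items (30-day RSOD frequency category, 7-day
#' typical-week drinking calendar, maximum drinks on one occasion), and
#' mobile-phone ownership.
#'
#' @param person_id,class_id opaque identifier strings.
#' @param gender `"male"` or `"female"`.
#' @param age_years integer age; ages outside 15-25 are accepted with a
#'   warning (the target population is vocational-school students).
#' @param education one of `"none"`, `"secondary"`, `"extended_secondary"`,
#'   `"technical_or_high"`.
#' @param migration `"none"`, `"one_parent"` or `"both_parents"` (parents
#'   born abroad).
#' @param smoking_item `"daily"`, `"occasional"`, `"former"` or `"never"`.
#' @param activity_hours_week non-negative hours of moderate-to-vigorous
#'   extracurricular physical activity per week.
#' @param rsod_category one of [rsod_categories()].
#' @param drinking_calendar integer vector of length 7 (standard drinks per
#'   day of a typical week, Monday..Sunday).
#' @param max_drinks_occasion non-negative integer, maximum drinks on a
#'   single occasion in the last 30 days.
#' @param owns_mobile logical; phone ownership is the program's eligibility
#'   criterion.
#' @return An object of class `screening_record` (a named list).
#' @seealso [validate_screening()]
#' @export
screening_record <- function(person_id, class_id, gender, age_years,
                             education, migration, smoking_item,
                             activity_hours_week, rsod_category,
                             drinking_calendar, max_drinks_occasion,
                             owns_mobile) {
  rec <- structure(list(
    person_id = as.character(person_id),
    class_id = as.character(class_id),
    gender = gender,
    age_years = as.integer(age_years),
    education = education,
    migration = migration,
    smoking_item = smoking_item,
    activity_hours_week = as.numeric(activity_hours_week),
    rsod_category = rsod_category,
    drinking_calendar = as.integer(drinking_calendar),
    max_drinks_occasion = as.integer(max_drinks_occasion),
    owns_mobile = isTRUE(owns_mobile)
  ), class = "screening_record")
  if (!is.na(rec$age_years) && (rec$age_years < 15 || rec$age_years > 25)) {
    warning(sprintf("age_years = %d is outside the expected 15-25 range for %s",
                    rec$age_years, rec$person_id))
  }
  rec
}

#' Validate a screening record
#'
#' Checks every type invariant of a screening record and reports violations
#' as data rather than raising errors, so a whole file can be validated in
#' one pass. An empty result means every downstream operation (risk
#' classification, feedback) accepts the record.
#'
#' @param record a [screening_record()] (or a compatible named list).
#' @return A tibble with columns `field` and `rule`, one row per violation;
#'   zero rows iff the record is well formed.
#' @export
validate_screening <- function(record) {
  v <- list()
  bad <- function(field, rule) v[[length(v) + 1]] <<- list(field = field, rule = rule)

  if (!nzchar(record$person_id %||% "")) bad("person_id", "must be a non-empty string")
  if (!nzchar(record$class_id %||% "")) bad("class_id", "must be a non-empty string")
  if (!isTRUE(record$gender %in% GENDERS))
    bad("gender", "must be 'male' or 'female'")
  if (!is.numeric(record$age_years) || is.na(record$age_years) || record$age_years < 15)
    bad("age_years", "must be an integer >= 15")
  if (!isTRUE(record$education %in% EDUCATION_LEVELS))
    bad("education", paste("must be one of:", paste(EDUCATION_LEVELS, collapse = ", ")))
  if (!isTRUE(record$migration %in% MIGRATION_LEVELS))
    bad("migration", paste("must be one of:", paste(MIGRATION_LEVELS, collapse = ", ")))
  if (!isTRUE(record$smoking_item %in% SMOKING_LEVELS))
    bad("smoking_item", paste("must be one of:", paste(SMOKING_LEVELS, collapse = ", ")))
  if (!is.numeric(record$activity_hours_week) || is.na(record$activity_hours_week) ||
      record$activity_hours_week < 0)
    bad("activity_hours_week", "must be a non-negative number")
  if (!isTRUE(record$rsod_category %in% rsod_categories()))
    bad("rsod_category", paste("must be one of:", paste(rsod_categories(), collapse = ", ")))
  cal <- record$drinking_calendar
  if (length(cal) != 7 || anyNA(cal) || any(cal < 0))
    bad("drinking_calendar", "must have exactly 7 non-negative entries")
  if (!is.numeric(record$max_drinks_occasion) || is.na(record$max_drinks_occasion) ||
      record$max_drinks_occasion < 0)
    bad("max_drinks_occasion", "must be a non-negative integer")
  if (!is.logical(record$owns_mobile) || is.na(record$owns_mobile))
    bad("owns_mobile", "must be TRUE or FALSE")

  if (length(v) == 0) {
    tibble(field = character(), rule = character())
  } else {
    bind_rows(lapply(v, as_tibble))
  }
}

#' Classify a smoking item answer as smoker / non-smoker
#'
#' Current daily and occasional smokers count as smokers; former and never
#' smokers do not.
#'
#' @param smoking_item `"daily"`, `"occasional"`, `"former"` or `"never"`
#'   (vectorised).
#' @return Logical vector.
#' @export
derive_smoker <- function(smoking_item) {
  if (length(smoking_item) == 0 || !all(smoking_item %in% SMOKING_LEVELS)) {
    abort_input(paste("smoking_item must be one of:",
                      paste(SMOKING_LEVELS, collapse = ", ")))
  }
  smoking_item %in% c("daily", "occasional")
}

#' Total standard drinks in a typical week
#'
#' Sums the 7-day drinking calendar (drinks per day of a typical week).
#'
#' @param drinking_calendar integer vector of length 7, each entry >= 0.
#' @return Integer total.
#' @export
weekly_drinks_total <- function(drinking_calendar) {
  if (length(drinking_calendar) != 7 || anyNA(drinking_calendar) ||
      any(drinking_calendar < 0)) {
    abort_input("drinking_calendar must be 7 non-negative integers")
  }
  as.integer(sum(drinking_calendar))
}

#' Collapse the 8 RSOD frequency categories into 3 risk-relevant bands
#'
#' Risk classification only distinguishes no occasions, 1-2 occasions, and
#' more than 2 occasions in the last 30 days; every category at or above
#' "3-4 times" exceeds two occasions.
#'
#' @param rsod_category one of [rsod_categories()] (vectorised).
#' @return Factor with levels `NONE`, `ONE_TO_TWO`, `MORE_THAN_TWO`.
#' @export
map_rsod_band <- function(rsod_category) {
  if (length(rsod_category) == 0 || !all(rsod_category %in% rsod_categories())) {
    abort_input(paste("rsod_category must be one of:",
                      paste(rsod_categories(), collapse = ", ")))
  }
  band <- ifelse(rsod_category == "never", "NONE",
          ifelse(rsod_category == "1-2", "ONE_TO_TWO", "MORE_THAN_TWO"))
  factor(band, levels = rsod_bands())
}

#' The three RSOD frequency bands, in increasing order
#' @return Character vector `c("NONE", "ONE_TO_TWO", "MORE_THAN_TWO")`.
#' @export
rsod_bands <- function() c("NONE", "ONE_TO_TWO", "MORE_THAN_TWO")

#' Any alcohol-related problem in the last 3 months
#'
#' TRUE iff at least one of the ten problem items is endorsed. Missing items
#' count as "no problem" (conservative: the reported outcome is a plain
#' yes/no with no missingness rule).
#'
#' @param problems logical vector of length 10 (p01..p10); `NA` allowed.
#' @return Single logical.
#' @export
any_problem <- function(problems) {
  if (length(problems) != 10) abort_input("problems must have exactly 10 items")
  isTRUE(any(problems, na.rm = TRUE))
}

#' Construct a program-entry baseline record
#'
#' Extends a screening record with the program-entry assessment: the ten
#' alcohol-related problem items, the stated importance of reducing
#' consumption, and the typical drinking day and time (which anchor the
#' biweekly drinking-day text messages).
#'
#' @param screening a validated [screening_record()].
#' @param problems logical vector of length 10 (p01..p10).
#' @param importance_reduce one of `"very_unimportant"`,
#'   `"rather_unimportant"`, `"rather_important"`, `"very_important"`.
#' @param typical_drinking_day weekday token `"mon"`..`"sun"`, or `NA` for
#'   participants who never drink.
#' @param typical_drinking_time hour of day (0-23), or `NA`.
#' @return An object of class `program_baseline`.
#' @export
program_baseline <- function(screening, problems, importance_reduce,
                             typical_drinking_day = NA,
                             typical_drinking_time = NA) {
  if (!inherits(screening, "screening_record"))
    abort_input("screening must be a screening_record")
  if (length(problems) != 10) abort_input("problems must have exactly 10 items")
  assert_scalar_choice(importance_reduce, IMPORTANCE_LEVELS, "importance_reduce")
  if (!is.na(typical_drinking_day))
    assert_scalar_choice(typical_drinking_day, WEEKDAYS, "typical_drinking_day")
  if (!is.na(typical_drinking_time) &&
      (typical_drinking_time < 0 || typical_drinking_time > 23))
    abort_input("typical_drinking_time must be an hour 0-23")
  structure(list(
    screening = screening,
    problems = as.logical(problems),
    importance_reduce = importance_reduce,
    typical_drinking_day = typical_drinking_day,
    typical_drinking_time = typical_drinking_time
  ), class = "program_baseline")
}

READ_LEVELS <- c("thorough", "short_look", "not_read")
VOLUME_PREFS <- c("ok", "fewer", "more")
EVAL_LEVELS <- c("rather_yes", "rather_no")

#' Construct a follow-up record
#'
#' The 3-month follow-up re-assesses the alcohol outcomes and adds
#' program-use and evaluation items. Every field is individually optional:
#' item missingness is encoded as `NA`, never as a sentinel value, and
#' reporting uses per-item denominators.
#'
#' @param person_id identifier matching the screening record.
#' @param rsod_category,drinking_calendar,max_drinks_occasion,problems as in
#'   [screening_record()] / [program_baseline()]; `NA` when missing.
#' @param received_regularly logical; SMS messages arrived regularly.
#' @param read_level `"thorough"`, `"short_look"` or `"not_read"`.
#' @param timing_ok logical; message timing judged appropriate.
#' @param volume_pref `"ok"`, `"fewer"` or `"more"` messages preferred.
#' @param feedback_comprehensible,feedback_interesting,feedback_tailored,
#'   sms_comprehensible,sms_helpful,sms_tailored evaluation items, each
#'   `"rather_yes"` / `"rather_no"` or `NA`.
#' @return An object of class `followup_record`.
#' @export
followup_record <- function(person_id,
                            rsod_category = NA, drinking_calendar = NULL,
                            max_drinks_occasion = NA, problems = NULL,
                            received_regularly = NA, read_level = NA,
                            timing_ok = NA, volume_pref = NA,
                            feedback_comprehensible = NA,
                            feedback_interesting = NA,
                            feedback_tailored = NA,
                            sms_comprehensible = NA, sms_helpful = NA,
                            sms_tailored = NA) {
  if (!is.na(rsod_category))
    assert_scalar_choice(rsod_category, rsod_categories(), "rsod_category")
  if (!is.null(drinking_calendar) && !all(is.na(drinking_calendar)) &&
      (length(drinking_calendar) != 7 || any(drinking_calendar < 0, na.rm = TRUE)))
    abort_input("drinking_calendar must be 7 non-negative integers or NULL")
  if (!is.null(problems) && length(problems) != 10)
    abort_input("problems must have exactly 10 items or be NULL")
  if (!is.na(read_level)) assert_scalar_choice(read_level, READ_LEVELS, "read_level")
  if (!is.na(volume_pref)) assert_scalar_choice(volume_pref, VOLUME_PREFS, "volume_pref")
  for (item in list(feedback_comprehensible, feedback_interesting,
                    feedback_tailored, sms_comprehensible, sms_helpful,
                    sms_tailored)) {
    if (!is.na(item)) assert_scalar_choice(item, EVAL_LEVELS, "evaluation item")
  }
  structure(list(
    person_id = as.character(person_id),
    rsod_category = rsod_category,
    drinking_calendar = drinking_calendar,
    max_drinks_occasion = max_drinks_occasion,
    problems = problems,
    received_regularly = received_regularly,
    read_level = read_level,
    timing_ok = timing_ok,
    volume_pref = volume_pref,
    feedback_comprehensible = feedback_comprehensible,
    feedback_interesting = feedback_interesting,
    feedback_tailored = feedback_tailored,
    sms_comprehensible = sms_comprehensible,
    sms_helpful = sms_helpful,
    sms_tailored = sms_tailored
  ), class = "followup_record")
}
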