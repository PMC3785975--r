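# Builders for well-formed records with overridable fields.

make_screening <- function(person_id = "p1", class_id = "c1", gender = "male",
                           age_years = 18, education = "secondary",
                           migration = "none", smoking_item = "never",
                           activity_hours_week = 4,
                           rsod_category = "1-2",
                           drinking_calendar = c(0, 0, 0, 2, 1, 6, 3),
                           max_drinks_occasion = 6, owns_mobile = TRUE) {
  screening_record(person_id, class_id, gender, age_years, education,
                   migration, smoking_item, activity_hours_week,
                   rsod_category, drinking_calendar, max_drinks_occasion,
                   owns_mobile)
}

make_baseline <- function(screening = make_screening(),
                          problems = rep(FALSE, 10),
                          importance_reduce = "rather_unimportant",
                          typical_drinking_day = "sat",
                          typical_drinking_time = 21) {
  program_baseline(screening, problems, importance_reduce,
                   typical_drinking_day, typical_drinking_time)
}

# Paired binary long data: n persons over n_classes, baseline positives b,
# follow-up positives f, maximally concordant deterministic layout.
paired_long <- function(outcome, n, b, f, n_classes = 36) {
  ids <- sprintf("%s%03d", outcome, seq_len(n))
  cls <- sprintf("c%02d", rep_len(seq_len(n_classes), n))
  base <- c(rep(1, b), rep(0, n - b))
  fu <- c(rep(1, f), rep(0, n - f))
  long_records(c(ids, ids), c(cls, cls),
               rep(c("baseline", "followup"), each = n), c(base, fu))
}
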