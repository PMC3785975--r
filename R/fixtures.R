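# Worked-example datasets.
#
# These constructors build, in code, small deterministic record-level
# datasets that encode the participant-flow, outcome and program-use
# tallies of the cohort the package's defaults emulate (490 students in 36
# classes; 364 program participants; 278-280 complete cases per outcome).
# They exist so the reporting and evaluation pipelines can be demonstrated
# and checked against known totals without any real data.

#' Worked-example participant flow data
#'
#' Record-level stage data: 490 students present, 488 consenting, 477
#' phone owners, 364 registered, 23 unsubscribed (via stop messages in the
#' SMS log), 280 participants and 87 eligible nonparticipants at follow-up.
#'
#' @return List with `screening`, `registrations`, `log`, `followups`,
#'   `n_present`, ready for [participant_flow()].
#' @export
demo_flow_data <- function() {
  n_cons <- 488
  ids <- sprintf("p%04d", seq_len(n_cons))
  owns <- c(rep(TRUE, 477), rep(FALSE, n_cons - 477))
  screening <- tibble(person_id = ids,
                      class_id = sprintf("c%02d", rep_len(1:36, n_cons)),
                      owns_mobile = owns)
  registrations <- ids[1:364]
  log <- sms_log()
  t0 <- as.POSIXct("2012-05-01 12:00:00", tz = "UTC")
  for (i in 1:23) {
    log <- apply_incoming(log, sms_event(t0 + i * 3600, "in",
                                         registrations[i], "STOP"))
  }
  followups <- tibble(person_id = c(ids[1:280], ids[365:451]))
  list(screening = screening, registrations = registrations, log = log,
       followups = followups, n_present = 490)
}

# deterministic paired binary columns from a 2x2 joint distribution
paired_binary <- function(n11, n10, n01, n00) {
  tibble(value_b = c(rep(1, n11 + n10), rep(0, n01 + n00)),
         value_f = c(rep(1, n11), rep(0, n10), rep(1, n01), rep(0, n00)))
}

#' Worked-example complete-case outcome data
#'
#' Long-format outcome records for program participants with the
#' complete-case margins: any RSOD 210/278 at baseline and 188/278 at
#' follow-up, frequent RSOD 134/278 to 114/278, any problem 57/280 to
#' 40/280, plus count outcomes (weekly drinks, 247 pairs; max drinks, 275
#' pairs) drawn reproducibly from the package's count model with the
#' default rate ratios. Persons are spread over 36 school classes.
#'
#' @return Tibble in the [study_outcomes_long()] layout.
#' @export
demo_outcome_data <- function() {
  joint <- list(
    rsod_any = c(172, 38, 16, 52),       # 210 -> 188 of 278
    rsod_frequent = c(100, 34, 14, 130), # 134 -> 114 of 278
    any_problem = c(30, 27, 10, 213)     # 57 -> 40 of 280
  )
  long <- bind_rows(lapply(names(joint), function(o) {
    j <- joint[[o]]
    pb <- paired_binary(j[1], j[2], j[3], j[4])
    n <- nrow(pb)
    ids <- sprintf("%s_%03d", o, seq_len(n))
    cls <- sprintf("c%02d", rep_len(1:36, n))
    bind_rows(
      tibble(outcome = o, person_id = ids, class_id = cls,
             time = "baseline", value = pb$value_b),
      tibble(outcome = o, person_id = ids, class_id = cls,
             time = "followup", value = pb$value_f))
  }))
  counts <- with_seed(20130902, {
    par_w <- zinb_moments(13.4, 15.3, 0.15)
    par_m <- zinb_moments(11.3, 10.3, 0.10)
    mk <- function(o, n, par, rr) {
      base <- as.integer(qzinb(runif(n), par))
      fu <- shift_count(base, par, rr, rho = 0.5)
      ids <- sprintf("%s_%03d", o, seq_len(n))
      cls <- sprintf("c%02d", rep_len(1:36, n))
      bind_rows(
        tibble(outcome = o, person_id = ids, class_id = cls,
               time = "baseline", value = as.numeric(base)),
        tibble(outcome = o, person_id = ids, class_id = cls,
               time = "followup", value = as.numeric(fu)))
    }
    bind_rows(mk("weekly_drinks", 247, par_w, 0.83),
              mk("max_drinks", 275, par_m, 0.91))
  })
  out <- bind_rows(long, counts)
  out$available <- !is.na(out$value)
  out
}

#' Worked-example program-use follow-up data
#'
#' One row per follow-up respondent (n = 280) with per-item validity
#' matching the reported program-use and evaluation tallies, e.g. 254 of
#' 269 receiving messages regularly and 124 of 249 reading them thoroughly;
#' missing answers are `NA`.
#'
#' @return Tibble usable with [program_use_table()].
#' @export
demo_program_use_data <- function() {
  n <- 280
  fill <- function(...) {
    groups <- list(...)
    vals <- unlist(lapply(groups, function(g) rep(g$value, g$n)))
    c(vals, rep(NA, n - length(vals)))
  }
  lv <- function(value, n) list(value = value, n = n)
  tibble(
    person_id = sprintf("p%04d", seq_len(n)),
    received_regularly = fill(lv(TRUE, 254), lv(FALSE, 15)),
    read_level = fill(lv("thorough", 124), lv("short_look", 111),
                      lv("not_read", 14)),
    timing_ok = fill(lv(TRUE, 196), lv(FALSE, 64)),
    volume_pref = fill(lv("ok", 149), lv("fewer", 92), lv("more", 18)),
    feedback_comprehensible = fill(lv("rather_yes", 250), lv("rather_no", 15)),
    feedback_interesting = fill(lv("rather_yes", 182), lv("rather_no", 76)),
    feedback_tailored = fill(lv("rather_yes", 127), lv("rather_no", 130)),
    sms_comprehensible = fill(lv("rather_yes", 232), lv("rather_no", 8)),
    sms_helpful = fill(lv("rather_yes", 71), lv("rather_no", 164)),
    sms_tailored = fill(lv("rather_yes", 79), lv("rather_no", 155))
  )
}
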