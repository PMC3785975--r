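# Participant-flow accounting and results-style summary tables.
#
# All printed percentages use half-up rounding to 1 decimal, and every
# denominator is the one conventional for its stage: consent/present,
# owners/consented, registered/owners, followed-up/owners,
# unsubscribed/registered. Summary tables use per-item (per-outcome)
# complete-case denominators, never listwise deletion.

#' Participant flow counts and percentages
#'
#' @param screening screening tibble of consenting students (must carry
#'   `person_id` and `owns_mobile`).
#' @param registrations character vector of registered participant ids
#'   (must be phone owners present in `screening`).
#' @param log an [sms_log()]; its unsubscriptions must concern registered
#'   participants.
#' @param followups tibble of follow-up attenders (`person_id`; attenders
#'   must appear in `screening`).
#' @param n_present number of students present at screening (>=
#'   `nrow(screening)`).
#' @return Object of class `flow_counts`: stage counts, and `percentages`
#'   (named, half-up 1 decimal): `consented_pct` (of present),
#'   `phone_owner_pct` (of consented), `registered_pct` (of owners),
#'   `followed_up_pct` (of owners), `unsubscribed_pct` (of registered).
#' @export
participant_flow <- function(screening, registrations, log, followups,
                             n_present) {
  owners <- screening$person_id[screening$owns_mobile]
  if (!all(registrations %in% owners))
    abort_input("registered ids must be consenting phone owners")
  unsub_ids <- names(log$unsubscribed_at)
  if (!all(unsub_ids %in% registrations))
    abort_input("unsubscribed ids must be registered participants")
  if (!all(followups$person_id %in% screening$person_id))
    abort_input("follow-up ids must exist in the screening data")
  n_cons <- nrow(screening)
  if (n_present < n_cons) abort_input("n_present must be >= number consenting")

  fu_eligible <- followups$person_id %in% owners
  counts <- list(
    present = n_present,
    consented = n_cons,
    phone_owners = length(owners),
    registered = length(registrations),
    unsubscribed = length(unsub_ids),
    followed_up = sum(fu_eligible),
    followed_up_participants = sum(followups$person_id %in% registrations),
    followed_up_nonparticipants = sum(fu_eligible &
                                        !followups$person_id %in% registrations)
  )
  pct <- function(num, den) if (den == 0) 0 else round_half_up(100 * num / den, 1)
  counts$percentages <- c(
    consented_pct = pct(counts$consented, counts$present),
    phone_owner_pct = pct(counts$phone_owners, counts$consented),
    registered_pct = pct(counts$registered, counts$phone_owners),
    followed_up_pct = pct(counts$followed_up, counts$phone_owners),
    unsubscribed_pct = pct(counts$unsubscribed, counts$registered)
  )
  structure(counts, class = "flow_counts")
}

#' @export
print.flow_counts <- function(x, ...) {
  p <- x$percentages
  cat(sprintf("present %d; consented %d (%.1f%%); phone owners %d (%.1f%%)\n",
              x$present, x$consented, p["consented_pct"], x$phone_owners,
              p["phone_owner_pct"]))
  cat(sprintf("registered %d (%.1f%%); unsubscribed %d (%.1f%%); followed up %d (%.1f%%)\n",
              x$registered, p["registered_pct"], x$unsubscribed,
              p["unsubscribed_pct"], x$followed_up, p["followed_up_pct"]))
  invisible(x)
}

#' Baseline / follow-up outcome summary table
#'
#' Complete-case summaries per outcome: for binary outcomes n (%) of the
#' per-outcome complete-case denominator (persons observed at both time
#' points); for counts mean (SD) to 1 decimal.
#'
#' @param long_data long outcome tibble ([study_outcomes_long()] layout).
#' @return Tibble with one row per outcome: `outcome`, `type`, `n` (complete
#'   cases), baseline and follow-up columns (`baseline_n`, `baseline_pct`
#'   or `baseline_mean`, `baseline_sd`, and the `followup_*`
#'   counterparts).
#' @export
outcome_table <- function(long_data) {
  binaries <- c("rsod_any", "rsod_frequent", "any_problem")
  rows <- lapply(intersect(OUTCOME_NAMES, unique(long_data$outcome)), function(o) {
    d <- long_data[long_data$outcome == o & !is.na(long_data$value), ]
    wide <- merge(d[d$time == "baseline", c("person_id", "value")],
                  d[d$time == "followup", c("person_id", "value")],
                  by = "person_id", suffixes = c("_b", "_f"))
    n <- nrow(wide)
    if (o %in% binaries) {
      tibble(outcome = o, type = "binary", n = n,
             baseline_n = sum(wide$value_b),
             baseline_pct = if (n) round_half_up(100 * mean(wide$value_b), 1) else 0,
             followup_n = sum(wide$value_f),
             followup_pct = if (n) round_half_up(100 * mean(wide$value_f), 1) else 0,
             baseline_mean = NA_real_, baseline_sd = NA_real_,
             followup_mean = NA_real_, followup_sd = NA_real_)
    } else {
      tibble(outcome = o, type = "count", n = n,
             baseline_n = NA_real_, baseline_pct = NA_real_,
             followup_n = NA_real_, followup_pct = NA_real_,
             baseline_mean = round_half_up(mean(wide$value_b), 1),
             baseline_sd = round_half_up(sd(wide$value_b), 1),
             followup_mean = round_half_up(mean(wide$value_f), 1),
             followup_sd = round_half_up(sd(wide$value_f), 1))
    }
  })
  bind_rows(rows)
}

#' Program-use and evaluation summary
#'
#' Summarises the follow-up program-use items with per-item denominators
#' (n with valid data): share receiving messages regularly, the read-level
#' distribution, timing approval, volume preference, and the six rather-yes
#' / rather-no evaluation items for the online feedback and the SMS
#' messages.
#'
#' @param followups tibble with one row per follow-up respondent and the
#'   program-use columns of [followup_record()] (missing = `NA`).
#' @return Tibble with columns `item`, `category`, `n_valid`, `count`,
#'   `pct` (half-up, 1 decimal); items with no valid data are flagged with
#'   `n_valid = 0` and `pct = NA`.
#' @export
program_use_table <- function(followups) {
  summarise_cat <- function(item, values, levels) {
    valid <- values[!is.na(values)]
    nv <- length(valid)
    if (nv == 0)
      return(tibble(item = item, category = levels, n_valid = 0L,
                    count = 0L, pct = NA_real_))
    bind_rows(lapply(levels, function(lv) {
      cnt <- sum(valid == lv)
      tibble(item = item, category = lv, n_valid = nv, count = cnt,
             pct = round_half_up(100 * cnt / nv, 1))
    }))
  }
  to_yesno <- function(x) ifelse(is.na(x), NA,
                                 ifelse(x %in% c(TRUE, "rather_yes"), "yes", "no"))
  bind_rows(
    summarise_cat("received_regularly", to_yesno(followups$received_regularly),
                  c("yes", "no")),
    summarise_cat("read_level", followups$read_level, READ_LEVELS),
    summarise_cat("timing_ok", to_yesno(followups$timing_ok), c("yes", "no")),
    summarise_cat("volume_pref", followups$volume_pref, VOLUME_PREFS),
    bind_rows(lapply(c("feedback_comprehensible", "feedback_interesting",
                       "feedback_tailored", "sms_comprehensible",
                       "sms_helpful", "sms_tailored"), function(it) {
      summarise_cat(it, followups[[it]], EVAL_LEVELS)
    }))
  )
}
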