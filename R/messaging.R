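# Tailored SMS planning and rendering.
#
# Dose and content pool depend on the risk group: the non-risk tier gets one
# weekly message for 12 weeks; the low- and high-risk tiers additionally get
# a biweekly message on their stated typical drinking day and time, focused
# on strategies to reduce drinking. "Biweekly" means every second week -- 6
# drinking-day messages over the 12 weeks, in odd weeks by default.

#' The ten SMS content categories
#'
#' @return Tibble with columns `id` (1..10) and `label`.
#' @export
content_categories <- function() {
  tibble(id = 1:10, label = c(
    "drinking and body weight/fitness",
    "resisting peer pressure",
    "pros of sensible drinking",
    "motivation to maintain sensible drinking",
    "motivation for sensible drinking",
    "alcohol-related problems",
    "maximum number of drinks on a single occasion and related risks",
    "risks of binge drinking",
    "importance of reducing alcohol consumption",
    "local outpatient services for alcohol counseling"))
}

#' Weekly content pool of a risk group
#'
#' Non-risk participants draw from categories 1-4; low-risk from 1-3 and
#' 5-9; high-risk additionally from category 10 (counseling services).
#' Category 4 (maintaining sensible drinking) is exclusive to the non-risk
#' tier.
#'
#' @param risk_group `"NON_RISK"`, `"LOW_RISK"` or `"HIGH_RISK"`.
#' @return Integer vector of category ids.
#' @export
category_pool <- function(risk_group) {
  risk_group <- as.character(risk_group)
  assert_scalar_choice(risk_group, risk_groups(), "risk_group")
  switch(risk_group,
         NON_RISK = c(1L, 2L, 3L, 4L),
         LOW_RISK = c(1L, 2L, 3L, 5L, 6L, 7L, 8L, 9L),
         HIGH_RISK = c(1L, 2L, 3L, 5L, 6L, 7L, 8L, 9L, 10L))
}

#' Messaging configuration
#'
#' @param weekly_day weekday token for the fixed weekly slot (default
#'   `"wed"`).
#' @param weekly_hour hour of day for the weekly slot (default 17).
#' @param n_weeks program length in weeks (default 12).
#' @param biweekly_phase `"odd"` (weeks 1,3,5,...) or `"even"` for the
#'   drinking-day slot.
#' @param sms_limit maximum rendered message length in characters (default
#'   480, i.e. three concatenated SMS).
#' @param stop_keywords case-insensitive keywords that trigger
#'   unsubscription when received; any incoming message flagged
#'   `manual_unsubscribe` also counts (the programme accepts any request to
#'   withdraw; keyword matching is the automated proxy).
#' @return A list of class `messaging_config`.
#' @export
messaging_config <- function(weekly_day = "wed", weekly_hour = 17,
                             n_weeks = 12, biweekly_phase = c("odd", "even"),
                             sms_limit = 480,
                             stop_keywords = c("stop", "ende", "weg")) {
  assert_scalar_choice(weekly_day, WEEKDAYS, "weekly_day")
  structure(list(weekly_day = weekly_day, weekly_hour = weekly_hour,
                 n_weeks = n_weeks, biweekly_phase = match.arg(biweekly_phase),
                 sms_limit = sms_limit,
                 stop_keywords = tolower(stop_keywords)),
            class = "messaging_config")
}

# First occurrence of (weekday, hour) at or after `from` (POSIXct, UTC).
next_weekday_time <- function(from, weekday, hour) {
  target <- match(weekday, WEEKDAYS)                 # 1 = Monday
  day0 <- as.POSIXct(trunc(from, "days"), tz = "UTC")
  wd0 <- as.integer(format(day0, "%u"))              # 1 = Monday
  cand <- day0 + ((target - wd0) %% 7) * 86400 + hour * 3600
  if (cand < from) cand <- cand + 7 * 86400
  cand
}

#' Build the 12-week tailored message plan for one participant
#'
#' Weekly messages go out at a fixed configured weekday and time, one per
#' week, with categories cycling through the risk group's pool in a seeded
#' random order (no immediate repeats; every pool category appears at least
#' once over 12 weeks). Low- and high-risk participants additionally get 6
#' biweekly messages on their stated typical drinking day and time.
#'
#' @param risk_group `"NON_RISK"`, `"LOW_RISK"` or `"HIGH_RISK"`.
#' @param baseline a [program_baseline()]; must carry
#'   `typical_drinking_day`/`typical_drinking_time` unless the group is
#'   NON_RISK.
#' @param start_datetime POSIXct program start.
#' @param rng_seed integer seed; the plan is a deterministic function of
#'   (group, baseline, start, seed).
#' @param templates template bank from [read_templates()] /
#'   [default_templates()].
#' @param config a [messaging_config()].
#' @return Object of class `message_plan`: `person_id`, `risk_group`,
#'   `entries` tibble (`send_datetime`, `slot`, `category_id`,
#'   `template_id`).
#' @export
plan_messages <- function(risk_group, baseline, start_datetime, rng_seed,
                          templates = default_templates(),
                          config = messaging_config()) {
  risk_group <- as.character(risk_group)
  assert_scalar_choice(risk_group, risk_groups(), "risk_group")
  if (!inherits(start_datetime, "POSIXct"))
    start_datetime <- as.POSIXct(start_datetime, tz = "UTC")
  pool <- category_pool(risk_group)
  n_weeks <- config$n_weeks

  with_seed(rng_seed, {
    order <- sample(pool)
    cats <- rep(order, length.out = n_weeks)
    first <- next_weekday_time(start_datetime, config$weekly_day, config$weekly_hour)
    weekly <- tibble(
      send_datetime = first + (seq_len(n_weeks) - 1) * 7 * 86400,
      slot = "weekly",
      category_id = cats,
      template_id = vapply(cats, function(cid)
        pick_template(templates, "weekly", cid, risk_group), character(1))
    )

    entries <- weekly
    if (risk_group != "NON_RISK") {
      day <- baseline$typical_drinking_day
      hr <- baseline$typical_drinking_time
      if (is.na(day) || is.na(hr))
        abort_input("typical drinking day/time required for LOW_RISK and HIGH_RISK plans")
      weeks <- if (config$biweekly_phase == "odd") seq(1, n_weeks, by = 2)
               else seq(2, n_weeks, by = 2)
      sends <- vapply(weeks, function(w) {
        win <- start_datetime + (w - 1) * 7 * 86400
        as.numeric(next_weekday_time(win, day, hr))
      }, numeric(1))
      dd <- tibble(
        send_datetime = as.POSIXct(sends, origin = "1970-01-01", tz = "UTC"),
        slot = "drinking_day",
        category_id = NA_integer_,
        template_id = vapply(seq_along(sends), function(i)
          pick_template(templates, "drinking_day", NA, risk_group), character(1))
      )
      entries <- bind_rows(weekly, dd)
    }
    entries <- arrange(entries, send_datetime, slot)
    structure(list(person_id = baseline$screening$person_id,
                   risk_group = risk_group,
                   start_datetime = start_datetime,
                   entries = entries),
              class = "message_plan")
  })
}

pick_template <- function(templates, slot, category_id, risk_group) {
  ok <- vapply(templates, function(t) {
    t$slot == slot &&
      (slot == "drinking_day" || identical(t$category_id, as.integer(category_id))) &&
      risk_group %in% t$risk_groups
  }, logical(1))
  ids <- vapply(templates[ok], `[[`, character(1), "id")
  if (length(ids) == 0)
    abort_config(sprintf("no template for slot=%s category=%s group=%s",
                         slot, category_id, risk_group))
  if (length(ids) == 1) ids else sample(ids, 1)
}

#' @export
print.message_plan <- function(x, ...) {
  cat(sprintf("<message_plan> %s (%s): %d messages, %s to %s\n",
              x$person_id, x$risk_group, nrow(x$entries),
              format(min(x$entries$send_datetime)),
              format(max(x$entries$send_datetime))))
  invisible(x)
}

#' @export
as_tibble.message_plan <- function(x, ...) {
  mutate(x$entries, person_id = x$person_id, risk_group = x$risk_group,
         .before = 1)
}

#' Render a message template
#'
#' Substitutes every `{placeholder}` in the template text from
#' `tailoring_vars`. Rendering fails, naming the placeholder, if a value is
#' missing, if unresolved markers remain, or if the rendered text exceeds
#' the configured SMS length limit.
#'
#' @param template_id id of a template in `templates`.
#' @param tailoring_vars named list of placeholder values.
#' @param templates template bank.
#' @param config a [messaging_config()] (for the length limit).
#' @return Rendered message text (single string).
#' @export
render_message <- function(template_id, tailoring_vars,
                           templates = default_templates(),
                           config = messaging_config()) {
  ids <- vapply(templates, `[[`, character(1), "id")
  i <- match(template_id, ids)
  if (is.na(i)) abort_input(paste("unknown template_id:", template_id))
  text <- templates[[i]]$text
  slots <- unique(gsub("[{}]", "", regmatches(text, gregexpr("\\{[a-z_0-9]+\\}", text))[[1]]))
  missing <- setdiff(slots, names(tailoring_vars))
  if (length(missing) > 0)
    abort_input(paste("missing placeholder value(s):", paste(missing, collapse = ", ")))
  for (s in slots) {
    text <- gsub(paste0("{", s, "}"), as.character(tailoring_vars[[s]]),
                 text, fixed = TRUE)
  }
  if (grepl("\\{[a-z_0-9]+\\}", text))
    abort_input("unresolved placeholder markers remain after rendering")
  if (nchar(text) > config$sms_limit)
    abort_input(sprintf("rendered message exceeds SMS limit (%d > %d chars)",
                        nchar(text), config$sms_limit))
  text
}

#' Read a template bank from YAML
#'
#' Each entry needs `id`, `slot` (`weekly`/`drinking_day`), `category_id`
#' (1-10 for weekly templates, absent for drinking-day templates),
#' `risk_groups` (subset of [risk_groups()]) and `text` with
#' `{placeholder}` slots.
#'
#' @param path YAML file.
#' @return List of template records.
#' @export
read_templates <- function(path) {
  bank <- yaml::read_yaml(path)$templates
  lapply(bank, function(t) {
    t$category_id <- if (is.null(t$category_id)) NA_integer_ else as.integer(t$category_id)
    t$risk_groups <- as.character(t$risk_groups)
    t
  })
}

#' Built-in English template bank
#'
#' One weekly template per (category, applicable risk groups) plus
#' drinking-day strategy templates, shipped as a YAML file in the package
#' and parsed with [read_templates()].
#'
#' @return List of template records.
#' @export
default_templates <- function() {
  read_templates(system.file("extdata", "templates.yaml", package = "alcsms"))
}

#' Tailoring variables for one participant
#'
#' Collects the second-level tailoring variables the SMS content draws on:
#' gender, motivation, problems, typical drinking day/time, weekly drinks,
#' maximum drinks on one occasion and its Widmark BAC estimate.
#'
#' @param baseline a [program_baseline()].
#' @param name salutation name (participants choose a username; defaults to
#'   the person id).
#' @param config a [feedback_config()] for the BAC constants.
#' @return Named list usable as `tailoring_vars` in [render_message()].
#' @export
tailoring_vars <- function(baseline, name = NULL, config = feedback_config()) {
  scr <- baseline$screening
  wk <- weekly_drinks_total(scr$drinking_calendar)
  bac <- estimate_bac_permille(scr$max_drinks_occasion, config$grams_per_drink,
                               config$default_weight_kg[[scr$gender]],
                               config$widmark_r[[scr$gender]])
  list(name = name %||% scr$person_id,
       gender = scr$gender,
       weekly_drinks = wk,
       max_drinks = scr$max_drinks_occasion,
       bac_permille = formatC(round_half_up(bac, 2), format = "f", digits = 2),
       importance = gsub("_", " ", baseline$importance_reduce),
       drinking_day = if (is.na(baseline$typical_drinking_day)) ""
                      else baseline$typical_drinking_day)
}
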