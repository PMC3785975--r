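# One-shot tailored normative feedback.
#
# The online feedback compares a participant's drinking to the actual norms
# of an age- and gender-specific reference group (social norms approach) and
# is tailored on exactly four baseline variables: gender, age, standard
# drinks in a typical week, and 30-day RSOD frequency. Everything else in
# the baseline influences only the SMS content.

AGE_BANDS <- c("15-16", "17-18", "19-20", "21+")

#' Age band used for norm lookup
#'
#' Default bands 15-16, 17-18, 19-20, 21+ match the age structure of the
#' target population (vocational-school students).
#'
#' @param age_years integer ages (vectorised).
#' @return Character vector of band labels.
#' @export
age_band <- function(age_years) {
  ifelse(age_years >= 21, "21+",
  ifelse(age_years >= 19, "19-20",
  ifelse(age_years >= 17, "17-18", "15-16")))
}

#' Build a normative reference table
#'
#' Strata are keyed by gender and age band; each stratum carries a reference
#' sample of weekly-drinks values and counts of the three RSOD frequency
#' bands. When a stratum is missing, lookup falls back to the nearest age
#' band within the same gender (preferring the younger neighbour), then to
#' the pooled sample of the gender.
#'
#' @param strata named list: `strata[[gender]][[age_band]]` is a list with
#'   elements `weekly_drinks` (numeric vector) and `rsod_band_counts`
#'   (named vector over `NONE`, `ONE_TO_TWO`, `MORE_THAN_TWO`).
#' @return An object of class `norm_table`.
#' @export
norm_table <- function(strata) {
  for (g in names(strata)) for (b in names(strata[[g]])) {
    s <- strata[[g]][[b]]
    if (length(s$weekly_drinks) == 0)
      abort_config(sprintf("empty weekly_drinks sample in stratum (%s, %s)", g, b))
    if (sum(unlist(s$rsod_band_counts)) <= 0)
      abort_config(sprintf("empty rsod_band_counts in stratum (%s, %s)", g, b))
  }
  structure(list(strata = strata), class = "norm_table")
}

#' Read a normative reference table from YAML or JSON
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return A [norm_table()].
#' @export
read_norms <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::fromJSON(path, simplifyVector = TRUE)
  norm_table(x$strata %||% x)
}

#' Built-in synthetic normative table
#'
#' The package ships a synthetic stand-in for the age- and gender-specific
#' reference norms (the original reference survey is not publicly
#' available); see `inst/extdata/norms_synthetic.yaml`.
#'
#' @return A [norm_table()].
#' @export
default_norms <- function() {
  read_norms(system.file("extdata", "norms_synthetic.yaml", package = "alcsms"))
}

# Locate the stratum for (gender, age), applying the fallback order.
norm_stratum <- function(norms, gender, age_years) {
  bands <- AGE_BANDS
  want <- age_band(age_years)
  g <- norms$strata[[gender]]
  if (is.null(g)) abort_config(sprintf("no norms for gender '%s'", gender))
  if (!is.null(g[[want]])) return(g[[want]])
  i <- match(want, bands)
  for (off in c(-1, 1, -2, 2, -3, 3)) {     # nearest band, younger first
    j <- i + off
    if (j >= 1 && j <= length(bands) && !is.null(g[[bands[j]]]))
      return(g[[bands[j]]])
  }
  pooled <- list(
    weekly_drinks = unlist(lapply(g, `[[`, "weekly_drinks")),
    rsod_band_counts = Reduce(`+`, lapply(g, function(s) unlist(s$rsod_band_counts)))
  )
  if (length(pooled$weekly_drinks) == 0)
    abort_config(sprintf("no usable norm stratum for (%s, age %s)", gender, age_years))
  pooled
}

#' Mid-rank percentile of a value within a reference sample
#'
#' Percentile = 100 x (number of reference values strictly below + half the
#' number equal) / n. The mid-rank convention makes the percentile symmetric
#' under ties and keeps it strictly inside (0, 100) for values observed in
#' the sample.
#'
#' @param value numeric scalar.
#' @param reference_sample non-empty numeric vector.
#' @return Percentile in \[0, 100\].
#' @export
percentile_rank <- function(value, reference_sample) {
  if (length(reference_sample) == 0) abort_input("reference_sample must be non-empty")
  100 * (sum(reference_sample < value) + 0.5 * sum(reference_sample == value)) /
    length(reference_sample)
}

#' Monthly cost of drinking
#'
#' Weekly drinks are converted to a monthly amount with 52/12 weeks per
#' month and rounded half-up to 2 decimals (currency style).
#'
#' @param weekly_drinks non-negative weekly standard drinks.
#' @param price_per_drink price of one standard drink (config currency).
#' @return Monthly cost, rounded to 2 decimals.
#' @export
drinking_cost <- function(weekly_drinks, price_per_drink) {
  if (any(weekly_drinks < 0) || any(price_per_drink < 0))
    abort_input("inputs must be >= 0")
  round_half_up(weekly_drinks * price_per_drink * 52 / 12, 2)
}

#' Weekly calories from alcohol
#'
#' Pure ethanol carries about 7.1 kcal per gram; mixer calories are not
#' counted.
#'
#' @param weekly_drinks non-negative weekly standard drinks.
#' @param grams_per_drink grams of ethanol per standard drink (default 12).
#' @param kcal_per_gram kilocalories per gram of ethanol (default 7.1).
#' @return Kilocalories per week.
#' @export
weekly_calories <- function(weekly_drinks, grams_per_drink = 12,
                            kcal_per_gram = 7.1) {
  if (any(weekly_drinks < 0) || any(grams_per_drink < 0) || any(kcal_per_gram < 0))
    abort_input("inputs must be >= 0")
  weekly_drinks * grams_per_drink * kcal_per_gram
}

#' Widmark estimate of blood alcohol concentration
#'
#' BAC in per-mille (g alcohol per kg body water-adjusted mass) for a single
#' occasion: ingested alcohol mass divided by (distribution factor r x body
#' weight). No elimination term is subtracted because the estimate addresses
#' the peak of one occasion. Typical r: 0.68 for men, 0.55 for women.
#'
#' @param n_drinks drinks on the occasion (>= 0).
#' @param grams_per_drink grams of ethanol per standard drink.
#' @param body_weight_kg body weight in kg (> 0).
#' @param widmark_r Widmark distribution factor (> 0).
#' @return BAC in per-mille.
#' @export
estimate_bac_permille <- function(n_drinks, grams_per_drink = 12,
                                  body_weight_kg = 72, widmark_r = 0.68) {
  if (any(n_drinks < 0)) abort_input("n_drinks must be >= 0")
  if (any(body_weight_kg <= 0) || any(widmark_r <= 0) || any(grams_per_drink <= 0))
    abort_input("grams_per_drink, body_weight_kg and widmark_r must be > 0")
  (n_drinks * grams_per_drink) / (widmark_r * body_weight_kg)
}

#' Feedback configuration
#'
#' @param price_per_drink assumed price of one standard drink (default 5.00,
#'   config currency).
#' @param grams_per_drink grams of ethanol per standard drink (default 12).
#' @param kcal_per_gram kcal per gram of ethanol (default 7.1).
#' @param default_weight_kg named list of assumed body weights per gender,
#'   used for illustrative BAC figures when no weight is recorded.
#' @param widmark_r named list of Widmark factors per gender.
#' @return A plain list of class `feedback_config`.
#' @export
feedback_config <- function(price_per_drink = 5.00, grams_per_drink = 12,
                            kcal_per_gram = 7.1,
                            default_weight_kg = list(male = 72, female = 60),
                            widmark_r = list(male = 0.68, female = 0.55)) {
  structure(list(price_per_drink = price_per_drink,
                 grams_per_drink = grams_per_drink,
                 kcal_per_gram = kcal_per_gram,
                 default_weight_kg = default_weight_kg,
                 widmark_r = widmark_r),
            class = "feedback_config")
}

#' Build the tailored normative feedback report
#'
#' A pure function of (baseline, norms, config). The report has exactly four
#' sections, in fixed order: (1) weekly drinks relative to the age- and
#' gender-specific reference group, (2) financial cost of drinking, (3)
#' calories consumed with alcohol, and (4) heavy-drinking occasions relative
#' to the reference group.
#'
#' @param baseline a [program_baseline()].
#' @param norms a [norm_table()].
#' @param config a [feedback_config()].
#' @return An object of class `feedback_report`: fields `drinks_week`,
#'   `percentile_vs_norm`, `monthly_cost`, `weekly_kcal`, `rsod_band`,
#'   `rsod_percentile`, `section_texts` (length 4).
#' @export
build_feedback <- function(baseline, norms, config = feedback_config()) {
  if (!inherits(baseline, "program_baseline"))
    abort_input("baseline must be a program_baseline")
  scr <- baseline$screening
  drinks_week <- weekly_drinks_total(scr$drinking_calendar)
  stratum <- norm_stratum(norms, scr$gender, scr$age_years)
  pct <- percentile_rank(drinks_week, stratum$weekly_drinks)

  band <- as.character(map_rsod_band(scr$rsod_category))
  counts <- unlist(stratum$rsod_band_counts)[rsod_bands()]
  counts[is.na(counts)] <- 0
  # percentile of the band within the reference band distribution (mid-rank
  # over band indices, weighting each reference person by their band)
  idx <- match(band, rsod_bands())
  rsod_pct <- 100 * (sum(counts[seq_len(idx - 1)]) + 0.5 * counts[idx]) / sum(counts)

  cost <- drinking_cost(drinks_week, config$price_per_drink)
  kcal <- weekly_calories(drinks_week, config$grams_per_drink, config$kcal_per_gram)

  band_text <- c(NONE = "no occasion", ONE_TO_TWO = "1-2 occasions",
                 MORE_THAN_TWO = "more than 2 occasions")[band]
  sections <- c(
    sprintf(paste0("In a typical week you drink %d standard drinks. ",
                   "You drink more than %s%% of %ss of your age."),
            drinks_week, formatC(round_half_up(pct, 1), format = "f", digits = 1),
            scr$gender),
    sprintf("At %.2f per drink, your drinking costs about %.2f per month.",
            config$price_per_drink, cost),
    sprintf("Your weekly drinking adds about %d kcal to your diet.",
            as.integer(round_half_up(kcal, 0))),
    sprintf(paste0("In the last 30 days you had %s with %d or more drinks. ",
                   "That places you above %s%% of %ss of your age."),
            band_text, risk_thresholds()$rsod_min_drinks[[scr$gender]],
            formatC(round_half_up(rsod_pct, 1), format = "f", digits = 1),
            scr$gender)
  )
  structure(list(
    person_id = scr$person_id,
    drinks_week = drinks_week,
    percentile_vs_norm = unname(pct),
    monthly_cost = cost,
    weekly_kcal = kcal,
    rsod_band = band,
    rsod_percentile = unname(rsod_pct),
    section_texts = sections
  ), class = "feedback_report")
}

#' Serialise a feedback report
#'
#' @param report a [build_feedback()] result.
#' @return JSON string (`feedback_to_json`) or a single plain-text string
#'   with the four numbered sections (`format.feedback_report`).
#' @export
feedback_to_json <- function(report) {
  jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA)
}

#' @export
format.feedback_report <- function(x, ...) {
  paste0(sprintf("(%d) %s", 1:4, x$section_texts), collapse = "\n")
}

#' @export
print.feedback_report <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
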