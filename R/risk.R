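# Three-tier drinking risk classification.
#
# Two indicators of problem drinking drive everything downstream:
#  (1) volume: a daily average of >= 30 g pure alcohol for men, >= 20 g for
#      women; with weekly instruments this corresponds to the 18 / 12
#      standard-drinks-per-week cutoffs used by the classifier;
#  (2) risky single-occasion drinking (RSOD, "binge drinking"): >= 5 drinks
#      on one occasion for men, >= 4 for women.

#' Risk classification thresholds
#'
#' @param rsod_min_drinks named list, minimum drinks on one occasion that
#'   constitute RSOD, per gender.
#' @param weekly_drinks_cutoff named list, weekly standard-drink cutoff per
#'   gender; a typical week at or above the cutoff rules out the non-risk
#'   tier.
#' @param daily_grams_cutoff named list, grams of pure alcohol per day that
#'   define volume problem drinking.
#' @param grams_per_standard_drink grams of ethanol in one standard drink.
#'   Swiss convention ranges 10-12 g; the default is 12 g.
#' @return An object of class `risk_thresholds`.
#' @export
risk_thresholds <- function(rsod_min_drinks = list(male = 5, female = 4),
                            weekly_drinks_cutoff = list(male = 18, female = 12),
                            daily_grams_cutoff = list(male = 30, female = 20),
                            grams_per_standard_drink = 12) {
  for (pair in list(rsod_min_drinks, weekly_drinks_cutoff, daily_grams_cutoff)) {
    if (any(unlist(pair) <= 0)) abort_config("thresholds must be strictly positive")
    if (pair$male < pair$female)
      abort_config("male threshold must be >= female threshold")
  }
  if (grams_per_standard_drink <= 0)
    abort_config("grams_per_standard_drink must be positive")
  structure(list(rsod_min_drinks = rsod_min_drinks,
                 weekly_drinks_cutoff = weekly_drinks_cutoff,
                 daily_grams_cutoff = daily_grams_cutoff,
                 grams_per_standard_drink = grams_per_standard_drink),
            class = "risk_thresholds")
}

#' The three risk tiers, in increasing order of risk
#' @return `c("NON_RISK", "LOW_RISK", "HIGH_RISK")`.
#' @export
risk_groups <- function() c("NON_RISK", "LOW_RISK", "HIGH_RISK")

#' Is a drinking occasion a risky single occasion (RSOD)?
#'
#' @param drinks non-negative number of standard drinks on the occasion
#'   (vectorised).
#' @param gender `"male"` or `"female"` (recycled).
#' @param thresholds a [risk_thresholds()] object.
#' @return Logical vector: TRUE iff drinks >= 5 (men) / 4 (women).
#' @export
is_rsod_occasion <- function(drinks, gender, thresholds = risk_thresholds()) {
  if (any(is.na(drinks)) || any(drinks < 0)) abort_input("drinks must be >= 0")
  if (!all(gender %in% GENDERS)) abort_input("gender must be 'male' or 'female'")
  drinks >= unlist(thresholds$rsod_min_drinks)[gender]
}

#' Assign the drinking risk group
#'
#' Tiers are defined from the 30-day RSOD frequency band and the typical
#' weekly volume:
#' \describe{
#'   \item{NON_RISK}{no RSOD occasion and fewer than 18 (men) / 12 (women)
#'     standard drinks in a typical week;}
#'   \item{LOW_RISK}{1-2 RSOD occasions, or no RSOD occasions with weekly
#'     drinks at or above the cutoff;}
#'   \item{HIGH_RISK}{more than 2 RSOD occasions.}
#' }
#' The rules are exhaustive and mutually exclusive; the RSOD band alone
#' decides HIGH_RISK regardless of volume, because the instrument is
#' categorical.
#'
#' @param gender `"male"` or `"female"` (vectorised, recycled).
#' @param rsod_band band from [map_rsod_band()] (`"NONE"`, `"ONE_TO_TWO"`,
#'   `"MORE_THAN_TWO"`).
#' @param weekly_drinks non-negative weekly standard drinks.
#' @param thresholds a [risk_thresholds()] object.
#' @return Factor with levels [risk_groups()].
#' @export
classify_risk <- function(gender, rsod_band, weekly_drinks,
                          thresholds = risk_thresholds()) {
  rsod_band <- as.character(rsod_band)
  if (!all(gender %in% GENDERS)) abort_input("gender must be 'male' or 'female'")
  if (!all(rsod_band %in% rsod_bands()))
    abort_input("rsod_band must be NONE, ONE_TO_TWO or MORE_THAN_TWO")
  if (any(is.na(weekly_drinks)) || any(weekly_drinks < 0))
    abort_input("weekly_drinks must be >= 0")
  cutoff <- unlist(thresholds$weekly_drinks_cutoff)[gender]
  group <- ifelse(rsod_band == "MORE_THAN_TWO", "HIGH_RISK",
           ifelse(rsod_band == "NONE" & weekly_drinks < cutoff,
                  "NON_RISK", "LOW_RISK"))
  factor(group, levels = risk_groups())
}

#' Volume indicator of problem drinking
#'
#' TRUE iff the typical weekly consumption corresponds to a daily average of
#' 30 g (men) / 20 g (women) or more of pure alcohol.
#'
#' @inheritParams classify_risk
#' @return Logical vector.
#' @export
volume_problem_drinking <- function(gender, weekly_drinks,
                                    thresholds = risk_thresholds()) {
  if (any(weekly_drinks < 0)) abort_input("weekly_drinks must be >= 0")
  daily_g <- weekly_drinks * thresholds$grams_per_standard_drink / 7
  daily_g >= unlist(thresholds$daily_grams_cutoff)[gender]
}

#' Classify every record of a screening table
#'
#' Convenience wrapper used by the command-line `classify` subcommand:
#' derives the weekly total and RSOD band from the raw items and appends a
#' `risk_group` column.
#'
#' @param df screening tibble (see [read_screening_csv()]).
#' @param thresholds a [risk_thresholds()] object.
#' @return `df` with `weekly_drinks`, `rsod_band` and `risk_group` appended.
#' @export
classify_records <- function(df, thresholds = risk_thresholds()) {
  cal <- as.matrix(df[CALENDAR_COLS])
  df$weekly_drinks <- as.integer(rowSums(cal))
  df$rsod_band <- map_rsod_band(df$rsod_category)
  df$risk_group <- classify_risk(df$gender, df$rsod_band, df$weekly_drinks,
                                 thresholds)
  df
}
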