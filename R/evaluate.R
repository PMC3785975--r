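# Outcome evaluation: five pre-post GEE models.

OUTCOME_NAMES <- c("rsod_any", "rsod_frequent", "weekly_drinks", "max_drinks",
                   "any_problem")

#' Long-format outcome data for a simulated study
#'
#' Stacks baseline and follow-up measurements of program participants for
#' the five outcome criteria: any RSOD in the last 30 days, frequent RSOD
#' (more than 2 occasions), weekly standard drinks, maximum drinks on an
#' occasion, and any alcohol-related problem. All available data enter: a
#' participant missing at follow-up (or missing a single item) still
#' contributes the rows they have.
#'
#' @param study a [simulate_cohort()] result.
#' @return Tibble with columns `outcome`, `person_id`, `class_id`, `time`,
#'   `value`, `available`.
#' @export
study_outcomes_long <- function(study) {
  scr <- study$screening
  part <- scr[scr$person_id %in% study$registrations, ]
  fu <- study$followup[study$followup$participant, ]
  bp <- study$baseline_program
  cls <- setNames(scr$class_id, scr$person_id)

  base_vals <- list(
    rsod_any = as.numeric(as.character(part$rsod_band) != "NONE"),
    rsod_frequent = as.numeric(as.character(part$rsod_band) == "MORE_THAN_TWO"),
    weekly_drinks = part$weekly_drinks,
    max_drinks = part$max_drinks_occasion,
    any_problem = as.numeric(bp$any_problem[match(part$person_id, bp$person_id)])
  )
  fu_band <- map_rsod_band(ifelse(is.na(fu$rsod_category), "never",
                                  fu$rsod_category))
  fu_band[is.na(fu$rsod_category)] <- NA
  fu_vals <- list(
    rsod_any = as.numeric(as.character(fu_band) != "NONE"),
    rsod_frequent = as.numeric(as.character(fu_band) == "MORE_THAN_TWO"),
    weekly_drinks = fu$weekly_drinks,
    max_drinks = fu$max_drinks_occasion,
    any_problem = as.numeric(fu$any_problem)
  )
  bind_rows(lapply(OUTCOME_NAMES, function(o) {
    bind_rows(
      tibble(outcome = o, person_id = part$person_id,
             class_id = unname(cls[part$person_id]), time = "baseline",
             value = as.numeric(base_vals[[o]])),
      tibble(outcome = o, person_id = fu$person_id,
             class_id = unname(cls[fu$person_id]), time = "followup",
             value = as.numeric(fu_vals[[o]]))
    )
  })) %>% mutate(available = !is.na(value))
}

#' Fit the five pre-post outcome models
#'
#' Logistic GEE for the three binary outcomes (reported as odds ratios) and
#' Poisson log-link GEE for the two counts (reported as incidence rate
#' ratios), all with cluster-robust variance over school classes and using
#' all available records.
#'
#' @param long_data a tibble in the layout of [study_outcomes_long()] (or a
#'   `simulated_study`, which is converted first).
#' @param cluster_by `"class"` or `"person"`.
#' @return Tibble with one row per outcome: `outcome`, `effect_type`,
#'   `estimate`, `conf_low`, `conf_high`, `p_value`, `n_persons`, `n_obs`,
#'   `converged`, and a `fit` list-column of [gee_fit()] results.
#' @export
evaluate_outcomes <- function(long_data, cluster_by = "class") {
  if (inherits(long_data, "simulated_study"))
    long_data <- study_outcomes_long(long_data)
  families <- c(rsod_any = "binomial", rsod_frequent = "binomial",
                weekly_drinks = "poisson", max_drinks = "poisson",
                any_problem = "binomial")
  outcomes <- intersect(OUTCOME_NAMES, unique(long_data$outcome))
  rows <- lapply(outcomes, function(o) {
    d <- long_data[long_data$outcome == o, ]
    fit <- gee_fit(d, family = families[[o]], cluster_by = cluster_by)
    tibble(outcome = o, effect_type = fit$effect_type,
           estimate = fit$effect, conf_low = fit$conf_int[1],
           conf_high = fit$conf_int[2], p_value = fit$p_value,
           n_persons = fit$n_persons, n_obs = fit$n_obs,
           converged = fit$converged, fit = list(fit))
  })
  bind_rows(rows)
}
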