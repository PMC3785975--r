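# Synthetic cohort simulator.
#
# Emulates the study conditions end to end: a screened vocational-school
# cohort (36 classes, ~490 students) with the reported demographic, smoking
# and drinking marginals; phone ownership as the eligibility criterion; a
# participation model favouring lower education and higher maximum drinks;
# an unsubscription model favouring smokers and frequent RSOD; follow-up
# attendance; and configurable pre-post effects (odds ratios for the binary
# outcomes, rate ratios for the counts) with within-person correlation.
# Class membership enters drinking through a shared random intercept, which
# induces the intra-class correlation that motivates the cluster-robust
# variance in the evaluation.

#' Simulation configuration
#'
#' Defaults encode the screened cohort the package's evaluation pipeline is
#' designed for: 490 students present in 36 school classes, 488 consenting,
#' 477 mobile-phone owners; the participant column of the baseline
#' characteristics table for the categorical marginals; weekly drinks with
#' mean 14.1 / SD 16.1 and maximum drinks with mean 11.6 / SD 10.8
#' (zero-inflated negative binomial, moments matched); participation
#' 364/477, unsubscription 23/364 and follow-up 367/477 as the marginal
#' rates implied by the default model intercepts; and pre-post effects
#' OR 0.66 (any RSOD), OR 0.76 (frequent RSOD), IRR 0.83 (weekly drinks),
#' IRR 0.91 (max drinks), OR 0.60 (problems).
#'
#' @param seed integer RNG seed (mandatory; the simulation is a
#'   deterministic function of the config).
#' @param n_present,n_consenting,n_phone_owners,n_classes cohort sizes.
#' @param p_female probability of female gender.
#' @param age_band_probs,migration_probs,education_probs,smoking_probs,
#'   rsod_probs,importance_probs categorical marginals (each must sum to 1
#'   after normalisation; names fixed by the instruments).
#' @param activity_mean,activity_sd weekly activity hours (gamma).
#' @param weekly_mean,weekly_sd,weekly_pi0 weekly-drinks ZINB targets.
#' @param max_mean,max_sd,max_pi0 max-drinks ZINB targets.
#' @param icc intra-class correlation of the latent drinking propensity.
#' @param weekly_latent_cor,max_latent_cor copula correlations linking the
#'   RSOD latent, weekly drinks and max drinks within a person.
#' @param participation_coef named vector `(intercept, low_education,
#'   max_drinks)` of the logistic participation model.
#' @param attrition_coef named vector `(intercept, smoker, rsod_band)` of
#'   the logistic unsubscription model.
#' @param followup_coef named vector `(intercept, smoker, rsod_band)` of
#'   the logistic follow-up attendance model (negative slopes: dropouts are
#'   more often smokers and frequent RSOD).
#' @param p_problem_item per-item probability of endorsing a problem
#'   (10 items; 0.0245 gives about 22% with any problem).
#' @param effect named list of pre-post effects: `or_rsod`, `or_frequent`,
#'   `irr_weekly`, `irr_max`, `or_problems`; applied to program
#'   participants only (nonparticipants stay at the null).
#' @param concordance within-person pre-post concordance of the binary
#'   problem outcome (0 = independent transitions, 1 = maximal).
#' @param prepost_rho Gaussian-copula correlation between baseline and
#'   follow-up latents for RSOD and the counts.
#' @param followup_missing named list of per-item missingness probabilities
#'   at follow-up (`rsod`, `weekly`, `max`, `problems`); the defaults
#'   reproduce per-outcome complete-case denominators a few persons below
#'   the number of attenders.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_present = 490, n_consenting = 488,
                       n_phone_owners = 477, n_classes = 36,
                       p_female = 0.245,
                       age_band_probs = c("15-16" = 0.201, "17-18" = 0.533,
                                          "19-20" = 0.198, "21+" = 0.069),
                       migration_probs = c(none = 0.508, one_parent = 0.190,
                                           both_parents = 0.302),
                       education_probs = c(none = 0.049, secondary = 0.824,
                                           extended_secondary = 0.107,
                                           technical_or_high = 0.019),
                       smoking_probs = c(daily = 0.35, occasional = 0.18,
                                         former = 0.12, never = 0.35),
                       rsod_probs = c("never" = 0.234, "1-2" = 0.291,
                                      "3-4" = 0.195, "5-6" = 0.132,
                                      "7-8" = 0.055, "9-10" = 0.038,
                                      "11-12" = 0.016, ">12" = 0.038),
                       importance_probs = c(very_unimportant = 0.451,
                                            rather_unimportant = 0.332,
                                            rather_important = 0.132,
                                            very_important = 0.085),
                       activity_mean = 4.5, activity_sd = 4.6,
                       weekly_mean = 14.1, weekly_sd = 16.1, weekly_pi0 = 0.15,
                       max_mean = 11.6, max_sd = 10.8, max_pi0 = 0.10,
                       icc = 0.05,
                       weekly_latent_cor = 0.6, max_latent_cor = 0.7,
                       participation_coef = c(intercept = 0.39,
                                              low_education = 0.5,
                                              max_drinks = 0.03),
                       attrition_coef = c(intercept = -3.22, smoker = 0.4,
                                          rsod_band = 0.25),
                       followup_coef = c(intercept = 1.69, smoker = -0.45,
                                         rsod_band = -0.20),
                       p_problem_item = 0.0245,
                       effect = list(or_rsod = 0.66, or_frequent = 0.76,
                                     irr_weekly = 0.83, irr_max = 0.91,
                                     or_problems = 0.60),
                       concordance = 0.5, prepost_rho = 0.5,
                       followup_missing = list(rsod = 0.007, weekly = 0.118,
                                               max = 0.018, problems = 0.0)) {
  if (missing(seed)) abort_config("seed is mandatory")
  for (p in list(age_band_probs, migration_probs, education_probs,
                 smoking_probs, rsod_probs, importance_probs)) {
    if (any(p < 0) || abs(sum(p) - 1) > 0.02)
      abort_config("marginal probabilities must be non-negative and sum to 1")
  }
  norm1 <- function(p) p / sum(p)
  structure(list(
    seed = as.integer(seed), n_present = n_present,
    n_consenting = n_consenting, n_phone_owners = n_phone_owners,
    n_classes = n_classes, p_female = p_female,
    age_band_probs = norm1(age_band_probs),
    migration_probs = norm1(migration_probs),
    education_probs = norm1(education_probs),
    smoking_probs = norm1(smoking_probs),
    rsod_probs = norm1(rsod_probs),
    importance_probs = norm1(importance_probs),
    activity_mean = activity_mean, activity_sd = activity_sd,
    weekly_par = zinb_moments(weekly_mean, weekly_sd, weekly_pi0),
    max_par = zinb_moments(max_mean, max_sd, max_pi0),
    icc = icc, weekly_latent_cor = weekly_latent_cor,
    max_latent_cor = max_latent_cor,
    participation_coef = participation_coef,
    attrition_coef = attrition_coef, followup_coef = followup_coef,
    p_problem_item = p_problem_item, effect = effect,
    concordance = concordance, prepost_rho = prepost_rho,
    followup_missing = followup_missing
  ), class = "sim_config")
}

plogis_ <- function(x) 1 / (1 + exp(-x))

#' Pre-post transition of a binary outcome with a target odds ratio
#'
#' Solves the follow-up prevalence `p2` from `odds(p2) = OR x odds(p1)`
#' (with `p1` the baseline prevalence of the supplied vector) and draws each
#' person's follow-up value from a transition matrix interpolating between
#' independence (`concordance = 0`) and maximal positive dependence
#' (`concordance = 1`): `P(follow = 1 | base = 1)` moves from `p2` to
#' `min(p2/p1, 1)`.
#'
#' @param baseline logical/0-1 vector of baseline values.
#' @param or target pre-post odds ratio (`or = 0` empties the outcome).
#' @param concordance within-person concordance in \[0, 1\].
#' @return Logical vector of follow-up values (same length).
#' @export
transition_binary <- function(baseline, or, concordance = 0.5) {
  b <- as.logical(baseline)
  p1 <- mean(b)
  p2 <- if (or == 0) 0
        else if (p1 %in% c(0, 1)) p1   # degenerate baseline: odds undefined
        else plogis_(log(or) + log(p1 / (1 - p1)))
  transition_to(b, p2, concordance)
}

# Transition to a target follow-up prevalence p2 with the concordance
# interpolation of transition_binary().
transition_to <- function(b, p2, concordance) {
  p1 <- mean(b)
  if (p1 %in% c(0, 1)) return(runif(length(b)) < p2)
  p11 <- (1 - concordance) * p2 + concordance * min(p2 / p1, 1)
  p01 <- (p2 - p1 * p11) / (1 - p1)
  p01 <- min(max(p01, 0), 1)
  runif(length(b)) < ifelse(b, p11, p01)
}

#' Pre-post shift of a ZINB count with a target rate ratio
#'
#' Maps each baseline count to its mid-CDF Gaussian latent, correlates a
#' follow-up latent with it (`rho`), and reads the follow-up count off a
#' ZINB whose NB mean is scaled by `rr` (same size and zero inflation), so
#' the marginal mean ratio equals `rr` while within-person rank correlation
#' is preserved.
#'
#' @param baseline integer counts.
#' @param par baseline ZINB parameters ([zinb_moments()]).
#' @param rr target rate ratio (follow-up mean / baseline mean).
#' @param rho within-person latent correlation.
#' @return Integer vector of follow-up counts.
#' @export
shift_count <- function(baseline, par, rr, rho = 0.5) {
  z <- zinb_latent(baseline, par)
  zf <- rho * z + sqrt(1 - rho^2) * rnorm(length(baseline))
  par2 <- list(pi0 = par$pi0, mu = par$mu * rr, size = par$size)
  as.integer(qzinb(pnorm(zf), par2))
}

# Spread a weekly total over 7 days, weighting the weekend.
spread_calendar <- function(total) {
  w <- c(0.05, 0.05, 0.08, 0.10, 0.22, 0.30, 0.20)
  if (total == 0) return(integer(7))
  as.integer(stats::rmultinom(1, total, w))
}

band_index <- function(band) match(as.character(band), rsod_bands()) - 1L

#' Simulate a full study cohort
#'
#' Generates screening records, eligibility, participation, program
#' baseline, unsubscription events (as an SMS log), follow-up attendance and
#' follow-up outcomes under the configured pre-post effects. Reproducible:
#' the same config (including its seed) yields the identical study.
#'
#' @param config a [sim_config()].
#' @return Object of class `simulated_study` with components `screening`
#'   (tibble, one row per consenting student, including derived
#'   `weekly_drinks`, `rsod_band`, `risk_group`), `n_present`,
#'   `registrations` (ids of program participants), `log` (an [sms_log()]
#'   carrying the unsubscription events), `followup` (tibble of follow-up
#'   attenders with item-level missingness), `baseline_program` (problem
#'   items etc. for participants), and `truth` (the effect parameters
#'   used).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) abort_config("config must be a sim_config")
  with_seed(config$seed, {
    n <- config$n_consenting
    ids <- sprintf("s%04d", seq_len(n))
    class_ids <- sprintf("c%02d", rep_len(seq_len(config$n_classes), n))
    class_eff <- rnorm(config$n_classes)

    gender <- ifelse(runif(n) < config$p_female, "female", "male")
    band_lab <- sample(names(config$age_band_probs), n, TRUE,
                       config$age_band_probs)
    age <- vapply(band_lab, function(b) switch(b,
      "15-16" = sample(15:16, 1), "17-18" = sample(17:18, 1),
      "19-20" = sample(19:20, 1), "21+" = sample(21:25, 1)), 0L)
    migration <- sample(names(config$migration_probs), n, TRUE,
                        config$migration_probs)
    education <- sample(names(config$education_probs), n, TRUE,
                        config$education_probs)
    smoking <- sample(names(config$smoking_probs), n, TRUE,
                      config$smoking_probs)
    activity <- round(rgamma(n, shape = (config$activity_mean / config$activity_sd)^2,
                             scale = config$activity_sd^2 / config$activity_mean), 1)

    # latent drinking propensity with class random intercept (induces the ICC)
    u <- sqrt(config$icc) * class_eff[as.integer(factor(class_ids))] +
         sqrt(1 - config$icc) * rnorm(n)
    cum_rsod <- cumsum(config$rsod_probs)
    rsod_cat <- rsod_categories()[findInterval(pnorm(u), c(0, cum_rsod),
                                               rightmost.closed = TRUE)]
    rho_w <- config$weekly_latent_cor
    v <- rho_w * u + sqrt(1 - rho_w^2) * rnorm(n)
    weekly <- as.integer(qzinb(pnorm(v), config$weekly_par))
    rho_m <- config$max_latent_cor
    m <- rho_m * v + sqrt(1 - rho_m^2) * rnorm(n)
    max_drinks <- as.integer(qzinb(pnorm(m), config$max_par))

    calendar <- t(vapply(weekly, spread_calendar, integer(7)))
    colnames(calendar) <- CALENDAR_COLS

    owns <- rep(FALSE, n)
    owns[sample.int(n, config$n_phone_owners)] <- TRUE

    screening <- as_tibble(cbind(
      tibble(person_id = ids, class_id = class_ids, gender = gender,
             age_years = as.integer(age), education = education,
             migration = migration, smoking_item = smoking,
             activity_hours_week = activity, rsod_category = rsod_cat),
      as_tibble(calendar),
      tibble(max_drinks_occasion = max_drinks, owns_mobile = owns)))
    screening <- classify_records(screening)

    # participation among phone owners
    low_edu <- screening$education %in% c("none", "secondary")
    cf <- config$participation_coef
    p_part <- plogis_(cf["intercept"] + cf["low_education"] * low_edu +
                        cf["max_drinks"] * screening$max_drinks_occasion)
    registered <- screening$owns_mobile & runif(n) < p_part
    reg_ids <- ids[registered]

    # program baseline for participants
    smoker <- derive_smoker(screening$smoking_item)
    n_reg <- sum(registered)
    problems <- matrix(runif(n_reg * 10) < config$p_problem_item, n_reg, 10,
                       dimnames = list(NULL, PROBLEM_COLS))
    baseline_program <- as_tibble(cbind(
      tibble(person_id = reg_ids),
      as_tibble(problems),
      tibble(any_problem = rowSums(problems) > 0,
             importance_reduce = sample(names(config$importance_probs), n_reg,
                                        TRUE, config$importance_probs),
             typical_drinking_day = sample(c("fri", "sat", "thu", "wed"), n_reg,
                                           TRUE, c(0.45, 0.35, 0.12, 0.08)),
             typical_drinking_time = sample(18:22, n_reg, TRUE))))

    # unsubscription (program attrition): smokers and frequent RSOD drop out more
    ac <- config$attrition_coef
    bidx <- band_index(screening$rsod_band)
    p_unsub <- plogis_(ac["intercept"] + ac["smoker"] * smoker +
                         ac["rsod_band"] * bidx)
    unsub <- registered & runif(n) < p_unsub
    log <- sms_log()
    t0 <- as.POSIXct("2012-05-01 08:00:00", tz = "UTC")
    for (i in which(unsub)) {
      log <- apply_incoming(log, sms_event(
        t0 + round(runif(1, 1, 83)) * 86400 + i, "in", ids[i], "STOP"))
    }

    # follow-up attendance (all eligible students are re-invited in class)
    fc <- config$followup_coef
    p_fu <- plogis_(fc["intercept"] + fc["smoker"] * smoker +
                      fc["rsod_band"] * bidx)
    attended <- screening$owns_mobile & runif(n) < p_fu

    # follow-up outcomes: configured effects for participants, null otherwise
    eff <- config$effect
    fu <- followup_outcomes(screening, baseline_program, registered, attended,
                            config, eff)

    structure(list(
      screening = screening, n_present = config$n_present,
      registrations = reg_ids, log = log,
      baseline_program = baseline_program,
      followup = fu, truth = eff, config = config
    ), class = "simulated_study")
  })
}

followup_outcomes <- function(screening, baseline_program, registered,
                              attended, config, eff) {
  idx <- which(attended)
  part <- registered[idx]
  n_fu <- length(idx)
  scr <- screening[idx, ]
  rho <- config$prepost_rho
  conc <- config$concordance

  base_any <- as.character(scr$rsod_band) != "NONE"
  base_freq <- as.character(scr$rsod_band) == "MORE_THAN_TWO"

  # follow-up RSOD band: the two nested binaries (any RSOD, frequent RSOD)
  # transition hierarchically -- any RSOD first with its odds ratio, then
  # frequent among the positives at the conditional target p2f/p2a -- so
  # both marginals hit their odds-ratio-implied targets in expectation and
  # a person can never be frequent without being positive
  follow_band <- function(sub, or_any, or_freq) {
    nn <- sum(sub)
    if (nn == 0) return(character(0))
    p1a <- mean(base_any[sub]); p1f <- mean(base_freq[sub])
    p2a <- plogis_(log(or_any) + log(p1a / (1 - p1a)))
    p2f <- plogis_(log(or_freq) + log(p1f / (1 - p1f)))
    fa <- transition_to(base_any[sub], p2a, conc)
    out <- rep("NONE", nn)
    pos <- which(fa)
    if (length(pos) > 0) {
      ff <- transition_to(base_freq[sub][pos], min(p2f / p2a, 1), conc)
      out[pos] <- ifelse(ff, "MORE_THAN_TWO", "ONE_TO_TWO")
    }
    out
  }
  band_fu <- character(n_fu)
  band_fu[part] <- follow_band(part, eff$or_rsod, eff$or_frequent)
  band_fu[!part] <- follow_band(!part, 1, 1)

  # map the band back to an 8-level category, re-using the baseline
  # conditional distribution of the frequent categories
  hi_cats <- rsod_categories()[3:8]
  hi_probs <- config$rsod_probs[3:8] / sum(config$rsod_probs[3:8])
  cat_fu <- ifelse(band_fu == "NONE", "never",
            ifelse(band_fu == "ONE_TO_TWO", "1-2", NA))
  n_hi <- sum(is.na(cat_fu))
  if (n_hi > 0) cat_fu[is.na(cat_fu)] <- sample(hi_cats, n_hi, TRUE, hi_probs)

  weekly_fu <- integer(n_fu)
  max_fu <- integer(n_fu)
  weekly_fu[part] <- shift_count(scr$weekly_drinks[part], config$weekly_par,
                                 eff$irr_weekly, rho)
  weekly_fu[!part] <- shift_count(scr$weekly_drinks[!part], config$weekly_par,
                                  1, rho)
  max_fu[part] <- shift_count(scr$max_drinks_occasion[part], config$max_par,
                              eff$irr_max, rho)
  max_fu[!part] <- shift_count(scr$max_drinks_occasion[!part], config$max_par,
                               1, rho)

  # problems: only assessed in the program, so only participants carry them
  prob_fu <- rep(NA, n_fu)
  bp <- baseline_program[match(scr$person_id, baseline_program$person_id), ]
  has_base_prob <- !is.na(bp$any_problem)
  prob_fu[part & has_base_prob] <- transition_binary(
    bp$any_problem[part & has_base_prob], eff$or_problems, config$concordance)

  miss <- config$followup_missing
  mask <- function(x, p) { x[runif(length(x)) < p] <- NA; x }
  tibble(person_id = scr$person_id,
         participant = part,
         rsod_category = mask(cat_fu, miss$rsod),
         weekly_drinks = mask(weekly_fu, miss$weekly),
         max_drinks_occasion = mask(max_fu, miss$max),
         any_problem = mask(prob_fu, miss$problems))
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(paste0("<simulated_study> %d present, %d screened, %d eligible, ",
                     "%d registered, %d unsubscribed, %d followed up\n"),
              x$n_present, nrow(x$screening), sum(x$screening$owns_mobile),
              length(x$registrations), length(x$log$unsubscribed_at),
              nrow(x$followup)))
  invisible(x)
}
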