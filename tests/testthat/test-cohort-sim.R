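small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_present = 62, n_consenting = 60,
             n_phone_owners = 57, n_classes = 6, ...)
}

test_that("ZINB parameters recover the target moments", {
  for (tgt in list(c(14.1, 16.1, 0.15), c(11.6, 10.8, 0.10))) {
    par <- zinb_moments(tgt[1], tgt[2], tgt[3])
    x <- 0:2000
    pmf <- diff(c(0, pzinb(x, par)))
    m <- sum(x * pmf)
    v <- sum(x^2 * pmf) - m^2
    expect_equal(m, tgt[1], tolerance = 1e-6)
    expect_equal(sqrt(v), tgt[2], tolerance = 1e-6)
  }
  expect_error(zinb_moments(10, 2, 0.1), class = "alcsms_config_error")
})

test_that("the same config and seed reproduce the identical study", {
  s1 <- simulate_cohort(small_cfg(seed = 17))
  s2 <- simulate_cohort(small_cfg(seed = 17))
  expect_identical(s1$screening, s2$screening)
  expect_identical(s1$followup, s2$followup)
  expect_identical(s1$registrations, s2$registrations)
  s3 <- simulate_cohort(small_cfg(seed = 18))
  expect_false(identical(s1$screening, s3$screening))
})

test_that("every simulated screening record passes validation", {
  study <- simulate_cohort(small_cfg(seed = 2))
  recs <- alcsms:::screening_from_df(study$screening)
  expect_true(all(vapply(recs, function(r) nrow(validate_screening(r)) == 0L,
                         TRUE)))
  # class sizes are roughly n/n_classes
  sizes <- table(study$screening$class_id)
  expect_true(all(sizes %in% c(10, 10)))
})

test_that("degenerate processes behave as configured: everyone participates,
           nobody unsubscribes, everyone attends follow-up", {
  cfg <- small_cfg(seed = 4,
                   participation_coef = c(intercept = 50, low_education = 0,
                                          max_drinks = 0),
                   attrition_coef = c(intercept = -50, smoker = 0,
                                      rsod_band = 0),
                   followup_coef = c(intercept = 50, smoker = 0,
                                     rsod_band = 0))
  study <- simulate_cohort(cfg)
  owners <- study$screening$person_id[study$screening$owns_mobile]
  expect_setequal(study$registrations, owners)
  expect_length(study$log$unsubscribed_at, 0)
  expect_setequal(study$followup$person_id, owners)
})

test_that("simulated marginals match the configured cohort profile", {
  # class size ~14 as in the emulated cohort, so the class random intercept
  # contributes its realistic (small) design effect to the Monte-Carlo error
  cfg <- sim_config(seed = 10, n_present = 10000, n_consenting = 10000,
                    n_phone_owners = 9770, n_classes = 720,
                    followup_missing = list(rsod = 0, weekly = 0, max = 0,
                                            problems = 0))
  study <- simulate_cohort(cfg)
  scr <- study$screening
  expect_equal(mean(scr$gender == "female"), 0.245, tolerance = 0.05)
  got_rsod <- as.numeric(table(factor(scr$rsod_category,
                                      levels = rsod_categories())) / nrow(scr))
  expect_true(all(abs(got_rsod - unname(cfg$rsod_probs)) < 0.015))
  expect_equal(mean(scr$weekly_drinks), 14.1, tolerance = 0.05)
  expect_equal(sd(scr$weekly_drinks), 16.1, tolerance = 0.08)
  expect_equal(mean(scr$max_drinks_occasion), 11.6, tolerance = 0.05)
  expect_equal(sd(scr$max_drinks_occasion), 10.8, tolerance = 0.08)
  expect_equal(mean(scr$age_years <= 16), 0.201, tolerance = 0.03)

  # participation near the model-implied marginal, and any-problem near 22%
  expect_equal(length(study$registrations) / sum(scr$owns_mobile), 0.763,
               tolerance = 0.03)
  expect_equal(mean(study$baseline_program$any_problem), 0.22,
               tolerance = 0.03)
})

test_that("dropping out is positively associated with smoking and RSOD band", {
  cfg <- sim_config(seed = 11, n_present = 8000, n_consenting = 8000,
                    n_phone_owners = 7800, n_classes = 36)
  study <- simulate_cohort(cfg)
  scr <- study$screening
  reg <- scr$person_id %in% study$registrations
  unsub <- scr$person_id %in% names(study$log$unsubscribed_at)
  d <- data.frame(unsub = unsub[reg],
                  smoker = derive_smoker(scr$smoking_item)[reg],
                  band = as.integer(scr$rsod_band)[reg])
  fit <- stats::glm(unsub ~ smoker + band, data = d, family = "binomial")
  expect_gt(unname(coef(fit)["smokerTRUE"]), 0)
  expect_gt(unname(coef(fit)["band"]), 0)
})

test_that("binary transitions hit the odds-ratio-implied follow-up prevalence", {
  with_seed(31, {
    base <- runif(10000) < 0.755
    # null: marginals preserved in expectation
    expect_equal(mean(transition_binary(base, 1, 0.5)), mean(base),
                 tolerance = 0.02)
    # OR 0 with no concordance empties the outcome
    expect_identical(sum(transition_binary(base, 0, 0)), 0L)
    # OR 0.66 on prevalence 0.755 -> odds 0.66 * 3.082 -> prevalence 0.670
    fu <- transition_binary(base, 0.66, 0.5)
    p1 <- mean(base)
    p2_target <- stats::plogis(log(0.66) + log(p1 / (1 - p1)))
    expect_equal(mean(fu), p2_target, tolerance = 0.015)
    expect_equal(p2_target, 0.670, tolerance = 0.01)
  })
})

test_that("count shifts scale the mean by the rate ratio and stay correlated", {
  par <- zinb_moments(14.1, 16.1, 0.15)
  with_seed(32, {
    base <- as.integer(qzinb(runif(20000), par))
    fu <- shift_count(base, par, 0.83, rho = 0.5)
    expect_equal(mean(fu) / mean(base), 0.83, tolerance = 0.04)
    expect_gt(cor(base, fu, method = "spearman"), 0.3)
    fu_null <- shift_count(base, par, 1, rho = 0.5)
    expect_equal(mean(fu_null), mean(base), tolerance = 0.5)
  })
})

test_that("the evaluation pipeline recovers the configured odds ratio from
           complete cases of simulated cohorts", {
  n_rep <- 40
  logors <- covered <- numeric(n_rep)
  for (s in seq_len(n_rep)) {
    study <- simulate_cohort(sim_config(seed = 5000 + s))
    long <- study_outcomes_long(study)
    d <- long[long$outcome == "rsod_any", ]
    cc <- intersect(d$person_id[d$time == "baseline" & !is.na(d$value)],
                    d$person_id[d$time == "followup" & !is.na(d$value)])
    fit <- gee_fit(d[d$person_id %in% cc, ], family = "binomial")
    logors[s] <- log(fit$effect)
    covered[s] <- fit$conf_int[1] <= 0.66 && 0.66 <= fit$conf_int[2]
  }
  mc_se <- sd(logors) / sqrt(n_rep)
  expect_lt(abs(mean(logors) - log(0.66)), 4 * mc_se)
  expect_gte(mean(covered), 0.85)
})

test_that("config validation rejects infeasible marginals and missing seeds", {
  expect_error(sim_config(), class = "alcsms_config_error")
  expect_error(sim_config(seed = 1, rsod_probs = c("never" = 0.9, "1-2" = 0.9,
                                                   "3-4" = 0.1, "5-6" = 0.1,
                                                   "7-8" = 0, "9-10" = 0,
                                                   "11-12" = 0, ">12" = 0)),
               class = "alcsms_config_error")
})
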