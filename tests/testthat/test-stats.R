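# Hand-coded cluster sandwich for a fitted two-column GLM: the independent
# numeric oracle for the robust variance.
hand_sandwich <- function(X, y, mu, w, cl) {
  A <- solve(t(X * w) %*% X)
  S <- rowsum(X * (y - mu), cl)
  A %*% (t(S) %*% S) %*% A
}

test_that("a constant count outcome is reproduced on the link scale", {
  d <- long_records(c("a", "a", "b", "b"), rep("c1", 4),
                    rep(c("baseline", "followup"), 2), rep(2, 4))
  d$class_id <- c("c1", "c1", "c2", "c2")
  fit <- gee_fit(d, family = "poisson")
  expect_equal(unname(exp(fit$coefficients["(Intercept)"])), 2, tolerance = 1e-8)
  expect_equal(fit$effect, 1, tolerance = 1e-8)
  expect_identical(fit$effect_type, "IRR")
})

test_that("the saturated logistic model reproduces the marginal odds ratio", {
  # 4 persons: baseline 3/4 positive, follow-up 2/4 positive
  d <- paired_long("x", 4, 3, 2, n_classes = 2)
  fit <- gee_fit(d, family = "binomial")
  expect_equal(fit$effect, (2 / 2) / (3 / 1), tolerance = 1e-8)
  expect_equal(exp(unname(fit$coefficients["time"])), fit$effect)
})

test_that("with one observation per cluster the robust SE is the HC0 sandwich", {
  y <- c(0, 1, 1, 0, 1, 1)
  tm <- c(0, 0, 0, 1, 1, 1)
  d <- long_records(paste0("p", 1:6), paste0("k", 1:6),
                    ifelse(tm == 0, "baseline", "followup"), y)
  fit <- gee_fit(d, family = "binomial", cluster_by = "class")
  X <- cbind(1, tm)
  mu <- 1 / (1 + exp(-drop(X %*% fit$coefficients)))
  V <- hand_sandwich(X, y, mu, mu * (1 - mu), paste0("k", 1:6))
  expect_equal(unname(fit$robust_se), unname(sqrt(diag(V))), tolerance = 1e-8)
})

test_that("the sandwich is invariant to cluster relabeling and halves under
           cluster replication", {
  d <- paired_long("x", 40, 25, 18, n_classes = 8)
  fit <- gee_fit(d, family = "binomial")
  relab <- d
  relab$class_id <- chartr("12345678", "53718264", relab$class_id)
  fit2 <- gee_fit(relab, family = "binomial")
  expect_equal(fit$vcov, fit2$vcov, tolerance = 1e-10)

  doubled <- d
  doubled$person_id <- paste0(d$person_id, "dup")
  doubled$class_id <- paste0(d$class_id, "dup")
  fit3 <- gee_fit(dplyr::bind_rows(d, doubled), family = "binomial")
  expect_equal(fit3$coefficients, fit$coefficients, tolerance = 1e-8)
  expect_equal(fit3$vcov, fit$vcov / 2, tolerance = 1e-8)
})

test_that("GEE coefficients and robust SEs agree with glm + sandwich::vcovCL", {
  set.seed(61)
  for (i in 1:10) {
    n <- 150
    family <- if (i %% 2 == 0) "binomial" else "poisson"
    cls <- sprintf("c%02d", sample(1:12, n, replace = TRUE))
    base <- if (family == "binomial") rbinom(n, 1, 0.6) else rpois(n, 6)
    fu <- if (family == "binomial") rbinom(n, 1, 0.5) else rpois(n, 5)
    d <- long_records(rep(sprintf("p%03d", 1:n), 2), rep(cls, 2),
                      rep(c("baseline", "followup"), each = n), c(base, fu))
    fit <- gee_fit(d, family = family, cluster_by = "class")
    ref <- stats::glm(value ~ (time == "followup"), data = d, family = family)
    Vref <- sandwich::vcovCL(ref, cluster = d$class_id, type = "HC0",
                             cadjust = FALSE)
    expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(fit$robust_se), unname(sqrt(diag(Vref))),
                 tolerance = 1e-6)
  }
})

test_that("degenerate designs are refused or flagged, never silent", {
  one_cluster <- paired_long("x", 6, 4, 3, n_classes = 1)
  expect_error(gee_fit(one_cluster, family = "binomial"),
               class = "alcsms_invalid_input")
  # complete separation: all negative at baseline, all positive at follow-up
  sep <- paired_long("x", 6, 0, 6, n_classes = 3)
  fit <- suppressWarnings(gee_fit(sep, family = "binomial"))
  expect_false(fit$converged)
  expect_error(gee_fit(paired_long("x", 4, 2, 2)[0, ], family = "binomial"),
               class = "alcsms_invalid_input")
})

test_that("available-case handling keeps persons with a single record", {
  d <- paired_long("x", 10, 6, 4, n_classes = 5)
  d$value[d$person_id == "x001" & d$time == "followup"] <- NA
  d$available <- !is.na(d$value)
  fit <- gee_fit(d, family = "binomial")
  expect_identical(fit$n_obs, 19L)
  expect_identical(fit$n_persons, 10L)
})

test_that("long_records enforces one row per person and time", {
  expect_error(long_records(c("a", "a"), c("c", "c"),
                            c("baseline", "baseline"), c(1, 0)),
               class = "alcsms_invalid_input")
  expect_error(long_records("a", "c", "midpoint", 1),
               class = "alcsms_invalid_input")
})

test_that("Pearson chi-square matches hand computation and stats::chisq.test", {
  flat <- chi_square_test(matrix(5, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  diag2 <- chi_square_test(matrix(c(10, 0, 0, 10), 2))
  expect_equal(diag2$statistic, 20)   # sum((O-E)^2/E) with E = 5 everywhere
  expect_identical(diag2$df, 1)
  expect_identical(chi_square_test(matrix(1:6, 2, 3))$df, 2)
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2)),
               class = "alcsms_invalid_input")

  set.seed(71)
  for (i in 1:100) {
    tab <- matrix(rpois(6, 8) + 1, 2, 3)
    got <- chi_square_test(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-8)
  }
})

test_that("Mann-Whitney U matches pair counting and reference implementations", {
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$U, 0)
  expect_equal(mann_whitney_u(c(1, 3), c(2, 4))$U, 1)

  set.seed(72)
  # exact branch: equals wilcox.test's exact p on tie-free small samples
  for (i in 1:50) {
    x <- sample(seq(0, 100, 0.5), 4)
    y <- sample(setdiff(seq(0, 100, 0.5), x), 5)
    got <- mann_whitney_u(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_identical(got$method, "exact")
    expect_equal(got$U, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-8)
  }
  # normal branch with ties: equals wilcox.test without continuity correction
  for (i in 1:50) {
    x <- sample(0:8, 25, replace = TRUE)
    y <- sample(0:8, 30, replace = TRUE)
    got <- mann_whitney_u(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = FALSE))
    expect_identical(got$method, "normal")
    expect_equal(got$U, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-8)
  }
})

test_that("evaluate_outcomes fits the five models with the right families", {
  study <- simulate_cohort(sim_config(seed = 5, n_present = 420,
                                      n_consenting = 410,
                                      n_phone_owners = 400, n_classes = 20))
  res <- evaluate_outcomes(study)
  expect_identical(res$outcome, c("rsod_any", "rsod_frequent", "weekly_drinks",
                                  "max_drinks", "any_problem"))
  expect_identical(res$effect_type, c("OR", "OR", "IRR", "IRR", "OR"))
  expect_true(all(res$converged))
  expect_true(all(res$conf_low < res$estimate & res$estimate < res$conf_high))
  expect_true(all(res$estimate > 0))
})
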