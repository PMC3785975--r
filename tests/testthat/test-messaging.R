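t0 <- as.POSIXct("2012-05-01 09:00:00", tz = "UTC")

test_that("content categories are the ten printed ones, defined once", {
  cc <- content_categories()
  expect_identical(cc$id, 1:10)
  expect_identical(anyDuplicated(cc$label), 0L)
  expect_identical(category_pool("NON_RISK"), 1:4)
  expect_setequal(category_pool("LOW_RISK"), c(1:3, 5:9))
  expect_setequal(category_pool("HIGH_RISK"), c(1:3, 5:10))
})

test_that("plans carry 12 weekly messages, plus 6 drinking-day messages for
           the risk tiers, all within the 12 weeks", {
  bl <- make_baseline()
  for (g in risk_groups()) {
    plan <- plan_messages(g, bl, t0, rng_seed = 7)
    weekly <- plan$entries[plan$entries$slot == "weekly", ]
    dd <- plan$entries[plan$entries$slot == "drinking_day", ]
    expect_identical(nrow(weekly), 12L)
    expect_identical(nrow(dd), if (g == "NON_RISK") 0L else 6L)
    expect_true(all(weekly$category_id %in% category_pool(g)))
    expect_true(all(plan$entries$send_datetime >= t0))
    expect_true(all(plan$entries$send_datetime < t0 + 12 * 7 * 86400))
    if (g != "NON_RISK") {
      expect_true(all(format(dd$send_datetime, "%u") == "6"))  # Saturday
      expect_true(all(format(dd$send_datetime, "%H") == "21"))
      # biweekly = every second week, 6 occurrences
      wk <- as.integer(floor(as.numeric(dd$send_datetime - t0,
                                        units = "days") / 7)) + 1L
      expect_identical(wk, c(1L, 3L, 5L, 7L, 9L, 11L))
    }
  }
})

test_that("every pool category appears at least once over the 12 weeks and
           the high-risk pool includes counseling services", {
  bl <- make_baseline()
  plan <- plan_messages("HIGH_RISK", bl, t0, rng_seed = 3)
  weekly <- plan$entries[plan$entries$slot == "weekly", ]
  expect_setequal(unique(weekly$category_id), category_pool("HIGH_RISK"))
  expect_true(10L %in% weekly$category_id)
})

test_that("plans are deterministic in the seed; seeds permute but never break
           pool membership, counts, or immediate-repeat avoidance", {
  bl <- make_baseline()
  p1 <- plan_messages("LOW_RISK", bl, t0, rng_seed = 42)
  p2 <- plan_messages("LOW_RISK", bl, t0, rng_seed = 42)
  expect_identical(p1$entries, p2$entries)
  for (s in 1:15) {
    p <- plan_messages("LOW_RISK", bl, t0, rng_seed = s)
    cats <- p$entries$category_id[p$entries$slot == "weekly"]
    expect_true(all(cats %in% category_pool("LOW_RISK")))
    expect_true(all(diff(cats) != 0))
  }
})

test_that("risk tiers without a stated drinking day cannot be planned", {
  bl <- make_baseline(typical_drinking_day = NA, typical_drinking_time = NA)
  expect_error(plan_messages("LOW_RISK", bl, t0, 1),
               class = "alcsms_invalid_input")
  expect_s3_class(plan_messages("NON_RISK", bl, t0, 1), "message_plan")
})

test_that("rendering substitutes placeholders and reports missing ones", {
  vars <- tailoring_vars(make_baseline(), name = "Peter")
  txt <- render_message("w02", vars)
  expect_match(txt, "Hi Peter\\.")
  expect_false(grepl("\\{", txt))
  expect_error(render_message("w07", list(name = "Peter")), "max_drinks")
})

test_that("the max-drinks template carries the computed Widmark figure", {
  scr <- make_screening(max_drinks_occasion = 14)
  vars <- tailoring_vars(make_baseline(screening = scr))
  bac <- estimate_bac_permille(14, 12, 72, 0.68)
  txt <- render_message("w07", vars)
  expect_match(txt, "14 drinks")
  expect_match(txt, sprintf("%.2f per mille", round_half_up(bac, 2)),
               fixed = TRUE)
})

test_that("a stop message unsubscribes, cancels pending sends, and is
           idempotent; other texts only append", {
  log <- sms_log()
  log <- apply_incoming(log, sms_event(t0, "in", "p1", "thanks"))
  expect_length(log$unsubscribed_at, 0)
  t_stop <- t0 + 20 * 86400
  log <- apply_incoming(log, sms_event(t_stop, "in", "p1", "  Stop "))
  expect_identical(log$unsubscribed_at[["p1"]], t_stop)
  log2 <- apply_incoming(log, sms_event(t_stop + 10, "in", "p1", "STOP"))
  expect_identical(log2$unsubscribed_at[["p1"]], t_stop)

  plan <- plan_messages("HIGH_RISK", make_baseline(), t0, 5)
  kept <- cancel_pending(plan, log)
  expect_true(all(kept$entries$send_datetime < t_stop))
  expect_lt(nrow(kept$entries), nrow(plan$entries))

  # no outgoing event can follow an unsubscription
  expect_error(log_outgoing(log, sms_event(t_stop + 60, "out", "p1", "hi")),
               class = "alcsms_invalid_input")
  # out-of-order incoming events are rejected
  expect_error(apply_incoming(log, sms_event(t0 - 60, "in", "p1", "x")),
               class = "alcsms_invalid_input")
  # manual override marks free-text withdrawal requests
  log3 <- apply_incoming(sms_log(), sms_event(t0, "in", "p9",
                                              "please no more messages",
                                              manual_unsubscribe = TRUE))
  expect_identical(names(log3$unsubscribed_at), "p9")
})

test_that("attrition rate is unsubscriptions over participants", {
  expect_identical(attrition_rate(sms_log(), 10), 0)
  log <- sms_log()
  for (i in 1:23) {
    log <- apply_incoming(log, sms_event(t0 + i, "in", paste0("p", i), "stop"))
  }
  expect_equal(attrition_rate(log, 364), 23 / 364)
  expect_equal(round_half_up(100 * attrition_rate(log, 364), 1), 6.3)
  expect_identical(attrition_rate(log, 23), 1)
})

test_that("SMS logs round-trip through JSONL with unsubscribe state rebuilt", {
  log <- sms_log()
  log <- log_outgoing(log, sms_event(t0, "out", "p1", "hello"))
  log <- apply_incoming(log, sms_event(t0 + 60, "in", "p1", "stop"))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_sms_log(log, path)
  back <- read_sms_log(path)
  expect_identical(nrow(back$events), 2L)
  expect_identical(names(back$unsubscribed_at), "p1")
})

test_that("plan invariants hold for 1,000 random participants", {
  set.seed(99)
  n_bad <- 0
  for (i in 1:1000) {
    g <- sample(risk_groups(), 1)
    bl <- make_baseline(
      screening = make_screening(person_id = paste0("r", i),
                                 gender = sample(c("male", "female"), 1),
                                 max_drinks_occasion = sample(0:25, 1)),
      typical_drinking_day = sample(c("mon", "tue", "wed", "thu", "fri",
                                      "sat", "sun"), 1),
      typical_drinking_time = sample(0:23, 1))
    plan <- plan_messages(g, bl, t0, rng_seed = i)
    n_dd <- sum(plan$entries$slot == "drinking_day")
    total_ok <- nrow(plan$entries) == if (g == "NON_RISK") 12L else 18L
    dd_ok <- n_dd == if (g == "NON_RISK") 0L else 6L
    cats <- plan$entries$category_id[plan$entries$slot == "weekly"]
    pool_ok <- all(cats %in% category_pool(g))
    cat10_ok <- g == "HIGH_RISK" || !10L %in% cats
    if (!(total_ok && dd_ok && pool_ok && cat10_ok)) n_bad <- n_bad + 1
  }
  expect_identical(n_bad, 0)
})
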