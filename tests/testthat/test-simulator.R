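small_params <- function(...) {
  sim_params(n_patients = 40L, n_weeks = 12L, ...)
}

# login-only settings for experiments that need many patients quickly
logins_only <- function(...) {
  sim_params(journal_given_login = 0, med_report_given_login = 0,
             pef_report_given_login = 0, zone_calc_given_login = 0,
             email_share = 0, reminder_response = 0, ...)
}

test_that("parameter validation rejects impossible settings before generation", {
  expect_error(sim_params(p0 = 1.2), "probability")
  expect_error(sim_params(lambda = -0.1), "lambda")
  expect_error(sim_params(p0 = 0.3, p_inf = 0.5), "p0 must be >= p_inf")
  expect_error(sim_params(sym_controlled = list(symptoms = 2, night = 0,
                                                limit = 0, severe = 0,
                                                reliever = 0)),
               "sym_controlled")
  expect_error(sim_params(tz = "Mars/Olympus"), "timezone")
})

test_that("an empty cohort yields an empty log", {
  sim <- simulate_cohort(sim_params(n_patients = 0L), seed = 1)
  expect_length(sim$cohort, 0)
  expect_equal(n_events(sim$log), 0L)
})

test_that("the same seed reproduces the event log bit-identically", {
  s1 <- simulate_cohort(small_params(), seed = 11)
  s2 <- simulate_cohort(small_params(), seed = 11)
  expect_identical(s1$log$events, s2$log$events)
  expect_identical(write_cohort(s1$cohort, withr::local_tempfile()) |>
                     readLines(),
                   write_cohort(s2$cohort, withr::local_tempfile()) |>
                     readLines())
  s3 <- simulate_cohort(small_params(), seed = 12)
  expect_false(identical(s1$log$events, s3$log$events))
})

test_that("simulated events respect the module contracts", {
  sim <- simulate_cohort(small_params(), seed = 3)
  ev <- sim$log$events
  expect_true(all(ev$event_type %in% EVENT_TYPES))
  expect_true(all(ev$timestamp >= sim$log$window[1] &
                    ev$timestamp <= sim$log$window[2]))
  expect_length(validate_cohort(sim$cohort), 0)
  # journal/medication/peakflow events only on login days (patient clocks)
  for (pid in unique(ev$patient_id)[1:5]) {
    pe <- ev[ev$patient_id == pid, ]
    login_days <- unique(as.Date(format(pe$timestamp[pe$event_type == "login"],
                                        "%Y-%m-%d", tz = "America/Toronto")))
    for (ty in c("journal", "medication_report", "peakflow_report")) {
      d <- as.Date(format(pe$timestamp[pe$event_type == ty], "%Y-%m-%d",
                          tz = "America/Toronto"))
      expect_true(all(d %in% login_days))
    }
  }
})

test_that("with lambda = 0 the weekly-active fraction stays roughly flat", {
  prm <- logins_only(n_patients = 150L, n_weeks = 10L, p0 = 0.7, p_inf = 0.7,
                     lambda = 0)
  sim <- simulate_cohort(prm, seed = 5)
  curve <- attrition_curve(sim$log, sim$cohort, n_weeks = 10)
  # expected level: P(active) x P(>=1 login | active); week 1 includes the
  # onboarding login so drop it
  expect_lt(diff(range(curve[-1])), 0.2)
  expect_gt(mean(curve[-1]), 0.45)
})

test_that("higher decay rates produce lower late-stage engagement", {
  act <- vapply(c(0.05, 0.3, 1.0), function(lam) {
    sim <- simulate_cohort(logins_only(n_patients = 120L, n_weeks = 12L,
                                       p0 = 0.95, p_inf = 0.2, lambda = lam),
                           seed = 21)
    mean(attrition_curve(sim$log, sim$cohort, n_weeks = 12)[9:12])
  }, numeric(1))
  expect_true(all(diff(act) < 0))
})

test_that("reminder-responsive patients produce a 19:00 login spike", {
  on <- simulate_cohort(small_params(reminder_response = 0.6), seed = 8)
  off <- simulate_cohort(small_params(reminder_response = 0.0), seed = 8)
  share19 <- function(sim) {
    h <- hour_histogram(sim$log)
    (h[["19"]] + h[["20"]]) / sum(h)
  }
  expect_gt(share19(on), share19(off))
  expect_gt(share19(on), 0.15)
})

test_that("good-day share rises with the controlled-state stay probability", {
  shares <- vapply(c(0.80, 0.95, 0.995), function(stay) {
    sim <- simulate_cohort(small_params(stay_controlled = stay), seed = 13)
    e <- journal_from_log(sim$log)
    mean(classify_day(e) == "good_day")
  }, numeric(1))
  expect_true(all(diff(shares) > 0))
})

test_that("the default preset lands in the observed engagement and symptom bands", {
  sim <- simulate_cohort(sim_params(), seed = 42)
  wk4 <- weekly_active_fraction(sim$log, sim$cohort, 4)
  expect_gt(wk4, 0.55)
  expect_lt(wk4, 0.80)
  e <- journal_from_log(sim$log)
  good <- mean(classify_day(e) == "good_day")
  ratio <- good / (1 - good)
  expect_gt(ratio, 1)    # 2:1 +/- 50%
  expect_lt(ratio, 3)
  # reminder volume of the same order as a daily-adherence deployment
  emails <- pppw_rate(sum(sim$log$events$event_type == "email_sent"), 123, 52)
  expect_gt(emails, 4)
  expect_lt(emails, 12)
})

test_that("the decay model inverts a noise-free curve to within 1%", {
  w <- 1:52
  y <- 0.4 + (0.9 - 0.4) * exp(-0.08 * w)
  cf <- coef(fit_attrition_decay(y))
  expect_equal(unname(cf["p0"]), 0.9, tolerance = 0.01)
  expect_equal(unname(cf["p_inf"]), 0.4, tolerance = 0.01)
  expect_equal(unname(cf["lambda"]), 0.08, tolerance = 0.01)
})

test_that("a constant curve fits as zero decay at the mean", {
  cf <- coef(fit_attrition_decay(rep(0.5, 52)))
  expect_equal(unname(cf["lambda"]), 0)
  expect_equal(unname(cf["p0"]), 0.5)
  expect_equal(unname(cf["p_inf"]), 0.5)
  expect_error(fit_attrition_decay(c(0.5, 1.2, 0.4)), "\\[0, 1\\]")
})

test_that("decay-fit accessors behave like a fitted model object", {
  y <- 0.4 + 0.5 * exp(-0.1 * (1:52)) + 0.01 * sin(1:52)
  y <- pmin(pmax(y, 0), 1)
  fit <- fit_attrition_decay(y)
  expect_s3_class(fit, "attrition_fit")
  expect_named(coef(fit), c("p0", "p_inf", "lambda"))
  expect_length(fitted(fit), 52)
  expect_equal(fitted(fit) + residuals(fit), y)
  expect_equal(predict(fit, week = 1:52), fitted(fit))
  expect_output(print(fit), "lambda")
})
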