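mini_cohort <- function(n, enrollment = "2013-02-01T14:00:00Z") {
  lapply(seq_len(n), function(i)
    make_profile(sprintf("q%02d", i), enrollment = enrollment))
}

login_log <- function(cohort, weeks_by_patient, hour = 12) {
  rows <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    w <- weeks_by_patient[[i]]
    if (length(w) == 0) return(NULL)
    data.frame(patient_id = cohort[[i]]$patient_id,
               timestamp = cohort[[i]]$enrollment + (w - 1) * 7 * 86400 +
                 hour * 3600,
               event_type = "login", payload = "", stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    return(event_log(cohort_id = "mini",
                     window = UTC0(c("2013-01-01", "2014-06-01"))))
  event_log(rows, cohort_id = "mini",
            window = UTC0(c("2013-01-01", "2014-06-01")))
}

test_that("pppw rates divide by cohort-size x observation-weeks", {
  expect_equal(pppw_rate(6396, 123, 52), 1)
  expect_equal(pppw_rate(0, 123, 52), 0)
  expect_equal(pppw_rate(200, 10, 4), 5)
  expect_equal(pppw_rate(2 * 200, 10, 4), 2 * pppw_rate(200, 10, 4))  # linear
  expect_error(pppw_rate(10, 0, 52), ">= 1")
})

test_that("weekly-active fractions count distinct patients on their enrollment clocks", {
  cohort <- mini_cohort(4)
  log <- login_log(cohort, list(c(1, 2), c(1, 2), c(2), integer(0)))
  expect_equal(weekly_active_fraction(log, cohort, 1), 0.5)
  expect_equal(weekly_active_fraction(log, cohort, 2), 0.75)
  expect_equal(weekly_active_fraction(log, cohort, 3), 0)

  # two logins in the same week count once
  log2 <- login_log(cohort, list(c(1, 1, 1), integer(0), integer(0), integer(0)))
  expect_equal(weekly_active_fraction(log2, cohort, 1), 0.25)

  empty <- login_log(cohort, list(integer(0), integer(0), integer(0), integer(0)))
  expect_equal(weekly_active_fraction(empty, cohort, 5), 0)
})

test_that("the attrition curve is the weekly-active series, with optional reference", {
  cohort <- mini_cohort(2)
  log <- login_log(cohort, list(1:52, c(1)))
  curve <- attrition_curve(log, cohort)
  expect_length(curve, 52)
  expect_equal(curve[1], 1)
  expect_equal(curve[2], 0.5)
  expect_equal(curve, vapply(1:52, function(w)
    weekly_active_fraction(log, cohort, w), numeric(1)))

  ref <- attrition_curve(log, cohort, reference = rep(0.5, 52))
  expect_equal(attr(ref, "reference"), rep(0.5, 52))

  full <- login_log(cohort, list(1:52, 1:52))
  expect_equal(unname(attrition_curve(full, cohort)), rep(1, 52))
})

test_that("hour histogram bins logins by local hour and conserves the total", {
  cohort <- mini_cohort(1)
  t <- as.POSIXct("2013-06-03 19:05:00", tz = "America/Toronto")
  log <- event_log(data.frame(patient_id = "q01", timestamp = t,
                              event_type = "login", payload = "",
                              stringsAsFactors = FALSE),
                   window = UTC0(c("2013-01-01", "2014-06-01")))
  h <- hour_histogram(log)
  expect_equal(unname(h[["19"]]), 1L)
  expect_equal(sum(h), 1L)

  big <- login_log(cohort, list(1:30), hour = 7)
  expect_equal(sum(hour_histogram(big)), 30L)
  m <- hour_histogram(big, by_month = TRUE, cohort = cohort)
  expect_equal(dim(m), c(24L, 12L))
  expect_equal(sum(m), 30L)
})

test_that("zone distribution covers all outcomes and sums to one", {
  t0 <- UTC0("2013-03-01T00:00:00Z")
  zones <- c(rep("green", 6), rep("yellow", 2), "red", "insufficient")
  ev <- data.frame(patient_id = "q01", timestamp = t0 + seq_along(zones) * 60,
                   event_type = "zone_calc",
                   payload = sprintf('{"zone":"%s","basis":"both"}', zones),
                   stringsAsFactors = FALSE)
  zd <- zone_distribution(event_log(ev))
  expect_equal(zd$count, c(6L, 2L, 1L, 1L))
  expect_equal(sum(zd$fraction), 1)
  expect_equal(zd$fraction[1], 0.6)

  solo <- zone_distribution(event_log(ev[zones == "green", ]))
  expect_equal(solo$fraction[solo$zone == "green"], 1)
  expect_error(zone_distribution(event_log()), "no zone_calc")
})

test_that("trigger frequencies sort descending and conserve mentions", {
  e <- journal_entries("p1", rep("2013-02-01T12:00:00Z", 4),
                       triggers = list(c("dust", "smoke"), "dust", "dust",
                                       character(0)))
  tf <- trigger_frequency(e)
  expect_identical(names(tf)[1], "dust")
  expect_equal(unname(tf), c(3L, 1L))
  expect_equal(sum(tf), 4L)
  expect_length(trigger_frequency(e[4, ]), 0)
})

test_that("monthly good-day summary buckets by enrollment month and omits empty months", {
  cohort <- mini_cohort(1)
  t0 <- cohort[[1]]$enrollment
  # 20 good then 10 episode days in month 1; 3 good days in month 3
  e <- journal_entries("q01",
                       c(t0 + (0:29) * 86400, t0 + (62:64) * 86400),
                       daytime_symptoms = c(rep(FALSE, 20), rep(TRUE, 10),
                                            rep(FALSE, 3)))
  g <- good_day_monthly(e, cohort)
  expect_equal(g$month, c(1L, 3L))
  expect_equal(g$good[1], 20L)
  expect_equal(g$episode[1], 10L)
  expect_equal(g$pct_good[1], 100 * 2 / 3, tolerance = 1e-10)
  expect_equal(g$pct_good[2], 100)
  expect_equal(g$pct_good + g$pct_episode, rep(100, 2))
})

test_that("weeks-with-login counts distinct enrollment-relative weeks", {
  cohort <- mini_cohort(3)
  log <- login_log(cohort, list(1:52, c(2, 2, 2, 5), integer(0)))
  w <- weeks_with_login(log, cohort)
  expect_equal(unname(w), c(52L, 2L, 0L))
  expect_equal(weeks_with_login(log, cohort, patient_id = "q02"), 2L)
  expect_error(weeks_with_login(log, cohort, patient_id = "nope"), "unknown")
})

test_that("rank-sum comparison: symmetry, an exact small-sample p, and tie fallback", {
  same <- rank_sum_compare(c(1, 2, 3), c(1.5, 2.5, 0.5))
  expect_gt(same$p_value, 0.6)

  r <- rank_sum_compare(c(1, 2, 3), c(4, 5, 6))
  expect_true(r$exact)
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)

  tied <- rank_sum_compare(c(1, 2, 2), c(2, 3, 4))
  expect_false(tied$exact)
  expect_true(tied$p_value > 0 && tied$p_value <= 1)

  expect_error(rank_sum_compare(numeric(0), 1:3), "non-empty")
})

test_that("SUS scoring maps the anchors of the 0-100 scale", {
  expect_equal(sus_score(rep(c(5, 1), 5)), 100)
  expect_equal(sus_score(rep(3, 10)), 50)
  expect_equal(sus_score(rep(c(1, 5), 5)), 0)
  expect_equal(sus_score(c(4, 2, 4, 2, 4, 2, 4, 2, 4, 2)), 75)
  expect_error(sus_score(rep(3, 9)), "exactly 10")
  expect_error(sus_score(c(rep(3, 9), 6)), "1..5")
})

test_that("Likert summaries bucket 1-2 / 3 / 4-5 over non-missing responses", {
  tbl <- data.frame(respondent_id = 1:10, item_id = "helpful",
                    response = c(1, 2, 3, 3, 4, 4, 5, 5, 5, NA))
  s <- likert_summary(tbl, "helpful")
  expect_equal(s$n, 9L)
  expect_equal(s$pct_disagree, 100 * 2 / 9)
  expect_equal(s$pct_neutral, 100 * 2 / 9)
  expect_equal(s$pct_agree, 100 * 5 / 9)
  expect_equal(s$pct_disagree + s$pct_neutral + s$pct_agree, 100)

  all3 <- data.frame(respondent_id = 1:4, item_id = "x", response = 3)
  s3 <- likert_summary(all3, "x")
  expect_equal(s3$pct_agree, 0)
  expect_equal(s3$pct_disagree, 0)
  expect_error(likert_summary(all3, "missing_item"), "no responses")
})

test_that("journal entries embedded in a log decode back field-for-field", {
  e <- journal_entries("p1", c("2013-02-01T12:00:00Z", "2013-02-02T12:00:00Z"),
                       daytime_symptoms = c(TRUE, FALSE),
                       reliever_doses = c(2L, 0L),
                       triggers = list(c("dust", "pets"), character(0)),
                       pef = c(410.5, NA))
  log <- event_log(window = UTC0(c("2013-01-01", "2013-12-31")))
  for (i in 1:2) {
    pay <- list(daytime_symptoms = e$daytime_symptoms[i],
                night_waking = FALSE, activity_limitation = FALSE,
                severe_flag = FALSE, reliever_doses = e$reliever_doses[i],
                triggers = e$triggers[[i]])
    if (!is.na(e$pef[i])) pay$pef <- e$pef[i]
    log <- append_event(log, event_record("p1", e$timestamp[i], "journal", pay))
  }
  back <- journal_from_log(log)
  expect_equal(back$daytime_symptoms, e$daytime_symptoms)
  expect_equal(back$reliever_doses, e$reliever_doses)
  expect_equal(back$triggers, e$triggers)
  expect_equal(back$pef, e$pef)
})
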