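test_that("peak-flow banding uses inclusive lower bounds", {
  th <- zone_thresholds(450, 300)
  expect_identical(classify_pef(450, th), "green")
  expect_identical(classify_pef(449, th), "yellow")
  expect_identical(classify_pef(300, th), "yellow")
  expect_identical(classify_pef(299, th), "red")
  expect_identical(classify_pef(c(500, 350, 100), th),
                   c("green", "yellow", "red"))
  expect_error(classify_pef(0, th), "invalid measurement")
  expect_error(classify_pef(-5, th), "invalid measurement")
})

test_that("symptom classification: green under criteria, severe dominates to red", {
  as_of <- UTC0("2013-02-08T12:00:00Z")
  quiet <- aggregate_window(make_week_entries(as_of), as_of)
  expect_identical(classify_symptoms(quiet), "green")

  four <- aggregate_window(make_week_entries(as_of, sym_days = 4), as_of)
  expect_identical(classify_symptoms(four), "yellow")

  sev <- aggregate_window(make_week_entries(as_of, sym_days = 7, nights = 7,
                                            reliever = 9, severe = TRUE), as_of)
  expect_identical(classify_symptoms(sev), "red")

  empty <- aggregate_window(journal_entries(character(0), character(0)), as_of)
  expect_error(classify_symptoms(empty), "n_entries > 0")
})

test_that("custom criteria move the green boundary", {
  as_of <- UTC0("2013-02-08T12:00:00Z")
  agg <- aggregate_window(make_week_entries(as_of, sym_days = 5), as_of)
  expect_identical(classify_symptoms(agg), "yellow")
  lax <- symptom_criteria(max_symptom_days_per_week = 5)
  expect_identical(classify_symptoms(agg, lax), "green")
})

test_that("zone assessment combines components worst-of and records its basis", {
  p <- make_profile()
  as_of <- UTC0("2013-02-10T12:00:00Z")

  none <- assess_zone(p, entries = make_week_entries(as_of)[0, ], as_of = as_of)
  expect_identical(none$zone, "insufficient")
  expect_identical(none$basis, "none")
  expect_null(none$instruction)

  both <- assess_zone(p, entries = make_week_entries(as_of, pef = 380),
                      as_of = as_of)
  expect_identical(both$zone, "yellow")  # symptoms green, pef yellow
  expect_identical(both$basis, "both")
  expect_identical(both$instruction$instructions, "step up")

  sym_only <- assess_zone(make_profile(requires_pef = FALSE),
                          entries = make_week_entries(as_of), as_of = as_of)
  expect_identical(sym_only$zone, "green")
  expect_identical(sym_only$basis, "symptoms_only")
})

test_that("a plan that relies on peak flow is insufficient without resolvable thresholds", {
  p <- make_profile(personal_best = NULL, requires_pef = TRUE)
  as_of <- UTC0("2013-02-10T12:00:00Z")
  res <- assess_zone(p, entries = make_week_entries(as_of, pef = 380),
                     as_of = as_of)
  expect_identical(res$zone, "insufficient")
  expect_identical(res$basis, "none")
})

test_that("a PEF older than the window never contributes", {
  p <- make_profile()
  as_of <- UTC0("2013-02-10T12:00:00Z")
  old_pef <- journal_entries("p1", as_of - 9 * 86400, pef = 200)
  recent <- make_week_entries(as_of)
  res <- assess_zone(p, entries = rbind(recent, old_pef), as_of = as_of)
  expect_identical(res$basis, "symptoms_only")
  expect_identical(res$zone, "green")
})

test_that("reset drops exactly the entries at or before the latest applicable reset", {
  as_of <- UTC0("2013-02-10T12:00:00Z")
  e <- journal_entries("p1", c(as_of - 3 * 86400, as_of - 86400),
                       daytime_symptoms = TRUE)
  t_reset <- as_of - 2 * 86400

  survived <- apply_reset(e, t_reset, as_of)
  expect_equal(nrow(survived), 1L)
  expect_equal(survived$timestamp, as_of - 86400)

  expect_equal(nrow(apply_reset(e, as_of, as_of)), 0L)          # all consumed
  expect_identical(apply_reset(e, NULL, as_of), e)              # identity
  expect_identical(apply_reset(e, as_of + 86400, as_of), e)     # future reset ignored
  at_exact <- apply_reset(e, as_of - 86400, as_of)              # strictly-after
  expect_equal(nrow(at_exact), 0L)
})

test_that("assessment after a reset ignores all information at or before it", {
  p <- make_profile()
  as_of <- UTC0("2013-02-10T12:00:00Z")
  bad <- journal_entries("p1", as_of - 2 * 86400, daytime_symptoms = TRUE,
                         severe_flag = TRUE, reliever_doses = 5L)
  good <- journal_entries("p1", as_of - 0:1 * 86400)
  t <- as_of - 36 * 3600

  without_reset <- assess_zone(p, entries = rbind(bad, good), as_of = as_of)
  expect_identical(without_reset$zone, "red")

  after_reset <- assess_zone(p, entries = apply_reset(rbind(bad, good), t, as_of),
                             as_of = as_of)
  only_good <- assess_zone(p, entries = good, as_of = as_of)
  expect_identical(after_reset$zone, only_good$zone)
  expect_identical(after_reset$zone, "green")
})

test_that("assessment is deterministic", {
  p <- make_profile()
  as_of <- UTC0("2013-02-10T12:00:00Z")
  e <- make_week_entries(as_of, sym_days = 2, nights = 1, pef = 455)
  r1 <- assess_zone(p, entries = e, as_of = as_of)
  r2 <- assess_zone(p, entries = e, as_of = as_of)
  expect_identical(r1, r2)
})
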