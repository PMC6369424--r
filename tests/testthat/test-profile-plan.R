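test_that("peak-flow thresholds resolve from personal best and pass through when absolute", {
  p <- make_profile(personal_best = 500)
  th <- resolve_pef_thresholds(p, green_frac = 0.9, red_frac = 0.6)
  expect_equal(th$green_lower, 450)
  expect_equal(th$yellow_lower, 300)
  expect_identical(th$source, "absolute")

  abs_p <- make_profile(absolute = TRUE)
  abs_p$thresholds <- zone_thresholds(420, 280)
  th2 <- resolve_pef_thresholds(abs_p)
  expect_equal(th2$green_lower, 420)
  expect_equal(th2$yellow_lower, 280)

  none <- make_profile(personal_best = NULL)
  expect_error(resolve_pef_thresholds(none), "unresolvable")
})

test_that("threshold resolution is idempotent and preserves zone ordering", {
  p <- make_profile(personal_best = 480)
  th <- resolve_pef_thresholds(p)
  p$thresholds <- th
  expect_identical(resolve_pef_thresholds(p), th)

  set.seed(42)
  for (k in 1:50) {
    gf <- runif(1, 0.5, 1)
    rf <- runif(1, 0.05, gf - 0.01)
    th <- resolve_pef_thresholds(make_profile(personal_best = runif(1, 200, 700)),
                                 green_frac = gf, red_frac = rf)
    expect_gt(th$green_lower, th$yellow_lower)
    expect_gt(th$yellow_lower, 0)
  }
})

test_that("fractional provider thresholds resolve against personal best", {
  p <- make_profile(personal_best = 400)
  p$thresholds <- zone_thresholds(0.85, 0.5, source = "fraction_of_personal_best")
  th <- resolve_pef_thresholds(p)
  expect_equal(th$green_lower, 340)
  expect_equal(th$yellow_lower, 200)
})

test_that("profile validation reports violations instead of throwing", {
  expect_length(validate_profile(make_profile()), 0)

  bad_act <- make_profile()
  bad_act$baseline_act <- 30
  v <- validate_profile(bad_act)
  expect_length(v, 1)
  expect_match(v, "\\[5, 25\\]")

  bad_th <- make_profile()
  bad_th$thresholds <- list(green_lower = 280, yellow_lower = 420,
                            source = "absolute")
  v <- validate_profile(bad_th)
  expect_length(v, 1)
  expect_match(v, "green_lower > yellow_lower")

  bad_med <- make_profile()
  bad_med$medications <- list(list(name = "x", med_class = "vitamin"))
  expect_match(validate_profile(bad_med), "controller or reliever")

  bad_time <- make_profile()
  bad_time$reminder_time <- "25:00"
  expect_match(validate_profile(bad_time), "clock time")
})

test_that("cohort validation flags duplicate patient ids", {
  cohort <- list(make_profile("a"), make_profile("a"), make_profile("b"))
  v <- validate_cohort(cohort)
  expect_length(v, 1)
  expect_match(v, "duplicated patient_id: a")
})

test_that("cohort JSON round-trips profiles with embedded plans", {
  cohort <- list(make_profile("p1", baseline_act = 18,
                              age_group = "fifty_plus"),
                 make_profile("p2", personal_best = NULL,
                              requires_pef = FALSE, controller = FALSE))
  path <- withr::local_tempfile(fileext = ".json")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_length(back, 2)
  expect_identical(back[[1]]$patient_id, "p1")
  expect_equal(back[[1]]$personal_best_pef, 500)
  expect_equal(back[[1]]$baseline_act, 18)
  expect_identical(back[[1]]$age_group, "fifty_plus")
  expect_identical(back[[1]]$enrollment, cohort[[1]]$enrollment)
  expect_true(plan_requires_pef(back[[1]]$action_plan))
  expect_false(plan_requires_pef(back[[2]]$action_plan))
  expect_identical(
    vapply(back[[1]]$medications, function(m) m$med_class, character(1)),
    c("reliever", "controller"))
})

test_that("an action plan has exactly one instruction record per zone", {
  ap <- action_plan(green = "a", yellow = "b", red = "c")
  expect_identical(ap$yellow$zone, "yellow")
  expect_error(action_plan(green = zone_instruction("red", "x"),
                           yellow = "b", red = "c"),
               "wrong zone")
})
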