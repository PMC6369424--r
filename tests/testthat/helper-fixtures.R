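# Shared fixtures and independent oracles, built in code.

UTC0 <- function(x) as.POSIXct(x, tz = "UTC")

make_profile <- function(patient_id = "p1",
                         enrollment = "2013-02-01T14:00:00Z",
                         personal_best = 500,
                         absolute = FALSE,
                         requires_pef = TRUE,
                         controller = TRUE, ...) {
  meds <- list(medication("salbutamol", "reliever"))
  if (controller) meds <- c(meds, list(medication("budesonide", "controller")))
  patient_profile(
    patient_id = patient_id, enrollment = enrollment,
    personal_best_pef = personal_best,
    medications = meds,
    thresholds = if (absolute) zone_thresholds(450, 300),
    action_plan = action_plan(
      green = zone_instruction("green", "carry on", requires_pef = requires_pef),
      yellow = zone_instruction("yellow", "step up", requires_pef = requires_pef),
      red = zone_instruction("red", "seek care", requires_pef = requires_pef)),
    ...)
}

# 7 daily entries realizing an aggregate: `sym_days` symptomatic days,
# `nights` night-waking entries, all reliever doses on entry 1, optional
# severe flag on entry 1, optional pef on the latest entry
make_week_entries <- function(as_of, sym_days = 0, nights = 0, reliever = 0,
                              severe = FALSE, pef = NA_real_,
                              patient_id = "p1") {
  as_of <- UTC0(as_of)
  ts <- as_of - (6:0) * 86400
  journal_entries(
    patient_id = patient_id, timestamp = ts,
    daytime_symptoms = seq_len(7) <= sym_days,
    night_waking = seq_len(7) <= nights,
    severe_flag = c(severe, rep(FALSE, 6)),
    reliever_doses = c(reliever, rep(0L, 6)),
    pef = c(rep(NA_real_, 6), pef))
}

# Independent brute-force evaluator of the zone decision table, written
# directly from the rules (defaults: green needs <4 symptom days, <1 night
# waking, <=3 reliever doses; severe -> red; pef: >=90% of personal best
# green, <60% red; components combine worst-of; lower bounds inclusive).
zone_oracle <- function(sym_days, nights, reliever, severe, pef_ratio = NA) {
  sym <- if (severe) "red"
         else if (sym_days <= 3 && nights <= 0 && reliever <= 3) "green"
         else "yellow"
  rank <- c(green = 1, yellow = 2, red = 3)
  r <- rank[[sym]]
  if (!is.na(pef_ratio)) {
    pz <- if (pef_ratio >= 0.9) "green" else if (pef_ratio < 0.6) "red" else "yellow"
    r <- max(r, rank[[pz]])
  }
  names(rank)[r]
}

# Exact two-sided rank-sum p by full enumeration of all rank partitions
# (valid without ties; the null is symmetric so the doubling and the
# tail-distance definitions coincide)
ranksum_enum_p <- function(a, b) {
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n)])
  idx <- utils::combn(n + m, n)
  ws <- colSums(matrix(r[idx], nrow = n))
  mu <- n * (n + m + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# a small mixed-type event table of n events for round-trip tests
make_mixed_events <- function(n, start = "2013-03-01T00:00:00Z") {
  t0 <- UTC0(start)
  types <- rep(c("login", "journal", "zone_calc", "email_sent",
                 "medication_report", "peakflow_report", "reset",
                 "clinic_visit"), length.out = n)
  payload <- character(n)
  payload[types == "journal"] <-
    '{"daytime_symptoms":true,"night_waking":false,"activity_limitation":false,"severe_flag":false,"reliever_doses":2,"triggers":["dust","smoke"]}'
  payload[types == "zone_calc"] <- '{"zone":"green","basis":"both"}'
  payload[types == "email_sent"] <- '{"email_kind":"adherence","message_id":7}'
  payload[types == "medication_report"] <- '{"med_class":"controller"}'
  payload[types == "peakflow_report"] <- '{"pef":432.5}'
  data.frame(patient_id = sprintf("P%03d", (seq_len(n) %% 40) + 1),
             timestamp = t0 + seq_len(n) * 137,
             event_type = types, payload = payload,
             stringsAsFactors = FALSE)
}
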