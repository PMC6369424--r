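# Synthetic-cohort behavior simulator.  Generates patient profiles and a
# full event log with the behavioral structure seen in deployed asthma
# self-management platforms: exponential engagement decay with a long-run
# floor, an evening spike of logins after the 19:00 reminder email, a
# morning usage block, surveillance bumps before scheduled clinic visits at
# weeks 26 and 52, higher engagement in patients aged 50+, and a two-state
# (controlled/uncontrolled) Markov symptom process consistent with
# mostly-controlled asthma (about two good days per symptom day).
# zone_calc events are produced by running the real zone engine on the
# simulated journals.

#' Simulation parameters
#'
#' All behavioral knobs of [simulate_cohort()], with defaults chosen as a
#' reference preset for a 123-patient, 52-week mostly-controlled cohort
#' (see the methods vignette for the rationale behind each value).
#'
#' The login model is two-level: a patient is *active* in week `w` with
#' probability `p_w = p_inf + (p0 - p_inf) exp(-lambda w)` (the decay model
#' of [fit_attrition_decay()]), and on each day of an active week logs in
#' spontaneously with probability `active_daily_login` and additionally,
#' on days an adherence email goes out, within two hours of the 19:00
#' email with probability `reminder_response`.
#'
#' @param n_patients Cohort size.
#' @param n_weeks Observation weeks per patient.
#' @param p0,p_inf,lambda Weekly-active decay model: initial probability,
#'   long-run floor, weekly decay rate (`p0 >= p_inf`, `lambda >= 0`).
#' @param active_daily_login Daily spontaneous login probability within an
#'   active week.
#' @param reminder_response Probability of an email-triggered login (19:00
#'   local + up to 2 h) on an adherence-email day of an active week.
#' @param morning_weight Share of spontaneous logins drawn from the
#'   05:00--10:00 local block (the rest spread over 10:00--23:00).
#' @param visit_weeks Scheduled clinic-visit weeks.
#' @param visit_boost Multiplier on login and reporting probabilities in
#'   the 2 enrollment-relative weeks ending at each visit week.
#' @param fifty_plus_share Fraction of patients aged 50+.
#' @param fifty_plus_boost Multiplier on the weekly-active probability for
#'   patients aged 50+ (capped at 0.98).
#' @param engagement_sd SD of the mean-1 gamma per-patient engagement
#'   multiplier applied to within-week login intensity and reporting
#'   propensities (0 disables heterogeneity).
#' @param stay_controlled,stay_uncontrolled Daily stay probabilities of the
#'   two-state symptom Markov chain.
#' @param sym_controlled,sym_uncontrolled Per-state daily probabilities:
#'   named lists with `symptoms`, `night`, `limit`, `severe`, `reliever`
#'   (probability of any reliever use that day).
#' @param pef_mean_controlled,pef_mean_uncontrolled Mean peak flow as a
#'   fraction of personal best per state.
#' @param pef_noise_sd SD of the multiplicative Gaussian noise on peak
#'   flow.
#' @param journal_given_login,med_report_given_login,pef_report_given_login,zone_calc_given_login
#'   Per-login-day reporting probabilities.
#' @param reset_prob Probability that a yellow/red zone result is followed
#'   by action-plan execution (a `reset` event 6 h later).
#' @param controller_share,email_share Fractions of patients with a
#'   controller prescription / with reminder emails enabled.
#' @param study_start First enrollment date (local).
#' @param enrol_span_days Enrollment staggered uniformly over this many
#'   days.
#' @param tz IANA timezone of the deployment.
#' @param seed Default RNG seed for [simulate_cohort()].
#' @return A validated list of class `"sim_params"`.
#' @export
sim_params <- function(n_patients = 123L, n_weeks = 52L,
                       p0 = 0.95, p_inf = 0.55, lambda = 0.30,
                       active_daily_login = 0.40,
                       reminder_response = 0.25,
                       morning_weight = 0.45,
                       visit_weeks = c(26L, 52L), visit_boost = 1.6,
                       fifty_plus_share = 49 / 122, fifty_plus_boost = 1.15,
                       engagement_sd = 0.5,
                       stay_controlled = 0.97, stay_uncontrolled = 0.85,
                       sym_controlled = list(symptoms = 0.10, night = 0.03,
                                             limit = 0.03, severe = 0.001,
                                             reliever = 0.06),
                       sym_uncontrolled = list(symptoms = 0.60, night = 0.30,
                                               limit = 0.40, severe = 0.02,
                                               reliever = 0.60),
                       pef_mean_controlled = 0.95,
                       pef_mean_uncontrolled = 0.72,
                       pef_noise_sd = 0.06,
                       journal_given_login = 0.83,
                       med_report_given_login = 0.10,
                       pef_report_given_login = 0.30,
                       zone_calc_given_login = 0.88,
                       reset_prob = 0.25,
                       controller_share = 0.95, email_share = 0.97,
                       study_start = "2013-01-07", enrol_span_days = 28L,
                       tz = "America/Toronto",
                       seed = 1L) {
  p <- as.list(environment())
  probs <- c("p0", "p_inf", "active_daily_login", "reminder_response",
             "morning_weight", "fifty_plus_share", "stay_controlled",
             "stay_uncontrolled", "journal_given_login",
             "med_report_given_login", "pef_report_given_login",
             "zone_calc_given_login", "reset_prob", "controller_share",
             "email_share")
  for (f in probs) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stop("invalid params: ", f, " must be a probability in [0, 1]")
  }
  for (st in c("sym_controlled", "sym_uncontrolled"))
    for (f in c("symptoms", "night", "limit", "severe", "reliever")) {
      v <- p[[st]][[f]]
      if (is.null(v) || !is.finite(v) || v < 0 || v > 1)
        stop("invalid params: ", st, "$", f, " must be a probability in [0, 1]")
    }
  if (!(p$lambda >= 0)) stop("invalid params: lambda must be >= 0")
  if (!(p$p0 >= p$p_inf)) stop("invalid params: p0 must be >= p_inf")
  if (!(p$n_patients >= 0) || !(p$n_weeks >= 1))
    stop("invalid params: n_patients >= 0 and n_weeks >= 1 required")
  if (!(p$engagement_sd >= 0)) stop("invalid params: engagement_sd must be >= 0")
  if (!(p$visit_boost > 0) || !(p$fifty_plus_boost > 0))
    stop("invalid params: boosts must be positive")
  if (!(p$tz %in% .olson())) stop("invalid params: unknown timezone ", p$tz)
  structure(p, class = "sim_params")
}

.substream <- function(seed, i, k = 0L) {
  as.integer((abs(as.numeric(seed)) %% 100003) * 20011 + i * 13 + k)
}

.cap <- function(p, hi = 0.95) pmin(pmax(p, 0), hi)

# vectorized canonical journal payload JSON
.journal_payloads <- function(e) {
  trig <- vapply(e$triggers, function(tr) {
    if (length(tr) == 0L) "[]"
    else paste0("[", paste0('"', tr, '"', collapse = ","), "]")
  }, character(1))
  lb <- function(x) ifelse(x, "true", "false")
  sprintf(paste0('{"daytime_symptoms":%s,"night_waking":%s,',
                 '"activity_limitation":%s,"severe_flag":%s,',
                 '"reliever_doses":%d,"triggers":%s%s}'),
          lb(e$daytime_symptoms), lb(e$night_waking),
          lb(e$activity_limitation), lb(e$severe_flag),
          e$reliever_doses, trig,
          ifelse(is.na(e$pef), "", sprintf(',"pef":%.1f', e$pef)))
}

.TRIGGER_POOL <- c("dust", "pollen", "smoke", "exercise", "cold air",
                   "pets", "stress", "viral infection")

#' Simulate a synthetic cohort and its event log
#'
#' Generates `n_patients` profiles (medications, personal-best peak flow,
#' thresholds, embedded action plans, demographics) and a full 52-week
#' event log: logins (decaying engagement, morning block, post-reminder
#' evening spike, pre-visit surveillance bumps), journal entries from the
#' two-state symptom process, medication and peak-flow reports, clinic
#' visits, `zone_calc` events computed by running [assess_zone()] on the
#' simulated journals with reset semantics, `reset` events when a
#' yellow/red plan is executed, and `email_sent` events from the real
#' [plan_reminders()] planner.
#'
#' One seeded generator drives the cohort; per-patient substreams are
#' derived deterministically from `(seed, patient index)`, so the log is
#' bit-identical for a given seed regardless of evaluation order.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed (default `params$seed`).
#' @return List with `cohort` (list of [patient_profile()]) and `log`
#'   (an [event_log()]).
#' @export
#' @examples
#' sim <- simulate_cohort(sim_params(n_patients = 5, n_weeks = 8), seed = 1)
#' print(sim$log)
simulate_cohort <- function(params = sim_params(), seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  tz <- p$tz
  D <- 7L * as.integer(p$n_weeks)
  start_day <- as.Date(p$study_start)
  win_start <- .local_clock_instant(start_day, "00:00", tz)
  win_end <- .local_clock_instant(start_day + p$enrol_span_days + D + 1L,
                                  "00:00", tz)

  if (p$n_patients == 0L)
    return(list(cohort = list(),
                log = event_log(cohort_id = "simulated",
                                window = c(win_start, win_end))))

  # ---- cohort-level attribute draws (one stream, fixed order) ----
  set.seed(.substream(seed, 0L))
  n <- as.integer(p$n_patients)
  offset <- sample.int(max(p$enrol_span_days, 1L), n, replace = TRUE) - 1L
  fifty <- stats::runif(n) < p$fifty_plus_share
  controller <- stats::runif(n) < p$controller_share
  email_on <- stats::runif(n) < p$email_share
  pb <- round(stats::rnorm(n, 480, 60))
  pb <- pmax(pb, 250)
  has_pef_plan <- stats::runif(n) < 0.9
  gshape <- if (p$engagement_sd > 0) 1 / p$engagement_sd^2 else NA_real_
  g <- if (p$engagement_sd > 0) stats::rgamma(n, shape = gshape, rate = gshape)
       else rep(1, n)
  college <- stats::runif(n) < 0.72
  smartphone <- stats::runif(n) < 0.67
  act <- pmin(25L, pmax(5L, round(stats::rnorm(n, 18.3, 4.9))))

  plan_tpl <- function(requires_pef) action_plan(
    green = zone_instruction("green",
      "Asthma under control: continue your regular controller medication.",
      requires_pef = requires_pef),
    yellow = zone_instruction("yellow",
      "Asthma worsening: step up therapy as prescribed and monitor closely.",
      medication_adjustments = list(controller = "increase per plan"),
      requires_pef = requires_pef),
    red = zone_instruction("red",
      "Danger: take reliever now and seek urgent medical care.",
      medication_adjustments = list(reliever = "take immediately"),
      requires_pef = requires_pef))

  cohort <- vector("list", n)
  per_patient <- vector("list", n)

  boost_weeks <- sort(unique(unlist(lapply(p$visit_weeks,
                                           function(v) c(v - 1L, v)))))
  visit_days <- (as.integer(p$visit_weeks) - 1L) * 7L + 4L

  for (i in seq_len(n)) {
    pid <- sprintf("P%03d", i)
    enrol_day <- start_day + offset[i]
    enrol <- .local_clock_instant(enrol_day, "09:00", tz) + (i %% 37) * 60
    meds <- list(medication("salbutamol", "reliever", "2 puffs PRN"))
    if (controller[i])
      meds <- c(list(medication("budesonide/formoterol", "controller",
                                "2 puffs BID")), meds)
    prof <- patient_profile(
      patient_id = pid, enrollment = enrol,
      personal_best_pef = if (has_pef_plan[i]) pb[i] else NULL,
      medications = meds,
      thresholds = if (has_pef_plan[i])
        zone_thresholds(0.90, 0.60, source = "fraction_of_personal_best"),
      action_plan = plan_tpl(has_pef_plan[i]),
      reminder_time = "19:00", tz = tz, email_enabled = email_on[i],
      age_group = if (fifty[i]) "fifty_plus" else "under_50",
      college_educated = college[i], has_smartphone = smartphone[i],
      baseline_act = act[i])
    cohort[[i]] <- prof

    # ---- per-patient behavior substream ----
    set.seed(.substream(seed, i))
    day_dates <- enrol_day + 0:(D - 1L)
    week <- rep(seq_len(p$n_weeks), each = 7L)
    midnight <- .local_clock_instant(day_dates, "00:00", tz)

    p_w <- p$p_inf + (p$p0 - p$p_inf) * exp(-p$lambda * seq_len(p$n_weeks))
    if (fifty[i]) p_w <- pmin(p_w * p$fifty_plus_boost, 0.98)
    active <- stats::runif(p$n_weeks) < p_w
    active_d <- active[week]

    vboost <- ifelse(week %in% boost_weeks, p$visit_boost, 1)
    q_d <- .cap(p$active_daily_login * g[i] * vboost)
    spont <- active_d & stats::runif(D) < q_d
    email_day <- email_on[i] & controller[i]
    remlog <- active_d & email_day & stats::runif(D) < p$reminder_response

    morning <- stats::runif(D) < p$morning_weight
    sp_hour <- ifelse(morning, 5 + stats::runif(D) * 5, 10 + stats::runif(D) * 13)
    sp_time <- midnight + round(sp_hour * 3600)
    rem_time <- midnight + round(19 * 3600 + stats::runif(D) * 7200)

    login_any <- spont | remlog
    first_login <- as.POSIXct(pmin(ifelse(spont, as.numeric(sp_time), Inf),
                                   ifelse(remlog, as.numeric(rem_time), Inf)),
                              origin = "1970-01-01", tz = "UTC")

    # symptom Markov chain over all days (1 = controlled, 2 = uncontrolled)
    stay <- c(p$stay_controlled, p$stay_uncontrolled)
    u <- stats::runif(D)
    state <- integer(D)
    s <- 1L
    for (d in seq_len(D)) {
      if (u[d] >= stay[s]) s <- 3L - s
      state[d] <- s
    }
    sc <- p$sym_controlled; su <- p$sym_uncontrolled
    pick <- function(f) ifelse(state == 1L, sc[[f]], su[[f]])
    sym <- stats::runif(D) < pick("symptoms")
    night <- stats::runif(D) < pick("night")
    limit <- stats::runif(D) < pick("limit")
    severe <- stats::runif(D) < pick("severe")
    reliever_use <- stats::runif(D) < pick("reliever")
    doses <- ifelse(reliever_use, 1L + stats::rpois(D, ifelse(state == 1L, 0.3, 1.2)), 0L)

    rep_boost <- .cap(g[i] * vboost, 3) # propensity scaling for reporting
    journal_day <- login_any & stats::runif(D) < .cap(p$journal_given_login * rep_boost)
    med_day <- login_any & stats::runif(D) < .cap(p$med_report_given_login * rep_boost)
    pef_day <- login_any & has_pef_plan[i] &
      stats::runif(D) < .cap(p$pef_report_given_login * rep_boost)
    zone_day <- login_any & stats::runif(D) < .cap(p$zone_calc_given_login, 1)

    pef_val <- round(pb[i] *
      ifelse(state == 1L, p$pef_mean_controlled, p$pef_mean_uncontrolled) *
      (1 + stats::rnorm(D, 0, p$pef_noise_sd)), 1)
    pef_val <- pmax(pef_val, 50)

    ntrig <- ifelse(sym & stats::runif(D) < 0.6, 1L + (stats::runif(D) < 0.3), 0L)
    trig_draws <- lapply(seq_len(D), function(d)
      if (ntrig[d] > 0L) sample(.TRIGGER_POOL, ntrig[d]) else character(0))

    jd <- which(journal_day)
    entries <- journal_entries(
      patient_id = pid,
      timestamp = first_login[jd] + 300,
      daytime_symptoms = sym[jd], night_waking = night[jd],
      activity_limitation = limit[jd], severe_flag = severe[jd],
      reliever_doses = doses[jd],
      triggers = trig_draws[jd],
      pef = ifelse(pef_day[jd], pef_val[jd], NA_real_))

    # sequential zone assessments with reset semantics (real engine)
    zres <- list()
    resets <- .as_utc(character(0))
    reset_u <- stats::runif(D)
    for (d in which(zone_day)) {
      t <- first_login[d] + 120
      ent <- entries[entries$timestamp <= t, , drop = FALSE]
      ent <- apply_reset(ent, resets, t)
      res <- assess_zone(cohort[[i]], entries = ent, as_of = t)
      zres[[length(zres) + 1L]] <- list(t = t, zone = res$zone, basis = res$basis)
      if (res$zone %in% c("yellow", "red") && reset_u[d] < p$reset_prob)
        resets <- c(resets, t + 6 * 3600)
    }

    # ---- assemble this patient's events ----
    ts <- list(); ty <- list(); pay <- list()
    add <- function(t, type, payload) {
      ts[[length(ts) + 1L]] <<- as.numeric(t)
      ty[[length(ty) + 1L]] <<- rep(type, length(t))
      pay[[length(pay) + 1L]] <<- rep_len(payload, length(t))
    }
    add(enrol, "login", "")                         # onboarding access
    if (any(spont)) add(sp_time[spont], "login", "")
    if (any(remlog)) add(rem_time[remlog], "login", "")
    if (nrow(entries)) {
      ts[[length(ts) + 1L]] <- as.numeric(entries$timestamp)
      ty[[length(ty) + 1L]] <- rep("journal", nrow(entries))
      pay[[length(pay) + 1L]] <- .journal_payloads(entries)
    }
    md <- which(med_day)
    if (length(md)) {
      cls <- ifelse(stats::runif(length(md)) < ifelse(controller[i], 0.6, 0),
                    "controller", "reliever")
      add2 <- sprintf('{"med_class":"%s"}', cls)
      ts[[length(ts) + 1L]] <- as.numeric(first_login[md] + 420)
      ty[[length(ty) + 1L]] <- rep("medication_report", length(md))
      pay[[length(pay) + 1L]] <- add2
    }
    pd <- which(pef_day)
    if (length(pd)) {
      ts[[length(ts) + 1L]] <- as.numeric(first_login[pd] + 360)
      ty[[length(ty) + 1L]] <- rep("peakflow_report", length(pd))
      pay[[length(pay) + 1L]] <- sprintf('{"pef":%.1f}', pef_val[pd])
    }
    if (length(zres)) {
      ts[[length(ts) + 1L]] <- vapply(zres, function(z) as.numeric(z$t), numeric(1))
      ty[[length(ty) + 1L]] <- rep("zone_calc", length(zres))
      pay[[length(pay) + 1L]] <- vapply(zres, function(z)
        sprintf('{"zone":"%s","basis":"%s"}', z$zone, z$basis), character(1))
    }
    if (length(resets)) add(resets, "reset", "")
    vis <- visit_days[visit_days <= D]
    if (length(vis))
      add(midnight[vis] + 14 * 3600, "clinic_visit", "")

    pe <- data.frame(
      patient_id = pid,
      timestamp = as.POSIXct(unlist(ts), origin = "1970-01-01", tz = "UTC"),
      event_type = unlist(ty), payload = unlist(pay),
      stringsAsFactors = FALSE)

    # reminder emails from the real planner over this patient's horizon
    if (email_on[i]) {
      mini <- structure(list(events = pe), class = "event_log")
      plan <- plan_reminders(cohort[[i]], mini,
                             horizon = c(enrol, enrol + D * 86400),
                             seed = .substream(seed, i, 1L))
      if (nrow(plan)) {
        epay <- sprintf('{"email_kind":"%s","message_id":%d}',
                        plan$email_kind, plan$message_id)
        pe <- rbind(pe, data.frame(patient_id = pid,
                                   timestamp = plan$timestamp,
                                   event_type = "email_sent",
                                   payload = epay,
                                   stringsAsFactors = FALSE))
      }
    }
    per_patient[[i]] <- pe
  }

  ev <- do.call(rbind, per_patient)
  ev <- ev[order(ev$timestamp, ev$patient_id, ev$event_type), , drop = FALSE]
  rownames(ev) <- NULL
  list(cohort = cohort,
       log = event_log(ev, cohort_id = "simulated",
                       window = c(win_start, win_end)))
}
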