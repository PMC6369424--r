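# Cohort-level utilization and questionnaire analytics over the event log:
# per-patient per-week rates, weekly-active (attrition) series, time-of-day
# histograms, zone-of-control distributions, good-day summaries, trigger
# frequencies, weeks-with-login subgroup comparison, SUS and Likert
# scoring.  Weeks and months are enrollment-relative (each patient's own
# clock), weeks numbered 1..52 from enrollment.

.enrollments <- function(cohort) {
  ts <- .as_utc(vapply(cohort, function(p) .format_utc(p$enrollment), character(1)))
  names(ts) <- vapply(cohort, function(p) p$patient_id, character(1))
  ts
}

#' Per-patient per-week event rate
#'
#' `total_events / (n_patients * n_weeks)`, the platform's headline
#' utilization unit ("pppw").  The denominator is cohort size times the
#' full observation period, regardless of individual attrition.
#'
#' @param total_events Total event count.
#' @param n_patients Cohort size (>= 1).
#' @param n_weeks Observation weeks (>= 1).
#' @return Rate, events per patient per week (unrounded; summaries display
#'   2 decimals).
#' @export
#' @examples
#' pppw_rate(19678, 123, 52)  # 3.08
pppw_rate <- function(total_events, n_patients, n_weeks) {
  if (!(n_patients >= 1) || !(n_weeks >= 1))
    stop("pppw_rate: n_patients and n_weeks must be >= 1")
  total_events / (n_patients * n_weeks)
}

.login_weeks <- function(log, cohort) {
  enr <- .enrollments(cohort)
  ev <- log$events[log$events$event_type == "login", , drop = FALSE]
  ev <- ev[ev$patient_id %in% names(enr), , drop = FALSE]
  if (nrow(ev) == 0L)
    return(data.frame(patient_id = character(0), week = integer(0)))
  wk <- .week_index(ev$timestamp, enr[ev$patient_id])
  unique(data.frame(patient_id = ev$patient_id, week = wk,
                    stringsAsFactors = FALSE))
}

#' Fraction of the cohort active in a given enrollment-relative week
#'
#' A patient is active in week `w` if they have at least one login whose
#' enrollment-relative week index equals `w`.
#'
#' @param log An [event_log()].
#' @param cohort List of [patient_profile()]s (defines enrollments and the
#'   denominator).
#' @param week Week index, 1--52.
#' @return Fraction in `[0, 1]`.
#' @export
weekly_active_fraction <- function(log, cohort, week) {
  stopifnot(week >= 1, length(cohort) >= 1)
  lw <- .login_weeks(log, cohort)
  length(unique(lw$patient_id[lw$week == week])) / length(cohort)
}

#' Weekly-active attrition curve
#'
#' The per-week fraction of patients with at least one login, weeks 1 to
#' `n_weeks` on each patient's enrollment clock.  An optional user-supplied
#' reference series (e.g. a published eHealth attrition curve) can be
#' attached for plotting.
#'
#' @param log An [event_log()].
#' @param cohort List of [patient_profile()]s.
#' @param n_weeks Number of weeks (default 52).
#' @param reference Optional numeric reference series, recycled/truncated
#'   to `n_weeks` and stored as attribute `"reference"`.
#' @return Numeric vector of length `n_weeks`, values in `[0, 1]`.
#' @export
attrition_curve <- function(log, cohort, n_weeks = 52L, reference = NULL) {
  lw <- .login_weeks(log, cohort)
  n <- length(cohort)
  out <- vapply(seq_len(n_weeks), function(w)
    length(unique(lw$patient_id[lw$week == w])) / n, numeric(1))
  if (!is.null(reference))
    attr(out, "reference") <- rep_len(as.numeric(reference), n_weeks)
  out
}

#' Login counts by local hour of day
#'
#' Bins login events by local hour 0--23.  With `by_month = TRUE` returns a
#' 24 x 12 matrix split by enrollment-relative month (requires `cohort`),
#' e.g. to check that a reminder-hour spike is sustained over the year.
#'
#' @param log An [event_log()].
#' @param by_month Split by enrollment-relative month 1--12?
#' @param cohort Cohort (needed for `by_month`).
#' @param tz Timezone for the local hour (default the platform's
#'   `"America/Toronto"`).
#' @return Named integer vector of length 24, or a 24 x 12 matrix; entries
#'   sum to the number of logins binned.
#' @export
hour_histogram <- function(log, by_month = FALSE, cohort = NULL,
                           tz = "America/Toronto") {
  ev <- log$events[log$events$event_type == "login", , drop = FALSE]
  hours <- factor(.local_hour(ev$timestamp, tz = tz), levels = 0:23)
  if (!by_month) {
    out <- table(hours)
    v <- as.integer(out)
    names(v) <- 0:23
    return(v)
  }
  if (is.null(cohort)) stop("by_month = TRUE requires the cohort")
  enr <- .enrollments(cohort)
  ev <- ev[ev$patient_id %in% names(enr), , drop = FALSE]
  hours <- factor(.local_hour(ev$timestamp, tz = tz), levels = 0:23)
  mo <- factor(pmin(pmax(.month_index(ev$timestamp, enr[ev$patient_id]), 1L), 12L),
               levels = 1:12)
  m <- table(hours, mo)
  out <- matrix(as.integer(m), nrow = 24, ncol = 12,
                dimnames = list(hour = 0:23, month = 1:12))
  out
}

#' Distribution of zone-of-control outcomes
#'
#' Counts and fractions of emitted `zone_calc` events by zone, including
#' the insufficient-data outcome; fractions sum to 1 over all zone
#' calculations.
#'
#' @param log An [event_log()] containing at least one `zone_calc` event.
#' @return `data.frame` with columns `zone`, `count`, `fraction`, rows
#'   ordered green, yellow, red, insufficient.
#' @export
zone_distribution <- function(log) {
  ev <- log$events[log$events$event_type == "zone_calc", , drop = FALSE]
  if (nrow(ev) == 0L) stop("no zone_calc events in the log")
  zones <- sub('.*"zone":"([a-z]+)".*', "\\1", ev$payload)
  bad <- !(zones %in% c("green", "yellow", "red", "insufficient"))
  if (any(bad)) {
    # fall back to a full JSON parse for non-canonical payloads
    zones[bad] <- vapply(ev$payload[bad], function(s) {
      z <- .payload_parse(s)$zone
      if (is.null(z)) NA_character_ else z
    }, character(1), USE.NAMES = FALSE)
  }
  if (anyNA(zones)) stop("zone_calc event without a zone payload")
  lev <- c("green", "yellow", "red", "insufficient")
  counts <- as.integer(table(factor(zones, levels = lev)))
  data.frame(zone = lev, count = counts, fraction = counts / sum(counts),
             stringsAsFactors = FALSE)
}

#' Reported trigger frequencies
#'
#' Total mention counts per trigger label across journal entries, sorted
#' in descending frequency (the platform's "Trends" view).
#'
#' @param entries A [journal_entries()] table.
#' @return Named integer vector, descending.
#' @export
trigger_frequency <- function(entries) {
  all <- unlist(entries$triggers, use.names = FALSE)
  if (length(all) == 0L) return(integer(0))
  tab <- table(all)
  v <- as.integer(tab)
  names(v) <- names(tab)
  sort(v, decreasing = TRUE)
}

#' Monthly good-day versus symptom-episode summary
#'
#' Buckets journaled days by enrollment-relative month (1--12) and counts
#' good days versus episode days per [classify_day()].  Multiple entries on
#' one local calendar day count as that day's worst classification (any
#' episode entry makes it an episode day).  Months with no journaled days
#' are omitted.
#'
#' @param entries A [journal_entries()] table.
#' @param cohort List of [patient_profile()]s (for enrollment clocks).
#' @param tz Timezone for calendar-day bucketing.
#' @return `data.frame` with `month`, `good`, `episode`, `pct_good`,
#'   `pct_episode`.
#' @export
good_day_monthly <- function(entries, cohort, tz = "America/Toronto") {
  if (nrow(entries) == 0L)
    return(data.frame(month = integer(0), good = integer(0),
                      episode = integer(0), pct_good = numeric(0),
                      pct_episode = numeric(0)))
  enr <- .enrollments(cohort)
  entries <- entries[entries$patient_id %in% names(enr), , drop = FALSE]
  day <- .local_day(entries$timestamp, tz = tz)
  cls <- classify_day(entries)
  key <- paste(entries$patient_id, day)
  # worst-of per patient-day
  is_episode <- tapply(cls == "episode_day", key, any)
  first <- !duplicated(key)
  mo <- pmin(pmax(.month_index(entries$timestamp[first],
                               enr[entries$patient_id[first]]), 1L), 12L)
  names(mo) <- key[first]
  mo <- mo[names(is_episode)]
  agg <- data.frame(month = as.integer(mo), episode = as.logical(is_episode))
  tab <- table(factor(agg$month, levels = 1:12), agg$episode)
  good <- if ("FALSE" %in% colnames(tab)) as.integer(tab[, "FALSE"]) else integer(12)
  epis <- if ("TRUE" %in% colnames(tab)) as.integer(tab[, "TRUE"]) else integer(12)
  keep <- (good + epis) > 0
  tot <- good + epis
  data.frame(month = (1:12)[keep], good = good[keep], episode = epis[keep],
             pct_good = 100 * good[keep] / tot[keep],
             pct_episode = 100 * epis[keep] / tot[keep])
}

#' Number of weeks with at least one login
#'
#' Distinct enrollment-relative weeks (1--`n_weeks`) in which a patient
#' logged in; the utilization measure used for subgroup comparison.
#'
#' @param log An [event_log()].
#' @param cohort List of [patient_profile()]s.
#' @param patient_id Optional single id; default returns the full named
#'   vector (zeros included).
#' @param n_weeks Number of observation weeks (default 52).
#' @return Named integer vector (or scalar), values in `0:n_weeks`.
#' @export
weeks_with_login <- function(log, cohort, patient_id = NULL, n_weeks = 52L) {
  lw <- .login_weeks(log, cohort)
  lw <- lw[lw$week >= 1L & lw$week <= n_weeks, , drop = FALSE]
  ids <- vapply(cohort, function(p) p$patient_id, character(1))
  counts <- vapply(ids, function(id) sum(lw$patient_id == id), integer(1))
  names(counts) <- ids
  if (!is.null(patient_id)) {
    if (!(patient_id %in% ids)) stop("unknown patient_id: ", patient_id)
    return(counts[[patient_id]])
  }
  counts
}

#' Wilcoxon rank-sum comparison of two utilization groups
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test, as used to compare
#' weeks-with-login between patient subgroups.  The exact null
#' distribution is used when the smaller group has at most 10 observations
#' and there are no ties; otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return List with `statistic` (Mann-Whitney U for group a), `p_value`
#'   (two-sided), and `exact` (logical).
#' @export
#' @examples
#' rank_sum_compare(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.10
rank_sum_compare <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  exact <- min(length(group_a), length(group_b)) <= 10L && !ties
  wt <- stats::wilcox.test(group_a, group_b, alternative = "two.sided",
                           exact = exact, correct = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' System Usability Scale score
#'
#' Standard SUS scoring of the 10 ordered item responses (1--5): odd items
#' contribute `response - 1`, even items `5 - response`, and the sum is
#' scaled by 2.5 onto 0--100.
#'
#' @param responses Numeric vector of exactly 10 responses in 1--5, in item
#'   order.
#' @return Score in `[0, 100]`.
#' @export
#' @examples
#' sus_score(rep(3, 10))  # 50
sus_score <- function(responses) {
  if (length(responses) != 10L)
    stop("SUS requires exactly 10 item responses")
  if (any(!is.finite(responses)) || any(responses < 1 | responses > 5))
    stop("SUS responses must be in 1..5")
  odd <- responses[seq(1, 9, by = 2)]
  even <- responses[seq(2, 10, by = 2)]
  2.5 * (sum(odd - 1) + sum(5 - even))
}

#' Summarize a 5-point Likert item into agreement buckets
#'
#' Percentages over non-missing responses: 1--2 disagree/strongly
#' disagree, 3 neutral, 4--5 agree/strongly agree.
#'
#' @param table `data.frame` with columns `respondent_id`, `item_id`,
#'   `response` (integers 1--5).
#' @param item_id Item to summarize.
#' @return List with `n` and `pct_disagree`, `pct_neutral`, `pct_agree`
#'   (percentages, unrounded; displays use 1 decimal).
#' @export
likert_summary <- function(table, item_id) {
  r <- table$response[table$item_id == item_id]
  r <- r[!is.na(r)]
  if (length(r) == 0L) stop("no responses for item ", item_id)
  if (any(r < 1 | r > 5)) stop("Likert responses must be in 1..5")
  n <- length(r)
  list(n = n,
       pct_disagree = 100 * sum(r <= 2) / n,
       pct_neutral = 100 * sum(r == 3) / n,
       pct_agree = 100 * sum(r >= 4) / n)
}

#' Journal entries embedded in an event log
#'
#' Decodes the payloads of `journal` events back into a
#' [journal_entries()] table.
#'
#' @param log An [event_log()].
#' @return A [journal_entries()] table.
#' @export
journal_from_log <- function(log) {
  ev <- log$events[log$events$event_type == "journal", , drop = FALSE]
  if (nrow(ev) == 0L) return(.empty_journal())
  pays <- lapply(ev$payload, .payload_parse)
  g <- function(f, default) vapply(pays, function(p) {
    v <- p[[f]]
    if (is.null(v)) default else v
  }, default)
  journal_entries(patient_id = ev$patient_id,
                  timestamp = ev$timestamp,
                  daytime_symptoms = g("daytime_symptoms", FALSE),
                  night_waking = g("night_waking", FALSE),
                  activity_limitation = g("activity_limitation", FALSE),
                  severe_flag = g("severe_flag", FALSE),
                  reliever_doses = as.integer(g("reliever_doses", 0L)),
                  triggers = lapply(pays, function(p)
                    as.character(unlist(p$triggers))),
                  pef = g("pef", NA_real_))
}

#' Cohort utilization summary
#'
#' Bundles the headline metrics computed from an event log: per-type totals
#' and pppw rates, the weekly-active series, the zone distribution, the
#' hour-of-day login histogram, the monthly good-day table, and the
#' per-patient weeks-with-login vector.
#'
#' @param log An [event_log()].
#' @param cohort List of [patient_profile()]s.
#' @param n_weeks Observation weeks per patient (default 52).
#' @param tz Timezone for local-clock metrics.
#' @return A list of class `"utilization_summary"`.
#' @export
utilization_summary <- function(log, cohort, n_weeks = 52L,
                                tz = "America/Toronto") {
  n <- length(cohort)
  totals <- vapply(EVENT_TYPES, function(ty)
    sum(log$events$event_type == ty), integer(1))
  rates <- vapply(totals, pppw_rate, numeric(1),
                  n_patients = n, n_weeks = n_weeks)
  entries <- journal_from_log(log)
  out <- list(n_patients = n, n_weeks = n_weeks,
              totals = totals, pppw = rates,
              weekly_active = attrition_curve(log, cohort, n_weeks = n_weeks),
              hour_histogram = hour_histogram(log, tz = tz),
              zone_distribution = if (totals[["zone_calc"]] > 0)
                zone_distribution(log) else NULL,
              good_day_monthly = good_day_monthly(entries, cohort, tz = tz),
              trigger_frequency = trigger_frequency(entries),
              weeks_with_login = weeks_with_login(log, cohort,
                                                  n_weeks = n_weeks))
  class(out) <- "utilization_summary"
  out
}

#' @export
print.utilization_summary <- function(x, ...) {
  cat("<utilization_summary>", x$n_patients, "patients,", x$n_weeks, "weeks\n")
  cat("  events per patient per week (pppw):\n")
  for (ty in names(x$pppw))
    if (x$totals[[ty]] > 0)
      cat(sprintf("    %-18s %8d  (%.2f pppw)\n", ty, x$totals[[ty]],
                  x$pppw[[ty]]))
  if (!is.null(x$zone_distribution)) {
    cat("  zone of control:\n")
    zd <- x$zone_distribution
    for (i in seq_len(nrow(zd)))
      cat(sprintf("    %-13s %6d  (%.2f%%)\n", zd$zone[i], zd$count[i],
                  100 * zd$fraction[i]))
  }
  wa <- x$weekly_active
  cat(sprintf("  weekly active: %.1f%% (week 1) -> %.1f%% (week %d)\n",
              100 * wa[1], 100 * wa[length(wa)], length(wa)))
  if (length(x$good_day_monthly$month)) {
    g <- sum(x$good_day_monthly$good); e <- sum(x$good_day_monthly$episode)
    cat(sprintf("  journaled days: %d good, %d episode (%.1f%% good)\n",
                g, e, 100 * g / (g + e)))
  }
  invisible(x)
}
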