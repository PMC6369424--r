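# Deterministic rule-based planner for the platform's three email kinds --
# welcome, daily controller-medication adherence reminders, and check-in
# emails after 7 days without access -- with randomized rotation of the
# reminder message bodies to mitigate alarm fatigue.

#' Rotating pool of reminder message bodies
#'
#' @param bodies Character vector of message texts (default: 30 generated
#'   placeholder bodies; deployments supply their own).
#' @return An object of class `"message_pool"`.
#' @export
message_pool <- function(bodies = default_message_bodies()) {
  bodies <- as.character(bodies)
  if (length(bodies) < 1L) stop("message pool must contain at least one body")
  structure(list(bodies = bodies), class = "message_pool")
}

#' Default reminder message bodies
#'
#' Thirty placeholder adherence-reminder texts; real deployments replace
#' them via [message_pool()].
#' @return Character vector of length 30.
#' @export
default_message_bodies <- function() {
  sprintf("Reminder %02d: it's time to take your controller medication.",
          seq_len(30))
}

#' Draw the next message body from the pool
#'
#' Uniform over the pool, excluding the immediately previous selection when
#' the pool has more than one body (no immediate repeats).  Uses R's
#' current RNG stream, so draws are reproducible under `set.seed()`.
#'
#' @param pool A [message_pool()].
#' @param prev 1-based id of the previous selection, or `NA`/`NULL` for the
#'   first draw.
#' @return Integer message id in `1:length(pool$bodies)`.
#' @export
#' @examples
#' set.seed(1)
#' p <- message_pool()
#' id1 <- select_body(p)
#' id2 <- select_body(p, prev = id1)  # never equal to id1
select_body <- function(pool, prev = NULL) {
  stopifnot(inherits(pool, "message_pool"))
  n <- length(pool$bodies)
  if (n == 1L) return(1L)
  ids <- seq_len(n)
  if (!is.null(prev) && !is.na(prev)) ids <- ids[ids != prev]
  ids[sample.int(length(ids), 1L)]
}

#' Plan reminder emails for one patient over a horizon
#'
#' Applies the platform's rule set over the half-open horizon
#' `[start, end)`:
#' * one **welcome** email at the enrollment instant (if within the
#'   horizon, and at most once per patient);
#' * one **adherence** email per local calendar day at the profile's
#'   reminder time (default 19:00 local) iff at least one controller
#'   medication is prescribed -- uncapped, regardless of platform use;
#' * one **check_in** email at reminder time on each day `D` such that the
#'   patient logged in on none of the 7 local calendar days ending at `D`
#'   and no check-in was sent in those 7 days (so a fully inactive patient
#'   is re-contacted every 7 days).
#'
#' With `email_enabled = FALSE` the plan is empty (not an error).  Message
#' bodies for adherence and check-in emails rotate through `pool` with no
#' immediate repeats; the welcome email uses body 1.  Given the same
#' profile, log, horizon and seed the plan is identical.
#'
#' @param profile A [patient_profile()].
#' @param log An [event_log()]; its `login` events for this patient define
#'   inactivity.
#' @param horizon Length-2 start/end instants, `[start, end)`.
#' @param pool A [message_pool()].
#' @param seed Optional integer seed for the body rotation.
#' @return A `data.frame` with columns `patient_id`, `timestamp` (UTC),
#'   `email_kind` (`welcome`/`adherence`/`check_in`), `message_id`, sorted
#'   by time.
#' @export
plan_reminders <- function(profile, log, horizon, pool = message_pool(),
                           seed = NULL) {
  v <- validate_profile(profile)
  if (length(v)) stop("invalid profile: ", paste(v, collapse = "; "))
  empty <- data.frame(patient_id = character(0),
                      timestamp = .as_utc(character(0)),
                      email_kind = character(0),
                      message_id = integer(0), stringsAsFactors = FALSE)
  if (!profile$email_enabled) return(empty)

  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }

  horizon <- .as_utc(horizon)
  start <- horizon[1L]; end <- horizon[2L]
  if (!(start < end)) stop("horizon start must be before end")
  tz <- profile$tz

  has_controller <- any(vapply(profile$medications, function(m)
    identical(m$med_class, "controller"), logical(1)))

  logins <- log$events[log$events$event_type == "login" &
                         log$events$patient_id == profile$patient_id, ,
                       drop = FALSE]
  login_days <- unique(.local_day(logins$timestamp, tz = tz))

  days <- seq(.local_day(start, tz = tz), .local_day(end, tz = tz), by = "day")
  send_at <- .as_utc(.local_clock_instant(days, profile$reminder_time, tz))
  in_horizon <- send_at >= start & send_at < end

  kinds <- character(0); times <- .as_utc(character(0))

  if (profile$enrollment >= start && profile$enrollment < end) {
    kinds <- "welcome"; times <- profile$enrollment
  }

  if (has_controller) {
    adh <- send_at[in_horizon]
    kinds <- c(kinds, rep("adherence", length(adh)))
    times <- c(times, adh)
  }

  # check-in scan: 7-calendar-day inactivity, 7-day suppression between
  # check-ins
  last_checkin_day <- as.Date(NA)
  ci_days <- as.Date(character(0))
  for (i in seq_along(days)) {
    if (!in_horizon[i]) next
    d <- days[i]
    window <- seq(d - 6, d, by = "day")
    if (any(window %in% login_days)) next
    if (!is.na(last_checkin_day) && (d - last_checkin_day) < 7) next
    # never nag before the patient has had 7 full calendar days on the
    # platform
    if ((d - .local_day(profile$enrollment, tz = tz)) < 6) next
    ci_days <- c(ci_days, d)
    last_checkin_day <- d
  }
  if (length(ci_days)) {
    ci_at <- .as_utc(.local_clock_instant(ci_days, profile$reminder_time, tz))
    kinds <- c(kinds, rep("check_in", length(ci_at)))
    times <- c(times, ci_at)
  }

  if (length(kinds) == 0L) return(empty)
  ord <- order(times, match(kinds, c("welcome", "adherence", "check_in")))
  kinds <- kinds[ord]; times <- times[ord]

  ids <- integer(length(kinds))
  prev <- NA_integer_
  for (i in seq_along(kinds)) {
    if (kinds[i] == "welcome") {
      ids[i] <- 1L
    } else {
      ids[i] <- select_body(pool, prev)
      prev <- ids[i]
    }
  }
  data.frame(patient_id = profile$patient_id,
             timestamp = .as_utc(times),
             email_kind = kinds,
             message_id = ids, stringsAsFactors = FALSE)
}

#' Append a reminder plan to an event log as email_sent events
#'
#' @param log An [event_log()].
#' @param plan Output of [plan_reminders()].
#' @return The extended [event_log()].
#' @export
emails_to_events <- function(log, plan) {
  if (nrow(plan) == 0L) return(log)
  pay <- sprintf('{"email_kind":"%s","message_id":%d}',
                 plan$email_kind, plan$message_id)
  ev <- .event_df(plan$patient_id, plan$timestamp, "email_sent", pay)
  log$events <- rbind(log$events, ev)
  log$events <- log$events[order(log$events$timestamp), , drop = FALSE]
  rownames(log$events) <- NULL
  log
}
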