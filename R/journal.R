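# Patient-day self-reports (symptoms, reliever use, triggers, optional peak
# flow) and the rolling-window aggregation that feeds the zone engine.

#' Build a table of journal entries
#'
#' One row per self-report.  All arguments are recycled to the length of
#' `timestamp`.  `triggers` is a list column (character vector per entry);
#' `pef` is the optional peak expiratory flow in L/min, `NA` when not
#' logged.
#'
#' @param patient_id Patient identifier(s).
#' @param timestamp Entry timestamps (ISO-8601 strings or POSIXct; stored
#'   UTC).
#' @param daytime_symptoms,night_waking,activity_limitation,severe_flag
#'   Logical symptom flags; `severe_flag` marks danger-level symptoms.
#' @param reliever_doses Non-negative count of reliever doses taken.
#' @param triggers List of character vectors of trigger labels.
#' @param pef Optional peak flow in L/min (`NA` when absent, must be > 0
#'   when present).
#' @return A `data.frame` of class `"journal_entries"`.
#' @export
#' @examples
#' journal_entries("p1", "2013-02-01T12:00:00Z",
#'                 daytime_symptoms = TRUE, reliever_doses = 1,
#'                 triggers = list("dust"))
journal_entries <- function(patient_id, timestamp,
                            daytime_symptoms = FALSE,
                            night_waking = FALSE,
                            activity_limitation = FALSE,
                            severe_flag = FALSE,
                            reliever_doses = 0L,
                            triggers = list(character(0)),
                            pef = NA_real_) {
  ts <- .as_utc(timestamp)
  n <- length(ts)
  if (!is.list(triggers)) triggers <- list(as.character(triggers))
  out <- data.frame(patient_id = rep_len(as.character(patient_id), n),
                    timestamp = ts,
                    daytime_symptoms = rep_len(as.logical(daytime_symptoms), n),
                    night_waking = rep_len(as.logical(night_waking), n),
                    activity_limitation = rep_len(as.logical(activity_limitation), n),
                    severe_flag = rep_len(as.logical(severe_flag), n),
                    reliever_doses = rep_len(as.integer(reliever_doses), n),
                    pef = rep_len(as.numeric(pef), n),
                    stringsAsFactors = FALSE)
  out$triggers <- rep_len(triggers, n)
  if (any(out$reliever_doses < 0, na.rm = TRUE))
    stop("reliever_doses must be >= 0")
  if (any(!is.na(out$pef) & out$pef <= 0))
    stop("pef must be > 0 when present")
  class(out) <- c("journal_entries", "data.frame")
  out
}

.empty_journal <- function() journal_entries(character(0), as.POSIXct(character(0), tz = "UTC"))

#' Aggregate journal entries over a trailing window
#'
#' Summarizes the entries in the half-open window
#' `(as_of - window_days, as_of]` into the counts consumed by
#' [classify_symptoms()].  `symptom_days` and `activity_limit_days` count
#' *distinct local calendar days* with at least one flagged entry (multiple
#' entries on one day are not double counted); `night_wakings` counts
#' flagged entries; `reliever_doses_total` sums doses; `latest_pef` is the
#' most recent in-window peak flow.  An empty window is valid and yields
#' zero counts.
#'
#' @param entries A [journal_entries()] table (one patient's entries).
#' @param as_of Assessment instant.
#' @param window_days Window length in days (default 7: guideline control
#'   criteria are weekly).
#' @param tz Timezone for calendar-day bucketing.
#' @return A list of class `"window_aggregate"` with fields `n_entries`,
#'   `symptom_days`, `night_wakings`, `activity_limit_days`,
#'   `reliever_doses_total`, `severe_any`, `latest_pef` (`NA` if none) and
#'   `window` (start/end instants).
#' @export
aggregate_window <- function(entries, as_of, window_days = 7, tz = "UTC") {
  stopifnot(window_days >= 1)
  as_of <- .as_utc(as_of)
  start <- as_of - window_days * 86400
  ts <- entries$timestamp
  keep <- ts > start & ts <= as_of
  e <- entries[keep, , drop = FALSE]
  n <- nrow(e)
  if (n == 0L) {
    agg <- list(n_entries = 0L, symptom_days = 0L, night_wakings = 0L,
                activity_limit_days = 0L, reliever_doses_total = 0L,
                severe_any = FALSE, latest_pef = NA_real_,
                window = c(start = start, end = as_of))
    class(agg) <- "window_aggregate"
    return(agg)
  }
  day <- .local_day(e$timestamp, tz = tz)
  latest_pef <- NA_real_
  has_pef <- !is.na(e$pef)
  if (any(has_pef)) {
    i <- which(has_pef)
    latest_pef <- e$pef[i[which.max(as.numeric(e$timestamp[i]))]]
  }
  agg <- list(n_entries = n,
              symptom_days = length(unique(day[e$daytime_symptoms])),
              night_wakings = sum(e$night_waking),
              activity_limit_days = length(unique(day[e$activity_limitation])),
              reliever_doses_total = sum(e$reliever_doses),
              severe_any = any(e$severe_flag),
              latest_pef = latest_pef,
              window = c(start = start, end = as_of))
  class(agg) <- "window_aggregate"
  agg
}

#' Classify journaled days as good days or symptom-episode days
#'
#' A *good day* is a journaled day with no symptoms: all four symptom flags
#' false **and** zero reliever doses (reliever use implies symptoms).  Any
#' flag or reliever dose makes it an episode day.
#'
#' @param entries A [journal_entries()] table.
#' @return Character vector, one of `"good_day"` / `"episode_day"` per
#'   entry.
#' @export
classify_day <- function(entries) {
  bad <- entries$daytime_symptoms | entries$night_waking |
    entries$activity_limitation | entries$severe_flag |
    entries$reliever_doses > 0
  ifelse(bad, "episode_day", "good_day")
}
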