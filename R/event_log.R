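# Append-only, time-stamped, typed event store: every record carries a
# patient id, a UTC timestamp, a type from a closed enum, and a
# type-specific JSON payload.  This is the substrate all utilization
# analytics run on.  File formats: CSV (payload as a JSON-encoded string
# column) and JSON lines (one event object per line).

#' Event types recognized by the log
#' @format Character vector of the closed event-type enum.
#' @export
EVENT_TYPES <- c("login", "journal", "medication_report", "peakflow_report",
                 "zone_calc", "email_sent", "reset", "clinic_visit")

.payload_json <- function(x) {
  if (is.null(x) || length(x) == 0L) return("")
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"))
}

.payload_parse <- function(s) {
  if (is.na(s) || !nzchar(s)) return(list())
  jsonlite::parse_json(s)
}

.event_df <- function(patient_id = character(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"),
                      event_type = character(0),
                      payload = character(0)) {
  data.frame(patient_id = as.character(patient_id),
             timestamp = .as_utc(timestamp),
             event_type = as.character(event_type),
             payload = as.character(payload),
             stringsAsFactors = FALSE)
}

#' Construct a single event record
#'
#' @param patient_id Non-empty patient identifier.
#' @param timestamp Event instant (ISO-8601 string or POSIXct; stored UTC).
#' @param event_type One of [EVENT_TYPES].
#' @param payload Optional named list of type-specific fields (encoded as
#'   JSON).
#' @return One-row event `data.frame`.
#' @export
event_record <- function(patient_id, timestamp, event_type, payload = NULL) {
  if (!is.character(patient_id) || !nzchar(patient_id))
    stop("patient_id must be a non-empty string")
  if (!(event_type %in% EVENT_TYPES))
    stop("unknown event_type '", event_type, "'; must be one of: ",
         paste(EVENT_TYPES, collapse = ", "))
  ts <- .as_utc(timestamp)
  if (is.na(ts)) stop("timestamp must be a valid ISO-8601 UTC instant")
  .event_df(patient_id, ts, event_type, .payload_json(payload))
}

#' Create an event log
#'
#' @param events Event `data.frame` (columns `patient_id`, `timestamp`,
#'   `event_type`, `payload`), or `NULL` for an empty log.
#' @param cohort_id Cohort identifier.
#' @param window Observation window, length-2 start/end; defaults to the
#'   range of the event timestamps (or an empty degenerate window).
#' @return An object of class `"event_log"` with fields `events`,
#'   `cohort_id`, `window`.
#' @export
event_log <- function(events = NULL, cohort_id = "cohort", window = NULL) {
  if (is.null(events)) events <- .event_df()
  stopifnot(all(c("patient_id", "timestamp", "event_type", "payload") %in%
                  names(events)))
  events$timestamp <- .as_utc(events$timestamp)
  bad <- which(!(events$event_type %in% EVENT_TYPES))
  if (length(bad))
    stop("unknown event_type at record ", bad[1L], ": '",
         events$event_type[bad[1L]], "'")
  if (is.null(window)) {
    window <- if (nrow(events)) range(events$timestamp)
              else .as_utc(c("1970-01-01", "1970-01-01"))
  } else {
    window <- .as_utc(window)
    if (nrow(events)) {
      out <- events$timestamp < window[1L] | events$timestamp > window[2L]
      if (any(out))
        stop("record ", which(out)[1L], " outside the observation window")
    }
  }
  structure(list(events = events, cohort_id = as.character(cohort_id)[1L],
                 window = window),
            class = "event_log")
}

#' Number of records in an event log
#' @param log An [event_log()].
#' @return Integer count.
#' @export
n_events <- function(log) nrow(log$events)

#' Append one record to an event log
#'
#' The log is value-semantic: the original is unchanged and a new log with
#' the record appended is returned.  Records outside the observation window
#' are rejected.
#'
#' @param log An [event_log()].
#' @param record An [event_record()] (one-row data frame).
#' @return The extended [event_log()].
#' @export
append_event <- function(log, record) {
  stopifnot(inherits(log, "event_log"))
  if (!(record$event_type[1L] %in% EVENT_TYPES))
    stop("unknown event_type '", record$event_type[1L], "'")
  ts <- .as_utc(record$timestamp[1L])
  if (ts < log$window[1L] || ts > log$window[2L])
    stop("rejected: timestamp ", .format_utc(ts),
         " outside the observation window [",
         .format_utc(log$window[1L]), ", ", .format_utc(log$window[2L]), "]")
  log$events <- rbind(log$events, record)
  log
}

#' Filter an event log by type and half-open interval
#'
#' Keeps exactly the records with the requested `event_type` (if given) and
#' timestamp in `[start, end)` (if an interval is given).
#'
#' @param log An [event_log()].
#' @param event_type Optional type from [EVENT_TYPES].
#' @param interval Optional length-2 start/end, half-open `[start, end)`.
#' @return A new [event_log()] with the matching records (window
#'   unchanged).
#' @export
filter_events <- function(log, event_type = NULL, interval = NULL) {
  stopifnot(inherits(log, "event_log"))
  keep <- rep_len(TRUE, nrow(log$events))
  if (!is.null(event_type)) {
    if (!(event_type %in% EVENT_TYPES))
      stop("unknown event_type '", event_type, "'")
    keep <- keep & log$events$event_type == event_type
  }
  if (!is.null(interval)) {
    interval <- .as_utc(interval)
    if (!(interval[1L] <= interval[2L])) stop("interval start must be <= end")
    keep <- keep & log$events$timestamp >= interval[1L] &
      log$events$timestamp < interval[2L]
  }
  out <- log
  out$events <- log$events[keep, , drop = FALSE]
  rownames(out$events) <- NULL
  out
}

#' @export
print.event_log <- function(x, ...) {
  cat("<event_log>", x$cohort_id, "--", nrow(x$events), "events,",
      length(unique(x$events$patient_id)), "patients\n")
  cat("  window:", .format_utc(x$window[1L]), "to",
      .format_utc(x$window[2L]), "\n")
  if (nrow(x$events)) {
    tab <- table(x$events$event_type)
    cat("  ", paste(names(tab), as.integer(tab), sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

.guess_format <- function(path, format) {
  if (format != "auto") return(format)
  if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
}

#' Write an event log to disk
#'
#' CSV: header `patient_id,timestamp,event_type,payload`, ISO-8601 UTC
#' timestamps, payload as a JSON-encoded string column.  JSON lines: one
#' event object per line with the payload as a nested object.
#'
#' @param log An [event_log()].
#' @param path Output file.
#' @param format `"csv"`, `"jsonl"`, or `"auto"` (by file extension).
#' @return `path`, invisibly.
#' @export
write_events <- function(log, path, format = c("auto", "csv", "jsonl")) {
  format <- .guess_format(path, match.arg(format))
  ev <- log$events
  if (format == "csv") {
    out <- data.frame(patient_id = ev$patient_id,
                      timestamp = .format_utc(ev$timestamp),
                      event_type = ev$event_type,
                      payload = ev$payload,
                      stringsAsFactors = FALSE)
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  } else {
    lines <- vapply(seq_len(nrow(ev)), function(i) {
      pay <- ev$payload[i]
      paste0('{"patient_id":', .payload_json(ev$patient_id[i]),
             ',"timestamp":"', .format_utc(ev$timestamp[i]),
             '","event_type":"', ev$event_type[i], '"',
             if (nzchar(pay)) paste0(',"payload":', pay) else "", "}")
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read an event log from disk
#'
#' Counterpart of [write_events()]; `write_events()` then `read_events()`
#' is the identity on records, field for field.  Malformed rows raise an
#' error naming the line number and the offending field.
#'
#' @param path Input file (CSV or JSON lines).
#' @param format `"csv"`, `"jsonl"`, or `"auto"` (by file extension).
#' @param cohort_id Cohort identifier to attach.
#' @param window Optional observation window; defaults to the record range.
#' @return An [event_log()].
#' @export
read_events <- function(path, format = c("auto", "csv", "jsonl"),
                        cohort_id = "cohort", window = NULL) {
  if (!file.exists(path)) stop("event-log file not found: ", path)
  format <- .guess_format(path, match.arg(format))
  if (format == "csv") {
    raw <- utils::read.csv(path, colClasses = "character")
    need <- c("patient_id", "timestamp", "event_type", "payload")
    miss <- setdiff(need, names(raw))
    if (length(miss))
      stop("schema error in ", path, ": missing column(s) ",
           paste(miss, collapse = ", "))
    if (nrow(raw) == 0L) return(event_log(cohort_id = cohort_id, window = window))
    ts <- .as_utc(raw$timestamp)
    if (anyNA(ts))
      stop("line ", which(is.na(ts))[1L] + 1L,
           ": field 'timestamp' is not a valid ISO-8601 instant")
    bad <- which(!(raw$event_type %in% EVENT_TYPES))
    if (length(bad))
      stop("line ", bad[1L] + 1L, ": field 'event_type' has unknown value '",
           raw$event_type[bad[1L]], "'")
    bad <- which(is.na(raw$patient_id) | !nzchar(raw$patient_id))
    if (length(bad))
      stop("line ", bad[1L] + 1L, ": field 'patient_id' is empty")
    ev <- .event_df(raw$patient_id, ts, raw$event_type, raw$payload)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) return(event_log(cohort_id = cohort_id, window = window))
    n <- length(lines)
    pid <- character(n); tss <- character(n); ety <- character(n)
    pay <- character(n)
    for (i in seq_len(n)) {
      obj <- tryCatch(jsonlite::parse_json(lines[i]),
                      error = function(e) NULL)
      if (is.null(obj)) stop("line ", i, ": not valid JSON")
      for (f in c("patient_id", "timestamp", "event_type"))
        if (is.null(obj[[f]])) stop("line ", i, ": field '", f, "' missing")
      if (!(obj$event_type %in% EVENT_TYPES))
        stop("line ", i, ": field 'event_type' has unknown value '",
             obj$event_type, "'")
      pid[i] <- obj$patient_id
      tss[i] <- obj$timestamp
      ety[i] <- obj$event_type
      pay[i] <- .payload_json(obj$payload)
    }
    ts <- .as_utc(tss)
    if (anyNA(ts))
      stop("line ", which(is.na(ts))[1L],
           ": field 'timestamp' is not a valid ISO-8601 instant")
    ev <- .event_df(pid, ts, ety, pay)
  }
  event_log(ev, cohort_id = cohort_id, window = window)
}
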