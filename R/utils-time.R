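# Internal time helpers. All stored timestamps are POSIXct in UTC; local
# clock logic (reminder times, calendar days, hour-of-day) converts through
# a per-profile IANA timezone.

.as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (inherits(x, "Date")) {
    return(as.POSIXct(as.character(x), tz = "UTC"))
  }
  if (is.numeric(x)) {
    return(as.POSIXct(x, origin = "1970-01-01", tz = "UTC"))
  }
  if (is.character(x)) {
    x1 <- sub("Z$", "", x)
    x1 <- sub("T", " ", x1, fixed = TRUE)
    out <- as.POSIXct(strptime(x1, "%Y-%m-%d %H:%M:%OS", tz = "UTC"))
    day_only <- is.na(out) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x1)
    if (any(day_only))
      out[day_only] <- as.POSIXct(strptime(paste(x1[day_only], "00:00:00"),
                                           "%Y-%m-%d %H:%M:%S", tz = "UTC"))
    return(out)  # unparseable strings stay NA; callers report the line
  }
  stop("cannot interpret timestamp of class ", paste(class(x), collapse = "/"))
}

.format_utc <- function(x) {
  format(.as_utc(x), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

# floor to local calendar day, returned as Date
.local_day <- function(t, tz = "UTC") {
  as.Date(format(t, "%Y-%m-%d", tz = tz))
}

.local_hour <- function(t, tz = "UTC") {
  as.integer(format(t, "%H", tz = tz))
}

# 1-based week index relative to an enrollment instant (week 1 = first
# 7 x 24 h from enrollment); values < 1 or > n_weeks are returned as is and
# filtered by callers
.week_index <- function(t, enrollment) {
  as.integer(floor(as.numeric(difftime(t, enrollment, units = "days")) / 7)) + 1L
}

# 1-based enrollment-relative month index over a 52-week year
# (30.333-day months so that months 1..12 tile weeks 1..52)
.month_index <- function(t, enrollment, n_weeks = 52L) {
  d <- as.numeric(difftime(t, enrollment, units = "days"))
  as.integer(floor(d / (7 * n_weeks / 12))) + 1L
}

# OlsonNames() re-reads the tz database on every call; cache it
.olson_cache <- new.env(parent = emptyenv())
.olson <- function() {
  if (is.null(.olson_cache$v)) .olson_cache$v <- OlsonNames()
  .olson_cache$v
}

.is_clock_time <- function(x) {
  is.character(x) && length(x) == 1L &&
    grepl("^([01]?[0-9]|2[0-3]):[0-5][0-9]$", x)
}

# the instant of local clock time `hm` ("HH:MM") on the local calendar day
# containing (or given as) `day`, in timezone tz, returned as UTC POSIXct
.local_clock_instant <- function(day, hm, tz) {
  as.POSIXct(paste(as.character(day), hm), tz = tz)
}
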