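# Air Quality Health Index (AQHI) risk banding and message lookup.  The
# AQHI is a 1-10(+) scale; readings come from a locally supplied CSV file
# (columns: location, timestamp, value) rather than a live feed.

#' Default AQHI band messages
#'
#' Asthma-oriented risk-reduction messages per AQHI band.  Deployments
#' supply their own table.
#'
#' @return Named character vector over bands `low`, `moderate`, `high`,
#'   `very_high`.
#' @export
aqhi_messages <- function() {
  c(low = "Ideal air quality: enjoy your usual outdoor activities.",
    moderate = "Consider reducing strenuous outdoor activity if you experience symptoms.",
    high = "Reduce or reschedule strenuous outdoor activity; keep your reliever inhaler at hand.",
    very_high = "Avoid strenuous outdoor activity; follow your asthma action plan closely.")
}

#' Band an AQHI value and look up its risk-reduction message
#'
#' Health Canada category cut points: 1--3 low risk, 4--6 moderate, 7--10
#' high, above 10 very high.  Banding is a total, monotone step function of
#' the value.  Vectorized.
#'
#' @param value AQHI reading(s), numeric `>= 1` (values above 10 allowed).
#' @param messages Named character vector mapping bands to message text.
#' @return A `data.frame` with columns `value`, `band`, `message`.
#' @export
#' @examples
#' aqhi_band(c(1, 3, 4, 7, 11))
aqhi_band <- function(value, messages = aqhi_messages()) {
  value <- as.numeric(value)
  if (any(!is.finite(value)) || any(value < 1))
    stop("invalid reading: AQHI values must be >= 1")
  stopifnot(all(c("low", "moderate", "high", "very_high") %in% names(messages)))
  band <- cut(value, breaks = c(-Inf, 3, 6, 10, Inf),
              labels = c("low", "moderate", "high", "very_high"),
              right = TRUE)
  band <- as.character(band)
  data.frame(value = value, band = band,
             message = unname(messages[band]),
             stringsAsFactors = FALSE)
}

#' Read AQHI readings from a local CSV file
#'
#' Expects columns `location`, `timestamp` (ISO-8601), `value`.
#'
#' @param path CSV file.
#' @return `data.frame` with `location`, `timestamp` (UTC POSIXct),
#'   `value`.
#' @export
read_aqhi <- function(path) {
  if (!file.exists(path)) stop("AQHI file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("location", "timestamp", "value")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("schema error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  ts <- .as_utc(raw$timestamp)
  if (anyNA(ts))
    stop("line ", which(is.na(ts))[1L] + 1L,
         ": field 'timestamp' is not a valid ISO-8601 instant")
  val <- as.numeric(raw$value)
  if (any(!is.finite(val)) || any(val < 1))
    stop("line ", which(!is.finite(val) | val < 1)[1L] + 1L,
         ": field 'value' must be a number >= 1")
  data.frame(location = as.character(raw$location), timestamp = ts,
             value = val, stringsAsFactors = FALSE)
}
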