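# The core decision algorithm: map a patient's recent journal window and
# peak-flow thresholds to a traffic-light zone of control, with an explicit
# insufficient-data outcome and reset-after-action-plan semantics.
#
# Zones: green (in control) < yellow (uncontrolled) < red (dangerously
# uncontrolled); components combine worst-of.

.ZONE_RANK <- c(green = 1L, yellow = 2L, red = 3L)

#' Symptom-based control criteria
#'
#' Weekly thresholds a patient must stay within to be in the green zone, in
#' the spirit of guideline control tables.  Defaults: daytime symptoms on
#' fewer than 4 days/week, no night waking, at most 3 reliever doses/week,
#' no activity limitation; danger-level symptoms are red regardless.  All
#' limits are configurable.
#'
#' @param max_symptom_days_per_week Green allows at most this many distinct
#'   symptom days (default 3, i.e. green requires < 4).
#' @param max_night_wakings Green allows at most this many night wakings
#'   (default 0).
#' @param max_reliever_doses_per_week Green allows at most this many
#'   reliever doses (default 3).
#' @param allow_activity_limitation If `FALSE` (default) any
#'   activity-limited day excludes green.
#' @return An object of class `"symptom_criteria"`.
#' @export
symptom_criteria <- function(max_symptom_days_per_week = 3L,
                             max_night_wakings = 0L,
                             max_reliever_doses_per_week = 3L,
                             allow_activity_limitation = FALSE) {
  stopifnot(max_symptom_days_per_week >= 0, max_night_wakings >= 0,
            max_reliever_doses_per_week >= 0)
  structure(list(max_symptom_days_per_week = as.integer(max_symptom_days_per_week),
                 max_night_wakings = as.integer(max_night_wakings),
                 max_reliever_doses_per_week = as.integer(max_reliever_doses_per_week),
                 allow_activity_limitation = isTRUE(allow_activity_limitation)),
            class = "symptom_criteria")
}

#' Band a peak-flow measurement into a control zone
#'
#' Lower bounds are inclusive: flow at exactly `green_lower` is green, at
#' exactly `yellow_lower` is yellow, and anything below `yellow_lower` is
#' red.  Vectorized over `pef`.
#'
#' @param pef Peak expiratory flow(s) in L/min; must be > 0.
#' @param thresholds Absolute [zone_thresholds()].
#' @return Character vector of `"green"`, `"yellow"`, `"red"`.
#' @export
#' @examples
#' th <- zone_thresholds(450, 300)
#' classify_pef(c(450, 449, 299), th)
classify_pef <- function(pef, thresholds) {
  .check_thresholds(thresholds)
  if (identical(thresholds$source, "fraction_of_personal_best"))
    stop("thresholds must be absolute; resolve with resolve_pef_thresholds()")
  if (any(!is.finite(pef)) || any(pef <= 0))
    stop("invalid measurement: pef must be a positive flow")
  ifelse(pef >= thresholds$green_lower, "green",
         ifelse(pef < thresholds$yellow_lower, "red", "yellow"))
}

#' Classify a symptom aggregate into a control zone
#'
#' Red if any danger-level symptoms were reported; green if every criterion
#' in `criteria` is met; yellow otherwise.  Requires a non-empty aggregate
#' (`n_entries > 0`): with no journal data the symptom component simply
#' does not exist (see [assess_zone()]).
#'
#' @param agg A [aggregate_window()] result with `n_entries > 0`.
#' @param criteria A [symptom_criteria()].
#' @return `"green"`, `"yellow"` or `"red"`.
#' @export
classify_symptoms <- function(agg, criteria = symptom_criteria()) {
  if (!isTRUE(agg$n_entries > 0))
    stop("classify_symptoms requires a non-empty aggregate (n_entries > 0)")
  if (isTRUE(agg$severe_any)) return("red")
  ok <- agg$symptom_days <= criteria$max_symptom_days_per_week &&
    agg$night_wakings <= criteria$max_night_wakings &&
    agg$reliever_doses_total <= criteria$max_reliever_doses_per_week &&
    (criteria$allow_activity_limitation || agg$activity_limit_days == 0)
  if (ok) "green" else "yellow"
}

#' Drop journal history consumed by an executed action plan
#'
#' The zone of control resets once the action plan has been executed: only
#' entries *strictly after* the latest reset event at or before `as_of`
#' survive (the executed plan consumes the entries that triggered it).
#' With no applicable reset event the entries are returned unchanged.
#'
#' @param entries A [journal_entries()] table.
#' @param reset_events Reset instants (any order; sorted internally).
#' @param as_of Assessment instant; resets after it are ignored.
#' @return The surviving subset of `entries`.
#' @export
apply_reset <- function(entries, reset_events, as_of) {
  as_of <- .as_utc(as_of)
  if (length(reset_events) == 0L) return(entries)
  rs <- sort(.as_utc(reset_events))
  rs <- rs[rs <= as_of]
  if (length(rs) == 0L) return(entries)
  cut <- rs[length(rs)]
  entries[entries$timestamp > cut, , drop = FALSE]
}

#' Assess a patient's current zone of control
#'
#' Combines the symptom component (from the trailing journal window) and
#' the peak-flow component (latest in-window measurement banded against the
#' resolved thresholds) by worst-of: red > yellow > green.  When neither
#' component exists -- no in-window entries and no in-window peak flow --
#' the result is `insufficient` rather than a default zone.  If the plan
#' relies on peak flow but thresholds cannot be resolved, the result is
#' likewise `insufficient`.  For green/yellow/red the result carries the
#' matching instruction record from the action plan.
#'
#' @param profile A valid [patient_profile()].
#' @param plan An [action_plan()]; defaults to the profile's embedded plan.
#' @param entries The patient's [journal_entries()] (already reset-filtered
#'   if reset semantics apply; see [apply_reset()]).
#' @param as_of Assessment instant.
#' @param window_days Trailing window length in days.
#' @param criteria [symptom_criteria()] for the symptom component.
#' @param green_frac,red_frac Fractions passed to
#'   [resolve_pef_thresholds()] when thresholds are fractional/absent.
#' @return A list of class `"zone_result"`: `zone` (`"green"`, `"yellow"`,
#'   `"red"`, `"insufficient"`), `basis` (`"symptoms_only"`, `"pef_only"`,
#'   `"both"`, `"none"`), `as_of`, `contributing_window`, and `instruction`
#'   (`NULL` for insufficient).
#' @export
assess_zone <- function(profile, plan = profile$action_plan, entries,
                        as_of, window_days = 7,
                        criteria = symptom_criteria(),
                        green_frac = 0.90, red_frac = 0.60) {
  v <- validate_profile(profile)
  if (length(v)) stop("invalid profile: ", paste(v, collapse = "; "))
  if (is.null(plan) || !inherits(plan, "action_plan"))
    stop("assess_zone requires an action_plan")
  as_of <- .as_utc(as_of)

  agg <- aggregate_window(entries, as_of, window_days = window_days,
                          tz = profile$tz)

  needs_pef <- plan_requires_pef(plan)
  thresholds <- tryCatch(
    resolve_pef_thresholds(profile, green_frac = green_frac, red_frac = red_frac),
    error = function(e) NULL)

  pef_zone <- NULL
  if (!is.na(agg$latest_pef)) {
    if (is.null(thresholds)) {
      if (needs_pef) {
        res <- list(zone = "insufficient", basis = "none", as_of = as_of,
                    contributing_window = agg$window, instruction = NULL)
        class(res) <- "zone_result"
        return(res)
      }
      # pef logged but unbandable and plan does not rely on it: ignore
    } else {
      pef_zone <- classify_pef(agg$latest_pef, thresholds)
    }
  }

  sym_zone <- if (agg$n_entries > 0L) classify_symptoms(agg, criteria) else NULL

  basis <- if (!is.null(sym_zone) && !is.null(pef_zone)) "both"
           else if (!is.null(sym_zone)) "symptoms_only"
           else if (!is.null(pef_zone)) "pef_only"
           else "none"
  zone <- if (basis == "none") "insufficient"
          else names(.ZONE_RANK)[max(.ZONE_RANK[c(sym_zone, pef_zone)])]

  res <- list(zone = zone, basis = basis, as_of = as_of,
              contributing_window = agg$window,
              instruction = if (zone == "insufficient") NULL else plan[[zone]])
  class(res) <- "zone_result"
  res
}

#' @export
print.zone_result <- function(x, ...) {
  cat("<zone_result>", toupper(x$zone),
      sprintf("(basis: %s)", x$basis), "\n")
  cat("  as of:", .format_utc(x$as_of), "\n")
  if (!is.null(x$instruction) && nzchar(x$instruction$instructions))
    cat("  action plan:", x$instruction$instructions, "\n")
  invisible(x)
}
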