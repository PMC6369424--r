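# Provider-authored "asthma app prescription": medications, peak-flow zone
# thresholds, per-zone action plan, and the patient account settings that
# drive reminders.  The platform never authors the plan itself -- it is
# provider input, validated and consumed downstream.

#' Create a medication record
#'
#' @param name Medication name; non-empty string.
#' @param med_class `"controller"` (maintenance anti-inflammatory) or
#'   `"reliever"` (fast-acting bronchodilator).
#' @param schedule Free-form dose description, e.g. `"2 puffs BID"`.
#' @return An object of class `"medication"`.
#' @export
#' @examples
#' medication("budesonide", "controller", "200 ug BID")
medication <- function(name, med_class = c("controller", "reliever"),
                       schedule = "") {
  med_class <- match.arg(med_class)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name, med_class = med_class,
                 schedule = as.character(schedule)[1L]),
            class = "medication")
}

#' Peak-flow zone thresholds
#'
#' Lower bounds of the green and yellow control zones.  With
#' `source = "absolute"` the values are flows in L/min; with
#' `source = "fraction_of_personal_best"` they are fractions in (0, 1] and
#' must be resolved against the patient's personal best with
#' [resolve_pef_thresholds()] before use.
#'
#' @param green_lower Lower bound of the green zone (inclusive).
#' @param yellow_lower Lower bound of the yellow zone (inclusive); flows
#'   below it are red.
#' @param source `"absolute"` or `"fraction_of_personal_best"`.
#' @return An object of class `"zone_thresholds"`.
#' @export
zone_thresholds <- function(green_lower, yellow_lower,
                            source = c("absolute", "fraction_of_personal_best")) {
  source <- match.arg(source)
  structure(list(green_lower = as.numeric(green_lower)[1L],
                 yellow_lower = as.numeric(yellow_lower)[1L],
                 source = source),
            class = "zone_thresholds")
}

.check_thresholds <- function(th) {
  if (!is.list(th) || is.null(th$green_lower) || is.null(th$yellow_lower))
    stop("invalid zone thresholds object")
  if (!isTRUE(th$green_lower > th$yellow_lower) || !isTRUE(th$yellow_lower > 0))
    stop("invalid zone thresholds: require green_lower > yellow_lower > 0")
  invisible(th)
}

#' One zone's entry in an action plan
#'
#' @param zone `"green"`, `"yellow"` or `"red"`.
#' @param instructions Provider-authored instruction text for this zone.
#' @param medication_adjustments Named character vector or list mapping
#'   medication names to adjustment text.
#' @param requires_pef Does this zone's assessment rely on peak-flow
#'   banding (i.e. was peak flow part of the plan)?
#' @return An object of class `"zone_instruction"`.
#' @export
zone_instruction <- function(zone = c("green", "yellow", "red"),
                             instructions = "",
                             medication_adjustments = list(),
                             requires_pef = FALSE) {
  zone <- match.arg(zone)
  structure(list(zone = zone,
                 instructions = as.character(instructions)[1L],
                 medication_adjustments = as.list(medication_adjustments),
                 requires_pef = isTRUE(requires_pef)),
            class = "zone_instruction")
}

#' Provider-authored per-zone action plan
#'
#' Exactly one instruction record per zone.  The plan is external input to
#' the decision engine; the engine pairs it with a computed zone of control
#' but never creates or edits it.
#'
#' @param green,yellow,red [zone_instruction()] records (plain instruction
#'   strings are accepted and wrapped).
#' @return An object of class `"action_plan"`.
#' @export
#' @examples
#' action_plan(green = "continue current medications",
#'             yellow = "double controller dose",
#'             red = "take reliever and seek urgent care")
action_plan <- function(green, yellow, red) {
  wrap <- function(x, z) {
    if (inherits(x, "zone_instruction")) {
      if (!identical(x$zone, z)) stop("instruction record for wrong zone: ",
                                      x$zone, " given as ", z)
      x
    } else zone_instruction(z, instructions = as.character(x))
  }
  structure(list(green = wrap(green, "green"),
                 yellow = wrap(yellow, "yellow"),
                 red = wrap(red, "red")),
            class = "action_plan")
}

#' Does any zone of a plan rely on peak flow?
#' @param plan An [action_plan()].
#' @return Logical scalar.
#' @export
plan_requires_pef <- function(plan) {
  stopifnot(inherits(plan, "action_plan"))
  any(vapply(plan, function(z) isTRUE(z$requires_pef), logical(1)))
}

#' Create a patient profile
#'
#' The clinical configuration entered at onboarding: identifier, enrollment
#' time, medications, optional personal-best peak flow and zone thresholds,
#' and the account settings (reminder time, timezone, email opt-in) used by
#' the reminder planner.  Construction is permissive; semantic invariants
#' are checked by [validate_profile()], which reports violations rather than
#' throwing, so that imported records can be triaged.
#'
#' @param patient_id Non-empty identifier, unique within a cohort.
#' @param enrollment Enrollment instant (ISO-8601 string or POSIXct; stored
#'   UTC).
#' @param personal_best_pef Personal-best peak expiratory flow in L/min, or
#'   `NULL`.
#' @param medications List of [medication()] records.
#' @param thresholds Optional [zone_thresholds()].
#' @param action_plan Optional [action_plan()] carried with the profile.
#' @param reminder_time Local clock time `"HH:MM"` for reminder emails;
#'   platform default 19:00.
#' @param tz IANA timezone in which `reminder_time` and calendar days are
#'   interpreted; default `"America/Toronto"`.
#' @param email_enabled Receive reminder emails?
#' @param age_group `"under_50"`, `"fifty_plus"` or `NULL`.
#' @param college_educated,has_smartphone Optional logicals (subgroup
#'   analytics).
#' @param baseline_act Optional Asthma Control Test score, 5--25.
#' @return An object of class `"patient_profile"`.
#' @export
patient_profile <- function(patient_id, enrollment,
                            personal_best_pef = NULL,
                            medications = list(),
                            thresholds = NULL,
                            action_plan = NULL,
                            reminder_time = "19:00",
                            tz = "America/Toronto",
                            email_enabled = TRUE,
                            age_group = NULL,
                            college_educated = NULL,
                            has_smartphone = NULL,
                            baseline_act = NULL) {
  structure(list(patient_id = as.character(patient_id)[1L],
                 enrollment = .as_utc(enrollment),
                 personal_best_pef = if (is.null(personal_best_pef)) NULL
                                     else as.numeric(personal_best_pef)[1L],
                 medications = medications,
                 thresholds = thresholds,
                 action_plan = action_plan,
                 reminder_time = reminder_time,
                 tz = tz,
                 email_enabled = isTRUE(email_enabled),
                 age_group = age_group,
                 college_educated = college_educated,
                 has_smartphone = has_smartphone,
                 baseline_act = if (is.null(baseline_act)) NULL
                                else as.numeric(baseline_act)[1L]),
            class = "patient_profile")
}

#' Validate a patient profile
#'
#' Checks the profile's semantic invariants and returns a character vector
#' of human-readable violation descriptions -- empty when the profile is
#' well formed.  Violations are reported, never thrown.
#'
#' @param profile A [patient_profile()] (or a compatible list).
#' @return Character vector of violations; `character(0)` if valid.
#' @export
validate_profile <- function(profile) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)

  pid <- profile$patient_id
  if (is.null(pid) || !is.character(pid) || length(pid) != 1L || !nzchar(pid))
    add("patient_id must be a non-empty string")
  if (is.null(profile$enrollment) || !inherits(profile$enrollment, "POSIXct") ||
      is.na(profile$enrollment))
    add("enrollment must be a valid timestamp")
  if (!is.null(profile$personal_best_pef) &&
      (!is.numeric(profile$personal_best_pef) ||
       is.na(profile$personal_best_pef) || profile$personal_best_pef <= 0))
    add("personal_best_pef must be a positive flow (L/min)")
  if (!.is_clock_time(profile$reminder_time))
    add("reminder_time must be a valid 24-h clock time \"HH:MM\"")
  if (!is.character(profile$tz) || !(profile$tz %in% .olson()))
    add("tz must be a known IANA timezone")
  if (!is.null(profile$baseline_act)) {
    act <- profile$baseline_act
    if (!is.numeric(act) || is.na(act) || act != round(act) ||
        act < 5 || act > 25)
      add("baseline_act must be an integer in the ACT range [5, 25]")
  }
  if (!is.null(profile$age_group) &&
      !(profile$age_group %in% c("under_50", "fifty_plus")))
    add("age_group must be \"under_50\" or \"fifty_plus\"")
  for (m in profile$medications) {
    if (is.null(m$name) || !nzchar(as.character(m$name)[1L]))
      add("medication name must be non-empty")
    if (is.null(m$med_class) || !(m$med_class %in% c("controller", "reliever")))
      add(sprintf("medication '%s': med_class must be controller or reliever",
                  if (is.null(m$name)) "?" else m$name))
  }
  th <- profile$thresholds
  if (!is.null(th)) {
    if (!is.numeric(th$green_lower) || !is.numeric(th$yellow_lower) ||
        !isTRUE(th$green_lower > th$yellow_lower) ||
        !isTRUE(th$yellow_lower > 0))
      add("thresholds must satisfy green_lower > yellow_lower > 0")
    if (identical(th$source, "fraction_of_personal_best") &&
        isTRUE(th$green_lower > 1))
      add("fractional thresholds must be <= 1")
  }
  if (!is.null(profile$action_plan) &&
      !inherits(profile$action_plan, "action_plan"))
    add("action_plan must be an action_plan object")
  v
}

#' Validate patient-id uniqueness across a cohort
#' @param cohort List of [patient_profile()] objects.
#' @return Character vector of violations (duplicated ids, per-profile
#'   problems prefixed with the id); empty if the cohort is well formed.
#' @export
validate_cohort <- function(cohort) {
  v <- character(0)
  ids <- vapply(cohort, function(p) as.character(p$patient_id)[1L], character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    v <- c(v, paste0("duplicated patient_id: ", dup))
  for (p in cohort) {
    pv <- validate_profile(p)
    if (length(pv)) v <- c(v, paste0(p$patient_id, ": ", pv))
  }
  v
}

#' Resolve peak-flow zone thresholds to absolute flows
#'
#' Provider-entered absolute thresholds pass through unchanged.  Fractional
#' thresholds (either stored on the profile with
#' `source = "fraction_of_personal_best"`, or the default fractions given
#' here) are multiplied by the personal-best peak flow.  The defaults --
#' green at or above 90% of personal best, red below 60% -- follow common
#' guideline-based traffic-light plans and are configurable per deployment.
#'
#' @param profile A [patient_profile()].
#' @param green_frac Fraction of personal best at/above which flow is green.
#' @param red_frac Fraction of personal best below which flow is red.
#' @return Absolute [zone_thresholds()] (idempotent on its own output).
#' @export
#' @examples
#' p <- patient_profile("p1", "2013-01-07T14:00:00Z", personal_best_pef = 500)
#' resolve_pef_thresholds(p)  # green >= 450, red < 300
resolve_pef_thresholds <- function(profile, green_frac = 0.90, red_frac = 0.60) {
  th <- profile$thresholds
  if (!is.null(th) && identical(th$source, "absolute")) {
    .check_thresholds(th)
    return(th)
  }
  pb <- profile$personal_best_pef
  if (!is.null(th) && identical(th$source, "fraction_of_personal_best")) {
    if (is.null(pb)) stop("thresholds unresolvable: fractional thresholds but no personal_best_pef")
    green_frac <- th$green_lower
    red_frac <- th$yellow_lower
  } else if (is.null(pb)) {
    stop("thresholds unresolvable: no absolute thresholds and no personal_best_pef")
  }
  if (!(red_frac > 0 && red_frac < green_frac && green_frac <= 1))
    stop("require 0 < red_frac < green_frac <= 1")
  out <- zone_thresholds(green_lower = pb * green_frac,
                         yellow_lower = pb * red_frac,
                         source = "absolute")
  .check_thresholds(out)
  out
}

#' @export
print.patient_profile <- function(x, ...) {
  cat("<patient_profile>", x$patient_id, "\n")
  cat("  enrolled:", .format_utc(x$enrollment), "\n")
  cat("  medications:", length(x$medications),
      sprintf("(%d controller)",
              sum(vapply(x$medications,
                         function(m) identical(m$med_class, "controller"),
                         logical(1)))), "\n")
  if (!is.null(x$personal_best_pef))
    cat("  personal best PEF:", x$personal_best_pef, "L/min\n")
  cat("  reminders:", if (x$email_enabled) x$reminder_time else "disabled",
      paste0("(", x$tz, ")"), "\n")
  invisible(x)
}

# ---- cohort JSON (one file: array of profile objects, embedded plans) ----

.profile_to_list <- function(p) {
  out <- list(patient_id = p$patient_id,
              enrollment = .format_utc(p$enrollment),
              reminder_time = p$reminder_time,
              tz = p$tz,
              email_enabled = p$email_enabled)
  if (!is.null(p$personal_best_pef)) out$personal_best_pef <- p$personal_best_pef
  if (length(p$medications))
    out$medications <- lapply(p$medications, function(m)
      list(name = m$name, med_class = m$med_class, schedule = m$schedule))
  if (!is.null(p$thresholds))
    out$thresholds <- list(green_lower = p$thresholds$green_lower,
                           yellow_lower = p$thresholds$yellow_lower,
                           source = p$thresholds$source)
  if (!is.null(p$action_plan))
    out$action_plan <- lapply(p$action_plan, function(z)
      list(instructions = z$instructions,
           medication_adjustments = z$medication_adjustments,
           requires_pef = z$requires_pef))
  for (f in c("age_group", "college_educated", "has_smartphone", "baseline_act"))
    if (!is.null(p[[f]])) out[[f]] <- p[[f]]
  out
}

.profile_from_list <- function(x) {
  meds <- lapply(x$medications %||% list(), function(m)
    medication(m$name, m$med_class, m$schedule %||% ""))
  th <- if (!is.null(x$thresholds))
    zone_thresholds(x$thresholds$green_lower, x$thresholds$yellow_lower,
                    x$thresholds$source %||% "absolute")
  ap <- if (!is.null(x$action_plan))
    action_plan(green = zone_instruction("green",
                  x$action_plan$green$instructions %||% "",
                  x$action_plan$green$medication_adjustments %||% list(),
                  isTRUE(x$action_plan$green$requires_pef)),
                yellow = zone_instruction("yellow",
                  x$action_plan$yellow$instructions %||% "",
                  x$action_plan$yellow$medication_adjustments %||% list(),
                  isTRUE(x$action_plan$yellow$requires_pef)),
                red = zone_instruction("red",
                  x$action_plan$red$instructions %||% "",
                  x$action_plan$red$medication_adjustments %||% list(),
                  isTRUE(x$action_plan$red$requires_pef)))
  patient_profile(patient_id = x$patient_id,
                  enrollment = x$enrollment,
                  personal_best_pef = x$personal_best_pef,
                  medications = meds,
                  thresholds = th,
                  action_plan = ap,
                  reminder_time = x$reminder_time %||% "19:00",
                  tz = x$tz %||% "America/Toronto",
                  email_enabled = x$email_enabled %||% TRUE,
                  age_group = x$age_group,
                  college_educated = x$college_educated,
                  has_smartphone = x$has_smartphone,
                  baseline_act = x$baseline_act)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a cohort of patient profiles as JSON
#'
#' One JSON document per cohort: an array of profile objects, each embedding
#' its medications, thresholds and action plan.
#'
#' @param cohort List of [patient_profile()] objects.
#' @param path File path.
#' @return `read_cohort()` returns the list of profiles; `write_cohort()`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  jsonlite::write_json(lapply(cohort, .profile_to_list), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  cohort <- lapply(raw, .profile_from_list)
  v <- validate_cohort(cohort)
  if (length(v)) stop("invalid cohort file ", path, ":\n  ",
                      paste(v, collapse = "\n  "))
  cohort
}
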