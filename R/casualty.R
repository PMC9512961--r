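# The in-silico casualty card: injuries, time/treatment-dependent physiology,
# treatment deadlines and the preventable-death flag.

#' Construct an injury
#'
#' @param body_region one of `"head"`, `"face"`, `"neck"`, `"thorax"`,
#'   `"abdomen"`, `"spine"`, `"upper-extremity"`, `"lower-extremity"`,
#'   `"external"`.
#' @param ais Abbreviated Injury Scale severity, integer 1-6.
#' @param required_treatments character vector of treatment-requirement ids
#'   addressing this injury (may be empty).
#' @return an object of class `"injury"`.
#' @export
injury <- function(body_region, ais, required_treatments = character()) {
  body_region <- match.arg(body_region, BODY_REGIONS)
  ais <- as.integer(ais)
  if (is.na(ais) || ais < 1L || ais > 6L)
    abort_config("AIS severity must be an integer in [1, 6], got %s", ais)
  structure(list(body_region = body_region, ais = ais,
                 required_treatments = as.character(required_treatments)),
            class = "injury")
}

#' Construct a treatment requirement
#'
#' A time-critical intervention at a hospital station.  The deadline is the
#' time by which the treatment must be *completed* (not merely started) to
#' avert death; a second, earlier deadline marks the onset of a severe
#' complication if exceeded.
#'
#' @param id requirement identifier (unique within a casualty).
#' @param station one of `"ED"`, `"CT"`, `"OR"`, `"ICU"`, `"WARD"`.
#' @param duration_min service time in minutes (> 0).
#' @param deadline_min minutes post-incident by which the treatment must be
#'   completed to avert death, or `NA` if not time-critical.
#' @param complication_deadline_min minutes post-incident after which a
#'   completed-late treatment counts as a severe complication, or `NA`.
#' @param staff_demand named integer vector, staff category -> count seized
#'   for the duration.
#' @param consumables named integer vector, supply item -> units consumed at
#'   treatment start.
#' @return an object of class `"treatment_requirement"`.
#' @export
treatment_requirement <- function(id, station, duration_min,
                                  deadline_min = NA_integer_,
                                  complication_deadline_min = NA_integer_,
                                  staff_demand = c(nurse = 1L),
                                  consumables = integer()) {
  station <- match.arg(station, STATIONS)
  duration_min <- as.integer(duration_min)
  if (duration_min <= 0L) abort_config("duration_min must be > 0 for '%s'", id)
  deadline_min <- as.integer(deadline_min)
  if (!is.na(deadline_min) && deadline_min <= 0L)
    abort_config("deadline_min must be > 0 when present for '%s'", id)
  staff_demand <- vapply(staff_demand, as.integer, integer(1))
  if (length(staff_demand) == 0 || !any(staff_demand >= 1L))
    abort_config("treatment '%s' must demand at least one staff member", id)
  structure(list(id = as.character(id), station = station,
                 duration_min = duration_min, deadline_min = deadline_min,
                 complication_deadline_min = as.integer(complication_deadline_min),
                 staff_demand = staff_demand,
                 consumables = vapply(consumables, as.integer, integer(1))),
            class = "treatment_requirement")
}

#' Construct a physiology snapshot
#'
#' Point-in-time vital signs in the ATLS parameter set used on the casualty
#' card margins.
#'
#' @param gcs Glasgow Coma Scale, integer 3-15.
#' @param sbp systolic blood pressure, mmHg (>= 0).
#' @param rr respiratory rate, breaths/min (>= 0).
#' @param ambulatory can the casualty walk?
#' @return an object of class `"physiology_snapshot"`.
#' @export
physiology_snapshot <- function(gcs, sbp, rr, ambulatory = FALSE) {
  gcs <- as.integer(gcs); sbp <- as.numeric(sbp); rr <- as.numeric(rr)
  if (gcs < 3L || gcs > 15L) abort_config("GCS must be in [3, 15], got %d", gcs)
  if (sbp < 0 || rr < 0) abort_config("SBP and RR must be non-negative")
  structure(list(gcs = gcs, sbp = sbp, rr = rr,
                 ambulatory = isTRUE(ambulatory)),
            class = "physiology_snapshot")
}

# Snapshot used to mark death once the untreated-death time has passed.
deceased_snapshot <- function() physiology_snapshot(3, 0, 0, FALSE)

#' Construct a physiological trajectory
#'
#' A trajectory is an ordered set of breakpoints; each breakpoint applies
#' from `from_min` minutes post-incident onward, provided the treatments in
#' its `condition` have all been completed.  An untreated casualty whose
#' time-critical deadline passes switches to the deceased marker.
#'
#' @param breakpoints list of lists with elements `from_min` (minutes),
#'   `condition` (character vector of treatment ids that must be complete)
#'   and `snapshot` (a [physiology_snapshot()]).
#' @param death_time_untreated_min minutes post-incident at which the
#'   casualty dies if no averting treatment is completed, or `NA`.
#' @return an object of class `"trajectory"`.
#' @export
trajectory <- function(breakpoints, death_time_untreated_min = NA_integer_) {
  times <- vapply(breakpoints, function(b) as.numeric(b$from_min), numeric(1))
  if (is.unsorted(times)) abort_config("trajectory breakpoints must be sorted by from_min")
  bps <- lapply(breakpoints, function(b) {
    list(from_min = as.integer(b$from_min),
         condition = as.character(b$condition %||% character()),
         snapshot = b$snapshot)
  })
  structure(list(breakpoints = bps,
                 death_time_untreated_min = as.integer(death_time_untreated_min)),
            class = "trajectory")
}

#' Construct a casualty
#'
#' The unit flowing through the system: injuries, trajectory, treatment
#' plan, trauma scores and the optimal-outcome flag used to classify deaths
#' as preventable.
#'
#' @param id casualty identifier.
#' @param injuries list of [injury()] objects.
#' @param treatments list of [treatment_requirement()] objects; executed in
#'   station order ED, CT, OR, ICU, WARD.
#' @param trajectory a [trajectory()].
#' @param survivable_if_optimal would optimal (unconstrained) treatment have
#'   averted death?
#' @param true_category the casualty's true triage category (`"RED"`,
#'   `"YELLOW"`, `"GREEN"`, `"DEAD"`).
#' @param ct_scan_min minutes of CT scanning requested by the injury panel,
#'   or `NA` for none.
#' @return an object of class `"casualty"` with ISS, NISS and RTS (at the
#'   initial snapshot) precomputed.
#' @export
casualty <- function(id, injuries, treatments, trajectory,
                     survivable_if_optimal, true_category,
                     ct_scan_min = NA_integer_) {
  true_category <- match.arg(true_category, TRIAGE_LEVELS)
  # requirements run in station order; within a station, in list order
  st <- vapply(treatments, function(x) x$station, character(1))
  treatments <- treatments[order(match(st, STATIONS))]
  ids <- vapply(treatments, function(x) x$id, character(1))
  if (anyDuplicated(ids)) abort_config("duplicate treatment ids in casualty '%s'", id)
  dl <- vapply(treatments, function(x) as.numeric(x$deadline_min), numeric(1))
  min_dl <- if (all(is.na(dl))) NA_integer_ else as.integer(min(dl, na.rm = TRUE))
  if (!is.na(trajectory$death_time_untreated_min) && !is.na(min_dl) &&
      trajectory$death_time_untreated_min != min_dl)
    abort_config("casualty '%s': death_time_untreated_min (%d) must equal the minimum treatment deadline (%d)",
                 id, trajectory$death_time_untreated_min, min_dl)
  first_snap <- trajectory$breakpoints[[1]]$snapshot
  structure(list(id = as.character(id), injuries = injuries,
                 treatments = treatments, trajectory = trajectory,
                 survivable_if_optimal = isTRUE(survivable_if_optimal),
                 true_category = true_category,
                 ct_scan_min = as.integer(ct_scan_min),
                 iss = compute_iss(injuries), niss = compute_niss(injuries),
                 rts = compute_rts(first_snap)),
            class = "casualty")
}

#' Physiology of a casualty at a given time
#'
#' Returns the snapshot of the latest breakpoint with `from_min <= t` whose
#' condition is a subset of the completed treatments.  If `t` has reached
#' the untreated death time and no deadline-carrying treatment has been
#' completed, the deceased marker (GCS 3, SBP 0, RR 0) is returned.
#'
#' @param cas a [casualty()].
#' @param t minutes post-incident (>= 0).
#' @param done character vector of completed treatment ids.
#' @return a [physiology_snapshot()].
#' @export
physiology_at <- function(cas, t, done = character()) {
  stopifnot(t >= 0)
  traj <- cas$trajectory
  dt <- traj$death_time_untreated_min
  if (!is.na(dt) && t >= dt) {
    critical <- vapply(cas$treatments, function(x) !is.na(x$deadline_min), logical(1))
    averting <- vapply(cas$treatments[critical], function(x) x$id, character(1))
    if (!any(averting %in% done)) return(deceased_snapshot())
  }
  best <- NULL
  for (b in traj$breakpoints) {
    if (b$from_min <= t && all(b$condition %in% done)) best <- b
  }
  if (is.null(best))
    abort_config("casualty '%s': no trajectory breakpoint matches t=%s, done={%s}",
                 cas$id, t, paste(done, collapse = ","))
  best$snapshot
}

#' Default physiological triage sieve thresholds
#'
#' Ambulatory casualties are GREEN; RR of zero is DEAD; an RR outside
#' \[rr_low, rr_high\], an SBP below `sbp_min` or a GCS at or below
#' `gcs_max` is RED; anything else is YELLOW.  The thresholds live in
#' configuration, not code, because published sieve variants differ.
#'
#' @param rr_low,rr_high,sbp_min,gcs_max numeric thresholds.
#' @return an object of class `"sieve_config"`.
#' @export
triage_sieve <- function(rr_low = 10, rr_high = 29, sbp_min = 90, gcs_max = 13) {
  structure(list(rr_low = rr_low, rr_high = rr_high,
                 sbp_min = sbp_min, gcs_max = gcs_max),
            class = "sieve_config")
}

#' Triage a physiology snapshot
#'
#' Deterministic physiological sieve: see [triage_sieve()] for the rule.
#'
#' @param snapshot a [physiology_snapshot()].
#' @param sieve a [triage_sieve()].
#' @return one of `"GREEN"`, `"DEAD"`, `"RED"`, `"YELLOW"`.
#' @export
triage <- function(snapshot, sieve = triage_sieve()) {
  if (snapshot$ambulatory) return("GREEN")
  if (snapshot$rr == 0) return("DEAD")
  if (snapshot$rr < sieve$rr_low || snapshot$rr > sieve$rr_high ||
      snapshot$sbp < sieve$sbp_min || snapshot$gcs <= sieve$gcs_max)
    return("RED")
  "YELLOW"
}

#' @export
print.casualty <- function(x, ...) {
  cat(sprintf("<casualty %s> %s  ISS %d  NISS %d  RTS %.4f  %s\n",
              x$id, x$true_category, x$iss, x$niss, x$rts,
              if (x$survivable_if_optimal) "survivable" else "unsurvivable"))
  for (tr in x$treatments)
    cat(sprintf("  %-14s %-4s %3d min%s\n", tr$id, tr$station, tr$duration_min,
                if (is.na(tr$deadline_min)) "" else sprintf("  deadline %d", tr$deadline_min)))
  invisible(x)
}

# Greedy feasibility oracle: with unlimited resources and service from t=0,
# can all time-critical requirements complete before their deadlines?
# Requirements are processed in earliest-deadline order.
schedule_feasible <- function(treatments) {
  dl <- vapply(treatments, function(x) as.numeric(x$deadline_min), numeric(1))
  crit <- treatments[!is.na(dl)]
  if (length(crit) == 0) return(TRUE)
  ord <- order(vapply(crit, function(x) x$deadline_min, integer(1)))
  t <- 0
  for (tr in crit[ord]) {
    t <- t + tr$duration_min
    if (t > tr$deadline_min) return(FALSE)
  }
  TRUE
}
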