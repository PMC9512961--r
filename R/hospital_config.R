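# Hospital configuration: finite resource pools with time-dependent
# mobilization after the major-incident alert.
#
# A "trauma unit" is the composite the capacity test counts: a prepared
# room with equipment plus the minimal qualified team able to manage one
# severely injured casualty in parallel.  Units, staff categories, ICU
# beds (plus reserve ventilators) and operating theatres all mobilize
# along step functions of time since alert, with separate office and
# non-office profiles.

mob_steps <- function(t, count) {
  m <- cbind(t = as.numeric(t), count = as.numeric(count))
  if (is.unsorted(m[, 1]) || is.unsorted(m[, 2]))
    abort_config("mobilization lists must be non-decreasing in time and count")
  m
}

#' Construct a hospital configuration
#'
#' All times are integer minutes; mobilization step lists are minutes
#' *after alert* (the alert itself sounds `alert_offset_min` after the
#' incident).  Every count must be non-negative and every mobilization
#' list non-decreasing in both coordinates.
#'
#' @param name hospital identifier.
#' @param trauma_unit_mobilization,staff_roster mobilization steps: a list
#'   with elements `office` and `non-office`; for the roster, each profile
#'   is itself a named list (staff category -> step matrix from
#'   `cbind(t, count)`).
#' @param n_trauma_units_max maximum parallel major-trauma units.
#' @param n_minor_units parallel low-resource treatment slots for the
#'   YELLOW/GREEN line (never used by REDs).
#' @param n_or_theatres,or_clearance_min,or_initial_occupied operating
#'   theatres; `or_initial_occupied` theatres are busy with planned surgery
#'   at alert (office profile only) and all clear `or_clearance_min`
#'   minutes after alert.
#' @param n_icu_beds,icu_reserve_ventilators ICU beds available at alert
#'   and extra ventilator places mobilized
#'   `icu_reserve_delay_min` after alert.
#' @param icu_reserve_delay_min minutes after alert at which reserve
#'   ventilator places come on line.
#' @param n_ward_beds ward beds (effectively unconstrained by default).
#' @param ct_in_ed is the CT scanner inside the ED? If not, every CT visit
#'   ties up the casualty's team for two transport legs.
#' @param ct_transport_min one-way ED-to-CT transport time.
#' @param n_ct number of CT scanners.
#' @param transport_staff_mobilization transport-staff pool steps (same
#'   `office`/`non-office` structure).
#' @param transfer_min inter-station transfer time.
#' @param transfer_fallback_category clinical staff category seized for a
#'   transfer when no transport staff is free (logged as indirect capacity
#'   loss); `NA` disables the fallback.
#' @param supplies named integer vector, supply item -> stock at alert.
#' @param restock optional data frame `(t_min, item, qty)` of resupply
#'   deliveries.
#' @param alert_offset_min minutes from incident to hospital alert.
#' @param or_icu_blocking may surgery start only when an ICU bed can be
#'   reserved for a casualty needing post-operative intensive care?
#' @param horizon_min simulation horizon.
#' @return an object of class `"hospital_config"`.
#' @export
hospital_config <- function(name = "hospital",
                            n_trauma_units_max = 16,
                            trauma_unit_mobilization = NULL,
                            n_minor_units = 10,
                            n_or_theatres = 20,
                            or_clearance_min = 30,
                            or_initial_occupied = 14,
                            n_icu_beds = 6,
                            icu_reserve_ventilators = 2,
                            icu_reserve_delay_min = 60,
                            n_ward_beds = 100,
                            ct_in_ed = FALSE,
                            ct_transport_min = 10,
                            n_ct = 1,
                            transport_staff_mobilization = NULL,
                            transfer_min = 5,
                            transfer_fallback_category = "nurse",
                            staff_roster = NULL,
                            supplies = c(chest_drain_set = 10, surgical_disposables = 30,
                                         ext_fixation_set = 6, blood_units = 80),
                            restock = NULL,
                            alert_offset_min = 5,
                            or_icu_blocking = TRUE,
                            horizon_min = 720) {
  counts <- c(n_trauma_units_max, n_minor_units, n_or_theatres, or_initial_occupied,
              n_icu_beds, icu_reserve_ventilators, n_ward_beds, n_ct)
  if (any(counts < 0)) abort_config("resource counts must be non-negative")
  if (or_initial_occupied > n_or_theatres)
    abort_config("or_initial_occupied (%d) exceeds n_or_theatres (%d)",
                 or_initial_occupied, n_or_theatres)
  if (is.null(trauma_unit_mobilization)) {
    trauma_unit_mobilization <- list(
      "office" = mob_steps(c(0, 10, 20, 30, 40),
                           pmin(c(2, 4, 8, 12, 16), n_trauma_units_max)),
      "non-office" = mob_steps(c(0, 15, 30, 50),
                               pmin(c(1, 3, 8, 16), n_trauma_units_max)))
  }
  if (is.null(staff_roster)) {
    staff_roster <- list(
      "office" = list(
        physician = mob_steps(c(0, 20, 40), c(6, 12, 18)),
        nurse = mob_steps(c(0, 30, 60), c(12, 30, 60)),
        surgeon = mob_steps(c(0, 30), c(8, 18)),
        icu_nurse = mob_steps(c(0, 60), c(6, 9))),
      "non-office" = list(
        physician = mob_steps(c(0, 30, 60), c(3, 12, 18)),
        nurse = mob_steps(c(0, 30, 60), c(6, 24, 60)),
        surgeon = mob_steps(c(0, 30, 60), c(3, 10, 18)),
        icu_nurse = mob_steps(c(0, 60), c(4, 9))))
  }
  if (is.null(transport_staff_mobilization)) {
    transport_staff_mobilization <- list(
      "office" = mob_steps(c(0, 30), c(2, 4)),
      "non-office" = mob_steps(c(0, 30), c(1, 4)))
  }
  for (prof in c("office", "non-office")) {
    if (is.null(trauma_unit_mobilization[[prof]]))
      abort_config("trauma_unit_mobilization lacks profile '%s'", prof)
    if (is.null(staff_roster[[prof]]))
      abort_config("staff_roster lacks profile '%s'", prof)
  }
  structure(list(name = name,
                 n_trauma_units_max = as.integer(n_trauma_units_max),
                 trauma_unit_mobilization = trauma_unit_mobilization,
                 n_minor_units = as.integer(n_minor_units),
                 n_or_theatres = as.integer(n_or_theatres),
                 or_clearance_min = as.integer(or_clearance_min),
                 or_initial_occupied = as.integer(or_initial_occupied),
                 n_icu_beds = as.integer(n_icu_beds),
                 icu_reserve_ventilators = as.integer(icu_reserve_ventilators),
                 icu_reserve_delay_min = as.integer(icu_reserve_delay_min),
                 n_ward_beds = as.integer(n_ward_beds),
                 ct_in_ed = isTRUE(ct_in_ed),
                 ct_transport_min = as.integer(ct_transport_min),
                 n_ct = as.integer(n_ct),
                 transport_staff_mobilization = transport_staff_mobilization,
                 transfer_min = as.integer(transfer_min),
                 transfer_fallback_category = transfer_fallback_category,
                 staff_roster = staff_roster,
                 supplies = vapply(supplies, as.integer, integer(1)),
                 restock = restock,
                 alert_offset_min = as.integer(alert_offset_min),
                 or_icu_blocking = isTRUE(or_icu_blocking),
                 horizon_min = as.integer(horizon_min)),
            class = "hospital_config")
}

#' The shipped "large hospital" default configuration
#'
#' A university-hospital-sized default: up to 16 parallel major-trauma
#' units after full mobilization, a large theatre block that clears
#' planned surgery on alert, a deliberately small ICU (the terminal
#' bottleneck), and a CT scanner outside the ED.  All values are authored
#' defaults for this package.
#'
#' @param ... overrides passed to [hospital_config()].
#' @return a [hospital_config()].
#' @export
default_hospital <- function(...) {
  args <- list(...)
  do.call(hospital_config, c(list(name = args$name %||% "large_hospital"),
                             args[setdiff(names(args), "name")]))
}

#' Mobilized count of a resource at a given time
#'
#' Step-function lookup on the mobilization list of the active profile.
#' Times are minutes post-incident; the step breakpoints are defined
#' relative to the alert.  Before the alert the baseline (time-0) count
#' applies: that is the on-duty complement.
#'
#' @param hospital a [hospital_config()].
#' @param resource `"trauma_unit"`, `"transport_staff"`, `"icu_bed"`,
#'   `"or_theatre"`, or a staff category named in the roster.
#' @param t minutes post-incident (vectorised).
#' @param profile `"office"` or `"non-office"`.
#' @return integer vector of available counts, non-decreasing in `t`.
#' @export
mobilized <- function(hospital, resource, t, profile = c("office", "non-office")) {
  profile <- match.arg(profile)
  ta <- pmax(0, t - hospital$alert_offset_min)
  m <- switch(resource,
    trauma_unit = hospital$trauma_unit_mobilization[[profile]],
    transport_staff = hospital$transport_staff_mobilization[[profile]],
    icu_bed = mob_steps(c(0, hospital$icu_reserve_delay_min),
                        c(hospital$n_icu_beds,
                          hospital$n_icu_beds + hospital$icu_reserve_ventilators)),
    or_theatre = {
      occ0 <- if (profile == "office") hospital$or_initial_occupied else 0L
      mob_steps(c(0, hospital$or_clearance_min),
                c(hospital$n_or_theatres - occ0, hospital$n_or_theatres))
    },
    hospital$staff_roster[[profile]][[resource]] %||%
      abort_config("unknown resource '%s'", resource))
  as.integer(step_lookup(m[, 1], m[, 2], ta, before = m[1, 2]))
}

# Maximum ever-mobilizable count, for the pre-simulation feasibility check.
mobilized_max <- function(hospital, resource, profile) {
  m <- switch(resource,
    trauma_unit = hospital$trauma_unit_mobilization[[profile]],
    transport_staff = hospital$transport_staff_mobilization[[profile]],
    hospital$staff_roster[[profile]][[resource]])
  if (is.null(m)) 0L else as.integer(m[nrow(m), 2])
}

#' @export
print.hospital_config <- function(x, ...) {
  cat(sprintf("<hospital_config '%s'>\n", x$name))
  cat(sprintf("  trauma units <= %d, minor slots %d, OR %d (clearance %d min), ICU %d+%d, wards %d\n",
              x$n_trauma_units_max, x$n_minor_units, x$n_or_theatres,
              x$or_clearance_min, x$n_icu_beds, x$icu_reserve_ventilators,
              x$n_ward_beds))
  cat(sprintf("  CT %s (n=%d, transport %d min); alert at +%d min; horizon %d min\n",
              if (x$ct_in_ed) "in ED" else "outside ED", x$n_ct,
              x$ct_transport_min, x$alert_offset_min, x$horizon_min))
  invisible(x)
}
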