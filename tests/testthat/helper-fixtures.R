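# Shared fixtures: hand-built casualties, flat-mobilization hospitals and
# literal arrival streams for hand-traceable engine runs.

# A casualty with explicitly given treatments and an auto-built trajectory
# consistent with the deadline invariants.
mk_casualty <- function(id, category = "RED", treatments = list(),
                        ct_scan_min = NA_integer_) {
  snap <- switch(category,
                 RED = physiology_snapshot(14, 80, 26),
                 YELLOW = physiology_snapshot(15, 110, 22),
                 GREEN = physiology_snapshot(15, 120, 16, ambulatory = TRUE),
                 DEAD = physiology_snapshot(3, 0, 0))
  dls <- vapply(treatments, function(x) as.numeric(x$deadline_min), numeric(1))
  min_dl <- if (length(dls) && any(!is.na(dls)))
    as.integer(min(dls, na.rm = TRUE)) else NA_integer_
  traj <- trajectory(list(list(from_min = 0, condition = character(),
                               snapshot = snap)),
                     death_time_untreated_min = min_dl)
  casualty(id, list(injury("thorax", if (category == "DEAD") 6L else 3L)),
           treatments, traj,
           survivable_if_optimal = category != "DEAD",
           true_category = category, ct_scan_min = ct_scan_min)
}

# One ED requirement with a mortality deadline: the minimal hand-trace unit.
ed_req <- function(id = "ed_tx", duration = 20, deadline = 60, comp = NA,
                   station = "ED", staff = c(nurse = 1L), consumables = integer()) {
  treatment_requirement(id, station, duration, deadline, comp,
                        staff_demand = staff, consumables = consumables)
}

# Hospital with flat (time-constant) mobilization so hand traces need no
# ramp-up bookkeeping.  Staff is ample unless overridden.
flat_hospital <- function(units = 2, minor = 5, or = 2, icu = 2, ward = 50,
                          name = "flat",
                          ct = 1, ct_in_ed = TRUE, ct_transport = 10,
                          transfer = 0, transport_staff = 99,
                          nurse = 99, surgeon = 99, icu_nurse = 99,
                          physician = 99,
                          supplies = c(chest_drain_set = 999,
                                       surgical_disposables = 999,
                                       ext_fixation_set = 999,
                                       blood_units = 999),
                          or_initial_occupied = 0, or_clearance = 0,
                          alert_offset = 0, or_icu_blocking = TRUE,
                          horizon = 600, restock = NULL,
                          icu_reserve = 0) {
  flat <- function(k) list("office" = mob_steps(0, k), "non-office" = mob_steps(0, k))
  roster1 <- list(physician = mob_steps(0, physician), nurse = mob_steps(0, nurse),
                  surgeon = mob_steps(0, surgeon), icu_nurse = mob_steps(0, icu_nurse))
  hospital_config(name = name,
                  n_trauma_units_max = units,
                  trauma_unit_mobilization = flat(units),
                  n_minor_units = minor,
                  n_or_theatres = or, or_clearance_min = or_clearance,
                  or_initial_occupied = or_initial_occupied,
                  n_icu_beds = icu, icu_reserve_ventilators = icu_reserve,
                  n_ward_beds = ward,
                  ct_in_ed = ct_in_ed, ct_transport_min = ct_transport, n_ct = ct,
                  transport_staff_mobilization = flat(transport_staff),
                  transfer_min = transfer,
                  staff_roster = list("office" = roster1, "non-office" = roster1),
                  supplies = supplies, restock = restock,
                  alert_offset_min = alert_offset,
                  or_icu_blocking = or_icu_blocking,
                  horizon_min = horizon)
}

# mob_steps is internal; reach it for fixture building
mob_steps <- surgesim:::mob_steps

# Literal arrival stream.
mk_stream <- function(ids, t, category = "RED", hospital = 1L,
                      mode = "ambulance") {
  if (length(ids) == 0) {
    df <- data.frame(arrival_min = integer(), casualty_id = character(),
                     hospital = integer(), mode = character(),
                     category = character(), depart_min = integer(),
                     stringsAsFactors = FALSE)
    class(df) <- c("arrival_stream", "data.frame")
    return(df)
  }
  df <- data.frame(arrival_min = as.integer(t), casualty_id = ids,
                   hospital = as.integer(hospital), mode = mode,
                   category = category, depart_min = as.integer(t),
                   stringsAsFactors = FALSE)
  df <- df[order(df$arrival_min, df$casualty_id), ]
  rownames(df) <- NULL
  class(df) <- c("arrival_stream", "data.frame")
  df
}

as_bank <- function(...) {
  cs <- list(...)
  stats::setNames(cs, vapply(cs, `[[`, character(1), "id"))
}

# A small two-hospital overload setting used by the coordination tests:
# hospital 1 is the designated centre with few trauma units; hospital 2
# sits a little further away with the same resources.
overload_region <- function() {
  list(hospitals = list(flat_hospital(units = 3, icu = 4, transfer = 0,
                                      ct_in_ed = TRUE, horizon = 480,
                                      name = "centre"),
                        flat_hospital(units = 3, icu = 4, transfer = 0,
                                      ct_in_ed = TRUE, horizon = 480,
                                      name = "support")),
       template = default_template(transport_time_min = c(5, 10)),
       fleet = ambulance_fleet(n_ambulances = 8))
}
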