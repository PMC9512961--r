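# Authored injury-panel library.
#
# Each panel is a template for one kind of casualty: injuries with AIS
# severities, the treatments they require (station, service time, mortality
# and complication deadlines, staff and material consumption) and a small
# physiological trajectory (initial state, untreated deterioration, and a
# stabilized branch once the first time-critical treatment is complete).
# All values are repo-authored: the real simulation-card data this system
# emulates are not public.  Deadlines are base values; the scenario
# generator jitters them per casualty.

panel_def <- function(id, category, injuries, treatments,
                      vitals, ct_scan_min = NA_integer_) {
  list(id = id, category = category, injuries = injuries,
       treatments = treatments, vitals = vitals, ct_scan_min = ct_scan_min)
}

tx <- function(id, station, duration, deadline = NA, comp_frac = 0.7,
               staff = c(nurse = 1L), consumables = integer(),
               comp_deadline = NA) {
  list(id = id, station = station, duration = duration,
       deadline = deadline, comp_frac = comp_frac, comp_deadline = comp_deadline,
       staff = staff, consumables = consumables)
}

vit <- function(gcs, sbp, rr, amb = FALSE) list(gcs = gcs, sbp = sbp, rr = rr, amb = amb)

#' The shipped injury-panel library
#'
#' @return named list of panel definitions, one per panel id.
#' @export
panel_library <- function() {
  panels <- list(
    # --- RED: immediate, life-threatening ------------------------------
    panel_def("red_thorax_penetrating", "RED",
      injuries = list(c("thorax", 4)),
      treatments = list(
        tx("chest_drain", "ED", 15, deadline = 60,
           staff = c(physician = 1L, nurse = 1L),
           consumables = c(chest_drain_set = 1L)),
        tx("thoracotomy", "OR", 60, deadline = 240,
           staff = c(surgeon = 1L, nurse = 2L),
           consumables = c(surgical_disposables = 1L, blood_units = 2L)),
        tx("icu_ventilation", "ICU", 360, staff = c(icu_nurse = 1L))),
      vitals = list(init = vit(14, 85, 26), worse = vit(12, 65, 34),
                    stabilized = vit(14, 95, 22))),
    panel_def("red_abdominal_bleed", "RED",
      injuries = list(c("abdomen", 4), c("spine", 2)),
      treatments = list(
        tx("resuscitation", "ED", 10, deadline = 45,
           staff = c(physician = 1L, nurse = 1L),
           consumables = c(blood_units = 2L)),
        tx("laparotomy", "OR", 75, deadline = 180,
           staff = c(surgeon = 1L, nurse = 2L),
           consumables = c(surgical_disposables = 1L, blood_units = 4L)),
        tx("icu_stabilisation", "ICU", 480, staff = c(icu_nurse = 1L))),
      vitals = list(init = vit(13, 80, 28), worse = vit(10, 60, 35),
                    stabilized = vit(14, 95, 24)),
      ct_scan_min = 10),
    panel_def("red_head_injury", "RED",
      injuries = list(c("head", 4), c("face", 2)),
      treatments = list(
        tx("airway_control", "ED", 10, deadline = 40,
           staff = c(physician = 1L, nurse = 1L)),
        tx("craniotomy", "OR", 90, deadline = 300,
           staff = c(surgeon = 1L, nurse = 2L),
           consumables = c(surgical_disposables = 1L)),
        tx("icu_neuro", "ICU", 720, staff = c(icu_nurse = 1L))),
      vitals = list(init = vit(9, 100, 12), worse = vit(6, 90, 8),
                    stabilized = vit(11, 105, 14)),
      ct_scan_min = 15),
    panel_def("red_pelvic_fracture", "RED",
      injuries = list(c("lower-extremity", 4), c("external", 2)),
      treatments = list(
        tx("pelvic_binder", "ED", 10, deadline = 60,
           staff = c(physician = 1L, nurse = 1L)),
        tx("external_fixation", "OR", 60, deadline = 360,
           staff = c(surgeon = 1L, nurse = 1L),
           consumables = c(ext_fixation_set = 1L, surgical_disposables = 1L,
                           blood_units = 2L)),
        tx("icu_monitoring", "ICU", 360, staff = c(icu_nurse = 1L))),
      vitals = list(init = vit(14, 82, 25), worse = vit(12, 62, 33),
                    stabilized = vit(15, 95, 20))),
    # --- YELLOW: urgent, can wait briefly ------------------------------
    panel_def("yellow_femur_fracture", "YELLOW",
      injuries = list(c("lower-extremity", 3)),
      treatments = list(
        tx("splint_analgesia", "ED", 15, staff = c(nurse = 1L)),
        tx("fracture_fixation", "OR", 60, comp_deadline = 720,
           staff = c(surgeon = 1L, nurse = 1L),
           consumables = c(ext_fixation_set = 1L, surgical_disposables = 1L)),
        tx("ward_care", "WARD", 720, staff = c(nurse = 1L))),
      vitals = list(init = vit(15, 110, 22), worse = vit(15, 100, 24),
                    stabilized = vit(15, 115, 18))),
    panel_def("yellow_open_forearm", "YELLOW",
      injuries = list(c("upper-extremity", 2), c("external", 1)),
      treatments = list(
        tx("wound_care", "ED", 15, staff = c(nurse = 1L)),
        tx("debridement", "OR", 45, comp_deadline = 720,
           staff = c(surgeon = 1L, nurse = 1L),
           consumables = c(surgical_disposables = 1L)),
        tx("ward_obs", "WARD", 480, staff = c(nurse = 1L))),
      vitals = list(init = vit(15, 115, 20), worse = vit(15, 108, 22),
                    stabilized = vit(15, 118, 17))),
    panel_def("yellow_blunt_abdomen", "YELLOW",
      injuries = list(c("abdomen", 2)),
      treatments = list(
        tx("ed_assessment", "ED", 20, staff = c(physician = 1L)),
        tx("ward_obs", "WARD", 720, staff = c(nurse = 1L))),
      vitals = list(init = vit(15, 112, 21), worse = vit(15, 104, 23),
                    stabilized = vit(15, 116, 18)),
      ct_scan_min = 10),
    # --- GREEN: minor, walking -----------------------------------------
    panel_def("green_lacerations", "GREEN",
      injuries = list(c("external", 1)),
      treatments = list(tx("suture", "ED", 10, staff = c(nurse = 1L))),
      vitals = list(init = vit(15, 120, 16, amb = TRUE))),
    panel_def("green_sprain", "GREEN",
      injuries = list(c("lower-extremity", 1)),
      treatments = list(tx("strapping", "ED", 8, staff = c(nurse = 1L))),
      vitals = list(init = vit(15, 118, 15, amb = TRUE))),
    panel_def("green_contusion", "GREEN",
      injuries = list(c("upper-extremity", 1)),
      treatments = list(tx("assessment", "ED", 5, staff = c(nurse = 1L))),
      vitals = list(init = vit(15, 122, 14, amb = TRUE))),
    # --- DEAD at scene --------------------------------------------------
    panel_def("dead_at_scene", "DEAD",
      injuries = list(c("head", 6)),
      treatments = list(),
      vitals = list(init = vit(3, 0, 0)))
  )
  names(panels) <- vapply(panels, `[[`, character(1), "id")
  panels
}

# Build one casualty from a panel, applying a multiplicative jitter factor
# to every mortality deadline.  Complication deadlines follow as
# comp_frac * deadline (earlier than the mortality deadline, so the window
# between them is where a late-but-survived treatment counts as a severe
# complication); panels may instead set an absolute comp_deadline.
build_casualty <- function(panel, id, jitter = 1) {
  inj <- lapply(panel$injuries, function(x) injury(x[1], as.integer(x[2])))
  trs <- lapply(panel$treatments, function(d) {
    dl <- if (is.na(d$deadline)) NA_integer_ else as.integer(round(d$deadline * jitter))
    cd <- if (!is.na(d$comp_deadline)) as.integer(round(d$comp_deadline * jitter))
          else if (!is.na(dl)) as.integer(round(dl * d$comp_frac))
          else NA_integer_
    treatment_requirement(d$id, d$station, d$duration, dl, cd,
                          staff_demand = d$staff, consumables = d$consumables)
  })
  dls <- vapply(trs, function(x) as.numeric(x$deadline_min), numeric(1))
  min_dl <- if (length(dls) && any(!is.na(dls))) as.integer(min(dls, na.rm = TRUE)) else NA_integer_
  v <- panel$vitals
  snap <- function(x) physiology_snapshot(x$gcs, x$sbp, x$rr, x$amb %||% FALSE)
  bps <- list(list(from_min = 0L, condition = character(), snapshot = snap(v$init)))
  if (!is.na(min_dl) && !is.null(v$worse)) {
    t_det <- max(1L, min_dl %/% 2L)
    first_crit <- trs[[which(!is.na(dls))[1]]]$id
    bps <- c(bps,
             list(list(from_min = t_det, condition = character(), snapshot = snap(v$worse)),
                  list(from_min = t_det, condition = first_crit, snapshot = snap(v$stabilized))))
  }
  traj <- trajectory(bps, death_time_untreated_min = min_dl)
  cas <- casualty(id, inj, trs, traj,
                  survivable_if_optimal = panel$category != "DEAD",
                  true_category = panel$category,
                  ct_scan_min = panel$ct_scan_min)
  if (cas$survivable_if_optimal && !schedule_feasible(cas$treatments))
    abort_config("panel '%s': no feasible optimal schedule after jitter %.3f",
                 panel$id, jitter)
  cas
}
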