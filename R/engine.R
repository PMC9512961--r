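# The discrete-event core.
#
# Casualties from an arrival stream are admitted to secondary triage and
# then flow through their treatment plan: ED (major-trauma units for REDs,
# a separate low-resource line for YELLOW/GREEN), CT, operating theatres,
# ICU and wards.  Every treatment consumes its full service time, staff
# demand and consumables; resources mobilize along step functions of time
# since alert.  Deaths are recorded the minute a time-critical requirement's
# deadline passes uncompleted; severe complications the minute a
# complication deadline passes.
#
# Time is integer minutes post-incident.  The engine is event-driven (it
# advances to the next scheduled event) and entirely deterministic:
# simultaneous events are processed in a fixed phase order (mobilization,
# restock, completions, deadline checks, arrivals, dispatch) and within a
# phase by a fixed priority key (triage category, earliest remaining
# mortality deadline, arrival order, casualty id).

CAT_RANK <- c(RED = 1L, YELLOW = 2L, GREEN = 3L, DEAD = 4L)

# Build a casualty's station plan: treatments grouped by station in
# canonical order, with the CT visit folded into the ED stage.
build_plan <- function(cas) {
  sts <- vapply(cas$treatments, `[[`, character(1), "station")
  stages <- lapply(intersect(STATIONS, unique(sts)), function(s) {
    list(station = s, trs = cas$treatments[sts == s], ct_after = FALSE)
  })
  if (!is.na(cas$ct_scan_min)) {
    ed <- which(vapply(stages, `[[`, character(1), "station") == "ED")
    if (length(ed) == 0)
      abort_config("casualty '%s': CT visit requires an ED stage", cas$id)
    stages[[ed]]$ct_after <- TRUE
  }
  stages
}

primary_resource <- function(station, category) {
  switch(station,
         ED = if (category == "RED") "trauma_unit" else "minor_slot",
         CT = "ct_scanner", OR = "theatre", ICU = "icu_bed", WARD = "ward_bed")
}

#' Run the hospital engine on an arrival stream
#'
#' @param hospital a [hospital_config()].
#' @param stream an arrival stream from [simulate_evacuation()] (rows for
#'   this hospital only are used when `hospital_index` is given).
#' @param bank the scenario whose casualty bank backs the stream (a
#'   `scenario`, or a named list of [casualty()] objects).
#' @param controller optional inflow controller: a function
#'   `(t, report) -> logical` called at each arrival with the current
#'   [status_report()]; casualties arriving while it returns `FALSE` are
#'   diverted (logged, never admitted).
#' @param seed stored in the result for the run manifest; the engine draws
#'   no random numbers.
#' @param profile `"office"` or `"non-office"` staff profile; defaults to
#'   the scenario's incident time of day.
#' @param hospital_index if the stream covers several hospitals, which one
#'   this engine instance serves.
#' @return an object of class `"event_log"`: a data frame with columns
#'   `t`, `id`, `event`, `station`, `detail` in deterministic
#'   chronological order, with the run configuration in attributes.
#' @export
run_hospital <- function(hospital, stream, bank, controller = NULL,
                         seed = NULL, profile = NULL, hospital_index = 1L) {
  if (inherits(bank, "scenario")) {
    profile <- profile %||% bank$incident_time_of_day
    bank <- bank_index(bank)
  }
  profile <- profile %||% "office"
  profile <- match.arg(profile, c("office", "non-office"))
  rows <- stream[stream$hospital == hospital_index, , drop = FALSE]
  missing_ids <- setdiff(rows$casualty_id, names(bank))
  if (length(missing_ids))
    abort_config("stream casualty id(s) not in bank: %s",
                 paste(missing_ids, collapse = ", "))
  horizon <- hospital$horizon_min
  alert <- hospital$alert_offset_min

  # --- pre-simulation feasibility: every staff demand must be mobilizable
  staff_cats <- names(hospital$staff_roster[[profile]])
  for (cid in rows$casualty_id) {
    for (tr in bank[[cid]]$treatments) {
      for (cat in names(tr$staff_demand)) {
        if (tr$staff_demand[[cat]] > mobilized_max(hospital, cat, profile))
          abort_config("treatment '%s' of '%s' demands %d x %s; roster maximum is %d",
                       tr$id, cid, tr$staff_demand[[cat]], cat,
                       mobilized_max(hospital, cat, profile))
      }
    }
  }

  n <- nrow(rows)
  cs <- new.env(parent = emptyenv())
  cs$log <- vector("list", 4096L); cs$nlog <- 0L
  log_ev <- function(t, id, event, station = "", detail = "") {
    cs$nlog <- cs$nlog + 1L
    if (cs$nlog > length(cs$log)) cs$log <- c(cs$log, vector("list", length(cs$log)))
    cs$log[[cs$nlog]] <- list(t = as.integer(t), id = id, event = event,
                              station = station, detail = as.character(detail))
  }

  # --- static mobilization timeline (config-derived, logged up front in time)
  cap_fun <- function(res) function(t) mobilized(hospital, res, t, profile)
  cap <- list(trauma_unit = cap_fun("trauma_unit"),
              icu_bed = cap_fun("icu_bed"),
              theatre = cap_fun("or_theatre"),
              transport_staff = cap_fun("transport_staff"),
              minor_slot = function(t) hospital$n_minor_units,
              ward_bed = function(t) hospital$n_ward_beds,
              ct_scanner = function(t) hospital$n_ct)
  staff_cap <- function(cat, t) mobilized(hospital, cat, t, profile)

  mob_resources <- c("trauma_unit", "icu_bed", "theatre", "transport_staff", staff_cats)
  res_cap_at <- function(res, t) {
    if (res %in% names(cap)) cap[[res]](t) else staff_cap(res, t)
  }
  mob_events <- list()
  for (res in mob_resources) {
    tt <- 0:horizon
    v <- res_cap_at(res, tt)
    chg <- which(diff(v) != 0)
    for (k in chg) mob_events[[length(mob_events) + 1L]] <-
      list(t = k, res = res, count = v[k + 1L])  # change effective at minute k
  }
  mob_times <- sort(unique(c(alert, vapply(mob_events, `[[`, numeric(1), "t"))))

  restock <- hospital$restock
  restock_times <- if (is.null(restock)) numeric() else sort(unique(restock$t_min))

  # --- per-casualty state
  ids <- rows$casualty_id
  plan <- lapply(ids, function(cid) build_plan(bank[[cid]]))
  catg <- vapply(ids, function(cid) bank[[cid]]$true_category, character(1))
  arrive_t <- rows$arrival_min
  phase <- rep("pre", n)          # pre/queued/blocked/service/ct_go/ct_queue/
                                   # ct_scan/ct_back/xfer_wait/xfer/terminal
  stage_i <- rep(1L, n); tr_i <- rep(1L, n)
  t_next <- rep(NA_real_, n)
  done <- vector("list", n); for (i in seq_len(n)) done[[i]] <- character()
  held_primary <- rep(NA_character_, n)
  held_icu_resv <- rep(FALSE, n)
  held_staff <- vector("list", n)
  held_transport <- rep(NA_character_, n)
  alive <- rep(TRUE, n)
  terminal <- rep(NA_character_, n)
  blocked_by <- rep(NA_character_, n)   # station blamed for last failed admission
  last_queue_t <- rep(NA_real_, n)
  stockout_flag <- vector("list", n)

  busy <- list(trauma_unit = 0L, minor_slot = 0L, ct_scanner = 0L, theatre = 0L,
               icu_bed = 0L, ward_bed = 0L, transport_staff = 0L)
  busy_staff <- stats::setNames(rep(0L, length(staff_cats)), staff_cats)
  stock <- hospital$supplies

  # deadline events (death + complication), sorted
  dl_rows <- list()
  for (i in seq_len(n)) {
    for (tr in bank[[ids[i]]]$treatments) {
      if (!is.na(tr$deadline_min))
        dl_rows[[length(dl_rows) + 1L]] <-
          list(t = tr$deadline_min, i = i, req = tr$id, kind = "death")
      if (!is.na(tr$complication_deadline_min))
        dl_rows[[length(dl_rows) + 1L]] <-
          list(t = tr$complication_deadline_min, i = i, req = tr$id, kind = "comp")
    }
  }
  if (length(dl_rows)) {
    ord <- order(vapply(dl_rows, `[[`, numeric(1), "t"),
                 match(vapply(dl_rows, `[[`, character(1), "kind"), c("death", "comp")),
                 vapply(dl_rows, `[[`, numeric(1), "i"))
    dl_rows <- dl_rows[ord]
  }

  next_dl <- function(i) {
    trs <- bank[[ids[i]]]$treatments
    v <- vapply(trs, function(x)
      if (!is.na(x$deadline_min) && !(x$id %in% done[[i]]))
        as.numeric(x$deadline_min) else Inf, numeric(1))
    if (length(v) == 0) Inf else min(v)
  }
  prio_order <- function(idx) {
    if (length(idx) <= 1) return(idx)
    idx[order(CAT_RANK[catg[idx]], vapply(idx, next_dl, numeric(1)),
              arrive_t[idx], ids[idx])]
  }

  cur_station <- function(i) {
    if (stage_i[i] > length(plan[[i]])) return(NA_character_)
    plan[[i]][[stage_i[i]]]$station
  }
  cur_tr <- function(i) plan[[i]][[stage_i[i]]]$trs[[tr_i[i]]]

  release_staff <- function(i, t) {
    if (!is.null(held_staff[[i]])) {
      sd <- held_staff[[i]]
      for (cat in names(sd)) busy_staff[cat] <<- busy_staff[cat] - sd[[cat]]
      log_ev(t, ids[i], "release", cur_station(i) %||% "",
             paste0("staff:", paste(names(sd), sd, sep = "=", collapse = ",")))
      held_staff[i] <<- list(NULL)
    }
  }
  release_primary <- function(i, t) {
    if (!is.na(held_primary[i])) {
      busy[[held_primary[i]]] <<- busy[[held_primary[i]]] - 1L
      log_ev(t, ids[i], "release", cur_station(i) %||% "", held_primary[i])
      held_primary[i] <<- NA_character_
    }
  }
  release_all <- function(i, t) {
    release_staff(i, t)
    if (phase[i] == "ct_scan") { busy$ct_scanner <<- busy$ct_scanner - 1L
      log_ev(t, ids[i], "release", "CT", "ct_scanner") }
    release_primary(i, t)
    if (held_icu_resv[i]) { busy$icu_bed <<- busy$icu_bed - 1L
      log_ev(t, ids[i], "release", "ICU", "icu_bed_reserved")
      held_icu_resv[i] <<- FALSE }
    if (!is.na(held_transport[i])) {
      if (held_transport[i] == "transport_staff")
        busy$transport_staff <<- busy$transport_staff - 1L
      else busy_staff[held_transport[i]] <<- busy_staff[held_transport[i]] - 1L
      log_ev(t, ids[i], "release", "", paste0("transfer:", held_transport[i]))
      held_transport[i] <<- NA_character_
    }
  }

  needs_icu_resv <- function(i) {
    if (!hospital$or_icu_blocking) return(FALSE)
    if (!identical(cur_station(i), "OR") || held_icu_resv[i]) return(FALSE)
    any(vapply(plan[[i]], `[[`, character(1), "station") == "ICU")
  }

  # can treatment `tr` start now? returns "" or the failing condition
  start_check <- function(i, tr, t) {
    for (cat in names(tr$staff_demand))
      if (busy_staff[cat] + tr$staff_demand[[cat]] > staff_cap(cat, t))
        return("staff")
    if (length(tr$consumables))
      for (item in names(tr$consumables)) {
        have <- if (item %in% names(stock)) stock[[item]] else 0L
        if (have < tr$consumables[[item]]) return("consumables")
      }
    ""
  }
  start_treatment <- function(i, t) {
    tr <- cur_tr(i)
    if (length(tr$consumables))
      for (item in names(tr$consumables))
        stock[item] <<- stock[[item]] - tr$consumables[[item]]
    sd <- tr$staff_demand
    for (cat in names(sd)) busy_staff[cat] <<- busy_staff[cat] + sd[[cat]]
    held_staff[[i]] <<- sd
    log_ev(t, ids[i], "seize", cur_station(i),
           paste0("staff:", paste(names(sd), sd, sep = "=", collapse = ",")))
    log_ev(t, ids[i], "treatment_start", cur_station(i), tr$id)
    phase[i] <<- "service"
    t_next[i] <<- t + tr$duration_min
  }

  begin_ct <- function(i, t) {
    if (hospital$ct_in_ed) {
      phase[i] <<- "ct_queue"; t_next[i] <<- NA
      log_ev(t, ids[i], "queue_enter", "CT", "ct_scan")
      last_queue_t[i] <<- t
    } else {
      phase[i] <<- "ct_go"
      t_next[i] <<- t + hospital$ct_transport_min
      log_ev(t, ids[i], "transfer_start", "CT", "team_to_ct")
    }
  }

  finish_stage <- function(i, t) {
    release_primary(i, t)
    stage_i[i] <<- stage_i[i] + 1L
    tr_i[i] <<- 1L
    if (stage_i[i] > length(plan[[i]])) {
      phase[i] <<- "terminal"; terminal[i] <<- "discharge"; t_next[i] <<- NA
      log_ev(t, ids[i], "discharge", "", "")
    } else if (hospital$transfer_min == 0) {
      phase[i] <<- "queued"; t_next[i] <<- NA
      log_ev(t, ids[i], "queue_enter", cur_station(i), "")
      last_queue_t[i] <<- t
    } else {
      phase[i] <<- "xfer_wait"; t_next[i] <<- NA
      last_queue_t[i] <<- t
    }
  }

  end_treatment <- function(i, t) {
    tr <- cur_tr(i)
    release_staff(i, t)
    done[[i]] <<- c(done[[i]], tr$id)
    log_ev(t, ids[i], "treatment_end", cur_station(i), tr$id)
    st <- plan[[i]][[stage_i[i]]]
    if (tr_i[i] < length(st$trs)) {
      tr_i[i] <<- tr_i[i] + 1L
      phase[i] <<- "blocked"; t_next[i] <<- NA
    } else if (st$station == "ED" && st$ct_after &&
               !(".ct" %in% done[[i]])) {
      begin_ct(i, t)
    } else {
      finish_stage(i, t)
    }
  }

  station_of_wait <- function(i) {
    # station blamed when a deadline lapses: where the casualty is stuck
    if (phase[i] == "pre") return("prehospital")
    if (phase[i] %in% c("queued", "blocked") && !is.na(blocked_by[i]))
      return(blocked_by[i])
    if (phase[i] %in% c("ct_go", "ct_queue", "ct_scan", "ct_back")) return("CT")
    st <- cur_station(i)
    if (is.na(st)) "ED" else st
  }

  # --- main event loop -------------------------------------------------
  arr_ord <- order(arrive_t, ids)
  arr_ptr <- 1L; dl_ptr <- 1L; mob_ptr <- 1L; rst_ptr <- 1L
  repeat {
    cand <- c(if (arr_ptr <= n) arrive_t[arr_ord[arr_ptr]] else Inf,
              if (dl_ptr <= length(dl_rows)) dl_rows[[dl_ptr]]$t else Inf,
              if (mob_ptr <= length(mob_times)) mob_times[mob_ptr] else Inf,
              if (rst_ptr <= length(restock_times)) restock_times[rst_ptr] else Inf,
              suppressWarnings(min(t_next, na.rm = TRUE)))
    t <- min(cand)
    if (!is.finite(t) || t > horizon) break

    # phase 1: alert + mobilization logging
    while (mob_ptr <= length(mob_times) && mob_times[mob_ptr] == t) {
      if (t == alert) log_ev(t, "alert", "alert", "", profile)
      evs <- Filter(function(e) e$t == t, mob_events)
      for (e in evs[order(vapply(evs, `[[`, character(1), "res"))])
        log_ev(t, e$res, "mobilize", "", e$count)
      mob_ptr <- mob_ptr + 1L
    }
    # phase 2: restock
    while (rst_ptr <= length(restock_times) && restock_times[rst_ptr] == t) {
      batch <- restock[restock$t_min == t, , drop = FALSE]
      for (k in seq_len(nrow(batch))) {
        item <- batch$item[k]
        stock[item] <- (if (item %in% names(stock)) stock[[item]] else 0L) + batch$qty[k]
        log_ev(t, item, "restock", "", batch$qty[k])
      }
      rst_ptr <- rst_ptr + 1L
    }
    # phase 3: completions
    comp_idx <- which(!is.na(t_next) & t_next == t & alive)
    for (i in prio_order(comp_idx)) {
      if (phase[i] == "service") end_treatment(i, t)
      else if (phase[i] == "ct_go") {
        log_ev(t, ids[i], "transfer_end", "CT", "team_to_ct")
        phase[i] <- "ct_queue"
        t_next[i] <- NA
        log_ev(t, ids[i], "queue_enter", "CT", "ct_scan")
        last_queue_t[i] <- t
      } else if (phase[i] == "ct_scan") {
        busy$ct_scanner <- busy$ct_scanner - 1L
        log_ev(t, ids[i], "release", "CT", "ct_scanner")
        log_ev(t, ids[i], "treatment_end", "CT", ".ct")
        done[[i]] <- c(done[[i]], ".ct")
        if (hospital$ct_in_ed) finish_stage(i, t)
        else { phase[i] <- "ct_back"; t_next[i] <- t + hospital$ct_transport_min
               log_ev(t, ids[i], "transfer_start", "ED", "team_from_ct") }
      } else if (phase[i] == "ct_back") {
        log_ev(t, ids[i], "transfer_end", "ED", "team_from_ct")
        t_next[i] <- NA
        finish_stage(i, t)
      } else if (phase[i] == "xfer") {
        log_ev(t, ids[i], "transfer_end", cur_station(i), held_transport[i])
        if (held_transport[i] == "transport_staff")
          busy$transport_staff <- busy$transport_staff - 1L
        else busy_staff[held_transport[i]] <- busy_staff[held_transport[i]] - 1L
        log_ev(t, ids[i], "release", "", paste0("transfer:", held_transport[i]))
        held_transport[i] <- NA_character_
        phase[i] <- "queued"; t_next[i] <- NA
        log_ev(t, ids[i], "queue_enter", cur_station(i), "")
        last_queue_t[i] <- t
      }
    }
    # phase 4: deadline events (deaths, then complications)
    while (dl_ptr <= length(dl_rows) && dl_rows[[dl_ptr]]$t == t) {
      e <- dl_rows[[dl_ptr]]; dl_ptr <- dl_ptr + 1L
      i <- e$i
      if (!alive[i] || e$req %in% done[[i]]) next
      if (identical(terminal[i], "divert")) next
      if (e$kind == "death") {
        log_ev(t, ids[i], "death", station_of_wait(i), e$req)
        release_all(i, t)
        alive[i] <- FALSE; phase[i] <- "terminal"; terminal[i] <- "death"
        t_next[i] <- NA
      } else {
        log_ev(t, ids[i], "complication", station_of_wait(i), e$req)
      }
    }
    # phase 5: arrivals
    while (arr_ptr <= n && arrive_t[arr_ord[arr_ptr]] == t) {
      i <- arr_ord[arr_ptr]; arr_ptr <- arr_ptr + 1L
      if (!alive[i]) next   # died before reaching hospital
      log_ev(t, ids[i], "arrive", "", rows$mode[i])
      snap <- physiology_at(bank[[ids[i]]], t, done[[i]])
      log_ev(t, ids[i], "triage2", "", triage(snap))
      if (!is.null(controller) &&
          !isTRUE(controller(t, engine_report(t, hospital, profile, busy, phase, catg)))) {
        log_ev(t, ids[i], "divert", "", "inflow_closed")
        phase[i] <- "terminal"; terminal[i] <- "divert"
        next
      }
      if (length(plan[[i]]) == 0) {
        log_ev(t, ids[i], "discharge", "", "no_treatment")
        phase[i] <- "terminal"; terminal[i] <- "discharge"
      } else {
        phase[i] <- "queued"
        log_ev(t, ids[i], "queue_enter", cur_station(i), "")
        last_queue_t[i] <- t
      }
    }
    # phase 6: dispatch
    repeat {
      any_started <- FALSE
      # (a) blocked casualties holding their primary resource
      for (i in prio_order(which(phase == "blocked"))) {
        fail <- start_check(i, cur_tr(i), t)
        if (fail == "") { start_treatment(i, t); any_started <- TRUE }
        else {
          blocked_by[i] <- cur_station(i)
          if (fail == "consumables") {
            key <- paste0(stage_i[i], ".", tr_i[i])
            if (is.null(stockout_flag[[i]][[key]])) {
              log_ev(t, ids[i], "stock_out", cur_station(i), cur_tr(i)$id)
              stockout_flag[[i]][[key]] <- TRUE
            }
          }
        }
      }
      # (b) CT scanner queue
      for (i in prio_order(which(phase == "ct_queue"))) {
        if (busy$ct_scanner < cap$ct_scanner(t)) {
          busy$ct_scanner <- busy$ct_scanner + 1L
          log_ev(t, ids[i], "queue_exit", "CT", "")
          log_ev(t, ids[i], "seize", "CT", "ct_scanner")
          log_ev(t, ids[i], "treatment_start", "CT", ".ct")
          phase[i] <- "ct_scan"
          t_next[i] <- t + bank[[ids[i]]]$ct_scan_min
          any_started <- TRUE
        }
      }
      # (c) station queues in canonical order; within ED, REDs (major line)
      #     are dispatched before the minor line
      for (stn in STATIONS) {
        for (major in c(TRUE, FALSE)) {
          qi <- which(phase == "queued" &
                      vapply(seq_len(n), function(j)
                        identical(cur_station(j), stn), logical(1)) &
                      if (stn == "ED") (catg == "RED") == major else major)
          for (i in prio_order(qi)) {
            res <- primary_resource(stn, catg[i])
            reserved_icu <- stn == "ICU" && held_icu_resv[i]
            if (!reserved_icu && busy[[res]] >= cap[[res]](t)) {
              blocked_by[i] <- stn; next
            }
            if (needs_icu_resv(i) && busy$icu_bed >= cap$icu_bed(t)) {
              blocked_by[i] <- "ICU"; next
            }
            fail <- start_check(i, cur_tr(i), t)
            if (fail != "") {
              blocked_by[i] <- stn
              if (fail == "consumables") {
                key <- paste0(stage_i[i], ".", tr_i[i])
                if (is.null(stockout_flag[[i]][[key]])) {
                  log_ev(t, ids[i], "stock_out", stn, cur_tr(i)$id)
                  stockout_flag[[i]][[key]] <- TRUE
                }
              }
              next
            }
            log_ev(t, ids[i], "queue_exit", stn, "")
            if (reserved_icu) {
              held_icu_resv[i] <- FALSE   # reservation becomes occupancy
              held_primary[i] <- res
            } else {
              busy[[res]] <- busy[[res]] + 1L
              held_primary[i] <- res
              log_ev(t, ids[i], "seize", stn, res)
              if (needs_icu_resv(i)) {
                busy$icu_bed <- busy$icu_bed + 1L
                held_icu_resv[i] <- TRUE
                log_ev(t, ids[i], "seize", "ICU", "icu_bed_reserved")
              }
            }
            blocked_by[i] <- NA_character_
            start_treatment(i, t)
            any_started <- TRUE
          }
        }
      }
      # (d) inter-station transfers
      for (i in prio_order(which(phase == "xfer_wait"))) {
        token <- NA_character_
        if (busy$transport_staff < cap$transport_staff(t)) token <- "transport_staff"
        else {
          fb <- hospital$transfer_fallback_category
          if (!is.na(fb) && fb %in% staff_cats &&
              busy_staff[fb] < staff_cap(fb, t)) token <- fb
        }
        if (is.na(token)) { blocked_by[i] <- "transport"; next }
        if (token == "transport_staff") busy$transport_staff <- busy$transport_staff + 1L
        else busy_staff[token] <- busy_staff[token] + 1L
        held_transport[i] <- token
        log_ev(t, ids[i], "seize", "",
               if (token == "transport_staff") "transfer:transport_staff"
               else paste0("transfer:", token))
        if (token != "transport_staff")
          log_ev(t, ids[i], "indirect_loss", cur_station(i), token)
        log_ev(t, ids[i], "transfer_start", cur_station(i), token)
        phase[i] <- "xfer"
        t_next[i] <- t + hospital$transfer_min
        blocked_by[i] <- NA_character_
        any_started <- TRUE
      }
      if (!any_started) break
    }
  }

  log <- do.call(rbind, lapply(cs$log[seq_len(cs$nlog)], function(r)
    data.frame(t = r$t, id = r$id, event = r$event, station = r$station,
               detail = r$detail, stringsAsFactors = FALSE)))
  if (is.null(log))
    log <- data.frame(t = integer(), id = character(), event = character(),
                      station = character(), detail = character(),
                      stringsAsFactors = FALSE)
  terminal[is.na(terminal) & phase != "pre"] <- "in_progress_at_horizon"
  terminal[is.na(terminal)] <- "never_arrived"
  structure(log,
            class = c("event_log", "data.frame"),
            hospital = hospital$name, profile = profile, seed = seed,
            horizon = horizon,
            terminal = stats::setNames(terminal, ids))
}

# Internal status snapshot used when an inflow controller is attached.
engine_report <- function(t, hospital, profile, busy, phase, catg) {
  free_tu <- mobilized(hospital, "trauma_unit", t, profile) - busy$trauma_unit
  list(t_min = t,
       free_trauma_units = free_tu,
       queued_red = sum(phase == "queued" & catg == "RED"),
       free_or = mobilized(hospital, "or_theatre", t, profile) - busy$theatre,
       free_icu = mobilized(hospital, "icu_bed", t, profile) - busy$icu_bed)
}

#' Timing of a CT visit
#'
#' With the scanner inside the ED the casualty's team is tied up for the
#' scan only; with the scanner elsewhere the team also escorts the
#' casualty both ways, adding two transport legs.
#'
#' @param hospital a [hospital_config()].
#' @param scan_min scan duration.
#' @param t_start minute the visit begins.
#' @return list with `t_start`, `t_end`, and `team_blocked_min`.
#' @export
ct_visit <- function(hospital, scan_min, t_start = 0) {
  extra <- if (hospital$ct_in_ed) 0L else 2L * hospital$ct_transport_min
  list(t_start = as.integer(t_start),
       t_end = as.integer(t_start + scan_min + extra),
       team_blocked_min = as.integer(scan_min + extra))
}

#' Canonical ordering of an event log
#'
#' Sorts rows by time, a fixed event-kind rank, id, station and detail so
#' that two logs describing the same history compare equal row-by-row.
#'
#' @param log an `event_log`.
#' @return the sorted data frame (plain).
#' @export
canonical_log <- function(log) {
  rank <- match(log$event,
                c("alert", "mobilize", "restock", "or_cleared", "transfer_end",
                  "release", "treatment_end", "complication", "death", "arrive",
                  "triage2", "divert", "queue_enter", "queue_exit", "seize",
                  "treatment_start", "stock_out", "indirect_loss",
                  "transfer_start", "discharge"))
  out <- as.data.frame(log)[order(log$t, rank, log$id, log$station, log$detail), ]
  rownames(out) <- NULL
  out
}

#' Per-item consumable usage and stock-out accounting
#'
#' @param log an `event_log` from [run_hospital()].
#' @param hospital the [hospital_config()] the log was produced under.
#' @param bank the scenario or casualty bank backing the log.
#' @return data frame per supply item: initial stock, units consumed,
#'   final stock and number of stock-out waits.
#' @export
consume_supplies <- function(log, hospital, bank) {
  if (inherits(bank, "scenario")) bank <- bank_index(bank)
  items <- names(hospital$supplies)
  used <- stats::setNames(rep(0L, length(items)), items)
  starts <- log[log$event == "treatment_start" & log$detail != ".ct", , drop = FALSE]
  for (k in seq_len(nrow(starts))) {
    cas <- bank[[starts$id[k]]]
    tr <- Filter(function(x) x$id == starts$detail[k], cas$treatments)[[1]]
    for (item in names(tr$consumables))
      used[item] <- used[item] + tr$consumables[[item]]
  }
  so <- log[log$event == "stock_out", , drop = FALSE]
  restocked <- stats::setNames(rep(0L, length(items)), items)
  if (!is.null(hospital$restock))
    for (k in seq_len(nrow(hospital$restock))) {
      it <- hospital$restock$item[k]
      if (it %in% items) restocked[it] <- restocked[it] + hospital$restock$qty[k]
    }
  data.frame(item = items,
             initial_stock = as.integer(hospital$supplies[items]),
             restocked = as.integer(restocked),
             consumed = as.integer(used[items]),
             final_stock = as.integer(hospital$supplies[items] + restocked - used[items]),
             n_stock_out_waits = vapply(items, function(it) {
               if (nrow(so) == 0) return(0L)
               sum(vapply(seq_len(nrow(so)), function(k) {
                 cas <- bank[[so$id[k]]]
                 tr <- Filter(function(x) x$id == so$detail[k], cas$treatments)[[1]]
                 it %in% names(tr$consumables)
               }, logical(1)))
             }, integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
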