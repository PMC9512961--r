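# Brute-force 1-minute time-stepped reference simulator.
#
# Independent implementation of the engine semantics: it advances the
# clock one minute at a time and re-evaluates the whole state with plain
# loops and no event calendar.  Used to verify that the event-driven
# engine's log is exactly reproduced.

# Drop the engine's run-metadata attributes so logs compare row-for-row.
strip_log <- function(x) {
  x <- as.data.frame(x)
  for (a in setdiff(names(attributes(x)), c("names", "row.names", "class")))
    attr(x, a) <- NULL
  rownames(x) <- NULL
  x
}

oracle_run <- function(hospital, stream, bank, profile = NULL,
                       hospital_index = 1L) {
  if (inherits(bank, "scenario")) {
    if (is.null(profile)) profile <- bank$incident_time_of_day
    bank <- surgesim:::bank_index(bank)
  }
  if (is.null(profile)) profile <- "office"
  rows <- stream[stream$hospital == hospital_index, , drop = FALSE]
  horizon <- hospital$horizon_min
  alert <- hospital$alert_offset_min
  n <- nrow(rows)
  ids <- rows$casualty_id
  arrive_t <- rows$arrival_min
  catg <- vapply(ids, function(cid) bank[[cid]]$true_category, character(1))
  plan <- lapply(ids, function(cid) surgesim:::build_plan(bank[[cid]]))

  LOG <- list()
  emit <- function(t, id, event, station = "", detail = "")
    LOG[[length(LOG) + 1L]] <<- data.frame(t = as.integer(t), id = id,
                                           event = event, station = station,
                                           detail = as.character(detail),
                                           stringsAsFactors = FALSE)

  staff_cats <- names(hospital$staff_roster[[profile]])
  rescap <- function(res, t) {
    switch(res,
           trauma_unit = mobilized(hospital, "trauma_unit", t, profile),
           minor_slot = hospital$n_minor_units,
           ct_scanner = hospital$n_ct,
           theatre = mobilized(hospital, "or_theatre", t, profile),
           icu_bed = mobilized(hospital, "icu_bed", t, profile),
           ward_bed = hospital$n_ward_beds,
           transport_staff = mobilized(hospital, "transport_staff", t, profile),
           mobilized(hospital, res, t, profile))
  }

  st <- list(phase = rep("pre", n), stage = rep(1L, n), tr = rep(1L, n),
             t_next = rep(NA_real_, n),
             done = lapply(seq_len(n), function(i) character()),
             primary = rep(NA_character_, n),
             icu_resv = rep(FALSE, n),
             staff = vector("list", n),
             token = rep(NA_character_, n),
             alive = rep(TRUE, n),
             terminal = rep(NA_character_, n),
             blocked_by = rep(NA_character_, n))
  busy <- c(trauma_unit = 0L, minor_slot = 0L, ct_scanner = 0L, theatre = 0L,
            icu_bed = 0L, ward_bed = 0L, transport_staff = 0L)
  busy_staff <- stats::setNames(rep(0L, length(staff_cats)), staff_cats)
  stock <- hospital$supplies
  so_flag <- lapply(seq_len(n), function(i) list())

  stn_of <- function(i) {
    if (st$stage[i] > length(plan[[i]])) NA_character_
    else plan[[i]][[st$stage[i]]]$station
  }
  tr_of <- function(i) plan[[i]][[st$stage[i]]]$trs[[st$tr[i]]]
  next_dl <- function(i) {
    v <- vapply(bank[[ids[i]]]$treatments, function(x)
      if (!is.na(x$deadline_min) && !(x$id %in% st$done[[i]]))
        as.numeric(x$deadline_min) else Inf, numeric(1))
    if (length(v)) min(v) else Inf
  }
  by_prio <- function(idx) {
    if (length(idx) <= 1) return(idx)
    rank <- c(RED = 1, YELLOW = 2, GREEN = 3, DEAD = 4)
    idx[order(rank[catg[idx]], vapply(idx, next_dl, numeric(1)),
              arrive_t[idx], ids[idx])]
  }
  staff_txt <- function(sd) paste0("staff:", paste(names(sd), sd, sep = "=",
                                                   collapse = ","))
  rel_staff <- function(i, t) {
    sd <- st$staff[[i]]
    if (!is.null(sd)) {
      for (cc in names(sd)) busy_staff[cc] <<- busy_staff[cc] - sd[[cc]]
      emit(t, ids[i], "release", stn_of(i) %||% "", staff_txt(sd))
      st$staff[i] <<- list(NULL)
    }
  }
  rel_primary <- function(i, t) {
    if (!is.na(st$primary[i])) {
      busy[st$primary[i]] <<- busy[st$primary[i]] - 1L
      emit(t, ids[i], "release", stn_of(i) %||% "", st$primary[i])
      st$primary[i] <<- NA_character_
    }
  }
  `%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

  start_tx <- function(i, t) {
    tr <- tr_of(i)
    for (item in names(tr$consumables))
      stock[item] <<- stock[[item]] - tr$consumables[[item]]
    for (cc in names(tr$staff_demand))
      busy_staff[cc] <<- busy_staff[cc] + tr$staff_demand[[cc]]
    st$staff[[i]] <<- tr$staff_demand
    emit(t, ids[i], "seize", stn_of(i), staff_txt(tr$staff_demand))
    emit(t, ids[i], "treatment_start", stn_of(i), tr$id)
    st$phase[i] <<- "service"
    st$t_next[i] <<- t + tr$duration_min
  }
  can_start <- function(i, t) {
    tr <- tr_of(i)
    for (cc in names(tr$staff_demand))
      if (busy_staff[cc] + tr$staff_demand[[cc]] > rescap(cc, t)) return("staff")
    for (item in names(tr$consumables)) {
      have <- if (item %in% names(stock)) stock[[item]] else 0L
      if (have < tr$consumables[[item]]) return("consumables")
    }
    ""
  }
  note_stockout <- function(i, t, stn) {
    key <- paste0(st$stage[i], ".", st$tr[i])
    if (is.null(so_flag[[i]][[key]])) {
      emit(t, ids[i], "stock_out", stn, tr_of(i)$id)
      so_flag[[i]][[key]] <<- TRUE
    }
  }
  finish_stage <- function(i, t) {
    rel_primary(i, t)
    st$stage[i] <<- st$stage[i] + 1L
    st$tr[i] <<- 1L
    if (st$stage[i] > length(plan[[i]])) {
      st$phase[i] <<- "terminal"; st$terminal[i] <<- "discharge"
      st$t_next[i] <<- NA
      emit(t, ids[i], "discharge", "", "")
    } else if (hospital$transfer_min == 0) {
      st$phase[i] <<- "queued"; st$t_next[i] <<- NA
      emit(t, ids[i], "queue_enter", stn_of(i), "")
    } else {
      st$phase[i] <<- "xfer_wait"; st$t_next[i] <<- NA
    }
  }
  begin_ct <- function(i, t) {
    if (hospital$ct_in_ed) {
      st$phase[i] <<- "ct_queue"; st$t_next[i] <<- NA
      emit(t, ids[i], "queue_enter", "CT", "ct_scan")
    } else {
      st$phase[i] <<- "ct_go"
      st$t_next[i] <<- t + hospital$ct_transport_min
      emit(t, ids[i], "transfer_start", "CT", "team_to_ct")
    }
  }
  end_tx <- function(i, t) {
    tr <- tr_of(i)
    rel_staff(i, t)
    st$done[[i]] <<- c(st$done[[i]], tr$id)
    emit(t, ids[i], "treatment_end", stn_of(i), tr$id)
    stg <- plan[[i]][[st$stage[i]]]
    if (st$tr[i] < length(stg$trs)) {
      st$tr[i] <<- st$tr[i] + 1L
      st$phase[i] <<- "blocked"; st$t_next[i] <<- NA
    } else if (stg$station == "ED" && stg$ct_after && !(".ct" %in% st$done[[i]])) {
      begin_ct(i, t)
    } else finish_stage(i, t)
  }
  wait_station <- function(i) {
    if (st$phase[i] == "pre") return("prehospital")
    if (st$phase[i] %in% c("queued", "blocked") && !is.na(st$blocked_by[i]))
      return(st$blocked_by[i])
    if (st$phase[i] %in% c("ct_go", "ct_queue", "ct_scan", "ct_back")) return("CT")
    s <- stn_of(i); if (is.na(s)) "ED" else s
  }
  kill <- function(i, t, req) {
    emit(t, ids[i], "death", wait_station(i), req)
    rel_staff(i, t)
    if (st$phase[i] == "ct_scan") {
      busy["ct_scanner"] <<- busy["ct_scanner"] - 1L
      emit(t, ids[i], "release", "CT", "ct_scanner")
    }
    rel_primary(i, t)
    if (st$icu_resv[i]) {
      busy["icu_bed"] <<- busy["icu_bed"] - 1L
      emit(t, ids[i], "release", "ICU", "icu_bed_reserved")
      st$icu_resv[i] <<- FALSE
    }
    if (!is.na(st$token[i])) {
      if (st$token[i] == "transport_staff")
        busy["transport_staff"] <<- busy["transport_staff"] - 1L
      else busy_staff[st$token[i]] <<- busy_staff[st$token[i]] - 1L
      emit(t, ids[i], "release", "", paste0("transfer:", st$token[i]))
      st$token[i] <<- NA_character_
    }
    st$alive[i] <<- FALSE; st$phase[i] <<- "terminal"
    st$terminal[i] <<- "death"; st$t_next[i] <<- NA
  }

  for (t in 0:horizon) {
    # 1: alert + mobilization (compare each resource with the previous minute)
    mobres <- sort(c("trauma_unit", "icu_bed", "theatre", "transport_staff",
                     staff_cats))
    changed <- if (t == 0) character() else
      mobres[vapply(mobres, function(r) {
        r2 <- if (r == "theatre") "or_theatre" else r
        mobilized2 <- function(tt) switch(r, theatre = rescap("theatre", tt),
                                          rescap(r, tt))
        mobilized2(t) != mobilized2(t - 1)
      }, logical(1))]
    if (t == alert || length(changed)) {
      if (t == alert) emit(t, "alert", "alert", "", profile)
      for (r in changed) emit(t, r, "mobilize", "", rescap(r, t))
    }
    # 2: restock
    if (!is.null(hospital$restock)) {
      batch <- hospital$restock[hospital$restock$t_min == t, , drop = FALSE]
      for (k in seq_len(nrow(batch))) {
        item <- batch$item[k]
        stock[item] <- (if (item %in% names(stock)) stock[[item]] else 0L) +
          batch$qty[k]
        emit(t, item, "restock", "", batch$qty[k])
      }
    }
    # 3: completions
    for (i in by_prio(which(!is.na(st$t_next) & st$t_next == t & st$alive))) {
      ph <- st$phase[i]
      if (ph == "service") end_tx(i, t)
      else if (ph == "ct_go") {
        emit(t, ids[i], "transfer_end", "CT", "team_to_ct")
        st$phase[i] <- "ct_queue"; st$t_next[i] <- NA
        emit(t, ids[i], "queue_enter", "CT", "ct_scan")
      } else if (ph == "ct_scan") {
        busy["ct_scanner"] <- busy["ct_scanner"] - 1L
        emit(t, ids[i], "release", "CT", "ct_scanner")
        emit(t, ids[i], "treatment_end", "CT", ".ct")
        st$done[[i]] <- c(st$done[[i]], ".ct")
        if (hospital$ct_in_ed) finish_stage(i, t)
        else {
          st$phase[i] <- "ct_back"
          st$t_next[i] <- t + hospital$ct_transport_min
          emit(t, ids[i], "transfer_start", "ED", "team_from_ct")
        }
      } else if (ph == "ct_back") {
        emit(t, ids[i], "transfer_end", "ED", "team_from_ct")
        st$t_next[i] <- NA
        finish_stage(i, t)
      } else if (ph == "xfer") {
        emit(t, ids[i], "transfer_end", stn_of(i), st$token[i])
        if (st$token[i] == "transport_staff")
          busy["transport_staff"] <- busy["transport_staff"] - 1L
        else busy_staff[st$token[i]] <- busy_staff[st$token[i]] - 1L
        emit(t, ids[i], "release", "", paste0("transfer:", st$token[i]))
        st$token[i] <- NA_character_
        st$phase[i] <- "queued"; st$t_next[i] <- NA
        emit(t, ids[i], "queue_enter", stn_of(i), "")
      }
    }
    # 4: deadlines (deaths before complications, in stream-row order)
    for (kind in c("death", "comp")) {
      for (i in seq_len(n)) {
        if (!st$alive[i] || identical(st$terminal[i], "divert")) next
        for (tr in bank[[ids[i]]]$treatments) {
          dl <- if (kind == "death") tr$deadline_min else tr$complication_deadline_min
          if (!is.na(dl) && dl == t && !(tr$id %in% st$done[[i]])) {
            if (kind == "death") { kill(i, t, tr$id); break }
            else emit(t, ids[i], "complication", wait_station(i), tr$id)
          }
        }
      }
    }
    # 5: arrivals (ordered by id within the minute)
    arr <- which(arrive_t == t)
    for (i in arr[order(ids[arr])]) {
      if (!st$alive[i]) next
      emit(t, ids[i], "arrive", "", rows$mode[i])
      snap <- physiology_at(bank[[ids[i]]], t, st$done[[i]])
      emit(t, ids[i], "triage2", "", triage(snap))
      if (length(plan[[i]]) == 0) {
        emit(t, ids[i], "discharge", "", "no_treatment")
        st$phase[i] <- "terminal"; st$terminal[i] <- "discharge"
      } else {
        st$phase[i] <- "queued"
        emit(t, ids[i], "queue_enter", stn_of(i), "")
      }
    }
    # 6: dispatch until stable
    repeat {
      started <- FALSE
      for (i in by_prio(which(st$phase == "blocked"))) {
        fail <- can_start(i, t)
        if (fail == "") { start_tx(i, t); started <- TRUE }
        else {
          st$blocked_by[i] <- stn_of(i)
          if (fail == "consumables") note_stockout(i, t, stn_of(i))
        }
      }
      for (i in by_prio(which(st$phase == "ct_queue"))) {
        if (busy["ct_scanner"] < rescap("ct_scanner", t)) {
          busy["ct_scanner"] <- busy["ct_scanner"] + 1L
          emit(t, ids[i], "queue_exit", "CT", "")
          emit(t, ids[i], "seize", "CT", "ct_scanner")
          emit(t, ids[i], "treatment_start", "CT", ".ct")
          st$phase[i] <- "ct_scan"
          st$t_next[i] <- t + bank[[ids[i]]]$ct_scan_min
          started <- TRUE
        }
      }
      for (stn in c("ED", "CT", "OR", "ICU", "WARD")) {
        for (major in c(TRUE, FALSE)) {
          qi <- which(st$phase == "queued" &
                        vapply(seq_len(n), function(j)
                          identical(stn_of(j), stn), logical(1)) &
                        (if (stn == "ED") (catg == "RED") == major else major))
          for (i in by_prio(qi)) {
            res <- surgesim:::primary_resource(stn, catg[i])
            resv <- stn == "ICU" && st$icu_resv[i]
            if (!resv && busy[res] >= rescap(res, t)) {
              st$blocked_by[i] <- stn; next
            }
            need_resv <- hospital$or_icu_blocking && stn == "OR" &&
              !st$icu_resv[i] &&
              any(vapply(plan[[i]], `[[`, character(1), "station") == "ICU")
            if (need_resv && busy["icu_bed"] >= rescap("icu_bed", t)) {
              st$blocked_by[i] <- "ICU"; next
            }
            fail <- can_start(i, t)
            if (fail != "") {
              st$blocked_by[i] <- stn
              if (fail == "consumables") note_stockout(i, t, stn)
              next
            }
            emit(t, ids[i], "queue_exit", stn, "")
            if (resv) {
              st$icu_resv[i] <- FALSE
              st$primary[i] <- res
            } else {
              busy[res] <- busy[res] + 1L
              st$primary[i] <- res
              emit(t, ids[i], "seize", stn, res)
              if (need_resv) {
                busy["icu_bed"] <- busy["icu_bed"] + 1L
                st$icu_resv[i] <- TRUE
                emit(t, ids[i], "seize", "ICU", "icu_bed_reserved")
              }
            }
            st$blocked_by[i] <- NA_character_
            start_tx(i, t)
            started <- TRUE
          }
        }
      }
      for (i in by_prio(which(st$phase == "xfer_wait"))) {
        token <- NA_character_
        if (busy["transport_staff"] < rescap("transport_staff", t))
          token <- "transport_staff"
        else {
          fb <- hospital$transfer_fallback_category
          if (!is.na(fb) && fb %in% staff_cats &&
              busy_staff[fb] < rescap(fb, t)) token <- fb
        }
        if (is.na(token)) { st$blocked_by[i] <- "transport"; next }
        if (token == "transport_staff")
          busy["transport_staff"] <- busy["transport_staff"] + 1L
        else busy_staff[token] <- busy_staff[token] + 1L
        st$token[i] <- token
        emit(t, ids[i], "seize", "", paste0("transfer:", token))
        if (token != "transport_staff")
          emit(t, ids[i], "indirect_loss", stn_of(i), token)
        emit(t, ids[i], "transfer_start", stn_of(i), token)
        st$phase[i] <- "xfer"
        st$t_next[i] <- t + hospital$transfer_min
        st$blocked_by[i] <- NA_character_
        started <- TRUE
      }
      if (!started) break
    }
  }
  if (length(LOG) == 0)
    return(data.frame(t = integer(), id = character(), event = character(),
                      station = character(), detail = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, LOG)
  rownames(out) <- NULL
  out
}

# A randomized small scenario + fleet + hospital setting (<= 10 casualties)
# used by the engine-vs-oracle equivalence checks.
random_small_setting <- function(seed) {
  set.seed(seed)
  n <- sample(2:10, 1)
  tpl <- default_template()
  sc <- generate_scenario(tpl, n, seed)
  fleet <- ambulance_fleet(n_ambulances = sample(1:3, 1),
                           dispatch_delay_min = sample(0:10, 1),
                           load_min = sample(2:6, 1),
                           unload_min = sample(0:5, 1),
                           spontaneous_fraction = sample(c(0, 0.5, 1), 1))
  h <- flat_hospital(units = sample(1:3, 1),
                     minor = sample(1:3, 1),
                     or = sample(1:2, 1),
                     icu = sample(1:2, 1),
                     ct = 1,
                     ct_in_ed = sample(c(TRUE, FALSE), 1),
                     ct_transport = sample(c(5, 10), 1),
                     transfer = sample(c(0, 5), 1),
                     transport_staff = sample(0:2, 1),
                     nurse = sample(3:6, 1),
                     surgeon = sample(1:3, 1),
                     icu_nurse = sample(1:2, 1),
                     physician = sample(2:4, 1),
                     supplies = c(chest_drain_set = sample(0:3, 1),
                                  surgical_disposables = sample(1:5, 1),
                                  ext_fixation_set = sample(0:2, 1),
                                  blood_units = sample(2:10, 1)),
                     or_icu_blocking = sample(c(TRUE, FALSE), 1),
                     alert_offset = sample(c(0, 5), 1),
                     horizon = 480)
  list(sc = sc, fleet = fleet, h = h)
}
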