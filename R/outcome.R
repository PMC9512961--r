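# Endpoints: preventable deaths with cause attribution, station load
# curves, and the numerically determined surge capacity per hospital
# component.

#' Score an event log into an outcome report
#'
#' A death is *preventable* when the casualty would have survived optimal
#' treatment (`survivable_if_optimal`) and the missed deadline elapsed
#' while the casualty was queued, blocked or still awaiting evacuation;
#' it is attributed to the station where the casualty was stuck (the
#' blocking resource), with the missed requirement and its wait recorded.
#'
#' @param log an `event_log` from [run_hospital()] (or several `rbind`ed).
#' @param bank the scenario (or named casualty list) backing the log.
#' @param phase_windows named numeric vector of right-open phase-window
#'   starts (minutes) used for the limiting-factor sequence.
#' @return an object of class `"outcome_report"`.
#' @export
score_outcomes <- function(log, bank,
                           phase_windows = c(ED_phase = 0, OR_phase = 120,
                                             ICU_phase = 480)) {
  if (inherits(bank, "scenario")) bank <- bank_index(bank)
  ids_in_log <- unique(log$id[log$event %in%
    c("arrive", "death", "complication", "divert")])
  missing_ids <- setdiff(ids_in_log, names(bank))
  if (length(missing_ids))
    abort_config("event log references casualty id(s) absent from bank: %s",
                 paste(missing_ids, collapse = ", "))

  deaths <- log[log$event == "death", , drop = FALSE]
  comps <- log[log$event == "complication", , drop = FALSE]
  mk_wait <- function(cid, t_dead) {
    qe <- log[log$id == cid & log$event %in% c("queue_enter", "arrive") &
              log$t <= t_dead, , drop = FALSE]
    if (nrow(qe) == 0) return(NA_integer_)
    t_dead - max(qe$t)
  }
  classify <- function(k) {
    cid <- deaths$id[k]
    data.frame(casualty_id = cid, t_min = deaths$t[k],
               station = deaths$station[k],
               missed_requirement = deaths$detail[k],
               deadline_min = deaths$t[k],
               wait_min = mk_wait(cid, deaths$t[k]),
               preventable = bank[[cid]]$survivable_if_optimal,
               stringsAsFactors = FALSE)
  }
  dtab <- if (nrow(deaths)) do.call(rbind, lapply(seq_len(nrow(deaths)), classify))
          else data.frame(casualty_id = character(), t_min = integer(),
                          station = character(), missed_requirement = character(),
                          deadline_min = integer(), wait_min = integer(),
                          preventable = logical(), stringsAsFactors = FALSE)
  ctab <- data.frame(casualty_id = comps$id, t_min = comps$t,
                     station = comps$station, requirement = comps$detail,
                     stringsAsFactors = FALSE)

  win_start <- sort(phase_windows)
  win_end <- c(win_start[-1], Inf)
  pressure <- rbind(dtab[dtab$preventable, c("t_min", "station")],
                    stats::setNames(ctab[, c("t_min", "station")],
                                    c("t_min", "station")))
  lfs <- do.call(rbind, lapply(seq_along(win_start), function(w) {
    seg <- pressure[pressure$t_min >= win_start[w] & pressure$t_min < win_end[w], ]
    data.frame(phase = names(win_start)[w], from_min = win_start[[w]],
               station = if (nrow(seg)) names(which.max(table(seg$station)))
                         else NA_character_,
               n_events = nrow(seg), stringsAsFactors = FALSE)
  }))

  structure(list(
    n_admitted = sum(log$event == "arrive"),
    n_diverted = sum(log$event == "divert"),
    preventable_deaths = dtab[dtab$preventable, , drop = FALSE],
    non_preventable_deaths = dtab[!dtab$preventable, , drop = FALSE],
    complications = ctab,
    limiting_factor_sequence = lfs), class = "outcome_report")
}

#' @export
print.outcome_report <- function(x, ...) {
  cat(sprintf("<outcome_report> admitted %d, diverted %d\n",
              x$n_admitted, x$n_diverted))
  cat(sprintf("  preventable deaths: %d  (non-preventable: %d, complications: %d)\n",
              nrow(x$preventable_deaths), nrow(x$non_preventable_deaths),
              nrow(x$complications)))
  if (nrow(x$preventable_deaths)) {
    tab <- table(x$preventable_deaths$station)
    cat("  by station:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  }
  for (k in seq_len(nrow(x$limiting_factor_sequence))) {
    r <- x$limiting_factor_sequence[k, ]
    cat(sprintf("  %s (from %d min): %s (%d events)\n",
                r$phase, r$from_min, r$station %||% "-", r$n_events))
  }
  invisible(x)
}

#' Station load curves from an event log
#'
#' Per-minute occupancy series per station: units in action, units at
#' disposal (mobilized minus in action), casualties waiting, and the
#' cumulative preventable-death count.  By construction
#' `in_action + at_disposal` equals the mobilized count at every minute.
#'
#' @param log an `event_log`.
#' @param hospital,bank the configuration and bank behind the log.
#' @param bin_min bin width in minutes (>= 1).
#' @param profile staff profile the log was run under.
#' @return tidy data frame `(t_bin, station, metric, value)`.
#' @export
load_curves <- function(log, hospital, bank, bin_min = 1,
                        profile = attr(log, "profile") %||% "office") {
  stopifnot(bin_min >= 1)
  if (inherits(bank, "scenario")) bank <- bank_index(bank)
  horizon <- attr(log, "horizon") %||% hospital$horizon_min
  tt <- seq(0L, horizon, by = 1L)
  res_station <- c(trauma_unit = "ED", minor_slot = "ED_minor", theatre = "OR",
                   icu_bed = "ICU", icu_bed_reserved = "ICU", ward_bed = "WARD")
  occ <- function(detail_set, station_lab) {
    delta <- integer(length(tt))
    sz <- log[log$event == "seize" & log$detail %in% detail_set, , drop = FALSE]
    rl <- log[log$event == "release" & log$detail %in% detail_set, , drop = FALSE]
    for (t0 in sz$t) delta[t0 + 1L] <- delta[t0 + 1L] + 1L
    for (t0 in rl$t) if (t0 <= horizon) delta[t0 + 1L] <- delta[t0 + 1L] - 1L
    cumsum(delta)
  }
  mob_of <- function(stn) {
    switch(stn,
           ED = mobilized(hospital, "trauma_unit", tt, profile),
           ED_minor = rep(hospital$n_minor_units, length(tt)),
           OR = mobilized(hospital, "or_theatre", tt, profile),
           ICU = mobilized(hospital, "icu_bed", tt, profile),
           WARD = rep(hospital$n_ward_beds, length(tt)))
  }
  waiting_of <- function(stn) {
    delta <- integer(length(tt))
    qe <- log[log$event == "queue_enter" & log$station == stn, , drop = FALSE]
    qx <- log[log$event %in% c("queue_exit", "death", "divert"), , drop = FALSE]
    for (t0 in qe$t) delta[t0 + 1L] <- delta[t0 + 1L] + 1L
    # a queue is left on admission or on death while queued
    for (k in seq_len(nrow(qe))) {
      cid <- qe$id[k]; t0 <- qe$t[k]
      after <- qx[qx$id == cid & qx$t >= t0, , drop = FALSE]
      after <- after[after$event != "queue_exit" | after$station == stn, , drop = FALSE]
      if (nrow(after)) {
        tx <- min(after$t)
        if (tx <= horizon) delta[tx + 1L] <- delta[tx + 1L] - 1L
      }
    }
    cumsum(delta)
  }
  stations <- c("ED", "ED_minor", "OR", "ICU", "WARD")
  det_sets <- list(ED = "trauma_unit", ED_minor = "minor_slot", OR = "theatre",
                   ICU = c("icu_bed", "icu_bed_reserved"), WARD = "ward_bed")
  prev_deaths <- log[log$event == "death", , drop = FALSE]
  if (nrow(prev_deaths)) {
    surv <- vapply(prev_deaths$id, function(cid) bank[[cid]]$survivable_if_optimal,
                   logical(1))
    prev_deaths <- prev_deaths[surv, , drop = FALSE]
  }
  cum_pd <- cumsum(tabulate(prev_deaths$t + 1L, nbins = length(tt)))
  bins <- (tt %/% bin_min) * bin_min
  agg <- function(v, f) as.vector(tapply(v, bins, f))
  t_bin <- sort(unique(bins))
  out <- list()
  for (stn in stations) {
    ia <- occ(det_sets[[stn]], stn)
    mob <- mob_of(stn)
    for (m in c("in_action", "at_disposal", "waiting")) {
      v <- switch(m, in_action = ia, at_disposal = mob - ia,
                  waiting = waiting_of(stn))
      out[[length(out) + 1L]] <- data.frame(
        t_bin = t_bin, station = stn, metric = m,
        value = agg(v, max), stringsAsFactors = FALSE)
    }
  }
  out[[length(out) + 1L]] <- data.frame(
    t_bin = t_bin, station = "all", metric = "cum_preventable_deaths",
    value = agg(cum_pd, max), stringsAsFactors = FALSE)
  do.call(rbind, out)
}

#' Arrival histogram per triage category
#'
#' The per-time-unit arrival counts behind the characteristic pictures:
#' wave-structured RED/YELLOW ambulance arrivals versus the continuous
#' GREEN stream.
#'
#' @param stream an arrival stream.
#' @param bin_min bin width (minutes).
#' @return data frame `(t_bin, category, n)`.
#' @export
arrival_histogram <- function(stream, bin_min = 5) {
  if (nrow(stream) == 0)
    return(data.frame(t_bin = integer(), category = character(), n = integer()))
  b <- (stream$arrival_min %/% bin_min) * bin_min
  agg <- stats::aggregate(list(n = stream$arrival_min),
                          by = list(t_bin = b, category = stream$category),
                          FUN = length)
  agg[order(agg$t_bin, agg$category), ]
}

#' Determine surge capacity by monotone bisection
#'
#' The capacity of a hospital component is the largest casualty load `n`
#' in `n_range` for which the full pipeline (scenario scaled to `n` with
#' preserved proportions, evacuation, engine run, outcome scoring) yields
#' zero preventable deaths -- and, by default, zero severe complications --
#' attributed to that component, in every one of `replicates` paired
#' replicate runs.  Monotonicity of the pass predicate in `n` is assumed
#' for the bisection and then audited with a +/-2 verification sweep; on
#' audit failure the search falls back to an exhaustive linear sweep and
#' warns.
#'
#' @param hospital a [hospital_config()].
#' @param template a [scenario_template()].
#' @param fleet an [ambulance_fleet()].
#' @param component `"overall"` or a station (`"ED"`, `"CT"`, `"OR"`,
#'   `"ICU"`, `"WARD"`, `"prehospital"`, `"transport"`).
#' @param n_range integer `c(n_lo, n_hi)` search interval.
#' @param seed master seed; replicate sub-seeds are split from it.
#' @param replicates stochastic replicates per load (1 = the single
#'   physical test run).
#' @param include_complications also require zero severe complications?
#' @param profile staff profile; defaults to the template's time of day.
#' @param policy destination policy for [simulate_evacuation()].
#' @return an object of class `"surge_capacity"`: the capacity, the
#'   evaluation table and the search method actually used.  If even
#'   `n_lo` fails, the capacity is `n_lo - 1` (meaning: strictly below
#'   the searched range).
#' @export
determine_capacity <- function(hospital, template, fleet,
                               component = "overall",
                               n_range = c(1, 60), seed = 1,
                               replicates = 1,
                               include_complications = TRUE,
                               profile = NULL, policy = "nearest") {
  stopifnot(length(n_range) == 2, n_range[1] < n_range[2])
  n_lo <- as.integer(n_range[1]); n_hi <- as.integer(n_range[2])
  profile <- profile %||% template$incident_time_of_day
  seeds <- split_seed(seed, replicates)
  cache <- new.env(parent = emptyenv())
  evaluate <- function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    ok <- TRUE
    for (r in seq_len(replicates)) {
      sc <- generate_scenario(template, n, seeds[r])
      stream <- simulate_evacuation(sc, fleet, policy = policy)
      log <- run_hospital(hospital, stream, sc, profile = profile)
      rep_out <- score_outcomes(log, sc)
      bad <- rep_out$preventable_deaths
      cmp <- rep_out$complications
      if (component != "overall") {
        bad <- bad[bad$station == component, , drop = FALSE]
        cmp <- cmp[cmp$station == component, , drop = FALSE]
      }
      if (nrow(bad) > 0 || (include_complications && nrow(cmp) > 0)) {
        ok <- FALSE; break
      }
    }
    cache[[key]] <- ok
    ok
  }
  method <- "bisection"
  if (!evaluate(n_lo)) {
    capacity <- n_lo - 1L
  } else if (evaluate(n_hi)) {
    capacity <- n_hi
  } else {
    lo <- n_lo; hi <- n_hi   # invariant: pass(lo), fail(hi)
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (evaluate(mid)) lo <- mid else hi <- mid
    }
    capacity <- lo
  }
  # verification sweep: +/-2 around the answer must be consistent with
  # a monotone pass predicate
  audit_ok <- TRUE
  for (m in max(n_lo, capacity - 2L):min(n_hi, capacity + 2L)) {
    if (m <= capacity && capacity >= n_lo && !evaluate(m)) audit_ok <- FALSE
    if (m > capacity && evaluate(m)) audit_ok <- FALSE
  }
  if (!audit_ok) {
    warning("capacity predicate not monotone near the bisection answer; ",
            "falling back to exhaustive linear sweep", call. = FALSE)
    method <- "linear_sweep"
    passes <- vapply(n_lo:n_hi, evaluate, logical(1))
    capacity <- if (any(passes)) (n_lo:n_hi)[max(which(passes))] else n_lo - 1L
  }
  evald <- sort(as.integer(ls(cache)))
  structure(list(capacity = as.integer(capacity), component = component,
                 method = method, replicates = replicates, seed = seed,
                 n_range = c(n_lo, n_hi),
                 include_complications = include_complications,
                 evaluations = data.frame(
                   n = evald,
                   pass = vapply(as.character(evald), function(k) cache[[k]],
                                 logical(1)))),
            class = "surge_capacity")
}

#' @export
print.surge_capacity <- function(x, ...) {
  cat(sprintf("<surge_capacity> component %s: %d casualties (seed %s, %d replicate%s, %s)\n",
              x$component, x$capacity, format(x$seed), x$replicates,
              if (x$replicates > 1) "s" else "", x$method))
  invisible(x)
}
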