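# Scene-to-hospital evacuation: a finite ambulance fleet shuttling between
# scene and hospitals produces the characteristic "wave" structure of RED
# and YELLOW arrivals; walking wounded leave in a continuous spontaneous
# stream not dependent on ambulances.

#' Construct an ambulance fleet
#'
#' @param n_ambulances number of vehicles (>= 1 unless the whole load is
#'   spontaneous).
#' @param capacity_stretcher stretcher cases (RED/YELLOW) per trip.
#' @param capacity_sitting sitting cases (GREEN) per trip.
#' @param dispatch_delay_min minutes until the vehicles first reach the
#'   scene.  The shipped default fleet is calibrated so that the first
#'   ambulance delivery reaches the hospital 15 minutes after the incident
#'   (dispatch 5 + load 5 + transport 5).
#' @param load_min,unload_min loading time at scene / unloading time at
#'   hospital, per trip.
#' @param spontaneous_fraction fraction of GREEN casualties leaving the
#'   scene by their own means (never by ambulance).
#' @param spontaneous_rate_per_min rate of the Poisson spontaneous-arrival
#'   stream (expected arrivals per minute).
#' @param spontaneous_start_min earliest spontaneous arrival time.
#' @param transport_time_min optional per-hospital transport times
#'   overriding the scenario template's geography.
#' @return an object of class `"ambulance_fleet"`.
#' @export
ambulance_fleet <- function(n_ambulances = 12, capacity_stretcher = 1,
                            capacity_sitting = 2, dispatch_delay_min = 5,
                            load_min = 5, unload_min = 5,
                            spontaneous_fraction = 0.8,
                            spontaneous_rate_per_min = 0.5,
                            spontaneous_start_min = 10,
                            transport_time_min = NULL) {
  stopifnot(n_ambulances >= 0, load_min >= 0, unload_min >= 0,
            dispatch_delay_min >= 0, capacity_stretcher >= 1,
            capacity_sitting >= 1,
            spontaneous_fraction >= 0, spontaneous_fraction <= 1)
  structure(list(n_ambulances = as.integer(n_ambulances),
                 capacity_stretcher = as.integer(capacity_stretcher),
                 capacity_sitting = as.integer(capacity_sitting),
                 dispatch_delay_min = as.integer(dispatch_delay_min),
                 load_min = as.integer(load_min),
                 unload_min = as.integer(unload_min),
                 spontaneous_fraction = spontaneous_fraction,
                 spontaneous_rate_per_min = spontaneous_rate_per_min,
                 spontaneous_start_min = as.integer(spontaneous_start_min),
                 transport_time_min = transport_time_min),
            class = "ambulance_fleet")
}

#' Simulate evacuation of a scenario to hospital(s)
#'
#' Ambulances cycle scene -> hospital -> scene; at each loading, waiting
#' REDs (ordered by untreated death time, then id) are taken before
#' YELLOWs, and YELLOWs before any non-spontaneous GREENs.  Dead-at-scene
#' casualties are never transported.  A configurable fraction of GREENs
#' instead arrives as a continuous Poisson stream at the nearest hospital.
#' Deterministic given `(scenario, fleet, policy)`; the spontaneous stream
#' uses a sub-seed split from the scenario seed.
#'
#' @param scenario a [generate_scenario()] result.
#' @param fleet an [ambulance_fleet()].
#' @param policy destination policy: `"nearest"`, `"round-robin"`,
#'   `"all-red-to-centre"` (REDs to hospital 1, others nearest), a
#'   [distribution_policy()], or a function
#'   `(t_load, casualty) -> hospital index` for externally controlled
#'   distribution.
#' @param centre hospital index of the designated trauma centre (for
#'   `"all-red-to-centre"`).
#' @return an object of class `"arrival_stream"`: a data frame with columns
#'   `arrival_min`, `casualty_id`, `hospital`, `mode`
#'   (`"ambulance"`/`"spontaneous"`), `category`, `depart_min`, sorted by
#'   arrival time.  Attribute `"at_scene"` lists casualty ids never
#'   evacuated (dead at scene).
#' @export
simulate_evacuation <- function(scenario, fleet, policy = "nearest", centre = 1L) {
  transport <- fleet$transport_time_min %||% scenario$template$transport_time_min
  n_hosp <- length(transport)
  assign_fn <- make_assigner(policy, transport, centre)

  cats <- vapply(scenario$casualties, `[[`, character(1), "true_category")
  ids <- vapply(scenario$casualties, `[[`, character(1), "id")
  dtime <- vapply(scenario$casualties,
                  function(x) as.numeric(x$trajectory$death_time_untreated_min),
                  numeric(1))

  sub <- split_seed(scenario$seed, 3L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(sub[2])

  # spontaneous GREEN evacuation: continuous stream, nearest hospital
  green_idx <- which(cats == "GREEN")
  n_spont <- round(fleet$spontaneous_fraction * length(green_idx))
  spont_idx <- if (n_spont > 0)
    sort(green_idx[sample.int(length(green_idx), n_spont)]) else integer()
  rows <- list()
  if (n_spont > 0) {
    gaps <- stats::rexp(n_spont, rate = fleet$spontaneous_rate_per_min)
    times <- fleet$spontaneous_start_min + as.integer(round(cumsum(gaps)))
    nearest <- which.min(transport)
    for (i in seq_len(n_spont)) {
      rows[[length(rows) + 1L]] <- data.frame(
        arrival_min = times[i], casualty_id = ids[spont_idx[i]],
        hospital = nearest, mode = "spontaneous",
        category = "GREEN", depart_min = times[i],
        stringsAsFactors = FALSE)
    }
  }

  # ambulance shuttle: loading priority RED (by untreated death time, id),
  # then YELLOW, then remaining GREEN
  wait_red <- order(ifelse(is.na(dtime[cats == "RED"]), Inf, dtime[cats == "RED"]))
  queue <- c(which(cats == "RED")[wait_red], which(cats == "YELLOW"),
             setdiff(which(cats == "GREEN"), spont_idx))
  if (fleet$n_ambulances > 0 && length(queue) > 0) {
    ready <- rep(fleet$dispatch_delay_min, fleet$n_ambulances)
    while (length(queue) > 0) {
      v <- which.min(ready)
      t_ready <- ready[v]
      head_cat <- cats[queue[1]]
      cap <- if (head_cat == "GREEN") fleet$capacity_sitting else fleet$capacity_stretcher
      # sitting and stretcher cases are not mixed on one trip
      take <- queue[seq_len(min(cap, length(queue)))]
      take <- take[cats[take] == head_cat]
      queue <- setdiff(queue, take)
      t_load_done <- t_ready + fleet$load_min
      h <- assign_fn(t_load_done, scenario$casualties[[take[1]]])
      if (!(h %in% seq_len(n_hosp)))
        abort_config("policy assigned unknown hospital %s (have %d)", h, n_hosp)
      t_arr <- t_load_done + transport[h]
      for (ci in take) {
        rows[[length(rows) + 1L]] <- data.frame(
          arrival_min = as.integer(t_arr), casualty_id = ids[ci],
          hospital = as.integer(h), mode = "ambulance",
          category = cats[ci], depart_min = as.integer(t_load_done),
          stringsAsFactors = FALSE)
      }
      ready[v] <- t_arr + fleet$unload_min + transport[h]
    }
  }

  stream <- if (length(rows)) do.call(rbind, rows) else
    data.frame(arrival_min = integer(), casualty_id = character(),
               hospital = integer(), mode = character(),
               category = character(), depart_min = integer(),
               stringsAsFactors = FALSE)
  stream <- stream[order(stream$arrival_min, stream$casualty_id), , drop = FALSE]
  rownames(stream) <- NULL
  if (anyDuplicated(stream$casualty_id))
    abort_config("internal error: casualty transported twice")
  attr(stream, "at_scene") <- setdiff(ids, stream$casualty_id)
  class(stream) <- c("arrival_stream", "data.frame")
  stream
}

#' Decompose an arrival stream into ambulance waves
#'
#' Partitions ambulance-mode RED/YELLOW arrivals into maximal runs
#' separated by gaps strictly greater than `gap_min`.
#'
#' @param stream an [simulate_evacuation()] result.
#' @param gap_min minimum silence (minutes) separating two waves.
#' @return data frame with one row per wave: `start`, `end`, `count`,
#'   `n_red`, `n_yellow`.
#' @export
wave_decomposition <- function(stream, gap_min = 10) {
  amb <- stream[stream$mode == "ambulance" &
                stream$category %in% c("RED", "YELLOW"), , drop = FALSE]
  if (nrow(amb) == 0)
    return(data.frame(start = integer(), end = integer(), count = integer(),
                      n_red = integer(), n_yellow = integer()))
  t <- sort(amb$arrival_min)
  brk <- c(0L, which(diff(t) > gap_min), length(t))
  out <- lapply(seq_len(length(brk) - 1L), function(i) {
    seg <- t[(brk[i] + 1L):brk[i + 1L]]
    segrows <- amb[amb$arrival_min >= seg[1] & amb$arrival_min <= seg[length(seg)], ]
    data.frame(start = seg[1], end = seg[length(seg)], count = length(seg),
               n_red = sum(segrows$category == "RED"),
               n_yellow = sum(segrows$category == "YELLOW"))
  })
  do.call(rbind, out)
}

# Resolve a destination policy to a closure (t_load, casualty) -> hospital.
make_assigner <- function(policy, transport, centre = 1L) {
  n_hosp <- length(transport)
  nearest <- which.min(transport)
  if (is.function(policy)) return(policy)
  if (inherits(policy, "distribution_policy"))
    return(policy_assigner(policy, transport, centre))
  if (is.character(policy)) {
    if (policy == "nearest") return(function(t, cas) nearest)
    if (policy == "all-red-to-centre")
      return(function(t, cas) if (cas$true_category == "RED") centre else nearest)
    if (policy == "round-robin") {
      k <- 0L
      return(function(t, cas) { k <<- k + 1L; ((k - 1L) %% n_hosp) + 1L })
    }
  }
  abort_config("unknown distribution policy")
}
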