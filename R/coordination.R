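# Regional "one step ahead" layer: hospital status reports, predictive
# inflow stop/reopen signals, and casualty-distribution policies across
# several hospitals.  The point of the predictive policy is to divert the
# casualty flow *before* a component is overloaded, not when it already
# is, and to reopen the inflow as soon as capacity is restored.

#' Construct a hospital status report
#'
#' @param t_min report time (minutes post-incident).
#' @param hospital hospital identifier.
#' @param free_trauma_units,queued_red,free_or,free_icu current counts.
#' @param units_freeing_within_lookahead trauma units predicted to free
#'   within the controller's lookahead window.
#' @param accepting is the hospital currently accepting severely injured?
#' @return an object of class `"status_report"`.
#' @export
status_report <- function(t_min, hospital, free_trauma_units, queued_red = 0,
                          free_or = 0, free_icu = 0,
                          units_freeing_within_lookahead = 0,
                          accepting = TRUE) {
  if (any(c(free_trauma_units, queued_red, free_or, free_icu) < 0))
    abort_config("status report counts must be non-negative")
  structure(list(t_min = t_min, hospital = hospital,
                 free_trauma_units = as.integer(free_trauma_units),
                 queued_red = as.integer(queued_red),
                 free_or = as.integer(free_or), free_icu = as.integer(free_icu),
                 units_freeing_within_lookahead =
                   as.integer(units_freeing_within_lookahead),
                 accepting = isTRUE(accepting)),
            class = "status_report")
}

#' Construct a casualty-distribution policy
#'
#' @param kind `"all-red-to-centre"` (every RED to the designated regional
#'   trauma centre regardless of its state), `"round-robin"`, or
#'   `"predictive-lookahead"` (divert before overload, reopen on restored
#'   capacity).
#' @param lookahead_min prediction horizon of the inflow controller.
#' @param reopen_threshold free trauma units required to reopen a closed
#'   inflow.
#' @param est_service_min assumed major-trauma service time used by the
#'   controller to project unit occupancy from the departure log.
#' @param report_latency_min age of the status information available to
#'   the controller (0 = perfect instantaneous reporting).
#' @return an object of class `"distribution_policy"`.
#' @export
distribution_policy <- function(kind = c("predictive-lookahead",
                                         "all-red-to-centre", "round-robin"),
                                lookahead_min = 20, reopen_threshold = 2,
                                est_service_min = 45, report_latency_min = 5) {
  kind <- match.arg(kind)
  stopifnot(lookahead_min >= 0, report_latency_min >= 0)
  structure(list(kind = kind, lookahead_min = lookahead_min,
                 reopen_threshold = as.integer(reopen_threshold),
                 est_service_min = as.integer(est_service_min),
                 report_latency_min = as.integer(report_latency_min)),
            class = "distribution_policy")
}

#' Predictive inflow signal
#'
#' Closes the inflow when the predicted arrivals within the lookahead
#' window exceed the free trauma units plus the units freeing within that
#' window; a closed inflow reopens once the free units reach the policy's
#' reopen threshold.  Deterministic.
#'
#' @param report a [status_report()] (its `accepting` field is the current
#'   signal state).
#' @param predicted_arrivals severely injured predicted to arrive within
#'   the lookahead window.
#' @param policy a [distribution_policy()] providing the thresholds.
#' @return logical: accept further casualties?
#' @export
inflow_signal <- function(report, predicted_arrivals,
                          policy = distribution_policy()) {
  if (report$accepting) {
    predicted_arrivals <=
      report$free_trauma_units + report$units_freeing_within_lookahead
  } else {
    report$free_trauma_units >= policy$reopen_threshold
  }
}

#' Distribute casualties over hospitals
#'
#' @param categories character vector of triage categories, one per
#'   casualty awaiting assignment.
#' @param reports list of [status_report()], one per hospital, in hospital
#'   order.
#' @param policy a [distribution_policy()].
#' @param centre index of the designated regional trauma centre.
#' @param nearest index of the nearest hospital (destination for the
#'   non-RED categories under the centre policy).
#' @return integer vector of hospital indices.  When no hospital is
#'   accepting, the hospital with maximal slack (free plus freeing units)
#'   is forced: casualties cannot be held at the scene indefinitely.
#' @export
distribute <- function(categories, reports, policy, centre = 1L,
                       nearest = 1L) {
  if (length(reports) == 0) abort_config("distribute() needs >= 1 hospital")
  n_hosp <- length(reports)
  slack <- vapply(reports, function(r)
    r$free_trauma_units + r$units_freeing_within_lookahead - r$queued_red,
    numeric(1))
  acc <- vapply(reports, `[[`, logical(1), "accepting")
  rr <- 0L
  vapply(seq_along(categories), function(k) {
    cat <- categories[k]
    switch(policy$kind,
      "all-red-to-centre" = if (cat == "RED") as.integer(centre) else as.integer(nearest),
      "round-robin" = { rr <<- rr + 1L; ((rr - 1L) %% n_hosp) + 1L },
      "predictive-lookahead" = {
        if (cat != "RED") return(as.integer(nearest))
        cand <- if (any(acc)) which(acc) else seq_len(n_hosp)
        h <- cand[which.max(slack[cand])]
        slack[h] <<- slack[h] - 1
        as.integer(h)
      })
  }, integer(1))
}

# Closure used by simulate_evacuation(): projects each hospital's trauma-unit
# occupancy from the (perfectly observed) departure log and applies the
# predictive stop/reopen signal per assignment.  State: per-hospital RED
# arrival times already committed, and the current accepting flag.
policy_assigner <- function(policy, transport, centre = 1L,
                            hospitals = NULL, profile = "office") {
  if (policy$kind != "predictive-lookahead") {
    n_hosp <- length(transport)
    nearest <- which.min(transport)
    rr <- 0L
    return(function(t, cas) {
      switch(policy$kind,
        "all-red-to-centre" = if (cas$true_category == "RED") as.integer(centre)
                              else as.integer(nearest),
        "round-robin" = { rr <<- rr + 1L; ((rr - 1L) %% n_hosp) + 1L })
    })
  }
  if (is.null(hospitals))
    abort_config("the predictive-lookahead policy needs the hospital configurations")
  n_hosp <- length(transport)
  nearest <- which.min(transport)
  assigned <- vector("list", n_hosp)   # committed RED arrival times
  accepting <- rep(TRUE, n_hosp)
  report_log <- list()
  assigner <- function(t, cas) {
    if (cas$true_category != "RED") return(as.integer(nearest))
    # evaluate every hospital's report at its projected arrival time,
    # using status information report_latency_min old
    reports <- lapply(seq_len(n_hosp), function(h) {
      t_arr <- t + transport[h]
      t_info <- max(0, t_arr - policy$report_latency_min)
      a <- assigned[[h]]
      in_service <- sum(a > t_info - policy$est_service_min & a <= t_info)
      mob <- mobilized(hospitals[[h]], "trauma_unit", t_arr, profile)
      freeing <- sum(a > t_info - policy$est_service_min &
                     a <= t_info - policy$est_service_min + policy$lookahead_min)
      status_report(t_arr, hospitals[[h]]$name,
                    free_trauma_units = max(0, mob - in_service),
                    queued_red = max(0, in_service - mob),
                    units_freeing_within_lookahead = freeing,
                    accepting = accepting[h])
    })
    predicted <- vapply(seq_len(n_hosp), function(h) {
      t_arr <- t + transport[h]
      sum(assigned[[h]] > t_arr - policy$lookahead_min) + 1L
    }, numeric(1))
    for (h in seq_len(n_hosp))
      accepting[h] <<- inflow_signal(reports[[h]], predicted[h], policy)
    slack <- vapply(seq_len(n_hosp), function(h)
      reports[[h]]$free_trauma_units +
        reports[[h]]$units_freeing_within_lookahead - predicted[h], numeric(1))
    cand <- if (any(accepting)) which(accepting) else seq_len(n_hosp)
    h <- cand[which.max(slack[cand])]
    assigned[[h]] <<- c(assigned[[h]], t + transport[h])
    report_log[[length(report_log) + 1L]] <<-
      c(t_decision = t, hospital = h,
        stats::setNames(vapply(reports, function(r)
          r$free_trauma_units, numeric(1)),
          paste0("free_h", seq_len(n_hosp))),
        accepting = sum(accepting))
    as.integer(h)
  }
  attr(assigner, "get_reports") <- function() {
    if (length(report_log) == 0) return(data.frame())
    as.data.frame(do.call(rbind, report_log))
  }
  assigner
}

#' Run a multi-hospital regional scenario
#'
#' Generates a scenario, distributes casualties over hospitals under the
#' given policy, runs every hospital's engine, and scores the pooled
#' outcome.  Policy comparisons should use the same `(template, n_total,
#' seed)` so that all stochastic draws are shared (common random numbers).
#'
#' @param hospitals list of [hospital_config()], in the order of the
#'   template's transport-time vector.
#' @param template a [scenario_template()] whose geography names one
#'   transport time per hospital.
#' @param fleet an [ambulance_fleet()].
#' @param n_total scenario size.
#' @param seed master seed.
#' @param policy a [distribution_policy()] (or a policy name accepted by
#'   [simulate_evacuation()]).
#' @param centre index of the regional trauma centre.
#' @return an object of class `"region_run"`: scenario, stream, one
#'   `event_log` per hospital, pooled `outcome_report`, and the
#'   controller's decision log.
#' @export
run_region <- function(hospitals, template, fleet, n_total, seed,
                       policy = distribution_policy(), centre = 1L) {
  if (length(hospitals) != template$n_hospitals)
    abort_config("%d hospital configs for %d transport times",
                 length(hospitals), template$n_hospitals)
  scenario <- generate_scenario(template, n_total, seed)
  transport <- fleet$transport_time_min %||% template$transport_time_min
  assigner <- if (inherits(policy, "distribution_policy"))
    policy_assigner(policy, transport, centre, hospitals,
                    profile = scenario$incident_time_of_day)
  else policy
  stream <- simulate_evacuation(scenario, fleet, policy = assigner,
                                centre = centre)
  logs <- lapply(seq_along(hospitals), function(h)
    run_hospital(hospitals[[h]], stream, scenario, hospital_index = h))
  pooled <- do.call(rbind, lapply(logs, as.data.frame))
  outcome <- score_outcomes(pooled, scenario)
  decisions <- if (is.function(assigner) && !is.null(attr(assigner, "get_reports")))
    attr(assigner, "get_reports")() else data.frame()
  structure(list(scenario = scenario, stream = stream, logs = logs,
                 outcome = outcome, policy = policy,
                 controller_log = decisions),
            class = "region_run")
}

#' @export
print.region_run <- function(x, ...) {
  kind <- if (inherits(x$policy, "distribution_policy")) x$policy$kind else "custom"
  cat(sprintf("<region_run> %d hospitals, n = %d, policy %s\n",
              length(x$logs), x$scenario$n_total, kind))
  print(x$outcome)
  invisible(x)
}
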