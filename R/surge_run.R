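# High-level single-hospital surge test: the whole pipeline in one call,
# returning a classed object with print/summary/plot methods.

#' Run a complete single-hospital surge-capacity test
#'
#' Generates a scenario, evacuates it with the fleet, runs the hospital
#' engine and scores the outcome.
#'
#' @param n_total scenario size (injured + dead at scene).
#' @param seed master seed (mandatory).
#' @param hospital a [hospital_config()].
#' @param template a [scenario_template()].
#' @param fleet an [ambulance_fleet()].
#' @param profile staff profile; defaults to the template's time of day.
#' @return an object of class `"surge_run"` bundling the scenario, the
#'   arrival stream, the event log, the wave decomposition and the
#'   [score_outcomes()] report.
#' @export
#' @examples
#' run <- surge_test(n_total = 60, seed = 42)
#' print(run)
surge_test <- function(n_total, seed, hospital = default_hospital(),
                       template = default_template(),
                       fleet = ambulance_fleet()) {
  scenario <- generate_scenario(template, n_total, seed)
  stream <- simulate_evacuation(scenario, fleet)
  log <- run_hospital(hospital, stream, scenario, seed = seed)
  outcome <- score_outcomes(log, scenario)
  structure(list(scenario = scenario, stream = stream, log = log,
                 waves = wave_decomposition(stream),
                 outcome = outcome, hospital = hospital, fleet = fleet,
                 seed = seed),
            class = "surge_run")
}

#' @export
print.surge_run <- function(x, ...) {
  cat(sprintf("<surge_run> '%s', n = %d, seed %d\n",
              x$hospital$name, x$scenario$n_total, x$seed))
  w <- x$waves
  if (nrow(w))
    cat(sprintf("  %d ambulance wave%s (first delivery %d min, sizes %s)\n",
                nrow(w), if (nrow(w) > 1) "s" else "",
                min(x$stream$arrival_min[x$stream$mode == "ambulance"]),
                paste(w$count, collapse = "/")))
  print(x$outcome)
  invisible(x)
}

#' @export
summary.surge_run <- function(object, ...) {
  o <- object$outcome
  list(n_total = object$scenario$n_total,
       n_admitted = o$n_admitted,
       n_preventable_deaths = nrow(o$preventable_deaths),
       n_non_preventable_deaths = nrow(o$non_preventable_deaths),
       n_complications = nrow(o$complications),
       deaths_by_station = if (nrow(o$preventable_deaths))
         table(o$preventable_deaths$station) else table(character()),
       waves = object$waves,
       limiting_factor_sequence = o$limiting_factor_sequence)
}

#' Plot the ED load picture of a surge run
#'
#' Base-graphics rendition of the classic ED load curve: trauma units in
#' action, units at disposal, REDs waiting, and cumulative preventable
#' deaths, against minutes post-incident.
#'
#' @param x a `surge_run`.
#' @param station station to plot (default `"ED"`).
#' @param ... passed to [graphics::plot()].
#' @export
plot.surge_run <- function(x, station = "ED", ...) {
  lc <- load_curves(x$log, x$hospital, x$scenario)
  seg <- lc[lc$station == station, ]
  ia <- seg[seg$metric == "in_action", ]
  ad <- seg[seg$metric == "at_disposal", ]
  wt <- seg[seg$metric == "waiting", ]
  pd <- lc[lc$metric == "cum_preventable_deaths", ]
  ylim <- c(0, max(ia$value + ad$value, wt$value, pd$value, 1))
  graphics::plot(ia$t_bin, ia$value, type = "s", col = "blue", lwd = 2,
                 xlab = "minutes post-incident", ylab = "count",
                 ylim = ylim, main = sprintf("%s load (%s)", station,
                                             x$hospital$name), ...)
  graphics::lines(ad$t_bin, ad$value, type = "s", col = "darkgreen", lwd = 2)
  graphics::lines(wt$t_bin, wt$value, type = "s", col = "red", lwd = 2)
  graphics::lines(pd$t_bin, pd$value, type = "s", col = "black", lwd = 2)
  graphics::legend("topright", bty = "n", lwd = 2,
                   col = c("blue", "darkgreen", "red", "black"),
                   legend = c("units in action", "units at disposal",
                              "waiting", "cum. preventable deaths"))
  invisible(x)
}
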