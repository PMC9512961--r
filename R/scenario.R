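# Scenario templates and the synthetic-scenario generator.
#
# A template fixes the casualty mix (triage-category proportions, injury
# panels per category, deadline jitter) and the transport geography.  A
# scenario instantiates the template at a target total (injured + dead),
# preserving the proportions by largest-remainder apportionment: scaling
# the load to the local population must not change the type and severity
# mix, only the count.

#' Construct a scenario template
#'
#' @param name template identifier.
#' @param category_proportions named numeric vector over
#'   RED/YELLOW/GREEN/DEAD, summing to 1.
#' @param panel_weights named list, per category, of named numeric weights
#'   over panel ids from [panel_library()] (non-negative, positive sum).
#' @param deadline_jitter half-width of the multiplicative deadline jitter:
#'   each casualty's mortality deadlines are scaled by a factor drawn
#'   uniformly from `[1 - deadline_jitter, 1 + deadline_jitter]`.
#' @param transport_time_min numeric vector of scene-to-hospital transport
#'   times, one per hospital; its length defines the number of hospitals.
#' @param incident_time_of_day `"office"` or `"non-office"`; selects the
#'   staff mobilization profile used downstream.
#' @return an object of class `"scenario_template"`.
#' @export
scenario_template <- function(name, category_proportions, panel_weights,
                              deadline_jitter = 0.15,
                              transport_time_min = 5,
                              incident_time_of_day = c("office", "non-office")) {
  incident_time_of_day <- match.arg(incident_time_of_day)
  p <- category_proportions[TRIAGE_LEVELS]
  if (anyNA(p)) abort_config("category_proportions must name all of %s",
                             paste(TRIAGE_LEVELS, collapse = ", "))
  if (abs(sum(p) - 1) > 1e-9) abort_config("category_proportions must sum to 1")
  lib <- panel_library()
  for (cat in setdiff(TRIAGE_LEVELS, "DEAD")) {
    w <- panel_weights[[cat]]
    if (is.null(w) || any(w < 0) || sum(w) <= 0)
      abort_config("panel_weights[['%s']] must be non-negative with positive sum", cat)
    bad <- setdiff(names(w), names(lib))
    if (length(bad)) abort_config("unknown panel id(s): %s", paste(bad, collapse = ", "))
    wrong <- names(w)[vapply(lib[names(w)], `[[`, character(1), "category") != cat]
    if (length(wrong)) abort_config("panel(s) %s are not category %s",
                                    paste(wrong, collapse = ", "), cat)
  }
  structure(list(name = name, category_proportions = p,
                 panel_weights = panel_weights,
                 deadline_jitter = deadline_jitter,
                 transport_time_min = as.numeric(transport_time_min),
                 n_hospitals = length(transport_time_min),
                 incident_time_of_day = incident_time_of_day),
            class = "scenario_template")
}

#' The shipped default scenario template
#'
#' A physical-violence mass-casualty mix with 10% RED, 30% YELLOW, 55%
#' GREEN and 5% dead at scene.  The proportions and panels are authored
#' for this package; they are not any published incident's mix.
#'
#' @param transport_time_min scene-to-hospital transport times (minutes).
#' @param incident_time_of_day `"office"` or `"non-office"`.
#' @return a [scenario_template()].
#' @export
default_template <- function(transport_time_min = 5,
                             incident_time_of_day = "office") {
  scenario_template(
    "default_mci",
    category_proportions = c(RED = 0.10, YELLOW = 0.30, GREEN = 0.55, DEAD = 0.05),
    panel_weights = list(
      RED = c(red_thorax_penetrating = 1, red_abdominal_bleed = 1,
              red_head_injury = 1, red_pelvic_fracture = 1),
      YELLOW = c(yellow_femur_fracture = 1, yellow_open_forearm = 1,
                 yellow_blunt_abdomen = 1),
      GREEN = c(green_lacerations = 1, green_sprain = 1, green_contusion = 1),
      DEAD = c(dead_at_scene = 1)),
    transport_time_min = transport_time_min,
    incident_time_of_day = incident_time_of_day)
}

#' Scale a template to a target casualty count
#'
#' Largest-remainder apportionment of `n_total` over the template's
#' category proportions; ties in the fractional remainders are broken in
#' the order RED > YELLOW > GREEN > DEAD.  Counts sum exactly to
#' `n_total`.
#'
#' @param template a [scenario_template()].
#' @param n_total target number of injured + dead (>= 1 for a non-empty
#'   scenario; 0 is allowed and gives all-zero counts).
#' @return named integer vector over the four triage categories.
#' @export
scale_scenario <- function(template, n_total) {
  stopifnot(n_total >= 0)
  largest_remainder(template$category_proportions, as.integer(n_total))
}

#' Generate a synthetic incident scenario
#'
#' Draws one casualty per apportioned slot: the panel is sampled from the
#' template's per-category weights and every mortality deadline receives a
#' per-casualty multiplicative jitter.  Deterministic given
#' `(template, n_total, seed)`.  Generated REDs always carry at least one
#' time-critical requirement and generated GREENs none; both are audited
#' at generation time, as is per-casualty optimal-schedule feasibility.
#'
#' @param template a [scenario_template()].
#' @param n_total total casualties (injured + dead at scene).
#' @param seed integer RNG seed (mandatory: scenarios must be reproducible).
#' @return an object of class `"scenario"`.
#' @export
generate_scenario <- function(template, n_total, seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    abort_config("generate_scenario() requires an explicit seed")
  counts <- scale_scenario(template, n_total)
  lib <- panel_library()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  casualties <- list()
  k <- 0L
  for (cat in TRIAGE_LEVELS) {
    nc <- counts[[cat]]
    if (nc == 0L) next
    w <- if (cat == "DEAD") c(dead_at_scene = 1) else template$panel_weights[[cat]]
    ids <- names(w)
    for (i in seq_len(nc)) {
      k <- k + 1L
      pid <- if (length(ids) == 1L) ids else sample(ids, 1L, prob = w)
      jit <- stats::runif(1, 1 - template$deadline_jitter, 1 + template$deadline_jitter)
      cas <- build_casualty(lib[[pid]], sprintf("c%04d", k), jitter = jit)
      if (cat == "RED" &&
          !any(vapply(cas$treatments, function(x) !is.na(x$deadline_min), logical(1))))
        abort_config("generated RED casualty without a time-critical requirement")
      if (cat == "GREEN" &&
          any(vapply(cas$treatments, function(x) !is.na(x$deadline_min), logical(1))))
        abort_config("generated GREEN casualty with a time-critical requirement")
      casualties[[k]] <- cas
    }
  }
  structure(list(template = template, n_total = as.integer(n_total),
                 counts = counts, seed = as.integer(seed),
                 incident_time_of_day = template$incident_time_of_day,
                 casualties = casualties),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario '%s'> n = %d (seed %d): %s\n",
              x$template$name, x$n_total, x$seed,
              paste(sprintf("%s %d", names(x$counts), x$counts), collapse = ", ")))
  invisible(x)
}

#' Summarise a scenario's casualty bank
#'
#' @param object a `scenario`.
#' @param ... unused.
#' @return data frame with one row per casualty: id, category, ISS, NISS,
#'   RTS, survivable flag and untreated death time.
#' @export
summary.scenario <- function(object, ...) {
  do.call(rbind, lapply(object$casualties, function(cas) {
    data.frame(id = cas$id, category = cas$true_category,
               iss = cas$iss, niss = cas$niss, rts = cas$rts,
               survivable_if_optimal = cas$survivable_if_optimal,
               death_time_untreated_min = cas$trajectory$death_time_untreated_min,
               stringsAsFactors = FALSE)
  }))
}

# Look up a casualty by id in a scenario's bank.
bank_index <- function(scenario) {
  ids <- vapply(scenario$casualties, `[[`, character(1), "id")
  stats::setNames(scenario$casualties, ids)
}
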