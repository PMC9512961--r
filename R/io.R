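# Serialization: configuration files, casualty banks, event logs and run
# manifests.  Everything is plain structured text (JSON, or YAML when the
# yaml package is available); no binary formats.

steps_to_list <- function(m) lapply(seq_len(nrow(m)), function(k) as.numeric(m[k, ]))
steps_from_list <- function(x) {
  m <- do.call(rbind, lapply(x, as.numeric))
  mob_steps(m[, 1], m[, 2])
}

read_structured <- function(path) {
  if (!file.exists(path)) abort_config("config file '%s' does not exist", path)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      abort_config("reading '%s' needs the yaml package", path)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  }
}

check_keys <- function(x, allowed, path, what) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    abort_config("%s: unknown field(s) in %s: %s", path, what,
                 paste(extra, collapse = ", "))
}

#' Load and validate a configuration file
#'
#' The file's `type` field selects the object: `hospital_config`,
#' `scenario_template`, `ambulance_fleet`, `distribution_policy` or
#' `scenario`.  Unknown fields are an error (no silent typos); defaults
#' for omitted fields are filled by the constructors, so the returned
#' object always carries every parameter explicitly.
#'
#' @param path JSON or YAML file.
#' @return the validated object.
#' @export
load_config <- function(path) {
  x <- read_structured(path)
  type <- x$type %||% abort_config("%s: missing 'type' field", path)
  x$type <- NULL
  obj <- switch(type,
    hospital_config = {
      check_keys(x, names(formals(hospital_config)), path, "hospital_config")
      for (f in c("trauma_unit_mobilization", "transport_staff_mobilization"))
        if (!is.null(x[[f]])) x[[f]] <- lapply(x[[f]], steps_from_list)
      if (!is.null(x$staff_roster))
        x$staff_roster <- lapply(x$staff_roster, function(p) lapply(p, steps_from_list))
      if (!is.null(x$supplies)) x$supplies <- unlist(x$supplies)
      if (!is.null(x$restock)) x$restock <- as.data.frame(x$restock)
      tryCatch(do.call(hospital_config, x),
               error = function(e) abort_config("%s: %s", path, conditionMessage(e)))
    },
    scenario_template = {
      check_keys(x, names(formals(scenario_template)), path, "scenario_template")
      x$category_proportions <- unlist(x$category_proportions)
      x$panel_weights <- lapply(x$panel_weights, unlist)
      x$transport_time_min <- unlist(x$transport_time_min)
      tryCatch(do.call(scenario_template, x),
               error = function(e) abort_config("%s: %s", path, conditionMessage(e)))
    },
    ambulance_fleet = {
      check_keys(x, names(formals(ambulance_fleet)), path, "ambulance_fleet")
      if (!is.null(x$transport_time_min)) x$transport_time_min <- unlist(x$transport_time_min)
      tryCatch(do.call(ambulance_fleet, x),
               error = function(e) abort_config("%s: %s", path, conditionMessage(e)))
    },
    distribution_policy = {
      check_keys(x, names(formals(distribution_policy)), path, "distribution_policy")
      tryCatch(do.call(distribution_policy, x),
               error = function(e) abort_config("%s: %s", path, conditionMessage(e)))
    },
    scenario = read_scenario_obj(x, path),
    abort_config("%s: unknown config type '%s'", path, type))
  obj
}

config_to_list <- function(obj) {
  if (inherits(obj, "hospital_config")) {
    x <- unclass(obj)
    x$trauma_unit_mobilization <- lapply(x$trauma_unit_mobilization, steps_to_list)
    x$transport_staff_mobilization <- lapply(x$transport_staff_mobilization, steps_to_list)
    x$staff_roster <- lapply(x$staff_roster, function(p) lapply(p, steps_to_list))
    x$supplies <- as.list(x$supplies)
    c(list(type = "hospital_config"), x)
  } else if (inherits(obj, "scenario_template")) {
    x <- unclass(obj)
    x$category_proportions <- as.list(x$category_proportions)
    x$panel_weights <- lapply(x$panel_weights, as.list)
    x$n_hospitals <- NULL
    c(list(type = "scenario_template"), x)
  } else if (inherits(obj, "ambulance_fleet")) {
    c(list(type = "ambulance_fleet"), unclass(obj))
  } else if (inherits(obj, "distribution_policy")) {
    c(list(type = "distribution_policy"), unclass(obj))
  } else abort_config("cannot serialize object of class %s", class(obj)[1])
}

#' Write a configuration object to JSON (or YAML)
#'
#' @param obj a hospital config, scenario template, fleet or policy.
#' @param path destination; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_config <- function(obj, path) {
  x <- config_to_list(obj)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      abort_config("writing '%s' needs the yaml package", path)
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null", na = "null")
  }
  invisible(path)
}

casualty_to_list <- function(cas) {
  list(id = cas$id,
       true_category = cas$true_category,
       iss = cas$iss, niss = cas$niss, rts = cas$rts,
       survivable_if_optimal = cas$survivable_if_optimal,
       ct_scan_min = cas$ct_scan_min,
       injuries = lapply(cas$injuries, function(i)
         list(body_region = i$body_region, ais = i$ais,
              required_treatments = as.list(i$required_treatments))),
       treatments = lapply(cas$treatments, function(tr)
         list(id = tr$id, station = tr$station, duration_min = tr$duration_min,
              deadline_min = tr$deadline_min,
              complication_deadline_min = tr$complication_deadline_min,
              staff_demand = as.list(tr$staff_demand),
              consumables = as.list(tr$consumables))),
       trajectory = list(
         death_time_untreated_min = cas$trajectory$death_time_untreated_min,
         breakpoints = lapply(cas$trajectory$breakpoints, function(b)
           list(from_min = b$from_min, condition = as.list(b$condition),
                snapshot = unclass(b$snapshot)))))
}

casualty_from_list <- function(x) {
  inj <- lapply(x$injuries, function(i)
    injury(i$body_region, i$ais, unlist(i$required_treatments) %||% character()))
  trs <- lapply(x$treatments, function(tr)
    treatment_requirement(tr$id, tr$station, tr$duration_min,
                          tr$deadline_min %||% NA_integer_,
                          tr$complication_deadline_min %||% NA_integer_,
                          staff_demand = unlist(tr$staff_demand),
                          consumables = if (length(tr$consumables))
                            unlist(tr$consumables) else integer()))
  bps <- lapply(x$trajectory$breakpoints, function(b)
    list(from_min = b$from_min,
         condition = unlist(b$condition) %||% character(),
         snapshot = physiology_snapshot(b$snapshot$gcs, b$snapshot$sbp,
                                        b$snapshot$rr, b$snapshot$ambulatory)))
  casualty(x$id, inj, trs,
           trajectory(bps, x$trajectory$death_time_untreated_min %||% NA_integer_),
           survivable_if_optimal = x$survivable_if_optimal,
           true_category = x$true_category,
           ct_scan_min = x$ct_scan_min %||% NA_integer_)
}

#' Write a scenario (casualty bank) to JSON, with a CSV summary
#'
#' One record per casualty (full card: injuries, treatments, trajectory,
#' scores, flags); a `*_summary.csv` with id, category, ISS, NISS, RTS and
#' the survivable flag is written alongside.
#'
#' @param scenario a `scenario`.
#' @param path destination JSON file.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  x <- list(type = "scenario",
            template = config_to_list(scenario$template)[-1],
            n_total = scenario$n_total, seed = scenario$seed,
            incident_time_of_day = scenario$incident_time_of_day,
            casualties = lapply(scenario$casualties, casualty_to_list))
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null", null = "null")
  utils::write.csv(summary(scenario),
                   sub("\\.json$", "_summary.csv", path), row.names = FALSE)
  invisible(path)
}

read_scenario_obj <- function(x, path) {
  tmpl <- x$template
  tmpl$category_proportions <- unlist(tmpl$category_proportions)
  tmpl$panel_weights <- lapply(tmpl$panel_weights, unlist)
  tmpl$transport_time_min <- unlist(tmpl$transport_time_min)
  tmpl$n_hospitals <- NULL
  template <- do.call(scenario_template, tmpl)
  casualties <- lapply(x$casualties, casualty_from_list)
  counts <- table(factor(vapply(casualties, `[[`, character(1), "true_category"),
                         levels = TRIAGE_LEVELS))
  structure(list(template = template, n_total = x$n_total,
                 counts = stats::setNames(as.integer(counts), TRIAGE_LEVELS),
                 seed = x$seed,
                 incident_time_of_day = x$incident_time_of_day,
                 casualties = casualties),
            class = "scenario")
}

#' Write an event log as CSV (and optionally JSONL)
#'
#' @param log an `event_log`.
#' @param path CSV destination.
#' @param jsonl also write a JSON-lines twin next to it?
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path, jsonl = FALSE) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  if (jsonl) {
    con <- file(sub("\\.csv$", ".jsonl", path), "w")
    on.exit(close(con))
    for (k in seq_len(nrow(log)))
      writeLines(jsonlite::toJSON(as.list(as.data.frame(log)[k, ]),
                                  auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Build a run manifest
#'
#' Records configuration hashes, seeds, package version and output paths
#' so that a rerun with an equal manifest reproduces the outputs
#' byte-for-byte.
#'
#' @param seed master seed.
#' @param params named list of start parameters.
#' @param config_files character vector of config file paths to hash.
#' @param outputs character vector of output paths.
#' @return list of class `"run_manifest"`.
#' @export
run_manifest <- function(seed, params = list(), config_files = character(),
                         outputs = character()) {
  hashes <- if (length(config_files))
    as.list(tools::md5sum(config_files)) else list()
  structure(list(package = "surgesim",
                 version = as.character(utils::packageVersion("surgesim")),
                 seed = seed, params = params,
                 config_hashes = hashes, outputs = outputs),
            class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path destination JSON file.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, na = "null")
  invisible(path)
}
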