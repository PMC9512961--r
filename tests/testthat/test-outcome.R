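# Outcome scoring, load curves, capacity determination.

test_that("preventable-death classification follows the survivability rule", {
  # hand trace: two REDs, one server; the queued one misses its deadline
  c1 <- mk_casualty("c1", "RED", list(ed_req("tx1", 20, 60)))
  c2 <- mk_casualty("c2", "RED", list(ed_req("tx2", 30, 45)))
  h <- flat_hospital(units = 1)
  log <- run_hospital(h, mk_stream(c("c1", "c2"), c(0, 0)), as_bank(c1, c2))
  out <- score_outcomes(log, as_bank(c1, c2))
  # c2 (deadline 45) served first 0-30; c1 then 30-50, survives (deadline 60)
  expect_identical(nrow(out$preventable_deaths), 0L)
  # tighten c1's deadline below c2's: c1 (deadline 40) now has priority and
  # is served 0-20; c2 follows 20-50 and its deadline 45 lapses in queue
  c1b <- mk_casualty("c1", "RED", list(ed_req("tx1", 20, 40)))
  logb <- run_hospital(h, mk_stream(c("c1", "c2"), c(0, 0)), as_bank(c1b, c2))
  outb <- score_outcomes(logb, as_bank(c1b, c2))
  expect_identical(outb$preventable_deaths$casualty_id, "c2")
  expect_identical(outb$preventable_deaths$station, "ED")
  expect_identical(outb$preventable_deaths$wait_min, 45L)
  expect_identical(nrow(outb$non_preventable_deaths), 0L)
})

test_that("an unsurvivable casualty dying on schedule is non-preventable", {
  tr <- ed_req("tx", 20, 30)
  traj <- trajectory(list(list(from_min = 0, condition = character(),
                               snapshot = physiology_snapshot(6, 60, 8))),
                     death_time_untreated_min = 30L)
  doomed <- casualty("d1", list(injury("head", 5)), list(tr), traj,
                     survivable_if_optimal = FALSE, true_category = "RED")
  h <- flat_hospital(units = 0)   # nothing can be treated
  log <- run_hospital(h, mk_stream("d1", 0), as_bank(doomed))
  out <- score_outcomes(log, as_bank(doomed))
  expect_identical(nrow(out$preventable_deaths), 0L)
  expect_identical(out$non_preventable_deaths$casualty_id, "d1")
})

test_that("all deadlines met means zero preventable deaths", {
  sc <- generate_scenario(default_template(), 30, seed = 17)
  stream <- simulate_evacuation(sc, ambulance_fleet())
  h <- flat_hospital(units = 16, icu = 30, or = 10, minor = 30)
  out <- score_outcomes(run_hospital(h, stream, sc), sc)
  expect_identical(nrow(out$preventable_deaths), 0L)
  expect_identical(nrow(out$non_preventable_deaths), 0L)
})

test_that("log/bank identifier mismatches are refused", {
  c1 <- mk_casualty("c1", "RED", list(ed_req()))
  log <- run_hospital(flat_hospital(), mk_stream("c1", 0), as_bank(c1))
  expect_error(score_outcomes(log, as_bank(mk_casualty("zz", "RED",
                                                       list(ed_req())))),
               "absent from bank")
})

test_that("load curves count occupancy exactly and satisfy the identity", {
  cas <- mk_casualty("c1", "RED", list(ed_req("tx", 20, NA)))
  h <- flat_hospital(units = 2, horizon = 100)
  log <- run_hospital(h, mk_stream("c1", 10), as_bank(cas))
  lc <- load_curves(log, h, as_bank(cas))
  ia <- lc[lc$station == "ED" & lc$metric == "in_action", ]
  expect_identical(ia$value[ia$t_bin %in% 10:29], rep(1L, 20))
  expect_identical(sum(ia$value), 20L)
  # identity: in_action + at_disposal = mobilized, every minute
  ad <- lc[lc$station == "ED" & lc$metric == "at_disposal", ]
  expect_identical(ia$value + ad$value,
                   mobilized(h, "trauma_unit", ia$t_bin, "office"))
})

test_that("load curves of an empty log are identically zero", {
  h <- flat_hospital(horizon = 50)
  log <- run_hospital(h, mk_stream(character(), integer()), list())
  lc <- load_curves(log, h, list())
  expect_true(all(lc$value[lc$metric %in%
                           c("in_action", "waiting",
                             "cum_preventable_deaths")] == 0))
})

test_that("a single server fits exactly three sequential identical REDs", {
  # duration 20, deadline 60: completions at 20, 40, 60 all just in time;
  # a fourth (completion 80) dies at 60.  Brute-force sweep n = 1..6.
  run_n <- function(k) {
    cs <- lapply(seq_len(k), function(j)
      mk_casualty(sprintf("c%d", j), "RED", list(ed_req(sprintf("tx%d", j),
                                                        20, 60))))
    bank <- do.call(as_bank, cs)
    log <- run_hospital(flat_hospital(units = 1),
                        mk_stream(names(bank), rep(0, k)), bank)
    nrow(score_outcomes(log, bank)$preventable_deaths)
  }
  deaths <- vapply(1:6, run_n, integer(1))
  expect_identical(deaths, c(0L, 0L, 0L, 1L, 2L, 3L))
  capacity <- max(which(deaths == 0L))
  expect_identical(capacity, 3L)
})

grid_template <- function() {
  scenario_template("grid",
                    c(RED = 0.5, YELLOW = 0.3, GREEN = 0.2, DEAD = 0),
                    list(RED = c(red_thorax_penetrating = 1,
                                 red_abdominal_bleed = 1),
                         YELLOW = c(yellow_femur_fracture = 1),
                         GREEN = c(green_lacerations = 1)),
                    deadline_jitter = 0, transport_time_min = 5)
}

test_that("bisection capacity equals the exhaustive linear sweep", {
  tpl <- grid_template()
  fleet <- ambulance_fleet(n_ambulances = 6)
  for (units in c(2, 4)) {
    h <- flat_hospital(units = units, icu = 4, or = 3, horizon = 480)
    cp <- determine_capacity(h, tpl, fleet, n_range = c(1, 14), seed = 5)
    sweep_pass <- vapply(1:14, function(n) {
      sc <- generate_scenario(tpl, n, split_seed(5, 1))
      stream <- simulate_evacuation(sc, fleet)
      out <- score_outcomes(run_hospital(h, stream, sc), sc)
      nrow(out$preventable_deaths) == 0 && nrow(out$complications) == 0
    }, logical(1))
    sweep_cap <- if (any(sweep_pass)) max(which(sweep_pass)) else 0L
    expect_identical(cp$capacity, as.integer(sweep_cap),
                     info = sprintf("units=%d", units))
  }
})

test_that("capacity is non-decreasing in every resource on a 3x3x3 grid", {
  tpl <- grid_template()
  fleet <- ambulance_fleet(n_ambulances = 6)
  grid <- expand.grid(units = c(1, 2, 3), or = c(1, 2, 3), icu = c(1, 2, 3))
  caps <- array(NA_integer_, dim = c(3, 3, 3))
  for (k in seq_len(nrow(grid))) {
    h <- flat_hospital(units = grid$units[k], or = grid$or[k],
                       icu = grid$icu[k], horizon = 480)
    cp <- determine_capacity(h, tpl, fleet, n_range = c(1, 12), seed = 5)
    caps[grid$units[k], grid$or[k], grid$icu[k]] <- cp$capacity
  }
  for (a in 1:3) for (b in 1:3) {
    expect_true(all(diff(caps[, a, b]) >= 0))   # trauma units
    expect_true(all(diff(caps[a, , b]) >= 0))   # theatres
    expect_true(all(diff(caps[a, b, ]) >= 0))   # ICU beds
  }
})

test_that("unlimited resources return the top of the search range", {
  tpl <- grid_template()
  h <- flat_hospital(units = 30, or = 10, icu = 40, minor = 40, ct = 5,
                     horizon = 480)
  cp <- determine_capacity(h, tpl, ambulance_fleet(n_ambulances = 30),
                           n_range = c(1, 10), seed = 3)
  expect_identical(cp$capacity, 10L)
})

test_that("identical inputs give byte-identical outcome reports", {
  r1 <- surge_test(n_total = 50, seed = 99)
  r2 <- surge_test(n_total = 50, seed = 99)
  expect_identical(serialize(r1$outcome, NULL), serialize(r2$outcome, NULL))
  expect_identical(strip_log(r1$log), strip_log(r2$log))
})
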