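# Ambulance shuttle, spontaneous GREEN stream, wave structure.

# a scenario of exactly k REDs built from the library panel, transport 5 min
red_only_scenario <- function(k, seed = 1) {
  tpl <- scenario_template("reds",
                           c(RED = 1, YELLOW = 0, GREEN = 0, DEAD = 0),
                           list(RED = c(red_thorax_penetrating = 1),
                                YELLOW = c(yellow_femur_fracture = 1),
                                GREEN = c(green_lacerations = 1)),
                           deadline_jitter = 0, transport_time_min = 5)
  generate_scenario(tpl, k, seed)
}

test_that("a single shuttling ambulance reproduces the hand-computed cycle", {
  sc <- red_only_scenario(2)
  fleet <- ambulance_fleet(n_ambulances = 1, dispatch_delay_min = 5,
                           load_min = 5, unload_min = 0,
                           spontaneous_fraction = 0)
  stream <- simulate_evacuation(sc, fleet)
  # dispatch 5 + load 5 + transport 5 = 15; then return 5, load 5, transport 5
  expect_identical(stream$arrival_min, c(15L, 30L))
  expect_identical(stream$mode, c("ambulance", "ambulance"))
})

test_that("the default fleet delivers the first casualty at 15 minutes", {
  sc <- generate_scenario(default_template(), 100, seed = 4)
  stream <- simulate_evacuation(sc, ambulance_fleet())
  expect_identical(min(stream$arrival_min[stream$mode == "ambulance"]), 15L)
})

test_that("no ambulances and no spontaneous evacuation give an empty stream", {
  tpl <- scenario_template("greens",
                           c(RED = 0, YELLOW = 0, GREEN = 1, DEAD = 0),
                           default_template()$panel_weights,
                           transport_time_min = 5)
  sc <- generate_scenario(tpl, 10, seed = 2)
  stream <- simulate_evacuation(sc, ambulance_fleet(n_ambulances = 0,
                                                    spontaneous_fraction = 0))
  expect_identical(nrow(stream), 0L)
  expect_setequal(attr(stream, "at_scene"),
                  vapply(sc$casualties, `[[`, character(1), "id"))
})

test_that("evacuation conserves casualties and never moves the dead", {
  sc <- generate_scenario(default_template(), 120, seed = 6)
  stream <- simulate_evacuation(sc, ambulance_fleet())
  ids <- vapply(sc$casualties, `[[`, character(1), "id")
  cats <- vapply(sc$casualties, `[[`, character(1), "true_category")
  expect_identical(anyDuplicated(stream$casualty_id), 0L)
  expect_setequal(c(stream$casualty_id, attr(stream, "at_scene")), ids)
  expect_setequal(attr(stream, "at_scene"), ids[cats == "DEAD"])
  # GREEN spontaneous fraction realized
  expect_identical(sum(stream$mode == "spontaneous"),
                   as.integer(round(0.8 * sum(cats == "GREEN"))))
})

test_that("scene loading priority: REDs board strictly before YELLOWs", {
  sc <- generate_scenario(default_template(), 80, seed = 8)
  stream <- simulate_evacuation(sc, ambulance_fleet(n_ambulances = 3))
  amb <- stream[stream$mode == "ambulance", ]
  last_red_depart <- max(amb$depart_min[amb$category == "RED"])
  first_yellow_depart <- min(amb$depart_min[amb$category == "YELLOW"])
  expect_gte(first_yellow_depart, last_red_depart)
})

test_that("wave decomposition partitions arrivals at the configured gap", {
  s <- mk_stream(sprintf("c%d", 1:5), c(15, 16, 17, 40, 41))
  w <- wave_decomposition(s, gap_min = 10)
  expect_identical(nrow(w), 2L)
  expect_identical(w$count, c(3L, 2L))
  expect_identical(w$start, c(15L, 40L))
  expect_identical(nrow(wave_decomposition(mk_stream(character(), integer()))), 0L)
})

test_that("deterministic single-hospital shuttle is periodic at the round-trip time", {
  sc <- red_only_scenario(6)
  fleet <- ambulance_fleet(n_ambulances = 1, dispatch_delay_min = 5,
                           load_min = 5, unload_min = 5,
                           spontaneous_fraction = 0)
  stream <- simulate_evacuation(sc, fleet)
  period <- fleet$load_min + 5 + fleet$unload_min + 5   # load+transport+unload+return
  expect_identical(unique(diff(stream$arrival_min)), as.integer(period))
  w <- wave_decomposition(stream, gap_min = period - 1)
  expect_identical(nrow(w), 6L)   # one casualty per round trip
  expect_identical(unique(diff(w$start)), as.integer(period))
})

test_that("policies address only known hospitals", {
  sc <- red_only_scenario(2)
  expect_error(simulate_evacuation(sc, ambulance_fleet(spontaneous_fraction = 0),
                                   policy = function(t, cas) 7L),
               "unknown hospital")
})
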