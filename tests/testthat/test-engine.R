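# Hospital engine: hand traces, mobilization, CT, supplies, conservation.

test_that("an empty stream yields only alert and mobilization events", {
  log <- run_hospital(default_hospital(), mk_stream(character(), integer()),
                      list())
  expect_true(all(log$event %in% c("alert", "mobilize")))
  expect_identical(sum(log$event == "death"), 0L)
  expect_identical(log$t[log$event == "alert"], 5L)
})

test_that("a lone RED with a free unit is treated immediately: hand trace", {
  cas <- mk_casualty("c1", "RED", list(ed_req(duration = 20, deadline = 60)))
  log <- run_hospital(flat_hospital(units = 1), mk_stream("c1", 15),
                      as_bank(cas))
  expect_identical(log$t[log$event == "treatment_start"], 15L)
  expect_identical(log$t[log$event == "treatment_end"], 35L)
  expect_identical(sum(log$event == "death"), 0L)
  expect_identical(sum(log$event == "discharge"), 1L)
})

test_that("the second RED at a single server dies in queue at its deadline", {
  c1 <- mk_casualty("c1", "RED", list(ed_req("tx1", 20, 60)))
  c2 <- mk_casualty("c2", "RED", list(ed_req("tx2", 20, 30)))
  log <- run_hospital(flat_hospital(units = 1), mk_stream(c("c1", "c2"),
                                                          c(10, 10)),
                      as_bank(c1, c2))
  # c2 has the earlier deadline, so it is served first; c1 (deadline 60)
  # waits and survives: 10-30 c2, 30-50 c1
  expect_identical(sum(log$event == "death"), 0L)
  # with reversed service capacity pressure: give c2 a deadline it cannot meet
  c3 <- mk_casualty("c3", "RED", list(ed_req("tx3", 20, 25)))
  log2 <- run_hospital(flat_hospital(units = 1), mk_stream(c("c1", "c3"),
                                                           c(0, 10)),
                       as_bank(c1, c3))
  d <- log2[log2$event == "death", ]
  expect_identical(d$id, "c3")
  expect_identical(d$t, 25L)
  expect_identical(d$station, "ED")
  expect_identical(d$detail, "tx3")
})

test_that("a deadline that cannot be met from arrival lapses mid-service", {
  # both arrive at 15 at a single server; the deadline-30 casualty has
  # priority (earliest deadline first) and starts at once, but completion
  # at 35 would overshoot: it dies mid-service at exactly t = 30, and the
  # freed unit serves the other casualty 30-50 within its deadline
  c1 <- mk_casualty("c1", "RED", list(ed_req("tx1", 20, 60)))
  c2 <- mk_casualty("c2", "RED", list(ed_req("tx2", 20, 30)))
  log <- run_hospital(flat_hospital(units = 1),
                      mk_stream(c("c1", "c2"), c(15, 15)), as_bank(c1, c2))
  expect_identical(log$t[log$event == "treatment_start" & log$id == "c2"], 15L)
  expect_identical(log$t[log$event == "death"], 30L)
  expect_identical(log$id[log$event == "death"], "c2")
  expect_identical(log$t[log$event == "treatment_end" & log$id == "c1"], 50L)
  expect_identical(sum(log$event == "discharge"), 1L)
})

test_that("treatment completion exactly at the deadline averts death", {
  cas <- mk_casualty("c1", "RED", list(ed_req("tx", 20, 20)))
  log <- run_hospital(flat_hospital(units = 1), mk_stream("c1", 0),
                      as_bank(cas))
  expect_identical(sum(log$event == "death"), 0L)
  # one minute later is too late
  cas2 <- mk_casualty("c2", "RED", list(ed_req("tx", 20, 19)))
  log2 <- run_hospital(flat_hospital(units = 1), mk_stream("c2", 0),
                       as_bank(cas2))
  expect_identical(log2$t[log2$event == "death"], 19L)
})

test_that("mobilized() is a step function anchored at the alert", {
  h <- default_hospital()
  expect_identical(mobilized(h, "trauma_unit", 0, "office"), 2L)   # on-duty baseline
  expect_identical(mobilized(h, "trauma_unit", 0, "non-office"), 1L)
  # non-office maximum is reached between 30 and 60 min after alert
  a <- h$alert_offset_min
  m_max <- max(mobilized(h, "trauma_unit", 0:720, "non-office"))
  t_full <- min(which(mobilized(h, "trauma_unit", 0:720, "non-office") == m_max)) - 1L
  expect_gt(t_full - a, 30)
  expect_lte(t_full - a, 60)
  # office profile dominates non-office pointwise, for every resource
  for (res in c("trauma_unit", "transport_staff", "physician", "nurse",
                "surgeon", "icu_nurse"))
    expect_true(all(mobilized(h, res, 0:720, "office") >=
                    mobilized(h, res, 0:720, "non-office")))
  expect_true(all(diff(mobilized(h, "trauma_unit", 0:720, "office")) >= 0))
})

test_that("CT outside the ED ties up the team for both transport legs", {
  h_in <- flat_hospital(ct_in_ed = TRUE)
  h_out <- flat_hospital(ct_in_ed = FALSE, ct_transport = 10)
  expect_identical(ct_visit(h_in, 10)$team_blocked_min, 10L)
  expect_identical(ct_visit(h_out, 10)$team_blocked_min, 30L)
  cas <- mk_casualty("c1", "RED", list(ed_req("tx", 10, NA)), ct_scan_min = 10L)
  for (h in list(h_in, h_out)) {
    log <- run_hospital(h, mk_stream("c1", 0), as_bank(cas))
    seize_t <- log$t[log$event == "seize" & log$detail == "trauma_unit"]
    release_t <- log$t[log$event == "release" & log$detail == "trauma_unit"]
    expect_identical(release_t - seize_t,
                     10L + ct_visit(h, 10)$team_blocked_min)
  }
  # no CT requested: no CT events at all
  cas2 <- mk_casualty("c2", "RED", list(ed_req("tx", 10, NA)))
  log2 <- run_hospital(h_out, mk_stream("c2", 0), as_bank(cas2))
  expect_identical(sum(log2$station == "CT"), 0L)
})

test_that("consumables are exhausted exactly and stock-outs are flagged", {
  mk5 <- function(k, stock) {
    cs <- lapply(seq_len(k), function(j)
      mk_casualty(sprintf("c%d", j), "YELLOW",
                  list(ed_req(sprintf("tx%d", j), 5, NA,
                              consumables = c(surgical_disposables = 1L)))))
    h <- flat_hospital(minor = 10,
                       supplies = c(surgical_disposables = stock))
    log <- run_hospital(h, mk_stream(sprintf("c%d", seq_len(k)),
                                     rep(0, k), category = "YELLOW"),
                        do.call(as_bank, cs))
    list(log = log, h = h, bank = do.call(as_bank, cs))
  }
  exact <- mk5(5, 5L)
  expect_identical(sum(exact$log$event == "stock_out"), 0L)
  ledger <- consume_supplies(exact$log, exact$h, exact$bank)
  expect_identical(ledger$final_stock[ledger$item == "surgical_disposables"], 0L)
  short <- mk5(5, 4L)
  expect_identical(sum(short$log$event == "stock_out"), 1L)
  # empty consumables: empty usage
  cas <- mk_casualty("z1", "YELLOW", list(ed_req("tx", 5, NA)))
  h0 <- flat_hospital(supplies = c(surgical_disposables = 3L))
  log0 <- run_hospital(h0, mk_stream("z1", 0, category = "YELLOW"), as_bank(cas))
  led0 <- consume_supplies(log0, h0, as_bank(cas))
  expect_true(all(led0$consumed == 0L))
})

test_that("a restock delivery releases a stock-out wait", {
  cas <- mk_casualty("c1", "YELLOW",
                     list(ed_req("tx", 5, NA,
                                 consumables = c(blood_units = 2L))))
  h <- flat_hospital(supplies = c(blood_units = 0L),
                     restock = data.frame(t_min = 30L, item = "blood_units",
                                          qty = 5L, stringsAsFactors = FALSE))
  log <- run_hospital(h, mk_stream("c1", 0, category = "YELLOW"), as_bank(cas))
  expect_identical(sum(log$event == "stock_out"), 1L)
  expect_identical(log$t[log$event == "treatment_start"], 30L)
})

test_that("un-mobilizable staff demand is rejected before simulation", {
  cas <- mk_casualty("c1", "RED",
                     list(ed_req("tx", 10, 60, staff = c(surgeon = 5L))))
  h <- flat_hospital(surgeon = 2)
  expect_error(run_hospital(h, mk_stream("c1", 0), as_bank(cas)),
               "roster maximum")
})

test_that("resource and flow conservation hold on a stressed default run", {
  run <- surge_test(n_total = 150, seed = 13)
  log <- run$log
  h <- run$hospital
  # seized <= mobilized for every primary resource, at every minute
  lc <- load_curves(log, h, run$scenario)
  for (stn in c("ED", "ED_minor", "OR", "ICU", "WARD")) {
    ia <- lc$value[lc$station == stn & lc$metric == "in_action"]
    ad <- lc$value[lc$station == stn & lc$metric == "at_disposal"]
    expect_true(all(ad >= 0))               # never over-seized
    expect_true(all(ia >= 0))
  }
  # every admitted casualty reaches exactly one terminal state
  terminal <- attr(log, "terminal")
  arrived <- unique(log$id[log$event == "arrive"])
  expect_true(all(terminal[arrived] %in%
                  c("death", "discharge", "divert", "in_progress_at_horizon")))
  deaths <- log$id[log$event == "death"]
  expect_identical(sum(log$event == "discharge"),
                   sum(terminal == "discharge"))
  expect_identical(anyDuplicated(deaths), 0L)
  # paired seize/release: every seize matched by a release or run end
  # (an ICU reservation is seized as "icu_bed_reserved" and, once occupied,
  # released as "icu_bed", so the two labels are pooled)
  for (res in list("trauma_unit", "minor_slot", "theatre",
                   c("icu_bed", "icu_bed_reserved"))) {
    ns <- sum(log$event == "seize" & log$detail %in% res)
    nr <- sum(log$event == "release" & log$detail %in% res)
    expect_gte(ns, nr)
  }
})

test_that("a RED never waits while a usable trauma unit sits idle", {
  # staff, supplies and transport are ample here, so an idle unit is a
  # genuinely usable unit: the work-conserving discipline must leave no
  # queued RED facing one
  sc <- generate_scenario(default_template(), 80, seed = 21)
  stream <- simulate_evacuation(sc, ambulance_fleet())
  h <- flat_hospital(units = 4, icu = 30, or = 10, ward = 100,
                     minor = 30, horizon = 600)
  log <- run_hospital(h, stream, sc)
  lc <- load_curves(log, h, sc)
  ed <- lc[lc$station == "ED", ]
  waiting <- ed$value[ed$metric == "waiting"]
  at_disposal <- ed$value[ed$metric == "at_disposal"]
  expect_true(any(waiting > 0))            # the load does queue
  expect_false(any(waiting > 0 & at_disposal > 0))
})

test_that("adding a trauma unit never worsens any casualty's ED wait", {
  tpl <- default_template()
  sc <- generate_scenario(tpl, 40, seed = 31)
  stream <- simulate_evacuation(sc, ambulance_fleet(n_ambulances = 4))
  waits <- lapply(c(2, 3, 4), function(k) {
    h <- flat_hospital(units = k, icu = 20, or = 10)
    log <- run_hospital(h, stream, sc)
    starts <- log[log$event == "treatment_start", ]
    first_start <- tapply(starts$t, starts$id, min)
    arr <- log[log$event == "arrive", ]
    arr_t <- stats::setNames(arr$t, arr$id)
    first_start - arr_t[names(first_start)]
  })
  common <- Reduce(intersect, lapply(waits, names))
  expect_true(all(waits[[2]][common] <= waits[[1]][common]))
  expect_true(all(waits[[3]][common] <= waits[[2]][common]))
})
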