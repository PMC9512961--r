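# Casualty cards: constructors, time/treatment-dependent physiology, triage.

test_that("constructors enforce the type invariants", {
  expect_error(injury("thorax", 0), "AIS")
  expect_error(injury("thorax", 7), "AIS")
  expect_error(injury("torso", 3))
  expect_error(treatment_requirement("x", "ED", 0), "duration_min")
  expect_error(treatment_requirement("x", "ED", 10, deadline_min = -5), "deadline_min")
  expect_error(treatment_requirement("x", "ED", 10, staff_demand = c(nurse = 0L)),
               "staff")
  expect_error(physiology_snapshot(2, 100, 10), "GCS")
  expect_error(physiology_snapshot(15, -1, 10), "non-negative")
  expect_error(trajectory(list(list(from_min = 10, condition = NULL,
                                    snapshot = physiology_snapshot(15, 120, 16)),
                               list(from_min = 5, condition = NULL,
                                    snapshot = physiology_snapshot(15, 120, 16)))),
               "sorted")
})

test_that("death_time_untreated_min must match the minimum deadline", {
  tr <- ed_req(deadline = 60)
  traj_bad <- trajectory(list(list(from_min = 0, condition = character(),
                                   snapshot = physiology_snapshot(14, 80, 26))),
                         death_time_untreated_min = 50L)
  expect_error(casualty("x", list(injury("thorax", 3)), list(tr), traj_bad,
                        TRUE, "RED"), "minimum treatment deadline")
})

fixture_casualty <- function() {
  # deteriorates at 30 untreated; stabilizes at 30 once tx1 is complete;
  # dies untreated at 60
  tr <- ed_req("tx1", duration = 20, deadline = 60)
  traj <- trajectory(list(
    list(from_min = 0, condition = character(),
         snapshot = physiology_snapshot(14, 100, 22)),
    list(from_min = 30, condition = character(),
         snapshot = physiology_snapshot(12, 70, 32)),
    list(from_min = 30, condition = "tx1",
         snapshot = physiology_snapshot(15, 110, 18))),
    death_time_untreated_min = 60L)
  casualty("fx", list(injury("thorax", 3)), list(tr), traj, TRUE, "RED")
}

test_that("physiology_at is a deadline-aware branch lookup", {
  cas <- fixture_casualty()
  expect_equal(physiology_at(cas, 0, character())$sbp, 100)     # first breakpoint
  expect_equal(physiology_at(cas, 29, character())$sbp, 100)    # right-continuous
  expect_equal(physiology_at(cas, 30, character())$sbp, 70)     # deteriorated
  expect_equal(physiology_at(cas, 45, "tx1")$sbp, 110)          # treated branch
  dead <- physiology_at(cas, 60, character())                   # untreated death
  expect_equal(c(dead$gcs, dead$sbp, dead$rr), c(3, 0, 0))
  expect_equal(physiology_at(cas, 60, "tx1")$sbp, 110)          # treatment averts
})

test_that("physiology_at never worsens when treatments are added", {
  sc <- generate_scenario(default_template(), 80, seed = 3)
  for (cas in sc$casualties) {
    all_tx <- vapply(cas$treatments, `[[`, character(1), "id")
    for (t in c(0, 15, 40, 90, 200)) {
      untreated <- tryCatch(physiology_at(cas, t, character()),
                            error = function(e) NULL)
      treated <- physiology_at(cas, t, all_tx)
      if (!is.null(untreated))
        expect_gte(compute_rts(treated), compute_rts(untreated))
    }
  }
})

test_that("the triage sieve is deterministic and total", {
  expect_identical(triage(physiology_snapshot(15, 120, 16, ambulatory = TRUE)),
                   "GREEN")
  expect_identical(triage(physiology_snapshot(3, 0, 0)), "DEAD")
  expect_identical(triage(physiology_snapshot(15, 70, 16)), "RED")
  expect_identical(triage(physiology_snapshot(15, 110, 35)), "RED")   # RR high
  expect_identical(triage(physiology_snapshot(15, 110, 5)), "RED")    # RR low
  expect_identical(triage(physiology_snapshot(13, 110, 16)), "RED")   # GCS
  expect_identical(triage(physiology_snapshot(15, 110, 22)), "YELLOW")
  # total: every generated initial snapshot maps to exactly one category
  sc <- generate_scenario(default_template(), 100, seed = 5)
  for (cas in sc$casualties) {
    cat <- triage(physiology_at(cas, 0, character()))
    expect_true(cat %in% c("RED", "YELLOW", "GREEN", "DEAD"))
    expect_identical(cat, cas$true_category)   # panels encode their category
  }
})

test_that("sieve thresholds are configuration, not code", {
  strict <- triage_sieve(sbp_min = 120)
  expect_identical(triage(physiology_snapshot(15, 110, 22), strict), "RED")
})

test_that("survivable casualties admit a feasible optimal schedule", {
  sc <- generate_scenario(default_template(), 120, seed = 9)
  for (cas in sc$casualties)
    if (cas$survivable_if_optimal)
      expect_true(surgesim:::schedule_feasible(cas$treatments))
})
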