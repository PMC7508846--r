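test_that("silencing-memory timelines encode compartment, coupling and the
           PcG mutation", {
  ant <- silencing_memory("anterior", pcg_mutant = TRUE)
  expect_equal(ant$C_program$time, c(0, 130))
  expect_equal(ant$C_program$C, c(0, 4))
  expect_length(ant$events, 1)
  expect_equal(ant$events[[1]]$time, 290)
  expect_equal(ant$events[[1]]$param, "p3")
  expect_equal(ant$events[[1]]$value, 0.001)
  # anterior: repressed during initiation, active from maintenance onset
  expect_equal(ant$p1_program$time, c(0, 290))
  expect_lt(ant$p1_program$value[1], ant$p1_program$value[2])
  post <- silencing_memory("posterior")
  expect_equal(nrow(post$p1_program), 1)
  expect_length(post$events, 0)
})

test_that("activation-memory timelines place a 1-h heat shock in or after
           the initiation phase", {
  for (h in c("early", "late")) {
    tl <- activation_memory(h)
    hs <- tl$p1_program
    expect_equal(hs$time[3] - hs$time[2], 60)
    expect_equal(hs$value[2], 0.8)
    expect_equal(hs$value[1], hs$value[3])
  }
  early <- activation_memory("early")$p1_program
  expect_true(early$time[2] >= 130 && early$time[3] <= 290)
  late <- activation_memory("late")$p1_program
  expect_gte(late$time[2], 290)
  none <- activation_memory("none")
  expect_equal(nrow(none$p1_program), 1)
  expect_equal(none$schedule$phase_bounds$horizon, 6000)
})

test_that("accumulation scenarios are fully uncoupled on the right
           lineage schedules", {
  soma <- accumulation_scenario("soma")
  expect_equal(soma$C_program$C, 0)
  expect_equal(soma$schedule$phase_bounds$horizon, 660)
  germ <- accumulation_scenario("germline")
  dt <- division_times(germ$schedule)
  expect_equal(length(dt), 10)
  expect_equal(soma$chromatin$p3, 0.25)
  expect_equal(soma$chromatin$p5, 0.04)
})

test_that("eye-disc scenarios carry the PRE/TRE-specific parameters and
           zone structure", {
  eya <- eyedisc_scenario("eya", n_positions = 10)
  expect_equal(unlist(eya$timelines[[5]]$chromatin),
               c(p3 = 0.2, p4 = 0.2, p5 = 0.17))
  bxd <- eyedisc_scenario("bxd", n_positions = 10)
  expect_equal(unlist(bxd$timelines[[5]]$chromatin),
               c(p3 = 0.25, p4 = 0.25, p5 = 0.04))
  # zone 1 stays uncoupled and repressed for the whole run
  z1 <- which(eya$positions$zone == 1L)
  for (i in z1) {
    expect_equal(eya$timelines[[i]]$C_program$C, 0)
    expect_equal(nrow(eya$timelines[[i]]$p1_program), 1)
  }
  # zones 2-3 couple at their activation onset with C = 2.5
  z23 <- which(eya$positions$zone > 1L)
  for (i in z23[1:2]) {
    cp <- eya$timelines[[i]]$C_program
    expect_equal(cp$C, c(0, 2.5))
    expect_equal(cp$time[2], eya$positions$activation_onset[i])
  }
  # posterior positions activate before anterior ones
  on <- eya$positions$activation_onset[z23]
  expect_true(all(diff(on) < 0))
  expect_error(eyedisc_scenario("eya", n_positions = 2), "n_positions")
})

test_that("timeline validation rejects malformed programs and events", {
  sch <- default_embryo_schedule()
  expect_error(scenario_timeline(sch, p1_program = data.frame(time = 10,
                                                              value = 0.1)),
               "start at time 0")
  expect_error(scenario_timeline(sch,
      p1_program = data.frame(time = c(0, 9999), value = c(0.1, 0.2))),
      "within")
  expect_error(scenario_timeline(sch,
      events = list(list(time = 100, param = "p9", value = 0.5))),
      "events")
})
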