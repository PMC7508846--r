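test_that("trajectories are deterministic in (timeline, seed) and conserve
           composition", {
  tl <- silencing_memory("anterior")
  t1 <- run_single(tl, seed = 123)
  t2 <- run_single(tl, seed = 123)
  expect_identical(t1, t2)
  t3 <- run_single(tl, seed = 124)
  expect_false(identical(t1$activity, t3$activity))
  expect_equal(t1$a_frac + t1$u_frac + t1$m_frac, rep(1, nrow(t1)))
  expect_equal(t1$state, t1$a_frac - t1$m_frac, tolerance = 1e-12)
  expect_equal(t1$time[1], 0)
  expect_equal(max(t1$time), 450)
})

test_that("an undriven promoter stays silent", {
  tl <- flat_timeline(p1 = 0, horizon = 500)
  tr <- run_single(tl, seed = 1)
  expect_equal(tr$activity, rep(0, nrow(tr)))
})

test_that("with constant parameters and no divisions the activity settles
           at p1 / (p1 + p2)", {
  tl <- flat_timeline(p1 = 0.1, horizon = 2000)
  ens <- run_ensemble(tl, 100, base_seed = 70)
  late <- ensemble_window_means(ens, c(500, 2000))
  expect_equal(mean(late), 0.5, tolerance = 0.03)
})

test_that("replicates are isolated: seeds are base + index and order does
           not matter", {
  tl <- flat_timeline(p1 = 0.1, horizon = 300)
  ens <- run_ensemble(tl, 3, base_seed = 5)
  expect_identical(ens$trajectories[[1]], run_single(tl, 5))
  expect_identical(ens$trajectories[[2]], run_single(tl, 6))
  one <- run_ensemble(tl, 1, base_seed = 5)
  expect_identical(one$trajectories[[1]], ens$trajectories[[1]])
})

test_that("sampling interval thins the recorded grid without changing the
           dynamics", {
  tl <- flat_timeline(p1 = 0.1, horizon = 400)
  full <- run_single(tl, seed = 2)
  thin <- run_single(tl, seed = 2, sample_every = 10)
  expect_equal(thin$time, seq(0, 400, by = 10))
  expect_equal(thin$activity, full$activity[full$time %in% thin$time])
})

test_that("with coupling off, promoter statistics are independent of the
           chromatin parameters", {
  tl1 <- flat_timeline(p1 = 0.1, chromatin_params(0.25, 0.25, 0.04),
                       horizon = 600)
  tl2 <- flat_timeline(p1 = 0.1, chromatin_params(0.05, 0.4, 0.3),
                       horizon = 600)
  m1 <- ensemble_window_means(run_ensemble(tl1, 400, base_seed = 61),
                              c(200, 600))
  m2 <- ensemble_window_means(run_ensemble(tl2, 400, base_seed = 461),
                              c(200, 600))
  expect_gt(suppressWarnings(ks.test(m1, m2)$p.value), 0.01)
})

test_that("timeline events override parameters from their onset", {
  sch <- flat_schedule(400)
  tl <- scenario_timeline(sch, chromatin_params(0.25, 0.25, 0),
                          p1_program = data.frame(time = 0, value = 0),
                          events = list(list(time = 200, param = "p3",
                                             value = 0)))
  cp <- pretre:::.compile_timeline(tl)
  expect_equal(cp$p3v[200], 0.25)  # step 200 starts at t = 199
  expect_equal(cp$p3v[201], 0)
  expect_equal(cp$p3v[400], 0)
})

test_that("grid scans cover the parameter grid and match single-cell
           ensembles", {
  expect_warning(g <- run_grid(c(0.25, 0.25), 0.04, 4, n = 2),
                 "deduplicated")
  expect_equal(nrow(g), 1)
  g2 <- suppressWarnings(run_grid(c(0.2, 0.25), c(0.04, 0.17), 4, n = 2))
  expect_equal(nrow(g2), 4)
  expect_true(all(c("memory_anterior_median", "variegation_anterior")
                  %in% names(g2)))
})
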