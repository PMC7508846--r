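test_that("memory score is the mean match to the target state and the two
           targets are complementary", {
  tr <- fake_ensemble(matrix(1, 1, 11))$trajectories[[1]]
  expect_equal(memory_score(tr, "active", c(0, 10)), 1)
  expect_equal(memory_score(tr, "repressed", c(0, 10)), 0)
  half <- fake_ensemble(matrix(0.5, 1, 11))$trajectories[[1]]
  expect_equal(memory_score(half, "active", c(0, 10)), 0.5)
  expect_equal(memory_score(half, "repressed", c(0, 10)), 0.5)
  set.seed(4)
  noisy <- fake_ensemble(matrix(runif(21), 1, 21))$trajectories[[1]]
  expect_equal(memory_score(noisy, "active", c(5, 15)) +
                 memory_score(noisy, "repressed", c(5, 15)), 1)
  expect_error(memory_score(tr, "active", c(50, 60)), "empty window")
})

test_that("window means average the activity over the window", {
  tr <- fake_ensemble(matrix(0.3, 1, 101))$trajectories[[1]]
  expect_equal(window_mean_activity(tr, c(0, 100)), 0.3)
  tr2 <- fake_ensemble(matrix(seq(0, 1, length.out = 11), 1, 11,
                              byrow = TRUE))$trajectories[[1]]
  expect_equal(window_mean_activity(tr2, c(5, 5)), 0.5)
})

test_that("the variegation index measures balanced extreme tails", {
  expect_equal(variegation_index(rep(0.5, 10)), 0)
  expect_equal(variegation_index(c(rep(0, 5), rep(1, 5))), 1)
  expect_equal(variegation_index(c(rep(0, 75), rep(1, 25))), 0.5)
  expect_error(variegation_index(0.5), "at least 2")
})

test_that("derepression time is the first persistent median crossing", {
  never <- fake_ensemble(matrix(0, 5, 200))
  expect_true(is.na(derepression_time(never)))
  step <- matrix(0, 5, 200)
  step[, 101:200] <- 1
  expect_equal(derepression_time(fake_ensemble(step)), 100)
  # a transient excursion does not count
  flicker <- step
  flicker[, 120] <- 0
  expect_equal(derepression_time(fake_ensemble(flicker)), 120)
})

test_that("accumulation curves reduce to the single replicate's own
           fractions", {
  tl <- accumulation_scenario("soma")
  ens <- run_ensemble(tl, 1, base_seed = 12)
  cur <- accumulation_curves(ens)
  expect_equal(cur$m_frac, ens$trajectories[[1]]$m_frac)
  expect_equal(cur$a_frac + cur$u_frac + cur$m_frac, rep(1, nrow(cur)))
})

test_that("gradient profiles are flat for flat discs and normalise to a
           unit maximum", {
  disc <- eyedisc_scenario("eya", n_positions = 5)
  res <- run_disc(disc, base_seed = 1, sample_every = 50)
  res$positions$window_mean <- rep(0.4, 5)
  prof <- gradient_profile(res, normalise = FALSE)
  expect_equal(prof$value, rep(0.4, 5))
  norm <- gradient_profile(res, normalise = TRUE)
  expect_equal(max(norm$value), 1)
  expect_equal(norm$value, rep(1, 5))
})

test_that("the eya element sharpens the enhancer gradient relative to the
           uncoupled promoter", {
  d0 <- run_disc(eyedisc_scenario("eya", C_late = 0, n_positions = 40),
                 base_seed = 50, sample_every = 10)
  de <- run_disc(eyedisc_scenario("eya", n_positions = 40),
                 base_seed = 50, sample_every = 10)
  ratio <- function(d) {
    pr <- gradient_profile(d, normalise = FALSE)
    max(pr$value) / mean(pr$value[pr$x > 0.9])
  }
  expect_gt(ratio(de), ratio(d0))
})

test_that("the eya disc varies less across positions than the bxd disc", {
  vi <- vapply(c("eya", "bxd"), function(p) {
    res <- run_disc(eyedisc_scenario(p), base_seed = 50, sample_every = 10)
    pos <- res$positions
    variegation_index(pos$window_mean[pos$zone > 1])
  }, 0)
  expect_lt(vi[["eya"]], vi[["bxd"]])
})
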