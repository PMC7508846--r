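test_that("array construction, serialisation and the state metric", {
  a <- chromatin_array(6, "U")
  expect_length(a, 6)
  expect_identical(chrom_string(a), "UUUUUU")
  expect_error(chromatin_array(1), "S must be")
  expect_error(chromatin_array(4, "X"), "fill")

  expect_equal(pretre_state(chromatin_array(10, "A")), 1)
  expect_equal(pretre_state(as_chromatin_array("AMUU")), 0)
  mixed <- chromatin_array(60, c(rep("A", 45), rep("M", 5), rep("U", 10)))
  expect_equal(pretre_state(mixed), (45 - 5) / 60, tolerance = 1e-12)
  expect_equal(sum(chromatin_counts(mixed)), 60)
})

test_that("feedback attempts convert stepwise via the mediator", {
  p_force <- chromatin_params(p3 = 1, p4 = 1, p5 = 0)
  a <- as_chromatin_array("UAM")
  # U mediator converts nothing
  expect_identical(chrom_string(feedback_attempt(a, 2, 1, p_force)), "UAM")
  # A mediator, M target, p4 = 1: one step only (M -> U, never M -> A)
  expect_identical(chrom_string(feedback_attempt(a, 3, 2, p_force)), "UAU")
  # M mediator, p3 = 0: nothing happens
  p0 <- chromatin_params(p3 = 0, p4 = 0, p5 = 0)
  expect_identical(chrom_string(feedback_attempt(a, 1, 3, p0)), "UAM")
  expect_error(feedback_attempt(a, 2, 2, p_force), "differ")
  expect_error(feedback_attempt(a, 9, 1, p_force), "invalid")
})

test_that("feedback-independent transitions follow the one-step rule", {
  a <- as_chromatin_array("AUM")
  expect_identical(chrom_string(noise_attempt(a, 1, chromatin_params(p5 = 0))),
                   "AUM")
  p1 <- chromatin_params(p5 = 1)
  expect_identical(chrom_string(noise_attempt(a, 1, p1)), "UUM")
  expect_identical(chrom_string(noise_attempt(a, 3, p1)), "AUU")
  # a U target splits evenly between A and M
  set.seed(11)
  draws <- replicate(1e4, unclass(noise_attempt(a, 2, p1))[2])
  expect_equal(mean(draws == 1L), 0.5, tolerance = 0.02)
})

test_that("sweeps conserve composition, are deterministic, and leave all-U
           absorbing without noise", {
  p <- chromatin_params(0.4, 0.3, 0.2)
  set.seed(3)
  a <- chromatin_array(12, sample(c("A", "U", "M"), 12, replace = TRUE))
  for (i in 1:20) {
    a <- chromatin_sweep(a, p)
    expect_equal(sum(chromatin_counts(a)), 12)
  }
  set.seed(5)
  s1 <- chromatin_sweep(chromatin_array(30, "U"), p, attempts = 300)
  set.seed(5)
  s2 <- chromatin_sweep(chromatin_array(30, "U"), p, attempts = 300)
  expect_identical(unclass(s1), unclass(s2))

  set.seed(6)
  absorb <- chromatin_sweep(chromatin_array(20, "U"),
                            chromatin_params(0.9, 0.9, 0), attempts = 5000)
  expect_identical(chrom_string(absorb), strrep("U", 20))
})

test_that("self-reinforcing feedback makes the array bistable in the
           long run", {
  set.seed(8)
  a <- chromatin_array(60, "U")
  p <- chromatin_params(0.25, 0.25, 0.04)
  st <- numeric(2000)
  for (i in 1:2000) {
    a <- chromatin_sweep(a, p)
    st[i] <- pretre_state(a)
  }
  expect_gt(mean(abs(st[501:2000])), 0.6)
})

test_that("replication wipes nucleosomes to U independently at the given
           probability", {
  a <- chromatin_array(60, "A")
  expect_identical(unclass(replicate_chromatin(a, 0)), unclass(a))
  expect_identical(chrom_string(replicate_chromatin(a, 1)), strrep("U", 60))
  set.seed(9)
  kept <- replicate(400, chromatin_counts(replicate_chromatin(a, 0.5))["A"])
  # surviving modified count is Binomial(60, 0.5)
  expect_equal(mean(kept), 30, tolerance = 0.5)
  bt <- binom.test(sum(kept), 400 * 60, p = 0.5)
  expect_gt(bt$p.value, 0.01)
})

test_that("A and M are statistically exchangeable when p3 = p4", {
  set.seed(42)
  p <- chromatin_params(0.25, 0.25, 0.04)
  na <- nm <- numeric(2000)
  for (i in 1:2000) {
    a <- chromatin_sweep(chromatin_array(20, "U"), p, attempts = 200)
    cc <- chromatin_counts(a)
    na[i] <- cc[["A"]]
    nm[i] <- cc[["M"]]
  }
  expect_gt(wilcox.test(na, nm)$p.value, 0.01)
})
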