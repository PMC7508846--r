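prom <- promoter_params(p1 = 0.02, p2 = 0.1)
chrom <- chromatin_params(0.25, 0.25, 0.04)

test_that("signed promoter state maps activity onto [-1, 1]", {
  expect_equal(signed_promoter_state(0), -1)
  expect_equal(signed_promoter_state(0.5), 0)
  expect_equal(signed_promoter_state(1), 1)
  expect_error(signed_promoter_state(1.2), "activity")
})

test_that("decoupling (C = 0) and neutral states are exact pass-throughs", {
  spec0 <- coupling_spec(C = 0)
  for (E in c(-1, -0.3, 0, 0.7, 1)) {
    adj <- adjust_parameters(prom, chrom, E, -E, spec0)
    expect_identical(adj$promoter$p1, prom$p1)
    expect_identical(adj$promoter$p2, prom$p2)
    expect_identical(adj$chromatin$p3, chrom$p3)
    expect_identical(adj$chromatin$p4, chrom$p4)
  }
  neutral <- adjust_parameters(prom, chrom, 0, 0, coupling_spec(C = 4))
  expect_identical(neutral$promoter$p1, prom$p1)
  expect_identical(neutral$chromatin$p3, chrom$p3)
})

test_that("model 1 evaluates the asymmetric multiplicative form", {
  spec <- coupling_spec(C = 4, model = 1)
  up <- adjust_parameters(prom, chrom, E = 1, P = 0, spec)
  expect_equal(up$promoter$p1, 0.02 * 5)      # favoured: q * (1 + C)
  expect_equal(up$promoter$p2, 0.1 / 5)       # disfavoured: q / (1 + C)
  dn <- adjust_parameters(prom, chrom, E = 0, P = -1, spec)
  expect_equal(dn$chromatin$p4, 0.25 / 5)
  expect_equal(dn$chromatin$p3, min(1, 0.25 * 5))
  expect_equal(dn$chromatin$p5, chrom$p5)     # p5 never adjusted
})

test_that("model 2 is signed-linear with clamping", {
  spec <- coupling_spec(C = 4, model = 2)
  adj <- adjust_parameters(prom, chrom, E = 0.5, P = 0, spec)
  expect_equal(adj$promoter$p1, 0.02 * 3)
  # 1 + C*x goes negative at x = -0.5: clamped to zero
  dn <- adjust_parameters(prom, chrom, E = -0.5, P = 0, spec)
  expect_equal(dn$promoter$p1, 0)
})

test_that("adjustments are monotone in the signals and stay in [0, 1]", {
  grid <- c(-1, -0.5, 0, 0.5, 1)
  for (model in 1:2) {
    spec <- coupling_spec(C = 3, model = model)
    p1s <- p2s <- p3s <- p4s <- numeric(0)
    for (E in grid) {
      adj <- adjust_parameters(prom, chrom, E, 0, spec)
      p1s <- c(p1s, adj$promoter$p1)
      p2s <- c(p2s, adj$promoter$p2)
    }
    for (P in grid) {
      adj <- adjust_parameters(prom, chrom, 0, P, spec)
      p3s <- c(p3s, adj$chromatin$p3)
      p4s <- c(p4s, adj$chromatin$p4)
    }
    expect_true(all(diff(p1s) >= 0))
    expect_true(all(diff(p2s) <= 0))
    expect_true(all(diff(p4s) >= 0))
    expect_true(all(diff(p3s) <= 0))
    expect_true(all(c(p1s, p2s, p3s, p4s) >= 0))
    expect_true(all(c(p1s, p2s, p3s, p4s) <= 1))
  }
})

test_that("model 1 is antisymmetric: opposite signals give reciprocal
           ratios", {
  spec <- coupling_spec(C = 2, model = 1)
  # small base value keeps both directions away from the clamp
  base <- promoter_params(p1 = 0.01, p2 = 0.01)
  for (E in c(0.25, 0.5, 0.9)) {
    r_up <- adjust_parameters(base, chrom, E, 0, spec)$promoter$p1 / base$p1
    r_dn <- adjust_parameters(base, chrom, -E, 0, spec)$promoter$p1 / base$p1
    expect_equal(r_dn, 1 / r_up, tolerance = 1e-12)
  }
})

test_that("out-of-range signals are rejected", {
  expect_error(adjust_parameters(prom, chrom, 1.5, 0, coupling_spec()),
               "E must be")
  expect_error(adjust_parameters(prom, chrom, 0, -2, coupling_spec()),
               "P must be")
})
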