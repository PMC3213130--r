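test_that("compute_pmr evaluates the scaled binomial ratio", {
  # zero numerator, identity ratio, and a hand-computed 110%
  expect_identical(compute_pmr(0, 1e5, 5500, 5.5e7), 0)
  expect_equal(compute_pmr(1, 1e4, 5500, 5.5e7), 100)
  expect_equal(compute_pmr(11, 1e5, 5500, 5.5e7), 110)
  # vectorised, values above 100 legal
  expect_equal(compute_pmr(c(0, 11), c(1e5, 1e5), 5500, 5.5e7), c(0, 110))
})

test_that("compute_pmr rejects degenerate draws", {
  expect_error(compute_pmr(1, 1e4, 0, 5.5e7), "undefined")
  expect_error(compute_pmr(1, 0, 5500, 5.5e7), "degenerate|satisfy")
  expect_error(compute_pmr(5, 4, 5500, 5.5e7), "satisfy")
})

test_that("sim_constants validates its invariants", {
  expect_error(sim_constants(fragments_per_genome = 0))
  expect_error(sim_constants(reference_genomes = -1))
  expect_error(sim_constants(conversion_efficiency = 0))
  expect_error(sim_constants(conversion_efficiency = 1.2))
  expect_silent(sim_constants(conversion_efficiency = 0.8))
})

test_that("fragment draws have the binomial means of the sampling model", {
  set.seed(101)
  # p = 0 never yields a methylated fragment
  d0 <- sample_fragment_draw(rep(50, 200), 0, default_consts)
  expect_true(all(d0$methylated_tumor == 0))
  # E[B] = G p/f = h p; E[B^r] = reference genomes
  d <- sample_fragment_draw(rep(100, 4000), 0.2, default_consts)
  expect_equal(d$fragments_tumor[1], 1e6)
  se_b <- sd(d$methylated_tumor) / sqrt(4000)
  expect_lt(abs(mean(d$methylated_tumor) - 20), 3 * se_b)
  se_br <- sd(d$methylated_reference) / sqrt(4000)
  expect_lt(abs(mean(d$methylated_reference) - 5500), 3 * se_br)
})

test_that("false-negative probability follows both closed forms", {
  expect_equal(prob_zero_detection(50, 0), 1)
  expect_equal(prob_zero_detection(0, 0.7), 1)
  expect_equal(prob_zero_detection(10, 0.2), 0.8^10)
  expect_equal(prob_zero_detection(10, 0.2, method = "fragment"),
               (1 - 0.2 / 1e4)^1e5)
  # monotone decreasing in p and in h
  p_grid <- prob_zero_detection(20, seq(0.05, 0.9, by = 0.05))
  expect_true(all(diff(p_grid) < 0))
  h_grid <- prob_zero_detection(c(1, 5, 20, 100), 0.3)
  expect_true(all(diff(h_grid) < 0))
  # the genome-level form approximates the exact fragment form as p -> 0
  # (within 0.01 for p <= 0.05 at any h; the gap grows with p)
  for (p in c(0.02, 0.05)) {
    for (h in c(1, 5, 15, 50, 200)) {
      expect_lt(abs(prob_zero_detection(h, p) -
                    prob_zero_detection(h, p, method = "fragment")), 0.01)
    }
  }
  expect_gt(abs(prob_zero_detection(10, 0.2) -
                prob_zero_detection(10, 0.2, method = "fragment")), 0.01)
})

test_that("simulated PMR is unbiased with the zero-inflation the model predicts", {
  set.seed(7)
  # p = 0 is always PMR 0
  expect_true(all(simulate_pmr(rep(10, 100), 0) == 0))
  # unbiasedness at fixed p, h: mean PMR/100 = p within 3 MC SE
  pmr <- simulate_pmr(rep(500, 10000), 0.2)
  se <- sd(pmr) / sqrt(10000)
  expect_lt(abs(mean(pmr) - 20), 3 * se)
  # empirical zero mass matches the exact binomial form
  pmr_low <- simulate_pmr(rep(10, 20000), 0.2)
  p0_exact <- prob_zero_detection(10, 0.2, method = "fragment")
  se0 <- sqrt(p0_exact * (1 - p0_exact) / 20000)
  expect_lt(abs(mean(pmr_low == 0) - p0_exact), 3 * se0)
  # at small p the genome-level form also tracks the empirical mass
  pmr_small <- simulate_pmr(rep(10, 20000), 0.05)
  expect_lt(abs(mean(pmr_small == 0) - prob_zero_detection(10, 0.05)),
            0.01 + 3 * se0)
})

test_that("PMR dispersion falls with DNA quantity and rises with methylation", {
  set.seed(21)
  h_deciles <- c(2, 5, 10, 25, 60, 150, 400)
  sds <- sapply(c(0.2, 0.8), function(p)
    sapply(h_deciles, function(h) sd(simulate_pmr(rep(h, 4000), p))))
  # SD strictly decreasing in h at both methylation levels
  expect_true(all(diff(sds[, 1]) < 0))
  expect_true(all(diff(sds[, 2]) < 0))
  # higher true proportion, larger PMR variation at every quantity
  expect_true(all(sds[, 2] > sds[, 1]))
})

test_that("an incompletely converted reference inflates PMR upward", {
  set.seed(31)
  partial <- sim_constants(conversion_efficiency = 0.8)
  pmr <- simulate_pmr(rep(500, 5000), 0.2, partial)
  # overestimation: mean exceeds 100 p (expected factor 1/0.8)
  expect_gt(mean(pmr), 20 + 3 * sd(pmr) / sqrt(5000))
})

test_that("a tiny reference triggers the bounded redraw, then errors", {
  set.seed(11)
  tiny <- sim_constants(reference_genomes = 1e-4)  # E[B^r] = 1e-4: mostly 0
  expect_error(simulate_pmr(rep(100, 50), 0.5, tiny, max_retries = 3L),
               "redraws")
})
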