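# small-scale readout settings used throughout this file; the full-scale
# experiment lives in the acceptance suite
small_readout <- function(...) {
  readout_spec(M = 2000, K = 20000, G = 100, ...)
}

test_that("odor pairs share glomerular draws and silence untargeted cells", {
  ro <- small_readout()
  dists <- default_distribution_set()
  # overlap one: identical vectors
  p1 <- sample_odor_pair(ro, dists, overlap = 1, seed = 3)
  expect_identical(p1$A, p1$B)
  # overlap zero: disjoint glomerular sets
  p0 <- sample_odor_pair(ro, dists, overlap = 0, seed = 3)
  expect_length(intersect(p0$glomeruli_A, p0$glomeruli_B), 0)
  # untargeted MCs are exactly zero; targeted glomeruli count is f_odor * G
  expect_equal(length(p0$glomeruli_A), round(ro$f_odor * ro$G))
  mc_glom <- rep(seq_len(ro$G), each = ro$mc_per_glom)
  expect_true(all(p0$A[!(mc_glom %in% p0$glomeruli_A)] == 0))
  # intermediate overlap: shared glomeruli contribute identical rates
  p5 <- sample_odor_pair(ro, dists, overlap = 0.5, seed = 3)
  shared <- intersect(p5$glomeruli_A, p5$glomeruli_B)
  expect_gt(length(shared), 0)
  idx <- which(mc_glom %in% shared)
  expect_identical(p5$A[idx], p5$B[idx])
})

test_that("feedback pairs realize the requested similarity structure", {
  ro <- small_readout()
  dists <- default_distribution_set()
  # fully shared excitatory feedback: identical change vectors
  f1 <- sample_feedback_pair(ro, dists, "mc_excitatory", share = 1, seed = 4)
  expect_identical(f1$exc_A, f1$exc_B)
  # of the p_FB * M targeted MCs, the zero-elevated law leaves a p_nz
  # fraction with a nonzero change
  n_t <- round(ro$p_FB * ro$M)
  expect_lt(abs(sum(f1$exc_A != 0) - n_t * dists$mc_change$p_nz),
            3 * sqrt(n_t * 0.31 * 0.69))
  # disjoint targets: near-zero similarity
  f0 <- sample_feedback_pair(ro, dists, "mc_excitatory", share = 0, seed = 4)
  expect_equal(cosine_similarity(f0$exc_A, f0$exc_B), 0, tolerance = 1e-12)
  # realized similarity increases monotonically with the share knob
  shares <- seq(0, 1, by = 0.25)
  sims <- vapply(shares, function(s) {
    f <- sample_feedback_pair(ro, dists, "mc_excitatory", s, seed = 5)
    cosine_similarity(f$exc_A, f$exc_B)
  }, numeric(1))
  expect_true(all(diff(sims) > -0.05))
  expect_true(all(abs(sims - shares) < 0.1))
  # combined kind adds an identical inhibitory background
  fc <- sample_feedback_pair(ro, dists, "combined", share = 0.5, seed = 6)
  expect_identical(fc$inh_A, fc$inh_B)
  expect_true(all(fc$inh_A <= 0 & fc$inh_A >= -2))
  # mixed kind: excitatory for one context, inhibitory for the other
  fm <- sample_feedback_pair(ro, dists, "mixed", seed = 7)
  expect_true(all(fm$exc_B == 0) && any(fm$exc_A > 0))
  expect_true(all(fm$inh_A == 0) && any(fm$inh_B < 0))
})

test_that("feedback application respects eligibility and nonnegativity", {
  rates <- c(0, 1, 3, 5)
  exc <- c(2, 0, 0, 1)
  inh <- c(-1, -1, -2, -2)
  out <- apply_feedback(rates, exc, inh, eligible_min = 2)
  # silent and weak cells are immune to inhibition; excitation always lands
  expect_equal(out, c(2, 1, 1, 4))
  expect_true(all(apply_feedback(rates, exc * 0, inh) >= 0))
})

test_that("cortical readout is balanced, deterministic and input-driven", {
  ro <- small_readout()
  dists <- default_distribution_set()
  sampling <- make_cortical_sampling(ro, seed = 10)
  pair <- sample_odor_pair(ro, dists, 0.5, seed = 11)
  cal <- calibrate_readout(list(pair$A, pair$B), sampling)
  k1 <- cortical_readout(pair$A, sampling, cal)
  k2 <- cortical_readout(pair$A, sampling, cal)
  expect_identical(k1, k2)
  expect_true(all(k1 > 0 & k1 < 1))
  # calibration: the strongly-active fraction matches the target
  expect_equal(mean(k1 > 0.5), ro$active_fraction, tolerance = 0.5)
  # zero rates: all units identical (pure symmetry)
  k0 <- cortical_readout(numeric(ro$M), sampling, cal)
  expect_equal(length(unique(k0)), 1)
  # each unit samples exactly round(qM) MCs
  expect_equal(sum(sampling$counts), ro$K * ro$m_per_unit)
})

test_that("similarity experiment sign pattern matches the gating regimes", {
  dists <- default_distribution_set()
  # high threshold at the size-stable scale: strongly shared feedback
  # raises similarity of similar odors more (positive fitted slope);
  # unshared feedback diverges, and the per-condition slope grows
  # monotonically with the realized feedback similarity
  ro_hi <- readout_spec(regime = "high")   # M = 10000, K = 100000
  ex_hi <- run_similarity_experiment(
    ro_hi, dists, overlap_grid = c(0.1, 0.3, 0.5, 0.7),
    share_grid = c(0, 0.5, 1), kind = "combined", trials = 2, seed = 301)
  hi <- ex_hi$conditions
  expect_gt(hi$slope[hi$share == 1], 0)
  expect_lt(hi$slope[hi$share == 0], 0)
  cond <- hi[order(hi$rho_FB), ]
  expect_true(all(diff(cond$slope) > 0))
  expect_gt(ex_hi$second_level$slope, 0)
  # rho_i decreases with glomerular overlap (in expectation)
  agg <- stats::aggregate(rho_i ~ overlap, data = ex_hi$data, FUN = mean)
  expect_true(all(diff(agg$rho_i[order(agg$overlap)]) > 0))
  # low threshold: reversal, negative slope with positive intercept even
  # for fully shared feedback
  ro_lo <- readout_spec(M = 8000, K = 80000, G = 400, regime = "low")
  ex_lo <- run_similarity_experiment(
    ro_lo, dists, overlap_grid = c(0.1, 0.3, 0.5, 0.7),
    share_grid = c(1), kind = "combined", trials = 2, seed = 302)
  expect_lt(ex_lo$conditions$slope[1], 0)
  expect_gt(ex_lo$conditions$intercept[1], 0)
})
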