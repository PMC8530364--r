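test_that("uniform-by-region draws respect exact region membership and seeds", {
  th <- threshold_spec(0.3, 0.8, 2)
  counts <- odor_pair_counts(5000, 3000, 2500, 2000, th)
  pop <- population_spec(5000, transfer = "step", theta_c = 0.8)
  fb <- fig3a_feedback()
  d1 <- sample_population(pop, fb, counts, seed = 5)
  d2 <- sample_population(pop, fb, counts, seed = 5)
  expect_identical(d1$responses, d2$responses)
  expect_identical(d1$dR_change, d2$dR_change)
  # exact counts above the response threshold
  expect_equal(sum(d1$responses[, 1] > th$theta_m), 3000)
  expect_equal(sum(d1$responses[, 2] > th$theta_m), 2500)
  expect_equal(sum(d1$responses[, 1] > th$theta_m &
                     d1$responses[, 2] > th$theta_m), 2000)
  # fully-overlapping odors put every responsive module in the AB region
  cab <- odor_pair_counts(5000, 2000, 2000, 2000, th)
  dab <- sample_population(pop, fb, cab, seed = 5)
  expect_equal(sum(xor(dab$responses[, 1] > th$theta_m,
                       dab$responses[, 2] > th$theta_m)), 0)
})

test_that("feedback case-label frequencies match their multinomial expectations", {
  fb <- feedback_spec(0.4, 0.125, 0.375, p_both = 0.5, p_flip = 0.2)
  th <- threshold_spec(0.3, 0.8, 2)
  counts <- odor_pair_counts(1e6, 6e5, 6e5, 4e5, th)
  pop <- population_spec(1e6, transfer = "step", theta_c = 0.8)
  d <- sample_population(pop, fb, counts, seed = 31)
  n <- 1e6
  tab <- table(d$case) / n
  cover <- fb$p_plus_A + fb$p_minus_A
  expected <- c(
    "both-same" = cover * fb$p_same,
    "both-flip" = cover * fb$p_flip,
    "A-only+" = fb$p_plus_A * (1 - fb$p_both),
    "A-only-" = fb$p_minus_A * (1 - fb$p_both))
  for (nm in names(expected)) {
    se <- sqrt(expected[[nm]] * (1 - expected[[nm]]) / n)
    expect_lt(abs(tab[[nm]] - expected[[nm]]), 3 * se)
  }
})

test_that("step-transfer similarity equals the counting formula on the same draw", {
  th <- threshold_spec(0.3, 0.8, 2)
  counts <- odor_pair_counts(20000, 12000, 12000, 8000, th)
  pop <- population_spec(20000, transfer = "step", theta_c = 0.8)
  fb <- fig3a_feedback(p_flip = 0.1)
  d <- sample_population(pop, fb, counts, seed = 8)
  sim <- empirical_similarity(d)
  CA <- sum(d$responses[, 1] >= 0.8)
  CB <- sum(d$responses[, 2] >= 0.8)
  CAB <- sum(d$responses[, 1] >= 0.8 & d$responses[, 2] >= 0.8)
  expect_equal(sim[["rho_i"]], CAB / sqrt(CA * CB))
  # identical columns give similarity one
  d2 <- d
  d2$responses[, 2] <- d2$responses[, 1]
  expect_equal(empirical_similarity(d2)[["rho_i"]], 1)
})

test_that("the analytic linear law matches the population oracle across random specs", {
  set.seed(1234)
  n_specs <- 8       # deeper coverage lives in the acceptance suite
  trials <- 4
  for (i in seq_len(n_specs)) {
    s <- random_valid_spec(N = 2e5)
    pop <- population_spec(2e5, transfer = "step", theta_c = s$th$theta_c)
    d <- vapply(seq_len(trials), function(t) {
      empirical_similarity(
        sample_population(pop, s$fb, s$counts,
                          seed = 1000 * i + t))[["delta_rho"]]
    }, numeric(1))
    se <- stats::sd(d) / sqrt(trials)
    pred <- s$analytic$Q2 * s$analytic$rho_i + s$analytic$Q1
    expect_lt(abs(mean(d) - pred), 3 * se + 1e-4)
  }
})

test_that("regression experiment recovers trivial and S1-style behavior", {
  th <- threshold_spec(0.3, 1.6, 2)
  mk <- function(f) odor_pair_counts(4e4, 2.4e4, 2.4e4, round(2.4e4 * f), th)
  grid <- lapply(c(0.4, 0.6, 0.8, 1.0), mk)
  # no feedback anywhere: flat zero line
  pop <- population_spec(4e4, transfer = "step", theta_c = 1.6)
  fb0 <- feedback_spec(0, 1, 0, 1, 0)
  r0 <- run_regression_experiment(pop, fb0, grid, trials = 2, seed = 2)
  expect_equal(r0$slope, 0, tolerance = 1e-8)
  expect_equal(r0$intercept, 0, tolerance = 1e-8)
  # Gaussian responses + sigmoid transfer, identical-sign Gaussian feedback:
  # convergence increases with initial similarity
  popg <- population_spec(4e4, response = "gaussian",
                          feedback_magnitude = "gaussian",
                          transfer = "sigmoid", theta_c = 1.6)
  fb_id <- feedback_spec(0.57, 1, 0, 1, 0)
  rg <- run_regression_experiment(popg, fb_id, grid, trials = 3, seed = 2)
  expect_gt(rg$slope, 0)
  # opposite-sign feedback: divergence increasing with similarity
  fb_op <- feedback_spec(0.57, 1, 0, 1, 1)
  rg2 <- run_regression_experiment(popg, fb_op, grid, trials = 3, seed = 2)
  expect_lt(rg2$slope, 0)
})

test_that("Gaussian identical-sign feedback has the stated similarity of 0.8", {
  th <- threshold_spec(0.3, 1.6, 2)
  counts <- odor_pair_counts(2e5, 1.2e5, 1.2e5, 8e4, th)
  popg <- population_spec(2e5, response = "gaussian",
                          feedback_magnitude = "gaussian",
                          transfer = "sigmoid", theta_c = 1.6)
  fb_id <- feedback_spec(0.57, 1, 0, 1, 0)
  d <- sample_population(popg, fb_id, counts, seed = 3)
  expect_equal(cosine_similarity(d$dR_change[, 1], d$dR_change[, 2]), 0.8,
               tolerance = 0.02)
})

test_that("single-layer control loses the gating distinction", {
  # with the identity transfer, moderately correlated and anticorrelated
  # feedback produce similar (non-diverging-with-similarity) trends
  th <- threshold_spec(0.3, 1.6, 2)
  mk <- function(f) odor_pair_counts(4e4, 2.4e4, 2.4e4, round(2.4e4 * f), th)
  grid <- lapply(c(0.4, 0.6, 0.8, 1.0), mk)
  popI <- population_spec(4e4, response = "gaussian",
                          feedback_magnitude = "gaussian",
                          transfer = "identity")
  fb_mod <- feedback_spec(0.57, 0.125, 0.375, 0.75, 0.075)  # rho_FB +0.6
  fb_ant <- feedback_spec(0.57, 0.125, 0.375, 0.75, 0.675)  # rho_FB -0.6
  r_mod <- run_regression_experiment(popI, fb_mod, grid, trials = 3, seed = 9)
  r_ant <- run_regression_experiment(popI, fb_ant, grid, trials = 3, seed = 9)
  expect_lt(abs(r_mod$slope - r_ant$slope), 0.15)
  # whereas the two-layer step transfer separates the same two conditions
  popS <- population_spec(4e4, response = "gaussian",
                          feedback_magnitude = "gaussian",
                          transfer = "sigmoid", theta_c = 1.6)
  s_mod <- run_regression_experiment(popS, fb_mod, grid, trials = 3, seed = 9)
  s_ant <- run_regression_experiment(popS, fb_ant, grid, trials = 3, seed = 9)
  expect_gt(abs(s_mod$slope - s_ant$slope), abs(r_mod$slope - r_ant$slope))
})

test_that("sampling error of delta_rho shrinks as one over sqrt(trials)", {
  th <- threshold_spec(0.3, 1.0, 2)
  counts <- odor_pair_counts(2e4, 1.2e4, 1.2e4, 8e3, th)
  pop <- population_spec(2e4, transfer = "step", theta_c = 1.0)
  fb <- fig3a_feedback(p_flip = 0.1)
  draw_se <- function(trials, rep_seed) {
    reps <- vapply(seq_len(20), function(r) {
      mean(vapply(seq_len(trials), function(t) {
        empirical_similarity(sample_population(
          pop, fb, counts, seed = rep_seed + 100 * r + t))[["delta_rho"]]
      }, numeric(1)))
    }, numeric(1))
    stats::sd(reps)
  }
  se4 <- draw_se(4, 1)
  se16 <- draw_se(16, 2)
  expect_equal(se4 / se16, 2, tolerance = 0.8)
})
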