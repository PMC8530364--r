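test_that("initial similarity equals the rescaled count ratio", {
  th <- threshold_spec(0.3, 0.8, 2)
  # hand arithmetic: Q0 = 1.2/1.7; N_A = N_B = 100, N_AB = 50
  counts <- odor_pair_counts(1000, 100, 100, 50, th)
  expect_equal(initial_similarity(counts, th), (1.2 / 1.7) * 50 / 100)
  # fully overlapping odors reach the ceiling Q0
  cts2 <- odor_pair_counts(1000, 80, 80, 80, th)
  expect_equal(initial_similarity(cts2, th), 1.2 / 1.7)
  # disjoint odors have zero similarity; empty odors are an error
  cts3 <- odor_pair_counts(1000, 80, 80, 0, th)
  expect_equal(initial_similarity(cts3, th), 0)
  cts4 <- odor_pair_counts(1000, 0, 80, 0, th)
  expect_error(initial_similarity(cts4, th), "undefined")
})

test_that("single-odor count shift reduces to its closed forms", {
  th <- threshold_spec(0.3, 0.8, 2)
  counts <- odor_pair_counts(1000, 600, 500, 400, th)
  # no feedback, no shift
  fb0 <- feedback_spec(0, 1, 0, 1, 0)
  expect_equal(single_odor_shift(counts, th, fb0, "A"), 0)
  # pure positive feedback below the threshold gap: dR * N_A / dRm
  fbp <- feedback_spec(0.4, 1, 0, 1, 0)
  expect_equal(single_odor_shift(counts, th, fbp, "A"), 0.4 * 600 / 1.7)
  expect_equal(single_odor_shift(counts, th, fbp, "B"), 0.4 * 500 / 1.7)
  # the sub-threshold promotion term engages only when dR > delta_theta
  fbx <- feedback_spec(0.6, 1, 0, 1, 0)
  expect_equal(single_odor_shift(counts, th, fbx, "A"),
               0.5 * 600 / 1.7 + 0.1 * (1000 - 600) / 0.3)
})

test_that("joint shifts vanish without feedback and rows 9-15 are gated", {
  th <- threshold_spec(0.3, 0.8, 2)
  counts <- odor_pair_counts(1000, 600, 500, 400, th)
  fb0 <- feedback_spec(0, 0.3, 0.3, 0.5, 0.1)
  expect_equal(joint_shift_contributions(counts, th, fb0)$total, 0)
  # theta_c >= theta_m + dR: every gated row is exactly zero
  fb <- fig3a_feedback(p_flip = 0.2, dR = 0.4)
  jc <- joint_shift_contributions(counts, th, fb)
  expect_identical(jc$contributions[9:15], rep(0, 7))
  # lowering theta_c below theta_m + dR engages them
  th_low <- threshold_spec(0.3, 0.6, 2)
  counts_low <- odor_pair_counts(1000, 600, 500, 400, th_low)
  jc_low <- joint_shift_contributions(counts_low, th_low, fb)
  expect_true(any(jc_low$contributions[9:15] != 0))
})

test_that("the linear law is exact and matches both closed-form slopes", {
  th <- threshold_spec(0.3, 1.0, 2)
  # identical full positive feedback: slope dR/(R_max - theta_c)
  fb_id <- feedback_spec(0.4, 1, 0, 1, 0)
  q_id <- linear_coefficients(th, fb_id, N = 2000, N_A = 800, N_B = 800)
  expect_equal(q_id[["Q2"]], 0.4 / 1.0, tolerance = 1e-10)
  expect_equal(q_id[["Q1"]], 0, tolerance = 1e-10)
  expect_equal(special_case_slope("identical", th, 0.4), 0.4)
  # worked example: rho_i = 0.5 gives delta_rho = 0.2
  counts <- odor_pair_counts(2000, 800, 800,
                             0.5 / (1 / 1.7) * sqrt(800 * 800), th)
  res <- similarity_after_feedback(counts, th, fb_id)
  expect_equal(res$rho_i, 0.5, tolerance = 1e-12)
  expect_equal(res$delta_rho, 0.2, tolerance = 1e-10)
  # opposite full feedback: slope sqrt(dRc^2 - dR^2)/dRc - 1
  fb_op <- feedback_spec(0.4, 1, 0, 1, 1)
  q_op <- linear_coefficients(th, fb_op, N = 2000, N_A = 800, N_B = 800)
  expect_equal(q_op[["Q2"]], sqrt(1 - 0.16) - 1, tolerance = 1e-10)
  expect_equal(special_case_slope("opposite", th, 0.4),
               sqrt(1 - 0.16) - 1, tolerance = 1e-12)
  expect_equal(special_case_slope("opposite", th, 0.4), -0.0835,
               tolerance = 2e-3)
  # closed forms refuse to apply outside the high-threshold regime
  th_low <- threshold_spec(0.3, 0.5, 2)
  expect_error(special_case_slope("identical", th_low, 0.4), "regime")
  # delta_rho = Q2 rho_i + Q1 holds within a similarity result
  set.seed(7)
  for (i in 1:10) {
    s <- random_valid_spec(N = 1e4)
    expect_equal(s$analytic$delta_rho,
                 s$analytic$Q2 * s$analytic$rho_i + s$analytic$Q1,
                 tolerance = 1e-9)
  }
})

test_that("coefficients are independent of the joint-count probe and of N_AB", {
  th <- fig3a_thresholds(0.6)          # low threshold: Q1 nonzero
  fb <- fig3a_feedback(p_flip = 0.1)
  qq <- linear_coefficients(th, fb, N = 1e4, N_A = 6e3, N_B = 6e3)
  # the law predicts delta_rho at any feasible N_AB
  for (nab in c(2200, 3500, 5000)) {
    counts <- odor_pair_counts(1e4, 6e3, 6e3, nab, th)
    res <- similarity_after_feedback(counts, th, fb)
    expect_equal(res$delta_rho, qq[["Q2"]] * res$rho_i + qq[["Q1"]],
                 tolerance = 1e-10)
  }
  expect_gt(qq[["Q1"]], 0)
})

test_that("full inhibitory feedback gives the negative threshold-shift slope", {
  th <- fig3a_thresholds(1.5)
  fb <- feedback_spec(0.4, 0, 1, 1, 0)
  qq <- linear_coefficients(th, fb, N = 1e4, N_A = 6e3, N_B = 6e3)
  expect_equal(qq[["Q2"]], -0.4 / 0.5, tolerance = 1e-10)
  expect_equal(qq[["Q1"]], 0, tolerance = 1e-10)
})

test_that("Q2 for identical positive feedback is nondecreasing in dR", {
  th <- threshold_spec(0.3, 1.0, 2)
  dRs <- seq(0, min(th$delta_theta, th$dRc), length.out = 12)
  q2 <- vapply(dRs, function(dR) {
    fb <- feedback_spec(dR, 1, 0, 1, 0)
    linear_coefficients(th, fb, 2000, 800, 800)[["Q2"]]
  }, numeric(1))
  expect_true(all(diff(q2) >= -1e-12))
  expect_equal(q2[1], 0, tolerance = 1e-12)
})

test_that("phase diagram recovers the convergence/divergence/mixed partition", {
  th_base <- threshold_spec(0.3, 0.8, 2)
  pd <- phase_diagram(theta_c_grid = c(0.5, 0.65, 0.8, 1.2, 1.7),
                      p_flip_grid = c(0, 0.25, 0.5),
                      th_base = th_base, dR = 0.4)
  # below theta_c = theta_m + dR = 0.7 all entries are mixed with Q1 > 0
  low <- pd[pd$theta_c < 0.7, ]
  expect_true(all(low$regime == "mixed"))
  expect_true(all(low$Q1 > 1e-9))
  # above the transition Q1 vanishes
  high <- pd[pd$theta_c > 0.7, ]
  expect_true(all(abs(high$Q1) < 1e-9))
  # in the realistic sparse band: correlated feedback converges,
  # anticorrelated diverges
  expect_equal(pd$regime[pd$theta_c == 1.7 & pd$p_flip == 0], "convergence")
  expect_equal(pd$regime[pd$theta_c == 1.7 & pd$p_flip == 0.5], "divergence")
  # rho_FB column follows the defining identity
  expect_equal(pd$rho_FB, 0.5 - 2 * pd$p_flip)
  # the marked active-fraction thresholds bracket the realistic band
  act <- attr(pd, "theta_c_active")
  expect_true(all(act > 1.5 & act < 2))
})
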