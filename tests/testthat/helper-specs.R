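# shared fixtures for the statistical-model tests

fig3a_thresholds <- function(theta_c = 0.8) threshold_spec(0.3, theta_c, 2)

fig3a_feedback <- function(p_flip = 0, dR = 0.4) {
  # coverage 0.5, inhibitory fraction 0.75, target overlap 0.5
  feedback_spec(dR, p_plus_A = 0.125, p_minus_A = 0.375,
                p_both = 0.5, p_flip = p_flip)
}

# a random valid (threshold, feedback, counts) triple; resamples until the
# joint feedback law is realizable and no shifted count collapses
random_valid_spec <- function(N = 1e6) {
  repeat {
    theta_m <- runif(1, 0.15, 0.5)
    theta_c <- runif(1, theta_m + 0.15, 1.8)
    th <- threshold_spec(theta_m, theta_c, 2)
    dR <- runif(1, 0.05, 0.5)
    coverage <- runif(1, 0.2, 0.9)
    inh <- runif(1, 0, 1)
    p_both_min <- if (coverage > 0.5) (2 * coverage - 1) / coverage else 0
    p_both <- runif(1, min(p_both_min + 0.05, 1), 1)
    p_flip <- runif(1, 0, p_both)
    fb <- try(feedback_spec(dR, coverage * (1 - inh), coverage * inh,
                            p_both, p_flip), silent = TRUE)
    if (inherits(fb, "try-error")) next
    p_odor <- runif(1, 0.3, 0.7)
    N_A <- round(p_odor * N)
    N_B <- round(runif(1, 0.3, 0.7) * N)
    lo <- max(N_A + N_B - N, 0)
    hi <- min(N_A, N_B)
    N_AB <- round(runif(1, lo + 0.1 * (hi - lo), hi - 0.1 * (hi - lo)))
    counts <- odor_pair_counts(N, N_A, N_B, N_AB, th)
    res <- try(similarity_after_feedback(counts, th, fb), silent = TRUE)
    if (inherits(res, "try-error")) next
    return(list(th = th, fb = fb, counts = counts, analytic = res))
  }
}
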