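test_that("granule-cell parameter sampling honors all three constraints", {
  gg <- sample_neuron_parameters("GC", 300, seed = 2)
  expect_true(all(gg$b < 0))
  s <- gg$b + gg$k * (gg$v_t - gg$v_r)
  rheo <- s^2 / (4 * gg$k)
  rin <- 1 / s
  expect_true(all(rheo >= 10 & rheo <= 70))
  expect_true(all(rin >= 0.25 & rin <= 1.5))
  # reproducibility
  expect_identical(gg, sample_neuron_parameters("GC", 300, seed = 2))
  # mitral-cell means recover the table values at large n
  mm <- sample_neuron_parameters("MC", 2e4, seed = 3)
  means <- izhikevich_means("MC")
  for (p in c("k", "a", "b", "C")) {
    se <- abs(means[[p]]) / 10 / sqrt(2e4)
    expect_lt(abs(mean(mm[[p]]) - means[[p]]), 4 * se)
  }
})

test_that("isolated neurons show class I vs class II excitability signatures", {
  gcp <- as.data.frame(izhikevich_means("GC"))
  mcp <- as.data.frame(izhikevich_means("MC"))
  rheo_gc <- izhikevich_rheobase(gcp)[["rheobase"]]
  rheo_mc <- izhikevich_rheobase(mcp)[["rheobase"]]
  # below rheobase the GC is silent; just above it fires at near-zero rate
  expect_equal(isolated_rate(gcp, 0.9 * rheo_gc), 0)
  r_low <- isolated_rate(gcp, 1.05 * rheo_gc)
  expect_gt(r_low, 0)
  expect_lt(r_low, 5)       # class I: continuous from zero
  # rate grows with current
  expect_gt(isolated_rate(gcp, 1.5 * rheo_gc), r_low)
  # the MC switches on with a substantial onset rate (class II): scan for
  # the first current step that elicits sustained firing
  currents <- seq(0.8, 1.3, by = 0.05) * rheo_mc
  rates <- vapply(currents, function(I) isolated_rate(mcp, I), numeric(1))
  onset <- rates[rates > 0][1]
  expect_gt(onset, 5 * r_low)
})

test_that("GC firing just above rheobase agrees with a fine-step integration", {
  gcp <- as.data.frame(izhikevich_means("GC"))
  rheo <- izhikevich_rheobase(gcp)[["rheobase"]]
  r1 <- isolated_rate(gcp, 1.05 * rheo, duration = 3000, dt = 0.1)
  r2 <- isolated_rate(gcp, 1.05 * rheo, duration = 3000, dt = 0.01)
  expect_gt(r1, 0)
  expect_lt(abs(r1 - r2) / r2, 0.1)
})

test_that("network simulation is stable at rest, deterministic and resets on spikes", {
  fx <- make_fixture_network(seed = 7, n_mc = 10, n_gc = 30)
  mcp <- sample_neuron_parameters("MC", 10, seed = 11)
  gcp <- sample_neuron_parameters("GC", 30, seed = 12)
  syn <- synapse_params()
  # no input: no spikes over 500 ms
  rec0 <- simulate_spiking_network(fx$graph, mcp, gcp, syn, NULL,
                                   duration = 500, seed = 1)
  expect_equal(sum(lengths(rec0$mc_spikes)) + sum(lengths(rec0$gc_spikes)), 0)
  # with odor drive: deterministic across reruns, spikes recorded
  prog <- stimulus_program(glomeruli = unique(fx$placement$mc$glomerulus))
  stim <- make_stimulus(prog, fx$placement, seed = 13)
  r1 <- simulate_spiking_network(fx$graph, mcp, gcp, syn, stim,
                                 duration = 1000 / 6, seed = 14,
                                 record_v = 1L)
  r2 <- simulate_spiking_network(fx$graph, mcp, gcp, syn, stim,
                                 duration = 1000 / 6, seed = 14)
  expect_identical(r1$mc_spikes, r2$mc_spikes)
  expect_gt(sum(spike_counts(r1)), 0)
  # after each recorded spike the voltage trace returns below threshold
  sp <- r1$mc_spikes[[1]]
  if (length(sp) > 0) {
    idx <- round(sp / r1$dt)
    expect_true(all(r1$v_trace[1, idx] <= mcp$c[1] + 1e-9))
  }
})

test_that("granule-cell inhibition can only reduce mitral spiking", {
  fx <- make_fixture_network(seed = 7, n_mc = 10, n_gc = 30)
  mcp <- sample_neuron_parameters("MC", 10, seed = 11)
  gcp <- sample_neuron_parameters("GC", 30, seed = 12)
  # strengthen GABA so the inhibitory pathway is clearly engaged
  syn <- synapse_params(g_GABA = 5, kappa = 0.05)
  prog <- stimulus_program(glomeruli = unique(fx$placement$mc$glomerulus),
                           fb_gc_fraction = 0.5, fb_gc_range = c(150, 200))
  stim <- make_stimulus(prog, fx$placement, seed = 13)
  with_inh <- simulate_spiking_network(fx$graph, mcp, gcp, syn, stim,
                                       duration = 1000 / 6, seed = 14)
  no_edges <- fx$graph
  no_edges$edges <- no_edges$edges[0, ]
  without <- simulate_spiking_network(no_edges, mcp, gcp, syn, stim,
                                      duration = 1000 / 6, seed = 14)
  expect_lte(sum(spike_counts(with_inh)), sum(spike_counts(without)))
})

test_that("halving the time step changes per-neuron sniff counts by at most one", {
  fx <- make_fixture_network(seed = 9, n_mc = 8, n_gc = 12)
  mcp <- sample_neuron_parameters("MC", 8, seed = 21)
  gcp <- sample_neuron_parameters("GC", 12, seed = 22)
  syn <- synapse_params()
  prog <- stimulus_program(glomeruli = unique(fx$placement$mc$glomerulus))
  stim <- make_stimulus(prog, fx$placement, seed = 23)
  rA <- simulate_spiking_network(fx$graph, mcp, gcp, syn, stim,
                                 duration = 1000 / 6, dt = 0.1, seed = 24)
  rB <- simulate_spiking_network(fx$graph, mcp, gcp, syn, stim,
                                 duration = 1000 / 6, dt = 0.05, seed = 24)
  expect_true(all(abs(spike_counts(rA) - spike_counts(rB)) <= 1))
})

test_that("stimulus realization honors target sets, ranges and the sniff cycle", {
  fx <- make_fixture_network(seed = 7, n_mc = 12, n_gc = 40)
  # empty glomerulus set: all-zero odor drive
  s0 <- make_stimulus(stimulus_program(glomeruli = integer()),
                      fx$placement, seed = 1)
  expect_true(all(s0$odor_amp == 0))
  expect_true(all(s0$mc_current(42) == 0))
  # targeted glomeruli only; amplitudes within the stated uniform range
  gl <- unique(fx$placement$mc$glomerulus)[1:2]
  s1 <- make_stimulus(stimulus_program(glomeruli = gl,
                                       fb_mc_fraction = 1 / 5,
                                       fb_gc_fraction = 1 / 8),
                      fx$placement, seed = 2)
  targeted <- fx$placement$mc$glomerulus %in% gl
  expect_true(all(s1$odor_amp[targeted] >= 300 & s1$odor_amp[targeted] <= 500))
  expect_true(all(s1$odor_amp[!targeted] == 0))
  expect_true(all(s1$fb_mc >= 0 & s1$fb_mc <= 300))
  expect_true(all(s1$fb_gc >= 0 & s1$fb_gc <= 200))
  expect_equal(sum(s1$fb_mc > 0), round(12 / 5))
  expect_equal(sum(s1$fb_gc > 0), round(40 / 8))
  # MCs of one glomerulus share a single amplitude draw
  expect_equal(length(unique(s1$odor_amp[targeted])), 2)
  # 6 Hz: the waveform is periodic with one sniff of 1000/6 ms
  t <- seq(0, 160, by = 0.5)
  expect_equal(s1$mc_current(10), s1$mc_current(10 + 1000 / 6),
               tolerance = 1e-9)
  # out-of-range feedback fraction is rejected
  expect_error(stimulus_program(fb_mc_fraction = 1.2), "fraction")
})
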