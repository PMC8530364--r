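## Conductance-based spiking simulation of the MC-GC network.  Izhikevich
## dynamics per cell, AMPA/NMDA synapses onto GCs, distance-attenuated GABA
## synapses onto MCs, oscillatory odor drive and constant feedback pulses;
## forward Euler at dt = 0.1 ms.

.izh_means <- list(
  MC = list(k = 2.5, a = 0.02, b = 12, c = -70, d = 13,
            v_r = -58, v_t = -49, v_c = 30, C = 191),
  GC = list(k = 0.067, a = 0.01, b = -0.133, c = -75, d = 2,
            v_r = -71, v_t = -39, v_c = 25, C = 48))

#' Mean Izhikevich parameters for a cell class
#'
#' @param class \code{"MC"} (class II mitral cell) or \code{"GC"} (class I
#'   granule cell).
#' @return Named list of the mean parameter values (conductance-based
#'   Izhikevich model: k in nS/mV, a in 1/ms, b in nS, c and voltages in mV,
#'   d in pA, C in pF).
#' @export
izhikevich_means <- function(class = c("MC", "GC")) {
  .izh_means[[match.arg(class)]]
}

#' Analytic rheobase and input resistance of an Izhikevich cell
#'
#' For the quadratic model with steady-state adaptation \code{u = b (v -
#' v_r)}, the saddle-node current (rheobase) is \code{(b + k dv)^2 / (4 k)}
#' with \code{dv = v_t - v_r}, and the small-signal input resistance at rest
#' is \code{1 / (b + k dv)} (GOhm for k in nS/mV and b in nS).
#'
#' @param p Named list or one-row data frame with \code{k}, \code{b},
#'   \code{v_r}, \code{v_t}.
#' @return Named vector \code{rheobase} (pA) and \code{R_in} (GOhm).
#' @export
izhikevich_rheobase <- function(p) {
  dv <- p$v_t - p$v_r
  s <- p$b + p$k * dv
  c(rheobase = s^2 / (4 * p$k), R_in = 1 / s)
}

#' Sample heterogeneous Izhikevich parameters for a population
#'
#' Every parameter is drawn Normal(mean, |mean|/10), except \code{b} and
#' \code{k} for granule cells, which are drawn Normal(mean, 2|mean|/3) and
#' rejection-sampled per cell (against that cell's own \code{v_r},
#' \code{v_t}) under the constraints \code{b < 0}, rheobase in \[10, 70\] pA
#' and input resistance in \[0.25, 1.5\] GOhm.
#'
#' @param class \code{"MC"} or \code{"GC"}.
#' @param n Number of cells.
#' @param seed Integer seed.
#' @param means Optional list overriding the class means.
#' @param max_tries Per-cell cap on rejection draws.
#' @return Data frame with one row per cell (columns \code{k}, \code{a},
#'   \code{b}, \code{c}, \code{d}, \code{v_r}, \code{v_t}, \code{v_c},
#'   \code{C}, \code{class}).
#' @export
sample_neuron_parameters <- function(class = c("MC", "GC"), n, seed = 1L,
                                     means = NULL, max_tries = 2000L) {
  class <- match.arg(class)
  .check_pos(n, "n")
  set.seed(seed)
  m <- if (is.null(means)) .izh_means[[class]] else means
  draw <- function(mu, sd_frac = 0.1) stats::rnorm(n, mu, abs(mu) * sd_frac)
  out <- data.frame(k = draw(m$k), a = draw(m$a), b = draw(m$b),
                    c = draw(m$c), d = draw(m$d),
                    v_r = draw(m$v_r), v_t = draw(m$v_t), v_c = draw(m$v_c),
                    C = abs(draw(m$C)))
  if (class == "GC") {
    for (i in seq_len(n)) {
      ok <- FALSE
      ## an extreme v_t - v_r draw can make the b/k constraints infeasible
      ## for that cell; in that case the cell's thresholds are redrawn
      for (outer in seq_len(50L)) {
        dv <- out$v_t[i] - out$v_r[i]
        for (tr in seq_len(max_tries)) {
          b <- stats::rnorm(1, m$b, abs(m$b) * 2 / 3)
          k <- stats::rnorm(1, m$k, abs(m$k) * 2 / 3)
          if (b >= 0 || k <= 0) next
          s <- b + k * dv
          if (s <= 0) next
          rheo <- s^2 / (4 * k)
          rin <- 1 / s
          if (rheo >= 10 && rheo <= 70 && rin >= 0.25 && rin <= 1.5) {
            out$b[i] <- b; out$k[i] <- k; ok <- TRUE; break
          }
        }
        if (ok) break
        out$v_r[i] <- stats::rnorm(1, m$v_r, abs(m$v_r) / 10)
        out$v_t[i] <- stats::rnorm(1, m$v_t, abs(m$v_t) / 10)
      }
      if (!ok) {
        stop("granule-cell b/k rejection sampling failed: constraints ",
             "infeasible with the configured means", call. = FALSE)
      }
    }
  }
  out$class <- class
  out
}

#' Synaptic parameters (Table of means)
#'
#' Mean conductances, kinetics and coupling constants of the dendrodendritic
#' synapse model.  \code{lambda_length} is the somatic-attenuation length
#' constant of the GABA conductance (\code{exp(-L / lambda_length)});
#' \code{kappa} scales the spike-independent (graded) GABA release triggered
#' by MC spikes at shared granule cells; \code{W = 0.5} is the gating
#' increment.
#'
#' @param g_AMPA,g_NMDA,g_GABA Peak conductances (nS).
#' @param kappa Graded-release scale (dimensionless, in (0,1)).
#' @param tau_AMPA,tau_NMDA_rise,tau_NMDA_decay,tau_GABA Time constants (ms).
#' @param lambda_length GABA attenuation length (um).
#' @param alpha NMDA activation rate (1/ms).
#' @param W Gating increment on a spike.
#' @param E_e,E_i Excitatory / inhibitory reversal potentials (mV).
#' @param Mg Extracellular magnesium concentration (mM) in the NMDA block.
#' @param heterogeneous If \code{TRUE}, per-synapse conductances and time
#'   constants are drawn Normal(mean, mean/10), truncated at zero.
#' @return An object of class \code{"synapse_params"}.
#' @export
synapse_params <- function(g_AMPA = 0.73, g_NMDA = 0.84, g_GABA = 0.13,
                           kappa = 0.006, tau_AMPA = 5.5,
                           tau_NMDA_rise = 10, tau_NMDA_decay = 80,
                           tau_GABA = 18, lambda_length = 675,
                           alpha = 0.1, W = 0.5,
                           E_e = 0, E_i = -70, Mg = 1,
                           heterogeneous = TRUE) {
  for (v in c("g_AMPA", "g_NMDA", "g_GABA", "tau_AMPA", "tau_NMDA_rise",
              "tau_NMDA_decay", "tau_GABA", "lambda_length", "alpha")) {
    .check_pos(get(v), v)
  }
  if (kappa <= 0 || kappa >= 1) stop("kappa must be in (0, 1)", call. = FALSE)
  structure(as.list(environment()), class = "synapse_params")
}

#' Stimulus program: oscillatory odor drive plus constant feedback pulses
#'
#' Odor input is an oscillatory current into the MCs of the targeted
#' glomeruli (default: half-wave-rectified sinusoid at the sniff frequency),
#' with the amplitude drawn uniformly per glomerulus.  External feedback is a
#' constant current pulse to a random subset of MCs and/or GCs.
#'
#' @param glomeruli Integer ids of odor-targeted glomeruli.
#' @param odor_amplitude_range Uniform range for the odor current (pA).
#' @param sniff_hz Respiration frequency (Hz); one sniff is
#'   \code{1/sniff_hz} seconds.
#' @param waveform \code{"half_sine"} or \code{"raised_cosine"}.
#' @param amplitude_per \code{"glomerulus"} (all MCs of a glomerulus share
#'   one draw) or \code{"mc"}.
#' @param fb_mc_fraction,fb_mc_range Fraction of MCs receiving a feedback
#'   pulse and its uniform amplitude range (pA).
#' @param fb_gc_fraction,fb_gc_range Same for GCs.
#' @param fb_onset,fb_duration Pulse window (ms); \code{Inf} duration means
#'   the pulse lasts to the end of the simulation.
#' @return An object of class \code{"stimulus_program"}.
#' @export
stimulus_program <- function(glomeruli = integer(),
                             odor_amplitude_range = c(300, 500),
                             sniff_hz = 6,
                             waveform = c("half_sine", "raised_cosine"),
                             amplitude_per = c("glomerulus", "mc"),
                             fb_mc_fraction = 0, fb_mc_range = c(0, 300),
                             fb_gc_fraction = 0, fb_gc_range = c(0, 200),
                             fb_onset = 0, fb_duration = Inf) {
  waveform <- match.arg(waveform)
  amplitude_per <- match.arg(amplitude_per)
  for (fr in c(fb_mc_fraction, fb_gc_fraction)) {
    if (fr < 0 || fr > 1) stop("feedback target fraction outside [0, 1]",
                               call. = FALSE)
  }
  structure(as.list(environment()), class = "stimulus_program")
}

#' Realize a stimulus program as per-neuron current traces
#'
#' Draws the per-glomerulus (or per-MC) odor amplitudes and the feedback
#' target sets and amplitudes, and returns closures evaluating the MC and GC
#' external currents at any time.
#'
#' @param program A \code{\link{stimulus_program}}.
#' @param placement A \code{\link{place_cells}} result (supplies the
#'   MC-glomerulus map and the population sizes).
#' @param seed Integer seed.
#' @return An object of class \code{"stimulus"} with fields
#'   \code{odor_amp} (per MC), \code{fb_mc}, \code{fb_gc} (per-cell pulse
#'   amplitudes), the pulse window, and \code{mc_current(t)},
#'   \code{gc_current(t)} evaluators (t in ms).
#' @export
make_stimulus <- function(program, placement, seed = 1L) {
  stopifnot(inherits(program, "stimulus_program"),
            inherits(placement, "cell_placement"))
  set.seed(seed)
  n_mc <- nrow(placement$mc)
  n_gc <- nrow(placement$gc)
  odor_amp <- numeric(n_mc)
  targeted <- placement$mc$glomerulus %in% program$glomeruli
  if (any(targeted)) {
    if (program$amplitude_per == "glomerulus") {
      amp_g <- stats::setNames(
        stats::runif(length(program$glomeruli),
                     program$odor_amplitude_range[1],
                     program$odor_amplitude_range[2]),
        program$glomeruli)
      odor_amp[targeted] <-
        amp_g[as.character(placement$mc$glomerulus[targeted])]
    } else {
      odor_amp[targeted] <- stats::runif(sum(targeted),
                                         program$odor_amplitude_range[1],
                                         program$odor_amplitude_range[2])
    }
  }
  fb_mc <- numeric(n_mc)
  n_fb_mc <- round(program$fb_mc_fraction * n_mc)
  if (n_fb_mc > 0) {
    idx <- sample.int(n_mc, n_fb_mc)
    fb_mc[idx] <- stats::runif(n_fb_mc, program$fb_mc_range[1],
                               program$fb_mc_range[2])
  }
  fb_gc <- numeric(n_gc)
  n_fb_gc <- round(program$fb_gc_fraction * n_gc)
  if (n_fb_gc > 0) {
    idx <- sample.int(n_gc, n_fb_gc)
    fb_gc[idx] <- stats::runif(n_fb_gc, program$fb_gc_range[1],
                               program$fb_gc_range[2])
  }
  omega <- 2 * pi * program$sniff_hz / 1000  # rad per ms
  wave <- if (program$waveform == "half_sine") {
    function(t) pmax(0, sin(omega * t))
  } else {
    function(t) 0.5 * (1 - cos(omega * t))
  }
  window <- c(program$fb_onset, program$fb_onset + program$fb_duration)
  structure(
    list(odor_amp = odor_amp, fb_mc = fb_mc, fb_gc = fb_gc,
         window = window, program = program, seed = seed,
         mc_current = function(t) {
           odor_amp * wave(t) +
             fb_mc * as.numeric(t >= window[1] && t < window[2])
         },
         gc_current = function(t) {
           fb_gc * as.numeric(t >= window[1] && t < window[2])
         }),
    class = "stimulus")
}

#' Simulate the spiking MC-GC network
#'
#' Forward-Euler integration (default dt = 0.1 ms) of the Izhikevich
#' membrane equations and synaptic gating variables.  On an MC spike the
#' AMPA/NMDA gates of its GC synapses are incremented, and the GABA gates of
#' all synapses onto MCs sharing its GCs receive the kappa-scaled
#' (spike-independent graded release) increment in the same step; on a GC
#' spike the GABA gates of its MC synapses receive the full increment.  The
#' GABA current onto an MC is attenuated by \code{exp(-L / lambda_length)}
#' with \code{L} the synapse's somatic distance; the NMDA current carries the
#' magnesium-block factor.
#'
#' @param graph A \code{\link{build_network}} result (may have zero edges).
#' @param mc_params,gc_params Data frames from
#'   \code{\link{sample_neuron_parameters}} with \code{graph$n_mc} /
#'   \code{graph$n_gc} rows.
#' @param syn A \code{\link{synapse_params}}.
#' @param stim A \code{\link{make_stimulus}} result, or \code{NULL} for no
#'   external input.
#' @param duration Simulated time (ms).
#' @param dt Euler step (ms).
#' @param seed Seed for the per-synapse parameter heterogeneity.
#' @param record_v Optional integer vector of MC ids whose voltage traces to
#'   keep.
#' @return An object of class \code{"spike_record"}: lists \code{mc_spikes}
#'   and \code{gc_spikes} of spike-time vectors (ms), the call parameters,
#'   and optional voltage traces.
#' @export
simulate_spiking_network <- function(graph, mc_params, gc_params, syn,
                                     stim = NULL, duration = 1000 / 6,
                                     dt = 0.1, seed = 1L, record_v = NULL) {
  stopifnot(inherits(graph, "connectivity_graph"),
            inherits(syn, "synapse_params"))
  n_mc <- graph$n_mc
  n_gc <- graph$n_gc
  stopifnot(nrow(mc_params) == n_mc, nrow(gc_params) == n_gc)
  set.seed(seed)
  ne <- nrow(graph$edges)
  e_mc <- graph$edges$mc
  e_gc <- graph$edges$gc
  ## per-synapse heterogeneity, truncated at zero
  het <- function(mu) {
    if (ne == 0) return(numeric(0))
    if (syn$heterogeneous) pmax(stats::rnorm(ne, mu, mu / 10), 1e-6 * mu)
    else rep(mu, ne)
  }
  gA <- het(syn$g_AMPA); gN <- het(syn$g_NMDA); gG <- het(syn$g_GABA)
  tA <- het(syn$tau_AMPA); tNr <- het(syn$tau_NMDA_rise)
  tNd <- het(syn$tau_NMDA_decay); tG <- het(syn$tau_GABA)
  att <- if (ne > 0) exp(-graph$edges$L / syn$lambda_length) else numeric(0)
  sA <- sN <- nN <- sG <- numeric(ne)

  v_mc <- mc_params$v_r; u_mc <- numeric(n_mc)
  v_gc <- gc_params$v_r; u_gc <- numeric(n_gc)
  n_steps <- ceiling(duration / dt)
  mc_sp <- vector("list", n_mc)
  gc_sp <- vector("list", n_gc)
  for (i in seq_len(n_mc)) mc_sp[[i]] <- numeric(0)
  for (i in seq_len(n_gc)) gc_sp[[i]] <- numeric(0)
  vtrace <- if (!is.null(record_v)) {
    matrix(NA_real_, length(record_v), n_steps)
  } else NULL

  for (step in seq_len(n_steps)) {
    t <- (step - 1) * dt
    I_mc <- if (is.null(stim)) numeric(n_mc) else stim$mc_current(t)
    I_gc <- if (is.null(stim)) numeric(n_gc) else stim$gc_current(t)
    if (ne > 0) {
      Vg <- v_gc[e_gc]
      block <- 1 / (1 + syn$Mg * exp(-0.062 * Vg) / 3.57)
      I_exc <- (sA * gA + sN * gN * block) * (Vg - syn$E_e)
      gc_syn <- rowsum(I_exc, e_gc, reorder = FALSE)
      I_gc[as.integer(rownames(gc_syn))] <-
        I_gc[as.integer(rownames(gc_syn))] - gc_syn[, 1]
      Vm <- v_mc[e_mc]
      I_inh <- sG * gG * att * (Vm - syn$E_i)
      mc_syn <- rowsum(I_inh, e_mc, reorder = FALSE)
      I_mc[as.integer(rownames(mc_syn))] <-
        I_mc[as.integer(rownames(mc_syn))] - mc_syn[, 1]
    }
    ## membrane update
    v_mc_new <- v_mc + dt / mc_params$C *
      (mc_params$k * (v_mc - mc_params$v_r) * (v_mc - mc_params$v_t) -
         u_mc + I_mc)
    u_mc <- u_mc + dt * mc_params$a *
      (mc_params$b * (v_mc - mc_params$v_r) - u_mc)
    v_mc <- v_mc_new
    v_gc_new <- v_gc + dt / gc_params$C *
      (gc_params$k * (v_gc - gc_params$v_r) * (v_gc - gc_params$v_t) -
         u_gc + I_gc)
    u_gc <- u_gc + dt * gc_params$a *
      (gc_params$b * (v_gc - gc_params$v_r) - u_gc)
    v_gc <- v_gc_new
    if (any(!is.finite(v_mc)) || any(abs(v_mc) > 1e4) ||
        any(!is.finite(v_gc)) || any(abs(v_gc) > 1e4)) {
      bad_mc <- which(!is.finite(v_mc) | abs(v_mc) > 1e4)
      bad_gc <- which(!is.finite(v_gc) | abs(v_gc) > 1e4)
      stop(sprintf("numerical blow-up at t = %.1f ms (MC %s; GC %s)", t,
                   paste(bad_mc, collapse = ","),
                   paste(bad_gc, collapse = ",")), call. = FALSE)
    }
    ## gating decay
    if (ne > 0) {
      sA <- sA - dt * sA / tA
      sG <- sG - dt * sG / tG
      sN <- sN + dt * (-sN / tNd + syn$alpha * nN * (1 - sN))
      nN <- nN - dt * nN / tNr
    }
    ## spike detection and reset (checked after the state update)
    sp_mc <- which(v_mc >= mc_params$v_c)
    if (length(sp_mc) > 0) {
      for (i in sp_mc) mc_sp[[i]] <- c(mc_sp[[i]], t + dt)
      v_mc[sp_mc] <- mc_params$c[sp_mc]
      u_mc[sp_mc] <- u_mc[sp_mc] + mc_params$d[sp_mc]
      if (ne > 0) {
        on <- e_mc %in% sp_mc
        sA[on] <- sA[on] + syn$W * (1 - sA[on])
        nN[on] <- nN[on] + syn$W * (1 - nN[on])
        ## graded GABA release at every synapse sharing a GC with a spiking
        ## MC, applied once per spiking MC via the closed-form compounding
        gc_hit <- tabulate(e_gc[on], nbins = n_gc)
        mult <- gc_hit[e_gc]
        upd <- mult > 0
        if (any(upd)) {
          sG[upd] <- 1 - (1 - syn$kappa * syn$W)^mult[upd] * (1 - sG[upd])
        }
      }
    }
    sp_gc <- which(v_gc >= gc_params$v_c)
    if (length(sp_gc) > 0) {
      for (i in sp_gc) gc_sp[[i]] <- c(gc_sp[[i]], t + dt)
      v_gc[sp_gc] <- gc_params$c[sp_gc]
      u_gc[sp_gc] <- u_gc[sp_gc] + gc_params$d[sp_gc]
      if (ne > 0) {
        on <- e_gc %in% sp_gc
        sG[on] <- sG[on] + syn$W * (1 - sG[on])
      }
    }
    if (!is.null(vtrace)) vtrace[, step] <- v_mc[record_v]
  }
  structure(
    list(mc_spikes = mc_sp, gc_spikes = gc_sp,
         duration = duration, dt = dt, seed = seed,
         v_trace = vtrace, record_v = record_v),
    class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat("Spike record:", length(x$mc_spikes), "MCs,", length(x$gc_spikes),
      "GCs over", x$duration, "ms (dt =", x$dt, "ms)\n")
  cat("  total spikes: MC", sum(lengths(x$mc_spikes)),
      " GC", sum(lengths(x$gc_spikes)), "\n")
  invisible(x)
}

#' Per-MC spike counts over a window
#'
#' @param record A \code{\link{simulate_spiking_network}} result.
#' @param window Time window (ms); default the whole simulation (one sniff
#'   when the duration is \code{1000/6} ms).
#' @param population \code{"mc"} or \code{"gc"}.
#' @return Integer vector of spike counts.
#' @export
spike_counts <- function(record, window = NULL, population = c("mc", "gc")) {
  population <- match.arg(population)
  sp <- if (population == "mc") record$mc_spikes else record$gc_spikes
  if (is.null(window)) window <- c(0, record$duration)
  vapply(sp, function(s) sum(s >= window[1] & s < window[2]), integer(1))
}

#' Isolated-neuron firing rate for a constant current step
#'
#' Convenience wrapper simulating a single unconnected neuron; used to probe
#' f-I curves (class I vs class II excitability signatures).
#'
#' @param params One-row data frame of Izhikevich parameters.
#' @param I Constant current (pA).
#' @param duration,dt Simulation time and step (ms).
#' @param discard Initial transient to discard (ms).
#' @return Firing rate in Hz over the retained window.
#' @export
isolated_rate <- function(params, I, duration = 2000, dt = 0.1,
                          discard = 200) {
  v <- params$v_r; u <- 0
  n_steps <- ceiling(duration / dt)
  count <- 0
  for (step in seq_len(n_steps)) {
    t <- (step - 1) * dt
    v_new <- v + dt / params$C *
      (params$k * (v - params$v_r) * (v - params$v_t) - u + I)
    u <- u + dt * params$a * (params$b * (v - params$v_r) - u)
    v <- v_new
    if (v >= params$v_c) {
      v <- params$c
      u <- u + params$d
      if (t >= discard) count <- count + 1
    }
  }
  count / ((duration - discard) / 1000)
}

#' Scaled-down spiking run summarizing firing-rate distributions
#'
#' Builds a miniature bulb network, presents a set of odors (each targeting
#' a subset of glomeruli with oscillatory drive) for one sniff, then repeats
#' the runs with direct excitatory feedback to a random fifth of the MCs and
#' with excitatory feedback to a random eighth of the GCs, and collects the
#' per-MC spike counts and count changes.  The output feeds
#' \code{\link{fit_rate_distributions}}; at this scale the fitted parameters
#' carry wide confidence intervals and serve as a qualitative check against
#' the packaged reference values, not a reproduction of them.
#'
#' @param n_mc,n_gc,n_glomeruli Network size (kept small by design).
#' @param n_odors Number of odors presented.
#' @param f_glom_odor Fraction of glomeruli targeted per odor.
#' @param seed Master seed.
#' @return List with \code{odor_rates} (spikes/sniff across odors and MCs),
#'   \code{mc_feedback_change}, \code{gc_feedback_change} (changes for
#'   eligible MCs, counts >= 2), and the \code{graph}.
#' @export
spiking_rate_summary <- function(n_mc = 40, n_gc = 160, n_glomeruli = 8,
                                 n_odors = 4, f_glom_odor = 0.25,
                                 seed = 1L) {
  layout <- layout_spec(n_mc = n_mc, n_gc = n_gc, n_glomeruli = n_glomeruli,
                        box = c(600, 600, 300), mc_disc_radius = 200,
                        mc_type1_z = 200, mc_type2_z = 240,
                        gc_vertex_z_range = c(20, 150),
                        gc_half_angle = pi / 5,
                        mc_dendrite_length = 5000, gc_spine_count = 2000,
                        spine_z_range = c(40, 300), spine_z_peak = 180)
  placement <- place_cells(layout, seed = derive_seed(seed, "place"))
  graph <- build_network(placement, seed = derive_seed(seed, "net"))
  mcp <- sample_neuron_parameters("MC", n_mc, derive_seed(seed, "mcp"))
  gcp <- sample_neuron_parameters("GC", n_gc, derive_seed(seed, "gcp"))
  syn <- synapse_params()
  n_target <- max(1L, round(f_glom_odor * n_glomeruli))
  odor_rates <- c()
  mc_change <- c()
  gc_change <- c()
  for (o in seq_len(n_odors)) {
    oseed <- derive_seed(seed, sprintf("odor-%d", o))
    set.seed(oseed)
    gloms <- sample.int(n_glomeruli, n_target)
    base_prog <- stimulus_program(glomeruli = gloms)
    stim0 <- make_stimulus(base_prog, placement, seed = oseed)
    rec0 <- simulate_spiking_network(graph, mcp, gcp, syn, stim0,
                                     duration = 1000 / 6,
                                     seed = derive_seed(seed, "sim"))
    c0 <- spike_counts(rec0)
    odor_rates <- c(odor_rates, c0)
    ## direct excitatory feedback to 1/5 of the MCs
    prog_mc <- stimulus_program(glomeruli = gloms, fb_mc_fraction = 1 / 5,
                                fb_mc_range = c(0, 300))
    stim1 <- make_stimulus(prog_mc, placement, seed = oseed)
    rec1 <- simulate_spiking_network(graph, mcp, gcp, syn, stim1,
                                     duration = 1000 / 6,
                                     seed = derive_seed(seed, "sim"))
    mc_change <- c(mc_change, spike_counts(rec1) - c0)
    ## excitatory feedback to 1/8 of the GCs (indirect inhibition)
    prog_gc <- stimulus_program(glomeruli = gloms, fb_gc_fraction = 1 / 8,
                                fb_gc_range = c(0, 200))
    stim2 <- make_stimulus(prog_gc, placement, seed = oseed)
    rec2 <- simulate_spiking_network(graph, mcp, gcp, syn, stim2,
                                     duration = 1000 / 6,
                                     seed = derive_seed(seed, "sim"))
    d <- spike_counts(rec2) - c0
    gc_change <- c(gc_change, d[c0 >= 2])
  }
  list(odor_rates = odor_rates, mc_feedback_change = mc_change,
       gc_feedback_change = gc_change, graph = graph)
}
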