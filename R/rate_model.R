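## Reduced mechanistic tier: large-M odor and feedback rate vectors drawn
## from the fitted firing-rate laws, passed through a balanced, sigmoid,
## threshold-gated random cortical readout; similarity experiments over
## grids of odor overlap and feedback similarity.

#' Readout specification for the reduced mechanistic model
#'
#' @param M Number of mitral cells.
#' @param K Number of cortical units.
#' @param G Number of glomeruli (MCs are partitioned evenly; \code{M/G} MCs
#'   per glomerulus).
#' @param q Fraction of MCs sampled by each cortical unit.
#' @param f_odor Fraction of glomeruli targeted by one odor.
#' @param p_FB Fraction of MCs targeted by direct positive feedback.
#' @param regime \code{"high"} (sparse cortical activation; the sigmoid
#'   threshold is calibrated so that \code{active_fraction} of units exceed
#'   it) or \code{"low"} (broad activation).
#' @param active_fraction Target strongly-active fraction; defaults to 0.03
#'   in the high-threshold regime (the sparse end of the experimentally
#'   reported piriform activation range, where threshold gating is
#'   selective enough for convergence to grow with initial similarity) and
#'   0.50 in the low regime.
#' @param steepness_frac The sigmoid's 10--90\% rise, as a fraction of the
#'   central input range (1st to 99th percentile of calibration inputs).
#' @return An object of class \code{"readout_spec"}.
#' @export
readout_spec <- function(M = 10000, K = 100000, G = 500, q = 0.07,
                         f_odor = 0.12, p_FB = 0.08,
                         regime = c("high", "low"),
                         active_fraction = NULL, steepness_frac = 0.1) {
  regime <- match.arg(regime)
  for (v in c("q", "f_odor", "p_FB")) {
    val <- get(v)
    if (val <= 0 || val >= 1) {
      stop(sprintf("'%s' must lie strictly in (0, 1)", v), call. = FALSE)
    }
  }
  if (round(q * M) < 1) stop("round(q * M) must be at least 1", call. = FALSE)
  if (M %% G != 0) {
    stop("M must be a multiple of G (even glomerular partition)",
         call. = FALSE)
  }
  if (is.null(active_fraction)) {
    active_fraction <- if (regime == "high") 0.03 else 0.50
  }
  structure(
    list(M = as.integer(M), K = as.integer(K), G = as.integer(G),
         q = q, f_odor = f_odor, p_FB = p_FB, regime = regime,
         active_fraction = active_fraction, steepness_frac = steepness_frac,
         m_per_unit = as.integer(round(q * M)),
         mc_per_glom = as.integer(M / G)),
    class = "readout_spec")
}

#' Fixed random cortical sampling of the mitral-cell population
#'
#' Each of the K units samples \code{round(q M)} distinct MCs uniformly
#' without replacement.  The sampling is fixed per network seed and shared
#' across odors, feedback conditions and the pre/post comparison, so
#' similarity changes reflect the inputs and not resampling noise.
#'
#' @param readout A \code{\link{readout_spec}}.
#' @param seed Integer seed.
#' @return An object of class \code{"cortical_sampling"} holding the
#'   sampling as a sparse 0/1 matrix (units by MCs), so that the input to
#'   all units is a single sparse matrix-vector product.
#' @export
make_cortical_sampling <- function(readout, seed = 1L) {
  stopifnot(inherits(readout, "readout_spec"))
  set.seed(seed)
  M <- readout$M; K <- readout$K; m <- readout$m_per_unit
  mcs <- integer(K * m)
  for (u in seq_len(K)) {
    mcs[((u - 1) * m + 1):(u * m)] <- sample.int(M, m)
  }
  units <- rep(seq_len(K), each = m)
  ## column-compressed form directly (columns = MCs), avoiding the
  ## triplet-sorting overhead of the generic constructor
  ord <- order(mcs, method = "radix")
  counts <- tabulate(mcs, nbins = M)
  P <- methods::new("dgCMatrix",
                    i = as.integer(units[ord] - 1L),
                    p = as.integer(c(0, cumsum(counts))),
                    x = rep(1, length(ord)),
                    Dim = c(K, M))
  structure(list(P = P, counts = counts, readout = readout, seed = seed),
            class = "cortical_sampling")
}

## summed sampled-MC rate for each cortical unit (length K)
.cortical_input <- function(rates, sampling) {
  as.numeric(sampling$P %*% rates)
}

#' Calibrate the cortical transfer function
#'
#' The balanced (mean-subtracted) inputs of one or more calibration rate
#' vectors set the sigmoid: the threshold is the quantile leaving the target
#' fraction of units above it, and the 10--90\% rise spans
#' \code{steepness_frac} of the central input range.
#'
#' @param rate_vectors List of MC rate vectors (calibration odors).
#' @param sampling A \code{\link{make_cortical_sampling}} result.
#' @return A list \code{threshold}, \code{steepness} of class
#'   \code{"readout_calibration"}.
#' @export
calibrate_readout <- function(rate_vectors, sampling) {
  readout <- sampling$readout
  balanced <- unlist(lapply(rate_vectors, function(r) {
    x <- .cortical_input(r, sampling)
    x - mean(x)
  }))
  threshold <- unname(stats::quantile(balanced, 1 - readout$active_fraction))
  span <- unname(diff(stats::quantile(balanced, c(0.01, 0.99))))
  steepness <- max(readout$steepness_frac * span, 1e-9) / (2 * base::log(9))
  structure(list(threshold = threshold, steepness = steepness),
            class = "readout_calibration")
}

#' Threshold-gated cortical activity for an MC rate vector
#'
#' Sums each unit's sampled MC rates, subtracts the mean input across units
#' (cortical balancing), and applies the calibrated sigmoid.
#'
#' @param rates Numeric MC rate vector (length M).
#' @param sampling A \code{\link{make_cortical_sampling}} result.
#' @param calibration A \code{\link{calibrate_readout}} result.
#' @return Numeric cortical activity vector (length K), values in (0, 1).
#' @export
cortical_readout <- function(rates, sampling, calibration) {
  stopifnot(length(rates) == sampling$readout$M)
  input <- .cortical_input(rates, sampling)
  balanced <- input - mean(input)
  1 / (1 + exp(-(balanced - calibration$threshold) / calibration$steepness))
}

#' Draw an odor pair with controlled glomerular overlap
#'
#' Each odor targets \code{round(f_odor G)} glomeruli; the pair shares the
#' requested fraction of them.  The rates of all MCs of a targeted
#' glomerulus are drawn from the odor law with a per-glomerulus substream
#' seed, so shared glomeruli contribute identical rates to both odors (at
#' overlap 1 the vectors coincide).  Untargeted MCs are exactly zero.
#'
#' @param readout A \code{\link{readout_spec}}.
#' @param dists A \code{\link{distribution_set}}.
#' @param overlap Shared fraction of targeted glomeruli, in \[0, 1\].
#' @param seed Integer seed for this pair.
#' @return List with rate vectors \code{A}, \code{B} and the targeted
#'   glomerulus sets.
#' @export
sample_odor_pair <- function(readout, dists, overlap, seed = 1L) {
  stopifnot(inherits(readout, "readout_spec"))
  if (overlap < 0 || overlap > 1) stop("overlap must be in [0, 1]",
                                       call. = FALSE)
  set.seed(seed)
  n_t <- round(readout$f_odor * readout$G)
  n_shared <- round(overlap * n_t)
  perm <- sample.int(readout$G)
  shared <- perm[seq_len(n_shared)]
  onlyA <- perm[n_shared + seq_len(n_t - n_shared)]
  onlyB <- perm[n_t + seq_len(n_t - n_shared)]
  glomsA <- c(shared, onlyA)
  glomsB <- c(shared, onlyB)
  mcs_of <- function(g) {
    as.vector(outer(seq_len(readout$mc_per_glom),
                    (g - 1) * readout$mc_per_glom, "+"))
  }
  fill <- function(gloms) {
    r <- numeric(readout$M)
    for (g in gloms) {
      set.seed(derive_seed(seed, paste0("glom-", g)))
      r[mcs_of(g)] <- draw_odor_rates(readout$mc_per_glom, dists)
    }
    r
  }
  list(A = fill(glomsA), B = fill(glomsB),
       glomeruli_A = sort(glomsA), glomeruli_B = sort(glomsB))
}

#' Draw a feedback pair with controlled similarity
#'
#' \code{kind = "mc_excitatory"}: each odor's context targets
#' \code{round(p_FB M)} MCs with changes from the zero-elevated skew normal
#' law; a fraction \code{share} of targets (and their draws) is common to
#' the two contexts, the rest disjoint and independent, so the realized
#' change-vector cosine similarity tracks \code{share}.
#' \code{kind = "gc_inhibitory"}: all MCs are eligible for negative changes
#' from the flipped lognormal law (masked at application time to MCs firing
#' at least 2 spikes/sniff); \code{share} controls the fraction of common
#' draws.  \code{kind = "mixed"}: excitatory changes for the first context,
#' inhibitory for the second.
#'
#' @param readout A \code{\link{readout_spec}}.
#' @param dists A \code{\link{distribution_set}}.
#' \code{kind = "combined"} reproduces the standard in silico experiment:
#' positive feedback to the \code{p_FB} subset (similarity controlled by
#' \code{share}) on top of the GC-mediated negative feedback to all MCs,
#' which is identical for the two contexts because it is shaped by the
#' shared bulbar network rather than by the targeted GC subset.
#'
#' @param kind \code{"combined"}, \code{"mc_excitatory"},
#'   \code{"gc_inhibitory"} or \code{"mixed"}.
#' @param share Shared fraction in \[0, 1\].
#' @param seed Integer seed.
#' @return List of change vectors \code{A}, \code{B} (length M) and
#'   \code{kind}.
#' @export
sample_feedback_pair <- function(readout, dists,
                                 kind = c("combined", "mc_excitatory",
                                          "gc_inhibitory", "mixed"),
                                 share = 1, seed = 1L) {
  kind <- match.arg(kind)
  if (share < 0 || share > 1) stop("share must be in [0, 1]", call. = FALSE)
  set.seed(seed)
  M <- readout$M
  zero <- numeric(M)
  exc_A <- exc_B <- inh_A <- inh_B <- zero
  if (kind %in% c("mc_excitatory", "combined", "mixed")) {
    n_fb <- round(readout$p_FB * M)
    n_sh <- if (kind == "mixed") 0L else round(share * n_fb)
    perm <- sample.int(M)
    shared <- perm[seq_len(n_sh)]
    ownA <- perm[n_sh + seq_len(n_fb - n_sh)]
    shared_draws <- draw_mc_changes(n_sh, dists)
    exc_A[shared] <- shared_draws
    exc_A[ownA] <- draw_mc_changes(n_fb - n_sh, dists)
    if (kind != "mixed") {
      ownB <- perm[n_fb + seq_len(n_fb - n_sh)]
      exc_B[shared] <- shared_draws
      exc_B[ownB] <- draw_mc_changes(n_fb - n_sh, dists)
    }
  }
  if (kind == "combined") {
    ## the GC-mediated background is shaped by the shared bulbar network,
    ## hence identical for the two contexts
    inh_A <- inh_B <- draw_gc_changes(M, dists)
  } else if (kind == "gc_inhibitory") {
    n_sh <- round(share * M)
    shared <- sample.int(M, n_sh)
    common <- draw_gc_changes(n_sh, dists)
    inh_A <- draw_gc_changes(M, dists)
    inh_B <- draw_gc_changes(M, dists)
    inh_A[shared] <- common
    inh_B[shared] <- common
  } else if (kind == "mixed") {
    inh_B <- draw_gc_changes(M, dists)
  }
  list(exc_A = exc_A, exc_B = exc_B, inh_A = inh_A, inh_B = inh_B,
       kind = kind)
}

#' Apply feedback change vectors to an odor rate vector
#'
#' Excitatory changes add directly; inhibitory (GC-mediated) changes apply
#' only to MCs firing at least \code{eligible_min} spikes per sniff (the
#' granule-cell pathway cannot silence an already-silent cell).  Rates are
#' clipped at zero.
#'
#' @param rates MC rate vector.
#' @param exc Excitatory change vector (nonnegative).
#' @param inh Inhibitory change vector (nonpositive).
#' @param eligible_min Eligibility threshold for inhibitory changes
#'   (spikes/sniff).
#' @return Updated rate vector.
#' @export
apply_feedback <- function(rates, exc, inh = NULL, eligible_min = 2) {
  eff <- exc
  if (!is.null(inh)) {
    keep <- rates >= eligible_min
    eff[keep] <- eff[keep] + inh[keep]
  }
  pmax(rates + eff, 0)
}

#' Odor-pair similarity experiment on the reduced mechanistic model
#'
#' For each odor-pair overlap in the grid (times \code{trials} replicates)
#' and each feedback-similarity level, computes cortical representations
#' before and after feedback and records initial similarity, final
#' similarity and the realized feedback similarity.  Per feedback level, a
#' least-squares line of the similarity change on the initial similarity is
#' fitted; a second-level regression relates the per-level slope to the mean
#' realized feedback similarity.
#'
#' @param readout A \code{\link{readout_spec}}.
#' @param dists A \code{\link{distribution_set}}.
#' @param overlap_grid Glomerular overlap fractions for the odor pairs.
#' @param share_grid Feedback shared fractions (one experiment condition
#'   each).
#' @param kind Feedback kind passed to \code{\link{sample_feedback_pair}}.
#' @param trials Odor-pair replicates per overlap value.
#' @param seed Master seed (sampling, calibration, pairs and feedback all
#'   use derived substreams).
#' @return An object of class \code{"similarity_experiment"}: \code{data}
#'   (one row per pair x condition), \code{conditions} (per-level fits:
#'   slope, intercept, r2, mean rho_FB), and \code{second_level} (slope,
#'   intercept, r2 of slope against rho_FB; NA with fewer than 3 levels).
#' @export
run_similarity_experiment <- function(readout, dists,
                                      overlap_grid = seq(0, 1, by = 0.2),
                                      share_grid = seq(0, 1, by = 0.25),
                                      kind = "combined",
                                      trials = 2, seed = 1L) {
  stopifnot(inherits(readout, "readout_spec"))
  if (length(overlap_grid) == 0 || length(share_grid) == 0) {
    stop("overlap and share grids must be nonempty", call. = FALSE)
  }
  sampling <- make_cortical_sampling(readout, derive_seed(seed, "sampling"))
  ## calibration from one representative pre-feedback odor
  cal_pair <- sample_odor_pair(readout, dists, overlap = 0.5,
                               seed = derive_seed(seed, "calibration"))
  calibration <- calibrate_readout(list(cal_pair$A, cal_pair$B), sampling)
  pairs <- expand.grid(overlap = overlap_grid, trial = seq_len(trials),
                       KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(pairs) * length(share_grid))
  k <- 0
  for (p in seq_len(nrow(pairs))) {
    pseed <- derive_seed(seed, sprintf("pair-%d", p))
    odors <- sample_odor_pair(readout, dists, pairs$overlap[p], pseed)
    KA <- cortical_readout(odors$A, sampling, calibration)
    KB <- cortical_readout(odors$B, sampling, calibration)
    rho_i <- cosine_similarity(KA, KB)
    for (s in seq_along(share_grid)) {
      fb <- sample_feedback_pair(readout, dists, kind, share_grid[s],
                                 derive_seed(seed, sprintf("fb-%d-%d", p, s)))
      rA <- apply_feedback(odors$A, fb$exc_A, fb$inh_A)
      rB <- apply_feedback(odors$B, fb$exc_B, fb$inh_B)
      effA <- rA - odors$A
      effB <- rB - odors$B
      rho_FB <- if (sum(effA^2) > 0 && sum(effB^2) > 0) {
        cosine_similarity(effA, effB)
      } else NA_real_
      KpA <- cortical_readout(rA, sampling, calibration)
      KpB <- cortical_readout(rB, sampling, calibration)
      rho_f <- cosine_similarity(KpA, KpB)
      k <- k + 1
      rows[[k]] <- data.frame(pair = p, overlap = pairs$overlap[p],
                              share = share_grid[s], rho_FB = rho_FB,
                              rho_i = rho_i, rho_f = rho_f,
                              delta_rho = rho_f - rho_i)
    }
  }
  data <- do.call(rbind, rows)
  conditions <- do.call(rbind, lapply(split(data, data$share), function(d) {
    if (nrow(d) < 3 || stats::sd(d$rho_i) == 0) {
      return(data.frame(share = d$share[1], rho_FB = mean(d$rho_FB),
                        slope = NA_real_, intercept = NA_real_,
                        r2 = NA_real_, n = nrow(d)))
    }
    fit <- stats::lm(delta_rho ~ rho_i, data = d)
    data.frame(share = d$share[1], rho_FB = mean(d$rho_FB, na.rm = TRUE),
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r2 = summary(fit)$r.squared, n = nrow(d))
  }))
  second <- list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_)
  ok <- stats::complete.cases(conditions[, c("rho_FB", "slope")])
  if (sum(ok) >= 3) {
    fit2 <- stats::lm(slope ~ rho_FB, data = conditions[ok, ])
    second <- list(slope = unname(stats::coef(fit2)[2]),
                   intercept = unname(stats::coef(fit2)[1]),
                   r2 = summary(fit2)$r.squared)
  }
  structure(list(data = data, conditions = conditions,
                 second_level = second, readout = readout, seed = seed,
                 calibration = calibration),
            class = "similarity_experiment")
}

#' @export
print.similarity_experiment <- function(x, ...) {
  cat("Similarity experiment:", nrow(x$data), "pair-condition rows;",
      nrow(x$conditions), "feedback levels\n")
  print(x$conditions, row.names = FALSE, digits = 4)
  if (!is.na(x$second_level$slope)) {
    cat(sprintf("  second-level: slope(delta_rho~rho_i) = %.4f * rho_FB + %.4f (r2 = %.4f)\n",
                x$second_level$slope, x$second_level$intercept,
                x$second_level$r2))
  }
  invisible(x)
}

#' @export
plot.similarity_experiment <- function(x, ...) {
  pal <- grDevices::hcl.colors(nrow(x$conditions), "Zissou 1")
  lev <- sort(unique(x$data$share))
  graphics::plot(x$data$rho_i, x$data$delta_rho,
                 col = pal[match(x$data$share, lev)], pch = 16,
                 xlab = expression(rho[i]), ylab = expression(Delta * rho),
                 ...)
  for (i in seq_along(lev)) {
    d <- x$conditions[x$conditions$share == lev[i], ]
    if (!is.na(d$slope)) graphics::abline(d$intercept, d$slope, col = pal[i])
  }
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
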