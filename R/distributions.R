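## The three firing-rate(-change) laws that summarize the spiking network:
## a generalized Pareto law for odor-evoked MC rates, a zero-elevated skew
## normal law for MC rate changes under direct excitatory feedback, and a
## flipped/shifted lognormal law for the (inhibitory) rate changes induced
## via excitatory feedback to the granule cells.  Rates are in spikes per
## sniff (one sniff = 1/6 s).

#' Generalized Pareto distribution
#'
#' Density, distribution function and random generation, in the (shape k,
#' scale sigma, location theta) parameterization with density
#' \code{(1/sigma) (1 + k (x - theta)/sigma)^(-1 - 1/k)}; for \code{k < 0}
#' the support is \code{[theta, theta - sigma/k]}.
#'
#' @param x Quantiles.
#' @param n Number of draws.
#' @param shape,scale,location Parameters (scale > 0).
#' @param log Return log-density?
#' @return Numeric vector.
#' @name gpd
NULL

#' @rdname gpd
#' @export
dgpd <- function(x, shape, scale, location = 0, log = FALSE) {
  .check_pos(scale, "scale")
  z <- (x - location) / scale
  if (abs(shape) < 1e-12) {
    ld <- ifelse(z >= 0, -z - base::log(scale), -Inf)
  } else {
    arg <- 1 + shape * z
    ld <- ifelse(z >= 0 & arg > 0,
                 (-1 - 1 / shape) * base::log(pmax(arg, 1e-300)) -
                   base::log(scale),
                 -Inf)
  }
  if (log) ld else exp(ld)
}

#' @rdname gpd
#' @export
pgpd <- function(x, shape, scale, location = 0) {
  z <- pmax((x - location) / scale, 0)
  if (abs(shape) < 1e-12) return(1 - exp(-z))
  arg <- pmax(1 + shape * z, 0)
  1 - arg^(-1 / shape)
}

#' @rdname gpd
#' @export
rgpd <- function(n, shape, scale, location = 0) {
  u <- stats::runif(n)
  if (abs(shape) < 1e-12) return(location - scale * base::log(1 - u))
  location + scale / shape * ((1 - u)^(-shape) - 1)
}

#' Skew normal distribution
#'
#' Density and random generation with location \code{xi}, scale
#' \code{omega} and shape \code{alpha}:
#' \code{f(x) = (2/omega) phi(z) Phi(alpha z)} with
#' \code{z = (x - xi)/omega}.
#'
#' @param x Quantiles.
#' @param n Number of draws.
#' @param xi,omega,alpha Location, scale (> 0), shape.
#' @param log Return log-density?
#' @return Numeric vector.
#' @name skewnormal
NULL

#' @rdname skewnormal
#' @export
dsnorm <- function(x, xi = 0, omega = 1, alpha = 0, log = FALSE) {
  .check_pos(omega, "omega")
  z <- (x - xi) / omega
  ld <- base::log(2) - base::log(omega) + stats::dnorm(z, log = TRUE) +
    stats::pnorm(alpha * z, log.p = TRUE)
  if (log) ld else exp(ld)
}

#' @rdname skewnormal
#' @export
rsnorm <- function(n, xi = 0, omega = 1, alpha = 0) {
  delta <- alpha / sqrt(1 + alpha^2)
  z0 <- stats::rnorm(n)
  z1 <- stats::rnorm(n)
  z <- delta * abs(z0) + sqrt(1 - delta^2) * z1
  xi + omega * z
}

#' Bundle of the three fitted firing-rate-change laws
#'
#' @param odor Named list \code{shape}, \code{scale}, \code{location} of the
#'   generalized Pareto odor-rate law (draws below zero are clipped to zero:
#'   rates are nonnegative).
#' @param mc_change Named list \code{p_nz}, \code{xi}, \code{omega},
#'   \code{alpha} of the zero-elevated skew normal law for MC rate changes
#'   under direct excitatory feedback.
#' @param gc_change Named list \code{meanlog}, \code{sdlog}, \code{shift},
#'   \code{scale}, \code{bound} of the flipped/shifted lognormal law for the
#'   inhibitory changes induced through the granule cells: a lognormal draw
#'   \code{y} maps to \code{max(-(y - shift) * scale, bound)} truncated to
#'   \code{[bound, 0]}, applied only to MCs firing at least 2 spikes per
#'   sniff.  The affine map anchors are part of the configuration (they are
#'   not re-estimated when fitting).
#' @return An object of class \code{"distribution_set"}.
#' @export
distribution_set <- function(odor, mc_change, gc_change) {
  stopifnot(odor$scale > 0, mc_change$omega > 0, gc_change$sdlog > 0,
            mc_change$p_nz >= 0, mc_change$p_nz <= 1, gc_change$bound <= 0)
  structure(list(odor = odor, mc_change = mc_change, gc_change = gc_change),
            class = "distribution_set")
}

#' The packaged reference distribution set
#'
#' Parameters of the three laws as extracted from long spiking-network runs:
#' generalized Pareto (k = -0.281, sigma = 3.331, theta = -0.4) for
#' odor-evoked spikes per sniff, zero-elevated skew normal (p_nz = 0.31,
#' alpha = 4.232, omega = 2.687, xi = 0.7785) for MC-feedback changes, and
#' lognormal (meanlog = 0.7957, sdlog = 0.2548) flipped and shifted onto
#' \code{\[-2, 0\]} for GC-mediated changes.  The affine map anchors the
#' lognormal's central 3-sigma log-range onto that interval.
#'
#' @return A \code{\link{distribution_set}}.
#' @export
default_distribution_set <- function() {
  meanlog <- 0.7957
  sdlog <- 0.2548
  qlo <- exp(meanlog - 3 * sdlog)
  qhi <- exp(meanlog + 3 * sdlog)
  distribution_set(
    odor = list(shape = -0.281, scale = 3.331, location = -0.4),
    mc_change = list(p_nz = 0.31, xi = 0.7785, omega = 2.687, alpha = 4.232),
    gc_change = list(meanlog = meanlog, sdlog = sdlog,
                     shift = qlo, scale = 2 / (qhi - qlo), bound = -2))
}

#' @export
print.distribution_set <- function(x, ...) {
  cat("Firing-rate distribution set (spikes/sniff)\n")
  cat(sprintf("  odor rates      : gen. Pareto k = %.4g, sigma = %.4g, theta = %.4g (clipped at 0)\n",
              x$odor$shape, x$odor$scale, x$odor$location))
  cat(sprintf("  MC feedback d-r : zero-elevated skew normal p_nz = %.3g, xi = %.4g, omega = %.4g, alpha = %.4g\n",
              x$mc_change$p_nz, x$mc_change$xi, x$mc_change$omega,
              x$mc_change$alpha))
  cat(sprintf("  GC feedback d-r : lognormal mu = %.4g, sigma = %.4g flipped/shifted to [%.3g, 0]\n",
              x$gc_change$meanlog, x$gc_change$sdlog, x$gc_change$bound))
  invisible(x)
}

#' Draws from the three packaged laws
#'
#' @param n Number of draws.
#' @param dists A \code{\link{distribution_set}}.
#' @return Numeric vector: nonnegative odor rates, mostly-positive MC
#'   changes (zeros with probability \code{1 - p_nz}), or nonpositive GC
#'   changes in \code{[bound, 0]}.
#' @name rate-draws
NULL

#' @rdname rate-draws
#' @export
draw_odor_rates <- function(n, dists = default_distribution_set()) {
  pmax(rgpd(n, dists$odor$shape, dists$odor$scale, dists$odor$location), 0)
}

#' @rdname rate-draws
#' @export
draw_mc_changes <- function(n, dists = default_distribution_set()) {
  p <- dists$mc_change
  nz <- stats::runif(n) < p$p_nz
  out <- numeric(n)
  out[nz] <- rsnorm(sum(nz), p$xi, p$omega, p$alpha)
  out
}

#' @rdname rate-draws
#' @export
draw_gc_changes <- function(n, dists = default_distribution_set()) {
  p <- dists$gc_change
  y <- stats::rlnorm(n, p$meanlog, p$sdlog)
  pmin(pmax(-(y - p$shift) * p$scale, p$bound), 0)
}

## maximum-likelihood fit of the generalized Pareto law; the location is
## anchored at the sample minimum (minus a vanishing offset) and (shape,
## log scale) are profiled numerically
.fit_gpd <- function(x) {
  theta <- min(x) - 1e-9 * max(1, abs(min(x)))
  nll <- function(par) {
    k <- par[1]; sigma <- exp(par[2])
    ll <- dgpd(x, k, sigma, theta, log = TRUE)
    if (any(!is.finite(ll))) return(1e10)
    -sum(ll)
  }
  fit <- stats::optim(c(-0.1, base::log(stats::sd(x))), nll,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  list(shape = fit$par[1], scale = exp(fit$par[2]), location = theta)
}

.fit_skew_normal <- function(x) {
  sk <- mean((x - mean(x))^3) / stats::sd(x)^3
  nll <- function(par) {
    ll <- dsnorm(x, par[1], exp(par[2]), par[3], log = TRUE)
    if (any(!is.finite(ll))) return(1e10)
    -sum(ll)
  }
  fit <- stats::optim(c(mean(x), base::log(stats::sd(x)), 2 * sign(sk)),
                      nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  list(xi = fit$par[1], omega = exp(fit$par[2]), alpha = fit$par[3])
}

#' Fit the three firing-rate laws from spiking-run summaries
#'
#' Maximum-likelihood fits: a generalized Pareto law to odor-evoked spike
#' counts per sniff; a zero-elevated skew normal law to MC rate changes
#' under direct feedback (the zero fraction estimated separately as the
#' empirical nonzero frequency); and a lognormal law to GC-mediated rate
#' changes of eligible MCs (count >= 2), after inverting the recorded affine
#' flip/shift map.
#'
#' @param odor_rates Numeric vector of odor-evoked spikes per sniff.
#' @param mc_feedback_change Numeric vector of rate changes under direct MC
#'   feedback (zeros included).
#' @param gc_feedback_change Numeric vector of rate changes under GC
#'   feedback (nonpositive), already restricted to eligible MCs; may be
#'   \code{NULL} to skip.
#' @param map Affine map anchors (\code{shift}, \code{scale}, \code{bound})
#'   used to invert the GC-change law; defaults to the packaged map.
#' @return A \code{\link{distribution_set}}.
#' @export
fit_rate_distributions <- function(odor_rates, mc_feedback_change,
                                   gc_feedback_change = NULL,
                                   map = default_distribution_set()$gc_change) {
  if (length(odor_rates) < 10) {
    stop("insufficient odor-rate samples for a distribution fit",
         call. = FALSE)
  }
  odor <- .fit_gpd(odor_rates)
  nz <- mc_feedback_change[mc_feedback_change != 0]
  p_nz <- length(nz) / length(mc_feedback_change)
  mc <- if (length(nz) >= 10) {
    c(list(p_nz = p_nz), .fit_skew_normal(nz))
  } else if (p_nz == 0) {
    list(p_nz = 0, xi = 0, omega = 1, alpha = 0)
  } else {
    stop("insufficient nonzero MC-change samples for a skew-normal fit",
         call. = FALSE)
  }
  gc <- list(meanlog = NA_real_, sdlog = NA_real_,
             shift = map$shift, scale = map$scale, bound = map$bound)
  if (!is.null(gc_feedback_change)) {
    y <- map$shift - gc_feedback_change / map$scale
    y <- y[y > 0]
    if (length(y) < 10) {
      stop("insufficient GC-change samples for a lognormal fit",
           call. = FALSE)
    }
    gc$meanlog <- mean(base::log(y))
    gc$sdlog <- stats::sd(base::log(y))
  }
  if (is.na(gc$sdlog) || gc$sdlog <= 0) gc$sdlog <- 1e-6
  distribution_set(odor = odor, mc_change = mc, gc_change = gc)
}
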