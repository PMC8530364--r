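## Exact analytic tier: threshold-gated cortical similarity before and after
## stochastic feedback, the 15-case joint-shift decomposition, and the linear
## law delta_rho = Q2 * rho_i + Q1.

#' Initial cortical similarity of an odor pair
#'
#' Under the uniform-by-region response model with a step cortical transfer,
#' the cortical counts are rescaled module counts,
#' \code{C_mu = (dRc/dRm) N_mu} (squared rescaling for the joint count), so
#' the cosine similarity of the binary cortical vectors is
#' \deqn{\rho_i = Q_0 N_{AB} / \sqrt{N_A N_B}, \qquad Q_0 = dR_c / dR_m.}
#'
#' @param counts An \code{\link{odor_pair_counts}}.
#' @param th A \code{\link{threshold_spec}}.
#' @return The initial similarity, in \code{[0, Q0]}.
#' @export
initial_similarity <- function(counts, th) {
  stopifnot(inherits(counts, "odor_pair_counts"), inherits(th, "threshold_spec"))
  if (counts$N_A == 0 || counts$N_B == 0) {
    stop("similarity undefined: no modules responsive to one of the odors",
         call. = FALSE)
  }
  Q0 <- th$dRc / th$dRm
  Q0 * counts$N_AB / sqrt(counts$N_A * counts$N_B)
}

#' Feedback-driven change in the single-odor cortical count
#'
#' Change in the number of modules above the cortical threshold for one odor.
#' Positive feedback promotes modules within \code{dR} below \code{theta_c};
#' negative feedback demotes modules within \code{dR} above it.  When the
#' feedback exceeds the threshold gap (\code{dR > delta_theta}) an extra term
#' promotes modules from below the response threshold.
#'
#' @param counts An \code{\link{odor_pair_counts}}.
#' @param th A \code{\link{threshold_spec}}.
#' @param fb A \code{\link{feedback_spec}}.
#' @param odor \code{"A"} or \code{"B"}; the B-side uses the derived marginals.
#' @return The (signed) count change \code{delta_C_total}.
#' @export
single_odor_shift <- function(counts, th, fb, odor = c("A", "B")) {
  odor <- match.arg(odor)
  stopifnot(inherits(counts, "odor_pair_counts"),
            inherits(th, "threshold_spec"), inherits(fb, "feedback_spec"))
  p_plus <- if (odor == "A") fb$p_plus_A else fb$p_plus_B
  p_minus <- if (odor == "A") fb$p_minus_A else fb$p_minus_B
  rho_resp <- if (odor == "A") counts$rho_A else counts$rho_B
  rho_unresp <- if (odor == "A") counts$rho_notA else counts$rho_notB
  dR <- fb$dR
  base <- (p_plus * min(dR, th$delta_theta) -
             p_minus * min(dR, th$dRc)) * rho_resp
  gate <- .heaviside(dR - th$delta_theta)
  base + gate * p_plus * min(dR - th$delta_theta, th$theta_m) * rho_unresp
}

#' The fifteen joint-shift contributions to the both-odor cortical count
#'
#' Each contribution is (probability of the required feedback-sign pattern)
#' x (area of the initial-rate region in the joint response plane) x (module
#' density of that region).  Rows 1-8 act on modules already responsive to
#' both odors; rows 9-15 promote modules unresponsive to at least one odor
#' and are gated by \code{H(dR - delta_theta)} (they vanish whenever
#' \code{theta_c >= theta_m + dR}).
#'
#' @inheritParams single_odor_shift
#' @return A list with \code{contributions} (length-15 numeric vector) and
#'   \code{total} (their sum).
#' @export
joint_shift_contributions <- function(counts, th, fb) {
  stopifnot(inherits(counts, "odor_pair_counts"),
            inherits(th, "threshold_spec"), inherits(fb, "feedback_spec"))
  dR <- fb$dR
  a_below <- min(dR, th$delta_theta)      # width reachable below theta_c
  a_above <- min(dR, th$dRc)              # width vulnerable above theta_c
  a_safe <- max(0, th$dRc - dR)           # width out of reach above theta_c
  a_sub <- min(dR - th$delta_theta, th$theta_m)  # sub-threshold reach
  gate <- .heaviside(dR - th$delta_theta)

  pA <- fb$p_plus_A; mA <- fb$p_minus_A
  pB <- fb$p_plus_B; mB <- fb$p_minus_B
  p_same <- fb$p_same; p_flip <- fb$p_flip; p_flip_A <- fb$p_flip_A

  d <- numeric(15)
  ## both responses in (theta_c - dR, theta_c): promoted if both increase
  d[1] <- pA * p_same * a_below^2 * counts$rho_AB
  ## one below / one above theta_c: promoted if the low one rises and the
  ## high one does not fall
  d[2] <- pA * (1 - p_flip) * a_below * a_above * counts$rho_AB
  d[3] <- pB * (1 - p_flip_A) * a_below * a_above * counts$rho_AB
  ## one below theta_c, the other beyond reach of negative feedback
  d[4] <- pA * a_below * a_safe * counts$rho_AB
  d[5] <- pB * a_below * a_safe * counts$rho_AB
  ## both in (theta_c, theta_c + dR): lost if at least one decreases
  d[6] <- -(mA + mB - mA * p_same) * a_above^2 * counts$rho_AB
  ## one vulnerable above theta_c, the other out of reach: lost if the
  ## vulnerable one decreases
  d[7] <- -mA * a_above * a_safe * counts$rho_AB
  d[8] <- -mB * a_above * a_safe * counts$rho_AB
  if (gate > 0) {
    ## sub-response-threshold promotions, only when dR > delta_theta
    d[9] <- pA * p_same * a_sub^2 * counts$rho_notAnotB
    d[10] <- pA * p_same * a_sub * th$delta_theta * counts$rho_notAB
    d[11] <- pA * p_same * a_sub * th$delta_theta * counts$rho_AnotB
    d[12] <- pA * (1 - p_flip) * a_sub * a_above * counts$rho_notAB
    d[13] <- pB * (1 - p_flip_A) * a_sub * a_above * counts$rho_AnotB
    d[14] <- pA * a_sub * a_safe * counts$rho_notAB
    d[15] <- pB * a_sub * a_safe * counts$rho_AnotB
  }
  list(contributions = d, total = sum(d))
}

#' Cortical similarity after feedback and the linear-law coefficients
#'
#' Applies the single-odor and joint count shifts and recomputes the cosine
#' similarity
#' \deqn{\rho_f = (C_{AB} + \delta C_{AB}^{tot}) /
#'       \sqrt{(C_A + \delta C_A^{tot})(C_B + \delta C_B^{tot})}.}
#' A shifted count that collapses to zero or below indicates a degenerate
#' feedback regime and raises an error rather than being clamped.
#'
#' @inheritParams single_odor_shift
#' @return An object of class \code{"similarity_result"}: fields
#'   \code{rho_i}, \code{rho_f}, \code{delta_rho}, the coefficients
#'   \code{Q0}, \code{Q1}, \code{Q2}, \code{Q3}, and the 15 per-case
#'   contributions.
#' @export
#' @examples
#' th <- threshold_spec(0.3, 1.0, 2)
#' fb <- feedback_spec(dR = 0.4, p_plus_A = 1, p_minus_A = 0,
#'                     p_both = 1, p_flip = 0)
#' counts <- odor_pair_counts(2000, 800, 800, 500, th)
#' res <- similarity_after_feedback(counts, th, fb)
#' all.equal(res$delta_rho, res$Q2 * res$rho_i + res$Q1)
similarity_after_feedback <- function(counts, th, fb) {
  stopifnot(inherits(counts, "odor_pair_counts"),
            inherits(th, "threshold_spec"), inherits(fb, "feedback_spec"))
  Q0 <- th$dRc / th$dRm
  C_A <- Q0 * counts$N_A
  C_B <- Q0 * counts$N_B
  C_AB <- Q0^2 * counts$N_AB
  dC_A <- single_odor_shift(counts, th, fb, "A")
  dC_B <- single_odor_shift(counts, th, fb, "B")
  joint <- joint_shift_contributions(counts, th, fb)
  denomA <- C_A + dC_A
  denomB <- C_B + dC_B
  if (denomA <= 0 || denomB <= 0) {
    bad <- paste(c("C_A", "C_B")[c(denomA <= 0, denomB <= 0)], collapse = ", ")
    stop(sprintf("degenerate feedback regime: shifted count(s) %s collapsed to <= 0",
                 bad), call. = FALSE)
  }
  rho_i <- initial_similarity(counts, th)
  rho_f <- (C_AB + joint$total) / sqrt(denomA * denomB)
  qq <- linear_coefficients(th, fb, N = counts$N,
                            N_A = counts$N_A, N_B = counts$N_B)
  structure(
    list(rho_i = rho_i, rho_f = rho_f, delta_rho = rho_f - rho_i,
         Q0 = Q0, Q1 = qq[["Q1"]], Q2 = qq[["Q2"]], Q3 = qq[["Q3"]],
         contributions = joint$contributions,
         delta_C_A = dC_A, delta_C_B = dC_B, delta_C_AB = joint$total),
    class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat("Similarity change under feedback\n")
  cat(sprintf("  rho_i = %.6g   rho_f = %.6g   delta_rho = %.6g\n",
              x$rho_i, x$rho_f, x$delta_rho))
  cat(sprintf("  linear law: delta_rho = Q2 rho_i + Q1 with Q2 = %.6g, Q1 = %.6g\n",
              x$Q2, x$Q1))
  invisible(x)
}

#' Coefficients of the linear similarity-change law
#'
#' The post-feedback similarity is affine in \code{N_AB} (the numerator of
#' \code{rho_f} is affine in \code{N_AB}; the denominator does not involve
#' it), so \code{Q1} and \code{Q3} are extracted exactly by evaluating
#' \code{rho_f} at \code{N_AB = 0} and at one interior probe, and
#' \code{Q2 = Q3/Q0 - 1}.  This is immune to any algebraic rearrangement of
#' the 15-case table.
#'
#' @param th A \code{\link{threshold_spec}}.
#' @param fb A \code{\link{feedback_spec}}.
#' @param N,N_A,N_B Marginal module counts (the joint count \code{N_AB} drops
#'   out of the coefficients).
#' @return Named numeric vector with \code{Q0}, \code{Q1}, \code{Q2},
#'   \code{Q3}.
#' @export
#' @examples
#' th <- threshold_spec(0.3, 0.8, 2)
#' fb <- feedback_spec(0.4, 0.125, 0.375, 0.5, 0)
#' linear_coefficients(th, fb, N = 1000, N_A = 600, N_B = 600)["Q1"]  # 0
linear_coefficients <- function(th, fb, N, N_A, N_B) {
  stopifnot(inherits(th, "threshold_spec"), inherits(fb, "feedback_spec"))
  Q0 <- th$dRc / th$dRm
  probe <- function(N_AB) {
    ## unvalidated constructor: a probe may sit on (or just past) the
    ## feasibility boundary; rho_f is affine in N_AB so the extraction is
    ## exact regardless
    counts <- structure(
      list(N = N, N_A = N_A, N_B = N_B, N_AB = N_AB,
           rho_A = N_A / th$dRm, rho_B = N_B / th$dRm,
           rho_notA = (N - N_A) / th$theta_m,
           rho_notB = (N - N_B) / th$theta_m,
           rho_AB = N_AB / th$dRm^2,
           rho_AnotB = (N_A - N_AB) / (th$dRm * th$theta_m),
           rho_notAB = (N_B - N_AB) / (th$dRm * th$theta_m),
           rho_notAnotB = (N - N_A - N_B + N_AB) / th$theta_m^2,
           th = th),
      class = "odor_pair_counts")
    C_AB <- Q0^2 * N_AB
    dC_A <- single_odor_shift(counts, th, fb, "A")
    dC_B <- single_odor_shift(counts, th, fb, "B")
    joint <- joint_shift_contributions(counts, th, fb)
    denomA <- Q0 * N_A + dC_A
    denomB <- Q0 * N_B + dC_B
    if (denomA <= 0 || denomB <= 0) {
      stop("degenerate feedback regime: a shifted single-odor count collapsed",
           call. = FALSE)
    }
    (C_AB + joint$total) / sqrt(denomA * denomB)
  }
  ## probes: N_AB = 0 and one interior value (any admissible value works;
  ## max(N_A + N_B - N, 0) is the smallest feasible joint count)
  lo <- max(N_A + N_B - N, 0)
  hi <- min(N_A, N_B)
  x1 <- lo
  x2 <- if (hi > lo) hi else lo + 1  # counts are treated as densities
  rho1 <- probe(x1)
  rho2 <- probe(x2)
  Q3 <- (rho2 - rho1) * sqrt(N_A * N_B) / (x2 - x1)
  Q1 <- rho1 - Q3 * x1 / sqrt(N_A * N_B)
  c(Q0 = Q0, Q1 = Q1, Q2 = Q3 / Q0 - 1, Q3 = Q3)
}

#' Closed-form slope for the two pure feedback scenarios
#'
#' In the high-threshold regime (\code{dR <= min(delta_theta, dRc)}) the full
#' machinery reduces to closed forms: identical full positive feedback for
#' both odors is equivalent to lowering the cortical threshold by \code{dR},
#' giving slope \code{dR / (R_max - theta_c)}; full positive feedback for one
#' odor and full negative for the other gives slope
#' \code{sqrt((R_max - theta_c)^2 - dR^2) / (R_max - theta_c) - 1}.
#'
#' @param kind \code{"identical"} or \code{"opposite"}.
#' @param th A \code{\link{threshold_spec}}.
#' @param dR Feedback magnitude; must satisfy
#'   \code{dR <= min(delta_theta, dRc)}.
#' @return The slope \code{Q2} of \code{delta_rho} versus \code{rho_i}.
#' @export
#' @examples
#' th <- threshold_spec(0.3, 1.0, 2)
#' special_case_slope("identical", th, 0.4)  # 0.4
#' special_case_slope("opposite", th, 0.4)   # ~ -0.0835
special_case_slope <- function(kind = c("identical", "opposite"), th, dR) {
  kind <- match.arg(kind)
  stopifnot(inherits(th, "threshold_spec"))
  .check_pos(dR, "dR", strict = FALSE)
  if (dR > min(th$delta_theta, th$dRc) + 1e-12) {
    stop("closed-form slopes require the high-threshold regime dR <= min(delta_theta, dRc)",
         call. = FALSE)
  }
  if (kind == "identical") {
    dR / th$dRc
  } else {
    sqrt(th$dRc^2 - dR^2) / th$dRc - 1
  }
}

#' Phase diagram of the linear-law coefficients
#'
#' Sweeps the cortical threshold and the sign-flip probability (holding the
#' feedback coverage, inhibitory fraction and target overlap fixed) and
#' classifies each grid point: \emph{convergence} (\code{Q2 > 0, Q1 = 0}),
#' \emph{divergence} (\code{Q2 < 0, Q1 = 0}) or \emph{mixed}
#' (\code{Q1 > 0}).  \code{Q1 = 0} is decided at tolerance \code{1e-9}.  The
#' flip probability parameterizes the y-axis; the feedback similarity
#' \code{rho_FB = p_both - 2 p_flip} is reported alongside.
#'
#' @param theta_c_grid Numeric vector of cortical thresholds (all in
#'   \code{(theta_m, R_max)}).
#' @param p_flip_grid Numeric vector of flip probabilities (all in
#'   \code{[0, p_both]}).
#' @param th_base A \code{\link{threshold_spec}} supplying \code{theta_m} and
#'   \code{R_max} (its \code{theta_c} is replaced along the grid).
#' @param dR Feedback magnitude.
#' @param coverage Total feedback coverage \code{p_plus_A + p_minus_A}.
#' @param inhibitory_fraction Fraction of affected modules receiving negative
#'   feedback for odor A.
#' @param p_both Target-overlap probability.
#' @param p_odor Probability that a module responds to an odor (sets
#'   \code{N_A = N_B = p_odor * N}).
#' @param N Total module count used for the (count-independent) coefficients.
#' @return A data frame of class \code{"phase_diagram"} with columns
#'   \code{theta_c}, \code{p_flip}, \code{rho_FB}, \code{Q1}, \code{Q2},
#'   \code{regime}, plus attributes \code{theta_c_transition}
#'   (\code{theta_m + dR}) and \code{theta_c_active} (thresholds activating
#'   15\%, 10\% and 3\% of cortical units).
#' @export
phase_diagram <- function(theta_c_grid, p_flip_grid, th_base, dR,
                          coverage = 0.5, inhibitory_fraction = 0.75,
                          p_both = 0.5, p_odor = 0.6, N = 1e4) {
  stopifnot(inherits(th_base, "threshold_spec"))
  p_minus_A <- coverage * inhibitory_fraction
  p_plus_A <- coverage - p_minus_A
  grid <- expand.grid(theta_c = theta_c_grid, p_flip = p_flip_grid,
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  Q1 <- Q2 <- rho_FB <- numeric(n)
  for (i in seq_len(n)) {
    th <- threshold_spec(th_base$theta_m, grid$theta_c[i], th_base$R_max)
    fb <- feedback_spec(dR, p_plus_A, p_minus_A, p_both, grid$p_flip[i])
    qq <- linear_coefficients(th, fb, N = N,
                              N_A = p_odor * N, N_B = p_odor * N)
    Q1[i] <- qq[["Q1"]]
    Q2[i] <- qq[["Q2"]]
    rho_FB[i] <- fb$rho_FB
  }
  regime <- ifelse(Q1 > 1e-9, "mixed",
                   ifelse(Q2 > 0, "convergence", "divergence"))
  out <- data.frame(theta_c = grid$theta_c, p_flip = grid$p_flip,
                    rho_FB = rho_FB, Q1 = Q1, Q2 = Q2, regime = regime,
                    stringsAsFactors = FALSE)
  ## thresholds at which a given fraction of cortical units is active:
  ## active fraction = p_odor * (R_max - theta_c)/(R_max - theta_m)
  frac <- c(0.15, 0.10, 0.03)
  attr(out, "theta_c_active") <- stats::setNames(
    th_base$R_max - frac / p_odor * th_base$dRm, paste0(frac * 100, "%"))
  attr(out, "theta_c_transition") <- th_base$theta_m + dR
  class(out) <- c("phase_diagram", "data.frame")
  out
}

#' @export
plot.phase_diagram <- function(x, ...) {
  tc <- sort(unique(x$theta_c))
  pf <- sort(unique(x$p_flip))
  z <- matrix(NA_real_, length(tc), length(pf))
  code <- ifelse(x$regime == "mixed", 0, ifelse(x$regime == "convergence", 1, -1))
  z[cbind(match(x$theta_c, tc), match(x$p_flip, pf))] <- code
  graphics::image(tc, pf, z, col = c("darkgreen", "steelblue", "firebrick"),
                  breaks = c(-1.5, -0.5, 0.5, 1.5),
                  xlab = expression(theta[c]), ylab = expression(p[flip]), ...)
  graphics::abline(v = attr(x, "theta_c_transition"), lty = 2)
  graphics::abline(v = attr(x, "theta_c_active"), lty = 3, col = "grey40")
  invisible(x)
}
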