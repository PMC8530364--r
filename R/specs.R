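#' Threshold specification for the statistical model
#'
#' Bundles the two activation thresholds and the response ceiling of the
#' two-layer statistical model.  A bulb "module" (the set of mitral cells
#' projecting to one cortical unit) is odor-responsive when its rate exceeds
#' the response threshold \code{theta_m}, and drives its cortical unit when
#' the rate exceeds the (higher) cortical activation threshold \code{theta_c}.
#'
#' @param theta_m Module response threshold (rate units).
#' @param theta_c Cortical activation threshold (rate units); must exceed
#'   \code{theta_m}.
#' @param R_max Maximum module response (rate units); must exceed
#'   \code{theta_c}.
#' @return An object of class \code{"threshold_spec"} with the inputs plus the
#'   derived ranges \code{delta_theta = theta_c - theta_m},
#'   \code{dRc = R_max - theta_c} and \code{dRm = R_max - theta_m}.
#' @export
#' @examples
#' threshold_spec(theta_m = 0.3, theta_c = 0.8, R_max = 2)
threshold_spec <- function(theta_m, theta_c, R_max) {
  .check_pos(theta_m, "theta_m")
  .check_pos(theta_c, "theta_c")
  .check_pos(R_max, "R_max")
  if (!(theta_m < theta_c && theta_c < R_max)) {
    stop("threshold_spec requires 0 < theta_m < theta_c < R_max", call. = FALSE)
  }
  structure(
    list(theta_m = theta_m, theta_c = theta_c, R_max = R_max,
         delta_theta = theta_c - theta_m,
         dRc = R_max - theta_c,
         dRm = R_max - theta_m),
    class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat("Threshold spec: theta_m =", x$theta_m, " theta_c =", x$theta_c,
      " R_max =", x$R_max, "\n")
  cat("  delta_theta =", x$delta_theta, " dRc =", x$dRc, " dRm =", x$dRm, "\n")
  invisible(x)
}

#' Feedback specification for an odor pair
#'
#' Describes the stochastic feedback associated with two odor contexts.  Each
#' module's rate is shifted by \code{+dR} or \code{-dR} (or unchanged) for each
#' odor; the joint structure across the two odors is controlled by
#' \code{p_both} (probability a module affected for odor A is also affected for
#' odor B) and \code{p_flip} (probability the B shift opposes the A shift).
#' The derived B-side marginals, the reverse-flip probability and the feedback
#' similarity \code{rho_FB = p_both - 2 p_flip} are filled in so that the
#' feedback-coverage equality \code{p_plus_B + p_minus_B = p_plus_A +
#' p_minus_A} holds exactly.
#'
#' @param dR Feedback magnitude (rate units, shared by all affected modules).
#' @param p_plus_A,p_minus_A Probabilities that a module's rate is increased /
#'   decreased by the feedback for odor A.
#' @param p_both Conditional probability that a module affected for A is also
#'   affected for B.
#' @param p_flip Conditional probability that the B feedback opposes the sign
#'   of the A feedback; must not exceed \code{p_both}.
#' @return An object of class \code{"feedback_spec"} with derived fields
#'   \code{p_same}, \code{p_plus_B}, \code{p_minus_B}, \code{p_flip_A} and
#'   \code{rho_FB}.
#' @export
#' @examples
#' fb <- feedback_spec(dR = 0.4, p_plus_A = 0.125, p_minus_A = 0.375,
#'                     p_both = 0.5, p_flip = 0)
#' fb$rho_FB   # p_both - 2 p_flip = 0.5
feedback_spec <- function(dR, p_plus_A, p_minus_A, p_both, p_flip) {
  .check_pos(dR, "dR", strict = FALSE)
  .check_prob(p_plus_A, "p_plus_A")
  .check_prob(p_minus_A, "p_minus_A")
  .check_prob(p_both, "p_both")
  .check_prob(p_flip, "p_flip")
  if (p_flip > p_both) {
    stop("invalid probability combination: p_flip > p_both", call. = FALSE)
  }
  if (p_plus_A + p_minus_A > 1 + 1e-12) {
    stop("invalid probability combination: p_plus_A + p_minus_A > 1",
         call. = FALSE)
  }
  spec <- structure(
    list(dR = dR, p_plus_A = p_plus_A, p_minus_A = p_minus_A,
         p_both = p_both, p_flip = p_flip),
    class = "feedback_spec")
  derive_feedback_probabilities(spec)
}

#' Fill in the derived probabilities of a feedback specification
#'
#' Computes \code{p_same = p_both - p_flip}, the B-side sign marginals
#' \deqn{p_{\pm B} = (p_{same} p_{\pm A} + p_{flip} p_{\mp A}) / p_{both},}
#' the reverse conditional \code{p_flip_A = p_flip * p_minus_A / p_plus_B}
#' (Bayes' rule; 0 when \code{p_plus_B = 0}), and the feedback similarity
#' \code{rho_FB = p_both - 2 p_flip}.  With these definitions the coverage
#' equality \code{p_plus_B + p_minus_B = p_plus_A + p_minus_A} is exact.
#'
#' @param spec A \code{"feedback_spec"} (possibly without derived fields).
#' @return The spec with derived fields filled.
#' @export
derive_feedback_probabilities <- function(spec) {
  stopifnot(inherits(spec, "feedback_spec"))
  p_same <- spec$p_both - spec$p_flip
  coverage <- spec$p_plus_A + spec$p_minus_A
  if (spec$p_both == 0) {
    ## no module is shared between the two feedbacks; the B marginals keep
    ## the coverage but the sign split is taken equal to A's
    p_plus_B <- spec$p_plus_A
    p_minus_B <- spec$p_minus_A
  } else {
    p_plus_B <- (p_same * spec$p_plus_A + spec$p_flip * spec$p_minus_A) /
      spec$p_both
    p_minus_B <- (p_same * spec$p_minus_A + spec$p_flip * spec$p_plus_A) /
      spec$p_both
  }
  p_flip_A <- if (p_plus_B > 0) spec$p_flip * spec$p_minus_A / p_plus_B else 0
  spec$p_same <- p_same
  spec$p_plus_B <- p_plus_B
  spec$p_minus_B <- p_minus_B
  spec$p_flip_A <- p_flip_A
  spec$rho_FB <- spec$p_both - 2 * spec$p_flip
  ## joint sampling of the two feedback signs also needs the conditional law
  ## of B's feedback given A unaffected; its total mass must be a probability
  if (coverage < 1) {
    q_aff <- coverage * (1 - spec$p_both) / (1 - coverage)
    if (q_aff > 1 + 1e-12) {
      stop(paste0("invalid probability combination: coverage ",
                  signif(coverage, 4), " with p_both ", signif(spec$p_both, 4),
                  " requires P(B affected | A unaffected) = ",
                  signif(q_aff, 4), " > 1"), call. = FALSE)
    }
  }
  spec
}

#' @export
print.feedback_spec <- function(x, ...) {
  cat("Feedback spec: dR =", x$dR, "\n")
  cat("  A marginals: p+ =", x$p_plus_A, " p- =", x$p_minus_A, "\n")
  cat("  joint: p_both =", x$p_both, " p_flip =", x$p_flip,
      " p_same =", x$p_same, "\n")
  cat("  derived B marginals: p+ =", signif(x$p_plus_B, 5),
      " p- =", signif(x$p_minus_B, 5),
      "  p_flip_A =", signif(x$p_flip_A, 5), "\n")
  cat("  feedback similarity rho_FB =", x$rho_FB, "\n")
  invisible(x)
}

#' Module counts for an odor pair
#'
#' Counts of bulb modules responsive (rate above \code{theta_m}) to each of
#' two odors, together with the region densities of the uniform-by-region
#' response model: responses are jointly uniform within each of the four
#' regions of the (A, B) response square cut at \code{theta_m}.
#'
#' @param N Total number of modules.
#' @param N_A,N_B Numbers of modules responsive to odor A / odor B.
#' @param N_AB Number of modules responsive to both odors.
#' @param th A \code{\link{threshold_spec}} used to compute region densities.
#' @return An object of class \code{"odor_pair_counts"} with densities
#'   \code{rho_A}, \code{rho_B} (per unit rate), \code{rho_AB},
#'   \code{rho_AnotB}, \code{rho_notAB}, \code{rho_notAnotB} (per unit area in
#'   response space).
#' @export
#' @examples
#' th <- threshold_spec(0.3, 0.8, 2)
#' odor_pair_counts(N = 1000, N_A = 600, N_B = 600, N_AB = 400, th = th)
odor_pair_counts <- function(N, N_A, N_B, N_AB, th) {
  stopifnot(inherits(th, "threshold_spec"))
  for (v in c("N", "N_A", "N_B", "N_AB")) {
    .check_pos(get(v), v, strict = FALSE)
  }
  if (N_AB > min(N_A, N_B) + 1e-9) {
    stop("N_AB cannot exceed min(N_A, N_B)", call. = FALSE)
  }
  if (N_A + N_B - N_AB > N + 1e-9) {
    stop("N_A + N_B - N_AB cannot exceed N", call. = FALSE)
  }
  structure(
    list(N = N, N_A = N_A, N_B = N_B, N_AB = N_AB,
         rho_A = N_A / th$dRm,
         rho_B = N_B / th$dRm,
         rho_notA = (N - N_A) / th$theta_m,
         rho_notB = (N - N_B) / th$theta_m,
         rho_AB = N_AB / th$dRm^2,
         rho_AnotB = (N_A - N_AB) / (th$dRm * th$theta_m),
         rho_notAB = (N_B - N_AB) / (th$dRm * th$theta_m),
         rho_notAnotB = (N - N_A - N_B + N_AB) / th$theta_m^2,
         th = th),
    class = "odor_pair_counts")
}

#' @export
print.odor_pair_counts <- function(x, ...) {
  cat("Odor pair counts: N =", x$N, " N_A =", x$N_A, " N_B =", x$N_B,
      " N_AB =", x$N_AB, "\n")
  invisible(x)
}
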