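## Finite-population Monte-Carlo tier: brute-force realization of the
## statistical model's assumptions, used as the oracle for the analytic
## machinery and for its generalization to Gaussian responses and sigmoid
## transfer.

#' Population specification for the Monte-Carlo simulator
#'
#' @param N Number of modules.
#' @param response \code{"uniform"} (joint uniform within the four
#'   response-threshold regions, with exact region counts) or
#'   \code{"gaussian"} (responsive modules draw normal rates, unresponsive
#'   modules are silent; the same region counts control the odor-pair
#'   overlap).
#' @param mu1,sigma1_sq Mean and variance of the Gaussian odor-response law.
#'   The source notation for the reference values is ambiguous between
#'   variances and standard deviations; the package default reads 0.42 and
#'   0.28 as standard deviations, which reproduces both the stated feedback
#'   similarity (0.8 for identical-sign feedback) and the stated cortical
#'   activation level at threshold 1.6.
#' @param feedback_magnitude \code{"fixed"} (all affected modules shift by
#'   exactly \code{dR}) or \code{"gaussian"} (each affected module/odor draws
#'   its own magnitude).
#' @param mu2,sigma2_sq Mean and variance of the Gaussian feedback-magnitude
#'   law.  Draws are not clipped; a negative magnitude draw flips the
#'   assigned sign, which is what keeps \code{|rho_FB| < 1} for Gaussian
#'   feedback.
#' @param transfer Cortical transfer: \code{"step"} (binary gate at
#'   \code{theta_c}), \code{"sigmoid"}, or \code{"identity"} (single-layer
#'   control with no cortical nonlinearity).
#' @param theta_c Cortical threshold / sigmoid inflection point.
#' @param steepness Sigmoid scale; default makes the 10--90\% rise span 10\%
#'   of \code{R_max}.
#' @param R_max Response ceiling used only to set the default steepness.
#' @return An object of class \code{"population_spec"}.
#' @export
population_spec <- function(N,
                            response = c("uniform", "gaussian"),
                            mu1 = 1.15, sigma1_sq = 0.42^2,
                            feedback_magnitude = c("fixed", "gaussian"),
                            mu2 = 0.57, sigma2_sq = 0.28^2,
                            transfer = c("step", "sigmoid", "identity"),
                            theta_c = NULL, steepness = NULL, R_max = 2) {
  response <- match.arg(response)
  feedback_magnitude <- match.arg(feedback_magnitude)
  transfer <- match.arg(transfer)
  .check_pos(N, "N")
  .check_pos(sigma1_sq, "sigma1_sq")
  .check_pos(sigma2_sq, "sigma2_sq")
  if (transfer != "identity" && is.null(theta_c)) {
    stop("theta_c must be supplied for step or sigmoid transfer", call. = FALSE)
  }
  if (transfer == "sigmoid" && is.null(steepness)) {
    steepness <- 0.1 * R_max / (2 * log(9))
  }
  structure(
    list(N = as.integer(N), response = response,
         mu1 = mu1, sigma1_sq = sigma1_sq,
         feedback_magnitude = feedback_magnitude,
         mu2 = mu2, sigma2_sq = sigma2_sq,
         transfer = transfer, theta_c = theta_c, steepness = steepness,
         R_max = R_max),
    class = "population_spec")
}

## joint feedback-sign assignment for one module population.
## Returns an N x 2 matrix of signs in {-1, 0, +1} realizing the marginal and
## conditional probabilities of the feedback spec.
.sample_feedback_signs <- function(N, fb) {
  coverage <- fb$p_plus_A + fb$p_minus_A
  u <- stats::runif(N)
  sA <- integer(N)
  sA[u < fb$p_plus_A] <- 1L
  sA[u >= fb$p_plus_A & u < coverage] <- -1L
  sB <- integer(N)
  aff <- sA != 0L
  if (any(aff)) {
    v <- stats::runif(sum(aff))
    same <- v < fb$p_same
    flip <- v >= fb$p_same & v < fb$p_both
    sB[aff][same] <- sA[aff][same]
    sB[aff][flip] <- -sA[aff][flip]
  }
  if (any(!aff) && coverage < 1) {
    qp <- fb$p_plus_B * (1 - fb$p_both) / (1 - coverage)
    qm <- fb$p_minus_B * (1 - fb$p_both) / (1 - coverage)
    w <- stats::runif(sum(!aff))
    sB[!aff][w < qp] <- 1L
    sB[!aff][w >= qp & w < qp + qm] <- -1L
  }
  cbind(A = sA, B = sB)
}

.case_labels <- function(signs) {
  sA <- signs[, 1]; sB <- signs[, 2]
  lab <- rep("none", nrow(signs))
  lab[sA != 0 & sB == 0] <- ifelse(sA[sA != 0 & sB == 0] > 0,
                                   "A-only+", "A-only-")
  lab[sA == 0 & sB != 0] <- ifelse(sB[sA == 0 & sB != 0] > 0,
                                   "B-only+", "B-only-")
  both <- sA != 0 & sB != 0
  lab[both] <- ifelse(sA[both] == sB[both], "both-same", "both-flip")
  lab
}

#' Draw a module population with feedback assignments
#'
#' The four odor-responsiveness regions receive exactly \code{N_AB},
#' \code{N_A - N_AB}, \code{N_B - N_AB} and the remaining modules.  Under
#' the uniform model each response is drawn uniform within its region's rate
#' range; under the Gaussian model responsive modules draw
#' Normal(\code{mu1}, \code{sigma1_sq}) rates and unresponsive modules are
#' silent.  Feedback signs follow the joint law of the feedback spec;
#' magnitudes are fixed at \code{fb$dR} or drawn from the Gaussian magnitude
#' law per module and odor.
#'
#' @param pop A \code{\link{population_spec}}.
#' @param fb A \code{\link{feedback_spec}}.
#' @param counts An \code{\link{odor_pair_counts}}.
#' @param seed Integer seed; the draw is bit-reproducible given the seed.
#' @return An object of class \code{"population_draw"}: \code{responses} and
#'   \code{dR_change} (both \code{N x 2}), feedback \code{signs} and
#'   per-module \code{case} labels.
#' @export
sample_population <- function(pop, fb, counts, seed = 1L) {
  stopifnot(inherits(pop, "population_spec"), inherits(fb, "feedback_spec"),
            inherits(counts, "odor_pair_counts"))
  set.seed(seed)
  N <- pop$N
  n_ab <- round(counts$N_AB)
  n_a <- round(counts$N_A) - n_ab
  n_b <- round(counts$N_B) - n_ab
  n_0 <- N - n_ab - n_a - n_b
  if (min(n_ab, n_a, n_b, n_0) < 0) {
    stop("infeasible region counts for the requested population size",
         call. = FALSE)
  }
  region <- rep(c("AB", "A", "B", "0"), times = c(n_ab, n_a, n_b, n_0))
  inA <- region %in% c("AB", "A")
  inB <- region %in% c("AB", "B")
  if (pop$response == "uniform") {
    th <- counts$th
    respA <- ifelse(inA, stats::runif(N, th$theta_m, th$R_max),
                    stats::runif(N, 0, th$theta_m))
    respB <- ifelse(inB, stats::runif(N, th$theta_m, th$R_max),
                    stats::runif(N, 0, th$theta_m))
  } else {
    sd1 <- sqrt(pop$sigma1_sq)
    respA <- ifelse(inA, stats::rnorm(N, pop$mu1, sd1), 0)
    respB <- ifelse(inB, stats::rnorm(N, pop$mu1, sd1), 0)
  }
  signs <- .sample_feedback_signs(N, fb)
  mag <- if (pop$feedback_magnitude == "fixed") {
    matrix(fb$dR, N, 2)
  } else {
    matrix(stats::rnorm(2 * N, pop$mu2, sqrt(pop$sigma2_sq)), N, 2)
  }
  structure(
    list(responses = cbind(A = respA, B = respB),
         dR_change = signs * mag,
         signs = signs,
         case = .case_labels(signs),
         region = region,
         pop = pop, fb = fb, seed = seed),
    class = "population_draw")
}

#' @export
print.population_draw <- function(x, ...) {
  cat("Population draw:", nrow(x$responses), "modules (",
      x$pop$response, "responses,", x$pop$transfer, "transfer )\n")
  print(table(x$case))
  invisible(x)
}

.apply_transfer <- function(R, pop) {
  switch(pop$transfer,
         step = as.numeric(R >= pop$theta_c),
         sigmoid = 1 / (1 + exp(-(R - pop$theta_c) / pop$steepness)),
         identity = R)
}

#' Empirical cortical similarity of a population draw
#'
#' Passes the response vectors through the configured cortical transfer,
#' before and after adding the feedback-induced rate changes, and returns the
#' cosine similarities.  With the step transfer this equals the counting
#' formula \code{C_AB / sqrt(C_A C_B)} on the same draw.
#'
#' @param draw A \code{\link{sample_population}} result.
#' @return Named numeric vector \code{rho_i}, \code{rho_f}, \code{delta_rho}.
#' @export
empirical_similarity <- function(draw) {
  stopifnot(inherits(draw, "population_draw"))
  pop <- draw$pop
  K_A <- .apply_transfer(draw$responses[, 1], pop)
  K_B <- .apply_transfer(draw$responses[, 2], pop)
  Kp_A <- .apply_transfer(draw$responses[, 1] + draw$dR_change[, 1], pop)
  Kp_B <- .apply_transfer(draw$responses[, 2] + draw$dR_change[, 2], pop)
  rho_i <- cosine_similarity(K_A, K_B)
  rho_f <- cosine_similarity(Kp_A, Kp_B)
  c(rho_i = rho_i, rho_f = rho_f, delta_rho = rho_f - rho_i)
}

#' Similarity-change regression experiment on the population simulator
#'
#' Sweeps the initial odor similarity (joint counts for the uniform model,
#' response correlations for the Gaussian model), draws \code{trials}
#' populations per grid point, bins the realized initial similarities into
#' quantile bins and reports per-bin means with normal-theory confidence
#' intervals plus the least-squares line of \code{delta_rho} on \code{rho_i}.
#'
#' @param pop A \code{\link{population_spec}}.
#' @param fb A \code{\link{feedback_spec}}.
#' @param similarity_grid A list of \code{\link{odor_pair_counts}} spanning
#'   the initial-similarity range (typically a sweep of \code{N_AB}).
#' @param trials Draws per grid point.
#' @param seed Master seed; each draw uses a derived sub-seed.
#' @param bins Number of quantile bins for the summary table.
#' @return A list of class \code{"regression_experiment"}: \code{data} (one
#'   row per draw), \code{bins} (per-bin summary), \code{fit} (the
#'   \code{lm}), \code{slope}, \code{intercept}.
#' @export
run_regression_experiment <- function(pop, fb, similarity_grid, trials = 10,
                                      seed = 1L, bins = 10) {
  stopifnot(inherits(pop, "population_spec"), inherits(fb, "feedback_spec"))
  if (length(similarity_grid) == 0) stop("similarity grid is empty")
  rows <- vector("list", length(similarity_grid) * trials)
  k <- 0
  for (g in seq_along(similarity_grid)) {
    for (t in seq_len(trials)) {
      k <- k + 1
      sub <- derive_seed(seed, sprintf("popdraw-%d-%d", g, t))
      draw <- sample_population(pop, fb, counts = similarity_grid[[g]],
                                seed = sub)
      sim <- empirical_similarity(draw)
      rows[[k]] <- data.frame(grid = g, trial = t,
                              rho_i = sim[["rho_i"]],
                              delta_rho = sim[["delta_rho"]])
    }
  }
  data <- do.call(rbind, rows)
  fit <- stats::lm(delta_rho ~ rho_i, data = data)
  ## quantile bins of rho_i, echoing the few-pairs-per-bin averaging of the
  ## numerical generalization
  nb <- max(1, min(bins, floor(nrow(data) / 2)))
  edges <- unique(stats::quantile(data$rho_i, probs = seq(0, 1, length.out = nb + 1)))
  if (length(edges) > 2) {
    bin_id <- cut(data$rho_i, edges, include.lowest = TRUE)
  } else {
    bin_id <- factor(rep(1, nrow(data)))
  }
  bin_tab <- do.call(rbind, lapply(split(data, bin_id), function(d) {
    if (nrow(d) == 0) return(NULL)
    se <- stats::sd(d$delta_rho) / sqrt(nrow(d))
    data.frame(rho_i = mean(d$rho_i), delta_rho = mean(d$delta_rho),
               n = nrow(d),
               ci_lo = mean(d$delta_rho) - 1.96 * se,
               ci_hi = mean(d$delta_rho) + 1.96 * se)
  }))
  structure(
    list(data = data, bins = bin_tab, fit = fit,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1])),
    class = "regression_experiment")
}

#' @export
print.regression_experiment <- function(x, ...) {
  cat("Similarity-change regression:", nrow(x$data), "draws\n")
  cat(sprintf("  delta_rho = %.5g * rho_i + %.5g\n", x$slope, x$intercept))
  invisible(x)
}

#' @export
plot.regression_experiment <- function(x, ...) {
  graphics::plot(x$data$rho_i, x$data$delta_rho, pch = 16,
                 col = grDevices::adjustcolor("grey30", 0.4),
                 xlab = expression(rho[i]), ylab = expression(Delta * rho), ...)
  graphics::abline(x$fit, col = "firebrick", lwd = 2)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
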