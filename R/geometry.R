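## Geometric generation of mitral cell - granule cell dendrodendritic
## connectivity.  MC lateral dendritic trees are laminar discs with a radial
## length-density profile rho_m(r) (um of dendrite per um^2); GC dendritic
## trees are inverted cones carrying a height-dependent spine count profile
## N_s(z) (spines per um of height).  The expected synapse count for a pair
## is lambda = rho_g(z) * q * pi * l where l is the dendritic length inside
## the disc-cone overlap, and the connection probability is 1 - exp(-lambda).

#' Layout specification for the bulb geometry
#'
#' All lengths are in micrometers; the z axis increases from the deep granule
#' cell layer toward the glomerular surface.
#'
#' The radial dendrite profile and the spine profile are not constrained in
#' shape by the available anatomy beyond their totals, so both are simple
#' parametric placeholders calibrated by totals and swappable via this spec:
#' \code{rho_m(r)} decays linearly to zero at the disc edge and integrates to
#' \code{mc_dendrite_length}; \code{N_s(z)} is triangular on
#' \code{spine_z_range} peaking at \code{spine_z_peak} and integrates to
#' \code{gc_spine_count}.
#'
#' @param n_mc,n_gc,n_glomeruli Cell and glomerulus counts.
#' @param box Numeric length-3 vector: x, y, z extents of the tissue box.
#' @param mc_disc_radius Radius of the MC lateral-dendrite disc.
#' @param mc_type1_z,mc_type2_z z-planes of deep (Type I) and superficial
#'   (Type II) MC discs.
#' @param mc_type1_fraction Fraction of MCs that are Type I.
#' @param gc_vertex_z_range Range for GC cone vertex z (deep-type GCs:
#'   default lower half of the box).
#' @param gc_half_angle GC cone half-angle (radians).
#' @param mc_dendrite_length Total lateral dendritic length per MC.
#' @param gc_spine_count Total spine count per GC.
#' @param spine_z_range,spine_z_peak Support and peak of the triangular
#'   spine-count profile.
#' @param r_dendrite Lateral dendrite radius (cylinder model).
#' @param d_shell Interaction-shell thickness (about one spine diameter).
#' @param q_area Interaction cross-section constant (um^2): the printed
#'   reference value \code{2.32}, or \code{"formula"} to use
#'   \code{(d_shell + r_dendrite)^2 - r_dendrite^2} (which evaluates to
#'   about 2.06 with the default geometry; the two disagree in the source
#'   anatomy and the choice is deliberately explicit).
#' @return An object of class \code{"layout_spec"}.
#' @export
layout_spec <- function(n_mc = 20, n_gc = 80, n_glomeruli = 4,
                        box = c(1000, 1000, 400),
                        mc_disc_radius = 425,
                        mc_type1_z = 270, mc_type2_z = 320,
                        mc_type1_fraction = 0.5,
                        gc_vertex_z_range = c(0, 200),
                        gc_half_angle = pi / 6,
                        mc_dendrite_length = 8000,
                        gc_spine_count = 2600,
                        spine_z_range = c(50, 400), spine_z_peak = 250,
                        r_dendrite = 0.5, d_shell = 1.02,
                        q_area = 2.32) {
  stopifnot(length(box) == 3, all(box > 0))
  for (v in c("n_mc", "n_gc", "n_glomeruli", "mc_disc_radius",
              "mc_dendrite_length", "gc_spine_count",
              "r_dendrite", "d_shell")) {
    .check_pos(get(v), v)
  }
  if (identical(q_area, "formula")) {
    q_area <- (d_shell + r_dendrite)^2 - r_dendrite^2
  }
  .check_pos(q_area, "q_area")
  if (2 * mc_disc_radius > min(box[1], box[2])) {
    stop("box too small for the requested MC disc radius", call. = FALSE)
  }
  stopifnot(gc_half_angle > 0, gc_half_angle < pi / 2,
            length(gc_vertex_z_range) == 2,
            gc_vertex_z_range[1] < gc_vertex_z_range[2],
            length(spine_z_range) == 2,
            spine_z_range[1] < spine_z_peak, spine_z_peak < spine_z_range[2])
  structure(
    list(n_mc = as.integer(n_mc), n_gc = as.integer(n_gc),
         n_glomeruli = as.integer(n_glomeruli),
         box = box, mc_disc_radius = mc_disc_radius,
         mc_type1_z = mc_type1_z, mc_type2_z = mc_type2_z,
         mc_type1_fraction = mc_type1_fraction,
         gc_vertex_z_range = gc_vertex_z_range,
         gc_half_angle = gc_half_angle,
         mc_dendrite_length = mc_dendrite_length,
         gc_spine_count = gc_spine_count,
         spine_z_range = spine_z_range, spine_z_peak = spine_z_peak,
         r_dendrite = r_dendrite, d_shell = d_shell, q_area = q_area),
    class = "layout_spec")
}

#' MC radial dendritic length density rho_m(r)
#'
#' Linearly decaying profile, zero at the disc edge, normalized so that the
#' disc integral equals the configured total dendritic length.
#'
#' @param r Radial distance(s) from the disc center (um).
#' @param layout A \code{\link{layout_spec}}.
#' @return Length density in um of dendrite per um^2.
#' @export
mc_dendrite_density <- function(r, layout) {
  R <- layout$mc_disc_radius
  rho0 <- 3 * layout$mc_dendrite_length / (pi * R^2)
  ifelse(r < R, rho0 * (1 - r / R), 0)
}

#' GC spine volume density rho_g(z) for one granule cell
#'
#' Triangular spine-count profile \code{N_s(z)} (spines per um height,
#' normalized to the configured total), divided by the cone cross-section
#' area at that height.  Zero below the cone vertex and outside the profile
#' support.
#'
#' @param z Height(s) (um).
#' @param vertex_z Cone vertex height of this GC.
#' @param layout A \code{\link{layout_spec}}.
#' @return Spine density in spines per um^3.
#' @export
gc_spine_density <- function(z, vertex_z, layout) {
  zr <- layout$spine_z_range
  zp <- layout$spine_z_peak
  peak <- 2 * layout$gc_spine_count / (zr[2] - zr[1])
  ns <- ifelse(z <= zr[1] | z >= zr[2], 0,
               ifelse(z <= zp, peak * (z - zr[1]) / (zp - zr[1]),
                      peak * (zr[2] - z) / (zr[2] - zp)))
  r_cone <- pmax(z - vertex_z, 0) * tan(layout$gc_half_angle)
  area <- pi * r_cone^2
  ifelse(r_cone > 0, ns / area, 0)
}

#' Place mitral cells, granule cells and glomeruli in the tissue box
#'
#' Glomeruli are placed uniformly at random in the x-y plane.  MCs are
#' partitioned as evenly as possible across glomeruli (remainders spread
#' deterministically over the first glomeruli) and each MC disc is centered
#' under its glomerulus at the Type I or Type II z-plane.  GC cone vertices
#' are uniform in x-y with z in the configured deep range.
#'
#' @param layout A \code{\link{layout_spec}}.
#' @param seed Integer seed; placement is reproducible.
#' @return An object of class \code{"cell_placement"} with data frames
#'   \code{glomeruli} (id, x, y), \code{mc} (id, glomerulus, x, y, z, radius,
#'   type) and \code{gc} (id, x, y, z, half_angle).
#' @export
place_cells <- function(layout, seed = 1L) {
  stopifnot(inherits(layout, "layout_spec"))
  set.seed(seed)
  g <- data.frame(id = seq_len(layout$n_glomeruli),
                  x = stats::runif(layout$n_glomeruli, 0, layout$box[1]),
                  y = stats::runif(layout$n_glomeruli, 0, layout$box[2]))
  ## even deterministic partition of MCs over glomeruli
  glom_of_mc <- rep(seq_len(layout$n_glomeruli),
                    length.out = layout$n_mc)
  glom_of_mc <- sort(glom_of_mc)
  type1 <- stats::runif(layout$n_mc) < layout$mc_type1_fraction
  mc <- data.frame(id = seq_len(layout$n_mc),
                   glomerulus = glom_of_mc,
                   x = g$x[glom_of_mc], y = g$y[glom_of_mc],
                   z = ifelse(type1, layout$mc_type1_z, layout$mc_type2_z),
                   radius = layout$mc_disc_radius,
                   type = ifelse(type1, "I", "II"))
  gc <- data.frame(id = seq_len(layout$n_gc),
                   x = stats::runif(layout$n_gc, 0, layout$box[1]),
                   y = stats::runif(layout$n_gc, 0, layout$box[2]),
                   z = stats::runif(layout$n_gc, layout$gc_vertex_z_range[1],
                                    layout$gc_vertex_z_range[2]),
                   half_angle = layout$gc_half_angle)
  structure(list(glomeruli = g, mc = mc, gc = gc, layout = layout,
                 seed = seed),
            class = "cell_placement")
}

#' @export
print.cell_placement <- function(x, ...) {
  cat("Cell placement:", nrow(x$mc), "MCs,", nrow(x$gc), "GCs,",
      nrow(x$glomeruli), "glomeruli (seed", x$seed, ")\n")
  invisible(x)
}

## angular width (radians) of the circle of radius r centered at the MC that
## lies inside a circle of radius r2 whose center is at distance d
.lens_angle <- function(r, d, r2) {
  if (d <= 1e-12) return(ifelse(r <= r2, 2 * pi, 0))
  cosarg <- (d^2 + r^2 - r2^2) / (2 * d * pmax(r, 1e-300))
  ifelse(r <= 1e-12, ifelse(d <= r2, 2 * pi, 0),
         ifelse(r + d <= r2, 2 * pi,
                ifelse(abs(d - r2) >= r & d > r2, 0,
                       2 * acos(pmin(1, pmax(-1, cosarg))))))
}

#' Dendritic length in the overlap of an MC disc and a GC cone
#'
#' Integrates \code{rho_m(r)} over the lens intersection of the MC disc with
#' the GC cone's circular cross-section at the MC's z-plane, in polar
#' coordinates about the MC center (the angular extent inside the second
#' circle is known in closed form, so the integral is one-dimensional and
#' handled by adaptive quadrature).  Returns 0 when the plane misses the
#' cone or the circles are disjoint.
#'
#' @param mc One row of the placement's \code{mc} data frame (list-like with
#'   \code{x}, \code{y}, \code{z}, \code{radius}).
#' @param gc One row of the placement's \code{gc} data frame (\code{x},
#'   \code{y}, \code{z}, \code{half_angle}).
#' @param layout A \code{\link{layout_spec}}.
#' @return Dendritic length l in the overlap (um).
#' @export
overlap_dendritic_length <- function(mc, gc, layout) {
  dz <- mc$z - gc$z
  if (dz <= 0) return(0)
  r2 <- dz * tan(gc$half_angle)
  d <- sqrt((mc$x - gc$x)^2 + (mc$y - gc$y)^2)
  R1 <- mc$radius
  if (d >= R1 + r2) return(0)
  lower <- max(0, d - r2)
  upper <- min(R1, d + r2)
  if (upper <= lower) {
    ## MC center inside the cross-section with the whole relevant annulus
    ## contained (d + R1 <= r2 handled by the integrand returning 2*pi)
    lower <- 0
    upper <- R1
  }
  f <- function(r) {
    mc_dendrite_density(r, layout) * .lens_angle(r, d, r2) * r
  }
  ## integrate over the full disc radius; the integrand is zero outside the
  ## lens so this is safe, and splitting at the lens bounds helps the
  ## quadrature near kinks
  pieces <- unique(pmin(pmax(c(0, lower, upper, R1), 0), R1))
  pieces <- sort(pieces)
  total <- 0
  for (i in seq_len(length(pieces) - 1)) {
    if (pieces[i + 1] - pieces[i] < 1e-9) next
    total <- total + stats::integrate(f, pieces[i], pieces[i + 1],
                                      rel.tol = 1e-8, abs.tol = 1e-10,
                                      subdivisions = 400L)$value
  }
  total
}

#' Expected synapse count and connection probability for an MC-GC pair
#'
#' \code{lambda = rho_g(z_intersect) * q * pi * l} with the spine density
#' evaluated at the MC disc plane (taken constant across the thin
#' interaction shell), and \code{p = 1 - exp(-lambda)} from the Poisson law
#' for at least one synapse.
#'
#' @inheritParams overlap_dendritic_length
#' @param l Optional precomputed overlap length; computed if missing.
#' @return Named vector \code{lambda} and \code{p_connect}.
#' @export
expected_synapses <- function(mc, gc, layout, l = NULL) {
  if (is.null(l)) l <- overlap_dendritic_length(mc, gc, layout)
  rho_g <- gc_spine_density(mc$z, gc$z, layout)
  lambda <- rho_g * layout$q_area * pi * l
  c(lambda = lambda, p_connect = 1 - exp(-lambda))
}

#' Build the MC-GC connectivity graph
#'
#' One Bernoulli draw per MC-GC pair at its geometric connection
#' probability; at most one edge per pair (multiple expected synapses
#' collapse to a single contact).  Each realized synapse's radial location is
#' sampled within the overlap lens with density proportional to
#' \code{rho_m(r) * arc(r)}, and recorded as the somatic distance \code{L}
#' that attenuates the GABA conductance.
#'
#' @param placement A \code{\link{place_cells}} result.
#' @param seed Integer seed.
#' @return An object of class \code{"connectivity_graph"}: \code{edges}
#'   (data frame mc, gc, L, lambda, p_connect), the \code{pairs} table of all
#'   candidate pairs with nonzero overlap, counts, and the seed.
#' @export
build_network <- function(placement, seed = 1L) {
  stopifnot(inherits(placement, "cell_placement"))
  layout <- placement$layout
  set.seed(seed)
  edges <- list()
  pairs <- list()
  k <- 0; ke <- 0
  for (j in seq_len(nrow(placement$gc))) {
    gc <- placement$gc[j, ]
    for (i in seq_len(nrow(placement$mc))) {
      mc <- placement$mc[i, ]
      l <- overlap_dendritic_length(mc, gc, layout)
      if (l <= 0) next
      es <- expected_synapses(mc, gc, layout, l = l)
      k <- k + 1
      pairs[[k]] <- data.frame(mc = mc$id, gc = gc$id, l = l,
                               lambda = es[["lambda"]],
                               p_connect = es[["p_connect"]])
      if (stats::runif(1) < es[["p_connect"]]) {
        L <- .sample_synapse_radius(mc, gc, layout)
        ke <- ke + 1
        edges[[ke]] <- data.frame(mc = mc$id, gc = gc$id, L = L,
                                  lambda = es[["lambda"]],
                                  p_connect = es[["p_connect"]])
      }
    }
  }
  edges <- if (ke > 0) do.call(rbind, edges) else
    data.frame(mc = integer(), gc = integer(), L = numeric(),
               lambda = numeric(), p_connect = numeric())
  pairs <- if (k > 0) do.call(rbind, pairs) else
    data.frame(mc = integer(), gc = integer(), l = numeric(),
               lambda = numeric(), p_connect = numeric())
  structure(
    list(edges = edges, pairs = pairs,
         n_mc = nrow(placement$mc), n_gc = nrow(placement$gc),
         seed = seed, layout = layout),
    class = "connectivity_graph")
}

## inverse-CDF sample of the synapse radial distance within the lens,
## weighted by rho_m(r) * arc(r) * r on a fine grid
.sample_synapse_radius <- function(mc, gc, layout) {
  dz <- mc$z - gc$z
  r2 <- dz * tan(gc$half_angle)
  d <- sqrt((mc$x - gc$x)^2 + (mc$y - gc$y)^2)
  grid <- seq(0, mc$radius, length.out = 512L)
  w <- mc_dendrite_density(grid, layout) * .lens_angle(grid, d, r2) * grid
  if (sum(w) <= 0) return(0)
  cdf <- cumsum(w) / sum(w)
  u <- stats::runif(1)
  grid[which.max(cdf >= u)]
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat("Connectivity graph:", x$n_mc, "MCs x", x$n_gc, "GCs;",
      nrow(x$edges), "synapses from", nrow(x$pairs),
      "overlapping pairs (seed", x$seed, ")\n")
  if (nrow(x$edges) > 0) {
    cat("  somatic distance L: median", signif(stats::median(x$edges$L), 4),
        "um; mean p_connect", signif(mean(x$pairs$p_connect), 4), "\n")
  }
  invisible(x)
}
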