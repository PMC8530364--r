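## Configuration, serialization and deterministic fixtures tying the tiers
## together.  Configs are YAML with blocks named after the model tiers;
## every referenced spec constructor revalidates its invariants eagerly and
## unknown keys are rejected.

.config_blocks <- c("tier", "seed", "thresholds", "feedback", "counts",
                    "population", "layout", "readout", "phase")

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, rejects unknown top-level keys, and eagerly
#' constructs (hence validates) every spec block present: \code{thresholds}
#' via \code{\link{threshold_spec}}, \code{feedback} via
#' \code{\link{feedback_spec}}, \code{counts} via
#' \code{\link{odor_pair_counts}} (requires \code{thresholds}),
#' \code{population} via \code{\link{population_spec}}, \code{layout} via
#' \code{\link{layout_spec}} and \code{readout} via
#' \code{\link{readout_spec}}.  A violated invariant propagates the
#' constructor's error, which names the offending constraint.
#'
#' @param path Path to a YAML file.
#' @return A list of class \code{"run_config"} holding the raw values and
#'   the constructed spec objects.
#' @export
load_run_config <- function(path) {
  ## keep single-letter keys like N literal (YAML 1.1 would read them as
  ## booleans)
  raw <- yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(x) x, "bool#no" = function(x) x))
  unknown <- setdiff(names(raw), .config_blocks)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- list(raw = raw, tier = raw$tier,
              seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed))
  if (!is.null(raw$thresholds)) {
    cfg$thresholds <- do.call(threshold_spec, raw$thresholds)
  }
  if (!is.null(raw$feedback)) {
    cfg$feedback <- do.call(feedback_spec, raw$feedback)
  }
  if (!is.null(raw$counts)) {
    if (is.null(cfg$thresholds)) {
      stop("'counts' requires a 'thresholds' block", call. = FALSE)
    }
    cfg$counts <- do.call(odor_pair_counts,
                          c(raw$counts, list(th = cfg$thresholds)))
  }
  if (!is.null(raw$population)) {
    cfg$population <- do.call(population_spec, raw$population)
  }
  if (!is.null(raw$layout)) {
    lay <- raw$layout
    for (nm in c("box", "gc_vertex_z_range", "spine_z_range")) {
      if (!is.null(lay[[nm]])) lay[[nm]] <- as.numeric(lay[[nm]])
    }
    cfg$layout <- do.call(layout_spec, lay)
  }
  if (!is.null(raw$readout)) {
    cfg$readout <- do.call(readout_spec, raw$readout)
  }
  cfg$phase <- raw$phase
  structure(cfg, class = "run_config")
}

#' Write a run configuration back to YAML
#'
#' Serializes the raw block values; a written config reloads to an equal
#' object (lossless round trip).
#'
#' @param cfg A \code{"run_config"} or a plain list of raw blocks.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  raw <- if (inherits(cfg, "run_config")) cfg$raw else cfg
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Write a run manifest next to an output
#'
#' Records the package version, the master seed, the configuration and a
#' content hash so that any output directory is self-describing.
#'
#' @param dir Output directory (created if needed).
#' @param cfg Configuration list (raw values).
#' @param seed Master seed.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, cfg = NULL, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "olfeedback",
    version = as.character(utils::packageVersion("olfeedback")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, config = cfg)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Serialize a connectivity graph to plain-text files
#'
#' Writes the edge and candidate-pair tables as CSV plus a JSON sidecar with
#' the layout and seed.
#'
#' @param graph A \code{\link{build_network}} result.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_connectivity <- function(graph, dir) {
  stopifnot(inherits(graph, "connectivity_graph"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(graph$edges, file.path(dir, "edges.csv"),
                   row.names = FALSE)
  utils::write.csv(graph$pairs, file.path(dir, "pairs.csv"),
                   row.names = FALSE)
  side <- graph$layout
  side$n_mc <- graph$n_mc; side$n_gc <- graph$n_gc; side$seed <- graph$seed
  jsonlite::write_json(unclass(side), file.path(dir, "layout.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a connectivity graph written by \code{\link{write_connectivity}}
#'
#' @param dir Directory containing \code{edges.csv}, \code{pairs.csv} and
#'   \code{layout.json}.
#' @return A \code{"connectivity_graph"}.
#' @export
read_connectivity <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "layout.json"),
                              simplifyVector = TRUE)
  edges <- utils::read.csv(file.path(dir, "edges.csv"))
  pairs <- utils::read.csv(file.path(dir, "pairs.csv"))
  n_mc <- side$n_mc; n_gc <- side$n_gc; seed <- side$seed
  side$n_mc <- side$n_gc <- side$seed <- NULL
  layout <- do.call(layout_spec, side)
  structure(list(edges = edges, pairs = pairs, n_mc = n_mc, n_gc = n_gc,
                 seed = seed, layout = layout),
            class = "connectivity_graph")
}

#' Deterministic miniature fixture network
#'
#' A small MC-GC network (at most 30 MCs and 120 GCs) in a compact box,
#' built from a fixed layout so that overlaps are hand-checkable and the
#' edge probabilities can be recomputed independently in a test suite.  Use
#' \code{empty = TRUE} for a variant whose GC cones sit entirely above the
#' MC planes (zero overlap everywhere, hence zero edges).
#'
#' @param seed Integer seed.
#' @param n_mc,n_gc Cell counts (capped at 30 / 120).
#' @param empty Build the zero-overlap variant?
#' @return A list with the \code{placement} and the \code{graph}.
#' @export
make_fixture_network <- function(seed = 1L, n_mc = 12, n_gc = 40,
                                 empty = FALSE) {
  n_mc <- min(n_mc, 30L)
  n_gc <- min(n_gc, 120L)
  layout <- layout_spec(
    n_mc = n_mc, n_gc = n_gc, n_glomeruli = max(2L, n_mc %/% 4L),
    box = c(400, 400, 300),
    mc_disc_radius = 150,
    mc_type1_z = if (empty) 20 else 200,
    mc_type2_z = if (empty) 30 else 240,
    gc_vertex_z_range = c(40, 120),
    gc_half_angle = pi / 4,
    mc_dendrite_length = 4000,
    gc_spine_count = 1500,
    spine_z_range = c(60, 300), spine_z_peak = 180)
  placement <- place_cells(layout, seed = seed)
  graph <- build_network(placement, seed = derive_seed(seed, "fixture-net"))
  list(placement = placement, graph = graph)
}
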