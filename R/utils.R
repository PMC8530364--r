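#' Cosine similarity between two numeric vectors
#'
#' The similarity measure used throughout the package to compare population
#' response vectors: \code{sum(x * y) / (||x|| ||y||)}.  A zero vector has no
#' direction, so similarity against it is an error rather than a conventional
#' 0 or 1.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A single number in \code{[-1, 1]}.
#' @export
#' @examples
#' cosine_similarity(c(1, 0, 1), c(1, 1, 0))
cosine_similarity <- function(x, y) {
  if (length(x) != length(y)) {
    stop("cosine_similarity: vectors must have equal length")
  }
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    stop("cosine_similarity: undefined for an all-zero vector")
  }
  sum(x * y) / (nx * ny)
}

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Every stochastic operation in a multi-stage run draws its seed from the
#' master seed plus a stable component label, so that re-running any single
#' stage reproduces its stream without replaying the whole pipeline.  The
#' label is hashed with a small polynomial rolling hash; the result is kept
#' strictly below 2^31 so it is always a valid R integer seed.
#'
#' @param master Integer master seed.
#' @param label Character scalar naming the substream.
#' @return An integer seed.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(label))
  h <- as.double(master %% 2147483647)
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

## internal validation helpers -------------------------------------------------

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

.check_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop(sprintf("'%s' must be a single %s number", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  }
  invisible(x)
}

.heaviside <- function(x) as.numeric(x >= 0)
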