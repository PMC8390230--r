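# Internal geometry helpers shared across modules.

# Coerce a coordinate argument to a 1x3 or nx3 numeric matrix (x, y, z).
asXYZ <- function(p, what = "coordinate") {
  if (is.numeric(p) && is.null(dim(p))) {
    if (length(p) %% 3L != 0L)
      stop(what, " must be (x, y, z) triples", call. = FALSE)
    p <- matrix(p, ncol = 3L, byrow = TRUE)
  }
  p <- as.matrix(p)
  if (ncol(p) != 3L)
    stop(what, " must have columns x, y, z", call. = FALSE)
  storage.mode(p) <- "double"
  colnames(p) <- c("x", "y", "z")
  p
}

vnorm <- function(v) sqrt(sum(v * v))

# Euclidean length of each segment of an n x 3 polyline (n - 1 values).
segmentLengths <- function(pts) {
  d <- diff(pts)
  sqrt(rowSums(d * d))
}

# Total polyline length in voxels.
polylineLengthVoxels <- function(pts) sum(segmentLengths(pts))

# Drop consecutive duplicate rows (within tol); warn if any were dropped.
collapseDuplicates <- function(pts, tol = 1e-9, warn = TRUE) {
  if (nrow(pts) < 2L) return(pts)
  keep <- c(TRUE, segmentLengths(pts) > tol)
  if (!all(keep) && warn)
    warning("duplicate consecutive nodes collapsed", call. = FALSE)
  pts[keep, , drop = FALSE]
}

stopIfNotPolyline <- function(pts) {
  if (!is.matrix(pts) || ncol(pts) != 3L || nrow(pts) < 2L)
    stop("polyline must be a matrix with >= 2 rows and columns x, y, z",
         call. = FALSE)
}

# Run code with a private RNG stream seeded from `seed`, restoring the
# caller's RNG state afterwards.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
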