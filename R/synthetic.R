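# Synthetic tubular root phantoms with known ground-truth geometry.
# Centerline types: straight, helix, sine, bezier (cubic). Curves are
# given parametrically on t in [0, 1] and sampled at 0.25-voxel arc
# steps for rasterization and ground truth.

curvePoint <- function(root, t) {
  switch(root$type,
    straight = {
      a <- root$from; b <- root$to
      cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]),
            a[3] + t * (b[3] - a[3]))
    },
    helix = {
      ang <- root$phase + 2 * pi * root$turns * t
      cbind(root$center[1] + root$radiusXY * cos(ang),
            root$center[2] + root$radiusXY * sin(ang),
            root$z0 + root$pitch * root$turns * t)
    },
    sine = {
      cbind(root$center[1] + root$amplitude *
              sin(2 * pi * root$cycles * t + root$phase),
            root$center[2] + 0 * t,
            root$z0 + root$length * t)
    },
    bezier = {
      p <- root$control  # 4 x 3 matrix
      b <- cbind((1 - t)^3, 3 * (1 - t)^2 * t, 3 * (1 - t) * t^2, t^3)
      b %*% p
    },
    stop("unknown centerline type: ", root$type, call. = FALSE))
}

# Arc-length-uniform samples of a centerline at `ds` voxel spacing.
sampleCurve <- function(root, ds = 0.25) {
  tFine <- seq(0, 1, length.out = 4001L)
  pts <- curvePoint(root, tFine)
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  total <- arc[length(arc)]
  sAt <- unique(c(seq(0, total, by = ds), total))
  tAt <- stats::approx(arc, tFine, xout = sAt, ties = "ordered")$y
  asXYZ(curvePoint(root, tAt))
}

# Closed-form arc length where available, else fine numeric quadrature.
analyticArcLength <- function(root) {
  switch(root$type,
    straight = vnorm(root$to - root$from),
    helix = sqrt((2 * pi * root$radiusXY)^2 + root$pitch^2) * root$turns,
    {
      tFine <- seq(0, 1, length.out = 200001L)
      sum(sqrt(rowSums(diff(curvePoint(root, tFine))^2)))
    })
}

defaultHelixRoot <- function() {
  list(type = "helix", center = c(32, 32), radiusXY = 8, pitch = 64,
       turns = 1.5, phase = 0, z0 = 8, radius = 3, intensity = 255L)
}

#' Describe a synthetic root phantom
#'
#' Builds the recipe for a phantom volume: bright tubular roots of known
#' centerline geometry in a dark background, with optional salt noise
#' (random voxels set to 255, mimicking speckle from soil voids) and
#' additive Gaussian noise. Each element of \code{roots} is a list with a
#' \code{type} and its parameters, plus \code{radius} (tube radius,
#' voxels) and \code{intensity} (8-bit):
#' \itemize{
#'   \item \code{straight}: \code{from}, \code{to} — (x, y, z) endpoints.
#'   \item \code{helix}: \code{center} (x, y), \code{radiusXY},
#'     \code{pitch} (z rise per turn), \code{turns}, \code{phase},
#'     \code{z0}.
#'   \item \code{sine}: \code{center} (x, y), \code{amplitude} (in x),
#'     \code{cycles}, \code{phase}, \code{z0}, \code{length} (z extent).
#'   \item \code{bezier}: \code{control}, a 4 x 3 matrix of control
#'     points.
#' }
#' The default is a single gently wavy helical root (radius 8 voxels,
#' pitch 64, 1.5 turns, tube radius 3) in a 128 x 64 x 64 volume — the
#' kind of smooth 3D waviness rice crown roots show in segmented CT
#' volumes.
#'
#' @param shape volume shape (depth, height, width) in voxels.
#' @param resolution voxel resolution in mm/voxel.
#' @param roots list of root descriptions (see above).
#' @param saltFraction fraction of voxels set to 255 (default 0).
#' @param gaussianSigma sd of additive Gaussian noise (default 0).
#' @param seed RNG seed for the noise (default 1).
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(shape = c(128, 64, 64), resolution = 0.3,
                        roots = list(defaultHelixRoot()),
                        saltFraction = 0, gaussianSigma = 0, seed = 1) {
  roots <- lapply(roots, function(r) {
    if (!is.null(r$control)) r$control <- asXYZ(r$control, "control points")
    for (f in c("from", "to", "center")) if (!is.null(r[[f]]))
      r[[f]] <- as.numeric(r[[f]])
    r
  })
  new("PhantomSpec", shape = as.integer(shape),
      resolution = as.numeric(resolution), roots = roots,
      saltFraction = as.numeric(saltFraction),
      gaussianSigma = as.numeric(gaussianSigma), seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d x %d x %d voxels, %d root(s)\n",
              object@shape[1], object@shape[2], object@shape[3],
              length(object@roots)))
  cat(sprintf("  noise: salt %.3f, gaussian sigma %.1f, seed %d\n",
              object@saltFraction, object@gaussianSigma, object@seed))
})

#' Rasterize a phantom
#'
#' Renders each tubular root into the volume: every voxel whose center
#' lies within \code{radius} of the centerline (point-to-curve distance,
#' curve sampled at 0.25-voxel arc steps) is set to the root's intensity.
#' Noise is applied after rasterization using the spec's seed. Ground
#' truth is returned in the same (x, y, z) voxel coordinate convention
#' used by the vectorization functions.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list with \code{volume} (a \linkS4class{RootVolume}),
#'   \code{polylines} (list of dense ground-truth centerline matrices),
#'   \code{arcLengths} (analytic arc lengths, voxels), and
#'   \code{angles} (analytic growth angles from the centerline
#'   endpoints, radians).
#' @export
rasterizePhantom <- function(spec) {
  validObject(spec)
  d <- spec@shape
  vol <- array(0L, dim = d)
  polylines <- vector("list", length(spec@roots))
  arcLengths <- numeric(length(spec@roots))
  angles <- numeric(length(spec@roots))
  lim <- c(d[3], d[2], d[1])  # xyz extents
  for (k in seq_along(spec@roots)) {
    root <- spec@roots[[k]]
    samp <- sampleCurve(root)
    if (any(samp < root$radius - 1e-9) ||
        any(sweep(samp, 2, lim - root$radius) > 1e-9))
      stop("phantom out of bounds (root ", k, ")", call. = FALSE)
    rad <- root$radius
    n <- nrow(samp)
    # inward tangents at the two ends: the tube gets flat ends (a finite
    # cylinder for a straight centerline), not spherical caps
    tanStart <- samp[2, ] - samp[1, ]
    tanStart <- tanStart / vnorm(tanStart)
    tanEnd <- samp[n - 1L, ] - samp[n, ]
    tanEnd <- tanEnd / vnorm(tanEnd)
    pStart <- samp[1, ]; pEnd <- samp[n, ]
    inCap <- function(cx, cy, cz, p0, tanIn) {
      d2 <- (cx - p0[1])^2 + (cy - p0[2])^2 + (cz - p0[3])^2
      d2 <= rad^2 & ((cx - p0[1]) * tanIn[1] + (cy - p0[2]) * tanIn[2] +
                       (cz - p0[3]) * tanIn[3]) < 0
    }
    for (i in seq_len(n)) {
      p <- samp[i, ]
      xs <- max(0L, floor(p[1] - rad - 0.5)):min(lim[1] - 1L,
                                                 ceiling(p[1] + rad - 0.5))
      ys <- max(0L, floor(p[2] - rad - 0.5)):min(lim[2] - 1L,
                                                 ceiling(p[2] + rad - 0.5))
      zs <- max(0L, floor(p[3] - rad - 0.5)):min(lim[3] - 1L,
                                                 ceiling(p[3] + rad - 0.5))
      cz <- rep(zs + 0.5, times = length(ys) * length(xs))
      cy <- rep(rep(ys + 0.5, each = length(zs)), times = length(xs))
      cx <- rep(xs + 0.5, each = length(zs) * length(ys))
      hit <- (cx - p[1])^2 + (cy - p[2])^2 + (cz - p[3])^2 <= rad^2 &
        !inCap(cx, cy, cz, pStart, tanStart) &
        !inCap(cx, cy, cz, pEnd, tanEnd)
      if (any(hit)) {
        idx <- cbind(cz[hit] + 0.5, cy[hit] + 0.5, cx[hit] + 0.5)
        vol[idx] <- pmax(vol[idx], as.integer(root$intensity))
      }
    }
    polylines[[k]] <- samp
    arcLengths[k] <- analyticArcLength(root)
    angles[k] <- rootGrowthAngle(samp)
  }
  if (spec@saltFraction > 0 || spec@gaussianSigma > 0) {
    vol <- withSeed(spec@seed, {
      v <- as.numeric(vol)
      if (spec@saltFraction > 0) {
        nSalt <- round(spec@saltFraction * length(v))
        v[sample.int(length(v), nSalt)] <- 255
      }
      if (spec@gaussianSigma > 0)
        v <- v + stats::rnorm(length(v), 0, spec@gaussianSigma)
      array(as.integer(pmin(255, pmax(0, round(v)))), dim = d)
    })
  }
  list(volume = RootVolume(vol, spec@resolution),
       polylines = polylines, arcLengths = arcLengths, angles = angles)
}

#' Write a volume as a directory of slice PNGs
#'
#' One zero-padded 8-bit grayscale PNG per horizontal slice
#' (\code{slice_0000.png}, \code{slice_0001.png}, ...), loadable by
#' \code{\link{loadVolume}} with bit-identical intensities.
#'
#' @param volume a \linkS4class{RootVolume}.
#' @param directory output directory (created if missing).
#' @return the directory, invisibly.
#' @export
writeVolume <- function(volume, directory) {
  d <- dim(volume@intensities)
  if (d[1] == 0L) stop("empty volume", call. = FALSE)
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  for (z in seq_len(d[1])) {
    png::writePNG(volume@intensities[z, , ] / 255,
                  target = file.path(directory,
                                     sprintf("slice_%04d.png", z - 1L)))
  }
  invisible(directory)
}

#' Read a PhantomSpec from JSON
#'
#' The JSON mirrors \code{\link{phantomSpec}}: \code{{"shape": [d,h,w],
#' "resolution_mm": r, "roots": [...], "noise": {"salt_fraction": f,
#' "gaussian_sigma": s}, "seed": k}}.
#'
#' @param path JSON file path.
#' @return A \linkS4class{PhantomSpec}.
#' @export
readPhantomSpec <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$shape) || is.null(obj$roots))
    stop("invalid phantom spec: need shape and roots", call. = FALSE)
  roots <- lapply(obj$roots, function(r) {
    r <- lapply(r, function(v)
      if (is.list(v)) do.call(rbind, lapply(v, as.numeric)) else v)
    for (f in c("from", "to", "center")) if (!is.null(r[[f]]))
      r[[f]] <- as.numeric(r[[f]])
    r
  })
  noise <- obj$noise
  phantomSpec(shape = as.integer(unlist(obj$shape)),
              resolution = if (is.null(obj$resolution_mm)) 0.3 else
                obj$resolution_mm,
              roots = roots,
              saltFraction = if (is.null(noise$salt_fraction)) 0 else
                noise$salt_fraction,
              gaussianSigma = if (is.null(noise$gaussian_sigma)) 0 else
                noise$gaussian_sigma,
              seed = if (is.null(obj$seed)) 1L else obj$seed)
}
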