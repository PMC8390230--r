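#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' RootVolume: a segmented 3D root image
#'
#' Container for a stack of 8-bit grayscale slices forming a 3D volume in
#' which root segments are bright against a dark background, together with
#' the isotropic voxel resolution. Intensities are stored as an integer
#' array indexed \code{[z, y, x]} (z = 0-based slice index + 1; z grows
#' with soil depth, z = 1 is the topmost slice). Continuous coordinates
#' are 0-based: voxel \code{(z, y, x)} spans the half-open cube
#' \code{[z, z+1) x [y, y+1) x [x, x+1)}, so its center sits at index + 0.5.
#'
#' @slot intensities integer array, dim \code{(depth, height, width)},
#'   values in 0..255.
#' @slot resolution numeric(1), voxel edge length in mm (isotropic, > 0).
#' @exportClass RootVolume
setClass("RootVolume",
  representation(intensities = "array", resolution = "numeric"))

setValidity("RootVolume", function(object) {
  a <- object@intensities
  if (length(dim(a)) != 3L)
    return("intensities must be a 3D array (depth, height, width)")
  if (!is.integer(a))
    return("intensities must be integer storage")
  if (length(a) > 0L && (min(a) < 0L || max(a) > 255L))
    return("intensities must lie in [0, 255]")
  r <- object@resolution
  if (length(r) != 1L || !is.finite(r) || r <= 0)
    return("resolution must be a single positive number (mm/voxel)")
  TRUE
})

#' RootNode: one single root of an RSA
#'
#' A single root (radicle or crown root) is described by the ordered relay
#' nodes an operator registered on it, the interpolation method used to
#' vectorize it, and (once vectorized) the cached polyline. Coordinates
#' are \code{(x, y, z)} in continuous voxel units.
#'
#' @slot id integer root identifier, stable, never reused after deletion.
#' @slot relayNodes numeric matrix, one row per relay node, columns x, y, z.
#' @slot interpolation character, one of "straight", "spline", "cog".
#' @slot polyline cached polyline matrix (columns x, y, z) or NULL.
#' @exportClass RootNode
setClass("RootNode",
  representation(id = "integer", relayNodes = "matrix",
                 interpolation = "character", polyline = "matrixOrNULL"))

setValidity("RootNode", function(object) {
  if (length(object@id) != 1L || is.na(object@id))
    return("id must be a single integer")
  rn <- object@relayNodes
  if (nrow(rn) < 1L || ncol(rn) != 3L)
    return("a root requires at least one relay node with (x, y, z)")
  if (anyDuplicated(round(rn, 12)))
    return("relay nodes must be distinct points")
  if (!object@interpolation %in% c("straight", "spline", "cog"))
    return("interpolation must be one of 'straight', 'spline', 'cog'")
  if (!is.null(object@polyline)) {
    pl <- object@polyline
    if (ncol(pl) != 3L || nrow(pl) < 2L)
      return("a cached polyline needs >= 2 (x, y, z) vertices")
  }
  TRUE
})

#' RSATree: the depth-2 root system architecture tree
#'
#' The whole RSA is a tree of depth exactly 2: one base node (the place
#' where the seed was sown), inner nodes for the single roots, and leaf
#' relay nodes marking points on each root. An RSA of one radicle and two
#' crown roots is one base node holding three root nodes.
#'
#' @slot base numeric(3), base node position (x, y, z) in voxel units.
#' @slot roots list of \linkS4class{RootNode}, in registration order.
#' @slot resolution numeric(1), voxel resolution in mm (> 0).
#' @slot annotations named list of free-form strings (cultivar, DAS, ...).
#' @slot nextId integer, next root id to assign (ids are never reused).
#' @exportClass RSATree
setClass("RSATree",
  representation(base = "numeric", roots = "list", resolution = "numeric",
                 annotations = "list", nextId = "integer"))

setValidity("RSATree", function(object) {
  if (length(object@base) != 3L || any(!is.finite(object@base)))
    return("base must be a finite (x, y, z) triple")
  if (length(object@resolution) != 1L || object@resolution <= 0)
    return("resolution must be a single positive number (mm/voxel)")
  ok <- vapply(object@roots, is, logical(1), class2 = "RootNode")
  if (!all(ok))
    return("roots must all be RootNode objects")
  ids <- vapply(object@roots, function(r) r@id, integer(1))
  if (anyDuplicated(ids))
    return("root ids must be unique")
  if (length(ids) && object@nextId <= max(ids))
    return("nextId must exceed every assigned root id")
  TRUE
})

#' TrackingConfig: parameters of center-of-gravity tracking
#'
#' Controls the COG tracking interpolation. The tracker advances
#' \code{step} voxels toward the current target node, then snaps the new
#' interpolated node to the intensity-weighted center of gravity of
#' above-threshold voxels inside a forward-looking cone (half-angle
#' \code{coneHalfAngle} degrees, truncated at \code{searchRadius} voxels)
#' pointing toward the target.
#'
#' @slot step numeric, voxels advanced per COG correction (>= 1; default 4).
#' @slot searchRadius numeric, cone length in voxels (>= step; default 8).
#' @slot coneHalfAngle numeric, cone half-angle in degrees (0, 90].
#' @slot intensityThreshold numeric 8-bit value; a voxel counts as root
#'   when its intensity is >= this (default 1, i.e. any nonzero voxel).
#' @slot maxSteps numeric safety cap on tracking steps; NA means the
#'   default 10 * (volume diagonal) / step, resolved at run time.
#' @slot arrivalRadius numeric, distance to the target node that counts
#'   as reached (default = step).
#' @exportClass TrackingConfig
setClass("TrackingConfig",
  representation(step = "numeric", searchRadius = "numeric",
                 coneHalfAngle = "numeric", intensityThreshold = "numeric",
                 maxSteps = "numeric", arrivalRadius = "numeric"))

setValidity("TrackingConfig", function(object) {
  if (object@step < 1) return("step must be >= 1 voxel")
  if (object@searchRadius < object@step)
    return("searchRadius must be >= step")
  if (object@coneHalfAngle <= 0 || object@coneHalfAngle > 90)
    return("coneHalfAngle must be in (0, 90] degrees")
  if (object@intensityThreshold < 0 || object@intensityThreshold > 255)
    return("intensityThreshold must be in [0, 255]")
  if (object@arrivalRadius <= 0) return("arrivalRadius must be > 0")
  TRUE
})

#' PhantomSpec: recipe for a synthetic tubular root volume
#'
#' Describes a phantom: the volume shape and resolution, one tubular root
#' per centerline (straight, helix, sine, or cubic Bezier), and a noise
#' model (salt voxels set to 255 plus additive Gaussian noise, clipped to
#' [0, 255]) emulating the speckle left by soil voids in segmented CT
#' images.
#'
#' @slot shape integer(3), volume shape (depth, height, width) in voxels.
#' @slot resolution numeric(1), voxel resolution in mm.
#' @slot roots list of centerline descriptions; see
#'   \code{\link{phantomSpec}}.
#' @slot saltFraction numeric in [0, 0.5), fraction of voxels set to 255.
#' @slot gaussianSigma numeric >= 0, sd of additive Gaussian noise
#'   (intensity units).
#' @slot seed integer RNG seed used when applying noise.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(shape = "integer", resolution = "numeric", roots = "list",
                 saltFraction = "numeric", gaussianSigma = "numeric",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 1L))
    return("shape must be three positive voxel counts (depth, height, width)")
  if (object@resolution <= 0) return("resolution must be > 0")
  if (object@saltFraction < 0 || object@saltFraction >= 0.5)
    return("saltFraction must be in [0, 0.5)")
  if (object@gaussianSigma < 0) return("gaussianSigma must be >= 0")
  if (length(object@roots) < 1L)
    return("a phantom needs at least one root")
  TRUE
})
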