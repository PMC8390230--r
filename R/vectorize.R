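#' Tracking configuration constructor
#'
#' @param step voxels advanced per COG correction; the tracker corrects
#'   its position with the local root center of gravity every \code{step}
#'   voxels of travel (default 4).
#' @param searchRadius length of the forward-looking COG cone in voxels
#'   (default \code{2 * step}).
#' @param coneHalfAngle half-angle of the cone in degrees (default 45).
#' @param intensityThreshold 8-bit value; voxels with intensity >= this
#'   count as root (default 1).
#' @param maxSteps safety cap on tracking steps; \code{NA} resolves to
#'   \code{10 * (volume diagonal) / step} at run time.
#' @param arrivalRadius distance to the current target node that counts
#'   as reached (default = \code{step}).
#' @return A \linkS4class{TrackingConfig}.
#' @export
trackingConfig <- function(step = 4, searchRadius = 2 * step,
                           coneHalfAngle = 45, intensityThreshold = 1,
                           maxSteps = NA_real_, arrivalRadius = step) {
  new("TrackingConfig", step = as.numeric(step),
      searchRadius = as.numeric(searchRadius),
      coneHalfAngle = as.numeric(coneHalfAngle),
      intensityThreshold = as.numeric(intensityThreshold),
      maxSteps = as.numeric(maxSteps),
      arrivalRadius = as.numeric(arrivalRadius))
}

setMethod("show", "TrackingConfig", function(object) {
  cat(sprintf(paste0("TrackingConfig: step=%g searchRadius=%g ",
                     "coneHalfAngle=%g deg threshold=%g arrivalRadius=%g ",
                     "maxSteps=%s\n"),
              object@step, object@searchRadius, object@coneHalfAngle,
              object@intensityThreshold, object@arrivalRadius,
              if (is.na(object@maxSteps)) "auto" else
                format(object@maxSteps)))
})

#' Straight interpolation
#'
#' Connects the base node and the relay nodes, in order, into a straight
#' polyline. No vertices are added; duplicate consecutive nodes are
#' collapsed with a warning.
#'
#' @param base base node (x, y, z).
#' @param relays relay nodes, matrix or flat vector of (x, y, z) triples,
#'   base-to-tip order; at least one.
#' @return polyline matrix, columns x, y, z, running base to tip.
#' @export
straightInterpolate <- function(base, relays) {
  pts <- rbind(asXYZ(base, "base"), asXYZ(relays, "relays"))
  if (nrow(pts) < 2L) stop("need a base node and >= 1 relay", call. = FALSE)
  collapseDuplicates(pts)
}

#' Spline interpolation
#'
#' Fits an interpolating cubic parametric spline (zero smoothing) through
#' the base and relay nodes under chord-length parameterization and
#' samples it densely. All registered nodes appear among the output
#' vertices; the endpoints equal the base and last relay exactly. With
#' only two distinct nodes the result degenerates to the straight case.
#'
#' @inheritParams straightInterpolate
#' @param samplesPerSpan sampled vertices added per inter-node span
#'   (default 10).
#' @return polyline matrix, columns x, y, z, base to tip.
#' @export
splineInterpolate <- function(base, relays, samplesPerSpan = 10) {
  pts <- rbind(asXYZ(base, "base"), asXYZ(relays, "relays"))
  if (nrow(pts) < 2L) stop("need a base node and >= 1 relay", call. = FALSE)
  pts <- collapseDuplicates(pts, warn = FALSE)
  n <- nrow(pts)
  if (n == 2L) return(straightInterpolate(pts[1, ], pts[2, ]))
  # chord-length parameter
  t <- c(0, cumsum(segmentLengths(pts)))
  # sample each span at samplesPerSpan sub-intervals, knots included once
  ts <- unlist(lapply(seq_len(n - 1L), function(i) {
    s <- seq(t[i], t[i + 1L], length.out = samplesPerSpan + 1L)
    if (i < n - 1L) s[-length(s)] else s
  }))
  out <- sapply(1:3, function(d) {
    f <- stats::splinefun(t, pts[, d], method = "natural")
    f(ts)
  })
  out <- asXYZ(out)
  # knots evaluate exactly at machine precision; pin them verbatim anyway
  knotIdx <- cumsum(c(1L, rep(samplesPerSpan, n - 1L)))
  out[knotIdx, ] <- pts
  collapseDuplicates(out, warn = FALSE)
}

# 6-connected flood fill of a logical mask from seed indices (linear
# indices into the mask array). Returns the logical component array.
# 6-connectivity keeps sparse salt noise from percolating into the root
# segment, which it does under 26-connectivity at realistic noise levels.
floodFill6 <- function(mask, seedIdx) {
  comp <- array(FALSE, dim(mask))
  comp[seedIdx] <- mask[seedIdx]
  if (!any(comp)) return(comp)
  d <- dim(mask)
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
              c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  repeat {
    grown <- comp
    for (k in seq_len(nrow(nb))) {
      dz <- nb[k, 1]; dy <- nb[k, 2]; dx <- nb[k, 3]
      zs <- max(1, 1 + dz):min(d[1], d[1] + dz)
      ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
      xs <- max(1, 1 + dx):min(d[3], d[3] + dx)
      grown[zs, ys, xs] <- grown[zs, ys, xs] |
        comp[zs - dz, ys - dy, xs - dx]
    }
    grown <- grown & mask
    if (identical(grown, comp)) break
    comp <- grown
  }
  comp
}

# Intensity-weighted COG of the root segment inside the forward cone:
# apex `apex` (xyz), axis `dir` (unit xyz), half-angle `halfAngleDeg`,
# length `radius`. Voxel centers sit at index + 0.5. Above-threshold
# voxels 6-connected to the voxels under the tracker (within 2 voxels of
# the apex) form the root segment; the COG is taken over that component
# intersected with the cone, weighted by raw intensity. When no bright
# voxel sits under the tracker the component filter is skipped and all
# cone voxels enter. Returns xyz or NULL when the cone holds no root.
coneCOG <- function(volume, apex, dir, radius, halfAngleDeg, threshold) {
  d <- dim(volume@intensities)  # (depth, height, width) = (z, y, x)
  lim <- c(d[3], d[2], d[1])    # xyz extents
  lo <- pmax(0L, as.integer(floor(apex - radius - 0.5)))
  hi <- pmin(lim - 1L, as.integer(ceiling(apex + radius - 0.5)))
  if (any(hi < lo)) return(NULL)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  sub <- volume@intensities[zs + 1L, ys + 1L, xs + 1L, drop = FALSE]
  w <- as.numeric(sub)                    # z fastest, then y, then x
  cz <- rep(zs + 0.5, times = length(ys) * length(xs))
  cy <- rep(rep(ys + 0.5, each = length(zs)), times = length(xs))
  cx <- rep(xs + 0.5, each = length(zs) * length(ys))
  rx <- cx - apex[1]; ry <- cy - apex[2]; rz <- cz - apex[3]
  dist <- sqrt(rx * rx + ry * ry + rz * rz)
  proj <- rx * dir[1] + ry * dir[2] + rz * dir[3]
  bright <- w >= threshold
  inCone <- dist > 1e-9 & dist <= radius &
    proj / dist >= cos(halfAngleDeg * pi / 180)
  if (!any(bright & inCone)) return(NULL)
  # the correction uses the COG of the root segment: the tracker must sit
  # on (or within 2 voxels of) bright voxels, and only the component
  # 6-connected to them enters the COG. Without a segment under the
  # tracker there is nothing to correct toward (isolated noise voxels in
  # the cone must not steer the track), so the caller falls back to the
  # geometric step.
  seedIdx <- which(bright & dist <= 2)
  if (length(seedIdx) == 0L) return(NULL)
  mask <- array(bright, dim = dim(sub))
  comp <- as.vector(floodFill6(mask, seedIdx))
  keep <- comp & inCone
  if (!any(keep)) return(NULL)
  wk <- w[keep]
  c(sum(cx[keep] * wk), sum(cy[keep] * wk), sum(cz[keep] * wk)) / sum(wk)
}

#' Center-of-gravity (COG) tracking
#'
#' Traces a single root through the volume. Tracking starts at the relay
#' node farthest (Euclidean) from the base node and proceeds node by node
#' in base-ward order until the base node is reached. At each step the
#' tracker computes the intensity-weighted COG of the root segment (the
#' above-threshold voxels 6-connected to the voxels under the tracker)
#' inside a forward-looking cone, and advances \code{step} voxels along
#' the direction to that COG — the COG determines the tracking direction,
#' which keeps the polyline on the root even when the registered nodes
#' are sparse and the image is noisy. The cone is aimed along the current
#' direction of travel (base-ward), and re-aimed straight at the target
#' node at the start of each leg, once the target is within
#' \code{searchRadius}, or when the track stops closing in on it. When
#' the tracker comes within \code{arrivalRadius} of the target, the
#' target's exact coordinate is appended and tracking continues to the
#' next node. If no root voxel lies in the cone, the tracker falls back
#' to the pure geometric step toward the target (no node is appended;
#' consecutive geometric steps toward one target are collinear, so the
#' polyline is unchanged). On an all-zero volume the output therefore
#' equals \code{\link{straightInterpolate}}.
#'
#' @param volume a \linkS4class{RootVolume}.
#' @inheritParams straightInterpolate
#' @param config a \linkS4class{TrackingConfig}.
#' @return polyline matrix, columns x, y, z, reversed to run base to tip;
#'   every registered node appears verbatim among the vertices.
#' @export
cogTrack <- function(volume, base, relays, config = trackingConfig()) {
  validObject(config)
  base <- asXYZ(base, "base")[1, ]
  relays <- asXYZ(relays, "relays")
  nodes <- rbind(base, relays)  # registration order, base first
  d <- dim(volume@intensities)
  if (is.na(config@maxSteps)) {
    diag <- sqrt(sum(as.numeric(d)^2))
    maxSteps <- ceiling(10 * diag / config@step)
  } else maxSteps <- config@maxSteps
  # start at the relay farthest from the base (first occurrence on ties)
  dists <- sqrt(rowSums(sweep(relays, 2, base)^2))
  startIdx <- which.max(dists) + 1L  # row in `nodes`
  out <- list(nodes[startIdx, ])
  cur <- nodes[startIdx, ]
  steps <- 0L
  prev <- NULL  # last travel direction (momentum for the cone axis)
  for (tIdx in rev(seq_len(startIdx - 1L))) {
    target <- nodes[tIdx, ]
    lastDist <- Inf
    away <- 0L  # consecutive steps that failed to close in on the target
    repeat {
      dt <- vnorm(target - cur)
      if (dt <= config@arrivalRadius) {
        out[[length(out) + 1L]] <- target
        prev <- NULL  # each leg starts with the cone aimed at its target
        cur <- target
        break
      }
      away <- if (dt >= lastDist) away + 1L else 0L
      lastDist <- dt
      steps <- steps + 1L
      if (steps > maxSteps)
        stop("tracking did not converge", call. = FALSE)
      toTarget <- (target - cur) / dt
      if (away >= 3L) {
        # stalled (e.g. circling the end of a root segment): force a
        # geometric step toward the target to guarantee progress
        prev <- config@step * toTarget
        cur <- cur + prev
        away <- 0L
        next
      }
      # the cone looks along the direction of travel (base-ward) while
      # the track keeps closing in on the target; it is re-aimed straight
      # at the target at the start of a leg, once the target is within
      # reach of the search window, or after a step that lost ground
      dirv <- if (is.null(prev) || vnorm(prev) < 1e-9 || away > 0L ||
                  dt <= config@searchRadius) toTarget
              else prev / vnorm(prev)
      cog <- coneCOG(volume, cur, dirv, config@searchRadius,
                     config@coneHalfAngle, config@intensityThreshold)
      if (is.null(cog)) {
        prev <- config@step * toTarget  # geometric fallback, no node
        cur <- cur + prev
      } else {
        # the COG sets the travel direction; advance at most `step`
        dcog <- cog - cur
        ncog <- vnorm(dcog)
        new <- if (ncog > config@step) cur + config@step * dcog / ncog
               else cog
        prev <- new - cur
        cur <- new
        out[[length(out) + 1L]] <- cur
      }
    }
  }
  pts <- do.call(rbind, rev(out))  # reverse: tip->base becomes base->tip
  colnames(pts) <- c("x", "y", "z")
  collapseDuplicates(pts, warn = FALSE)
}

#' Vectorize one root of a tree
#'
#' Dispatches to the chosen interpolation algorithm and caches the
#' resulting polyline on the root node. Re-running with identical inputs
#' yields an identical polyline.
#'
#' @inheritParams getRoot
#' @param method "straight", "spline", or "cog".
#' @param volume a \linkS4class{RootVolume}; required for method "cog".
#' @param config a \linkS4class{TrackingConfig} (cog only).
#' @param samplesPerSpan sampled vertices per span (spline only).
#' @return The updated tree with the polyline cached on the root.
#' @export
vectorizeRoot <- function(tree, rootId,
                          method = c("straight", "spline", "cog"),
                          volume = NULL, config = trackingConfig(),
                          samplesPerSpan = 10) {
  method <- match.arg(method)
  i <- rootIndex(tree, rootId)
  node <- tree@roots[[i]]
  pl <- switch(method,
    straight = straightInterpolate(tree@base, node@relayNodes),
    spline = splineInterpolate(tree@base, node@relayNodes,
                               samplesPerSpan = samplesPerSpan),
    cog = {
      if (is.null(volume))
        stop("COG tracking requires a volume", call. = FALSE)
      cogTrack(volume, tree@base, node@relayNodes, config)
    })
  node@polyline <- pl
  node@interpolation <- method
  tree@roots[[i]] <- node
  tree
}

#' Vectorize every root of a tree
#'
#' @inheritParams vectorizeRoot
#' @return The updated tree.
#' @export
vectorizeAll <- function(tree, method = c("straight", "spline", "cog"),
                         volume = NULL, config = trackingConfig(),
                         samplesPerSpan = 10) {
  method <- match.arg(method)
  for (id in rootIds(tree))
    tree <- vectorizeRoot(tree, id, method, volume = volume,
                          config = config, samplesPerSpan = samplesPerSpan)
  tree
}
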