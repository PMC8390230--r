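#' Create an RSA tree
#'
#' Builds the depth-2 tree that represents a monocot root system: one base
#' node at the seed position, with single roots (radicle and crown roots)
#' added via \code{\link{addRoot}}, each holding its relay nodes.
#'
#' @param base base node position (x, y, z), voxel units (where the seed
#'   was sown).
#' @param resolution voxel resolution in mm/voxel.
#' @param annotations optional named list of free-form strings (cultivar,
#'   days after sowing, ...).
#' @return An \linkS4class{RSATree} with no roots.
#' @examples
#' tr <- RSATree(base = c(32, 32, 2), resolution = 0.3)
#' tr <- addRoot(tr, rbind(c(30, 30, 10), c(25, 28, 40)))
#' nRoots(tr)
#' @export
RSATree <- function(base, resolution, annotations = list()) {
  new("RSATree", base = as.numeric(asXYZ(base, "base")[1, ]),
      roots = list(), resolution = as.numeric(resolution),
      annotations = annotations, nextId = 1L)
}

#' Number of single roots N in the tree
#' @param tree an \linkS4class{RSATree}.
#' @return integer count.
#' @export
nRoots <- function(tree) length(tree@roots)

#' Root identifiers in registration order
#' @inheritParams nRoots
#' @return integer vector of root ids.
#' @export
rootIds <- function(tree) vapply(tree@roots, function(r) r@id, integer(1))

#' Base node position of the tree
#' @inheritParams nRoots
#' @return numeric(3), (x, y, z) in voxel units.
#' @export
baseNode <- function(tree) tree@base

#' @rdname intensities
#' @export
setMethod("resolutionMM", "RSATree", function(x) x@resolution)

#' Annotations attached to a tree
#' @inheritParams nRoots
#' @return named list.
#' @export
annotations <- function(tree) tree@annotations

rootIndex <- function(tree, rootId) {
  i <- match(as.integer(rootId), rootIds(tree))
  if (is.na(i)) stop("no root with id ", rootId, call. = FALSE)
  i
}

#' Fetch one root node
#' @inheritParams nRoots
#' @param rootId integer root id.
#' @return A \linkS4class{RootNode}.
#' @export
getRoot <- function(tree, rootId) tree@roots[[rootIndex(tree, rootId)]]

#' Relay nodes of one root
#' @inheritParams getRoot
#' @return numeric matrix, columns x, y, z, one row per relay node.
#' @export
relayNodes <- function(tree, rootId) getRoot(tree, rootId)@relayNodes

#' Cached polyline of one root
#' @inheritParams getRoot
#' @return numeric matrix (columns x, y, z) or NULL if not vectorized yet.
#' @export
rootPolyline <- function(tree, rootId) getRoot(tree, rootId)@polyline

#' Register a single root
#'
#' Adds one root (inner node) described by its ordered relay nodes — the
#' points an operator registered along the root, typically at least both
#' ends of the root segment. N increments by one; the new root's id is
#' \code{nextRootId(tree)} before the call.
#'
#' @inheritParams nRoots
#' @param relayNodes numeric matrix (or flat vector) of (x, y, z) relay
#'   nodes in base-to-tip order; at least one node.
#' @param interpolation default interpolation method recorded for the
#'   root: "straight", "spline", or "cog".
#' @return The updated tree.
#' @export
addRoot <- function(tree, relayNodes, interpolation = "straight") {
  if (is.null(relayNodes) || length(relayNodes) == 0L)
    stop("root requires at least one node", call. = FALSE)
  rn <- asXYZ(relayNodes, "relay nodes")
  node <- new("RootNode", id = tree@nextId, relayNodes = rn,
              interpolation = interpolation, polyline = NULL)
  tree@roots <- c(tree@roots, list(node))
  tree@nextId <- tree@nextId + 1L
  validObject(tree)
  tree
}

#' Id that the next registered root will receive
#' @inheritParams nRoots
#' @return integer.
#' @export
nextRootId <- function(tree) tree@nextId

#' Remove a single root
#'
#' The root's id is retired, never reused.
#'
#' @inheritParams getRoot
#' @return The updated tree.
#' @export
removeRoot <- function(tree, rootId) {
  tree@roots[[rootIndex(tree, rootId)]] <- NULL
  tree
}

setMethod("show", "RSATree", function(object) {
  cat(sprintf("RSATree: %d single root(s), base at (%g, %g, %g)\n",
              nRoots(object), object@base[1], object@base[2],
              object@base[3]))
  cat(sprintf("  resolution: %g mm/voxel\n", object@resolution))
  for (r in object@roots)
    cat(sprintf("  root %d: %d relay node(s), %s%s\n", r@id,
                nrow(r@relayNodes), r@interpolation,
                if (is.null(r@polyline)) "" else
                  sprintf(", polyline of %d vertices", nrow(r@polyline))))
})

## ---- rinfo JSON persistence -------------------------------------------

coordList <- function(m) unname(lapply(seq_len(nrow(m)),
                                       function(i) as.numeric(m[i, ])))

#' Serialize an RSA tree to rinfo JSON
#'
#' The rinfo ("root information") format is a small self-describing JSON
#' object: \code{{"format": "rinfo", "version": 1, "resolution_mm": r,
#' "base": {"xyz": [x,y,z]}, "roots": [{"id", "interpolation",
#' "relay_nodes", "polyline"}], "annotations": {}}}. Coordinates are in
#' voxel units with the resolution alongside, so physical traits stay
#' recomputable.
#'
#' @inheritParams nRoots
#' @return a JSON string.
#' @seealso \code{\link{fromRinfo}}, \code{\link{writeRinfo}}
#' @export
toRinfo <- function(tree) {
  roots <- lapply(tree@roots, function(r) list(
    id = r@id,
    interpolation = r@interpolation,
    relay_nodes = coordList(r@relayNodes),
    polyline = if (is.null(r@polyline)) NULL else coordList(r@polyline)))
  obj <- list(format = "rinfo", version = 1L,
              resolution_mm = tree@resolution,
              base = list(xyz = as.numeric(tree@base)),
              roots = roots,
              annotations = tree@annotations)
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
}

rinfoFail <- function(path) stop("invalid rinfo: ", path, call. = FALSE)

rinfoCoords <- function(x, path, minRows = 1L) {
  if (is.null(x)) rinfoFail(path)
  m <- tryCatch({
    if (is.matrix(x)) x else do.call(rbind, lapply(x, as.numeric))
  }, error = function(e) rinfoFail(path))
  if (!is.numeric(m) || is.null(dim(m)) || ncol(m) != 3L ||
      nrow(m) < minRows || any(!is.finite(m)))
    rinfoFail(path)
  asXYZ(m)
}

#' Parse rinfo JSON into an RSA tree
#'
#' Validates against the rinfo schema; a malformed document raises
#' \code{"invalid rinfo: <path to offending field>"}.
#'
#' @param text a JSON string (as produced by \code{\link{toRinfo}}).
#' @return An \linkS4class{RSATree}.
#' @export
fromRinfo <- function(text) {
  obj <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e) stop("invalid rinfo: not JSON",
                                           call. = FALSE))
  if (!identical(obj$format, "rinfo")) rinfoFail("format")
  if (is.null(obj$version) || obj$version != 1) rinfoFail("version")
  r <- obj$resolution_mm
  if (!is.numeric(r) || length(r) != 1L || r <= 0) rinfoFail("resolution_mm")
  if (is.null(obj$base) || is.null(obj$base$xyz)) rinfoFail("base.xyz")
  base <- rinfoCoords(list(obj$base$xyz), "base.xyz")[1, ]
  ann <- obj$annotations
  if (is.null(ann)) ann <- list()
  tree <- RSATree(base, r, annotations = ann)
  if (is.null(obj$roots)) rinfoFail("roots")
  maxId <- 0L
  for (k in seq_along(obj$roots)) {
    ro <- obj$roots[[k]]
    p <- sprintf("roots[%d]", k)
    if (is.null(ro$id) || is.null(ro$interpolation)) rinfoFail(p)
    if (!ro$interpolation %in% c("straight", "spline", "cog"))
      rinfoFail(paste0(p, ".interpolation"))
    rn <- rinfoCoords(ro$relay_nodes, paste0(p, ".relay_nodes"))
    pl <- if (is.null(ro$polyline)) NULL else
      rinfoCoords(ro$polyline, paste0(p, ".polyline"), minRows = 2L)
    node <- new("RootNode", id = as.integer(ro$id), relayNodes = rn,
                interpolation = ro$interpolation, polyline = pl)
    tree@roots <- c(tree@roots, list(node))
    maxId <- max(maxId, node@id)
  }
  tree@nextId <- maxId + 1L
  validObject(tree)
  tree
}

#' Write / read rinfo files
#'
#' @inheritParams nRoots
#' @param path file path (conventionally with extension ".rinfo").
#' @return \code{writeRinfo}: the path, invisibly. \code{readRinfo}: an
#'   \linkS4class{RSATree}.
#' @export
writeRinfo <- function(tree, path) {
  writeLines(toRinfo(tree), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname writeRinfo
#' @export
readRinfo <- function(path) {
  fromRinfo(paste(readLines(path, warn = FALSE), collapse = "\n"))
}
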