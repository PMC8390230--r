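#' Construct a RootVolume
#'
#' @param intensities numeric or integer 3D array, dim
#'   \code{(depth, height, width)}, values 0..255.
#' @param resolution voxel resolution in mm/voxel (> 0).
#' @return A \linkS4class{RootVolume}.
#' @examples
#' v <- RootVolume(array(0L, c(4, 8, 8)), resolution = 0.3)
#' dim(v)
#' @export
RootVolume <- function(intensities, resolution) {
  a <- as.array(intensities)
  storage.mode(a) <- "integer"
  new("RootVolume", intensities = a, resolution = as.numeric(resolution))
}

#' @describeIn RootVolume-class volume shape (depth, height, width) in voxels.
#' @param x a RootVolume.
#' @export
setMethod("dim", "RootVolume", function(x) dim(x@intensities))

#' @rdname intensities
#' @export
setMethod("intensities", "RootVolume", function(x) x@intensities)

#' @rdname intensities
#' @export
setMethod("resolutionMM", "RootVolume", function(x) x@resolution)

setMethod("show", "RootVolume", function(object) {
  d <- dim(object)
  cat(sprintf("RootVolume: %d x %d x %d voxels (depth x height x width)\n",
              d[1], d[2], d[3]))
  cat(sprintf("  resolution: %g mm/voxel\n", object@resolution))
  cat(sprintf("  intensity range: [%d, %d]\n",
              min(object@intensities), max(object@intensities)))
})

supportedSliceExt <- c("png", "tif", "tiff", "jpg", "jpeg")

# Read one slice file as a numeric matrix of 8-bit intensities, or the
# raw higher-depth values flagged for later rescaling.
readSlice <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]  # first channel of RGB(A)
    v <- img * 255
    if (max(abs(v - round(v))) < 1e-6)
      return(list(values = round(v), is8bit = TRUE))
    # 16-bit PNG: readPNG scaled by 65535
    return(list(values = img * 65535, is8bit = FALSE))
  }
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    return(list(values = img, is8bit = max(img) <= 255))
  }
  if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("reading JPEG slices requires the EBImage package", call. = FALSE)
    img <- EBImage::imageData(EBImage::readImage(path))
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    img <- t(img)  # EBImage stores (x, y); we want (row = y, col = x)
    return(list(values = round(img * 255), is8bit = TRUE))
  }
  stop("unsupported slice format: ", basename(path), call. = FALSE)
}

#' Load a directory of grayscale slice images as a 3D volume
#'
#' Slice files (PNG, TIFF, or JPEG) are stacked in lexicographic filename
#' order; the z index equals the stack position, with z = 0 the topmost
#' slice (soil surface) and z increasing with depth. 8-bit values are
#' preserved exactly. Inputs at a higher bit depth are min-max rescaled
#' to 0..255 with a warning.
#'
#' @param directory path containing one image file per horizontal plane.
#' @param resolution voxel resolution in mm/voxel.
#' @return A \linkS4class{RootVolume}.
#' @seealso \code{\link{writeVolume}}, \code{\link{projectVolume}}
#' @export
loadVolume <- function(directory, resolution) {
  if (!dir.exists(directory))
    stop("no slices found: directory does not exist: ", directory,
         call. = FALSE)
  files <- list.files(directory,
                      pattern = paste0("\\.(", paste(supportedSliceExt,
                                                     collapse = "|"), ")$"),
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0L)
    stop("no slices found in ", directory, call. = FALSE)
  files <- files[order(basename(files), method = "radix")]
  slices <- lapply(files, readSlice)
  shapes <- vapply(slices, function(s) dim(s$values), integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("inconsistent slice dimensions across ", directory, call. = FALSE)
  vol <- array(0, dim = c(length(slices), shapes[1, 1], shapes[2, 1]))
  for (k in seq_along(slices)) vol[k, , ] <- slices[[k]]$values
  if (!all(vapply(slices, `[[`, logical(1), "is8bit")) || max(vol) > 255) {
    warning("non-8-bit input rescaled to 8-bit (min-max)", call. = FALSE)
    rng <- range(vol)
    vol <- if (diff(rng) == 0) vol * 0 else
      round((vol - rng[1]) / diff(rng) * 255)
  }
  RootVolume(vol, resolution)
}

#' Project a volume onto a plane
#'
#' Per-pixel maximum (or mean) intensity along one axis, the computation
#' behind a projection image used for visual QC of the vectorization.
#'
#' @param volume a \linkS4class{RootVolume}.
#' @param axis one of "z", "y", "x": the axis collapsed.
#' @param mode "max" (maximum intensity projection) or "mean".
#' @return An integer matrix of 8-bit values. For axis "z" the result is
#'   (height x width); for "y", (depth x width); for "x", (depth x height).
#' @export
projectVolume <- function(volume, axis = c("z", "y", "x"),
                          mode = c("max", "mean")) {
  axis <- match.arg(axis)
  mode <- match.arg(mode)
  a <- volume@intensities
  margin <- switch(axis, z = c(2L, 3L), y = c(1L, 3L), x = c(1L, 2L))
  f <- if (mode == "max") max else mean
  img <- apply(a, margin, f)
  img <- round(img)
  storage.mode(img) <- "integer"
  img
}

#' Write a projection image as PNG
#'
#' @param image integer matrix of 8-bit values, as from
#'   \code{\link{projectVolume}}.
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
writeProjection <- function(image, path) {
  png::writePNG(image / 255, target = path)
  invisible(path)
}
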