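#' Accessors for rootvec containers
#'
#' \code{intensities} returns a volume's raw integer array indexed
#' (z, y, x); \code{resolutionMM} the voxel resolution in mm/voxel of a
#' volume or tree.
#'
#' @param x a \linkS4class{RootVolume} or \linkS4class{RSATree}.
#' @return the array, or the resolution as numeric(1).
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname intensities
#' @export
setGeneric("resolutionMM", function(x) standardGeneric("resolutionMM"))
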