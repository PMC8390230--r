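#' Root growth angle
#'
#' Angle between the horizontal plane and the chord connecting the two
#' end vertices of a root polyline:
#' \deqn{\theta = \tan^{-1}\!\left(\frac{|z_n - z_1|}
#'   {\sqrt{(x_n - x_1)^2 + (y_n - y_1)^2}}\right)}
#' Only the end vertices enter; a vertically plunging root (zero
#' horizontal displacement) gives \eqn{\pi/2}.
#'
#' @param polyline matrix of vertices (columns x, y, z), base to tip.
#' @return angle in radians, in \eqn{[0, \pi/2]}.
#' @export
rootGrowthAngle <- function(polyline) {
  stopIfNotPolyline(polyline)
  p1 <- polyline[1, ]
  pn <- polyline[nrow(polyline), ]
  dz <- abs(pn[3] - p1[3])
  dh <- sqrt((pn[1] - p1[1])^2 + (pn[2] - p1[2])^2)
  if (dh == 0) return(pi / 2)
  unname(atan(dz / dh))
}

#' Root length
#'
#' Cumulative Euclidean distance over consecutive polyline vertices,
#' scaled from voxels to cm:
#' \deqn{L = \frac{r}{10} \sum_{i=1}^{n-1}
#'   \sqrt{(x_{i+1}-x_i)^2 + (y_{i+1}-y_i)^2 + (z_{i+1}-z_i)^2}}
#' with r the voxel resolution in mm/voxel.
#'
#' @inheritParams rootGrowthAngle
#' @param resolution voxel resolution r in mm/voxel (> 0).
#' @return length in cm.
#' @export
rootLength <- function(polyline, resolution) {
  stopIfNotPolyline(polyline)
  if (resolution <= 0) stop("resolution must be > 0", call. = FALSE)
  resolution / 10 * polylineLengthVoxels(polyline)
}

#' Average root growth angle of an RSA
#'
#' \deqn{\bar\theta = \frac{1}{N} \sum_{I=1}^{N} \theta_I}
#'
#' @param angles numeric vector of per-root growth angles, radians.
#' @return mean angle in radians.
#' @export
averageGrowthAngle <- function(angles) {
  if (length(angles) == 0L) stop("no roots", call. = FALSE)
  mean(angles)
}

#' Total root length of an RSA
#'
#' \deqn{TL = \sum_{I=1}^{N} L_I}
#'
#' @param lengths numeric vector of per-root lengths, cm.
#' @return total length in cm.
#' @export
totalRootLength <- function(lengths) {
  if (length(lengths) == 0L) stop("no roots", call. = FALSE)
  sum(lengths)
}

#' Resample a polyline at voxel resolution
#'
#' Linear resampling along the polyline so consecutive output vertices
#' are at most 1 voxel apart: each segment is walked in arc-length steps
#' of exactly \code{spacing} voxels, and the original vertices are
#' retained. Geometry (and hence total length) is preserved because every
#' inserted vertex lies on an existing segment.
#'
#' @inheritParams rootGrowthAngle
#' @param spacing arc-length step in voxels (default 1).
#' @return resampled polyline matrix.
#' @export
resamplePolyline <- function(polyline, spacing = 1) {
  stopIfNotPolyline(polyline)
  out <- list(polyline[1, ])
  for (i in seq_len(nrow(polyline) - 1L)) {
    a <- polyline[i, ]
    b <- polyline[i + 1L, ]
    s <- vnorm(b - a)
    if (s > spacing + 1e-12) {
      k <- seq(spacing, s - 1e-12, by = spacing)
      for (t in k / s) out[[length(out) + 1L]] <- a + t * (b - a)
    }
    out[[length(out) + 1L]] <- b
  }
  pts <- do.call(rbind, out)
  colnames(pts) <- c("x", "y", "z")
  collapseDuplicates(pts, warn = FALSE)
}

#' Root distribution index (RDI)
#'
#' The depth centroid of the vertical root distribution, in cm — larger
#' values mean deeper rooting:
#' \deqn{RDI = \frac{r}{10}\left[\frac{1}{N}\sum_{I=1}^{N}
#'   \left\{\frac{1}{n'_I}\sum_{i=1}^{n'_I} z_{(I,i)}\right\}
#'   - z_b\right]}
#' where \eqn{z_{(I,i)}} are the vertex depths of the I-th root polyline
#' after resampling at voxel resolution (\eqn{n'_I} vertices) and
#' \eqn{z_b} is the base node depth. Roots reaching above the base node
#' contribute negatively and are averaged as-is.
#'
#' @param polylines list of polyline matrices, each already resampled at
#'   voxel resolution (see \code{\link{resamplePolyline}}).
#' @param baseZ depth z_b of the base node, voxels.
#' @param resolution voxel resolution r in mm/voxel.
#' @return RDI in cm.
#' @export
rdi <- function(polylines, baseZ, resolution) {
  if (length(polylines) == 0L) stop("no roots", call. = FALSE)
  perRoot <- vapply(polylines, function(pl) mean(pl[, 3]), numeric(1))
  resolution / 10 * (mean(perRoot) - baseZ)
}

#' Per-root traits of a vectorized tree
#'
#' @inheritParams nRoots
#' @return data.frame with one row per root: root_id, method, theta_rad,
#'   theta_deg, length_cm.
#' @export
singleRootTraits <- function(tree) {
  rows <- lapply(tree@roots, function(r) {
    if (is.null(r@polyline))
      stop("vectorize before export: root ", r@id, call. = FALSE)
    th <- rootGrowthAngle(r@polyline)
    data.frame(root_id = r@id, method = r@interpolation,
               theta_rad = th, theta_deg = th * 180 / pi,
               length_cm = rootLength(r@polyline, tree@resolution))
  })
  if (length(rows) == 0L)
    return(data.frame(root_id = integer(), method = character(),
                      theta_rad = numeric(), theta_deg = numeric(),
                      length_cm = numeric()))
  do.call(rbind, rows)
}

#' RSA-level traits of a vectorized tree
#'
#' Mean growth angle, total root length, and RDI (polylines are resampled
#' at voxel resolution before the RDI depth averaging).
#'
#' @inheritParams nRoots
#' @return list with n_roots, mean_theta_rad, mean_theta_deg,
#'   total_length_cm, rdi_cm (the trait fields are NA when n_roots is 0).
#' @export
rsaTraits <- function(tree) {
  per <- singleRootTraits(tree)
  if (nrow(per) == 0L)
    return(list(n_roots = 0L, mean_theta_rad = NA_real_,
                mean_theta_deg = NA_real_, total_length_cm = NA_real_,
                rdi_cm = NA_real_))
  resampled <- lapply(tree@roots, function(r) resamplePolyline(r@polyline))
  th <- averageGrowthAngle(per$theta_rad)
  list(n_roots = nrow(per),
       mean_theta_rad = th,
       mean_theta_deg = th * 180 / pi,
       total_length_cm = totalRootLength(per$length_cm),
       rdi_cm = rdi(resampled, tree@base[3], tree@resolution))
}

fmt6 <- function(x) {
  if (length(x) == 0L) return(character(0))
  ifelse(is.na(x), "", vapply(x, function(v) format(signif(v, 6)),
                              character(1)))
}

#' Export traits as CSV
#'
#' Writes two RFC 4180 CSV files into \code{dir}: \code{roots.csv} with
#' one row per root (root_id, method, theta_deg, length_cm) and
#' \code{summary.csv} with one row (n_roots, mean_theta_deg,
#' total_length_cm, rdi_cm). Numbers are printed with 6 significant
#' digits. An empty tree yields a summary row with n_roots = 0 and empty
#' trait fields.
#'
#' @inheritParams nRoots
#' @param dir output directory (created if missing).
#' @return character(2) of file paths, invisibly.
#' @export
exportTraitsCsv <- function(tree, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  per <- singleRootTraits(tree)
  rsa <- rsaTraits(tree)
  perOut <- data.frame(root_id = per$root_id, method = per$method,
                       theta_deg = fmt6(per$theta_deg),
                       length_cm = fmt6(per$length_cm))
  perPath <- file.path(dir, "roots.csv")
  utils::write.csv(perOut, perPath, row.names = FALSE, quote = FALSE)
  sumOut <- data.frame(n_roots = rsa$n_roots,
                       mean_theta_deg = fmt6(rsa$mean_theta_deg),
                       total_length_cm = fmt6(rsa$total_length_cm),
                       rdi_cm = fmt6(rsa$rdi_cm))
  sumPath <- file.path(dir, "summary.csv")
  utils::write.csv(sumOut, sumPath, row.names = FALSE, quote = FALSE)
  invisible(c(perPath, sumPath))
}
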