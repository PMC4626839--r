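#' Voxel mask: a 3D binary occupancy grid with physical spacing
#'
#' The basic measurable object: a logical 3D array whose voxel centres sit at
#' `origin + (index - 0.5) * spacing` (0-based index + 0.5), all in mm.
#' Anisotropic spacing is allowed; all geometry downstream works in physical
#' mm coordinates, never in index space.
#'
#' @param occupancy 3D logical (or coercible) array.
#' @param spacing voxel spacing in mm; scalar or length-3, all > 0.
#' @param origin physical coordinate (mm) of the corner of voxel (1,1,1).
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(occupancy, spacing, origin = c(0, 0, 0)) {
  if (length(dim(occupancy)) != 3L)
    stop("`occupancy` must be a 3D array")
  if (!is.logical(occupancy)) {
    occupancy <- array(as.logical(occupancy), dim = dim(occupancy))
  }
  if (anyNA(occupancy)) stop("`occupancy` must not contain NA")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all spacing components must be > 0")
  origin <- rep_len(as.numeric(origin), 3L)
  structure(list(occupancy = occupancy, spacing = spacing, origin = origin),
            class = "voxel_mask")
}

#' CT-like scalar volume
#'
#' @param intensity 3D numeric array of finite attenuation-like values.
#' @param spacing voxel spacing in mm (scalar or length-3, > 0).
#' @param origin physical coordinate (mm) of the corner of voxel (1,1,1).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(intensity, spacing, origin = c(0, 0, 0)) {
  if (length(dim(intensity)) != 3L) stop("`intensity` must be a 3D array")
  storage.mode(intensity) <- "double"
  if (any(!is.finite(intensity))) stop("intensity values must be finite")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all spacing components must be > 0")
  origin <- rep_len(as.numeric(origin), 3L)
  structure(list(intensity = intensity, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$occupancy)
  cat(sprintf("<voxel_mask> %d x %d x %d voxels, spacing %s mm, %d occupied (%.2f mm^3)\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              sum(x$occupancy), mask_volume(x)))
  invisible(x)
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %s mm, intensity [%.3g, %.3g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' Voxel-count volume of a mask
#'
#' Number of occupied voxels times the voxel volume, in mm^3. This is the
#' Cavalieri-style reference measure the Fakir estimator converges to as the
#' grid spacing shrinks to the voxel size.
#'
#' @param mask a [voxel_mask].
#' @return volume in mm^3.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  sum(mask$occupancy) * prod(mask$spacing)
}

#' Voxel-face surface area of a mask
#'
#' Total area of voxel faces separating occupied from unoccupied voxels
#' (array borders count as unoccupied). Note this measures the digitized
#' staircase boundary, which systematically exceeds the smooth surface area;
#' it is reported as a crude reference, not an unbiased estimate.
#'
#' @param mask a [voxel_mask].
#' @return surface area in mm^2.
#' @export
mask_voxel_surface <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  occ <- mask$occupancy
  sp <- mask$spacing
  d <- dim(occ)
  # exposed faces along each axis; pad with background at borders
  exposed <- function(axis) {
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    a <- aperm(occ, perm)
    n <- dim(a)[1]
    pad <- array(FALSE, dim = c(1, dim(a)[2], dim(a)[3]))
    lo <- array(c(pad, a), dim = dim(a) + c(1, 0, 0))    # shifted
    hi <- array(c(a, pad), dim = dim(a) + c(1, 0, 0))
    sum(lo != hi)
  }
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  sum(vapply(1:3, exposed, numeric(1)) * face_area)
}

# Physical-coordinate bounding box (2 x 3 matrix: rows lo, hi) of the
# occupied region, optionally padded by `margin` mm on every side.
mask_bbox <- function(mask, margin = 0) {
  occ <- mask$occupancy
  if (!any(occ)) return(NULL)
  idx <- which(occ, arr.ind = TRUE)
  lo <- (apply(idx, 2, min) - 1) * mask$spacing + mask$origin - margin
  hi <- apply(idx, 2, max) * mask$spacing + mask$origin + margin
  rbind(lo = lo, hi = hi)
}
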