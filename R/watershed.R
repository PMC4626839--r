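#' Otsu threshold of a numeric array
#'
#' Exhaustive search over histogram bin boundaries for the cutoff maximizing
#' the between-class variance of the two resulting intensity classes.
#'
#' @param x numeric vector or array of finite values.
#' @param n_bins histogram resolution (default 256).
#' @return the threshold value.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- as.numeric(x)
  rng <- range(x)
  if (rng[1] == rng[2]) stop("constant image: no threshold separates two classes")
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  omega <- cumsum(p)                 # class-0 mass up to each cut
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  valid <- omega > 0 & omega < 1
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[valid] <- (mu_t * omega[valid] - mu[valid])^2 /
    (omega[valid] * (1 - omega[valid]))
  k <- which.max(sigma_b)
  br[k + 1]                          # upper edge of the last class-0 bin
}

#' Threshold a CT volume into a bone mask
#'
#' @param ct a [ct_volume()].
#' @param mode `"auto"` (Otsu between-class-variance threshold) or `"fixed"`.
#' @param value cutoff for `mode = "fixed"`; voxels with intensity >= value
#'   are bone.
#' @return a [voxel_mask()] of bone voxels, with the threshold used attached
#'   as attribute `"threshold"`.
#' @export
threshold_bone <- function(ct, mode = c("auto", "fixed"), value = NULL) {
  stopifnot(inherits(ct, "ct_volume"))
  mode <- match.arg(mode)
  thr <- if (mode == "auto") otsu_threshold(ct$intensity) else {
    if (is.null(value)) stop("`value` required for mode = \"fixed\"")
    value
  }
  m <- voxel_mask(ct$intensity >= thr, ct$spacing, ct$origin)
  attr(m, "threshold") <- thr
  m
}

#' Euclidean distance map of a mask
#'
#' Exact distance in mm from every voxel centre to the nearest occupied
#' voxel centre, honouring anisotropic spacing (separable lower-envelope
#' algorithm). `Inf` everywhere if the mask is empty.
#'
#' @param mask a [voxel_mask()].
#' @return numeric array of distances (mm), same shape as the mask.
#' @export
distance_map <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  d <- edt_cpp(mask$occupancy, dim(mask$occupancy), mask$spacing)
  array(d, dim = dim(mask$occupancy))
}

#' Build a watershed relief
#'
#' `"gradient"` mode takes a [ct_volume()] and returns the gradient magnitude
#' of the intensity by mm-aware central differences (one-sided at borders);
#' basins form inside homogeneous regions. `"distance"` mode takes a bone
#' [voxel_mask()] and returns the negated distance-to-bone transform, so
#' cavity centres (far from bone) are the deepest basin minima; this is the
#' robust choice for binary-bone inputs whose gradients are degenerate.
#'
#' @param source a `ct_volume` (gradient mode) or `voxel_mask` (distance mode).
#' @param mode `"distance"` (default) or `"gradient"`.
#' @return numeric 3D array (the relief).
#' @export
build_relief <- function(source, mode = c("distance", "gradient")) {
  mode <- match.arg(mode)
  if (mode == "gradient") {
    if (!inherits(source, "ct_volume"))
      stop("gradient relief needs a `ct_volume`")
    g2 <- 0
    for (ax in 1:3) {
      g2 <- g2 + axis_gradient(source$intensity, ax, source$spacing[ax])^2
    }
    sqrt(g2)
  } else {
    if (!inherits(source, "voxel_mask"))
      stop("distance relief needs a `voxel_mask`")
    -distance_map(source)
  }
}

# central differences along one axis (one-sided at the two border slices)
axis_gradient <- function(a, axis, h) {
  n <- dim(a)[axis]
  if (n == 1) return(array(0, dim = dim(a)))
  idx_up <- pmin(seq_len(n) + 1L, n)
  idx_dn <- pmax(seq_len(n) - 1L, 1L)
  denom <- (idx_up - idx_dn) * h
  up <- switch(axis, a[idx_up, , , drop = FALSE],
               a[, idx_up, , drop = FALSE], a[, , idx_up, drop = FALSE])
  dn <- switch(axis, a[idx_dn, , , drop = FALSE],
               a[, idx_dn, , drop = FALSE], a[, , idx_dn, drop = FALSE])
  sweep_denom <- array(0, dim = dim(a))
  if (axis == 1) sweep_denom[] <- denom else if (axis == 2)
    sweep_denom[] <- rep(denom, each = dim(a)[1]) else
    sweep_denom[] <- rep(denom, each = dim(a)[1] * dim(a)[2])
  (up - dn) / sweep_denom
}

#' Marker set for watershed flooding
#'
#' @param dim integer length-3 array dimensions.
#' @param cavity matrix (or length-3 vector) of 1-based voxel indices seeding
#'   the cavity basin.
#' @param exterior same, seeding the exterior basin; the default `"border"`
#'   marks every face voxel of the volume.
#' @return integer array; 0 = unlabeled, 1 = cavity, 2 = exterior.
#' @export
marker_set <- function(dim, cavity, exterior = "border") {
  mk <- array(0L, dim = dim)
  if (identical(exterior, "border")) {
    mk[c(1, dim[1]), , ] <- 2L
    mk[, c(1, dim[2]), ] <- 2L
    mk[, , c(1, dim[3])] <- 2L
  } else {
    mk[rbind(exterior)] <- 2L
  }
  cavity <- rbind(cavity)
  if (any(mk[cavity] == 2L)) stop("cavity and exterior markers overlap")
  mk[cavity] <- 1L
  if (!any(mk == 1L) || !any(mk == 2L))
    stop("both cavity and exterior markers must be nonempty")
  mk
}

#' Marker-based priority-flood watershed
#'
#' Floods the relief from the marker voxels with a minimum-relief priority
#' queue: the queue is seeded with the markers (in ascending linear-index
#' order), the voxel with the lowest relief is popped and fixed to the label
#' of the neighbour that first claimed it, and its unclaimed neighbours are
#' pushed. Ties in relief are broken by queue insertion order, which makes
#' the result deterministic. Every voxel ends up labeled.
#'
#' @param relief numeric 3D array of finite values.
#' @param markers integer array of the same shape; 0 = unlabeled, positive
#'   values = seed labels (see [marker_set()]).
#' @param connectivity 6 (faces only, default) or 26.
#' @return integer label array of the same shape.
#' @export
watershed_labels <- function(relief, markers, connectivity = 6) {
  stopifnot(length(dim(relief)) == 3, all(dim(relief) == dim(markers)))
  if (any(!is.finite(relief))) stop("relief must be finite")
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  lab <- watershed_cpp(as.numeric(relief), dim(relief),
                       as.integer(markers), as.integer(connectivity))
  array(lab, dim = dim(relief))
}

#' Morphological closing of a mask with a Euclidean ball
#'
#' Dilation followed by erosion with a ball of radius `radius_mm`, both via
#' exact distance transforms (dilate: distance-to-mask <= r; erode:
#' distance-to-complement > r). Closing seals openings narrower than the
#' ball diameter (e.g. cranial foramina) while leaving surfaces whose
#' curvature radius exceeds `radius_mm` in place.
#'
#' @param mask a [voxel_mask()].
#' @param radius_mm ball radius in mm; 0 returns the mask unchanged.
#' @return the closed [voxel_mask()].
#' @export
close_mask <- function(mask, radius_mm) {
  stopifnot(inherits(mask, "voxel_mask"), radius_mm >= 0)
  if (radius_mm == 0 || !any(mask$occupancy)) return(mask)
  # pad with background so the dilated set is eroded against the (conceptual)
  # open space beyond the array as well
  p <- ceiling(radius_mm / mask$spacing) + 1L
  d <- dim(mask$occupancy)
  occ <- array(FALSE, dim = d + 2 * p)
  occ[p[1] + seq_len(d[1]), p[2] + seq_len(d[2]), p[3] + seq_len(d[3])] <-
    mask$occupancy
  pm <- voxel_mask(occ, mask$spacing)
  dil <- distance_map(pm) <= radius_mm
  inv <- voxel_mask(!dil, mask$spacing)
  closed <- distance_map(inv) > radius_mm
  closed <- closed[p[1] + seq_len(d[1]), p[2] + seq_len(d[2]),
                   p[3] + seq_len(d[3])]
  voxel_mask(closed, mask$spacing, mask$origin)
}

#' Extract a cavity from a CT-like volume
#'
#' The automated endocast pipeline: threshold the bone ([threshold_bone()]),
#' seal foramina by morphological closing ([close_mask()]), build a distance
#' (or gradient) relief, and flood it by marker-based watershed from the
#' cavity seed against an exterior marker on the full volume border. The
#' cavity mask is the cavity-labeled, non-bone region.
#'
#' If, after closing, the cavity region still meets the exterior region
#' through non-bone voxels, the result is flagged `leaky` (the "cavity" is
#' open to the outside and its measures are unreliable).
#'
#' @param ct a [ct_volume()].
#' @param cavity_seed length-3 (or k x 3) 1-based voxel index inside the
#'   cavity; must not lie in bone.
#' @param close_radius closing ball radius in mm (default 2 voxels).
#' @param connectivity flooding connectivity, 6 (default) or 26.
#' @param threshold `"auto"` or a fixed numeric cutoff.
#' @param relief `"distance"` (default) or `"gradient"`.
#' @param fakir_d optional grid spacing; if given, a seven-fold Fakir
#'   measurement (`fakir_rotations` rotations) of the cavity mask is added
#'   to the measures.
#' @param fakir_rotations rotations for the optional Fakir measurement.
#' @return object of class `segmentation_result`: `labels` (full label
#'   array), `cavity` ([voxel_mask()]), `bone` (closed bone mask), `leaky`
#'   flag, `threshold`, and `measures` (list with `volume_mm3`,
#'   `surface_voxel_mm2`, and optionally `fakir`).
#' @export
extract_cavity <- function(ct, cavity_seed, close_radius = 2 * max(ct$spacing),
                           connectivity = 6, threshold = "auto",
                           relief = c("distance", "gradient"),
                           fakir_d = NULL, fakir_rotations = 10) {
  stopifnot(inherits(ct, "ct_volume"))
  relief <- match.arg(relief)
  bone <- if (identical(threshold, "auto")) {
    threshold_bone(ct, "auto")
  } else {
    threshold_bone(ct, "fixed", value = threshold)
  }
  seed <- rbind(cavity_seed)
  if (any(bone$occupancy[seed]))
    stop("cavity seed lies inside bone")
  bone <- close_mask(bone, close_radius)
  if (any(bone$occupancy[seed]))
    stop("cavity seed was sealed over by closing; reduce close_radius or move seed")

  rel <- if (relief == "distance") build_relief(bone, "distance")
         else build_relief(ct, "gradient")
  mk <- marker_set(dim(ct$intensity), seed)
  lab <- watershed_labels(rel, mk, connectivity)

  occ <- lab == 1L & !bone$occupancy
  leaky <- regions_meet(lab, bone$occupancy)
  if (leaky)
    warning("cavity is connected to the exterior after closing; result flagged leaky")
  cavity <- voxel_mask(occ, ct$spacing, ct$origin)

  measures <- list(volume_mm3 = mask_volume(cavity),
                   surface_voxel_mm2 = mask_voxel_surface(cavity))
  if (!is.null(fakir_d) && any(occ)) {
    measures$fakir <- fakir_replicate(cavity, direction_set("sevenfold"),
                                      d = fakir_d,
                                      n_rotations = fakir_rotations)
  }
  structure(list(labels = lab, cavity = cavity, bone = bone, leaky = leaky,
                 threshold = attr(bone, "threshold"),
                 voxel_volume_mm3 = prod(ct$spacing),
                 measures = measures, connectivity = connectivity,
                 close_radius = close_radius, relief = relief),
            class = "segmentation_result")
}

# TRUE when cavity-labeled and exterior-labeled NON-BONE voxels are
# face-adjacent, i.e. the two basins meet inside the open space
regions_meet <- function(lab, bone) {
  a <- lab == 1L & !bone
  b <- lab == 2L & !bone
  d <- dim(lab)
  adj <- function(m1, m2, axis) {
    n <- d[axis]
    if (n < 2) return(FALSE)
    switch(axis,
      any(m1[-n, , ] & m2[-1, , ]) || any(m2[-n, , ] & m1[-1, , ]),
      any(m1[, -n, ] & m2[, -1, ]) || any(m2[, -n, ] & m1[, -1, ]),
      any(m1[, , -n] & m2[, , -1]) || any(m2[, , -n] & m1[, , -1]))
  }
  adj(a, b, 1) || adj(a, b, 2) || adj(a, b, 3)
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> cavity %.2f mm^3 (%d voxels)%s\n",
              x$measures$volume_mm3, sum(x$cavity$occupancy),
              if (x$leaky) " [LEAKY]" else ""))
  invisible(x)
}
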