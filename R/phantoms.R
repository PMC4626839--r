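# Synthetic phantoms with analytic ground truth. Voxelization is by
# centre-point inside-test (no partial-volume antialiasing): voxel (i,j,k)
# is occupied when its centre satisfies the analytic inclusion test. This is
# unbiased for volume as the spacing shrinks and matches what the Fakir
# estimator consumes (binary masks).

# voxel-centre coordinate grids for an array spanning [-half, half] per axis
centre_grid <- function(half_extent, spacing) {
  n <- ceiling(2 * half_extent / spacing)
  lapply(1:3, function(i) ((seq_len(n[i]) - 0.5) * spacing[i]) - n[i] * spacing[i] / 2)
}

check_feature <- function(feature_mm, spacing, what) {
  if (any(spacing > feature_mm / 4))
    stop("voxel spacing too coarse for the smallest feature of the ", what,
         " (need spacing <= ", signif(feature_mm / 4, 3), " mm)")
}

#' Sphere phantom
#'
#' @param radius radius in mm.
#' @param spacing voxel spacing in mm (scalar or length 3); must not exceed
#'   `radius / 4`.
#' @param margin empty border around the object, mm (default 2 voxels).
#' @return list with `mask` ([voxel_mask()]) and `truth` (analytic
#'   `volume` mm^3 and `surface` mm^2).
#' @export
phantom_sphere <- function(radius, spacing, margin = 2 * max(spacing)) {
  spacing <- rep_len(spacing, 3)
  check_feature(radius, spacing, "sphere")
  g <- centre_grid(rep(radius + margin, 3), spacing)
  r2 <- outer(outer(g[[1]]^2, g[[2]]^2, `+`), g[[3]]^2, `+`)
  mask <- voxel_mask(r2 <= radius^2, spacing)
  list(mask = mask,
       truth = list(volume = 4 / 3 * pi * radius^3,
                    surface = 4 * pi * radius^2))
}

#' Ellipsoid phantom
#'
#' Axis-aligned ellipsoid with semi-axes `(a, b, c)` mm. The surface truth is
#' the closed-form spheroid area when two semi-axes coincide, otherwise a
#' fine midpoint-quadrature value (its grid recorded in the truth).
#'
#' @param semi_axes length-3 positive semi-axes in mm.
#' @param spacing voxel spacing in mm; must not exceed `min(semi_axes) / 4`.
#' @param margin empty border in mm.
#' @return list with `mask` and `truth` (`volume`, `surface`,
#'   `surface_method`).
#' @export
phantom_ellipsoid <- function(semi_axes, spacing, margin = 2 * max(spacing)) {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0))
  spacing <- rep_len(spacing, 3)
  check_feature(min(semi_axes), spacing, "ellipsoid")
  g <- centre_grid(semi_axes + margin, spacing)
  q <- outer(outer((g[[1]] / semi_axes[1])^2, (g[[2]] / semi_axes[2])^2, `+`),
             (g[[3]] / semi_axes[3])^2, `+`)
  mask <- voxel_mask(q <= 1, spacing)
  surf <- ellipsoid_surface(semi_axes[1], semi_axes[2], semi_axes[3])
  list(mask = mask,
       truth = list(volume = 4 / 3 * pi * prod(semi_axes),
                    surface = surf$area, surface_method = surf$method))
}

#' Analytic / quadrature surface area of an ellipsoid
#'
#' Closed form for spheres and spheroids (oblate and prolate); midpoint
#' quadrature on the `(theta, phi)` parameterization for triaxial shapes.
#'
#' @param a,b,c semi-axes in mm.
#' @param n quadrature resolution per angle for the triaxial case.
#' @return list with `area` (mm^2) and `method`.
#' @export
ellipsoid_surface <- function(a, b, c, n = 2000) {
  ax <- sort(c(a, b, c), decreasing = TRUE)
  if (abs(ax[1] - ax[3]) < 1e-12)
    return(list(area = 4 * pi * ax[1]^2, method = "sphere"))
  if (abs(ax[1] - ax[2]) < 1e-12) {        # oblate: a = b > c
    A <- ax[1]; C <- ax[3]
    e <- sqrt(1 - C^2 / A^2)
    return(list(area = 2 * pi * A^2 * (1 + (1 - e^2) / e * atanh(e)),
                method = "oblate"))
  }
  if (abs(ax[2] - ax[3]) < 1e-12) {        # prolate: a > b = c
    A <- ax[1]; C <- ax[2]
    e <- sqrt(1 - C^2 / A^2)
    return(list(area = 2 * pi * C^2 * (1 + A / (C * e) * asin(e)),
                method = "prolate"))
  }
  # triaxial: S = int |x_theta x x_phi| dtheta dphi, midpoint rule
  th <- (seq_len(n) - 0.5) * pi / n
  ph <- (seq_len(n) - 0.5) * 2 * pi / n
  st <- sin(th); ct <- cos(th)
  integrand <- outer(st, rep(1, n)) *
    sqrt(outer((b * c * st)^2, cos(ph)^2) +
         outer((a * c * st)^2, sin(ph)^2) +
         outer((a * b * ct)^2, rep(1, n)))
  list(area = sum(integrand) * (pi / n) * (2 * pi / n),
       method = sprintf("quadrature_%dx%d", n, n))
}

#' Planar lamina (thin plate) phantom
#'
#' Axis-aligned plate of `side x side x thickness` mm, normal along z; the
#' strongly anisotropic worst case for single-grid surface estimation. When
#' `thickness` equals the z spacing the plate is exactly one voxel thick by
#' construction.
#'
#' @param side in-plane edge length, mm.
#' @param thickness plate thickness, mm.
#' @param spacing voxel spacing in mm.
#' @param margin empty border in mm.
#' @return list with `mask` and `truth` (volume and surface of the realized
#'   voxelized box, which is exact for an axis-aligned box).
#' @export
phantom_lamina <- function(side, thickness, spacing, margin = 2 * max(spacing)) {
  spacing <- rep_len(spacing, 3)
  nx <- max(1L, round(side / spacing[1]))
  ny <- max(1L, round(side / spacing[2]))
  nz <- max(1L, round(thickness / spacing[3]))
  mx <- ceiling(margin / spacing)
  d <- c(nx, ny, nz) + 2 * mx
  occ <- array(FALSE, dim = d)
  occ[mx[1] + seq_len(nx), mx[2] + seq_len(ny), mx[3] + seq_len(nz)] <- TRUE
  lx <- nx * spacing[1]; ly <- ny * spacing[2]; lz <- nz * spacing[3]
  list(mask = voxel_mask(occ, spacing),
       truth = list(volume = lx * ly * lz,
                    surface = 2 * (lx * ly + lx * lz + ly * lz),
                    realized_dims = c(lx, ly, lz)))
}

#' Axis-aligned solid box phantom
#'
#' Exactly voxelized box; useful for closed-form intersection-count checks.
#'
#' @param sides length-3 edge lengths in mm.
#' @param spacing voxel spacing in mm.
#' @param margin empty border in mm.
#' @return list with `mask` and `truth` as in [phantom_lamina()].
#' @export
phantom_box <- function(sides, spacing, margin = 2 * max(spacing)) {
  sides <- rep_len(sides, 3)
  spacing <- rep_len(spacing, 3)
  n <- pmax(1L, round(sides / spacing))
  mx <- ceiling(margin / spacing)
  occ <- array(FALSE, dim = n + 2 * mx)
  occ[mx[1] + seq_len(n[1]), mx[2] + seq_len(n[2]), mx[3] + seq_len(n[3])] <- TRUE
  l <- n * spacing
  list(mask = voxel_mask(occ, spacing),
       truth = list(volume = prod(l),
                    surface = 2 * (l[1] * l[2] + l[1] * l[3] + l[2] * l[3]),
                    realized_dims = l))
}

#' Hollow spherical shell phantom, optionally pierced by foramina
#'
#' Bone-like shell `r_inner <= |x| <= r_outer`, with optional cylindrical
#' holes drilled through it along coordinate axes (mimicking cranial
#' foramina). The cavity truth is the analytic inner-sphere volume, which
#' sub-closing-radius holes do not change.
#'
#' @param r_inner,r_outer inner/outer shell radii in mm.
#' @param spacing voxel spacing in mm; must not exceed a quarter of the
#'   shell thickness.
#' @param holes optional data.frame with columns `axis` (1, 2 or 3) and
#'   `diameter` (mm): a through-going cylinder per row.
#' @param margin empty border in mm.
#' @return list with `mask` (shell), `truth` (`cavity_volume`,
#'   `cavity_surface` of the intact inner sphere) and `holes`.
#' @export
phantom_hollow_shell <- function(r_inner, r_outer, spacing, holes = NULL,
                                 margin = 2 * max(spacing)) {
  stopifnot(r_outer > r_inner, r_inner > 0)
  spacing <- rep_len(spacing, 3)
  check_feature(r_outer - r_inner, spacing, "shell wall")
  g <- centre_grid(rep(r_outer + margin, 3), spacing)
  x2 <- g[[1]]^2; y2 <- g[[2]]^2; z2 <- g[[3]]^2
  r2 <- outer(outer(x2, y2, `+`), z2, `+`)
  occ <- r2 >= r_inner^2 & r2 <= r_outer^2
  if (!is.null(holes)) {
    for (i in seq_len(nrow(holes))) {
      ax <- holes$axis[i]
      rad <- holes$diameter[i] / 2
      check_feature(holes$diameter[i], spacing, "foramen")
      t2 <- switch(ax,
                   outer(outer(0 * x2, y2, `+`), z2, `+`),
                   outer(outer(x2, 0 * y2, `+`), z2, `+`),
                   outer(outer(x2, y2, `+`), 0 * z2, `+`))
      occ <- occ & !(t2 <= rad^2)
    }
  }
  list(mask = voxel_mask(occ, spacing),
       truth = list(cavity_volume = 4 / 3 * pi * r_inner^3,
                    cavity_surface = 4 * pi * r_inner^2),
       holes = holes)
}

#' Three-compartment "brain" phantom
#'
#' Three tangent prolate ellipsoids in a row (prosencephalon, mesencephalon,
#' rhombencephalon), sized so their analytic volumes realize the requested
#' fractions of the total. Default fractions are the adult-mean compartment
#' fractions of the bundled pheasant dataset (0.64 / 0.16 / 0.20), default
#' total volume their adult grand-mean whole brain.
#'
#' @param total_volume whole-"brain" volume in mm^3.
#' @param fractions_volume length-3 positive fractions summing to 1.
#' @param aspect transverse-to-long axis ratio of each ellipsoid, in (0, 1].
#' @param spacing voxel spacing in mm.
#' @param margin empty border in mm.
#' @return list with `labels` (integer array: 0 background, 1..3 regions),
#'   `mask` (union [voxel_mask()]), `region_masks`, `spacing`, and `truth`
#'   (per-region analytic `volumes` and `surfaces`, plus totals).
#' @export
phantom_brain3 <- function(total_volume = 3556,
                           fractions_volume = c(0.64, 0.16, 0.20),
                           aspect = 0.7, spacing = 0.25,
                           margin = 2 * max(spacing)) {
  stopifnot(length(fractions_volume) == 3, all(fractions_volume > 0),
            abs(sum(fractions_volume) - 1) < 1e-9)
  spacing <- rep_len(spacing, 3)
  vols <- total_volume * fractions_volume
  a <- (vols / (4 / 3 * pi * aspect^2))^(1 / 3)  # long semi-axes
  b <- aspect * a
  check_feature(min(b), spacing, "smallest compartment")
  cx <- cumsum(c(a[1], a[1] + a[2], a[2] + a[3]))  # tangent centres on x
  half <- c((sum(a) * 2) / 2 + margin, max(b) + margin, max(b) + margin)
  g <- centre_grid(half, spacing)
  labels <- array(0L, dim = c(length(g[[1]]), length(g[[2]]), length(g[[3]])))
  for (k in 1:3) {
    xs <- (g[[1]] - (cx[k] - sum(a))) / a[k]   # recentre: chain starts at -sum(a)
    qy <- outer((g[[2]] / b[k])^2, (g[[3]] / b[k])^2, `+`)
    # explicit loop over x-slices keeps memory modest
    for (i in seq_along(g[[1]])) {
      q <- xs[i]^2 + qy
      sel <- q <= 1 & labels[i, , ] == 0L
      if (any(sel)) labels[i, , ][sel] <- k
    }
  }
  region_masks <- lapply(1:3, function(k)
    voxel_mask(labels == k, spacing))
  surfaces <- vapply(1:3, function(k)
    ellipsoid_surface(a[k], b[k], b[k])$area, numeric(1))
  list(labels = labels,
       mask = voxel_mask(labels > 0L, spacing),
       region_masks = region_masks, spacing = spacing,
       truth = list(volumes = vols, surfaces = surfaces,
                    total_volume = total_volume,
                    fractions_volume = fractions_volume,
                    semi_axes = cbind(a = a, b = b, c = b)))
}

#' CT-like rendering of a bone mask
#'
#' Renders a bone mask at high intensity over a low background, with
#' optional seeded Gaussian noise, emulating a reconstructed (contrast
#' enhanced) micro-CT volume.
#'
#' @param bone_mask a [voxel_mask()] of the bone.
#' @param bone_intensity,background_intensity attenuation-like levels.
#' @param noise_sd Gaussian noise SD (same units); 0 for noise-free.
#' @param seed optional integer seed for the noise.
#' @return a [ct_volume()].
#' @export
phantom_ct <- function(bone_mask, bone_intensity = 1000,
                       background_intensity = 0, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(bone_mask, "voxel_mask"))
  if (!is.null(seed)) set.seed(seed)
  img <- array(background_intensity, dim = dim(bone_mask$occupancy))
  img[bone_mask$occupancy] <- bone_intensity
  if (noise_sd > 0) img <- img + rnorm(length(img), sd = noise_sd)
  ct_volume(img, bone_mask$spacing, bone_mask$origin)
}
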