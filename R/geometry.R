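#' Probe direction sets
#'
#' Builds the direction set of a Fakir probe: a single canonical axis, an
#' orthogonal triplet, or the seven-fold set made of the 3 cube axes plus the
#' 4 normalized body diagonals of the unit cube. Weights are the convex
#' combination applied to the per-grid partial estimates; they default to
#' equal (each grid alone is unbiased under isotropic rotation, so any convex
#' weighting is too). For the seven-fold probe an optimized axial:diagonal
#' weighting can be supplied (see [optimize_sevenfold_weights()]).
#'
#' @param kind one of `"single"`, `"triple"`, `"sevenfold"`.
#' @param weights optional positive weights (length 1, 3 or 7) summing to 1.
#' @return An object of class `direction_set` with fields `kind`,
#'   `directions` (m x 3 matrix of unit rows) and `weights`.
#' @export
#' @examples
#' direction_set("triple")
direction_set <- function(kind = c("single", "triple", "sevenfold"),
                          weights = NULL) {
  kind <- match.arg(kind)
  dirs <- switch(kind,
    single = matrix(c(0, 0, 1), nrow = 1),
    triple = diag(3),
    sevenfold = rbind(diag(3),
                      matrix(c(1, 1, 1,
                               -1, 1, 1,
                               1, -1, 1,
                               -1, -1, 1) / sqrt(3), nrow = 4, byrow = TRUE)))
  m <- nrow(dirs)
  if (is.null(weights)) weights <- rep(1 / m, m)
  weights <- as.numeric(weights)
  if (length(weights) != m || any(weights <= 0))
    stop("`weights` must be ", m, " positive values")
  if (abs(sum(weights) - 1) > 1e-12)
    stop("`weights` must sum to 1")
  structure(list(kind = kind, directions = dirs, weights = weights),
            class = "direction_set")
}

#' @export
print.direction_set <- function(x, ...) {
  cat(sprintf("<direction_set> %s probe, %d direction(s)\n", x$kind,
              nrow(x$directions)))
  invisible(x)
}

#' Seven-fold direction set with a given axial weight fraction
#'
#' Convenience wrapper: total weight `axial_fraction` is shared equally by
#' the 3 axial grids, the remainder equally by the 4 diagonal grids.
#'
#' @param axial_fraction total weight on the three axial directions, in (0,1).
#' @return a `direction_set`.
#' @export
sevenfold_weighted <- function(axial_fraction) {
  stopifnot(axial_fraction > 0, axial_fraction < 1)
  direction_set("sevenfold",
                weights = c(rep(axial_fraction / 3, 3),
                            rep((1 - axial_fraction) / 4, 4)))
}

#' Haar-uniform random rotation
#'
#' Samples a rotation matrix uniformly over SO(3) via a unit quaternion built
#' from four standard normal deviates. Uses the current R RNG stream, so a
#' fixed `set.seed()` gives a reproducible rotation.
#'
#' @return 3x3 rotation matrix (orthonormal, determinant +1).
#' @export
#' @examples
#' set.seed(1); R <- random_rotation()
#' crossprod(R)  # identity
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  quaternion_to_matrix(q)
}

quaternion_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3)  # column-major: columns are images of e1, e2, e3
}

is_rotation <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

# Canonical transverse orthonormal basis (v, w) for direction u, with signs
# flipped so each basis vector's dominant component is positive. For the
# coordinate axes this returns canonical axes, which the grid-staggering
# bookkeeping relies on.
transverse_basis <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- cross3(u, a); v <- v / sqrt(sum(v^2))
  w <- cross3(u, v)
  fix_sign <- function(x) if (x[which.max(abs(x))] < 0) -x else x
  list(v = fix_sign(v), w = fix_sign(w))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# which canonical axis (1,2,3) a unit vector equals, or NA
canonical_axis <- function(v, tol = 1e-9) {
  for (i in 1:3) {
    e <- numeric(3); e[i] <- 1
    if (max(abs(v - e)) < tol) return(i)
  }
  NA_integer_
}

#' Build Fakir line grids over a bounding box
#'
#' For every direction of the probe, constructs a lattice of parallel lines
#' with transverse spacing `d` under a shared rotation, clips each line to
#' the box, and drops lines that miss it. Lattices are anchored at the box
#' corner plus a uniform random offset in `[0, d)` per transverse axis.
#'
#' When `staggered = TRUE` the grids are mutually adjusted ("fakir bed"
#' interleaving): transverse axes shared between grids use one common base
#' offset, and the second grid using a given axis is shifted by `d/2` along
#' it, so that line positions of different grids interleave at half spacing.
#' Diagonal grids of the seven-fold probe (whose transverse axes are not
#' canonical) alternate a `d/2` shift instead.
#'
#' @param bbox 2 x 3 matrix, rows = (lo, hi) corner coordinates in mm.
#' @param dset a [direction_set()].
#' @param d grid spacing in mm; must be smaller than the shortest box edge.
#' @param rotation 3x3 rotation applied to all directions (default identity;
#'   use [random_rotation()] for isotropic designs).
#' @param staggered mutually interleave the grids (default `TRUE`).
#' @param offsets optional list of per-grid length-2 offsets in `[0, d)`,
#'   overriding the random draw (used for deterministic examples).
#' @return list of `line_grid` objects; each has the rotated `direction`,
#'   transverse basis `v`, `w`, spacing `d`, `offset`, `area_per_line`
#'   (= d^2), an `n x 3` matrix `base` of line base points and an `n x 2`
#'   matrix `trange` of clipped parametric extents.
#' @export
build_grid <- function(bbox, dset, d, rotation = diag(3), staggered = TRUE,
                       offsets = NULL) {
  stopifnot(inherits(dset, "direction_set"))
  bbox <- as.matrix(bbox)
  if (!all(dim(bbox) == c(2, 3)) || any(bbox[2, ] <= bbox[1, ]))
    stop("`bbox` must be a 2 x 3 (lo, hi) matrix with positive extents")
  if (!is_rotation(rotation)) stop("`rotation` is not a rotation matrix")
  if (!(d > 0)) stop("`d` must be > 0")
  if (d >= min(bbox[2, ] - bbox[1, ]))
    stop("grid spacing `d` must be smaller than the shortest bbox edge")

  m <- nrow(dset$directions)
  axis_base <- runif(3) * d       # shared per-canonical-axis base offsets
  axis_used <- integer(3)

  grids <- vector("list", m)
  for (k in seq_len(m)) {
    u0 <- dset$directions[k, ]
    tb <- transverse_basis(u0)
    off <- numeric(2)
    for (j in 1:2) {
      b0 <- if (j == 1) tb$v else tb$w
      ax <- canonical_axis(b0)
      if (staggered && !is.na(ax)) {
        shift <- axis_used[ax] * d / 2
        axis_used[ax] <- axis_used[ax] + 1L
        off[j] <- (axis_base[ax] + shift) %% d
      } else {
        # diagonal grids share no transverse axis with any other grid, so
        # mutual adjustment does not apply; independent offset
        off[j] <- runif(1) * d
      }
    }
    if (!is.null(offsets)) off <- offsets[[k]] %% d

    u <- as.numeric(rotation %*% u0)
    v <- as.numeric(rotation %*% tb$v)
    w <- as.numeric(rotation %*% tb$w)

    corners <- as.matrix(expand.grid(bbox[, 1], bbox[, 2], bbox[, 3]))
    pv <- corners %*% v
    pw <- corners %*% w
    av <- seq_from_to(min(pv) + off[1], max(pv), d)
    aw <- seq_from_to(min(pw) + off[2], max(pw), d)
    lat <- as.matrix(expand.grid(a = av, b = aw))
    base <- cbind(lat[, 1] * v[1] + lat[, 2] * w[1],
                  lat[, 1] * v[2] + lat[, 2] * w[2],
                  lat[, 1] * v[3] + lat[, 2] * w[3])
    tr <- clip_lines_bbox(base, u, bbox)
    keep <- tr[, 2] > tr[, 1]
    grids[[k]] <- structure(
      list(direction = u, v = v, w = w, d = d, offset = off,
           rotation = rotation, area_per_line = d^2,
           lattice = c(length(av), length(aw)),
           base = base[keep, , drop = FALSE],
           trange = tr[keep, , drop = FALSE]),
      class = "line_grid")
  }
  grids
}

# half-open arithmetic lattice [from, to): matches one line per tributary
# square of area d^2 (seq() endpoint fuzz would close the interval)
seq_from_to <- function(from, to, by) {
  n <- ceiling((to - from) / by - 1e-9)
  if (n < 1) return(numeric(0))
  from + (seq_len(n) - 1) * by
}

# slab-clip a bundle of parallel lines (rows of `base`, shared direction u)
# against an axis-aligned box; returns n x 2 (t_min, t_max), collapsed range
# where the line misses
clip_lines_bbox <- function(base, u, bbox) {
  n <- nrow(base)
  tmin <- rep(-Inf, n); tmax <- rep(Inf, n)
  for (i in 1:3) {
    if (abs(u[i]) < 1e-14) {
      miss <- base[, i] < bbox[1, i] | base[, i] > bbox[2, i]
      tmin[miss] <- 0; tmax[miss] <- 0
    } else {
      t1 <- (bbox[1, i] - base[, i]) / u[i]
      t2 <- (bbox[2, i] - base[, i]) / u[i]
      lo <- pmin(t1, t2); hi <- pmax(t1, t2)
      tmin <- pmax(tmin, lo); tmax <- pmin(tmax, hi)
    }
  }
  cbind(tmin, tmax)
}

#' @export
print.line_grid <- function(x, ...) {
  cat(sprintf("<line_grid> %d lines, d = %g mm, direction (%.3f, %.3f, %.3f)\n",
              nrow(x$base), x$d, x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Serialize probe geometry to JSON
#'
#' Plain-JSON provenance record of a probe: directions, weights, spacing,
#' rotation matrix and per-grid offsets, so a measurement can be reproduced.
#'
#' @param dset a [direction_set()].
#' @param grids list returned by [build_grid()] (optional).
#' @param seed the seed used, if any.
#' @param file optional path; if given, JSON is written there.
#' @return JSON string (invisibly when written to file).
#' @export
probe_provenance <- function(dset, grids = NULL, seed = NULL, file = NULL) {
  doc <- list(kind = dset$kind,
              directions = dset$directions,
              weights = dset$weights,
              seed = seed)
  if (!is.null(grids)) {
    doc$spacing <- grids[[1]]$d
    doc$rotation <- grids[[1]]$rotation
    doc$offsets <- lapply(grids, function(g) g$offset)
    doc$n_lines <- vapply(grids, function(g) nrow(g$base), integer(1))
  }
  js <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE, null = "null")
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(js))
  }
  js
}
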