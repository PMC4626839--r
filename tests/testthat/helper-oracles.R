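# Independent brute-force oracles used across tests.

# Priority-flood watershed by explicit linear scan: the queue is a plain
# data frame, the minimum-(relief, insertion order) entry is found with
# order() each iteration. Quadratic, only for tiny instances.
flood_oracle <- function(relief, markers, connectivity = 6) {
  d <- dim(relief)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1, ]

  labels <- array(0L, dim = d)
  claimed <- markers > 0
  seeds <- which(markers > 0)                     # ascending linear index
  q_idx <- seeds
  q_rel <- relief[seeds]
  q_ord <- seq_along(seeds)
  q_lab <- as.integer(markers[seeds])
  counter <- length(seeds)

  to_xyz <- function(i) {
    i0 <- i - 1L
    c(i0 %% d[1], (i0 %/% d[1]) %% d[2], i0 %/% (d[1] * d[2])) + 1L
  }
  while (length(q_idx)) {
    j <- order(q_rel, q_ord)[1]
    idx <- q_idx[j]; lab <- q_lab[j]
    q_idx <- q_idx[-j]; q_rel <- q_rel[-j]; q_ord <- q_ord[-j]; q_lab <- q_lab[-j]
    labels[idx] <- lab
    p <- to_xyz(idx)
    for (r in seq_len(nrow(offs))) {
      q <- p + c(offs$dx[r], offs$dy[r], offs$dz[r])
      if (any(q < 1) || any(q > d)) next
      li <- q[1] + d[1] * ((q[2] - 1) + d[2] * (q[3] - 1))
      if (claimed[li]) next
      claimed[li] <- TRUE
      counter <- counter + 1
      q_idx <- c(q_idx, li); q_rel <- c(q_rel, relief[li])
      q_ord <- c(q_ord, counter); q_lab <- c(q_lab, lab)
    }
  }
  labels
}

# brute-force Euclidean distance to the nearest TRUE voxel centre
edt_oracle <- function(occ, spacing) {
  d <- dim(occ)
  pts <- which(occ, arr.ind = TRUE)
  if (nrow(pts) == 0) return(array(Inf, dim = d))
  coords <- sweep(pts - 1, 2, spacing, `*`)
  out <- array(0, dim = d)
  all_idx <- which(array(TRUE, dim = d), arr.ind = TRUE)
  all_co <- sweep(all_idx - 1, 2, spacing, `*`)
  for (i in seq_len(nrow(all_idx))) {
    dv <- sweep(coords, 2, all_co[i, ], `-`)
    out[i] <- sqrt(min(rowSums(dv^2)))
  }
  out
}

# exhaustive Otsu: try every midpoint between consecutive distinct values,
# maximize between-class variance directly
otsu_oracle <- function(x) {
  v <- sort(unique(as.numeric(x)))
  cuts <- (v[-1] + v[-length(v)]) / 2
  best <- -Inf; best_cut <- NA
  for (ct in cuts) {
    lo <- x[x < ct]; hi <- x[x >= ct]
    w0 <- length(lo) / length(x); w1 <- 1 - w0
    sb <- w0 * w1 * (mean(hi) - mean(lo))^2
    if (sb > best) { best <- sb; best_cut <- ct }
  }
  best_cut
}

# sphere mask helpers for trace tests
sphere_centre_mm <- function(ph) dim(ph$mask$occupancy) * ph$mask$spacing / 2
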