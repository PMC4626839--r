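test_that("Otsu threshold separates a bimodal image and matches brute force", {
  set.seed(12)
  x <- c(rnorm(4000, 0, 50), rnorm(3000, 1000, 50))
  thr <- otsu_threshold(x)
  expect_gt(thr, 100)     # strictly between the two modes
  expect_lt(thr, 900)
  # the gap between well-separated modes is a plateau of the between-class
  # variance, so thresholds may differ; the binarization must agree
  thr_o <- otsu_oracle(sample(x, 800))   # oracle is quadratic; subsample
  expect_gt(thr_o, 100)
  expect_lt(thr_o, 900)
  expect_gt(mean((x >= thr) == (x >= thr_o)), 0.999)

  expect_error(otsu_threshold(rep(3, 100)), "constant")
})

test_that("bone thresholding works in auto and fixed modes", {
  sh <- phantom_hollow_shell(4, 6, 0.5)
  ct <- phantom_ct(sh$mask, bone_intensity = 1000, noise_sd = 40, seed = 3)
  auto <- threshold_bone(ct, "auto")
  expect_gt(attr(auto, "threshold"), 100)
  expect_lt(attr(auto, "threshold"), 900)
  # recovered bone agrees almost everywhere with the generating mask
  expect_gt(mean(auto$occupancy == sh$mask$occupancy), 0.999)

  fx <- threshold_bone(ct, "fixed", value = 500)
  expect_equal(attr(fx, "threshold"), 500)
  expect_identical(fx$occupancy, ct$intensity >= 500)
  expect_error(threshold_bone(ct, "fixed"), "value")
})

test_that("distance transform matches the brute-force oracle (anisotropic)", {
  set.seed(6)
  occ <- array(runif(10 * 12 * 9) < 0.08, dim = c(10, 12, 9))
  occ[5, 6, 4] <- TRUE   # ensure nonempty
  sp <- c(0.5, 0.7, 1.1)
  m <- voxel_mask(occ, sp)
  expect_equal(distance_map(m), edt_oracle(occ, sp), tolerance = 1e-9)
})

test_that("reliefs behave as specified on degenerate inputs", {
  ct <- ct_volume(array(7, dim = c(5, 5, 5)), 0.5)
  expect_equal(build_relief(ct, "gradient"), array(0, dim = c(5, 5, 5)))

  # single bone voxel: distance relief is minimal at the farthest corner
  occ <- array(FALSE, dim = c(6, 6, 6)); occ[1, 1, 1] <- TRUE
  rel <- build_relief(voxel_mask(occ, 1), "distance")
  expect_equal(which.min(rel), which(array(seq_len(216), dim = dim(occ)) ==
                                     216))

  # hollow shell: the cavity's basin minimum is at the shell centre
  # (brute-force distance: the centre voxels are farthest from bone among
  # all cavity voxels)
  sh <- phantom_hollow_shell(4, 6, 0.5)
  rel2 <- build_relief(sh$mask, "distance")
  n <- dim(rel2)
  cc <- lapply(1:3, function(i) ((seq_len(n[i]) - 0.5) * 0.5) - n[i] * 0.5 / 2)
  r2 <- outer(outer(cc[[1]]^2, cc[[2]]^2, `+`), cc[[3]]^2, `+`)
  cavity <- r2 < 16
  ctr <- ceiling(n / 2)
  inner <- rel2[ctr[1] + (-1:1), ctr[2] + (-1:1), ctr[3] + (-1:1)]
  expect_equal(min(rel2[cavity]), min(inner))

  expect_error(build_relief(sh$mask, "gradient"), "ct_volume")
  expect_error(build_relief(ct, "distance"), "voxel_mask")
})

test_that("watershed splits a 1D double basin at the central peak", {
  relief <- array(c(2, 1, 2, 1, 2), dim = c(5, 1, 1))
  markers <- array(0L, dim = c(5, 1, 1))
  markers[2] <- 1L; markers[4] <- 2L
  lab <- watershed_labels(relief, markers, connectivity = 6)
  expect_equal(as.integer(lab), c(1L, 1L, 1L, 2L, 2L))
})

test_that("watershed labels every voxel, deterministically", {
  set.seed(14)
  relief <- array(0, dim = c(7, 6, 5))           # uniform relief
  mk <- marker_set(dim(relief), cavity = c(4, 3, 3))
  l1 <- watershed_labels(relief, mk)
  l2 <- watershed_labels(relief, mk)
  expect_true(all(l1 > 0))
  expect_identical(l1, l2)
  expect_error(watershed_labels(array(c(Inf, rep(0, 7)), dim = c(2, 2, 2)),
                                array(c(1L, rep(0L, 6), 2L), dim = c(2, 2, 2))),
               "finite")
  expect_error(marker_set(c(5, 5, 5), cavity = c(1, 1, 1)), "overlap")
})

test_that("priority flood agrees with the brute-force oracle", {
  set.seed(23)
  for (conn in c(6, 26)) {
    relief <- array(runif(8 * 9 * 7), dim = c(8, 9, 7))   # unique values
    markers <- array(0L, dim = dim(relief))
    markers[2, 3, 2] <- 1L
    markers[7, 7, 6] <- 2L
    fast <- watershed_labels(relief, markers, connectivity = conn)
    slow <- flood_oracle(relief, markers, connectivity = conn)
    expect_identical(fast, slow)
  }
})

test_that("morphological closing seals narrow holes and preserves flats", {
  bx <- phantom_box(c(5, 5, 5), 0.5)
  closed <- close_mask(bx$mask, 1)
  expect_identical(closed$occupancy, bx$mask$occupancy)  # flat faces unchanged

  sh <- phantom_hollow_shell(6, 8, 0.25,
                             holes = data.frame(axis = 1, diameter = 1))
  sealed <- close_mask(sh$mask, 0.75)
  # hole sealed: the interior no longer connects to the exterior
  rel <- build_relief(sealed, "distance")
  mk <- marker_set(dim(rel), cavity = ceiling(dim(rel) / 2))
  lab <- watershed_labels(rel, mk)
  expect_false(fakir3d:::regions_meet(lab, sealed$occupancy))
  expect_identical(close_mask(bx$mask, 0), bx$mask)
})

test_that("cavity extraction recovers the analytic inner-sphere volume", {
  truth <- 4 / 3 * pi * 8^3
  ctr_seed <- function(ct) ceiling(dim(ct$intensity) / 2)

  sh <- phantom_hollow_shell(8, 10, 0.25)
  ct <- phantom_ct(sh$mask, 1000, 0, noise_sd = 30, seed = 5)
  seg <- extract_cavity(ct, ctr_seed(ct), close_radius = 0.75)
  expect_false(seg$leaky)
  expect_equal(seg$measures$volume_mm3, truth, tolerance = 0.02)

  # pierced by 3 sub-closing-radius foramina: same cavity within 2%
  shp <- phantom_hollow_shell(8, 10, 0.25,
                              holes = data.frame(axis = 1:3, diameter = 1))
  ctp <- phantom_ct(shp$mask, 1000, 0, noise_sd = 30, seed = 6)
  seg2 <- extract_cavity(ctp, ctr_seed(ctp), close_radius = 0.75)
  expect_false(seg2$leaky)
  expect_equal(seg2$measures$volume_mm3, truth, tolerance = 0.02)

  # determinism
  seg3 <- extract_cavity(ctp, ctr_seed(ctp), close_radius = 0.75)
  expect_identical(seg2$labels, seg3$labels)

  # measures recomputable from the mask
  expect_equal(seg$measures$volume_mm3, mask_volume(seg$cavity))
  # every voxel labeled
  expect_true(all(seg$labels > 0L))
})

test_that("degenerate cavity inputs fail loudly instead of silently", {
  ss <- phantom_sphere(5, 0.5)
  ct <- phantom_ct(ss$mask, 1000, 0)
  # seed inside bone
  expect_error(extract_cavity(ct, ceiling(dim(ct$intensity) / 2),
                              close_radius = 0.5), "bone")
  # seed outside a solid object: no cavity, flagged leaky
  expect_warning(seg <- extract_cavity(ct, c(2, 2, 2), close_radius = 0.5),
                 "leaky")
  expect_true(seg$leaky)
})

test_that("cavity boundary sits on a relief ridge above both seeds", {
  sh <- phantom_hollow_shell(4, 6, 0.5)
  ct <- phantom_ct(sh$mask, 1000, 0)
  seg <- extract_cavity(ct, ceiling(dim(ct$intensity) / 2), close_radius = 0.5)
  rel <- build_relief(seg$bone, "distance")
  lab <- seg$labels
  d <- dim(lab)
  # face-adjacent label-discordant pairs along x
  a <- lab[-d[1], , ] != lab[-1, , ]
  ridge_ok <- rel[-d[1], , ][a] >= min(rel) & rel[-1, , ][a] >= min(rel)
  expect_true(all(ridge_ok))
  # boundary relief is above the cavity seed's relief (the global basin)
  expect_true(all(pmax(rel[-d[1], , ][a], rel[-1, , ][a]) > min(rel)))
})

test_that("watershed cavity measures agree with a Fakir measurement", {
  sh <- phantom_hollow_shell(8, 10, 0.25)
  ct <- phantom_ct(sh$mask, 1000, 0)
  seg <- extract_cavity(ct, ceiling(dim(ct$intensity) / 2), close_radius = 0.6,
                        fakir_d = 1.25, fakir_rotations = 6)
  fk <- seg$measures$fakir
  expect_equal(fk$volume, seg$measures$volume_mm3, tolerance = 0.01)
  expect_equal(fk$surface, sh$truth$cavity_surface, tolerance = 0.03)
})
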