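test_that("RC is the VOI mean over truth in percent and is linear in image scale", {
  ph <- small_phantom(32)
  m <- ph$labels$data == 3
  img <- volume_image(array(4.2, dim(ph$activity$data)), 7.2)
  expect_equal(compute_rc(img, m, 4.2), 100)
  expect_equal(compute_rc(volume_image(img$data / 2, 7.2), m, 4.2), 50)
  expect_equal(compute_rc(volume_image(img$data * 3, 7.2), m, 4.2), 300)
  expect_error(compute_rc(img, array(FALSE, dim(img$data)), 4.2), "empty")
  expect_error(compute_rc(img, m, 0), "positive")
})

test_that("RC of the blurred 48 ml sphere agrees with an independent dense convolution oracle", {
  ph <- small_phantom(48)
  sig_vox <- 1.27 * 10 / 7.2
  pkg <- blur_for_test(ph$activity$data, 1.27)
  oracle <- fft_blur_oracle(ph$activity$data, sig_vox)
  m3 <- ph$labels$data == 3
  rc_pkg <- 100 * mean(pkg[m3]) / 4.2
  rc_oracle <- 100 * mean(oracle[m3]) / 4.2
  expect_lt(abs(rc_pkg - rc_oracle) / rc_oracle, 0.01)
})

test_that("CNR follows the four-VOI definition and is scale invariant", {
  d <- c(20, 20, 20)
  a <- array(0.3, d)
  voi <- array(FALSE, d); voi[9:12, 9:12, 9:12] <- TRUE
  a[voi] <- 9
  # four two-voxel background VOIs with values 1 -/+ sqrt(2):
  # per-VOI mean exactly 1, per-VOI sample sd exactly 2
  bgs <- lapply(1:4, function(i) {
    m <- array(FALSE, d); m[2 * i, 2, c(2, 4)] <- TRUE; m
  })
  for (m in bgs) a[m] <- 1 + c(-sqrt(2), sqrt(2))
  img <- volume_image(a, 7.2)
  expect_equal(compute_cnr(img, voi, bgs), (9 - 1) / 2, tolerance = 1e-12)
  # mu_VOI == mu_Background gives 0
  a0 <- a; a0[voi] <- 1
  expect_equal(compute_cnr(volume_image(a0, 7.2), voi, bgs), 0,
               tolerance = 1e-12)
  # invariant under pure intensity scaling
  dbl <- volume_image(2 * img$data, 7.2)
  expect_equal(compute_cnr(dbl, voi, bgs), compute_cnr(img, voi, bgs))
  expect_error(compute_cnr(volume_image(array(1, d), 7.2), voi, bgs),
               "degenerate|zero")
})

test_that("background VOIs respect volumes, clearances and disjointness", {
  ph <- small_phantom(48)
  masks <- place_background_vois(ph$spec, ph$activity, seed = 7)
  expect_length(masks, 4)
  boxes <- attr(masks, "boxes")
  vols <- sort(vapply(boxes, function(b) b$volume_ml, numeric(1)))
  expect_equal(vols, c(54, 145, 260, 280))
  # voxelized volumes near nominal
  for (i in seq_along(masks)) {
    vol <- sum(masks[[i]]) * voxel_volume_ml(ph$activity)
    expect_lt(abs(vol - boxes[[i]]$volume_ml) / boxes[[i]]$volume_ml, 0.35)
  }
  # pairwise disjoint and disjoint from spheres
  all_m <- Reduce(`+`, masks)
  expect_true(all(all_m <= 1))
  expect_true(all(ph$labels$data[Reduce(`|`, masks)] == 4))
  # clearance: no VOI voxel within 3 cm of a sphere surface
  g <- coord_grids(ph$activity)
  for (s in 1:3) {
    dctr <- sqrt((g$x - ph$spec$sphere_centers_cm[s, 1])^2 +
                 (g$y - ph$spec$sphere_centers_cm[s, 2])^2 +
                 (g$z - ph$spec$sphere_centers_cm[s, 3])^2)
    expect_true(all(dctr[Reduce(`|`, masks)] >
                      ph$spec$sphere_radii_cm[s] + 3 - 0.63))  # voxel diag/2
  }
  # deterministic under the seed
  masks2 <- place_background_vois(ph$spec, ph$activity, seed = 7)
  expect_identical(masks, masks2)
})

test_that("isocontour segmentation honours threshold, connectivity and monotonicity", {
  d <- c(32, 32, 32)
  g <- coord_grids(volume_image(array(0, d), 7.2))
  # centre the blob on a voxel centre so the maximum is unique
  ctr <- c(g$x[17, 1, 1], g$y[1, 17, 1], g$z[1, 1, 17])
  blob <- exp(-((g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2) /
                (2 * 2^2))
  img <- volume_image(blob, 7.2)
  all_m <- array(TRUE, d)
  m100 <- isocontour_segment(img, all_m, 100)
  expect_equal(sum(m100), 1)
  expect_true(blob[m100] == max(blob))
  # 50% isocontour diameter matches the blob FWHM within one voxel
  m50 <- isocontour_segment(img, all_m, 50)
  width_vox <- diff(range(which(apply(m50, 1, any)))) + 1
  fwhm_vox <- sigma_to_fwhm(2) * 10 / 7.2
  expect_lt(abs(width_vox - fwhm_vox), 1.01)
  # volume non-increasing in threshold
  vols <- vapply(seq(30, 95, 5), function(p)
    sum(isocontour_segment(img, all_m, p)), numeric(1))
  expect_true(all(diff(vols) <= 0))
  # two hot spots: only the component containing the global max is kept
  two <- array(0, d)
  two[8, 8, 8] <- 5; two[24, 24, 24] <- 10
  m <- isocontour_segment(volume_image(two, 7.2), all_m, 40)
  expect_true(m[24, 24, 24]); expect_false(m[8, 8, 8])
  expect_error(isocontour_segment(img, array(FALSE, d), 50), "empty")
})

test_that("isocontour threshold calibration picks the volume-matching candidate", {
  d <- c(32, 32, 32)
  g <- coord_grids(volume_image(array(0, d), 7.2))
  blob <- exp(-(g$x^2 + g$y^2 + g$z^2) / (2 * 2.5^2))
  img <- volume_image(blob, 7.2)
  all_m <- array(TRUE, d)
  # construct the true volume as exactly the 70% isocontour volume
  v70 <- sum(isocontour_segment(img, all_m, 70)) * voxel_volume_ml(img)
  expect_equal(as.numeric(calibrate_isocontour_threshold(
    img, all_m, v70, candidate_pcts = seq(40, 95, 5))), 70)
  expect_equal(as.numeric(calibrate_isocontour_threshold(
    img, all_m, 48, candidate_pcts = 65)), 65)
})
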