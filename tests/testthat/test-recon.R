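test_that("one EM update on a 2-voxel/1-bin system matches the closed form", {
  # grid 1 x 2 x 1, single angle at 0 degrees: one detector bin sees both
  # voxels; attenuation weights from the interleaved convention
  mu1 <- 0.12; mu2 <- 0.08; dcm <- 0.72
  mu <- volume_image(array(c(mu1, mu2), c(1, 2, 1)), 7.2)
  w1 <- exp(-dcm * (0.5 * mu1 + mu2))
  w2 <- exp(-dcm * 0.5 * mu2)
  cnt <- 7
  proj <- projection_set(array(cnt, c(1, 1, 1)), 0, 7.2, 1)
  r <- map_mlem(proj, mu, recon_config(1, beta = 0, prior = "none"),
                cfg_noblur())
  expect_equal(as.vector(r$data), rep(cnt / (w1 + w2), 2), tolerance = 1e-12)
})

test_that("Poisson log-likelihood is non-decreasing for plain MLEM", {
  ph <- small_phantom(32)
  win <- default_windows()[["440keV"]]
  acq <- acquisition_spec(16, 10, 32, 7.2, seed = 5)
  sim <- simulate_projections(ph$activity, ph$mu, win, acq,
                              sensitivity = 2e-4)
  r <- map_mlem(sim$photopeak, ph$mu,
                recon_config(25, beta = 0, prior = "none"), cfg_noblur())
  ll <- attr(r, "loglik")
  expect_true(all(diff(ll) >= -1e-7 * abs(ll[-1])))
  expect_true(all(r$data >= 0))
})

test_that("scatter entering the EM denominator lowers the reconstructed background", {
  ph <- small_phantom(32)
  win <- default_windows()[["440keV"]]
  acq <- acquisition_spec(16, 120, 32, 7.2, seed = 6)
  kt <- make_kernel_table(voxel_cm = 0.72)
  sim <- simulate_projections(ph$activity, ph$mu, win, acq,
                              scatter_model = kt, sensitivity = 2e-4)
  cfg <- recon_config(20, beta = 0, prior = "none")
  r_no <- map_mlem(sim$photopeak, ph$mu, cfg, cfg_noblur())
  r_true <- map_mlem(sim$photopeak, ph$mu, cfg, cfg_noblur(),
                     scatter = sim$scatter_truth)
  bg <- ph$labels$data == 4
  expect_gt(mean(r_no$data[bg]), mean(r_true$data[bg]))
})

test_that("the Gaussian post-filter is identity at 0, matches the closed-form profile, and preserves interior mass", {
  d <- c(33, 33, 33)
  a <- array(0, d); a[17, 17, 17] <- 1
  v <- volume_image(a, 7.2)
  expect_identical(gaussian_postfilter(v, 0)$data, v$data)
  f <- gaussian_postfilter(v, 30)
  sig_vox <- fwhm_to_sigma(30) / 7.2
  prof <- f$data[17:24, 17, 17] / f$data[17, 17, 17]
  expect_equal(prof, exp(-(0:7)^2 / (2 * sig_vox^2)), tolerance = 0.02)
  expect_lt(abs(sum(f$data) - 1), 0.001)
})

test_that("calibration factors round-trip an independently simulated homogeneous phantom within 3%", {
  spec <- phantom_spec(sphere_volumes_ml = numeric(0), voxel_mm = 7.2)
  ph <- build_phantom(spec, 40)
  win <- default_windows()[["440keV"]]
  pc <- projector_config(0.35, 0.02)
  rcfg <- recon_config(60, beta = 0.01, scatter_mode = "none")
  recon_of <- function(seed) {
    acq <- acquisition_spec(32, 120, 40, 7.2, seed = seed)
    # high-sensitivity configuration: the round-trip property is about the
    # calibration chain, not the extreme low-count regime
    sim <- simulate_projections(ph$activity, ph$mu, win, acq, cfg = pc,
                                sensitivity = 5e-4)
    gaussian_postfilter(map_mlem(sim$photopeak, ph$mu, rcfg, pc), 30)
  }
  cf <- compute_calibration_factor(recon_of(101), 0.5)
  expect_gt(cf$value, 0)
  other <- apply_calibration(recon_of(202), cf)
  voi <- sphere_mask(other, c(0, 0, 0), 8)
  expect_equal(mean(other$data[voi]), 500, tolerance = 0.03)
})

test_that("trivial calibration arithmetic holds and factors are mode-specific", {
  v <- volume_image(array(0.5, c(24, 24, 24)), 7.2)
  attr(v, "window") <- "440keV"; attr(v, "scatter_mode") <- "TDSC"
  cf <- compute_calibration_factor(v, 0.5, voi_diameter_cm = 8)
  expect_equal(cf$value, 1000)   # kBq/ml truth over (counts/s)/voxel mean
  half <- volume_image(v$data / 2, 7.2)
  attr(half, "window") <- "440keV"; attr(half, "scatter_mode") <- "TDSC"
  expect_equal(compute_calibration_factor(half, 0.5, 8)$value, 2000)
  wrong <- half
  attr(wrong, "scatter_mode") <- "DEW"
  expect_error(apply_calibration(wrong, cf), "scatter mode")
  zero <- volume_image(array(0, c(24, 24, 24)), 7.2)
  expect_error(compute_calibration_factor(zero, 0.5, 8), "positive")
})
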