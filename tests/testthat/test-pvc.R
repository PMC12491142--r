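test_that("sigma and FWHM arithmetic round-trips and matches the quadrature rule", {
  expect_equal(fwhm_to_sigma(30), 12.7398, tolerance = 1e-4)
  expect_equal(fwhm_to_sigma(0), 0)
  x <- 17.3
  expect_equal(sigma_to_fwhm(fwhm_to_sigma(x)), x)
  expect_equal(combine_sigma_quadrature(3, 4), 5)
  expect_equal(combine_sigma_quadrature(2.2, 0), 2.2)
})

test_that("RL is the identity for a delta PSF and conserves flux", {
  ph <- small_phantom(40)
  img <- volume_image(blur_for_test(ph$activity$data, 1.5), 7.2)
  expect_identical(rl_deconvolve(img, psf_model(0), 10)$data, img$data)
  out <- rl_deconvolve(img, psf_model(1.5), 15)
  expect_lt(abs(sum(out$data) - sum(img$data)) / sum(img$data), 0.001)
  expect_true(all(out$data >= 0))
  expect_error(rl_deconvolve(volume_image(array(-1, c(4, 4, 4)), 7.2),
                             psf_model(1), 1), "non-negative")
})

test_that("RL recovery of the 48 ml sphere increases strictly with iterations on noiseless input", {
  ph <- small_phantom(40)
  img <- volume_image(blur_for_test(ph$activity$data, 1.5), 7.2)
  m3 <- ph$labels$data == 3
  rcs <- vapply(1:15, function(k)
    compute_rc(rl_deconvolve(img, psf_model(1.5), k), m3, 4.2), numeric(1))
  expect_true(all(diff(rcs) > 0))
})

test_that("IY recovers regional means within 2% on a noiseless blurred piecewise phantom", {
  ph <- small_phantom(40)
  img <- volume_image(blur_for_test(ph$activity$data, 1.0), 7.2)
  out <- iy_correct(img, ph$labels, psf_model(1.0), 10)
  truth <- c(4.2, 4.2, 4.2, 0.5)
  for (l in 1:4) {
    m <- ph$labels$data == l
    expect_equal(mean(out$data[m]), truth[l], tolerance = 0.02)
  }
  expect_true(all(out$data >= 0))
})

test_that("IY degenerate cases: single region and delta PSF leave the image unchanged", {
  set.seed(2)
  a <- array(runif(20^3) + 0.2, rep(20, 3))
  img <- volume_image(a, 7.2)
  one <- volume_image(array(1, rep(20, 3)), 7.2)
  out <- iy_correct(img, one, psf_model(1.2), 10)
  expect_equal(out$data, img$data, tolerance = 0.005)
  expect_identical(iy_correct(img, one, psf_model(0), 5)$data, img$data)
  ph <- small_phantom(32)
  expect_error(iy_correct(volume_image(array(1, rep(16, 3)), 7.2),
                          ph$labels, psf_model(1), 2), "grid")
})

test_that("matched-filter sigma estimation returns the generating grid value", {
  ph <- small_phantom(48)
  truth <- ph$activity
  recon <- volume_image(blur_for_test(truth$data, 1.5), 7.2)
  est <- estimate_psf_sigma(truth, recon, ph$spec$sphere_centers_cm,
                            ph$spec$sphere_radii_cm)
  expect_equal(est$sigma_cm, 1.5)
  expect_identical(est$origin, "matched_filter")
  # one-element grid returns that element
  est1 <- estimate_psf_sigma(truth, recon, ph$spec$sphere_centers_cm,
                             ph$spec$sphere_radii_cm, sigma_grid_cm = 0.75)
  expect_equal(est1$sigma_cm, 0.75)
  # overlapping expanded VOIs are rejected
  close_ctr <- rbind(c(0, 0, 0), c(4, 0, 0))
  expect_error(estimate_psf_sigma(truth, recon, close_ctr, c(2.27, 2.27)),
               "overlap")
})

test_that("the PVC workflow honours the filter-ordering rules", {
  ph <- small_phantom(32)
  img <- volume_image(blur_for_test(ph$activity$data, 1.5), 7.2)
  psf <- psf_model(1.5)
  rl <- apply_pvc_workflow(img, pvc_config("RL", 7), psf)
  aud <- attr(rl, "audit")
  expect_match(aud[1], "RL")
  expect_match(aud[2], "post-filter")
  iy <- apply_pvc_workflow(img, pvc_config("IY", 10), psf,
                           regions = ph$labels)
  aud <- attr(iy, "audit")
  expect_match(aud[1], "pre-filter")
  sig_comb <- combine_sigma_quadrature(1.5, fwhm_to_sigma(30) / 10)
  expect_match(aud[2], sprintf("combined sigma %.2f", sig_comb))
  expect_error(apply_pvc_workflow(img, pvc_config("IY"), psf), "region")
  # delta PSF with a single RL iteration reduces to filtering only
  flt <- apply_pvc_workflow(img, pvc_config("RL", 1), psf_model(0))
  expect_equal(flt$data, gaussian_postfilter(img, 30)$data)
})
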