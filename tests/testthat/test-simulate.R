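test_that("expected counts scale linearly with dwell time and emission probability", {
  ph <- small_phantom(32)
  win <- default_windows()[["440keV"]]
  kt <- make_kernel_table(voxel_cm = 0.72)
  s10 <- simulate_projections(ph$activity, ph$mu, win,
                              acquisition_spec(8, 10, 32, 7.2, seed = 1),
                              scatter_model = kt, noise = FALSE)
  s120 <- simulate_projections(ph$activity, ph$mu, win,
                               acquisition_spec(8, 120, 32, 7.2, seed = 1),
                               scatter_model = kt, noise = FALSE)
  expect_equal(s120$photopeak$counts, 12 * s10$photopeak$counts,
               tolerance = 1e-12)
  win2 <- energy_window(440, 0.2, win$emission_probability / 2,
                        win$scatter_windows, mu_water_cm = win$mu_water_cm)
  shalf <- simulate_projections(ph$activity, ph$mu, win2,
                                acquisition_spec(8, 10, 32, 7.2, seed = 1),
                                scatter_model = kt, noise = FALSE)
  expect_equal(shalf$photopeak$counts, s10$photopeak$counts / 2,
               tolerance = 1e-12)
})

test_that("zero dwell time yields all-zero counts", {
  ph <- small_phantom(24)
  win <- default_windows()[["440keV"]]
  s <- simulate_projections(ph$activity, ph$mu, win,
                            acquisition_spec(4, 0, 24, 7.2, seed = 2))
  expect_true(all(s$photopeak$counts == 0))
})

test_that("a fixed seed reproduces identical projection sets", {
  ph <- small_phantom(24)
  win <- default_windows()[["218keV"]]
  kt <- make_kernel_table(voxel_cm = 0.72)
  acq <- acquisition_spec(8, 10, 24, 7.2, seed = 33)
  s1 <- simulate_projections(ph$activity, ph$mu, win, acq, scatter_model = kt)
  s2 <- simulate_projections(ph$activity, ph$mu, win, acq, scatter_model = kt)
  expect_identical(s1$photopeak$counts, s2$photopeak$counts)
  expect_identical(s1$scatter_windows$lower$counts,
                   s2$scatter_windows$lower$counts)
  expect_identical(s1$photopeak$meta$seed, 33L)
})

test_that("disabling the scatter model gives primaries only and zero scatter windows", {
  ph <- small_phantom(24)
  win <- default_windows()[["218keV"]]
  s <- simulate_projections(ph$activity, ph$mu, win,
                            acquisition_spec(4, 10, 24, 7.2, seed = 3),
                            scatter_model = NULL, noise = FALSE)
  expect_equal(s$photopeak$counts, s$primary_truth$counts)
  expect_true(all(s$scatter_truth$counts == 0))
  expect_true(all(s$scatter_windows$lower$counts == 0))
})

test_that("scatter-window expectations make the EWSC estimators unbiased for the true scatter", {
  ph <- small_phantom(32)
  kt <- make_kernel_table(voxel_cm = 0.72)
  for (wname in c("440keV", "218keV")) {
    win <- default_windows()[[wname]]
    s <- simulate_projections(ph$activity, ph$mu, win,
                              acquisition_spec(4, 10, 32, 7.2, seed = 4),
                              scatter_model = kt, noise = FALSE)
    est <- if (wname == "440keV")
      dew_estimate(s$scatter_windows$lower, wa_from_window_test(win))
    else
      tew_estimate(s$scatter_windows$lower, s$scatter_windows$upper,
                   wa_from_window_test(win))
    expect_equal(est$counts, s$scatter_truth$counts, tolerance = 1e-10)
  }
})

test_that("mismatched grids are rejected", {
  ph <- small_phantom(24)
  mu_other <- volume_image(array(0.1, rep(16, 3)), 7.2)
  win <- default_windows()[["440keV"]]
  expect_error(simulate_projections(ph$activity, mu_other, win,
                                    acquisition_spec(4, 10, 16, 7.2)),
               "grid")
})

test_that("projection sets round-trip through their NIfTI + JSON container", {
  ph <- small_phantom(24)
  win <- default_windows()[["440keV"]]
  s <- simulate_projections(ph$activity, ph$mu, win,
                            acquisition_spec(4, 10, 24, 7.2, seed = 5))
  stem <- tempfile()
  write_projection_set(s$photopeak, stem)
  back <- read_projection_set(stem)
  expect_equal(back$counts, s$photopeak$counts)
  expect_equal(back$angles_deg, s$photopeak$angles_deg)
  expect_equal(back$window, s$photopeak$window)
})
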