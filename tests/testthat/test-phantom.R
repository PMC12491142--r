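test_that("voxelized sphere volumes match the analytic targets and a brute-force lattice scan", {
  spec <- phantom_spec(voxel_mm = 4.8)
  ph <- build_phantom(spec, 96)
  vox_ml <- (4.8 / 10)^3
  for (i in 1:3) {
    vol <- sum(ph$labels$data == i) * vox_ml
    # within a one-voxel surface shell of the analytic volume
    r <- spec$sphere_radii_cm[i]
    shell <- 4 * pi * r^2 * (4.8 / 10)
    expect_lt(abs(vol - spec$sphere_volumes_ml[i]), shell)
  }
  # brute-force lattice enumeration for the 48 ml sphere
  ctr <- spec$sphere_centers_cm[3, ]
  r3 <- spec$sphere_radii_cm[3]
  ax <- seq(-(96 - 1) / 2, (96 - 1) / 2) * 0.48
  cnt <- 0L
  for (x in ax) for (y in ax) {
    dz2 <- r3^2 - (x - ctr[1])^2 - (y - ctr[2])^2
    if (dz2 >= 0)
      cnt <- cnt + sum((ax - ctr[3])^2 <= dz2)
  }
  expect_identical(sum(ph$labels$data == 3), cnt)
})

test_that("voxelized volumes converge to the analytic value as voxels shrink", {
  errs <- vapply(c(7.2, 3.6), function(v) {
    spec <- phantom_spec(voxel_mm = v)
    ph <- build_phantom(spec, round(340 / v))
    vol <- sum(ph$labels$data == 3) * (v / 10)^3
    abs(vol - 48) / 48
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], 0.05)
})

test_that("phantom fields, labels and degenerate activities behave", {
  spec <- phantom_spec()
  ph <- build_phantom(spec, 48)
  expect_equal(sort(unique(as.vector(ph$labels$data))), 0:4)
  # background fills the cylinder interior outside spheres
  expect_true(all(ph$activity$data[ph$labels$data == 4] == 0.5))
  expect_true(all(ph$activity$data[ph$labels$data == 0] == 0))
  expect_true(all(ph$mu$data[ph$labels$data == 0] == 0))
  expect_true(all(ph$mu$data[ph$labels$data >= 1] == spec$mu_water_cm))
  # zero concentrations give an identically zero activity volume
  z <- build_phantom(phantom_spec(sphere_ac_kbq_ml = 0,
                                  background_ac_kbq_ml = 0), 32)
  expect_true(all(z$activity$data == 0))
})

test_that("invalid phantom geometries are rejected with diagnostics", {
  expect_error(phantom_spec(sphere_centers_cm = rbind(c(0, 0, 0),
                                                      c(1, 0, 0),
                                                      c(10, 0, 0))),
               "overlap")
  expect_error(phantom_spec(sphere_centers_cm = rbind(c(11, 0, 0),
                                                      c(-6, 0, 0),
                                                      c(0, 6, 0))),
               "outside")
  expect_error(phantom_spec(sphere_volumes_ml = c(-1, 10, 10)), "positive")
})

test_that("kernel table covers 2-40 cm, clamps deep queries, and the slope law is flat beyond 40 cm", {
  kt <- make_kernel_table()
  expect_length(kt$table$depths_cm, 20)
  k55 <- kernel_at_depth(kt$table, 55)
  k40 <- kernel_at_depth(kt$table, 40)
  expect_identical(k55$slope, k40$slope)
  # slope change under 3% per extra 2 cm beyond 40 cm under the default law
  law <- function(d) 0.25 + (0.5 - 0.25) * exp(-d / 15)
  dd <- seq(40, 60, by = 2)
  rel <- abs(diff(law(dd))) / law(dd)[-length(dd)]
  expect_true(all(rel < 0.03))
  # shallow queries warn and use the nearest entry
  expect_warning(ks <- kernel_at_depth(kt$table, 0.5), "nearest")
  expect_identical(ks$slope, kernel_at_depth(kt$table, 2)$slope)
  expect_error(make_kernel_table(depths_cm = c(4, 2)), "increasing")
})

test_that("specs validate their inputs", {
  expect_error(energy_window(440, 1.2, 0.2), "width_fraction")
  expect_error(energy_window(440, 0.2, 1.2), "emission_probability")
  expect_error(acquisition_spec(n_projections = 0), "n_projections")
  expect_error(acquisition_spec(time_per_projection = -1), ">= 0")
})

test_that("phantom and acquisition specs round-trip through YAML", {
  spec <- phantom_spec()
  f <- tempfile(fileext = ".yaml")
  write_spec_yaml(spec, f)
  spec2 <- read_spec_yaml(f)
  expect_equal(spec2$sphere_centers_cm, spec$sphere_centers_cm)
  expect_equal(spec2$cylinder_height_cm, spec$cylinder_height_cm)
  acq <- acquisition_spec(32, 10, 64, 4.8, seed = 9L)
  write_spec_yaml(acq, f)
  expect_equal(read_spec_yaml(f)$angles_deg, acq$angles_deg)
})
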