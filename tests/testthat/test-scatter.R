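mkps <- function(counts, n = 4) {
  projection_set(array(counts, c(n, n, 2)), c(0, 180), 4.8, 10)
}

test_that("DEW scales the lower window by the width ratio and is linear", {
  wa <- window_arithmetic(peak_width_kev = 88, lower_width_kev = 44)
  lo <- mkps(10)
  est <- dew_estimate(lo, wa)
  expect_true(all(est$counts == 20))
  expect_true(all(dew_estimate(mkps(0), wa)$counts == 0))
  est2 <- dew_estimate(mkps(20), wa)
  expect_equal(est2$counts, 2 * est$counts)
})

test_that("TEW reproduces the trapezoid arithmetic", {
  wa <- window_arithmetic(43.6, 35.6, 53.4)
  est <- tew_estimate(mkps(356), mkps(0), wa)
  expect_equal(est$counts[1], 218.0, tolerance = 1e-12)
  expect_true(all(tew_estimate(mkps(0), mkps(0), wa)$counts == 0))
  # flat spectrum: C_l/W_l = C_u/W_u = r gives r * W_p
  r <- 3.5
  est2 <- tew_estimate(mkps(r * 35.6), mkps(r * 53.4), wa)
  expect_equal(est2$counts[1], r * 43.6, tolerance = 1e-12)
  expect_error(tew_estimate(mkps(1), mkps(1, n = 5), wa), "geometry")
})

test_that("mono-exponential tail fits recover generating parameters", {
  x <- seq(1, 10, length.out = 30)
  y <- 5 * exp(-0.3 * x)
  fit <- fit_tail_monoexp(x, y)
  expect_equal(fit$amplitude, 5, tolerance = 1e-6)
  expect_equal(fit$slope, 0.3, tolerance = 1e-6)
  # 5% multiplicative noise: slope within 10%
  set.seed(21)
  yn <- y * (1 + 0.05 * rnorm(30))
  fitn <- fit_tail_monoexp(x, yn)
  expect_lt(abs(fitn$slope - 0.3) / 0.3, 0.1)
  expect_error(fit_tail_monoexp(x, rep(0, 30)), "positive")
  expect_error(fit_tail_monoexp(x[1:2], y[1:2]), "3")
})

test_that("scatter-to-primary model fit recovers (A, B, gamma) and its limits", {
  p <- seq(0, 4, length.out = 15)
  y <- 3 - 2 * exp(-0.5 * p) - 1
  m <- fit_sf_model(p, y)
  expect_equal(m$A, 3, tolerance = 1e-4)
  expect_equal(m$B, 2, tolerance = 1e-4)
  expect_equal(m$gamma, 0.5, tolerance = 1e-4)
  # path length 0 evaluates to A - B - 1
  expect_equal(sf_eval(m, 0), 3 - 2 - 1, tolerance = 1e-6)
  # degenerate B = 0 generator: constant at A - 1
  yc <- rep(1.5 - 1, 15)
  mc <- fit_sf_model(p, yc)
  expect_equal(sf_eval(mc, p), rep(0.5, 15), tolerance = 1e-6)
  expect_error(fit_sf_model(p[1:3], y[1:3]), "4")
})

test_that("kernel tables round-trip through CSV and match the shipped example", {
  kt <- make_kernel_table()
  f <- tempfile(fileext = ".csv")
  write_kernel_table_csv(kt$table, f)
  back <- read_kernel_table_csv(f)
  expect_equal(back$depths_cm, kt$table$depths_cm)
  expect_equal(back$slopes_cm, kt$table$slopes_cm)
  shipped <- read_kernel_table_csv(
    system.file("extdata", "synthetic_kernel_table.csv",
                package = "acspect"))
  expect_equal(shipped$slopes_cm, kt$table$slopes_cm, tolerance = 1e-12)
})

test_that("negative scatter-to-primary models are rejected at construction", {
  expect_error(sf_model(1.6, 1.1, 0.7), "negative")
})

test_that("TDSC single-voxel projection equals the hand-assembled kernel row times SF", {
  # 5 mm voxels so the 10 cm slice depth hits a tabulated kernel entry
  n <- 44; vox <- 5
  mu <- volume_image(array(0.15, rep(n, 3)), vox)
  jj <- n - 20                       # depth to surface = 20 * 0.5 = 10 cm
  a <- array(0, rep(n, 3)); a[22, jj, 22] <- 1
  img <- volume_image(a, vox)
  kt <- make_kernel_table(voxel_cm = 0.5)
  sp <- suppressWarnings(
    tdsc_scatter_projection(img, mu, kt$table, kt$sf, 0))
  # independent assembly: slope from the smooth law at exactly 10 cm,
  # kernel truncated at 5/slope and unit-normalized, scaled by SF at the
  # slice's attenuation path
  b <- 0.25 + 0.25 * exp(-10 / 15)
  h <- ceiling((5 / b) / 0.5)
  off <- (-h:h) * 0.5
  r <- sqrt(outer(off^2, off^2, "+"))
  K <- exp(-b * r); K[r > 5 / b] <- 0; K <- K / sum(K)
  path <- 0.15 * (n - jj + 0.5) * 0.5
  sf <- 1.5 - 0.45 * exp(-0.5 * path) - 1
  expected <- matrix(0, n, n)
  for (da in -h:h) for (db in -h:h) {
    ia <- 22 + da; kb <- 22 + db
    if (ia >= 1 && ia <= n && kb >= 1 && kb <= n)
      expected[ia, kb] <- K[da + h + 1, db + h + 1] * sf
  }
  expect_lt(max(abs(sp - expected)), 1e-12)
})

test_that("TDSC is zero for a zero estimate and deeper sources scatter more under a rising SF", {
  n <- 40
  mu <- volume_image(array(0.15, rep(n, 3)), 7.2)
  z <- volume_image(array(0, rep(n, 3)), 7.2)
  kt <- make_kernel_table(voxel_cm = 0.72)
  expect_true(all(suppressWarnings(
    tdsc_scatter_projection(z, mu, kt$table, kt$sf, 0)) == 0))
  one_src <- function(jj) {
    a <- array(0, rep(n, 3)); a[20, jj, 20] <- 1
    sum(suppressWarnings(tdsc_scatter_projection(
      volume_image(a, 7.2), mu, kt$table, kt$sf, 0)))
  }
  # deeper source (smaller j) has longer path, larger SF
  expect_gt(one_src(n - 28), one_src(n - 14))
})

test_that("TDSC rejects mismatched grids", {
  kt <- make_kernel_table(voxel_cm = 0.72)
  a <- volume_image(array(1, rep(16, 3)), 7.2)
  m <- volume_image(array(0.1, rep(20, 3)), 7.2)
  expect_error(tdsc_scatter_projection(a, m, kt$table, kt$sf, 0), "grid")
})
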