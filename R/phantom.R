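#' Digital phantom specification
#'
#' Describes the sphere-in-cylinder phantom used throughout the package: a
#' water cylinder containing hot spheres over a warm background. Defaults
#' reproduce the reference measurement geometry: an 8.7 L cylinder of 25 cm
#' diameter holding spheres of 191, 100 and 48 ml filled at 4.2 kBq/ml over a
#' 0.5 kBq/ml background. Sphere centres default to a 6.5 cm ring in the
#' lower half of the cylinder, which keeps the spheres apart, inside the
#' cylinder, and leaves the upper half free for background VOIs; the ring
#' radius is the smallest for which spherical VOIs expanded by 2 cm (used by
#' matched-filter PSF estimation) stay pairwise disjoint.
#'
#' @param cylinder_diameter_cm cylinder diameter (cm).
#' @param cylinder_volume_ml cylinder volume (ml); fixes the height.
#' @param sphere_volumes_ml sphere volumes (ml).
#' @param sphere_centers_cm matrix (n x 3) of sphere centres (cm), origin at
#'   the cylinder centre; `NULL` places them on the default ring.
#' @param sphere_ac_kbq_ml activity concentration in the spheres (kBq/ml).
#' @param background_ac_kbq_ml background activity concentration (kBq/ml).
#' @param mu_water_cm linear attenuation coefficient of water (1/cm) for the
#'   energy window being simulated.
#' @param voxel_mm isotropic voxel size (mm).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(cylinder_diameter_cm = 25,
                         cylinder_volume_ml = 8700,
                         sphere_volumes_ml = c(191, 100, 48),
                         sphere_centers_cm = NULL,
                         sphere_ac_kbq_ml = 4.2,
                         background_ac_kbq_ml = 0.5,
                         mu_water_cm = 0.102,
                         voxel_mm = 7.2) {
  nsph <- length(sphere_volumes_ml)
  if (nsph > 0 && any(sphere_volumes_ml <= 0))
    stop("sphere volumes must be positive")
  if (sphere_ac_kbq_ml < 0 || background_ac_kbq_ml < 0)
    stop("activity concentrations must be non-negative")
  if (is.null(sphere_centers_cm) && nsph > 0) {
    ang <- (90 + 120 * (seq_len(nsph) - 1)) * pi / 180
    sphere_centers_cm <- cbind(6.5 * cos(ang), 6.5 * sin(ang), rep(-4.5, nsph))
  }
  if (nsph > 0) sphere_centers_cm <- matrix(sphere_centers_cm, ncol = 3)
  spec <- structure(list(
    cylinder_diameter_cm = cylinder_diameter_cm,
    cylinder_volume_ml = cylinder_volume_ml,
    cylinder_height_cm = cylinder_volume_ml /
      (pi * (cylinder_diameter_cm / 2)^2),
    sphere_volumes_ml = sphere_volumes_ml,
    sphere_centers_cm = sphere_centers_cm,
    sphere_radii_cm = if (nsph > 0) (3 * sphere_volumes_ml / (4 * pi))^(1/3)
                      else numeric(0),
    sphere_ac_kbq_ml = sphere_ac_kbq_ml,
    background_ac_kbq_ml = background_ac_kbq_ml,
    mu_water_cm = mu_water_cm,
    voxel_mm = voxel_mm), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  n <- length(spec$sphere_volumes_ml)
  if (n == 0) return(invisible(TRUE))
  R <- spec$cylinder_diameter_cm / 2
  H <- spec$cylinder_height_cm
  r <- spec$sphere_radii_cm
  ctr <- spec$sphere_centers_cm
  for (i in seq_len(n)) {
    rad_xy <- sqrt(sum(ctr[i, 1:2]^2))
    if (rad_xy + r[i] > R + 1e-9 || abs(ctr[i, 3]) + r[i] > H / 2 + 1e-9)
      stop(sprintf("sphere %d (r = %.2f cm) extends outside the cylinder", i, r[i]))
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- sqrt(sum((ctr[i, ] - ctr[j, ])^2))
      if (d < r[i] + r[j] - 1e-9)
        stop(sprintf("spheres %d and %d overlap (centre distance %.2f cm < %.2f cm)",
                     i, j, d, r[i] + r[j]))
    }
  }
  invisible(TRUE)
}

#' Energy-window specification
#'
#' @param center_kev window centre (keV).
#' @param width_fraction fractional window width (0-1), e.g. 0.2 for 20%.
#' @param emission_probability photons per decay falling in this window.
#' @param scatter_windows list of `c(center_kev, width_fraction)` pairs for
#'   the adjacent scatter windows (empty for windows corrected without EWSC).
#' @param label window label.
#' @param mu_water_cm water attenuation coefficient at this energy (1/cm).
#' @return An object of class `energy_window`.
#' @export
energy_window <- function(center_kev, width_fraction, emission_probability,
                          scatter_windows = list(), label = NULL,
                          mu_water_cm = 0.15) {
  if (width_fraction <= 0 || width_fraction >= 1)
    stop("width_fraction must lie in (0, 1)")
  if (emission_probability < 0 || emission_probability > 1)
    stop("emission_probability must lie in [0, 1]")
  if (is.null(label)) label <- sprintf("%gkeV", center_kev)
  structure(list(center_kev = center_kev, width_fraction = width_fraction,
                 width_kev = center_kev * width_fraction,
                 emission_probability = emission_probability,
                 scatter_windows = scatter_windows, label = label,
                 mu_water_cm = mu_water_cm),
            class = "energy_window")
}

#' The three imageable Ac-225 energy windows
#'
#' 440 keV (Bi-213, 20% width, emission probability 25.9%, one lower 10%
#' scatter window for DEW), 218 keV (Fr-221, 20% width, 11.4%, 20% scatter
#' windows at 178 and 267 keV for TEW), and the 78 keV X-ray window (50%
#' width; corrected with TDSC or left uncorrected). The X-ray window's
#' effective emission probability (0.50 per decay) is a synthetic effective
#' yield covering the overlapping daughter X-ray emissions plus collimator
#' lead X-rays. Water attenuation coefficients are 0.102, 0.134 and
#' 0.184 1/cm at 440, 218 and 78 keV.
#'
#' @return Named list of three `energy_window` objects.
#' @export
default_windows <- function() {
  list(
    "440keV" = energy_window(440, 0.20, 0.259,
                             scatter_windows = list(lower = c(407, 0.10)),
                             label = "440keV", mu_water_cm = 0.102),
    "218keV" = energy_window(218, 0.20, 0.114,
                             scatter_windows = list(lower = c(178, 0.20),
                                                    upper = c(267, 0.20)),
                             label = "218keV", mu_water_cm = 0.134),
    "78keV"  = energy_window(78, 0.50, 0.50,
                             scatter_windows = list(),
                             label = "78keV", mu_water_cm = 0.184))
}

#' Acquisition protocol
#'
#' Defaults follow the reference protocol: 32 projections over a 360 degree
#' orbit, 128 x 128 bins of 4.80 mm; the low-count (LC) protocol uses
#' 10 s per projection and the high-count (HC) protocol 120 s.
#'
#' @param n_projections number of projection angles.
#' @param time_per_projection_s dwell time per projection (s).
#' @param matrix_size detector bins per side.
#' @param bin_mm detector bin size (mm).
#' @param angular_range_deg total orbit (degrees).
#' @param seed integer seed controlling Poisson sampling.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(n_projections = 32, time_per_projection_s = 10,
                             matrix_size = 128, bin_mm = 4.8,
                             angular_range_deg = 360, seed = 1L) {
  if (n_projections < 1) stop("n_projections must be >= 1")
  if (time_per_projection_s < 0) stop("time_per_projection must be >= 0")
  structure(list(n_projections = as.integer(n_projections),
                 time_per_projection_s = time_per_projection_s,
                 matrix_size = as.integer(matrix_size), bin_mm = bin_mm,
                 angular_range_deg = angular_range_deg,
                 angles_deg = angular_range_deg *
                   (seq_len(n_projections) - 1) / n_projections,
                 seed = as.integer(seed)),
            class = "acquisition_spec")
}

#' Voxelize a phantom specification
#'
#' Builds the activity, attenuation and label volumes on a cubic grid. A
#' voxel belongs to a region when its centre lies inside the analytic shape.
#' Labels: 0 exterior (air), 1..n the spheres (in the order of
#' `sphere_volumes_ml`), n+1 the cylinder background.
#'
#' @param spec a [phantom_spec()].
#' @param grid_n grid size per axis (voxels).
#' @return list with `volume_image` elements `activity` (kBq/ml), `mu`
#'   (1/cm) and `labels` plus the background label id.
#' @export
build_phantom <- function(spec, grid_n = 64) {
  validate_phantom_spec(spec)
  tmpl <- volume_image(array(0, rep(grid_n, 3)), voxel_mm = spec$voxel_mm)
  g <- coord_grids(tmpl)
  R <- spec$cylinder_diameter_cm / 2
  H <- spec$cylinder_height_cm
  inside_cyl <- (g$x^2 + g$y^2 <= R^2) & (abs(g$z) <= H / 2)
  n <- length(spec$sphere_volumes_ml)
  labels <- array(0L, dim = dim(tmpl$data))
  labels[inside_cyl] <- n + 1L
  for (i in seq_len(n)) {
    ctr <- spec$sphere_centers_cm[i, ]
    r2 <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2
    labels[r2 <= spec$sphere_radii_cm[i]^2] <- i
  }
  activity <- array(0, dim = dim(tmpl$data))
  activity[labels == n + 1L] <- spec$background_ac_kbq_ml
  if (n > 0) activity[labels >= 1L & labels <= n] <- spec$sphere_ac_kbq_ml
  mu <- array(0, dim = dim(tmpl$data))
  mu[inside_cyl] <- spec$mu_water_cm
  list(activity = volume_image(activity, spec$voxel_mm),
       mu = volume_image(mu, spec$voxel_mm),
       labels = volume_image(labels + 0, spec$voxel_mm),
       background_label = n + 1L)
}

#' Spherical voxel mask
#'
#' @param template a `volume_image` providing the grid.
#' @param center_cm sphere centre (cm).
#' @param radius_cm sphere radius (cm).
#' @return logical array mask.
#' @export
sphere_mask <- function(template, center_cm, radius_cm) {
  g <- coord_grids(template)
  (g$x - center_cm[1])^2 + (g$y - center_cm[2])^2 +
    (g$z - center_cm[3])^2 <= radius_cm^2
}
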