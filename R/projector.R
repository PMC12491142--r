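#' Projector configuration
#'
#' Parameters of the rotation-based parallel-beam projector. The detector
#' response is a distance-dependent isotropic Gaussian with
#' `sigma(d) = psf_sigma0_cm + psf_slope * d` for a plane at distance `d`
#' (cm) from the detector face. `ray_step_cm` is used only by the
#' ray-marching path-length routine ([attenuation_path_length()]).
#'
#' @param psf_sigma0_cm intrinsic resolution sigma (cm), >= 0.
#' @param psf_slope sigma growth per cm of source-detector distance, >= 0.
#' @param interpolation `"linear"` (bilinear rotation, default) or
#'   `"nearest"`.
#' @param ray_step_cm step for ray marching (cm).
#' @return An object of class `projector_config`.
#' @export
projector_config <- function(psf_sigma0_cm = 0.35, psf_slope = 0.03,
                             interpolation = c("linear", "nearest"),
                             ray_step_cm = 0.1) {
  interpolation <- match.arg(interpolation)
  if (psf_sigma0_cm < 0 || psf_slope < 0)
    stop("psf_sigma0_cm and psf_slope must be non-negative")
  structure(list(psf_sigma0_cm = psf_sigma0_cm, psf_slope = psf_slope,
                 interpolation = interpolation, ray_step_cm = ray_step_cm),
            class = "projector_config")
}

# per-plane blur sigmas in voxel units for a grid with ny planes
plane_sigmas_vox <- function(cfg, ny, voxel_cm) {
  d <- (ny - seq_len(ny)) * voxel_cm           # distance to detector face
  (cfg$psf_sigma0_cm + cfg$psf_slope * d) / voxel_cm
}

# attenuation weight cubes exp(-path) in the rotated frame, one per angle
atten_weight_list <- function(mu, angles_deg, nearest = FALSE) {
  if (is.null(mu)) return(NULL)
  vcm <- vox_cm(mu)
  lapply(angles_deg, function(a) {
    murot <- rotate_xy_cpp(mu$data, a * pi / 180, FALSE, nearest)
    exp(-atten_path_cpp(murot, vcm))
  })
}

#' Forward projection
#'
#' For each angle the volume is rotated so the detector lies beyond the
#' +y face, every detector-parallel plane is blurred with its
#' distance-dependent Gaussian, weighted by the attenuation survival factor
#' `exp(-integral of mu)` along the ray to the detector (half-voxel
#' self-attenuation at the source voxel), and summed along the rays.
#'
#' @param image `volume_image` to project.
#' @param mu attenuation `volume_image` (1/cm) on the same grid, or `NULL`
#'   for no attenuation.
#' @param cfg a [projector_config()].
#' @param angles_deg projection angles (degrees).
#' @param w_list optional precomputed attenuation weights (internal reuse).
#' @return A [projection_set()] of expected count rates (image units summed
#'   along rays), `time_s = 1`.
#' @export
forward_project <- function(image, mu = NULL, cfg = projector_config(),
                            angles_deg, w_list = NULL) {
  stopifnot(is_volume(image))
  if (anyNA(image$data)) stop("image contains NA/NaN")
  if (!is.null(mu)) check_same_grid(image, mu, "image and mu")
  d <- dim(image$data)
  vcm <- vox_cm(image)
  nearest <- cfg$interpolation == "nearest"
  sig <- plane_sigmas_vox(cfg, d[2], vcm)
  if (is.null(w_list)) w_list <- atten_weight_list(mu, angles_deg, nearest)
  empty <- array(0, c(0, 0, 0))
  proj <- array(0, c(d[1], d[3], length(angles_deg)))
  for (t in seq_along(angles_deg)) {
    w <- if (is.null(w_list)) empty else w_list[[t]]
    proj[, , t] <- forward_one_cpp(image$data, w, sig,
                                   angles_deg[t] * pi / 180, nearest)
  }
  projection_set(proj, angles_deg, bin_mm = image$voxel_mm, time_s = 1,
                 window = "forward_model")
}

#' Back projection (exact adjoint of [forward_project()])
#'
#' @param proj a [projection_set()].
#' @param mu attenuation volume or `NULL`.
#' @param cfg a [projector_config()].
#' @param grid_dim volume dimensions, needed when `mu` is `NULL`.
#' @param voxel_mm voxel size (mm) when `mu` is `NULL`.
#' @param w_list optional precomputed attenuation weights.
#' @return A `volume_image`.
#' @export
back_project <- function(proj, mu = NULL, cfg = projector_config(),
                         grid_dim = NULL, voxel_mm = NULL, w_list = NULL) {
  stopifnot(is_projection_set(proj))
  if (anyNA(proj$counts)) stop("projections contain NA/NaN")
  if (!is.null(mu)) {
    grid_dim <- dim(mu$data); voxel_mm <- mu$voxel_mm
  }
  if (is.null(grid_dim) || is.null(voxel_mm))
    stop("grid_dim and voxel_mm are required when mu is NULL")
  vcm <- voxel_mm / 10
  nearest <- cfg$interpolation == "nearest"
  sig <- plane_sigmas_vox(cfg, grid_dim[2], vcm)
  if (is.null(w_list)) w_list <- atten_weight_list(mu, proj$angles_deg, nearest)
  empty <- array(0, c(0, 0, 0))
  acc <- array(0, grid_dim)
  for (t in seq_along(proj$angles_deg)) {
    w <- if (is.null(w_list)) empty else w_list[[t]]
    acc <- acc + back_one_cpp(matrix(proj$counts[, , t],
                                     grid_dim[1], grid_dim[3]), w, sig,
                              proj$angles_deg[t] * pi / 180,
                              grid_dim[1], grid_dim[2], grid_dim[3], nearest)
  }
  volume_image(acc, voxel_mm)
}

#' Attenuation path length from a voxel to the surface
#'
#' Discrete line integral of mu (dimensionless, `sum(mu_i * step)`) from a
#' voxel centre to the volume boundary along a detector direction, computed
#' by ray marching with trilinear sampling at `cfg$ray_step_cm`.
#'
#' @param mu attenuation `volume_image` (1/cm).
#' @param voxel_index integer `c(i, j, k)` (1-based) of the voxel of
#'   interest.
#' @param direction_deg detector azimuth (degrees); the ray runs in the
#'   transaxial plane towards the detector, which for 0 degrees lies beyond
#'   the +y face.
#' @param cfg a [projector_config()] (for `ray_step_cm`).
#' @return Dimensionless attenuation path length.
#' @export
attenuation_path_length <- function(mu, voxel_index, direction_deg = 0,
                                    cfg = projector_config()) {
  stopifnot(is_volume(mu))
  d <- dim(mu$data)
  if (any(voxel_index < 1) || any(voxel_index > d))
    stop("voxel_index outside the grid")
  vcm <- vox_cm(mu)
  th <- direction_deg * pi / 180
  dir <- c(-sin(th), cos(th), 0)   # matches the rotated-frame +y convention
  step <- cfg$ray_step_cm
  pos <- (voxel_index - 1)         # voxel units
  dvox <- dir / vcm
  total <- 0
  repeat {
    # trilinear sample at pos (0-based voxel coordinates, edge clamped so
    # the integral runs to the volume boundary half a voxel beyond the
    # outermost centres)
    ps <- pmin(pmax(pos, 0), d - 1)
    p0 <- floor(ps); f <- ps - p0
    val <- 0
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
      q <- pmin(p0 + c(a, b, cc), d - 1)
      w <- prod(ifelse(c(a, b, cc) == 1, f, 1 - f))
      val <- val + w * mu$data[q[1] + 1, q[2] + 1, q[3] + 1]
    }
    total <- total + val * step
    pos <- pos + dvox * step
    if (any(pos < -0.5) || any(pos > d - 0.5)) break
  }
  # half-step correction: the first sample sits on the voxel centre
  total - 0.5 * step *
    mu$data[voxel_index[1], voxel_index[2], voxel_index[3]]
}
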