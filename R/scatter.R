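#' Energy-window widths for scatter estimation
#'
#' @param peak_width_kev photopeak window width (keV).
#' @param lower_width_kev lower scatter window width (keV).
#' @param upper_width_kev upper scatter window width (keV), `NULL` for DEW.
#' @return An object of class `window_arithmetic`.
#' @export
window_arithmetic <- function(peak_width_kev, lower_width_kev,
                              upper_width_kev = NULL) {
  if (peak_width_kev <= 0 || lower_width_kev <= 0 ||
      (!is.null(upper_width_kev) && upper_width_kev <= 0))
    stop("window widths must be positive")
  structure(list(peak_width_kev = peak_width_kev,
                 lower_width_kev = lower_width_kev,
                 upper_width_kev = upper_width_kev),
            class = "window_arithmetic")
}

# widths for a window's configured scatter windows
wa_from_window <- function(win) {
  sw <- win$scatter_windows
  if (length(sw) == 0) stop(sprintf("window %s has no scatter windows", win$label))
  lower <- sw$lower
  upper <- if (!is.null(sw$upper)) sw$upper else NULL
  window_arithmetic(win$width_kev, lower[1] * lower[2],
                    if (!is.null(upper)) upper[1] * upper[2] else NULL)
}

#' Dual-energy-window scatter estimate
#'
#' Bin-wise scaling of the lower-window counts by the width ratio
#' `W_peak / W_lower`.
#'
#' @param lower `projection_set` of lower scatter-window counts.
#' @param wa a [window_arithmetic()].
#' @return `projection_set` of estimated photopeak scatter counts.
#' @export
dew_estimate <- function(lower, wa) {
  stopifnot(is_projection_set(lower), inherits(wa, "window_arithmetic"))
  if (any(lower$counts < 0)) stop("counts must be non-negative")
  est <- lower$counts * (wa$peak_width_kev / wa$lower_width_kev)
  projection_set(est, lower$angles_deg, lower$bin_mm, lower$time_s,
                 window = paste0(lower$window, ":DEW"),
                 meta = lower$meta)
}

#' Triple-energy-window scatter estimate
#'
#' Trapezoidal estimate `(C_l / W_l + C_u / W_u) / 2 * W_p` per bin;
#' non-negative by construction (clipped defensively).
#'
#' @param lower,upper `projection_set`s of the scatter-window counts.
#' @param wa a [window_arithmetic()] with both widths set.
#' @return `projection_set` of estimated photopeak scatter counts.
#' @export
tew_estimate <- function(lower, upper, wa) {
  stopifnot(is_projection_set(lower), is_projection_set(upper))
  if (is.null(wa$upper_width_kev)) stop("TEW needs an upper window width")
  check_same_proj_geom(lower, upper, "TEW scatter windows")
  est <- (lower$counts / wa$lower_width_kev +
          upper$counts / wa$upper_width_kev) / 2 * wa$peak_width_kev
  est <- pmax(est, 0)
  projection_set(est, lower$angles_deg, lower$bin_mm, lower$time_s,
                 window = paste0(lower$window, ":TEW"),
                 meta = lower$meta)
}

#' Mono-exponential fit to a scatter-profile tail
#'
#' Least-squares fit of `a * exp(-b * x)` to the tail of a lateral scatter
#' profile (log-linear initialisation refined by nonlinear least squares).
#'
#' @param x lateral distances.
#' @param counts profile values.
#' @param tail_region logical or integer index selecting the tail samples;
#'   defaults to all samples.
#' @return list with `amplitude`, `slope`, `fitted`, and `rss`.
#' @export
fit_tail_monoexp <- function(x, counts, tail_region = NULL) {
  if (is.null(tail_region)) tail_region <- seq_along(x)
  xs <- x[tail_region]; ys <- counts[tail_region]
  if (length(ys) < 3 || any(ys <= 0))
    stop("tail region must contain at least 3 strictly positive samples")
  init <- stats::lm(log(ys) ~ xs)
  start <- list(a = exp(coef(init)[[1]]), b = -coef(init)[[2]])
  if (start$b <= 0) stop("tail does not decay; mono-exponential fit rejected")
  fit <- tryCatch(
    minpack.lm::nlsLM(ys ~ a * exp(-b * xs), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("mono-exponential tail fit failed: ",
                             conditionMessage(e)))
  co <- coef(fit)
  list(amplitude = co[["a"]], slope = co[["b"]],
       fitted = fitted(fit), rss = sum(residuals(fit)^2))
}

#' Fit the scatter-to-primary model
#'
#' Nonlinear least squares for `SF(p) = A - B * exp(-gamma * p) - 1` against
#' sampled scatter-to-primary fractions.
#'
#' @param path_lengths attenuation path lengths (dimensionless).
#' @param sf_values observed scatter-to-primary fractions.
#' @param voxel_cm voxel size recorded in the returned model.
#' @return An [sf_model()] with a `fit` attribute (rss, residuals).
#' @export
fit_sf_model <- function(path_lengths, sf_values, voxel_cm = NA_real_) {
  if (length(path_lengths) < 4)
    stop("need at least 4 samples spanning the path-length range")
  p <- path_lengths; y <- sf_values
  if (stats::sd(y) < 1e-10 * (1 + abs(mean(y)))) {
    # constant data: B = 0 generator, model reduces to A - 1
    m <- sf_model(mean(y) + 1, 0, 0.5, voxel_cm = voxel_cm,
                  p_max = max(p) * 1.5 + 1)
    attr(m, "fit") <- list(rss = 0, residuals = rep(0, length(y)))
    return(m)
  }
  startA <- max(y) + 1.05
  startB <- max(startA - 1 - min(y), 0.1)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A - B * exp(-g * p) - 1,
                      start = list(A = startA, B = startB, g = 0.5),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("scatter-to-primary fit did not converge: ",
                             conditionMessage(e),
                             "; residual range of data: ",
                             paste(signif(range(y), 4), collapse = " .. ")))
  co <- coef(fit)
  m <- sf_model(co[["A"]], co[["B"]], co[["g"]], voxel_cm = voxel_cm,
                p_max = max(p) * 1.5 + 1)
  attr(m, "fit") <- list(rss = sum(residuals(fit)^2),
                         residuals = as.numeric(residuals(fit)))
  m
}

# ---------------------------------------------------------------------------
# transmission-dependent scatter correction internals

# Per-angle geometry for TDSC: rotated attenuation paths, the in-medium
# source mask, per-plane depth below the surface, and a shared kernel cache.
tdsc_precompute <- function(mu, table, angles_deg, nearest = FALSE,
                            warn = FALSE) {
  d <- dim(mu$data)
  vcm <- vox_cm(mu)
  per_angle <- lapply(angles_deg, function(a) {
    murot <- rotate_xy_cpp(mu$data, a * pi / 180, FALSE, nearest)
    path <- atten_path_cpp(murot, vcm)
    support <- apply(murot > 1e-9, 2, any)
    j_surf <- if (any(support)) max(which(support)) else 0L
    depths <- rep(NA_real_, d[2])
    if (j_surf > 0) depths[1:j_surf] <- (j_surf - (1:j_surf)) * vcm
    list(path = path, medium = (murot > 1e-9) + 0, depths = depths)
  })
  all_depths <- sort(unique(round(unlist(lapply(per_angle, `[[`, "depths")), 6)))
  all_depths <- all_depths[!is.na(all_depths)]
  if (warn && length(all_depths) > 0 && min(all_depths) < min(table$depths_cm))
    warning(sprintf("slice depth %.2f cm below the shallowest kernel entry; using the nearest entry",
                    min(all_depths)))
  kernels <- lapply(all_depths, function(dd)
    kernel_matrix(table, dd, vcm, warn = FALSE))
  kidx_per_angle <- lapply(per_angle, function(pa) {
    idx <- match(round(pa$depths, 6), all_depths)
    idx[is.na(idx)] <- 0L
    as.integer(idx)
  })
  list(per_angle = per_angle, kernels = kernels,
       kidx = kidx_per_angle, angles_deg = angles_deg, nearest = nearest)
}

# scatter projections (all angles) for an image estimate, using a precompute
tdsc_scatter_counts <- function(image_data, pre, sf) {
  d <- dim(image_data)
  out <- array(0, c(d[1], d[3], length(pre$angles_deg)))
  for (t in seq_along(pre$angles_deg)) {
    rot <- rotate_xy_cpp(image_data, pre$angles_deg[t] * pi / 180,
                         FALSE, pre$nearest)
    out[, , t] <- tdsc_angle_cpp(rot, pre$per_angle[[t]]$path,
                                 pre$per_angle[[t]]$medium,
                                 pre$kernels, pre$kidx[[t]],
                                 sf$A, sf$B, sf$gamma)
  }
  out
}

#' Transmission-dependent scatter projection for one angle
#'
#' Each detector-parallel slice of the image estimate is convolved with the
#' scatter kernel for that slice's depth below the surface (taken from the
#' attenuation-map support along the detector direction), every voxel of the
#' convolved slice is scaled by the scatter-to-primary fraction at its
#' attenuation path length, and the assembled scatter image is summed along
#' the rays without further PSF blurring or attenuation.
#'
#' @param image current image estimate (`volume_image`).
#' @param mu attenuation map on the same grid.
#' @param table a [scatter_kernel_table()].
#' @param sf an [sf_model()].
#' @param angle_deg projection angle (degrees).
#' @param cfg a [projector_config()] (interpolation convention only).
#' @return matrix of scatter values on the detector grid.
#' @export
tdsc_scatter_projection <- function(image, mu, table, sf, angle_deg,
                                    cfg = projector_config()) {
  stopifnot(is_volume(image), is_volume(mu))
  check_same_grid(image, mu, "image and mu")
  pre <- tdsc_precompute(mu, table, angle_deg,
                         nearest = cfg$interpolation == "nearest",
                         warn = TRUE)
  tdsc_scatter_counts(image$data, pre, sf)[, , 1]
}
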