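#' VOI statistics
#'
#' @param image a `volume_image`.
#' @param mask logical array on the image grid.
#' @param label optional VOI label.
#' @return list with `mean`, `sd`, `volume_ml`, `n_voxels`, `label`.
#' @export
voi_stats <- function(image, mask, label = "") {
  stopifnot(is_volume(image))
  if (!any(mask)) stop("empty VOI mask")
  v <- image$data[mask]
  list(mean = mean(v), sd = stats::sd(v),
       volume_ml = sum(mask) * voxel_volume_ml(image),
       n_voxels = sum(mask), label = label)
}

#' Recovery coefficient
#'
#' `RC = 100 * mean(image within VOI) / true_ac` (percent, no spill-over
#' correction).
#'
#' @param image calibrated `volume_image`.
#' @param voi_mask logical array.
#' @param true_ac true activity concentration (same units as the image).
#' @return RC in percent.
#' @export
compute_rc <- function(image, voi_mask, true_ac) {
  if (true_ac <= 0) stop("true_ac must be positive")
  if (!any(voi_mask)) stop("empty VOI mask")
  100 * mean(image$data[voi_mask]) / true_ac
}

#' Contrast-to-noise ratio
#'
#' `CNR = (mu_VOI - mu_Background) / sigma_Background`, where the
#' background mean is the average of the per-VOI means and the background
#' standard deviation the average of the per-VOI standard deviations over
#' the (four) background VOIs.
#'
#' @param image a `volume_image`.
#' @param voi_mask logical array for the signal VOI.
#' @param bg_masks list of logical arrays for the background VOIs.
#' @return dimensionless CNR.
#' @export
compute_cnr <- function(image, voi_mask, bg_masks) {
  if (!any(voi_mask)) stop("empty signal VOI")
  if (length(bg_masks) == 0 || !all(vapply(bg_masks, any, logical(1))))
    stop("background VOIs must be non-empty")
  mu_voi <- mean(image$data[voi_mask])
  mu_bg <- mean(vapply(bg_masks, function(m) mean(image$data[m]), numeric(1)))
  sd_bg <- mean(vapply(bg_masks, function(m) stats::sd(image$data[m]),
                       numeric(1)))
  if (!is.finite(sd_bg) || sd_bg <= 0)
    stop("degenerate (noiseless) background: sigma is zero")
  (mu_voi - mu_bg) / sd_bg
}

#' Auto-placed rectangular background VOIs
#'
#' Places axis-aligned boxes of the requested volumes inside the cylinder by
#' seeded rejection sampling, at least `min_dist_cm` from every sphere
#' surface, disjoint from each other. Default volumes follow the reference
#' set (54, 145, 260 and 280 ml).
#'
#' @param spec a [phantom_spec()].
#' @param template `volume_image` providing the grid.
#' @param volumes_ml VOI volumes (ml).
#' @param min_dist_cm minimum distance from any sphere surface (cm).
#' @param seed RNG seed.
#' @param max_tries rejection-sampling attempts per VOI.
#' @return list of logical mask arrays (named `bg1` ...), with a `boxes`
#'   attribute giving centres and edge lengths (cm).
#' @export
place_background_vois <- function(spec, template,
                                  volumes_ml = c(54, 145, 260, 280),
                                  min_dist_cm = 3, seed = 1L,
                                  max_tries = 20000) {
  stopifnot(inherits(spec, "phantom_spec"), is_volume(template))
  R <- spec$cylinder_diameter_cm / 2
  H <- spec$cylinder_height_cm
  ctr <- spec$sphere_centers_cm
  rad <- spec$sphere_radii_cm
  nsph <- length(rad)
  boxes <- list()
  with_seed(seed, {
    for (vi in order(volumes_ml, decreasing = TRUE)) {
      V <- volumes_ml[vi]
      h <- min(V^(1/3), 6)
      s <- sqrt(V / h)
      half <- c(s, s, h) / 2
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        # uniform in the cylinder cross-section, away from the rim
        repeat {
          cxy <- runif(2, -R, R)
          if (sqrt(sum(cxy^2)) <= R) break
        }
        cz <- runif(1, -H / 2 + half[3], H / 2 - half[3])
        cen <- c(cxy, cz)
        # fully inside the cylinder
        if (sqrt(sum((abs(cxy) + half[1:2])^2)) > R) next
        # clearance from every sphere surface
        ok <- TRUE
        for (ss in seq_len(nsph)) {
          gap <- pmax(abs(ctr[ss, ] - cen) - half, 0)
          if (sqrt(sum(gap^2)) < rad[ss] + min_dist_cm) { ok <- FALSE; break }
        }
        if (!ok) next
        # disjoint from previously accepted boxes
        for (b in boxes) {
          if (all(abs(b$center - cen) < b$half + half)) { ok <- FALSE; break }
        }
        if (!ok) next
        boxes[[length(boxes) + 1]] <- list(center = cen, half = half,
                                           volume_ml = V)
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf("could not place a %.0f ml background VOI after %d tries",
                     V, max_tries))
    }
  })
  g <- coord_grids(template)
  masks <- lapply(boxes, function(b)
    abs(g$x - b$center[1]) <= b$half[1] &
    abs(g$y - b$center[2]) <= b$half[2] &
    abs(g$z - b$center[3]) <= b$half[3])
  names(masks) <- paste0("bg", seq_along(masks))
  attr(masks, "boxes") <- boxes
  masks
}

#' Isocontour segmentation
#'
#' Voxels of the search region at or above `threshold_pct` percent of the
#' regional maximum, restricted to the 26-connected component containing the
#' maximum voxel.
#'
#' @param image a `volume_image`.
#' @param search_region logical array restricting the search.
#' @param threshold_pct isocontour threshold in percent of the regional max
#'   (0 < threshold <= 100).
#' @return logical mask array.
#' @export
isocontour_segment <- function(image, search_region, threshold_pct) {
  stopifnot(is_volume(image), threshold_pct > 0, threshold_pct <= 100)
  if (!any(search_region)) stop("empty search region")
  vals <- image$data
  mx <- max(vals[search_region])
  cand <- search_region & (vals >= threshold_pct / 100 * mx - 1e-12)
  seed <- which(search_region & vals == mx)[1]
  comp <- component_from_seed_cpp(as.logical(cand), dim(vals),
                                  as.integer(seed - 1L))
  array(comp, dim(vals))
}

#' Calibrate the isocontour threshold against a known volume
#'
#' Returns the candidate threshold whose isocontour mask volume deviates
#' least (in absolute terms) from the true volume; ties break toward the
#' smaller threshold.
#'
#' @param image a `volume_image`.
#' @param search_region logical array around the reference object.
#' @param true_volume_ml known object volume (ml); default 48 (the smallest
#'   phantom sphere).
#' @param candidate_pcts candidate thresholds (percent); default 40-95 in
#'   5% steps.
#' @return the selected threshold (percent), with attribute `volumes_ml`.
#' @export
calibrate_isocontour_threshold <- function(image, search_region,
                                           true_volume_ml = 48,
                                           candidate_pcts = seq(40, 95, 5)) {
  if (length(candidate_pcts) == 0) stop("no candidate thresholds")
  vols <- vapply(candidate_pcts, function(p)
    sum(isocontour_segment(image, search_region, p)) *
      voxel_volume_ml(image), numeric(1))
  best <- candidate_pcts[which.min(abs(vols - true_volume_ml))]
  attr(best, "volumes_ml") <- stats::setNames(vols, candidate_pcts)
  best
}
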