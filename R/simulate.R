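#' Simulate SPECT projections for one energy window
#'
#' Expected photopeak counts are the attenuated, resolution-blurred forward
#' projection of the activity map scaled by dwell time, emission probability
#' and detector sensitivity. When a scatter model is supplied, an additive
#' scatter term is generated with the same depth-dependent kernel formalism
#' used by transmission-dependent scatter correction; adjacent scatter
#' windows receive the width-scaled fraction of that scatter term. All
#' Poisson sampling is governed by the acquisition seed.
#'
#' @param activity activity-concentration `volume_image` (kBq/ml).
#' @param mu attenuation `volume_image` (1/cm) on the same grid.
#' @param window an [energy_window()].
#' @param acq an [acquisition_spec()].
#' @param scatter_model `NULL` for primaries only, or a list with `table`
#'   ([scatter_kernel_table()]) and `sf` ([sf_model()]).
#' @param cfg a [projector_config()].
#' @param sensitivity detector efficiency (counts per emitted photon
#'   reaching the ideal detector); single scalar per window.
#' @param scatter_mismatch multiplier applied to the simulated scatter term
#'   so the correction can be exercised under an imperfect model (default 1,
#'   matched model).
#' @param scatter_window_fraction scale of the scatter-window expectation
#'   relative to the width-proportional share of the photopeak scatter.
#' @param noise `FALSE` returns expected counts without Poisson sampling.
#' @return list with `photopeak` (a [projection_set()]), `scatter_windows`
#'   (named list of projection sets, possibly empty), and the noise-free
#'   `primary_truth` and `scatter_truth` sets.
#' @export
simulate_projections <- function(activity, mu, window, acq,
                                 scatter_model = NULL,
                                 cfg = projector_config(),
                                 sensitivity = 1e-4,
                                 scatter_mismatch = 1,
                                 scatter_window_fraction = 1,
                                 noise = TRUE) {
  stopifnot(is_volume(activity), is_volume(mu),
            inherits(window, "energy_window"),
            inherits(acq, "acquisition_spec"))
  check_same_grid(activity, mu, "activity and mu")
  angles <- acq$angles_deg
  t_s <- acq$time_per_projection_s
  scale <- voxel_volume_ml(activity) * 1000 *
    window$emission_probability * sensitivity * t_s
  fp <- forward_project(activity, mu, cfg, angles)
  primary <- fp$counts * scale
  if (!is.null(scatter_model)) {
    pre <- tdsc_precompute(mu, scatter_model$table, angles,
                           nearest = cfg$interpolation == "nearest")
    scatter <- tdsc_scatter_counts(activity$data, pre, scatter_model$sf) *
      scale * scatter_mismatch
  } else {
    scatter <- array(0, dim(primary))
  }
  meta <- list(seed = acq$seed, sensitivity = sensitivity,
               emission_probability = window$emission_probability,
               scatter_mismatch = scatter_mismatch)
  mk <- function(counts, label, time = t_s)
    projection_set(counts, angles, acq$bin_mm, time, window = label,
                   meta = meta)
  sw_expected <- list()
  for (nm in names(window$scatter_windows)) {
    sw <- window$scatter_windows[[nm]]
    frac <- (sw[1] * sw[2]) / window$width_kev * scatter_window_fraction
    sw_expected[[nm]] <- scatter * frac
  }
  if (noise) {
    res <- with_seed(acq$seed, {
      pk <- array(rpois(length(primary), primary + scatter), dim(primary))
      sws <- lapply(sw_expected, function(e)
        array(rpois(length(e), e), dim(e)))
      list(pk = pk, sws = sws)
    })
  } else {
    res <- list(pk = primary + scatter, sws = sw_expected)
  }
  sw_sets <- list()
  for (nm in names(sw_expected))
    sw_sets[[nm]] <- mk(res$sws[[nm]], paste0(window$label, ":", nm))
  list(photopeak = mk(res$pk, window$label),
       scatter_windows = sw_sets,
       primary_truth = mk(primary, paste0(window$label, ":primary")),
       scatter_truth = mk(scatter, paste0(window$label, ":scatter")))
}
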