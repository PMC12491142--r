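#' Read and write specification objects as YAML
#'
#' Phantom, acquisition and projector specifications round-trip through
#' plain YAML so that study configurations can live outside R scripts.
#'
#' @param spec a `phantom_spec`, `acquisition_spec` or `projector_config`.
#' @param path YAML file path.
#' @export
write_spec_yaml <- function(spec, path) {
  cls <- class(spec)[1]
  obj <- unclass(spec)
  if (cls == "phantom_spec" && !is.null(obj$sphere_centers_cm))
    obj$sphere_centers_cm <- apply(obj$sphere_centers_cm, 1, as.numeric,
                                   simplify = FALSE)
  yaml::write_yaml(c(list(.class = cls), obj), path)
  invisible(path)
}

#' @rdname write_spec_yaml
#' @export
read_spec_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  cls <- obj$.class
  obj$.class <- NULL
  switch(cls,
    phantom_spec = phantom_spec(
      cylinder_diameter_cm = obj$cylinder_diameter_cm,
      cylinder_volume_ml = obj$cylinder_volume_ml,
      sphere_volumes_ml = as.numeric(obj$sphere_volumes_ml),
      sphere_centers_cm = if (length(obj$sphere_volumes_ml) > 0)
        do.call(rbind, lapply(obj$sphere_centers_cm, as.numeric)) else NULL,
      sphere_ac_kbq_ml = obj$sphere_ac_kbq_ml,
      background_ac_kbq_ml = obj$background_ac_kbq_ml,
      mu_water_cm = obj$mu_water_cm,
      voxel_mm = obj$voxel_mm),
    acquisition_spec = acquisition_spec(
      n_projections = obj$n_projections,
      time_per_projection_s = obj$time_per_projection_s,
      matrix_size = obj$matrix_size, bin_mm = obj$bin_mm,
      angular_range_deg = obj$angular_range_deg, seed = obj$seed),
    projector_config = projector_config(
      psf_sigma0_cm = obj$psf_sigma0_cm, psf_slope = obj$psf_slope,
      interpolation = obj$interpolation, ray_step_cm = obj$ray_step_cm),
    stop("unknown spec class in YAML: ", cls))
}
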