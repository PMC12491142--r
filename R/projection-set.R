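#' Stack of 2-D count projections
#'
#' Projections are stored as an `(nbin_u, nbin_v, n_angles)` array: `u` is the
#' transaxial detector coordinate, `v` the axial one. Counts carry the
#' acquisition dwell time and an energy-window tag so that downstream
#' operations can refuse mismatched inputs.
#'
#' @param counts numeric 3-D array of counts (or expected counts).
#' @param angles_deg projection angles in degrees, one per slice of `counts`.
#' @param bin_mm detector bin size (mm, square bins).
#' @param time_s dwell time per projection (s).
#' @param window energy-window label, e.g. `"440keV"`.
#' @param meta optional list of provenance fields (seed, model flags ...).
#' @return An object of class `projection_set`.
#' @export
projection_set <- function(counts, angles_deg, bin_mm, time_s,
                           window = "unknown", meta = list()) {
  stopifnot(is.array(counts), length(dim(counts)) == 3L)
  if (dim(counts)[3] != length(angles_deg))
    stop("number of angle entries does not match projection stack depth")
  if (anyNA(counts)) stop("projection counts contain NA/NaN")
  structure(list(counts = counts, angles_deg = as.numeric(angles_deg),
                 bin_mm = bin_mm, time_s = time_s, window = window,
                 meta = meta),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<projection_set> %s: %d x %d bins, %d angles, %.3g s/projection\n",
    x$window, d[1], d[2], d[3], x$time_s))
  cat(sprintf("  total counts %.6g\n", sum(x$counts)))
  invisible(x)
}

is_projection_set <- function(x) inherits(x, "projection_set")

check_same_proj_geom <- function(a, b, what = "projection sets") {
  ok <- identical(dim(a$counts), dim(b$counts)) &&
    isTRUE(all.equal(a$angles_deg, b$angles_deg)) &&
    isTRUE(all.equal(a$bin_mm, b$bin_mm))
  if (!ok) stop(sprintf("%s do not share acquisition geometry", what))
  invisible(TRUE)
}

#' Write / read a projection set (NIfTI stack plus JSON sidecar)
#'
#' @param p a `projection_set`.
#' @param stem file stem; writes `<stem>.nii.gz` and `<stem>.json`.
#' @export
write_projection_set <- function(p, stem) {
  stopifnot(is_projection_set(p))
  img <- RNifti::asNifti(p$counts, pixdim = c(p$bin_mm, p$bin_mm, 1))
  RNifti::writeNifti(img, paste0(stem, ".nii.gz"))
  side <- list(angles_deg = p$angles_deg, bin_mm = p$bin_mm,
               time_s = p$time_s, window = p$window, meta = p$meta)
  jsonlite::write_json(side, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_projection_set
#' @export
read_projection_set <- function(stem) {
  img <- RNifti::readNifti(paste0(stem, ".nii.gz"))
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  projection_set(array(as.numeric(img), dim = dim(img)),
                 angles_deg = side$angles_deg, bin_mm = side$bin_mm,
                 time_s = side$time_s, window = side$window,
                 meta = as.list(side$meta))
}
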