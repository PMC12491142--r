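#' 3-D scalar volume with voxel geometry
#'
#' Container for an isotropically sampled 3-D scalar grid (activity
#' concentration, count rate, linear attenuation, or integer labels).
#'
#' @param data numeric 3-D array.
#' @param voxel_mm isotropic voxel edge length in millimetres.
#' @param origin physical position (cm) of the centre of voxel `[1,1,1]`;
#'   defaults to placing the grid centre at the origin.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, voxel_mm, origin = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            is.numeric(voxel_mm), voxel_mm > 0)
  if (anyNA(data)) stop("volume contains NA/NaN values")
  d <- dim(data)
  vcm <- voxel_mm / 10
  if (is.null(origin)) origin <- -(d - 1) / 2 * vcm
  structure(list(data = data, voxel_mm = voxel_mm, origin = origin),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_image> %d x %d x %d voxels, %.2f mm isotropic\n",
              d[1], d[2], d[3], x$voxel_mm))
  cat(sprintf("  range [%.4g, %.4g], sum %.6g\n",
              min(x$data), max(x$data), sum(x$data)))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "volume_image")

vox_cm <- function(v) v$voxel_mm / 10

#' Voxel volume in millilitres
#'
#' @param v a `volume_image`.
#' @return voxel volume (ml; 1 cm^3 == 1 ml).
#' @export
voxel_volume_ml <- function(v) (v$voxel_mm / 10)^3

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$voxel_mm, b$voxel_mm))
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("%s do not share a grid (dims %s vs %s, voxel %.3g vs %.3g mm)",
                 what, paste(dim(a$data), collapse = "x"),
                 paste(dim(b$data), collapse = "x"),
                 a$voxel_mm, b$voxel_mm))
  invisible(TRUE)
}

# physical coordinates (cm) of voxel centres along each axis
axis_coords <- function(v) {
  d <- dim(v$data)
  lapply(1:3, function(a) v$origin[a] + (seq_len(d[a]) - 1) * vox_cm(v))
}

#' Coordinate grids for a volume
#'
#' Returns three arrays with the x, y, z physical coordinates (cm) of every
#' voxel centre. Useful for constructing masks.
#' @param v a `volume_image`.
#' @return list with arrays `x`, `y`, `z`.
#' @export
coord_grids <- function(v) {
  d <- dim(v$data)
  ax <- axis_coords(v)
  list(x = array(rep(ax[[1]], times = d[2] * d[3]), d),
       y = array(rep(rep(ax[[2]], each = d[1]), times = d[3]), d),
       z = array(rep(ax[[3]], each = d[1] * d[2]), d))
}

#' Write / read a volume as NIfTI
#'
#' @param v a `volume_image`.
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   `volume_image`.
#' @export
write_volume <- function(v, path) {
  stopifnot(is_volume(v))
  img <- RNifti::asNifti(v$data,
                         pixdim = rep(v$voxel_mm, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1]
  volume_image(array(as.numeric(img), dim = dim(img)), voxel_mm = vox)
}
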