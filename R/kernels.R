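#' Depth-indexed scatter kernel table
#'
#' One mono-exponential kernel per slab depth: the lateral scatter signal
#' behind `depth` cm of water decays as `amplitude * exp(-slope * r)`.
#' Between tabulated depths, slope and amplitude are interpolated linearly;
#' queries beyond the deepest entry are clamped to it (the standard rule when
#' the patient is thicker than the deepest simulated slab), and queries below
#' the shallowest entry use the shallowest one.
#'
#' @param depths_cm strictly increasing slab depths (cm).
#' @param slopes_cm per-depth exponential decay constants (1/cm), positive.
#' @param amplitudes per-depth kernel scales (default 1).
#' @param normalization `"unit_sum"` (kernel sums to one before applying the
#'   amplitude) or `"none"`.
#' @return An object of class `scatter_kernel_table`.
#' @export
scatter_kernel_table <- function(depths_cm, slopes_cm,
                                 amplitudes = rep(1, length(depths_cm)),
                                 normalization = c("unit_sum", "none")) {
  normalization <- match.arg(normalization)
  n <- length(depths_cm)
  if (length(slopes_cm) != n || length(amplitudes) != n)
    stop("depths, slopes and amplitudes must have the same length")
  if (n < 1) stop("kernel table needs at least one depth")
  if (is.unsorted(depths_cm, strictly = TRUE) || any(depths_cm <= 0))
    stop("depths must be strictly increasing and positive")
  if (any(slopes_cm <= 0)) stop("slopes must be positive")
  structure(list(depths_cm = depths_cm, slopes_cm = slopes_cm,
                 amplitudes = amplitudes, normalization = normalization),
            class = "scatter_kernel_table")
}

#' Scatter-to-primary fraction model
#'
#' The scatter-to-primary fraction as a function of the attenuation path
#' length p (dimensionless, sum of mu_i * voxel size along the ray to the
#' surface): `SF(p) = A - B * exp(-gamma * p) - 1`. The model must be
#' non-negative over the admissible path range, which is validated on
#' construction.
#'
#' @param A,B,gamma model coefficients.
#' @param voxel_cm voxel size used when the path lengths were accumulated.
#' @param p_max largest admissible path length used for validation.
#' @return An object of class `sf_model`.
#' @export
sf_model <- function(A, B, gamma, voxel_cm = NA_real_, p_max = 10) {
  pr <- seq(0, p_max, length.out = 201)
  if (min(A - B * exp(-gamma * pr) - 1) < -1e-9)
    stop("scatter-to-primary model is negative over the admissible path range")
  structure(list(A = A, B = B, gamma = gamma, voxel_cm = voxel_cm,
                 p_max = p_max), class = "sf_model")
}

#' Evaluate a scatter-to-primary model
#'
#' @param sf an [sf_model()].
#' @param path attenuation path length(s), dimensionless.
#' @return SF value(s), clipped at zero.
#' @export
sf_eval <- function(sf, path) {
  pmax(sf$A - sf$B * exp(-sf$gamma * path) - 1, 0)
}

#' Build a synthetic kernel table and scatter-to-primary model
#'
#' Stand-in for the Monte-Carlo slab simulations that calibrate
#' transmission-dependent scatter correction: tail slopes follow a smooth
#' slope law `b(d) = b_inf + (b0 - b_inf) * exp(-d / d_scale)` and the
#' scatter-to-primary coefficients are taken as given. The default law
#' (b0 = 0.5, b_inf = 0.25, d_scale = 15 cm) changes by well under 3% per
#' additional 2 cm beyond 40 cm depth, matching the behaviour that justifies
#' clamping deeper queries to the 40 cm entry.
#'
#' @param depths_cm slab depths; default 2-40 cm in 2 cm steps.
#' @param slope_law list with `b0`, `b_inf`, `d_scale_cm`, or a
#'   `function(depth_cm)` returning slopes (1/cm).
#' @param sf_coeffs numeric `c(A, B, gamma)` for the [sf_model()].
#' @param voxel_cm voxel size recorded in the SF model.
#' @return list with elements `table` ([scatter_kernel_table()]) and `sf`
#'   ([sf_model()]).
#' @export
make_kernel_table <- function(depths_cm = seq(2, 40, by = 2),
                              slope_law = list(b0 = 0.5, b_inf = 0.25,
                                               d_scale_cm = 15),
                              sf_coeffs = c(A = 1.5, B = 0.45, gamma = 0.5),
                              voxel_cm = NA_real_) {
  if (is.unsorted(depths_cm, strictly = TRUE) || any(depths_cm <= 0))
    stop("depths must be strictly increasing and positive")
  slopes <- if (is.function(slope_law)) slope_law(depths_cm)
            else slope_law$b_inf + (slope_law$b0 - slope_law$b_inf) *
                 exp(-depths_cm / slope_law$d_scale_cm)
  list(table = scatter_kernel_table(depths_cm, slopes),
       sf = sf_model(sf_coeffs[[1]], sf_coeffs[[2]], sf_coeffs[[3]],
                     voxel_cm = voxel_cm))
}

#' Read / write kernel tables as CSV
#'
#' Plain `depth_cm, slope, amplitude` columns.
#'
#' @param table a [scatter_kernel_table()].
#' @param path CSV file path.
#' @export
write_kernel_table_csv <- function(table, path) {
  utils::write.csv(data.frame(depth_cm = table$depths_cm,
                              slope = table$slopes_cm,
                              amplitude = table$amplitudes),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kernel_table_csv
#' @param normalization convention tag for the reconstructed table.
#' @export
read_kernel_table_csv <- function(path, normalization = "unit_sum") {
  df <- utils::read.csv(path)
  scatter_kernel_table(df$depth_cm, df$slope, df$amplitude,
                       normalization = normalization)
}

#' Kernel parameters at a queried depth
#'
#' Linear interpolation between tabulated depths; clamped to the end entries
#' (deep clamp per the >40 cm rule; shallow clamp with a warning when
#' `warn = TRUE`).
#'
#' @param table a [scatter_kernel_table()].
#' @param depth_cm queried depth (cm).
#' @param warn warn when the query is shallower than the table.
#' @return list with `slope` and `amplitude`.
#' @export
kernel_at_depth <- function(table, depth_cm, warn = TRUE) {
  d <- table$depths_cm
  if (depth_cm < d[1]) {
    if (warn)
      warning(sprintf("depth %.2f cm below the shallowest table entry (%.2f cm); using the nearest entry",
                      depth_cm, d[1]))
    depth_cm <- d[1]
  }
  if (depth_cm > d[length(d)]) depth_cm <- d[length(d)]
  list(slope = stats::approx(d, table$slopes_cm, xout = depth_cm)$y,
       amplitude = stats::approx(d, table$amplitudes, xout = depth_cm)$y)
}

#' 2-D scatter kernel matrix for a depth
#'
#' Isotropic in the detector-parallel plane, truncated at radius 5 / slope
#' and normalized according to the table's convention.
#'
#' @param table a [scatter_kernel_table()].
#' @param depth_cm queried depth (cm).
#' @param voxel_cm lateral sampling (cm).
#' @param warn passed to [kernel_at_depth()].
#' @return odd-sized square matrix.
#' @export
kernel_matrix <- function(table, depth_cm, voxel_cm, warn = TRUE) {
  kp <- kernel_at_depth(table, depth_cm, warn = warn)
  rmax_cm <- 5 / kp$slope
  h <- max(1L, as.integer(ceiling(rmax_cm / voxel_cm)))
  off <- (-h:h) * voxel_cm
  r <- sqrt(outer(off^2, off^2, "+"))
  K <- exp(-kp$slope * r)
  K[r > rmax_cm] <- 0
  if (table$normalization == "unit_sum") K <- K / sum(K)
  K * kp$amplitude
}
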