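# Shared fixtures: everything is generated in code at test time.

# projector without resolution modelling (exact ray sums)
cfg_noblur <- function() projector_config(psf_sigma0_cm = 0, psf_slope = 0)

# a small uniform-mu volume with a single unit voxel
unit_voxel_volume <- function(n = 32, at = c(16, 18, 16), voxel_mm = 7.2,
                              mu = 0.15) {
  a <- array(0, rep(n, 3))
  a[at[1], at[2], at[3]] <- 1
  list(img = volume_image(a, voxel_mm),
       mu = volume_image(array(mu, rep(n, 3)), voxel_mm))
}

# default phantom voxelized at a given grid
small_phantom <- function(grid_n = 48, voxel_mm = 7.2) {
  spec <- phantom_spec(voxel_mm = voxel_mm)
  c(build_phantom(spec, grid_n), list(spec = spec))
}

# window-width arithmetic for a configured energy window
wa_from_window_test <- function(win) acspect:::wa_from_window(win)

# Gaussian blur in the family the PVC methods assume (renormalised,
# flux-preserving); used to construct blurred inputs for recovery tests
blur_for_test <- function(a, sigma_cm, voxel_mm = 7.2) {
  acspect:::blur_norm(a, sigma_cm * 10 / voxel_mm)
}

# independent dense Gaussian convolution oracle (FFT in plain R, generous
# zero padding; independent of the compiled blur path)
fft_blur_oracle <- function(a, sigma_vox) {
  d <- dim(a)
  h <- ceiling(4 * sigma_vox)
  dp <- d + 2 * h
  pad <- array(0, dp)
  pad[seq_len(d[1]) + h, seq_len(d[2]) + h, seq_len(d[3]) + h] <- a
  ax <- function(n) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    exp(-0.5 * x^2 / sigma_vox^2)
  }
  kx <- ax(dp[1]); ky <- ax(dp[2]); kz <- ax(dp[3])
  K <- outer(outer(kx, ky), kz)
  K <- K / sum(K)
  conv <- Re(fft(fft(pad) * fft(K), inverse = TRUE)) / prod(dp)
  conv[seq_len(d[1]) + h, seq_len(d[2]) + h, seq_len(d[3]) + h]
}
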