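# Internal FFT helpers shared by the forward model and the reconstruction.
# All k-space coordinates are in cycles/mm on the unshifted FFT grid.

fft_freq <- function(n, d = 1) {
  idx <- 0:(n - 1)
  idx[idx > n %/% 2] <- idx[idx > n %/% 2] - n
  idx / (n * d)
}

fft3 <- function(x) fft(x)
ifft3 <- function(x) fft(x, inverse = TRUE) / length(x)

# Zero-pad an array at the trailing end of each dimension
pad_array <- function(x, dim_out) {
  d <- dim(x)
  if (all(d == dim_out)) return(x)
  out <- array(0, dim = dim_out)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- x
  out
}

crop_array <- function(x, dim_out) {
  x[seq_len(dim_out[1]), seq_len(dim_out[2]), seq_len(dim_out[3]), drop = FALSE]
}

# Even (mirror) extension to twice the size along every axis; used so spectral
# differentiation sees a continuous periodic signal.
mirror_extend <- function(x) {
  d <- dim(x)
  x <- x[c(seq_len(d[1]), rev(seq_len(d[1]))), , , drop = FALSE]
  x <- x[, c(seq_len(d[2]), rev(seq_len(d[2]))), , drop = FALSE]
  x[, , c(seq_len(d[3]), rev(seq_len(d[3]))), drop = FALSE]
}

# Squared spatial-frequency magnitude |k|^2 on the FFT grid (cycles^2/mm^2)
ksq_grid <- function(dim, voxel_size) {
  kx <- fft_freq(dim[1], voxel_size[1])
  ky <- fft_freq(dim[2], voxel_size[2])
  kz <- fft_freq(dim[3], voxel_size[3])
  k2 <- array(0, dim = dim)
  k2 <- outer(outer(kx^2, ky^2, `+`), kz^2, `+`)
  dim(k2) <- dim
  k2
}

# (k . b_hat)^2 on the FFT grid for an arbitrary unit field direction
kdotb_sq_grid <- function(dim, voxel_size, b_hat) {
  kx <- fft_freq(dim[1], voxel_size[1])
  ky <- fft_freq(dim[2], voxel_size[2])
  kz <- fft_freq(dim[3], voxel_size[3])
  kb <- outer(outer(kx * b_hat[1], ky * b_hat[2], `+`), kz * b_hat[3], `+`)
  dim(kb) <- dim
  kb^2
}

# Spectral Laplacian multiplier: -(2*pi)^2 |k|^2
laplacian_multiplier <- function(dim, voxel_size) {
  -(2 * pi)^2 * ksq_grid(dim, voxel_size)
}

# FFT of a normalised sphere kernel of given radius (mm), centred at the
# origin of the periodic grid. Used for spherical-mean-value filtering.
smv_kernel_fft <- function(dim, voxel_size, radius_mm) {
  cx <- fft_freq(dim[1]) * dim[1] * voxel_size[1]
  cy <- fft_freq(dim[2]) * dim[2] * voxel_size[2]
  cz <- fft_freq(dim[3]) * dim[3] * voxel_size[3]
  r2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
  dim(r2) <- dim
  ker <- array(0, dim = dim)
  ker[r2 <= radius_mm^2] <- 1
  ker <- ker / sum(ker)
  fft3(ker)
}

# Circular convolution of a real array with a kernel given in k-space
fft_convolve <- function(x, kernel_fft) {
  Re(ifft3(fft3(x) * kernel_fft))
}
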