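#' @useDynLib gaussflex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft rnorm runif median sd cor prcomp quantile setNames
#' @importFrom utils head tail
NULL

# Orthonormal 2D FFT of a matrix (unitary: ||fft2o(x)|| == ||x||).
fft2o <- function(x, inverse = FALSE) {
  stats::fft(x, inverse = inverse) / sqrt(length(x))
}

# Orthonormal 3D FFT of an array.
fft3o <- function(x, inverse = FALSE) {
  stats::fft(x, inverse = inverse) / sqrt(length(x))
}

# Orthonormal 2D FFT applied slice-wise to an n x n x B array.
fft2o_batch <- function(x, inverse = FALSE) {
  d <- dim(x)
  out <- array(0i, d)
  s <- sqrt(as.numeric(d[1]) * d[2])
  for (b in seq_len(d[3])) out[, , b] <- stats::fft(x[, , b], inverse = inverse) / s
  out
}

# Signed integer frequency index for an even-sized DFT grid:
# 0, 1, ..., n/2-1, -n/2, ..., -1
fft_index <- function(n) {
  j <- 0:(n - 1)
  ifelse(j < n / 2, j, j - n)
}

# Spatial frequencies (cycles/Angstrom) along one axis.
fft_freq <- function(n, pixel_size) fft_index(n) / (n * pixel_size)

# n x n matrices of kx, ky (cycles/Angstrom) in FFT order.
freq_grid2 <- function(n, pixel_size) {
  f <- fft_freq(n, pixel_size)
  list(kx = matrix(f, n, n), ky = matrix(f, n, n, byrow = TRUE))
}

# Integer Fourier-shell index (0-based) for every element of an n x n grid.
shell_index2 <- function(n) {
  s <- fft_index(n)
  r <- sqrt(outer(s^2, s^2, "+"))
  pmin(as.integer(round(r)), as.integer(n / 2))
}

shell_index3 <- function(n) {
  s <- fft_index(n)
  r2 <- outer(outer(s^2, s^2, "+"), s^2, "+")
  pmin(as.integer(round(sqrt(r2))), as.integer(n / 2))
}

# 0-based index vector mapping data-grid FFT bins into an oversampled grid
# of size n_fine = n * os (same Fourier spacing, wider coverage).
crop_index <- function(n, n_fine) {
  s <- fft_index(n)
  (s %% n_fine) + 1L
}

# fftshift for matrices / 3D arrays (DC moved to centre index n/2, 0-based).
fftshift2 <- function(x) {
  n <- nrow(x)
  i <- c((n / 2 + 1):n, 1:(n / 2))
  x[i, i]
}

ifftshift2 <- fftshift2  # even n: shift is its own inverse

fftshift3 <- function(x) {
  n <- dim(x)[1]
  i <- c((n / 2 + 1):n, 1:(n / 2))
  x[i, i, i]
}
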