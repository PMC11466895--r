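# Image formation: a (deformed) Gaussian model is projected by splatting
# its centre points onto an oversampled 2D grid with bilinear weights,
# Fourier transformed, and multiplied by the analytic Gaussian transfer and
# the CTF. All Fourier images live on the data-sized n x n grid in FFT
# order; the orthonormal convention (fft / n) is used everywhere, so
# Parseval holds with constant 1 between real and Fourier space.

#' Imaging context
#'
#' Precomputes grids and index maps shared by all forward evaluations.
#'
#' @param box image size in pixels.
#' @param pixel_size pixel size in Angstrom.
#' @param oversample real-space oversampling factor of the splat grid
#'   (default 2).
#' @return list used by the forward-model functions.
#' @export
make_imaging_context <- function(box, pixel_size, oversample = 2) {
  nf <- box * oversample
  ci <- crop_index(box, nf)
  crop2 <- as.matrix(expand.grid(ci, ci))
  k2 <- {
    fg <- freq_grid2(box, pixel_size)
    fg$kx^2 + fg$ky^2
  }
  list(n = box, pixel = pixel_size, os = oversample, nf = nf,
       pixel_fine = pixel_size / oversample,
       crop_lin = crop2[, 1] + (crop2[, 2] - 1L) * nf,
       k2 = k2, shells = shell_index2(box))
}

# Analytic 2D Fourier transform of the projected 3D Gaussian
# exp(-|x|^2/s^2): projection has FT pi^{3/2} s^3 exp(-pi^2 s^2 k^2); the
# 1/pixel^2 converts the continuous transform to sampled-image DFT units.
gaussian_transfer <- function(ctx, s) {
  (pi^1.5 * s^3 / ctx$pixel^2) * exp(-(pi^2 * s^2) * ctx$k2)
}

# Project per-particle positions and splat. Dmat: (B*Ng) x 3 particle-major
# positions (Angstrom); R_list: list of B rotation matrices; shifts: B x 2.
# Returns pixel coordinates on the fine grid plus bookkeeping.
project_batch <- function(ctx, Dmat, R_list, shifts, ng) {
  B <- length(R_list)
  xy <- matrix(0, B * ng, 2)
  for (b in seq_len(B)) {
    rows <- (b - 1L) * ng + seq_len(ng)
    xy[rows, ] <- Dmat[rows, , drop = FALSE] %*% t(R_list[[b]][1:2, ])
    xy[rows, 1] <- xy[rows, 1] + shifts[b, 1]
    xy[rows, 2] <- xy[rows, 2] + shifts[b, 2]
  }
  px <- xy[, 1] / ctx$pixel_fine + ctx$nf / 2
  py <- xy[, 2] / ctx$pixel_fine + ctx$nf / 2
  oob <- sum(px < 0 | px > ctx$nf - 1 | py < 0 | py > ctx$nf - 1)
  list(px = px, py = py, oob = oob, B = B, ng = ng,
       img_id = rep(seq_len(B), each = ng))
}

# Forward model for a batch. model widths/amplitudes/class weights are
# applied per class; ctf_mat is n^2 x B. Returns complex n x n x B plus a
# cache for the backward pass.
forward_batch <- function(ctx, model, Dmat, R_list, shifts, ctf_mat,
                          keep_cache = TRUE) {
  pj <- project_batch(ctx, Dmat, R_list, shifts, nrow(model$centers))
  n <- ctx$n; B <- pj$B; ng <- pj$ng
  nc <- length(model$widths)
  g <- array(0i, c(n, n, B))
  fines <- if (keep_cache) vector("list", nc) else NULL
  Ts <- vector("list", nc)
  crops <- vector("list", nc)
  for (j in seq_len(nc)) {
    w <- rep(model$amplitudes[j] * model$class_weights[j, ], B)
    fine <- splat_points_cpp(pj$px, pj$py, w, pj$img_id, ctx$nf, B)
    Ff <- fft2o_batch(fine) * ctx$os  # raw fine FFT / n
    Gc <- array(Ff[rep(ctx$crop_lin, B) +
                   rep((seq_len(B) - 1L) * ctx$nf^2, each = n * n)],
                c(n, n, B))
    Ts[[j]] <- gaussian_transfer(ctx, model$widths[j])
    crops[[j]] <- if (keep_cache) Gc else NULL
    g <- g + Gc * array(as.vector(ctf_mat) * rep(as.vector(Ts[[j]]), B),
                        c(n, n, B))
  }
  cache <- if (keep_cache)
    list(pj = pj, Ts = Ts, crops = crops, ctf_mat = ctf_mat) else NULL
  list(g = g, oob = pj$oob, cache = cache)
}

# Backward pass: dG is the (Wirtinger) gradient wrt g, complex n x n x B.
# Returns gradients wrt the particle-major deformed positions (Angstrom),
# wrt log widths and log amplitudes, and the per-image splat-weight
# gradient (for amplitude bookkeeping).
forward_backward <- function(ctx, model, cache, dG, R_list) {
  pj <- cache$pj
  n <- ctx$n; B <- pj$B; ng <- pj$ng; nf <- ctx$nf
  nc <- length(model$widths)
  dP <- matrix(0, B * ng, 2)
  d_log_s <- numeric(nc); d_log_a <- numeric(nc)
  ctf_vec <- as.vector(cache$ctf_mat)
  for (j in seq_len(nc)) {
    Tj <- cache$Ts[[j]]
    filt <- array(ctf_vec * rep(as.vector(Tj), B), c(n, n, B))
    dGc <- dG * filt  # conj not needed: filter is real
    # pad back into the fine grid and apply the adjoint FFT
    pad <- array(0i, c(nf, nf, B))
    pad[rep(ctx$crop_lin, B) +
        rep((seq_len(B) - 1L) * nf^2, each = n * n)] <- dGc
    grad_fine <- Re(fft2o_batch(pad, inverse = TRUE)) * ctx$os
    w <- rep(model$amplitudes[j] * model$class_weights[j, ], B)
    gg <- gather_grad_cpp(grad_fine, pj$px, pj$py, w, pj$img_id, nf)
    dP <- dP + gg[, 1:2]
    # amplitude (shared, via log): sum over points of w * dL/dw
    d_log_a[j] <- sum(gg[, 3] * w)
    # width: dT/ds = T * (3/s - 2 pi^2 s k^2); accumulate over batch
    s <- model$widths[j]
    dTds <- Tj * (3 / s - 2 * pi^2 * s * ctx$k2)
    A <- cache$crops[[j]] * array(ctf_vec, c(n, n, B))
    d_log_s[j] <- s * sum(Re(Conj(dG) * A) *
                          array(rep(as.vector(dTds), B), c(n, n, B)))
  }
  dXY <- dP / ctx$pixel_fine
  dD <- matrix(0, B * ng, 3)
  for (b in seq_len(B)) {
    rows <- (b - 1L) * ng + seq_len(ng)
    dD[rows, ] <- dXY[rows, , drop = FALSE] %*% R_list[[b]][1:2, ]
  }
  list(dD = dD, d_log_s = d_log_s, d_log_a = d_log_a)
}

#' Simulate a projection image of a Gaussian model
#'
#' Splats projected 2D points with bilinear interpolation on an oversampled
#' grid, transforms to Fourier space and applies the Gaussian transfer and
#' the CTF.
#'
#' @param points2d Ng x 2 matrix of projected centre positions (Angstrom).
#' @param model a [gaussian_model] (widths/amplitudes/class weights used).
#' @param ctf_array n x n real CTF in FFT order (e.g. [ctf_evaluate]), or
#'   NULL for no CTF.
#' @param box image size in pixels.
#' @param pixel_size pixel size in Angstrom.
#' @param oversample splat-grid oversampling factor (default 2).
#' @return object of class `fourier_image`: list with `data` (complex
#'   n x n, FFT order, orthonormal scaling) and `pixel_size`. The count of
#'   clipped out-of-bounds points is attached as attribute `"clipped"`.
#' @export
splat_and_filter <- function(points2d, model, ctf_array, box, pixel_size,
                             oversample = 2) {
  ctx <- make_imaging_context(box, pixel_size, oversample)
  ng <- nrow(points2d)
  px <- points2d[, 1] / ctx$pixel_fine + ctx$nf / 2
  py <- points2d[, 2] / ctx$pixel_fine + ctx$nf / 2
  oob <- sum(px < 0 | px > ctx$nf - 1 | py < 0 | py > ctx$nf - 1)
  if (oob == ng) stop("splat_and_filter: all points out of bounds")
  if (oob > 0.01 * ng)
    warning(sprintf("splat_and_filter: %d of %d points clipped", oob, ng))
  if (is.null(ctf_array)) ctf_array <- matrix(1, box, box)
  g <- matrix(0i, box, box)
  for (j in seq_along(model$widths)) {
    w <- model$amplitudes[j] * model$class_weights[j, ]
    fine <- splat_points_cpp(px, py, w, rep(1L, length(px)), ctx$nf, 1L)
    Ff <- stats::fft(array(fine, c(ctx$nf, ctx$nf))) / box
    g <- g + matrix(Ff[ctx$crop_lin], box, box) * ctf_array *
      gaussian_transfer(ctx, model$widths[j])
  }
  structure(list(data = g, pixel_size = pixel_size, box = box),
            class = "fourier_image", clipped = oob)
}

#' Real-space image from a `fourier_image`
#' @param fimg a `fourier_image`.
#' @return n x n real matrix.
#' @export
fourier_to_real <- function(fimg) {
  Re(stats::fft(fimg$data, inverse = TRUE)) / fimg$box
}

#' Estimate the radial noise spectrum
#'
#' Computes the resolution-dependent noise weights as the radially
#' averaged power of the residual between experimental images and the
#' (undeformed) consensus-model projections, over a subset of particles.
#' Shell values are floored at `eps`.
#'
#' @param particles a `particle_stack` with images.
#' @param model a [gaussian_model].
#' @param subset_size number of particles used (default 256, or all if
#'   fewer).
#' @param eps positive floor for the shell weights.
#' @param oversample splat-grid oversampling factor.
#' @return object of class `noise_model`: list with `weights` (one value
#'   per Fourier shell, length `n/2 + 1`) and `pixel_size`.
#' @export
estimate_noise_spectrum <- function(particles, model, subset_size = 256,
                                    eps = 1e-10, oversample = 2) {
  meta <- particles$meta
  n <- dim(particles$images)[1]
  ctx <- make_imaging_context(n, particles$pixel_size, oversample)
  take <- seq_len(min(subset_size, nrow(meta)))
  R_list <- lapply(take, function(i)
    euler_matrix(meta$rot[i], meta$tilt[i], meta$psi[i]))
  shifts <- cbind(meta$shift_x[take], meta$shift_y[take])
  ctf <- ctf_stack(meta[take, ], n, particles$pixel_size)
  ng <- nrow(model$centers)
  Dmat <- model$centers[rep(seq_len(ng), length(take)), , drop = FALSE]
  fw <- forward_batch(ctx, model, Dmat, R_list, shifts, ctf,
                      keep_cache = FALSE)
  pow <- numeric(n / 2 + 1); cnt <- numeric(n / 2 + 1)
  sh <- as.vector(ctx$shells) + 1L
  for (b in seq_along(take)) {
    yF <- fft2o(particles$images[, , take[b]])
    resid2 <- as.vector(Mod(fw$g[, , b] - yF)^2)
    pow <- pow + rowsum(resid2, sh)[, 1]
    cnt <- cnt + rowsum(rep(1, length(sh)), sh)[, 1]
  }
  w <- pmax(pow / cnt, eps)
  structure(list(weights = w, pixel_size = particles$pixel_size, eps = eps),
            class = "noise_model")
}

#' Sigma-weighted Fourier data loss
#'
#' \deqn{F = \frac{1}{|B|} \sum_i \sum_k |g_i(k) - y_i(k)|^2 / \Sigma(shell(k))}
#'
#' @param g,y complex Fourier images: matrices or n x n x B arrays.
#' @param noise a `noise_model`, or NULL for unit weights.
#' @return nonnegative scalar; zero iff `g == y`.
#' @export
data_loss <- function(g, y, noise = NULL) {
  if (is.matrix(g)) { g <- array(g, c(dim(g), 1)); y <- array(y, c(dim(y), 1)) }
  n <- dim(g)[1]; B <- dim(g)[3]
  smap <- sigma_map(n, noise)
  sum(Mod(g - y)^2 / array(rep(smap, B), dim(g))) / B
}

sigma_map <- function(n, noise) {
  if (is.null(noise)) return(matrix(1, n, n))
  matrix(noise$weights[shell_index2(n) + 1L], n, n)
}
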