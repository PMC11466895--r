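test_that("CTF limits and symmetry behave as the weak-phase model", {
  # pure amplitude contrast: DC value is -1
  ct <- ctf_params(12000, 12000, 0, amplitude_contrast = 1)
  arr <- ctf_evaluate(ct, 32, 3)
  expect_equal(arr[1, 1], -1)
  # A = 0.1: DC value -A
  ct2 <- ctf_params(15000)
  arr2 <- ctf_evaluate(ct2, 32, 3)
  expect_equal(arr2[1, 1], -0.1)
  # zero astigmatism: rotationally symmetric (compare transposes)
  expect_lt(max(abs(arr2 - t(arr2))), 1e-9)
})

test_that("the first CTF zero matches an independent root solver", {
  lambda <- gaussflex:::electron_wavelength(300)
  z <- 1e4  # 1.0 um defocus
  cs <- 2.7e7
  a <- 0.1
  chi <- function(k) pi * lambda * z * k^2 - pi / 2 * cs * lambda^3 * k^4
  f <- function(k) -(sqrt(1 - a^2) * sin(chi(k)) + a * cos(chi(k)))
  root <- uniroot(f, c(1e-3, 0.1))$root
  box <- 96; px <- 1.5
  arr <- ctf_evaluate(ctf_params(z, z, 0, 300, 2.7, 0.1), box, px)
  prof <- arr[1:(box / 2), 1]  # kx axis, ky = 0
  k_axis <- (0:(box / 2 - 1)) / (box * px)
  cross <- which(prof[-1] * prof[-length(prof)] < 0)[1]
  expect_lt(abs(k_axis[cross] - root), 1 / (box * px))
})

test_that("project_points implements the pose conventions", {
  set.seed(4)
  C <- matrix(runif(30, -10, 10), 10)
  expect_equal(project_points(C, list(rot = 0, tilt = 0, psi = 0)),
               C[, 1:2])
  p90 <- project_points(C, list(rot = 90, tilt = 0, psi = 0))
  expect_equal(p90, cbind(-C[, 2], C[, 1]), tolerance = 1e-12)
  # projection is a contraction of pairwise distances
  for (k in 1:10) {
    pose <- list(rot = runif(1, 0, 360), tilt = runif(1, 0, 180),
                 psi = runif(1, 0, 360))
    xy <- project_points(C, pose)
    d2 <- dist(xy); d3 <- dist(C)
    expect_true(all(d2 <= d3 + 1e-9))
  }
})

test_that("a centred Gaussian splat has symmetric modulus and flat phase", {
  m1 <- gaussian_model(matrix(0, 1, 3), widths = 5, amplitudes = 1)
  fi <- splat_and_filter(matrix(0, 1, 2), m1, NULL, 32, 3)
  # demodulate the centre-offset phase ramp (origin at pixel n/2)
  j <- 0:31
  ramp <- outer((-1)^j, (-1)^j)
  g <- fi$data * ramp
  sel <- gaussflex:::shell_index2(32) < 8  # below half Nyquist
  expect_lt(max(abs(Arg(g[sel]))), 1e-6)
  expect_lt(max(abs(Mod(g) - Mod(t(g)))), 1e-8)
})

test_that("shifting points applies the Fourier shift theorem", {
  m <- toy_model(6, seed = 5, extent = 20)
  xy <- m$centers[, 1:2]
  t0 <- c(6, -9)
  f0 <- splat_and_filter(xy, m, NULL, 32, 3)
  f1 <- splat_and_filter(sweep(xy, 2, t0, "+"), m, NULL, 32, 3)
  fg <- gaussflex:::freq_grid2(32, 3)
  pred <- f0$data * exp(-2i * pi * (fg$kx * t0[1] + fg$ky * t0[2]))
  sel <- gaussflex:::shell_index2(32) < 8
  expect_lt(max(Mod(f1$data[sel] - pred[sel])) / max(Mod(f0$data)), 1e-4)
})

test_that("Fourier projection matches the real-space rotate-project oracle", {
  set.seed(7)
  box <- 32; px <- 3
  m <- gaussian_model(matrix(runif(24, -25, 25), 8), widths = 4,
                      amplitudes = 2)
  pose <- list(rot = 25, tilt = 55, psi = 110, shift = c(4, -5))
  ctf <- ctf_evaluate(ctf_params(15000, 14000, 20), box, px)
  fi <- splat_and_filter(project_points(m$centers, pose), m, ctf, box, px)
  # oracle: render 3D, rotate by trilinear resampling, sum along z, FFT
  R <- euler_matrix(pose$rot, pose$tilt, pose$psi)
  vol <- render_density(m, box, px)$data
  ax <- (0:(box - 1) - box / 2) * px
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  rot <- array(gaussflex:::sample_volume_cpp(vol, box, px, g %*% R),
               rep(box, 3))
  proj <- apply(rot, c(1, 2), sum) * px
  fg <- gaussflex:::freq_grid2(box, px)
  oracle <- (fft(proj) / box) * ctf *
    exp(-2i * pi * (fg$kx * pose$shift[1] + fg$ky * pose$shift[2]))
  ncc <- Re(sum(fi$data * Conj(oracle))) /
    sqrt(sum(Mod(fi$data)^2) * sum(Mod(oracle)^2))
  expect_gt(ncc, 0.99)
})

test_that("total image intensity equals the analytic Gaussian integral", {
  # CTF = 1, no clipping: sum of pixels = sum_j a_j pi^{3/2} s^3 / pixel^2
  m <- toy_model(4, seed = 6, width = 5, amp = 1.2, extent = 12)
  fi <- splat_and_filter(m$centers[, 1:2], m, NULL, 48, 3)
  img <- fourier_to_real(fi)
  expected <- 4 * 1.2 * pi^1.5 * 5^3 / 3^2
  expect_equal(sum(img), expected, tolerance = 1e-3)
})

test_that("out-of-bounds points are clipped with warning, all-out errors", {
  m <- toy_model(10, seed = 7, extent = 5)
  far <- matrix(500, 10, 2)
  expect_error(splat_and_filter(far, m, NULL, 24, 3), "out of bounds")
  mixed <- rbind(m$centers[1:9, 1:2], c(500, 500))
  expect_warning(splat_and_filter(mixed, m, NULL, 24, 3), "clipped")
})

test_that("noise spectrum is floored for perfect data and flat for white noise", {
  sim <- tiny_static_sim()
  # zero-noise images generated by the same forward path
  ns <- estimate_noise_spectrum(sim$particles, sim$scene$model)
  expect_lt(max(ns$weights), 1e-5)   # residuals at float/Hermitian level
  # with white noise of known variance the shells sit near the variance
  set.seed(8)
  v <- 0.25
  noisy <- sim$particles
  noisy$images <- noisy$images +
    array(rnorm(length(noisy$images), 0, sqrt(v)), dim(noisy$images))
  ns2 <- estimate_noise_spectrum(noisy, sim$scene$model)
  mid <- 3:10  # interior shells
  expect_true(all(ns2$weights[mid] > 0.8 * v & ns2$weights[mid] < 1.2 * v))
  # permutation invariance
  perm <- sample(nrow(noisy$meta))
  ns3 <- estimate_noise_spectrum(subset_particles(noisy, perm),
                                 sim$scene$model)
  # subset selection differs under permutation only through ordering of
  # the same full set (24 < 256 particles, all used)
  expect_equal(sort(ns3$weights), sort(ns2$weights), tolerance = 1e-8)
})

test_that("data loss is a Sigma-weighted squared distance", {
  set.seed(9)
  g <- matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8, 8)
  expect_equal(data_loss(g, g), 0)
  y <- matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8, 8)
  l1 <- data_loss(g, y)
  expect_gt(l1, 0)
  # duplicated batch leaves the mean loss unchanged
  G <- array(c(g, g), c(8, 8, 2)); Y <- array(c(y, y), c(8, 8, 2))
  expect_equal(data_loss(G, Y), l1)
  # Parseval: with Sigma = 1 the Fourier loss equals the real-space MSE
  a <- matrix(rnorm(24^2), 24); b <- matrix(rnorm(24^2), 24)
  lf <- data_loss(gaussflex:::fft2o(a), gaussflex:::fft2o(b))
  expect_equal(lf, sum((a - b)^2), tolerance = 1e-10)
})

test_that("forward gradients agree with finite differences", {
  set.seed(3)
  ns <- asNamespace("gaussflex")
  box <- 16; px <- 3; ng <- 8; B <- 2
  ctx <- ns$make_imaging_context(box, px, 2)
  m <- toy_model(ng, seed = 31, extent = 15)
  meta <- toy_meta(B, seed = 32, box = box)
  Rl <- ns$pose_matrices(meta)
  sh <- cbind(meta$shift_x, meta$shift_y)
  ctf <- ns$ctf_stack(meta, box, px)
  m2 <- m; m2$centers <- m$centers + matrix(rnorm(ng * 3, 0, 2), ng)
  y <- ns$forward_batch(ctx, m2, m2$centers[rep(1:ng, B), ], Rl, sh, ctf,
                        keep_cache = FALSE)$g
  lossfun <- function(Dmat) {
    g <- ns$forward_batch(ctx, m, Dmat, Rl, sh, ctf, keep_cache = FALSE)$g
    sum(Mod(g - y)^2) / B
  }
  Dmat <- m$centers[rep(1:ng, B), ]
  fw <- ns$forward_batch(ctx, m, Dmat, Rl, sh, ctf)
  bwd <- ns$forward_backward(ctx, m, fw$cache, 2 * (fw$g - y) / B, Rl)
  h <- 1e-4
  for (k in sample(seq_along(Dmat), 10)) {
    Dp <- Dmat; Dp[k] <- Dp[k] + h
    Dm <- Dmat; Dm[k] <- Dm[k] - h
    fd <- (lossfun(Dp) - lossfun(Dm)) / (2 * h)
    expect_equal(bwd$dD[k], fd, tolerance = 1e-4)
  }
})

test_that("the image is pose-equivariant", {
  # rotating the model and un-rotating the pose gives the same image
  m <- toy_model(5, seed = 12, extent = 18)
  box <- 32; px <- 3
  pose <- list(rot = 40, tilt = 70, psi = 15, shift = c(0, 0))
  Q <- euler_matrix(30, 0, 0)   # extra in-plane rotation about z
  f1 <- splat_and_filter(project_points(m$centers, pose), m, NULL, box, px)
  # compose: R_pose %*% Q applied to Q^T-rotated model
  m2 <- m; m2$centers <- m$centers %*% Q   # rows: Q^T c
  R2 <- euler_matrix(pose$rot, pose$tilt, pose$psi) %*% t(t(Q))
  f2 <- splat_and_filter(m2$centers %*% t((euler_matrix(pose$rot, pose$tilt,
                                                        pose$psi) %*% Q)[1:2, ]),
                         m2, NULL, box, px)
  expect_lt(max(Mod(f1$data - f2$data)) / max(Mod(f1$data)), 1e-6)
})
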