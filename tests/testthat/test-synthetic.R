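test_that("scenes are reproducible from their seed", {
  s1 <- make_hinge_scene(n_particles = 10, seed = 4)
  s2 <- make_hinge_scene(n_particles = 10, seed = 4)
  expect_identical(s1$model$centers, s2$model$centers)
  sim1 <- simulate_particles(s1)
  sim2 <- simulate_particles(s2)
  expect_identical(sim1$particles$images, sim2$particles$images)
  expect_identical(sim1$truth$theta, sim2$truth$theta)
})

test_that("hinge deformations are isometric within each domain", {
  scene <- make_hinge_scene(n_gaussians = 20, n_moving = 8,
                            n_particles = 2, seed = 6)
  for (theta in c(-20, -5, 12, 20)) {
    def <- scene_deformed_centers(scene, theta)
    for (dom in list(scene$static, scene$moving)) {
      d0 <- dist(scene$model$centers[dom, ])
      d1 <- dist(def[dom, ])
      expect_lt(max(abs(d0 - d1)), 1e-10)
    }
  }
  # theta = 0 degenerates to the consensus
  expect_equal(scene_deformed_centers(scene, 0), scene$model$centers)
})

test_that("the isometry penalty vanishes on intra-domain edges only", {
  scene <- make_hinge_scene(n_gaussians = 20, n_moving = 8,
                            n_particles = 2, seed = 6)
  C <- scene$model$centers
  def <- scene_deformed_centers(scene, 18)
  full <- build_neighbor_graph(C)
  intra <- full
  keep <- (full$edges[, 1] <= 12) == (full$edges[, 2] <= 12)
  intra$edges <- full$edges[keep, , drop = FALSE]
  cross <- full
  cross$edges <- full$edges[!keep, , drop = FALSE]
  expect_lt(isometry_regularizer(C, def, intra), 1e-10)
  if (nrow(cross$edges) > 0)
    expect_gt(isometry_regularizer(C, def, cross), 1e-4)
})

test_that("requested SNR is realized within 20 percent", {
  scene <- make_hinge_scene(n_particles = 200, box = 32, snr = 0.1,
                            seed = 8)
  sim <- simulate_particles(scene)
  # measured signal power / noise power over the stack
  measured <- sim$signal_power / sim$noise_sd^2
  expect_gt(measured, 0.08)
  expect_lt(measured, 0.12)
  # empirical check: residual variance against a clean re-simulation
  clean <- simulate_particles({ s <- scene; s$snr <- 0; s })
  resid <- sim$particles$images - clean$particles$images
  expect_equal(var(as.vector(resid)), sim$noise_sd^2, tolerance = 0.05)
})

test_that("colored noise follows the requested radial spectrum shape", {
  scene <- make_hinge_scene(n_particles = 64, box = 32, snr = 0.2,
                            noise = "colored", seed = 12)
  sim <- simulate_particles(scene)
  clean <- simulate_particles({ s <- scene; s$snr <- 0; s })
  resid <- sim$particles$images - clean$particles$images
  pow <- matrix(0, 17, 1)
  sh <- gaussflex:::shell_index2(32) + 1
  acc <- numeric(17); cnt <- numeric(17)
  for (i in 1:64) {
    P <- Mod(gaussflex:::fft2o(resid[, , i]))^2
    acc <- acc + rowsum(as.vector(P), as.vector(sh))[, 1]
    cnt <- cnt + rowsum(rep(1, 32^2), as.vector(sh))[, 1]
  }
  spec <- acc / cnt / 64
  # monotone decreasing power toward high frequency
  expect_gt(spec[2], spec[10])
  expect_gt(spec[10] / spec[16], 1.5)
})

test_that("zero-noise static images equal the forward model exactly", {
  sim <- tiny_static_sim()
  m <- sim$scene$model
  i <- 5
  meta <- sim$particles$meta
  pose <- list(rot = meta$rot[i], tilt = meta$tilt[i], psi = meta$psi[i],
               shift = c(meta$shift_x[i], meta$shift_y[i]))
  ctf <- ctf_evaluate(ctf_params(meta$defocus_u[i], meta$defocus_v[i],
                                 meta$astig_angle[i]), 24, 3)
  g <- splat_and_filter(project_points(m$centers, pose), m, ctf, 24, 3)
  img <- fourier_to_real(g)
  expect_lt(max(abs(img - sim$particles$images[, , i])) / max(abs(img)),
            1e-6)
})

test_that("STAR/MRCS round trip preserves the simulated metadata", {
  sim <- tiny_static_sim()
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  back <- read_particles(file.path(dir, "particles.star"), dir)
  expect_equal(back$meta$rot, sim$particles$meta$rot, tolerance = 1e-6)
  expect_equal(back$meta$defocus_u, sim$particles$meta$defocus_u,
               tolerance = 1e-4)
  expect_equal(back$meta$halfset, sim$particles$meta$halfset)
  gt <- read_volume(file.path(dir, "ground_truth.mrc"))
  expect_equal(dim(gt$data), rep(24L, 3))
})

test_that("recovery error is zero for exact and gauge-shifted estimates", {
  scene <- make_hinge_scene(n_gaussians = 15, n_moving = 5,
                            n_particles = 12, seed = 14)
  sim <- simulate_particles(scene)
  tru <- true_positions(sim, 1:12)
  expect_equal(deformation_recovery_error(tru, tru)$median, 0,
               tolerance = 1e-10)
  # global rigid transform of everything: removed by the gauge alignment
  set.seed(15)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  t0 <- c(4, -2, 7)
  est <- tru
  for (i in 1:12) est[, , i] <- sweep(tru[, , i] %*% t(Q), 2, t0, "+")
  err <- deformation_recovery_error(tru, est)
  expect_lt(err$median, 1e-8)
})

test_that("random estimates give the quadrature-sum error", {
  # true and estimated displacement fields independent and zero-mean:
  # per-particle RMS error approximates sqrt(rms_true^2 + rms_est^2)
  set.seed(16)
  ng <- 40; N <- 200
  ref <- matrix(runif(ng * 3, -20, 20), ng)
  s_t <- 2; s_e <- 3
  tru <- array(0, c(ng, 3, N)); est <- array(0, c(ng, 3, N))
  for (i in 1:N) {
    tru[, , i] <- ref + matrix(rnorm(ng * 3, 0, s_t), ng)
    est[, , i] <- ref + matrix(rnorm(ng * 3, 0, s_e), ng)
  }
  err <- deformation_recovery_error(tru, est, true_ref = ref,
                                    est_ref = ref)
  expected <- sqrt(3 * (s_t^2 + s_e^2))  # 3 coordinates per point
  expect_equal(err$mean, expected, tolerance = 0.05)
})
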