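#' Synthetic two-domain hinge scene
#'
#' Builds a ground-truth Gaussian scene with a static domain and a hinged
#' domain that rotates rigidly about a pivot axis, mimicking the
#' mass-conserving domain motions the deformation model is designed for.
#' The per-particle hinge angle is drawn uniformly from
#' `angle_range` (degrees). Within each domain the deformation is exactly
#' isometric.
#'
#' @param n_gaussians total pseudo-atoms (default 60).
#' @param n_moving pseudo-atoms in the hinged domain (default 20).
#' @param angle_range hinge-angle range in degrees (default c(-20, 20)).
#' @param axis,pivot hinge axis (unit 3-vector) and pivot point (Angstrom).
#' @param n_particles number of particles (default 1000).
#' @param box,pixel_size image grid (default 48 px at 3 Angstrom).
#' @param snr target signal-to-noise ratio: noiseless-image variance over
#'   noise variance inside a circular mask of radius `0.45 * box`
#'   (default 0.1).
#' @param noise `"white"` or `"colored"` (radial `1/(1+(k/k0)^2)` power).
#' @param defocus_range defocus range in Angstrom (default 0.8-2.5 um).
#' @param width Gaussian width (Angstrom).
#' @param shift_max maximal in-plane shift magnitude (Angstrom).
#' @param seed scene seed; everything downstream is reproducible from it.
#' @return object of class `gf_scene`.
#' @export
make_hinge_scene <- function(n_gaussians = 60, n_moving = 20,
                             angle_range = c(-20, 20),
                             axis = c(0, 0, 1), pivot = c(0, 6, 0),
                             n_particles = 1000, box = 48, pixel_size = 3,
                             snr = 0.1, noise = "white",
                             defocus_range = c(0.8e4, 2.5e4), width = 5,
                             shift_max = 3, seed = 1) {
  stopifnot(n_moving < n_gaussians, n_moving >= 1)
  rng <- local_rng(seed)
  axis <- axis / sqrt(sum(axis^2))
  extent <- box * pixel_size / 2
  n_static <- n_gaussians - n_moving
  # static domain: blob left of the pivot; moving domain: blob to the right
  static_c <- c(-0.30, 0, 0) * extent
  moving_c <- c(0.28, 0, 0) * extent
  draw_blob <- function(n, centre, radius) {
    pts <- matrix(rng$rnorm(3 * n, 0, radius / 2), ncol = 3)
    r <- sqrt(rowSums(pts^2))
    too_far <- r > radius
    pts[too_far, ] <- pts[too_far, ] * (radius / r[too_far])
    sweep(pts, 2, centre, "+")
  }
  centers <- rbind(draw_blob(n_static, static_c, 0.28 * extent),
                   draw_blob(n_moving, moving_c, 0.20 * extent))
  model <- gaussian_model(centers, width, 1)
  structure(list(model = model, moving = seq.int(n_static + 1, n_gaussians),
                 static = seq_len(n_static), axis = axis, pivot = pivot,
                 angle_range = angle_range, n_particles = n_particles,
                 box = box, pixel_size = pixel_size, snr = snr,
                 noise = noise, defocus_range = defocus_range,
                 shift_max = shift_max, seed = seed),
            class = "gf_scene")
}

#' @export
print.gf_scene <- function(x, ...) {
  cat(sprintf(paste0("<gf_scene> hinge: %d static + %d moving Gaussians, ",
                     "theta in [%g, %g] deg, %d particles, box %d @ %.1f A, ",
                     "SNR %.3g\n"),
              length(x$static), length(x$moving), x$angle_range[1],
              x$angle_range[2], x$n_particles, x$box, x$pixel_size, x$snr))
  invisible(x)
}

# Rodrigues rotation matrix about a unit axis by angle (radians).
axis_rotation <- function(axis, angle) {
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' True deformed positions for a hinge angle
#'
#' @param scene a `gf_scene`.
#' @param theta hinge angle in degrees.
#' @return Ng x 3 matrix of deformed pseudo-atom positions.
#' @export
scene_deformed_centers <- function(scene, theta) {
  C <- scene$model$centers
  R <- axis_rotation(scene$axis, theta * pi / 180)
  mv <- scene$moving
  C[mv, ] <- sweep(sweep(C[mv, , drop = FALSE], 2, scene$pivot, "-") %*%
                     t(R), 2, scene$pivot, "+")
  C
}

#' Simulate a particle dataset from a scene
#'
#' Each image is the CTF-filtered Fourier-space projection of the
#' per-particle deformed Gaussian model (the same image-formation path
#' used in training), plus noise scaled to the scene's target SNR. Poses
#' are uniform over the sphere with uniform in-plane rotation; half-set
#' labels alternate.
#'
#' @param scene a `gf_scene`.
#' @param oversample splat oversampling factor (default 2).
#' @return list of class `gf_simulation`: `particles` (a `particle_stack`),
#'   `truth` (data frame with per-particle theta, pose, defocus,
#'   noise_sd), `scene`, and `noise_sd` actually applied.
#' @export
simulate_particles <- function(scene, oversample = 2) {
  rng <- local_rng(scene$seed + 1)
  N <- scene$n_particles
  n <- scene$box
  ctx <- make_imaging_context(n, scene$pixel_size, oversample)
  theta <- rng$runif(N, scene$angle_range[1], scene$angle_range[2])
  meta <- data.frame(
    image_index = seq_len(N),
    rot = rng$runif(N, 0, 360),
    tilt = acos(rng$runif(N, -1, 1)) * 180 / pi,
    psi = rng$runif(N, 0, 360),
    shift_x = rng$runif(N, -scene$shift_max, scene$shift_max),
    shift_y = rng$runif(N, -scene$shift_max, scene$shift_max),
    defocus_u = rng$runif(N, scene$defocus_range[1], scene$defocus_range[2]),
    defocus_v = 0, astig_angle = rng$runif(N, 0, 180),
    voltage = 300, cs = 2.7, amplitude_contrast = 0.1, phase_shift = 0,
    halfset = rep_len(c(1L, 2L), N),
    image_name = sprintf("%06d@particles.mrcs", seq_len(N)),
    stringsAsFactors = FALSE)
  meta$defocus_v <- meta$defocus_u * (1 + rng$runif(N, -0.02, 0.02))
  ctf <- ctf_stack(meta, n, scene$pixel_size)
  R_list <- pose_matrices(meta)
  shifts <- cbind(meta$shift_x, meta$shift_y)
  ng <- nrow(scene$model$centers)
  images <- array(0, c(n, n, N))
  mask <- {
    fg <- expand.grid(seq_len(n) - 1 - n / 2, seq_len(n) - 1 - n / 2)
    matrix(sqrt(fg[, 1]^2 + fg[, 2]^2) <= 0.45 * n, n, n)
  }
  sig_pow <- 0
  chunk_size <- 128
  for (chunk in split(seq_len(N), ceiling(seq_len(N) / chunk_size))) {
    Dmat <- do.call(rbind, lapply(chunk, function(i)
      scene_deformed_centers(scene, theta[i])))
    fw <- forward_batch(ctx, scene$model, Dmat, R_list[chunk],
                        shifts[chunk, , drop = FALSE],
                        ctf[, chunk, drop = FALSE], keep_cache = FALSE)
    for (k in seq_along(chunk)) {
      img <- Re(stats::fft(fw$g[, , k], inverse = TRUE)) / n
      images[, , chunk[k]] <- img
      sig_pow <- sig_pow + stats::var(img[mask])
    }
  }
  sig_pow <- sig_pow / N
  noise_sd <- if (scene$snr > 0) sqrt(sig_pow / scene$snr) else 0
  if (noise_sd > 0) {
    if (scene$noise == "white") {
      images <- images + array(rng$rnorm(n * n * N, 0, noise_sd),
                               c(n, n, N))
    } else {
      # colored noise: radial power 1/(1 + (k/k0)^2), k0 at half Nyquist
      fg <- freq_grid2(n, scene$pixel_size)
      k0 <- 1 / (4 * scene$pixel_size)
      spec <- 1 / (1 + (sqrt(fg$kx^2 + fg$ky^2) / k0)^2)
      spec <- spec / mean(spec)          # unit average power
      for (i in seq_len(N)) {
        w <- matrix(rng$rnorm(n * n, 0, noise_sd), n, n)
        cn <- Re(stats::fft(fft2o(w) * sqrt(spec), inverse = TRUE)) / n
        images[, , i] <- images[, , i] + cn
      }
    }
  }
  truth <- cbind(meta[, c("image_index", "rot", "tilt", "psi", "shift_x",
                          "shift_y", "defocus_u", "defocus_v", "halfset")],
                 theta = theta, noise_sd = noise_sd)
  structure(list(particles = particle_stack(meta, images, scene$pixel_size),
                 truth = truth, scene = scene, noise_sd = noise_sd,
                 signal_power = sig_pow),
            class = "gf_simulation")
}

#' Write a simulated dataset to disk
#'
#' Writes the MRCS stack + STAR metadata, the ground-truth consensus
#' volume (MRC) and the ground-truth parameter table (JSON).
#'
#' @param sim a `gf_simulation`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_particles(sim$particles, file.path(dir, "particles.star"))
  vol <- render_density(sim$scene$model, sim$scene$box,
                        sim$scene$pixel_size)
  write_volume(vol, file.path(dir, "ground_truth.mrc"))
  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                       digits = NA, dataframe = "columns")
  invisible(dir)
}

#' True inverse-deformation fields of a simulation
#'
#' Returns a field generator for [backproject_deformed]: for particle `i`
#' the inverse displacement at a grid point is the rigid back-rotation by
#' `-theta_i` when the point lies in the hinged domain (assigned by
#' proximity to the deformed domain centres), zero otherwise.
#'
#' @param sim a `gf_simulation`.
#' @param box,voxel_size reconstruction grid (defaults to the scene grid).
#' @return function `(i) -> gf_field` of kind `"inverse"`.
#' @export
true_inverse_fields <- function(sim, box = sim$scene$box,
                                voxel_size = sim$scene$pixel_size,
                                coarsen = 2) {
  scene <- sim$scene
  m <- as.integer(box / coarsen)
  voxel_c <- voxel_size * coarsen
  ax <- (seq_len(m) - 1 - m / 2) * voxel_c
  gx <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  function(i) {
    theta <- sim$truth$theta[i]
    def <- scene_deformed_centers(scene, theta)
    mvd <- def[scene$moving, , drop = FALSE]
    std <- def[scene$static, , drop = FALSE]
    dm <- nearest_dist(gx, mvd)
    ds <- nearest_dist(gx, std)
    Rb <- axis_rotation(scene$axis, -theta * pi / 180)
    back <- sweep(sweep(gx, 2, scene$pivot, "-") %*% t(Rb), 2,
                  scene$pivot, "+") - gx
    v <- back * as.numeric(dm < ds)
    full <- upsample_field_cpp(as.vector(v), m, voxel_c,
                               as.integer(box), voxel_size)
    displacement_field(full, box, voxel_size, kind = "inverse")
  }
}

# Distance from each row of X to its nearest row of P (small P).
nearest_dist <- function(X, P) {
  d2 <- rep(Inf, nrow(X))
  for (j in seq_len(nrow(P))) {
    dj <- (X[, 1] - P[j, 1])^2 + (X[, 2] - P[j, 2])^2 +
      (X[, 3] - P[j, 3])^2
    d2 <- pmin(d2, dj)
  }
  sqrt(d2)
}

#' Per-particle deformation recovery error with gauge removal
#'
#' Deformations are identifiable only up to the consensus gauge: a single
#' global rigid transform is removed by Kabsch alignment of the estimated
#' reference onto the true reference, and the per-particle RMS distance
#' between the aligned estimated and true positions is reported.
#'
#' @param true_pos Ng x 3 x N array of true per-particle positions.
#' @param est_pos Ng x 3 x N array of estimated positions (corresponded
#'   Gaussians).
#' @param true_ref,est_ref Ng x 3 reference (consensus) positions;
#'   defaults to the per-array means over particles.
#' @return list with `per_particle` (RMS error in Angstrom, length N),
#'   `median`, `mean`, and the fitted rigid transform.
#' @export
deformation_recovery_error <- function(true_pos, est_pos,
                                       true_ref = NULL, est_ref = NULL) {
  stopifnot(all(dim(true_pos) == dim(est_pos)))
  N <- dim(true_pos)[3]
  if (is.null(true_ref)) true_ref <- apply(true_pos, c(1, 2), mean)
  if (is.null(est_ref)) est_ref <- apply(est_pos, c(1, 2), mean)
  tr <- kabsch(est_ref, true_ref)
  per <- vapply(seq_len(N), function(i) {
    est_al <- sweep(est_pos[, , i] %*% t(tr$R), 2, tr$t, "+")
    sqrt(mean(rowSums((est_al - true_pos[, , i])^2)))
  }, 0)
  list(per_particle = per, median = stats::median(per), mean = mean(per),
       transform = tr)
}

# Rigid transform (R, t) minimizing ||P R^T + t - Q||_F.
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cq - as.vector(R %*% cp)
  list(R = R, t = t)
}
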