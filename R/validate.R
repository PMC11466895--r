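#' Subset a particle stack
#'
#' @param particles a `particle_stack`.
#' @param idx particle indices to keep.
#' @return a `particle_stack` with the selected particles.
#' @export
subset_particles <- function(particles, idx) {
  meta <- particles$meta[idx, , drop = FALSE]
  meta$image_index <- seq_len(nrow(meta))
  particle_stack(meta,
                 if (is.null(particles$images)) NULL
                 else particles$images[, , idx, drop = FALSE],
                 particles$pixel_size)
}

#' Hold out a validation subset
#'
#' Splits particles into a training set and a validation set. The
#' validation particles are excluded from decoder (and Gaussian) updates
#' during training but are still passed through the encoder so their
#' latent embedding is trained (see `validation_idx` in
#' [train_halfset_vae]). The split is deterministic given `seed`.
#'
#' @param particles a `particle_stack`.
#' @param fraction validation fraction in (0, 0.5); default 0.10.
#' @param seed split seed.
#' @return list with `train_idx`, `validation_idx`, and the corresponding
#'   `train` / `validation` particle stacks.
#' @export
split_for_validation <- function(particles, fraction = 0.10, seed = 1) {
  stopifnot(fraction > 0, fraction < 0.5)
  N <- nrow(particles$meta)
  rng <- local_rng(seed)
  n_val <- max(1L, round(fraction * N))
  validation_idx <- sort(rng$sample_int(N, n_val))
  train_idx <- setdiff(seq_len(N), validation_idx)
  list(train_idx = train_idx, validation_idx = validation_idx,
       train = subset_particles(particles, train_idx),
       validation = subset_particles(particles, validation_idx))
}

#' Per-particle deformation-error estimates from the two half-set decoders
#'
#' For each validation particle the image is fed through both encoders;
#' each decoder is evaluated on its own consensus model with the latent
#' mean from its own encoder, and the two displacement estimates are
#' compared at corresponded positions:
#' `err[i, j] = || delta1_j(particle i) - delta2_j(particle i) ||`.
#' When the two consensus models have unequal sizes, Gaussians are
#' corresponded by nearest neighbour after rigid alignment (flagged in
#' the report).
#'
#' @param particles validation particles (a `particle_stack` with images).
#' @param vae1,vae2 trained `gf_vae_half` objects.
#' @return object of class `validation_report`: list with `per_gaussian`
#'   (N x Ng matrix of error norms, Angstrom), `per_particle` (data frame
#'   with median and max per particle), `summary` and `matched_by_nn`.
#' @export
estimate_deformation_error <- function(particles, vae1, vae2) {
  n <- dim(particles$images)[1]
  X1 <- vae_encoder_input(particles, vae1)
  X2 <- vae_encoder_input(particles, vae2)
  mu1 <- encode(X1, vae1$encoder)$mu
  mu2 <- encode(X2, vae2$encoder)$mu
  c1 <- vae1$model$centers
  c2 <- vae2$model$centers
  matched_by_nn <- FALSE
  if (nrow(c1) != nrow(c2)) {
    matched_by_nn <- TRUE
    tr <- kabsch_subsample(c2, c1)
    c2_al <- sweep(c2 %*% t(tr$R), 2, tr$t, "+")
    map <- vapply(seq_len(nrow(c1)), function(j)
      which.min(rowSums(sweep(c2_al, 2, c1[j, ])^2)), 1L)
  } else map <- seq_len(nrow(c1))
  N <- nrow(mu1)
  ng <- nrow(c1)
  fw1 <- dec_forward(vae1$decoder, mu1, c1, keep_cache = FALSE)
  fw2 <- dec_forward(vae2$decoder, mu2, c2, keep_cache = FALSE)
  d1 <- fw1$delta
  d2 <- fw2$delta
  per_gaussian <- matrix(0, N, ng)
  for (i in seq_len(N)) {
    r1 <- (i - 1) * ng + seq_len(ng)
    r2 <- (i - 1) * nrow(c2) + map
    per_gaussian[i, ] <- sqrt(rowSums((d1[r1, , drop = FALSE] -
                                       d2[r2, , drop = FALSE])^2))
  }
  per_particle <- data.frame(
    particle = seq_len(N),
    median_err = apply(per_gaussian, 1, stats::median),
    max_err = apply(per_gaussian, 1, max))
  structure(list(per_gaussian = per_gaussian, per_particle = per_particle,
                 summary = c(median = stats::median(per_gaussian),
                             mean = mean(per_gaussian),
                             q90 = unname(stats::quantile(per_gaussian, 0.9))),
                 matched_by_nn = matched_by_nn),
            class = "validation_report")
}

# Rebuild a trained half's encoder inputs for new particles using the
# same preprocessing (phase flip + low-pass) and normalization.
vae_encoder_input <- function(particles, vae) {
  n <- dim(particles$images)[1]
  N <- nrow(particles$meta)
  yF <- array(0i, c(n, n, N))
  for (i in seq_len(N)) yF[, , i] <- fft2o(particles$images[, , i])
  ctf <- ctf_stack(particles$meta, n, particles$pixel_size)
  lp <- if (is.null(vae$norm$lowpass)) 1 else vae$norm$lowpass
  pf <- isTRUE(vae$norm$phase_flip)
  encoder_input(yF, ctf, lp, center = vae$norm$mean,
                scale = vae$norm$sd, phase_flip = pf)
}

# Kabsch when point sets have different sizes: align on the smaller set's
# nearest neighbours (coarse but only used as a fallback).
kabsch_subsample <- function(P, Q) {
  m <- min(nrow(P), nrow(Q))
  kabsch(P[seq_len(m), , drop = FALSE], Q[seq_len(m), , drop = FALSE])
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(paste0("<validation_report> %d particles x %d Gaussians; ",
                     "median error %.3f A (q90 %.3f A)%s\n"),
              nrow(x$per_gaussian), ncol(x$per_gaussian),
              x$summary["median"], x$summary["q90"],
              if (x$matched_by_nn) " [nearest-neighbour correspondence]"
              else ""))
  invisible(x)
}

#' Export a per-Gaussian error field as a volume
#'
#' Samples the per-Gaussian mean error norms onto the map grid as Gaussian
#' blobs (for visualization in external viewers).
#'
#' @param report a `validation_report`.
#' @param model the consensus [gaussian_model] whose centres the errors
#'   refer to.
#' @param box,voxel_size output grid.
#' @return A [volume_grid] whose intensity is the error in Angstrom.
#' @export
error_field_volume <- function(report, model, box, voxel_size) {
  err <- colMeans(report$per_gaussian)
  vol <- numeric(box^3)
  for (j in seq_len(nrow(model$centers))) {
    m1 <- gaussian_model(model$centers[j, , drop = FALSE],
                         model$widths[1], 1)
    vol <- vol + err[j] * render_density(m1, box, voxel_size)$data
  }
  volume_grid(array(vol, rep(box, 3)), voxel_size)
}
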