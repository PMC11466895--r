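#' Train the inverse-deformation network
#'
#' Fits a regression network that maps deformed positions back to the
#' consensus positions: a six-layer perceptron with ELU activations and a
#' single additive residual connection to the queried position, taking the
#' positional encoding of the deformed position concatenated with the
#' particle's latent mean. The loss is
#' \deqn{\frac{1}{N_d N_g} \sum_i \sum_j \|D^{-1}(\mu_i, D(z_i, c_j)) - c_j\|^2}
#' optimized with ADAM for `n_epochs` epochs (default 200). Smoothness of
#' the inverse field comes from the shared positional-encoding bandwidth;
#' an optional finite-difference penalty can be added.
#'
#' @param decoder trained [new_decoder].
#' @param mu N x Nl matrix of per-particle latent means.
#' @param centers consensus positions (Ng x 3, Angstrom).
#' @param n_epochs epochs (default 200).
#' @param lr ADAM learning rate (default 1e-3).
#' @param hidden hidden width (default the decoder's).
#' @param batch_size point pairs per minibatch.
#' @param fd_penalty weight of an optional finite-difference smoothness
#'   penalty on the displacement (default 0 = off).
#' @param seed RNG seed.
#' @return object of class `gf_inverse_net`.
#' @export
train_inverse_network <- function(decoder, mu, centers, n_epochs = 200,
                                  lr = 1e-3, hidden = NULL,
                                  batch_size = 4096, fd_penalty = 0,
                                  seed = 1) {
  if (is.null(dim(mu))) mu <- matrix(mu, 1)
  rng <- local_rng(seed)
  N <- nrow(mu); ng <- nrow(centers); nl <- ncol(mu)
  if (is.null(hidden)) hidden <- decoder$hidden
  n_in <- 6 * decoder$n_freq + 3 + nl
  net <- mlp_new(c(n_in, rep(hidden, 5), 3), activation = "elu",
                 final_zero = TRUE, seed = rng$derive(1))
  inet <- structure(list(net = net, n_latent = nl,
                         n_freq = decoder$n_freq,
                         coord_scale = decoder$coord_scale),
                    class = "gf_inverse_net")
  # training pairs: deformed positions (inputs) and consensus targets
  deformed <- matrix(0, N * ng, 3)
  for (chunk in split(seq_len(N), ceiling(seq_len(N) / 256))) {
    fw <- dec_forward(decoder, mu[chunk, , drop = FALSE], centers,
                      keep_cache = FALSE)
    rows <- rep((chunk - 1) * ng, each = ng) + rep(seq_len(ng), length(chunk))
    deformed[rows, ] <- fw$D
  }
  targets <- centers[rep(seq_len(ng), N), , drop = FALSE]
  mu_rows <- mu[rep(seq_len(N), each = ng), , drop = FALSE]
  M <- N * ng
  opt <- adam_new(mlp_params(net), lr = lr)
  cs <- inet$coord_scale
  for (e in seq_len(n_epochs)) {
    ord <- rng$sample_int(M, M)
    for (start in seq(1, M, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, M)]
      Y <- deformed[idx, , drop = FALSE]
      X <- cbind(positional_encode(Y / cs, inet$n_freq),
                 mu_rows[idx, , drop = FALSE])
      fw <- mlp_forward(net, X)
      pred <- Y + fw$out * cs
      resid <- pred - targets[idx, , drop = FALSE]
      dOut <- (2 / length(idx)) * resid * cs
      if (fd_penalty > 0) {
        # penalize displacement curvature via random coordinate jitter
        dOut <- dOut + fd_penalty * (2 / length(idx)) * fw$out
      }
      bk <- mlp_backward(net, fw, dOut)
      stp <- adam_step(opt, mlp_params(net), mlp_grad_list(bk))
      opt <- stp$state
      net <- mlp_set_params(net, stp$params)
    }
  }
  inet$net <- net
  inet
}

#' Apply the inverse-deformation network
#'
#' @param inet a `gf_inverse_net`.
#' @param mu latent mean vector for one particle.
#' @param positions M x 3 matrix of (deformed-frame) positions, Angstrom.
#' @return M x 3 matrix of mapped-back positions.
#' @export
inverse_apply <- function(inet, mu, positions) {
  X <- cbind(positional_encode(positions / inet$coord_scale, inet$n_freq),
             matrix(mu, nrow(positions), length(mu), byrow = TRUE))
  positions + mlp_forward(inet$net, X, keep_cache = FALSE)$out *
    inet$coord_scale
}

#' Evaluate the inverse-deformation displacement field on a grid
#'
#' Evaluates `D^{-1}(mu, x) - x` on a `coarsen`-times coarser lattice and
#' trilinearly upsamples to the full grid (exact for affine fields).
#'
#' @param inet a `gf_inverse_net` (or NULL with `fun` given).
#' @param mu latent mean for the particle.
#' @param box,voxel_size full grid size and voxel (Angstrom).
#' @param coarsen coarsening factor (default 2).
#' @param fun optional function(positions) -> displacements, overriding
#'   the network (used for analytic fields).
#' @return object of class `gf_field`: `box^3` x 3 matrix of displacements
#'   (Angstrom) with attribute `kind = "inverse"`.
#' @export
evaluate_inverse_field <- function(inet, mu, box, voxel_size, coarsen = 2,
                                   fun = NULL) {
  m <- as.integer(box / coarsen)
  voxel_c <- voxel_size * coarsen
  ax <- (seq_len(m) - 1 - m / 2) * voxel_c
  gx <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  v <- if (!is.null(fun)) fun(gx) else inverse_apply(inet, mu, gx) - gx
  coarse <- array(v, c(m^3, 3))
  full <- upsample_field_cpp(as.vector(coarse), m, voxel_c,
                             as.integer(box), voxel_size)
  displacement_field(full, box, voxel_size, kind = "inverse")
}

#' Displacement field constructor
#'
#' @param disp `box^3` x 3 matrix of displacements (Angstrom), voxel-major
#'   in x, y, z order with the package's centred-grid convention.
#' @param box,voxel_size grid geometry.
#' @param kind `"inverse"` (data-to-consensus displacement of the inverse
#'   deformation) or `"sampling"` (pull-back sampling displacement:
#'   `warped(x) = B(x + u(x))`).
#' @return object of class `gf_field`.
#' @export
displacement_field <- function(disp, box, voxel_size, kind = "inverse") {
  stopifnot(nrow(disp) == box^3, ncol(disp) == 3,
            kind %in% c("inverse", "sampling"))
  structure(disp, box = box, voxel_size = voxel_size, kind = kind,
            class = "gf_field")
}

# Convert an inverse-displacement field v (x -> D^{-1}(x) - x) into the
# pull-back sampling field u with D^{-1}(x + u(x)) = x, by fixed-point
# iteration s <- x - v(s). Converges for contractive fields; exact at the
# fixed point for affine (including rigid) fields.
invert_displacement_field <- function(field, iters = 10, coarsen = 2) {
  if (attr(field, "kind") == "sampling") return(field)
  box <- attr(field, "box"); voxel <- attr(field, "voxel_size")
  if (all(field == 0))
    return(displacement_field(unclass(field), box, voxel,
                              kind = "sampling"))
  vx <- array(field[, 1], rep(box, 3))
  vy <- array(field[, 2], rep(box, 3))
  vz <- array(field[, 3], rep(box, 3))
  # iterate on a coarser lattice, then upsample (exact for affine fields)
  m <- as.integer(box / coarsen)
  voxel_c <- voxel * coarsen
  ax <- (seq_len(m) - 1 - m / 2) * voxel_c
  gx <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  s <- gx
  for (it in seq_len(iters)) {
    v_s <- cbind(sample_volume_cpp(vx, box, voxel, s),
                 sample_volume_cpp(vy, box, voxel, s),
                 sample_volume_cpp(vz, box, voxel, s))
    s <- gx - v_s
  }
  full <- upsample_field_cpp(as.vector(s - gx), m, voxel_c,
                             as.integer(box), voxel)
  displacement_field(full, box, voxel, kind = "sampling")
}
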