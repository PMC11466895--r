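#' Create an image encoder
#'
#' Fully connected encoder with three linear layers and ReLU activations.
#' The final layer is zero-initialized, so at initialization every image
#' maps to `mu = 0`, `sigma = 1`.
#'
#' @param box image size in pixels (input dimension is `box^2`).
#' @param n_latent latent dimensionality (default 10).
#' @param hidden hidden width; by default scaled with the box size
#'   (`min(256, 4 * box)`).
#' @param sigma_init initial posterior standard deviation (the log-variance
#'   head bias); default 0.5, which keeps early latent samples from being
#'   dominated by the reparameterization noise while staying within a
#'   factor 2 of unity.
#' @param seed initialization seed.
#' @return object of class `gf_encoder`.
#' @export
new_encoder <- function(box, n_latent = 10, hidden = NULL,
                        sigma_init = 0.5, seed = 1) {
  if (is.null(hidden)) hidden <- min(256L, 4L * box)
  net <- mlp_new(c(box * box, hidden, hidden, 2 * n_latent),
                 activation = "relu", final_zero = TRUE, seed = seed)
  net$b[[3]][n_latent + seq_len(n_latent)] <- 2 * log(sigma_init)
  structure(list(net = net, box = box, n_latent = n_latent,
                 hidden = hidden), class = "gf_encoder")
}

#' Encode images to latent distributions
#'
#' @param images a single image matrix, an n x n x B array, or a B x n^2
#'   matrix of flattened images.
#' @param encoder a [new_encoder] object.
#' @return list with `mu` (B x Nl), `sigma` (B x Nl, positive) and the
#'   forward cache (for training).
#' @export
encode <- function(images, encoder) {
  X <- flatten_images(images, encoder$box)
  fw <- mlp_forward(encoder$net, X)
  nl <- encoder$n_latent
  mu <- fw$out[, seq_len(nl), drop = FALSE]
  logvar <- fw$out[, nl + seq_len(nl), drop = FALSE]
  list(mu = mu, sigma = exp(0.5 * logvar), cache = fw)
}

flatten_images <- function(images, box) {
  if (is.matrix(images) && ncol(images) == box * box) return(images)
  if (is.matrix(images)) return(matrix(as.vector(images), 1))
  d <- dim(images)
  t(matrix(images, d[1] * d[2], d[3]))
}

#' Sample a latent vector by reparameterization
#'
#' `z = mu + sigma * eps`, `eps ~ N(0, I)`. With `sigma = 0` this returns
#' `mu` exactly; the draw is deterministic given `seed`.
#'
#' @param code list with `mu` and `sigma` (vectors or matrices).
#' @param seed integer seed.
#' @return sample(s) with the shape of `mu`. The noise draw is attached as
#'   attribute `"eps"`.
#' @export
sample_latent <- function(code, seed) {
  rng <- local_rng(seed)
  eps <- rng$rnorm(length(code$mu))
  if (!is.null(dim(code$mu))) dim(eps) <- dim(code$mu)
  z <- code$mu + code$sigma * eps
  attr(z, "eps") <- eps
  z
}

#' Create a coordinate-based deformation decoder
#'
#' Eight linear layers with ELU activations. The input is the positional
#' encoding of a (normalized) 3D position concatenated with the latent
#' vector; the output is a residual displacement added to the queried
#' position: `D(z, x) = x + delta(z, x)`. The final layer is
#' zero-initialized so the decoder starts as the identity deformation.
#'
#' @param n_latent latent dimensionality.
#' @param coord_scale half box extent in Angstrom used to normalize
#'   positions to `[-1, 1]` before encoding; also scales the raw network
#'   output back to Angstrom.
#' @param hidden hidden width (7 hidden layers); default
#'   `min(192, coord_scale is ignored, 192)`; pass a smaller value for
#'   small boxes.
#' @param n_freq positional-encoding frequency count (default 10).
#' @param seed initialization seed.
#' @return object of class `gf_decoder`.
#' @export
new_decoder <- function(n_latent, coord_scale, hidden = 192, n_freq = 10,
                        seed = 1) {
  n_in <- 6 * n_freq + 3 + n_latent
  net <- mlp_new(c(n_in, rep(hidden, 7), 3), activation = "elu",
                 final_zero = TRUE, seed = seed)
  structure(list(net = net, n_latent = n_latent, n_freq = n_freq,
                 coord_scale = coord_scale, hidden = hidden),
            class = "gf_decoder")
}

# Forward pass for a batch: Z is B x Nl, positions Ng x 3 (Angstrom).
# Row order of the output is particle-major: (b-1)*Ng + j.
dec_forward <- function(decoder, Z, positions, keep_cache = TRUE) {
  if (is.null(dim(Z))) Z <- matrix(Z, 1)
  B <- nrow(Z); ng <- nrow(positions)
  xn <- positions / decoder$coord_scale
  pe <- positional_encode(xn, decoder$n_freq)
  X <- cbind(pe[rep(seq_len(ng), times = B), , drop = FALSE],
             Z[rep(seq_len(B), each = ng), , drop = FALSE])
  fw <- mlp_forward(decoder$net, X, keep_cache)
  delta <- fw$out * decoder$coord_scale
  D <- positions[rep(seq_len(ng), times = B), , drop = FALSE] + delta
  list(D = D, delta = delta, cache = fw, B = B, ng = ng, xn = xn)
}

# Backprop: dD is the loss gradient wrt the deformed positions
# ((B*Ng) x 3). Returns decoder parameter grads, dZ (B x Nl) and the
# gradient wrt the queried positions (Ng x 3, summed over the batch),
# including both the identity path and the positional-encoding path.
dec_backward <- function(decoder, fwd, dD) {
  bk <- mlp_backward(decoder$net, fwd$cache, dD * decoder$coord_scale)
  n_pe <- 6 * decoder$n_freq + 3
  dX <- bk$dX
  dPE <- dX[, seq_len(n_pe), drop = FALSE]
  dZ_rows <- dX[, n_pe + seq_len(decoder$n_latent), drop = FALSE]
  grp_b <- rep(seq_len(fwd$B), each = fwd$ng)
  dZ <- rowsum(dZ_rows, grp_b, reorder = TRUE)
  xn_rows <- fwd$xn[rep(seq_len(fwd$ng), times = fwd$B), , drop = FALSE]
  dxn <- positional_encode_backward(xn_rows, dPE, decoder$n_freq)
  grp_g <- rep(seq_len(fwd$ng), times = fwd$B)
  dC_pe <- rowsum(dxn, grp_g, reorder = TRUE) / decoder$coord_scale
  dC_id <- rowsum(dD, grp_g, reorder = TRUE)
  list(params = mlp_grad_list(bk), dZ = dZ, dC = dC_pe + dC_id)
}

#' Evaluate the deformation decoder
#'
#' Returns the deformed positions `D(z, x) = x + delta(z, x)` for one
#' latent vector or a batch.
#'
#' @param decoder a [new_decoder] object.
#' @param z latent vector (length Nl) or B x Nl matrix.
#' @param positions Ng x 3 matrix of query positions (Angstrom).
#' @return Ng x 3 matrix for a single `z`, else an Ng x 3 x B array.
#' @export
decode_deformation <- function(decoder, z, positions) {
  single <- is.null(dim(z))
  fw <- dec_forward(decoder, z, positions, keep_cache = FALSE)
  if (single) return(fw$D)
  ng <- nrow(positions)
  array(aperm(array(fw$D, c(ng, fw$B, 3)), c(1, 3, 2)), c(ng, 3, fw$B))
}
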