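#' Training configuration for a half-set VAE
#'
#' @param n_epochs number of epochs after warm-up.
#' @param warmup_epochs initial epochs in which only the Gaussian
#'   parameters (centres, widths, amplitudes) are optimized (default 10).
#' @param lr_gaussians,lr_encoder,lr_decoder ADAM learning rates
#'   (defaults 1e-4, 1e-3, 1e-4).
#' @param batch_size minibatch size (default 64).
#' @param lambda_ratio target gradient-norm ratio `r` for the dynamic
#'   regularization weight (default 0.9).
#' @param stop_k stop training after the data loss has increased this many
#'   times, counted cumulatively over epochs (default 40).
#' @param freeze_every,freeze_len after every `freeze_every` epochs the
#'   encoder and decoder are frozen for `freeze_len` epochs and only the
#'   Gaussian parameters are adjusted (defaults 30 and 5).
#' @param replace_every at every `replace_every`-th epoch where the
#'   decoder is not frozen, the consensus positions are replaced by the
#'   predicted conformation with the smallest displacement (default 10).
#' @param beta_rel KL weight relative to the data-loss scale measured at
#'   the end of warm-up (default 1e-3).
#' @param latent_dim latent dimensionality (default 10).
#' @param hidden_encoder,hidden_decoder hidden widths; `NULL` scales them
#'   with the box size.
#' @param n_freq positional-encoding frequencies (default 10).
#' @param oversample splat-grid oversampling (default 2).
#' @param probe_size particles in the fixed probe subset used for the
#'   lambda update and consensus replacement (default 100).
#' @param regularizer `"smooth"` (neighbour-graph isometry + repulsion,
#'   recalculated every epoch), `"atomic"` (fixed bond graph, isometry
#'   only; requires `graph`), or `"none"`.
#' @param reg_on_gaussians if FALSE (default) the deformation priors act
#'   on the network parameters only and the Gaussian parameters are
#'   updated against the data term alone; if TRUE the regularizer
#'   gradient also flows into the consensus positions.
#' @param keep_best return the model/network state of the epoch with the
#'   lowest data loss rather than the final epoch (default TRUE); the
#'   training trajectory is unaffected.
#' @param tail_average average the encoder and decoder weights over the
#'   last `tail_average` epochs (0 = off); a Polyak-style average that
#'   damps end-of-training oscillation. Ignored when `keep_best` selects
#'   an earlier epoch.
#' @param sigma_init initial posterior standard deviation of the encoder.
#' @param encoder_lowpass low-pass fraction of Nyquist applied to the
#'   encoder input images (1 = none).
#' @param encoder_phase_flip multiply encoder inputs by the CTF sign so
#'   contrast is defocus-consistent (default FALSE).
#' @param seed master seed for initialization, shuffling and latent draws.
#' @return list of class `gf_config`.
#' @export
vae_training_config <- function(n_epochs = 60, warmup_epochs = 10,
                                lr_gaussians = 1e-4, lr_encoder = 1e-3,
                                lr_decoder = 1e-4, batch_size = 64,
                                lambda_ratio = 0.9, stop_k = 40,
                                freeze_every = 30, freeze_len = 5,
                                replace_every = 10, beta_rel = 1e-3,
                                latent_dim = 10, hidden_encoder = NULL,
                                hidden_decoder = NULL, n_freq = 10,
                                oversample = 2, probe_size = 100,
                                regularizer = "smooth", keep_best = TRUE,
                                reg_on_gaussians = FALSE,
                                tail_average = 0, sigma_init = 0.5,
                                encoder_lowpass = 1,
                                encoder_phase_flip = FALSE, seed = 1) {
  stopifnot(lambda_ratio > 0, lambda_ratio <= 1, stop_k >= 1,
            warmup_epochs >= 0, freeze_every > 0, freeze_len >= 0,
            replace_every > 0)
  structure(as.list(environment()), class = "gf_config")
}

#' Epoch schedule of the training heuristics
#'
#' Expands the warm-up / freeze / replacement heuristics into a per-epoch
#' table: during warm-up only Gaussian parameters are optimized; after
#' every `freeze_every` post-warm-up epochs the networks are frozen for
#' `freeze_len` epochs; at every `replace_every`-th unfrozen epoch the
#' consensus positions are replaced.
#'
#' @param n_epochs post-warm-up epochs.
#' @param config a [vae_training_config].
#' @return data frame with columns `epoch` (1-based post-warm-up),
#'   `networks_update` and `replace`.
#' @export
training_schedule <- function(n_epochs, config = vae_training_config()) {
  period <- config$freeze_every + config$freeze_len
  epoch <- seq_len(n_epochs)
  pos <- ((epoch - 1) %% period) + 1
  frozen <- pos > config$freeze_every
  unfixed_count <- cumsum(!frozen)
  replace <- !frozen & unfixed_count %% config$replace_every == 0 &
    unfixed_count > 0
  data.frame(epoch = epoch, networks_update = !frozen, replace = replace)
}

#' Stopping epoch under the cumulative-increase rule
#'
#' Training stops once the per-epoch data loss has increased (relative to
#' the previous epoch) for the `k`-th time, counted cumulatively.
#'
#' @param losses numeric vector of per-epoch data losses.
#' @param k increase budget (default 40).
#' @return index of the epoch at which training stops, or `length(losses)`
#'   if the budget is never exhausted.
#' @export
stopping_epoch <- function(losses, k = 40) {
  if (length(losses) < 2) return(length(losses))
  inc <- cumsum(diff(losses) > 0)
  hit <- which(inc >= k)
  if (length(hit) == 0) length(losses) else hit[1] + 1L
}

# Internal: assemble precomputed per-particle tensors for training.
prep_training_data <- function(particles, oversample, lowpass = 1,
                               phase_flip = FALSE) {
  n <- dim(particles$images)[1]
  N <- nrow(particles$meta)
  ctx <- make_imaging_context(n, particles$pixel_size, oversample)
  yF <- array(0i, c(n, n, N))
  for (i in seq_len(N)) yF[, , i] <- fft2o(particles$images[, , i])
  meta <- particles$meta
  ctf <- ctf_stack(meta, n, particles$pixel_size)
  list(ctx = ctx, yF = yF, ctf = ctf,
       R_list = pose_matrices(meta),
       shifts = cbind(meta$shift_x, meta$shift_y),
       Ximg = encoder_input(yF, ctf, lowpass, phase_flip = phase_flip),
       N = N, n = n)
}

# Encoder input assembly: raw real-space images by default (standardized
# globally); optional low-pass and CTF phase flip are available but off,
# since the raw-image encoder performed best on the benchmark scenes.
# yF: n x n x N orthonormal Fourier images; ctf: n^2 x N.
encoder_input <- function(yF, ctf, lowpass = 1, center = NULL,
                          scale = NULL, phase_flip = FALSE) {
  n <- dim(yF)[1]
  N <- dim(yF)[3]
  keep <- shell_index2(n) <= lowpass * (n / 2)
  X <- matrix(0, N, n * n)
  for (i in seq_len(N)) {
    gi <- yF[, , i] * keep
    if (phase_flip) gi <- gi * sign(matrix(ctf[, i], n, n))
    X[i, ] <- as.vector(Re(stats::fft(gi, inverse = TRUE)) / n)
  }
  if (is.null(center)) center <- mean(X)
  if (is.null(scale)) scale <- stats::sd(X)
  out <- (X - center) / scale
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

current_graph <- function(st) {
  if (st$config$regularizer == "atomic") st$fixed_graph
  else build_neighbor_graph(st$model$centers)
}

# One minibatch: forward, losses, gradients. idx indexes particles;
# phase: "warmup" | "full" | "frozen". Returns losses and gradient lists.
vae_batch_grads <- function(st, idx, phase, eps_mat = NULL,
                            parts = c("data", "reg")) {
  td <- st$td; ctx <- td$ctx
  B <- length(idx); ng <- nrow(st$model$centers)
  enc_cache <- NULL; dec_fwd <- NULL
  if (phase == "warmup") {
    Z <- NULL
    Dmat <- st$model$centers[rep(seq_len(ng), B), , drop = FALSE]
  } else {
    code <- encode(td$Ximg[idx, , drop = FALSE], st$encoder)
    enc_cache <- code$cache
    if (is.null(eps_mat)) eps_mat <- matrix(0, B, st$config$latent_dim)
    Z <- code$mu + code$sigma * eps_mat
    dec_fwd <- dec_forward(st$decoder, Z, st$model$centers)
    Dmat <- dec_fwd$D
  }
  R_list <- td$R_list[idx]
  fw <- forward_batch(ctx, st$model, Dmat, R_list,
                      td$shifts[idx, , drop = FALSE],
                      td$ctf[, idx, drop = FALSE])
  yB <- td$yF[, , idx, drop = FALSE]
  smap <- sigma_map(ctx$n, st$noise)
  resid <- fw$g - yB
  wres <- resid / array(rep(smap, B), dim(resid))
  loss_data <- sum(Mod(resid)^2 / array(rep(smap, B), dim(resid))) / B
  dD <- matrix(0, B * ng, 3)
  d_log_s <- 0; d_log_a <- 0
  if ("data" %in% parts) {
    dG <- 2 * wres / B
    bwd <- forward_backward(ctx, st$model, fw$cache, dG, R_list)
    dD <- dD + bwd$dD
    d_log_s <- bwd$d_log_s; d_log_a <- bwd$d_log_a
  }
  rg <- reg_batch(st$model$centers, Dmat, B, st$graph$edges, st$tau)
  use_rep <- st$config$regularizer == "smooth"
  loss_reg <- (rg$rd + if (use_rep) rg$rr else 0) / B
  dC_rest <- matrix(0, ng, 3)
  dC_reg_id <- matrix(0, ng, 3)
  reg_on_c <- isTRUE(st$config$reg_on_gaussians)
  if ("reg" %in% parts && st$config$regularizer != "none") {
    scale <- if ("data" %in% parts) st$lambda / B else 1 / B
    dD <- dD + scale * rg$dD
    if (reg_on_c) {
      dC_rest <- scale * rg$dC
    } else {
      # consensus follows the data term only: remove the (dominant,
      # identity-path) regularizer contribution from the centre gradient
      dC_reg_id <- rowsum(scale * rg$dD, rep(seq_len(ng), B),
                          reorder = TRUE)
    }
  }
  out <- list(loss_data = loss_data, loss_rd = rg$rd / B,
              loss_rr = rg$rr / B, loss_reg = loss_reg, oob = fw$oob,
              d_log_s = d_log_s, d_log_a = d_log_a)
  if (phase == "warmup") {
    out$dC <- rowsum(dD, rep(seq_len(ng), B), reorder = TRUE) + dC_rest
    return(out)
  }
  if (length(parts) == 0) return(out)
  dbk <- dec_backward(st$decoder, dec_fwd, dD)
  out$dec_grads <- dbk$params
  out$dC <- dbk$dC + dC_rest - dC_reg_id
  # KL and encoder backprop
  nl <- st$config$latent_dim
  mu <- enc_cache$out[, seq_len(nl), drop = FALSE]
  logvar <- enc_cache$out[, nl + seq_len(nl), drop = FALSE]
  sigma <- exp(0.5 * logvar)
  out$loss_kl <- 0.5 * sum(mu^2 + sigma^2 - 1 - logvar) / B
  dMu <- dbk$dZ + st$beta * mu / B
  dSigma <- dbk$dZ * eps_mat + st$beta * (sigma - 1 / sigma) / B
  dLogvar <- dSigma * sigma * 0.5
  ebk <- mlp_backward(st$encoder$net, enc_cache, cbind(dMu, dLogvar))
  out$enc_grads <- mlp_grad_list(ebk)
  out
}

# Gaussian parameters in optimizer units: centres in normalized box units
# (Angstrom / coord_scale), widths and amplitudes on the log scale, so one
# ADAM learning rate is meaningful for all three.
gaussian_params <- function(model, cs) list(model$centers / cs,
                                            log(model$widths),
                                            log(model$amplitudes))

set_gaussian_params <- function(model, params, cs) {
  model$centers <- params[[1]] * cs
  model$widths <- exp(params[[2]])
  model$amplitudes <- exp(params[[3]])
  model
}

# Deterministic full-set data loss (z = mu, no updates), in chunks.
eval_data_loss <- function(st, idx = seq_len(st$td$N), chunk = 125) {
  tot <- 0
  for (part in split(idx, ceiling(seq_along(idx) / chunk))) {
    gr <- vae_batch_grads(st, part,
                          if (is.null(st$encoder)) "warmup" else "full",
                          eps_mat = matrix(0, length(part),
                                           st$config$latent_dim),
                          parts = character(0))
    tot <- tot + gr$loss_data * length(part)
  }
  tot / length(idx)
}

# Gradient norms of the data term and the (unweighted) regularizer wrt the
# decoder parameters, on a fixed probe batch with z = mu.
measure_grad_norms <- function(st, idx) {
  gF <- vae_batch_grads(st, idx, "full", parts = "data")
  gR <- vae_batch_grads(st, idx, "full", parts = "reg")
  list(nF = param_norm(gF$dec_grads), nR = param_norm(gR$dec_grads))
}

#' Train the deformation VAE for one half set
#'
#' Runs warm-up (Gaussian parameters only), then joint optimization of the
#' encoder, decoder and Gaussian parameters with the dynamic
#' regularization weight, the freeze/replacement heuristics and the
#' cumulative-increase stopping rule. The neighbour graph is recalculated
#' from the reference model after every epoch (smooth regularizer).
#'
#' @param particles a `particle_stack` with images (one half set).
#' @param model initial [gaussian_model] (e.g. [initialize_from_map]).
#' @param config a [vae_training_config].
#' @param graph fixed bond graph for `regularizer = "atomic"`.
#' @param validation_idx particle indices (into `particles`) excluded from
#'   decoder and Gaussian updates; they still contribute encoder updates
#'   so their embedding is trained.
#' @param verbose print per-epoch progress.
#' @param hook optional monitoring callback `function(state, epoch)` run
#'   after every post-warm-up epoch.
#' @return object of class `gf_vae_half`: encoder, decoder, updated model,
#'   per-particle `mu` and `sigma`, noise model, final graph, lambda and a
#'   per-epoch `history` data frame.
#' @export
train_halfset_vae <- function(particles, model, config = vae_training_config(),
                              graph = NULL, validation_idx = NULL,
                              verbose = FALSE, hook = NULL) {
  stopifnot(inherits(particles, "particle_stack"),
            !is.null(particles$images))
  if (config$regularizer == "atomic" && is.null(graph))
    stop("atomic regularizer requires a bond graph")
  rng <- local_rng(config$seed)
  td <- prep_training_data(particles, config$oversample,
                           lowpass = config$encoder_lowpass,
                           phase_flip = config$encoder_phase_flip)
  n <- td$n
  hidden_dec <- if (is.null(config$hidden_decoder))
    min(192L, max(32L, 2L * n)) else config$hidden_decoder
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$td <- td
  st$model <- model
  st$fixed_graph <- graph
  st$encoder <- new_encoder(n, config$latent_dim, config$hidden_encoder,
                            sigma_init = config$sigma_init,
                            seed = rng$derive(1))
  st$decoder <- new_decoder(config$latent_dim,
                            coord_scale = n * particles$pixel_size / 2,
                            hidden = hidden_dec, n_freq = config$n_freq,
                            seed = rng$derive(2))
  st$noise <- estimate_noise_spectrum(particles, model,
                                      oversample = config$oversample)
  st$graph <- current_graph(st)
  st$tau <- st$graph$c_mean
  st$lambda <- 0
  st$beta <- 0
  N <- td$N
  train_idx <- setdiff(seq_len(N), validation_idx)
  probe <- train_idx[seq_len(min(config$probe_size, length(train_idx)))]
  cs <- n * particles$pixel_size / 2
  opt_g <- adam_new(gaussian_params(model, cs), lr = config$lr_gaussians)
  opt_e <- NULL; opt_d <- NULL
  history <- list()
  # One sweep. Training particles update everything the phase allows;
  # validation particles are passed through afterwards and contribute
  # only encoder updates (their embedding keeps training).
  run_epoch <- function(phase) {
    tot <- c(data = 0, rd = 0, rr = 0, kl = 0, oob = 0)
    do_batches <- function(indices, enc_only) {
      ord <- indices[sample_with(rng, length(indices))]
      nb <- ceiling(length(ord) / config$batch_size)
      for (bi in seq_len(nb)) {
        idx <- ord[((bi - 1) * config$batch_size + 1):
                   min(bi * config$batch_size, length(ord))]
        eps <- if (phase == "warmup") NULL else
          matrix(rng$rnorm(length(idx) * config$latent_dim), length(idx))
        gr <- vae_batch_grads(st, idx, phase, eps_mat = eps)
        tot["data"] <<- tot["data"] + gr$loss_data * length(idx)
        tot["rd"] <<- tot["rd"] + gr$loss_rd * length(idx)
        tot["rr"] <<- tot["rr"] + gr$loss_rr * length(idx)
        tot["oob"] <<- tot["oob"] + gr$oob
        if (!is.null(gr$loss_kl))
          tot["kl"] <<- tot["kl"] + gr$loss_kl * length(idx)
        if (phase == "full" && !is.null(gr$enc_grads)) {
          stp <- adam_step(opt_e, mlp_params(st$encoder$net), gr$enc_grads)
          opt_e <<- stp$state
          st$encoder$net <- mlp_set_params(st$encoder$net, stp$params)
        }
        if (enc_only) next
        if (phase == "full" && !is.null(gr$dec_grads)) {
          stp <- adam_step(opt_d, mlp_params(st$decoder$net), gr$dec_grads)
          opt_d <<- stp$state
          st$decoder$net <- mlp_set_params(st$decoder$net, stp$params)
        }
        gp <- list(gr$dC * cs, gr$d_log_s, gr$d_log_a)
        stp <- adam_step(opt_g, gaussian_params(st$model, cs), gp)
        opt_g <<- stp$state
        st$model <- set_gaussian_params(st$model, stp$params, cs)
      }
    }
    do_batches(train_idx, enc_only = FALSE)
    if (length(validation_idx) > 0 && phase != "warmup")
      do_batches(validation_idx, enc_only = TRUE)
    denom <- if (phase == "warmup") length(train_idx) else N
    tot / c(denom, denom, denom, denom, 1)
  }
  # ---- warm-up ----
  for (e in seq_len(config$warmup_epochs)) {
    tot <- run_epoch("warmup")
    history[[length(history) + 1]] <-
      data.frame(stage = "warmup", epoch = e, data_loss = tot["data"],
                 eval_loss = NA, rd = tot["rd"], rr = tot["rr"], kl = NA,
                 lambda = 0, replaced = FALSE, frozen = FALSE)
    if (verbose) message(sprintf("warmup %d: F = %.4g", e, tot["data"]))
    st$graph <- current_graph(st); st$tau <- st$graph$c_mean
  }
  # ---- joint phase ----
  opt_e <- adam_new(mlp_params(st$encoder$net), lr = config$lr_encoder)
  opt_d <- adam_new(mlp_params(st$decoder$net), lr = config$lr_decoder)
  sched <- training_schedule(config$n_epochs, config)
  losses <- numeric(0)
  best <- list(loss = Inf)
  tail_sum <- NULL; tail_n <- 0L
  tail_start <- config$n_epochs - config$tail_average + 1L
  for (e in seq_len(config$n_epochs)) {
    frozen <- !sched$networks_update[e]
    phase <- if (frozen) "frozen" else "full"
    # dynamic lambda from gradient-norm ratio on the probe batch
    if (st$config$regularizer != "none") {
      gn <- measure_grad_norms(st, probe)
      if (gn$nR > 0)
        st$lambda <- update_lambda(gn$nF, gn$nR, config$lambda_ratio,
                                   st$lambda)
    }
    if (st$beta == 0 && length(losses) == 0) {
      # KL weight relative to the per-pixel data-loss scale at warm-up end
      f0 <- if (length(history)) history[[length(history)]]$data_loss
            else as.numeric(n)^2
      st$beta <- config$beta_rel * max(f0 / n^2, .Machine$double.eps)
    }
    tot <- run_epoch(if (frozen) "frozen" else "full")
    # frozen epochs: only Gaussian parameters were updated inside
    # run_epoch via phase ("frozen" batches skip network updates)
    replaced <- FALSE
    if (sched$replace[e]) {
      st$model$centers <- replacement_positions(st, probe)
      replaced <- TRUE
    }
    st$graph <- current_graph(st); st$tau <- st$graph$c_mean
    if (config$tail_average > 0 && e >= tail_start) {
      cur <- c(mlp_params(st$encoder$net), mlp_params(st$decoder$net))
      tail_sum <- if (is.null(tail_sum)) cur else Map(`+`, tail_sum, cur)
      tail_n <- tail_n + 1L
    }
    eval_loss <- eval_data_loss(st)
    losses <- c(losses, eval_loss)
    if (config$keep_best && eval_loss < best$loss)
      best <- list(loss = eval_loss, encoder = st$encoder,
                   decoder = st$decoder, model = st$model,
                   graph = st$graph, epoch = e)
    history[[length(history) + 1]] <-
      data.frame(stage = if (frozen) "frozen" else "train", epoch = e,
                 data_loss = tot["data"], eval_loss = eval_loss,
                 rd = tot["rd"], rr = tot["rr"],
                 kl = tot["kl"], lambda = st$lambda, replaced = replaced,
                 frozen = frozen)
    if (verbose)
      message(sprintf("epoch %d%s: F = %.4g Rd = %.3g Rr = %.3g lam = %.3g",
                      e, if (frozen) " (frozen)" else "", tot["data"],
                      tot["rd"], tot["rr"], st$lambda))
    if (!is.null(hook)) hook(st, e)
    if (sum(diff(losses) > 0) >= config$stop_k) break
  }
  if (tail_n > 0) {
    avg <- lapply(tail_sum, function(p) p / tail_n)
    ne <- length(mlp_params(st$encoder$net))
    st$encoder$net <- mlp_set_params(st$encoder$net, avg[seq_len(ne)])
    st$decoder$net <- mlp_set_params(st$decoder$net, avg[-seq_len(ne)])
  }
  best_epoch <- NA_integer_
  if (config$keep_best && is.finite(best$loss)) {
    st$encoder <- best$encoder; st$decoder <- best$decoder
    st$model <- best$model; st$graph <- best$graph
    best_epoch <- best$epoch
  }
  # final embedding of every particle
  code <- encode(td$Ximg, st$encoder)
  out <- list(encoder = st$encoder, decoder = st$decoder, model = st$model,
              mu = code$mu, sigma = code$sigma, noise = st$noise,
              graph = st$graph, lambda = st$lambda, best_epoch = best_epoch,
              history = do.call(rbind, history), config = config,
              norm = list(mean = attr(td$Ximg, "center"),
                          sd = attr(td$Ximg, "scale"),
                          lowpass = config$encoder_lowpass,
                          phase_flip = config$encoder_phase_flip))
  class(out) <- "gf_vae_half"
  out
}

sample_with <- function(rng, n) rng$sample_int(n, n)

# Predicted conformation with the smallest mean displacement from the
# current reference, over the probe subset; used for consensus replacement.
replacement_positions <- function(st, probe) {
  code <- encode(st$td$Ximg[probe, , drop = FALSE], st$encoder)
  fw <- dec_forward(st$decoder, code$mu, st$model$centers,
                    keep_cache = FALSE)
  ng <- nrow(st$model$centers)
  disp <- sqrt(rowSums(fw$delta^2))
  mean_disp <- rowsum(disp, rep(seq_along(probe), each = ng))[, 1]
  best <- which.min(mean_disp)
  fw$D[(best - 1) * ng + seq_len(ng), , drop = FALSE]
}

#' @export
print.gf_vae_half <- function(x, ...) {
  h <- x$history
  cat(sprintf(paste0("<gf_vae_half> %d Gaussians, latent %d; %d epochs ",
                     "(final F = %.4g, lambda = %.3g)\n"),
              nrow(x$model$centers), x$config$latent_dim, nrow(h),
              h$data_loss[nrow(h)], x$lambda))
  invisible(x)
}

#' Synchronize the half-set reference models
#'
#' Builds a binary mask covering all voxels within `radius` of the half-1
#' consensus positions, ranks the half-2 predicted conformations by the
#' number of Gaussians falling inside the mask, and replaces the half-2
#' consensus positions with the average of the `n_avg` highest-ranked
#' predictions.
#'
#' @param model_half1,model_half2 the two consensus [gaussian_model]s.
#' @param vae_half2 trained `gf_vae_half` for half set 2 (its decoder and
#'   per-particle `mu` are used).
#' @param box,voxel_size grid on which the mask is built.
#' @param radius mask radius in Angstrom (default 6).
#' @param n_avg number of predictions averaged (default 100).
#' @return updated `model_half2`.
#' @export
synchronize_halfset_references <- function(model_half1, model_half2,
                                           vae_half2, box, voxel_size,
                                           radius = 6, n_avg = 100) {
  mask <- centers_mask(model_half1$centers, box, voxel_size, radius)
  N <- nrow(vae_half2$mu)
  ng <- nrow(model_half2$centers)
  counts <- numeric(N)
  preds <- vector("list", N)
  for (chunk in split(seq_len(N), ceiling(seq_len(N) / 200))) {
    fw <- dec_forward(vae_half2$decoder, vae_half2$mu[chunk, , drop = FALSE],
                      model_half2$centers, keep_cache = FALSE)
    for (k in seq_along(chunk)) {
      D <- fw$D[(k - 1) * ng + seq_len(ng), , drop = FALSE]
      preds[[chunk[k]]] <- D
      counts[chunk[k]] <- sum(in_mask(mask, D, box, voxel_size))
    }
  }
  top <- order(counts, decreasing = TRUE)[seq_len(min(n_avg, N))]
  avg <- Reduce(`+`, preds[top]) / length(top)
  model_half2$centers <- avg
  model_half2
}

centers_mask <- function(centers, box, voxel_size, radius) {
  mask <- array(FALSE, c(box, box, box))
  rv <- ceiling(radius / voxel_size)
  half <- box / 2
  for (i in seq_len(nrow(centers))) {
    v <- centers[i, ] / voxel_size + half           # 0-based voxel coords
    rng <- lapply(1:3, function(d)
      max(0, floor(v[d] - rv)):min(box - 1, ceiling(v[d] + rv)))
    gx <- expand.grid(rng[[1]], rng[[2]], rng[[3]])
    d2 <- (gx[, 1] - v[1])^2 + (gx[, 2] - v[2])^2 + (gx[, 3] - v[3])^2
    keep <- d2 <= (radius / voxel_size)^2
    if (any(keep))
      mask[as.matrix(gx[keep, ]) + 1L] <- TRUE
  }
  mask
}

in_mask <- function(mask, positions, box, voxel_size) {
  v <- round(positions / voxel_size + box / 2)
  ok <- v[, 1] >= 0 & v[, 1] < box & v[, 2] >= 0 & v[, 2] < box &
    v[, 3] >= 0 & v[, 3] < box
  res <- logical(nrow(positions))
  res[ok] <- mask[v[ok, , drop = FALSE] + 1L]
  res
}
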