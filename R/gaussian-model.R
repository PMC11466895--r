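#' Gaussian pseudo-atom model
#'
#' The consensus density is represented as a sum of isotropic 3D Gaussians
#' \deqn{f(x) = \sum_j \sum_i d_{j,i} a_j \exp(-\|x - c_i\|^2 / s_j^2)}
#' with `Ng` centres `c` (Angstrom), `Nc` width classes with widths `s`
#' and amplitudes `a`, and a column-stochastic class-weight matrix `d`
#' (each Gaussian's weights sum to 1). `Nc = 1` (a single shared width and
#' amplitude) is the default used throughout.
#'
#' @param centers Ng x 3 matrix of centres (Angstrom).
#' @param widths length-Nc vector of positive widths (Angstrom).
#' @param amplitudes length-Nc vector of positive amplitudes.
#' @param class_weights Nc x Ng nonnegative matrix with unit column sums;
#'   defaults to all-ones for `Nc = 1`.
#' @return object of class `gaussian_model`.
#' @export
gaussian_model <- function(centers, widths, amplitudes,
                           class_weights = NULL) {
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 3)
  nc <- length(widths)
  stopifnot(length(amplitudes) == nc, all(widths > 0), all(amplitudes > 0))
  if (is.null(class_weights))
    class_weights <- matrix(1 / nc, nc, nrow(centers))
  class_weights <- as.matrix(class_weights)
  stopifnot(nrow(class_weights) == nc, ncol(class_weights) == nrow(centers))
  if (any(class_weights < 0) ||
      any(abs(colSums(class_weights) - 1) > 1e-8))
    stop("gaussian_model: class weights must be nonnegative with unit column sums")
  structure(list(centers = centers, widths = widths,
                 amplitudes = amplitudes, class_weights = class_weights),
            class = "gaussian_model")
}

#' @export
print.gaussian_model <- function(x, ...) {
  cat(sprintf("<gaussian_model> %d Gaussians, %d width class(es), s = %s A\n",
              nrow(x$centers), length(x$widths),
              paste(signif(x$widths, 3), collapse = ", ")))
  invisible(x)
}

#' Render a Gaussian model onto a cubic grid
#'
#' Evaluates the model density at every voxel centre of a cubic grid with
#' the package coordinate convention (world origin at voxel `n/2`).
#'
#' @param model a [gaussian_model].
#' @param n grid size (voxels per axis).
#' @param voxel_size voxel size in Angstrom.
#' @param cutoff Gaussians are truncated beyond `cutoff` widths from their
#'   centre (default 6, relative error < 1e-15).
#' @return A [volume_grid].
#' @export
render_density <- function(model, n, voxel_size, cutoff = 6) {
  data <- render_density_cpp(model$centers, model$widths, model$amplitudes,
                             model$class_weights, as.integer(n), voxel_size,
                             cutoff)
  volume_grid(data, voxel_size)
}

#' Initialize a Gaussian model from a density map
#'
#' Thresholds the map and fills the region above the threshold with
#' `n_gaussians` randomly placed Gaussians (uniform within randomly chosen
#' above-threshold voxels). A single width class is used; the width is set
#' from the nominal point spacing of the support and the shared amplitude
#' is scaled so that the L2 norm of the rendered model matches the norm of
#' the map. Class weights are random on the simplex when `n_classes > 1`.
#'
#' @param volume a [volume_grid].
#' @param threshold density threshold; centres fall only in voxels whose
#'   value exceeds it.
#' @param n_gaussians number of pseudo-atoms.
#' @param seed integer seed; the initialization is deterministic given it.
#' @param n_classes number of width classes (default 1).
#' @return A [gaussian_model].
#' @export
initialize_from_map <- function(volume, threshold, n_gaussians, seed,
                                n_classes = 1) {
  n <- dim(volume$data)[1]
  vx <- volume$voxel_size
  above <- which(volume$data > threshold)
  if (length(above) < n_gaussians)
    stop(sprintf(paste0("initialize_from_map: only %d voxels above ",
                        "threshold, need %d"), length(above), n_gaussians))
  rng <- local_rng(seed)
  pick <- above[rng$sample_int(length(above), n_gaussians,
                               replace = length(above) < n_gaussians)]
  idx <- arrayInd(pick, dim(volume$data)) - 1L  # 0-based voxel indices
  # jitter uniformly inside the voxel, keeping the enclosing voxel fixed
  jit <- matrix(rng$runif(3 * n_gaussians, -0.499, 0.499), ncol = 3)
  centers <- (idx + jit - n / 2) * vx
  # width from mean nearest-point spacing of the support
  support_vol <- length(above) * vx^3
  width <- max(1.2 * vx, (support_vol / n_gaussians)^(1 / 3) * 0.75)
  dmat <- if (n_classes == 1) matrix(1, 1, n_gaussians) else {
    w <- matrix(rng$runif(n_classes * n_gaussians), n_classes)
    sweep(w, 2, colSums(w), "/")
  }
  model <- gaussian_model(centers, rep(width, n_classes),
                          rep(1, n_classes), dmat)
  # scale amplitudes so the rendered norm matches the map norm
  rendered <- render_density(model, n, vx)
  nr <- sqrt(sum(rendered$data^2))
  nm <- sqrt(sum(volume$data^2))
  if (nr > 0) model$amplitudes <- model$amplitudes * nm / nr
  model
}

#' Neighbour graph over pseudo-atom centres
#'
#' Builds the smoothness-regularization connectivity: first every point is
#' connected to its two nearest neighbours (graph F); `c_mean` is the mean
#' edge length of the deduplicated undirected 2-NN edge set; the returned
#' edge set E then contains every pair closer than `1.5 * c_mean`.
#'
#' @param centers N x 3 matrix of positions (Angstrom), N >= 2.
#' @return object of class `edge_graph`: list with `edges` (m x 2 integer
#'   matrix, i < j), `c_mean`, and `source = "knn_heuristic"`.
#' @export
build_neighbor_graph <- function(centers) {
  centers <- as.matrix(centers)
  ng <- nrow(centers)
  if (ng < 2) stop("build_neighbor_graph: need at least 2 points")
  dm <- as.matrix(stats::dist(centers))
  diag(dm) <- Inf
  k <- min(2L, ng - 1L)
  nn_edges <- matrix(0L, 0, 2)
  for (i in seq_len(ng)) {
    nb <- order(dm[i, ])[seq_len(k)]
    nn_edges <- rbind(nn_edges, cbind(pmin(i, nb), pmax(i, nb)))
  }
  nn_edges <- unique(nn_edges)
  c_mean <- mean(dm[nn_edges])
  close <- which(dm < 1.5 * c_mean & upper.tri(dm), arr.ind = TRUE)
  edges <- cbind(close[, 1], close[, 2])
  colnames(edges) <- NULL
  structure(list(edges = edges[order(edges[, 1], edges[, 2]), , drop = FALSE],
                 c_mean = c_mean, source = "knn_heuristic"),
            class = "edge_graph")
}

#' @export
print.edge_graph <- function(x, ...) {
  cat(sprintf("<edge_graph> %d edges (%s), c_mean = %.3f A\n",
              nrow(x$edges), x$source, x$c_mean))
  invisible(x)
}

#' Persist a Gaussian model as a self-describing table
#'
#' Writes one row per Gaussian (x, y, z, class weights) plus a graph edge
#' list and scalar parameters, as plain-text TSV/JSON files sharing a stem.
#'
#' @param model a [gaussian_model].
#' @param graph optional [build_neighbor_graph] result.
#' @param stem output path stem; writes `<stem>_gaussians.tsv`,
#'   `<stem>_edges.tsv` and `<stem>_params.json`.
#' @return `stem`, invisibly.
#' @export
write_gaussian_model <- function(model, stem, graph = NULL) {
  tab <- data.frame(x = model$centers[, 1], y = model$centers[, 2],
                    z = model$centers[, 3])
  wt <- t(model$class_weights)
  colnames(wt) <- paste0("d", seq_len(ncol(wt)))
  utils::write.table(cbind(tab, wt), paste0(stem, "_gaussians.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(widths = model$widths,
                            amplitudes = model$amplitudes),
                       paste0(stem, "_params.json"), digits = NA)
  if (!is.null(graph)) {
    utils::write.table(data.frame(i = graph$edges[, 1], j = graph$edges[, 2]),
                       paste0(stem, "_edges.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(stem)
}

#' Read a Gaussian model written by [write_gaussian_model]
#' @param stem path stem used when writing.
#' @return A [gaussian_model].
#' @export
read_gaussian_model <- function(stem) {
  tab <- utils::read.table(paste0(stem, "_gaussians.tsv"), header = TRUE,
                           sep = "\t")
  pars <- jsonlite::read_json(paste0(stem, "_params.json"),
                              simplifyVector = TRUE)
  dcols <- grep("^d[0-9]+$", names(tab))
  gaussian_model(as.matrix(tab[, c("x", "y", "z")]), pars$widths,
                 pars$amplitudes, t(as.matrix(tab[, dcols, drop = FALSE])))
}
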