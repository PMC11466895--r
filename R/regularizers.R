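#' Local-isometry deformation regularizer
#'
#' Penalizes changes of edge lengths under the deformation:
#' \deqn{R_d = \sum_{(i,j) \in E} (\|c_i - c_j\| - \|\Gamma(c_i) - \Gamma(c_j)\|)^2}
#' The value is zero for the identity and for any global rigid motion.
#'
#' @param positions Ng x 3 matrix of reference positions (Angstrom).
#' @param deformed Ng x 3 matrix of deformed positions.
#' @param graph an `edge_graph`.
#' @return scalar penalty (Angstrom^2).
#' @export
isometry_regularizer <- function(positions, deformed, graph) {
  e <- graph$edges
  if (nrow(e) == 0) return(0)
  d0 <- edge_lengths(positions, e)
  d1 <- edge_lengths(deformed, e)
  sum((d0 - d1)^2)
}

#' Repulsion regularizer
#'
#' Penalizes connected Gaussians that come closer than `tau` after
#' deformation:
#' \deqn{R_r = \sum_{(i,j) \in E,\ \|\Gamma(c_i)-\Gamma(c_j)\| < \tau}
#'   (\|\Gamma(c_i)-\Gamma(c_j)\| - \tau)^2}
#' The default `tau` is the graph's `c_mean`.
#'
#' @param deformed Ng x 3 matrix of deformed positions.
#' @param graph an `edge_graph`.
#' @param tau repulsion distance in Angstrom (default `graph$c_mean`).
#' @return scalar penalty (Angstrom^2).
#' @export
repulsion_regularizer <- function(deformed, graph, tau = graph$c_mean) {
  if (is.null(tau) || !is.finite(tau) || tau <= 0)
    stop("repulsion_regularizer: tau must be > 0")
  e <- graph$edges
  if (nrow(e) == 0) return(0)
  d1 <- edge_lengths(deformed, e)
  sum((d1[d1 < tau] - tau)^2)
}

edge_lengths <- function(pos, edges) {
  dd <- pos[edges[, 1], , drop = FALSE] - pos[edges[, 2], , drop = FALSE]
  sqrt(rowSums(dd^2))
}

# Batched regularizer value + gradients for training.
# Dmat: (B*Ng) x 3 particle-major deformed positions; C: Ng x 3 reference.
# Returns sum over the batch of (Rd + Rr), per-term totals, gradient wrt
# Dmat, and gradient wrt C (through the rest lengths), all unweighted.
reg_batch <- function(C, Dmat, B, edges, tau) {
  K <- nrow(edges)
  if (K == 0) {
    return(list(rd = 0, rr = 0, dD = Dmat * 0, dC = C * 0))
  }
  ng <- nrow(C)
  off <- rep((seq_len(B) - 1L) * ng, each = K)
  ii <- rep(edges[, 1], B) + off
  jj <- rep(edges[, 2], B) + off
  d0 <- rep(edge_lengths(C, edges), B)
  diff <- Dmat[ii, , drop = FALSE] - Dmat[jj, , drop = FALSE]
  d1 <- sqrt(rowSums(diff^2))
  d1s <- pmax(d1, 1e-12)
  unit <- diff / d1s
  # isometry
  gap <- d0 - d1
  rd <- sum(gap^2)
  coef_d <- -2 * gap                       # d rd / d d1
  # repulsion
  close <- d1 < tau
  rr <- sum((d1[close] - tau)^2)
  coef_r <- ifelse(close, 2 * (d1 - tau), 0)
  coef <- coef_d + coef_r
  gvec <- unit * coef
  dD <- rowsum(rbind(gvec, -gvec), c(ii, jj), reorder = FALSE)
  ord <- as.integer(rownames(dD))
  dDfull <- matrix(0, B * ng, 3)
  dDfull[ord, ] <- dD
  # gradient wrt reference positions through d0 (isometry only)
  diff0 <- C[edges[, 1], , drop = FALSE] - C[edges[, 2], , drop = FALSE]
  d0e <- pmax(edge_lengths(C, edges), 1e-12)
  unit0 <- diff0 / d0e
  # gap is ordered edge-major within each particle: sum over batch per edge
  gap_edge <- rowSums(matrix(gap, K, B))
  g0 <- unit0 * (2 * gap_edge)
  dC <- rowsum(rbind(g0, -g0), c(edges[, 1], edges[, 2]), reorder = FALSE)
  dCfull <- matrix(0, ng, 3)
  dCfull[as.integer(rownames(dC)), ] <- dC
  list(rd = rd, rr = rr, dD = dDfull, dC = dCfull)
}

#' Dynamic regularization weight
#'
#' Recomputes the regularization weight so the gradient-norm ratio between
#' the weighted regularizer and the data term equals the target `r`:
#' `lambda = r * |grad F| / |grad R|`. With `r = 1` both gradient norms
#' are equal; the recommended default is `r = 0.9`.
#'
#' @param grad_norm_data norm of the data-loss gradient.
#' @param grad_norm_reg norm of the (unweighted) regularizer gradient.
#' @param r target ratio in `(0, 1]` (default 0.9).
#' @param prev previous lambda, returned (with a warning) when
#'   `grad_norm_reg` is zero.
#' @return updated lambda.
#' @export
update_lambda <- function(grad_norm_data, grad_norm_reg, r = 0.9,
                          prev = 1) {
  if (!is.finite(grad_norm_reg) || grad_norm_reg <= 0) {
    warning("update_lambda: zero regularizer gradient; keeping previous lambda")
    return(prev)
  }
  r * grad_norm_data / grad_norm_reg
}
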