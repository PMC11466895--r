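# Greek-letter rank of a side-chain atom name (CB -> 2, CG/OG/SG -> 3, ...).
greek_rank <- function(atom_name) {
  pos <- substring(sub("^[A-Z]+?([ABGDEZH])", "\\1", atom_name), 1, 1)
  r <- match(pos, c("A", "B", "G", "D", "E", "Z", "H"))
  r[is.na(r)] <- 8L
  r
}

barycenter <- function(df) colMeans(df[, c("x", "y", "z"), drop = FALSE])

# One coarse-grained group: position, amplitude mass (summed Z), label.
cg_group <- function(pos, z_sum) list(pos = pos, z = z_sum)

# Coarse-grain a single amino-acid residue into groups.
# Returns list of groups; group 1 is the main-chain Gaussian.
cg_amino <- function(res) {
  nm <- res$atom_name
  mc_atoms <- res[nm %in% c("N", "C", "O"), , drop = FALSE]
  if (nrow(mc_atoms) == 0) return(NULL)
  # CA mass is assigned to the main-chain group; its position is the
  # barycentre of N, C, O only.
  mc_mass <- sum(element_z(mc_atoms$element)) +
    sum(element_z(res$element[nm == "CA"]))
  groups <- list(cg_group(barycenter(mc_atoms), mc_mass))
  side <- res[!nm %in% c("N", "C", "O", "CA", "OXT"), , drop = FALSE]
  resn <- res$res_name[1]
  if (resn == "GLY" || nrow(side) == 0) return(groups)
  if (resn %in% c("SER", "CYS", "ALA", "VAL", "THR")) {
    cb <- res[nm == "CB", , drop = FALSE]
    if (nrow(cb) == 0) return(groups)
    groups[[2]] <- cg_group(barycenter(cb), sum(element_z(side$element)))
    return(groups)
  }
  if (resn == "PRO") {
    abgd <- res[nm %in% c("CA", "CB", "CG", "CD"), , drop = FALSE]
    groups[[2]] <- cg_group(barycenter(abgd), sum(element_z(side$element)))
    return(groups)
  }
  rank <- greek_rank(nm)
  abg_sel <- nm == "CA" | (rank <= 3 & !nm %in% c("N", "C", "O", "OXT"))
  abg <- res[abg_sel, , drop = FALSE]
  side_abg_mass <- sum(element_z(res$element[abg_sel & nm != "CA"]))
  groups[[2]] <- cg_group(barycenter(abg), side_abg_mass)
  rest <- res[rank > 3 & !nm %in% c("N", "C", "O", "OXT", "CA"), ,
              drop = FALSE]
  if (nrow(rest) == 0) return(groups)
  if (resn %in% c("TYR", "TRP")) {
    # two additional Gaussians: split the remaining atoms at the median
    # greek rank (inner vs outer half of the ring system)
    rr <- greek_rank(rest$atom_name)
    ord <- order(rr, rest$atom_name)
    rest <- rest[ord, , drop = FALSE]
    h <- ceiling(nrow(rest) / 2)
    g1 <- rest[seq_len(h), , drop = FALSE]
    g2 <- rest[-seq_len(h), , drop = FALSE]
    groups[[3]] <- cg_group(barycenter(g1), sum(element_z(g1$element)))
    if (nrow(g2) > 0)
      groups[[4]] <- cg_group(barycenter(g2), sum(element_z(g2$element)))
  } else {
    groups[[3]] <- cg_group(barycenter(rest), sum(element_z(rest$element)))
  }
  groups
}

# Coarse-grain one nucleotide into 4 groups: phosphate, sugar barycentre,
# and two base groups. Group 1-2 form the main chain.
cg_nucleotide <- function(res) {
  nm <- res$atom_name
  is_p <- nm %in% c("P", "OP1", "OP2", "OP3", "O1P", "O2P")
  is_sugar <- grepl("'", nm)
  p_atoms <- res[is_p, , drop = FALSE]
  sugar <- res[is_sugar, , drop = FALSE]
  base <- res[!is_p & !is_sugar, , drop = FALSE]
  groups <- list()
  if (nrow(p_atoms) > 0) {
    ppos <- if ("P" %in% nm) unlist(res[nm == "P", c("x", "y", "z")])
            else barycenter(p_atoms)
    groups[[length(groups) + 1]] <-
      cg_group(ppos, sum(element_z(p_atoms$element)))
  }
  if (nrow(sugar) > 0)
    groups[[length(groups) + 1]] <-
      cg_group(barycenter(sugar), sum(element_z(sugar$element)))
  if (nrow(base) > 0) {
    h <- ceiling(nrow(base) / 2)
    g1 <- base[seq_len(h), , drop = FALSE]
    g2 <- base[-seq_len(h), , drop = FALSE]
    groups[[length(groups) + 1]] <-
      cg_group(barycenter(g1), sum(element_z(g1$element)))
    if (nrow(g2) > 0)
      groups[[length(groups) + 1]] <-
        cg_group(barycenter(g2), sum(element_z(g2$element)))
  }
  groups
}

#' Coarse-grain an atomic model into a Gaussian model and bond graph
#'
#' Per amino acid: one main-chain Gaussian at the barycentre of the N, C
#' and O atoms; side chains get one Gaussian at the barycentre of the
#' alpha/beta/gamma atoms (PRO: alpha/beta/gamma/delta; SER, CYS, ALA,
#' VAL, THR: the beta position; GLY: none), larger residues one extra
#' Gaussian at the barycentre of the remaining side-chain atoms and TYR and
#' TRP two extra. Per nucleotide: four Gaussians (phosphate, sugar
#' barycentre, two base groups). Amplitudes are proportional to the summed
#' atomic numbers of each group's heavy atoms (the alpha carbon counts
#' toward the main-chain group). Edges connect consecutive main-chain
#' Gaussians along each chain and chain each residue's side-chain Gaussians
#' back to its main-chain Gaussian.
#'
#' @param structure an `atomic_structure` from [read_structure].
#' @param width shared Gaussian width in Angstrom (single class).
#' @return list with `model` (a [gaussian_model] whose amplitude is the
#'   mean group mass, with per-Gaussian mass folded into class weights
#'   times amplitude via the returned `masses` attribute), `graph` (an
#'   `edge_graph` with `source = "atomic_bonds"`), `masses` (per-Gaussian
#'   relative amplitude), and `skipped` (count of unknown residues).
#' @export
coarse_grain_atomic_model <- function(structure, width = 2.5) {
  stopifnot(inherits(structure, "atomic_structure"))
  centers <- NULL
  masses <- numeric()
  edges <- matrix(0L, 0, 2)
  skipped <- 0L
  res_split <- split(as.data.frame(structure),
                     list(structure$chain, structure$res_index), drop = TRUE)
  ord <- order(vapply(res_split, function(r) r$chain[1], ""),
               vapply(res_split, function(r) r$res_index[1], 1))
  res_split <- res_split[ord]
  prev_mc <- NA_integer_
  prev_chain <- ""
  for (res in res_split) {
    resn <- res$res_name[1]
    is_aa <- resn %in% AA3
    is_nuc <- resn %in% NUC3
    if (!is_aa && !is_nuc) {
      warning("skipping unknown residue ", resn, call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    groups <- if (is_aa) cg_amino(res) else cg_nucleotide(res)
    if (is.null(groups) || length(groups) == 0) next
    base_idx <- length(masses)
    for (g in groups) {
      centers <- rbind(centers, g$pos)
      masses <- c(masses, g$z)
    }
    mc_idx <- base_idx + 1L
    # side-chain / base groups: chain each to the previous one, anchored
    # at the main-chain Gaussian
    if (length(groups) > 1) {
      for (k in 2:length(groups))
        edges <- rbind(edges, c(base_idx + k - 1L, base_idx + k))
    }
    # consecutive main-chain connection along the chain
    if (!is.na(prev_mc) && res$chain[1] == prev_chain)
      edges <- rbind(edges, c(prev_mc, mc_idx))
    # nucleotide main chain is phosphate + sugar: link forward from sugar
    prev_mc <- if (is_nuc && length(groups) >= 2) base_idx + 2L else mc_idx
    prev_chain <- res$chain[1]
  }
  if (is.null(centers)) stop("coarse_grain_atomic_model: no residues recognized")
  rownames(centers) <- NULL
  edges <- unique(cbind(pmin(edges[, 1], edges[, 2]),
                        pmax(edges[, 1], edges[, 2])))
  c_mean <- if (nrow(edges) > 0) {
    mean(sqrt(rowSums((centers[edges[, 1], , drop = FALSE] -
                       centers[edges[, 2], , drop = FALSE])^2)))
  } else NA_real_
  graph <- list(edges = edges[order(edges[, 1], edges[, 2]), , drop = FALSE],
                c_mean = c_mean, source = "atomic_bonds")
  class(graph) <- "edge_graph"
  model <- gaussian_model(centers, width, mean(masses))
  list(model = model, graph = graph, masses = masses / mean(masses),
       skipped = skipped)
}
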