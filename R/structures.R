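AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL", "MSE")

NUC3 <- c("A", "C", "G", "U", "T", "DA", "DC", "DG", "DT", "DU")

ATOMIC_NUMBER <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16, SE = 34,
                   FE = 26, MG = 12, ZN = 30, MN = 25, CA = 20, K = 19,
                   NA. = 11, CL = 17)

element_z <- function(elements) {
  z <- ATOMIC_NUMBER[toupper(elements)]
  z[is.na(z)] <- 6  # unknown elements treated as carbon-weight
  unname(z)
}

#' Read an atomic structure (PDB/mmCIF)
#'
#' Loads a model through \pkg{bio3d}, drops hydrogens and resolves
#' alternate locations to the highest-occupancy copy. Residue names are
#' checked against standard amino-acid and nucleotide dictionaries;
#' non-standard residues are kept but flagged.
#'
#' @param pdb_path path to a PDB or mmCIF file.
#' @return object of class `atomic_structure`: a data frame of heavy atoms
#'   with columns element, x, y, z, atom_name, res_name, res_index, chain,
#'   is_standard.
#' @export
read_structure <- function(pdb_path) {
  pdb <- if (grepl("\\.cif$", pdb_path)) bio3d::read.cif(pdb_path)
         else bio3d::read.pdb(pdb_path)
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("read_structure: empty model")
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- sub("^[0-9]*", "", at$elety)
    elem <- substring(elem, 1, 1)
  }
  keep <- toupper(trimws(elem)) != "H" & !grepl("^[0-9]*H", at$elety)
  at <- at[keep, , drop = FALSE]
  elem <- trimws(elem[keep])
  # resolve altlocs: keep highest occupancy per (chain, resno, atom name)
  key <- paste(at$chain, at$resno, at$elety)
  occ <- if (!is.null(at$o)) at$o else rep(1, nrow(at))
  ord <- order(key, -occ)
  at <- at[ord, , drop = FALSE]; elem <- elem[ord]; key <- key[ord]
  first <- !duplicated(key)
  at <- at[first, , drop = FALSE]; elem <- elem[first]
  at <- at[order(at$chain, at$resno, at$eleno), , drop = FALSE]
  elem2 <- trimws(if (!is.null(at$elesy)) at$elesy else elem)
  res_name <- trimws(at$resid)
  out <- data.frame(element = elem2, x = at$x, y = at$y, z = at$z,
                    atom_name = trimws(at$elety), res_name = res_name,
                    res_index = at$resno, chain = at$chain,
                    is_standard = res_name %in% c(AA3, NUC3),
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0) stop("read_structure: no heavy atoms found")
  class(out) <- c("atomic_structure", "data.frame")
  out
}
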