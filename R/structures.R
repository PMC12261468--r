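#' Ligand bond graph
#'
#' Heavy-atom bond graph of one or more ligand fragments. This is the object
#' the harmonic prior is built from: its graph Laplacian is the precision
#' matrix of the prior over ligand coordinates, so bonded atoms are sampled
#' close together.
#'
#' @param atom_elements character vector of element symbols, one per heavy atom.
#' @param bonds integer matrix with two columns (1-based atom indices), one
#'   row per bond, or `NULL` for a bond-less graph.
#' @return An object of class `ligand_graph` with fields `atom_elements`,
#'   `bonds` (m x 2 integer matrix), `fragment_ids` (connected-component
#'   label per atom) and `n_atoms`.
#' @examples
#' lg <- ligand_graph(c("C", "C", "O"), rbind(c(1, 2), c(2, 3)))
#' graph_laplacian(lg)
#' @export
ligand_graph <- function(atom_elements, bonds = NULL) {
  n <- length(atom_elements)
  if (n < 1) stop_input("ligand_graph: need at least one atom")
  if (is.null(bonds) || length(bonds) == 0) {
    bonds <- matrix(integer(0), ncol = 2)
  } else {
    bonds <- matrix(as.integer(bonds), ncol = 2)
  }
  if (nrow(bonds) > 0) {
    if (any(bonds < 1L | bonds > n)) {
      stop_input("ligand_graph: bond index out of range [1, %d]", n)
    }
    if (any(bonds[, 1] == bonds[, 2])) stop_input("ligand_graph: self-bond")
  }
  g <- structure(
    list(atom_elements = as.character(atom_elements), bonds = bonds,
         fragment_ids = integer(n), n_atoms = n),
    class = "ligand_graph"
  )
  g$fragment_ids <- connected_components(n, bonds)
  g
}

# Connected components by repeated label propagation (n is small here).
connected_components <- function(n, bonds) {
  lab <- seq_len(n)
  if (nrow(bonds) > 0) {
    repeat {
      changed <- FALSE
      for (k in seq_len(nrow(bonds))) {
        i <- bonds[k, 1]; j <- bonds[k, 2]
        m <- min(lab[i], lab[j])
        if (lab[i] != m || lab[j] != m) {
          lab[lab == max(lab[i], lab[j])] <- m
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  match(lab, sort(unique(lab)))
}

#' @export
print.ligand_graph <- function(x, ...) {
  cat(sprintf("ligand_graph: %d atoms, %d bonds, %d fragment(s)\n",
              x$n_atoms, nrow(x$bonds), max(x$fragment_ids)))
  invisible(x)
}

#' Bead-chain or real protein structure
#'
#' Holds the residue sequence, the C-alpha trace used for alignment and
#' TM-score, and the full heavy-atom coordinates the flow transports.
#'
#' @param sequence character scalar (one-letter residue codes) or character
#'   vector of residue types; its length is the residue count.
#' @param ca_coords S x 3 matrix of C-alpha coordinates (Angstrom).
#' @param heavy_coords N x 3 matrix of all heavy-atom coordinates; must
#'   contain at least one atom per residue (N >= S). Defaults to the
#'   C-alpha trace itself.
#' @param atom_to_residue integer vector mapping each heavy atom to its
#'   residue (1-based).
#' @param chain_ids optional per-residue chain identifiers (multi-chain
#'   proteins are concatenated into one residue list).
#' @return An object of class `protein_structure`.
#' @export
protein_structure <- function(sequence, ca_coords,
                              heavy_coords = ca_coords,
                              atom_to_residue = seq_len(nrow(ca_coords)),
                              chain_ids = NULL) {
  if (length(sequence) == 1 && nchar(sequence[1]) > 1) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  s <- length(sequence)
  ca_coords <- as_coord_matrix(ca_coords, "ca_coords")
  heavy_coords <- as_coord_matrix(heavy_coords, "heavy_coords")
  if (s < 1) stop_input("protein_structure: empty sequence")
  if (nrow(ca_coords) != s) {
    stop_input("protein_structure: %d residues but %d C-alpha rows",
               s, nrow(ca_coords))
  }
  if (nrow(heavy_coords) < s) {
    stop_input("protein_structure: fewer heavy atoms (%d) than residues (%d)",
               nrow(heavy_coords), s)
  }
  atom_to_residue <- as.integer(atom_to_residue)
  if (length(atom_to_residue) != nrow(heavy_coords) ||
      any(atom_to_residue < 1L | atom_to_residue > s)) {
    stop_input("protein_structure: atom_to_residue must map every heavy atom to a residue")
  }
  if (!all(is.finite(ca_coords)) || !all(is.finite(heavy_coords))) {
    stop_input("protein_structure: non-finite coordinates")
  }
  structure(
    list(sequence = sequence, ca_coords = ca_coords,
         heavy_coords = heavy_coords, atom_to_residue = atom_to_residue,
         chain_ids = chain_ids %||% rep("A", s),
         n_residues = s, n_heavy = nrow(heavy_coords)),
    class = "protein_structure"
  )
}

as_coord_matrix <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3) stop_input("%s: expected an n x 3 matrix", what)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("protein_structure: %d residues, %d heavy atoms, %d chain(s)\n",
              x$n_residues, x$n_heavy, length(unique(x$chain_ids))))
  invisible(x)
}

#' Protein-ligand complex at a flow time
#'
#' @param protein a [protein_structure()].
#' @param ligand_coords NL x 3 matrix of ligand heavy-atom coordinates.
#' @param ligand_graph a [ligand_graph()] with matching atom count.
#' @param t flow time in `[0, 1]`; 0 is the apo/prior state, 1 the holo state.
#' @return An object of class `complex_structure`.
#' @export
complex_structure <- function(protein, ligand_coords, ligand_graph, t = 0) {
  stopifnot(inherits(protein, "protein_structure"),
            inherits(ligand_graph, "ligand_graph"))
  ligand_coords <- as_coord_matrix(ligand_coords, "ligand_coords")
  if (nrow(ligand_coords) != ligand_graph$n_atoms) {
    stop_input("complex_structure: %d ligand coordinate rows but graph has %d atoms",
               nrow(ligand_coords), ligand_graph$n_atoms)
  }
  if (!is.numeric(t) || length(t) != 1 || t < 0 || t > 1) {
    stop_input("complex_structure: t must be a scalar in [0, 1]")
  }
  structure(
    list(protein = protein, ligand_coords = ligand_coords,
         ligand_graph = ligand_graph, t = as.numeric(t)),
    class = "complex_structure"
  )
}

#' @export
print.complex_structure <- function(x, ...) {
  cat(sprintf("complex_structure (t = %.3f): %d residues, %d protein heavy atoms, %d ligand atoms\n",
              x$t, x$protein$n_residues, x$protein$n_heavy,
              x$ligand_graph$n_atoms))
  invisible(x)
}

#' Stack complex coordinates into one matrix
#'
#' The flow acts on all heavy atoms jointly; this returns protein heavy
#' atoms followed by ligand atoms as one (NP + NL) x 3 matrix.
#'
#' @param cs a [complex_structure()].
#' @return Numeric matrix of stacked coordinates.
#' @export
complex_coords <- function(cs) {
  rbind(cs$protein$heavy_coords, cs$ligand_coords)
}

#' Rebuild a complex from stacked coordinates
#'
#' Inverse of [complex_coords()]: splits an (NP + NL) x 3 matrix back into
#' the protein and ligand blocks of a template complex. C-alpha coordinates
#' are refreshed from the heavy-atom block using the template's C-alpha
#' atom positions within each residue.
#'
#' @param template a [complex_structure()] supplying topology.
#' @param coords stacked coordinate matrix as from [complex_coords()].
#' @param t flow time for the rebuilt complex.
#' @return A [complex_structure()].
#' @export
set_complex_coords <- function(template, coords, t = template$t) {
  coords <- as_coord_matrix(coords, "coords")
  np <- template$protein$n_heavy
  nl <- template$ligand_graph$n_atoms
  if (nrow(coords) != np + nl) {
    stop_input("set_complex_coords: expected %d rows, got %d", np + nl, nrow(coords))
  }
  prot <- template$protein
  heavy <- coords[seq_len(np), , drop = FALSE]
  ca_idx <- ca_atom_indices(prot)
  prot$heavy_coords <- heavy
  prot$ca_coords <- heavy[ca_idx, , drop = FALSE]
  complex_structure(prot, coords[np + seq_len(nl), , drop = FALSE],
                    template$ligand_graph, t = t)
}

# Index of the heavy atom standing for each residue's C-alpha: the heavy
# atom closest to the stored C-alpha, resolved once from the template.
ca_atom_indices <- function(protein) {
  vapply(seq_len(protein$n_residues), function(r) {
    idx <- which(protein$atom_to_residue == r)
    d2 <- rowSums((protein$heavy_coords[idx, , drop = FALSE] -
                     matrix(protein$ca_coords[r, ], length(idx), 3,
                            byrow = TRUE))^2)
    idx[which.min(d2)]
  }, integer(1))
}
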