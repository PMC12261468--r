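#' Write a complex to a PDB file
#'
#' Protein heavy atoms become ATOM records (C-alpha as `CA`, pseudo
#' side-chain beads as `CB`, further atoms as `CG`, ...), the ligand
#' becomes HETATM records with residue name `LIG` on chain `L`. Chain
#' identifiers of multi-chain proteins are preserved. Serial and residue
#' numbers are 1-based, as PDB requires.
#'
#' @param cs a [complex_structure()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_complex_pdb <- function(cs, file) {
  rec <- complex_pdb_records(cs)
  bio3d::write.pdb(file = file, xyz = rec$xyz, type = rec$type,
                   resno = rec$resno, resid = rec$resid, chain = rec$chain,
                   elety = rec$elety, eleno = seq_along(rec$resno),
                   elesy = rec$elesy)
  invisible(file)
}

complex_pdb_records <- function(cs) {
  p <- cs$protein
  n_p <- p$n_heavy
  n_l <- cs$ligand_graph$n_atoms
  # per-residue atom naming: CA for the C-alpha slot, then CB, CG, ...
  ca_idx <- ca_atom_indices(p)
  elety_p <- character(n_p)
  side_names <- c("CB", "CG", "CD", "CE", "CZ", "CH")
  for (r in seq_len(p$n_residues)) {
    idx <- which(p$atom_to_residue == r)
    k <- 0
    for (i in idx) {
      if (i == ca_idx[r]) {
        elety_p[i] <- "CA"
      } else {
        k <- k + 1
        elety_p[i] <- side_names[min(k, length(side_names))]
      }
    }
  }
  resid_p <- bio3d::aa123(p$sequence)[p$atom_to_residue]
  elety_l <- paste0(cs$ligand_graph$atom_elements, seq_len(n_l))
  list(
    xyz = as.numeric(t(rbind(p$heavy_coords, cs$ligand_coords))),
    type = c(rep("ATOM", n_p), rep("HETATM", n_l)),
    resno = c(p$atom_to_residue, rep(p$n_residues + 1L, n_l)),
    resid = c(resid_p, rep("LIG", n_l)),
    chain = c(p$chain_ids[p$atom_to_residue], rep("L", n_l)),
    elety = c(elety_p, elety_l),
    elesy = c(substr(elety_p, 1, 1), cs$ligand_graph$atom_elements)
  )
}

#' Read a complex from a PDB file
#'
#' Inverse of [write_complex_pdb()]: ATOM records become the protein
#' (the `CA` atom of each residue is its C-alpha), HETATM records the
#' ligand. The bond graph cannot be recovered from a PDB file, so one
#' must be supplied (or a bond-less graph is used).
#'
#' @param file PDB path.
#' @param graph optional [ligand_graph()] for the HETATM block.
#' @param t flow time to stamp on the complex (default 0).
#' @return A [complex_structure()] (or a bare [protein_structure()] if
#'   the file has no HETATM records and no graph is given).
#' @export
read_complex_pdb <- function(file, graph = NULL, t = 0) {
  if (!file.exists(file)) stop_input("read_complex_pdb: no such file: %s", file)
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom
  prot_rows <- at$type == "ATOM"
  lig_rows <- at$type == "HETATM"
  pa <- at[prot_rows, , drop = FALSE]
  res_key <- paste(pa$chain, pa$resno)
  res_fac <- factor(res_key, levels = unique(res_key))
  atom_to_residue <- as.integer(res_fac)
  ca_rows <- which(pa$elety == "CA")
  if (length(ca_rows) != nlevels(res_fac)) {
    stop_input("read_complex_pdb: expected one CA per residue in %s", file)
  }
  seq1 <- bio3d::aa321(pa$resid[ca_rows])
  heavy <- cbind(pa$x, pa$y, pa$z)
  prot <- protein_structure(seq1, heavy[ca_rows, , drop = FALSE], heavy,
                            atom_to_residue,
                            chain_ids = pa$chain[ca_rows])
  if (!any(lig_rows) && is.null(graph)) return(prot)
  la <- at[lig_rows, , drop = FALSE]
  if (is.null(graph)) {
    graph <- ligand_graph(gsub("[0-9]", "", la$elety))
  }
  complex_structure(prot, cbind(la$x, la$y, la$z), graph, t = t)
}

#' Write a sampling trajectory as a multi-model PDB
#'
#' One MODEL/ENDMDL block per solver state, so the transport from the
#' prior to the holo prediction can be played back in any molecular
#' viewer.
#'
#' @param trajectory a `flow_trajectory` carrying a complex template.
#' @param file output path.
#' @param stride keep every `stride`-th state (default 1 = all).
#' @return `file`, invisibly.
#' @export
write_trajectory_pdb <- function(trajectory, file, stride = 1) {
  if (is.null(trajectory$template)) {
    stop_input("write_trajectory_pdb: trajectory has no complex template")
  }
  rec <- complex_pdb_records(trajectory$template)
  keep <- unique(c(seq(1, length(trajectory$states), by = stride),
                   length(trajectory$states)))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  con <- file(file, "w")
  on.exit(close(con), add = TRUE)
  for (m in seq_along(keep)) {
    x <- trajectory$states[[keep[m]]]
    bio3d::write.pdb(file = tmp, xyz = as.numeric(t(x)), type = rec$type,
                     resno = rec$resno, resid = rec$resid,
                     chain = rec$chain, elety = rec$elety,
                     eleno = seq_along(rec$resno), elesy = rec$elesy)
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(grep("^(ATOM|HETATM|TER)", readLines(tmp), value = TRUE), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Read a ligand bond graph from SMILES, SDF, or a bond-list file
#'
#' Accepts (i) a SMILES string (multi-fragment, dot-separated SMILES
#' yield multiple fragment ids), parsed with ChemmineR/ChemmineOB;
#' (ii) a path to an SDF file; or (iii) a path to a plain bond-list text
#' file -- one element symbol per line, then `BOND i j` lines with
#' 0-based atom indices -- which needs no cheminformatics dependency.
#' Hydrogens are stripped; only heavy atoms are kept.
#'
#' @param x SMILES string or file path.
#' @return A [ligand_graph()].
#' @export
read_ligand <- function(x) {
  if (length(x) != 1 || !is.character(x)) stop_input("read_ligand: need one string")
  if (file.exists(x)) {
    if (grepl("\\.sdf$", x, ignore.case = TRUE)) return(ligand_from_sdf_file(x))
    return(read_bond_list(x))
  }
  ligand_from_smiles(x)
}

ligand_from_smiles <- function(smiles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop_input("read_ligand: SMILES parsing needs ChemmineR + ChemmineOB; use the bond-list format instead")
  }
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "lig"))),
    error = function(e) stop_input("read_ligand: unparseable SMILES '%s' (%s)",
                                   smiles, conditionMessage(e))
  )
  ligand_from_sdf(sdfset[[1]])
}

ligand_from_sdf_file <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop_input("read_ligand: SDF parsing needs ChemmineR")
  }
  sdfset <- ChemmineR::read.SDFset(path)
  ligand_from_sdf(sdfset[[1]])
}

ligand_from_sdf <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  elements <- gsub("_.*$", "", rownames(ab))
  bb <- ChemmineR::bondblock(sdf)
  bonds <- if (nrow(bb) > 0) cbind(as.integer(bb[, 1]), as.integer(bb[, 2])) else NULL
  heavy <- which(toupper(elements) != "H")
  remap <- match(seq_along(elements), heavy)
  if (!is.null(bonds)) {
    keep <- bonds[, 1] %in% heavy & bonds[, 2] %in% heavy
    bonds <- cbind(remap[bonds[keep, 1]], remap[bonds[keep, 2]])
    if (nrow(bonds) == 0) bonds <- NULL
  }
  ligand_graph(elements[heavy], bonds)
}

read_bond_list <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  bond_rows <- grepl("^BOND\\b", lines)
  elements <- lines[!bond_rows]
  bad <- !grepl("^[A-Z][a-z]?$", elements)
  if (any(bad)) stop_input("read_bond_list: bad element token '%s'", elements[bad][1])
  bonds <- NULL
  for (ln in lines[bond_rows]) {
    parts <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(parts) != 3) stop_input("read_bond_list: bad bond line '%s'", ln)
    bonds <- rbind(bonds, as.integer(parts[2:3]) + 1L)  # 0-based on disk
  }
  ligand_graph(elements, bonds)
}

#' Write a ligand bond graph as a bond-list file
#'
#' @param graph a [ligand_graph()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_bond_list <- function(graph, file) {
  lines <- c("# cfmdock bond-list ligand (0-based bond indices)",
             graph$atom_elements)
  if (nrow(graph$bonds) > 0) {
    lines <- c(lines, sprintf("BOND %d %d", graph$bonds[, 1] - 1L,
                              graph$bonds[, 2] - 1L))
  }
  writeLines(lines, file)
  invisible(file)
}

#' Run configuration
#'
#' Bundles the tunable parameters of the pipeline: solver settings,
#' coupling thresholds, prior noise, field architecture, and the
#' run-level seed all randomness derives from.
#'
#' @param solver a [solver_config()].
#' @param thresholds a [coupling_thresholds()].
#' @param noise_sigma training noise scale in Angstrom (default `1e-4`).
#' @param field a [field_config()].
#' @param seed run-level integer seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(solver = solver_config(),
                       thresholds = coupling_thresholds(),
                       noise_sigma = 1e-4,
                       field = field_config(),
                       seed = 1L) {
  structure(list(solver = solver, thresholds = thresholds,
                 noise_sigma = noise_sigma, field = field,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Unknown keys (at the top level or inside any section) are rejected so
#' that typos fail loudly instead of silently using defaults.
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop_input("load_run_config: no such file: %s", path)
  y <- yaml::read_yaml(path)
  check_keys <- function(got, allowed, section) {
    extra <- setdiff(names(got), allowed)
    if (length(extra) > 0) {
      stop_input("load_run_config: unknown key '%s' in %s", extra[1], section)
    }
  }
  check_keys(y, c("solver", "thresholds", "noise_sigma", "field", "seed"),
             "top level")
  sol <- y$solver %||% list()
  check_keys(sol, c("n_steps", "eta", "clamp_lo", "clamp_hi", "seed"), "solver")
  thr <- y$thresholds %||% list()
  check_keys(thr, c("c_tm", "c_rmsd", "min_residues", "max_residues",
                    "min_ligand_atoms", "max_ligand_atoms"), "thresholds")
  fld <- y$field %||% list()
  check_keys(fld, c("hidden_width", "n_layers", "neighbor_cutoff",
                    "time_embedding_dim", "seed"), "field")
  run_config(
    solver = do.call(solver_config, sol),
    thresholds = do.call(coupling_thresholds, thr),
    noise_sigma = y$noise_sigma %||% 1e-4,
    field = do.call(field_config, fld),
    seed = y$seed %||% 1L
  )
}

#' Save a run configuration to YAML
#'
#' @param config a [run_config()].
#' @param path output file.
#' @return `path`, invisibly. `load_run_config(save_run_config(x, p))`
#'   reproduces `x` (round-trip idempotence).
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  y <- list(
    solver = unclass(config$solver),
    thresholds = unclass(config$thresholds),
    noise_sigma = config$noise_sigma,
    field = unclass(config$field),
    seed = config$seed
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Filter a pool of apo-holo pairs into a manifest
#'
#' Runs [apo_holo_filter()] over a list of pairs and tabulates the
#' outcome -- the TSV-friendly pair manifest of the unbalanced coupling.
#'
#' @param pairs list of `list(apo=, holo=)` pairs.
#' @param thresholds a [coupling_thresholds()].
#' @return A data.frame with columns `pair`, `tm`, `rmsd`, `accepted`,
#'   `reason`.
#' @export
filter_pairs <- function(pairs, thresholds = coupling_thresholds()) {
  rows <- lapply(seq_along(pairs), function(k) {
    d <- apo_holo_filter(pairs[[k]]$apo, pairs[[k]]$holo, thresholds)
    data.frame(pair = k, tm = d$tm, rmsd = d$rmsd,
               accepted = d$accepted, reason = d$reject_reason)
  })
  do.call(rbind, rows)
}
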