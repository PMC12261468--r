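#' Toy apo-holo system specification
#'
#' Defines one synthetic bead-chain protein-ligand system with a known
#' apo-to-holo deformation, emulating a curated training pair. Proteins
#' are self-avoiding bead chains with one C-alpha and one pseudo
#' side-chain atom per residue (so heavy-atom and C-alpha bookkeeping
#' differ, as in real structures); ligands are random connected bond
#' graphs with bead coordinates packed into a surface pocket.
#'
#' @param n_residues protein length (default 60).
#' @param n_ligand_atoms total ligand heavy atoms (default 12).
#' @param n_fragments number of ligand fragments (default 1).
#' @param deformation_mode one of `"rigid_ligand_shift"` (ligand
#'   translated out of the pocket by exactly `deformation_scale`),
#'   `"pocket_hinge"` (a chain segment rotated about a hinge so the RMS
#'   C-alpha displacement equals `deformation_scale`), or
#'   `"global_deform"` (smooth low-frequency backbone perturbation with
#'   RMS amplitude `deformation_scale`).
#' @param deformation_scale magnitude in Angstrom (default 4).
#' @param affinity_alpha pK units gained per protein-ligand heavy-atom
#'   contact (default 0.1).
#' @param affinity_noise_sd pK-scale noise on the synthetic affinity
#'   (default 0.5, the order of experimental affinity uncertainty).
#' @param seed integer seed; every quantity is reproducible from it.
#' @return An object of class `toy_system_spec`.
#' @export
toy_system_spec <- function(n_residues = 60, n_ligand_atoms = 12,
                            n_fragments = 1,
                            deformation_mode = c("rigid_ligand_shift",
                                                 "pocket_hinge",
                                                 "global_deform"),
                            deformation_scale = 4,
                            affinity_alpha = 0.1,
                            affinity_noise_sd = 0.5,
                            seed = 1L) {
  deformation_mode <- match.arg(deformation_mode)
  if (n_residues < 4) stop_input("toy_system_spec: need at least 4 residues")
  if (n_ligand_atoms < 1) stop_input("toy_system_spec: need at least 1 ligand atom")
  if (n_fragments < 1 || n_fragments > n_ligand_atoms) {
    stop_input("toy_system_spec: n_fragments must be in [1, n_ligand_atoms]")
  }
  if (deformation_scale < 0) stop_input("toy_system_spec: deformation_scale must be >= 0")
  structure(
    list(n_residues = as.integer(n_residues),
         n_ligand_atoms = as.integer(n_ligand_atoms),
         n_fragments = as.integer(n_fragments),
         deformation_mode = deformation_mode,
         deformation_scale = deformation_scale,
         affinity_alpha = affinity_alpha,
         affinity_noise_sd = affinity_noise_sd,
         seed = as.integer(seed)),
    class = "toy_system_spec"
  )
}

# One-letter residue alphabet for bead chains.
aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# Self-avoiding random walk of C-alpha beads, step 3.8 A, minimum
# bead separation 3.6 A for non-neighbors.
build_backbone <- function(s) {
  ca <- matrix(0, s, 3)
  dir <- random_unit()
  for (r in 2:s) {
    for (try in 1:60) {
      cand_dir <- dir + 0.9 * rnorm(3)
      cand_dir <- cand_dir / sqrt(sum(cand_dir^2))
      cand <- ca[r - 1, ] + 3.8 * cand_dir
      prev <- ca[seq_len(max(1, r - 2)), , drop = FALSE]
      if (r == 2 || min(sqrt(rowSums(sweep(prev, 2, cand)^2))) > 3.6) break
    }
    ca[r, ] <- cand
    dir <- cand_dir
  }
  ca
}

#' Generate one synthetic apo-holo complex pair
#'
#' Builds the bound (holo) complex first -- bead-chain protein with the
#' ligand packed into a surface pocket -- then derives the unbound (apo)
#' state by applying the requested deformation. The synthetic binding
#' affinity is `affinity_alpha * contacts(holo) + N(0, affinity_noise_sd)`
#' in pK units, with contacts counted as protein-ligand heavy-atom pairs
#' within 4.5 Angstrom.
#'
#' @param spec a [toy_system_spec()].
#' @return List with `apo` and `holo` ([complex_structure()] objects,
#'   residue-matched), `true_affinity` (pK), `contacts` (integer), and
#'   `spec`.
#' @export
generate_system <- function(spec) {
  stopifnot(inherits(spec, "toy_system_spec"))
  set.seed(substream_seed(spec$seed, "system"))
  s <- spec$n_residues
  nl <- spec$n_ligand_atoms

  ca <- build_backbone(s)
  # pseudo side-chain bead 1.5 A off each C-alpha
  cb <- ca + t(vapply(seq_len(s), function(r) 1.5 * random_unit(),
                      numeric(3)))
  heavy <- matrix(0, 2 * s, 3)
  heavy[2 * seq_len(s) - 1, ] <- ca
  heavy[2 * seq_len(s), ] <- cb
  atom_to_residue <- rep(seq_len(s), each = 2)
  sequence <- sample(aa_alphabet, s, replace = TRUE)
  prot <- protein_structure(sequence, ca, heavy, atom_to_residue)

  # pocket: middle residue, displaced outward from the protein centroid
  m <- floor(s / 2)
  outward <- ca[m, ] - colMeans(ca)
  nrm <- sqrt(sum(outward^2))
  outward <- if (nrm > 1e-8) outward / nrm else random_unit()
  # 4.2 A offset: deliberately off the 4.5 A contact cutoff so no pair
  # sits exactly on the contact boundary
  pocket_center <- ca[m, ] + 4.2 * outward

  lig <- build_ligand(nl, spec$n_fragments, pocket_center)
  holo <- complex_structure(prot, lig$coords, lig$graph, t = 1)

  apo <- apply_deformation(holo, spec$deformation_mode,
                           spec$deformation_scale)
  nc <- count_contacts(holo)
  affinity <- spec$affinity_alpha * nc + rnorm(1, sd = spec$affinity_noise_sd)
  list(apo = apo, holo = holo, true_affinity = affinity,
       contacts = nc, spec = spec)
}

# Random connected bond graph per fragment (spanning tree plus an
# occasional ring-closing edge) with bead coordinates grown at 1.5 A
# bond length around the pocket center.
build_ligand <- function(nl, n_fragments, pocket_center) {
  frag_sizes <- diff(round(seq(0, nl, length.out = n_fragments + 1)))
  frag_sizes[frag_sizes < 1] <- 1
  frag_sizes[length(frag_sizes)] <- nl - sum(frag_sizes[-length(frag_sizes)])
  elements <- sample(c("C", "C", "C", "N", "O"), nl, replace = TRUE)
  bonds <- NULL
  coords <- matrix(0, nl, 3)
  offset <- 0
  for (f in seq_along(frag_sizes)) {
    k <- frag_sizes[f]
    center <- pocket_center + if (f == 1) c(0, 0, 0) else 3 * random_unit()
    coords[offset + 1, ] <- center
    if (k > 1) {
      for (a in 2:k) {
        parent <- sample.int(a - 1, 1)
        bonds <- rbind(bonds, c(offset + parent, offset + a))
        coords[offset + a, ] <- coords[offset + parent, ] + 1.5 * random_unit()
      }
      if (k >= 4 && runif(1) < 0.5) {
        bonds <- rbind(bonds, c(offset + 1, offset + k))  # ring closure
      }
    }
    offset <- offset + k
  }
  list(graph = ligand_graph(elements, bonds), coords = coords)
}

apply_deformation <- function(holo, mode, scale) {
  prot <- holo$protein
  lig <- holo$ligand_coords
  if (scale == 0) {
    return(complex_structure(prot, lig, holo$ligand_graph, t = 0))
  }
  if (mode == "rigid_ligand_shift") {
    # undocking displacement: out of the pocket along the outward normal
    # (away from the protein centroid), jittered, magnitude exactly `scale`
    outward <- colMeans(lig) - colMeans(prot$ca_coords)
    outward <- outward / sqrt(sum(outward^2))
    dir <- outward + 0.4 * rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    lig <- sweep(lig, 2, -scale * dir)
  } else if (mode == "pocket_hinge") {
    prot <- hinge_deform(prot, scale)
  } else {
    prot <- global_deform(prot, scale)
  }
  complex_structure(prot, lig, holo$ligand_graph, t = 0)
}

rotation_about_axis <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# Rotate the C-terminal segment about a hinge residue; the angle is
# solved by bisection so the RMS C-alpha displacement equals `scale`.
hinge_deform <- function(prot, scale) {
  s <- prot$n_residues
  h <- max(2, floor(s / 3))
  axis <- random_unit()
  pivot <- prot$ca_coords[h, ]
  seg <- which(prot$atom_to_residue > h)
  displace <- function(angle) {
    R <- rotation_about_axis(axis, angle)
    hv <- prot$heavy_coords
    hv[seg, ] <- sweep(sweep(hv[seg, , drop = FALSE], 2, pivot) %*% t(R),
                       2, -pivot)
    hv
  }
  rms_ca <- function(angle) {
    hv <- displace(angle)
    ca <- hv[2 * seq_len(s) - 1, , drop = FALSE]
    sqrt(mean(rowSums((ca - prot$ca_coords)^2)))
  }
  lo <- 0; hi <- pi
  if (rms_ca(hi) < scale) {
    ang <- hi  # saturated: half-turn is the largest hinge motion
  } else {
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (rms_ca(mid) < scale) lo <- mid else hi <- mid
    }
    ang <- (lo + hi) / 2
  }
  hv <- displace(ang)
  protein_structure(prot$sequence, hv[2 * seq_len(s) - 1, , drop = FALSE],
                    hv, prot$atom_to_residue, prot$chain_ids)
}

# Smooth low-frequency sinusoidal backbone perturbation, normalized so
# the RMS C-alpha displacement equals `scale` exactly.
global_deform <- function(prot, scale) {
  s <- prot$n_residues
  u <- seq(0, 1, length.out = s)
  disp <- matrix(0, s, 3)
  for (k in 1:3) {
    phase <- runif(3, 0, 2 * pi)
    amp <- matrix(rnorm(3 * 3), 3, 3)
    for (ax in 1:3) {
      disp[, ax] <- disp[, ax] + amp[k, ax] * sin(pi * k * u + phase[ax])
    }
  }
  disp <- disp * scale / sqrt(mean(rowSums(disp^2)))
  hv <- prot$heavy_coords + disp[prot$atom_to_residue, ]
  protein_structure(prot$sequence, prot$ca_coords + disp, hv,
                    prot$atom_to_residue, prot$chain_ids)
}

#' Count protein-ligand heavy-atom contacts
#'
#' @param cs a [complex_structure()].
#' @param cutoff contact distance in Angstrom (default 4.5).
#' @return Integer number of protein-ligand atom pairs within `cutoff`.
#' @export
count_contacts <- function(cs, cutoff = 4.5) {
  p <- cs$protein$heavy_coords
  l <- cs$ligand_coords
  d2 <- outer(rowSums(p^2), rep(1, nrow(l))) +
    outer(rep(1, nrow(p)), rowSums(l^2)) - 2 * p %*% t(l)
  sum(d2 < cutoff^2)
}

#' Generate a stratified benchmark suite of toy systems
#'
#' Produces a deterministic manifest of system specifications stratified
#' across deformation modes, with disjoint seed blocks for the training
#' and held-out splits (held-out seeds are offset by a large constant).
#'
#' @param n_systems total number of systems.
#' @param spec_ranges named list overriding ranges: `n_residues`
#'   (length-2), `n_ligand_atoms` (length-2), `deformation_scale`
#'   (length-2), `modes` (character subset of deformation modes),
#'   `affinity_alpha`, `affinity_noise_sd`.
#' @param seed run-level seed.
#' @param heldout_fraction fraction of systems in the held-out split
#'   (default 0.3).
#' @return A data.frame manifest, one row per system, with a `split`
#'   column (`"train"`/`"heldout"`) and every `toy_system_spec` field.
#' @export
generate_benchmark_suite <- function(n_systems, spec_ranges = list(),
                                     seed = 1L, heldout_fraction = 0.3) {
  rng <- modifyList(list(
    n_residues = c(40, 80), n_ligand_atoms = c(8, 16),
    deformation_scale = c(2, 6),
    modes = c("rigid_ligand_shift", "pocket_hinge", "global_deform"),
    affinity_alpha = 0.1, affinity_noise_sd = 0.5,
    n_fragments = 1
  ), spec_ranges)
  set.seed(substream_seed(seed, "suite"))
  n_held <- round(n_systems * heldout_fraction)
  manifest <- data.frame(
    system_id = seq_len(n_systems),
    split = c(rep("train", n_systems - n_held), rep("heldout", n_held)),
    deformation_mode = rng$modes[(seq_len(n_systems) - 1) %% length(rng$modes) + 1],
    n_residues = sample(rng$n_residues[1]:rng$n_residues[2], n_systems,
                        replace = TRUE),
    n_ligand_atoms = sample(rng$n_ligand_atoms[1]:rng$n_ligand_atoms[2],
                            n_systems, replace = TRUE),
    n_fragments = rng$n_fragments,
    deformation_scale = runif(n_systems, rng$deformation_scale[1],
                              rng$deformation_scale[2]),
    affinity_alpha = rng$affinity_alpha,
    affinity_noise_sd = rng$affinity_noise_sd,
    stringsAsFactors = FALSE
  )
  base <- substream_seed(seed, "systems")
  manifest$seed <- ifelse(manifest$split == "train",
                          (base + manifest$system_id) %% 2147483629,
                          (base + 100000 + manifest$system_id) %% 2147483629)
  manifest
}

#' Realize a manifest row as a system
#'
#' @param row one row of a [generate_benchmark_suite()] manifest.
#' @return The [generate_system()] output for that row.
#' @export
system_from_manifest <- function(row) {
  generate_system(toy_system_spec(
    n_residues = row$n_residues, n_ligand_atoms = row$n_ligand_atoms,
    n_fragments = row$n_fragments, deformation_mode = row$deformation_mode,
    deformation_scale = row$deformation_scale,
    affinity_alpha = row$affinity_alpha,
    affinity_noise_sd = row$affinity_noise_sd, seed = row$seed
  ))
}

#' Sample decoy poses of a complex with known quality
#'
#' Produces perturbed copies of the bound complex -- rigid ligand
#' displacements of random magnitude plus per-atom conformational
#' jitter -- together with their ligand RMSD to the reference pose. This
#' is the labelled (structure, quality) set the confidence head is
#' trained and evaluated on.
#'
#' @param system a [generate_system()] result.
#' @param n number of decoys.
#' @param seed integer seed.
#' @param max_shift maximum rigid displacement in Angstrom (default 6).
#' @param max_jitter maximum per-atom jitter scale in Angstrom (default 1).
#' @return List with `structures` (list of [complex_structure()]) and
#'   `rmsd` (numeric ligand RMSD of each decoy to the bound pose).
#' @export
sample_decoy_poses <- function(system, n, seed = 1L, max_shift = 6,
                               max_jitter = 1) {
  set.seed(substream_seed(seed, "decoys"))
  holo <- system$holo
  outward <- colMeans(holo$ligand_coords) -
    colMeans(holo$protein$ca_coords)
  outward <- outward / sqrt(sum(outward^2))
  out <- lapply(seq_len(n), function(k) {
    lig <- holo$ligand_coords
    # flow-sample-like errors: mostly radial under/overshoot of the
    # pocket approach (jittered outward axis), occasionally isotropic
    dir <- if (runif(1) < 0.75) outward + 0.5 * rnorm(3) else rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    lig <- sweep(lig, 2, -runif(1, 0, max_shift) * dir)
    lig <- lig + matrix(rnorm(length(lig), sd = runif(1, 0, max_jitter)),
                        nrow(lig), 3)
    complex_structure(holo$protein, lig, holo$ligand_graph, t = 1)
  })
  list(structures = out,
       rmsd = vapply(out, function(cs) ligand_rmsd(cs, holo), numeric(1)))
}

#' Deform a bound complex to a target measured similarity
#'
#' Constructs an apo partner whose ligand-proximity-weighted alignment
#' against the holo protein measures (as close as possible) a requested
#' (TM-score, RMSD) pair -- the controlled way to probe the coupling
#' filter's acceptance region. Deviations are applied to disjoint pairs
#' of adjacent residues in equal and opposite amounts along the pair
#' axis, so they carry no net force or torque and the optimal
#' superposition stays at the identity; the number of moved residues
#' sets the TM-score and the deviation magnitude is calibrated against
#' the measured pipeline by a short fixed-point iteration so the RMSD
#' lands on target.
#'
#' @param system a [generate_system()] result (its holo complex is used).
#' @param tm_target desired measured TM-score.
#' @param rmsd_target desired measured RMSD in Angstrom.
#' @param rmsd_pad relative padding applied to the final deviation scale
#'   (e.g. `1e-7` to land just above an RMSD threshold); default 0.
#' @return List with `apo`, `holo`, and the measured `tm` and `rmsd`.
#' @export
deform_to_similarity <- function(system, tm_target, rmsd_target,
                                 rmsd_pad = 0) {
  holo <- system$holo
  prot <- holo$protein
  s <- prot$n_residues
  if (rmsd_target == 0 || tm_target >= 1) {
    apo <- complex_structure(prot, holo$ligand_coords, holo$ligand_graph, 0)
    d <- apo_holo_filter(apo, holo, coupling_thresholds())
    return(list(apo = apo, holo = holo, tm = d$tm, rmsd = d$rmsd))
  }
  d0 <- tm_d0(s)
  tm_of <- function(k, D) 1 - (k / s) * (1 - 1 / (1 + (D / d0)^2))
  # residues paired by similar alignment weight (least-weighted first) so
  # the deviations barely couple to the weighted superposition
  wts <- ligand_proximity_weights(prot, holo$ligand_coords)
  ord <- order(wts)
  best_k <- NA
  best_err <- Inf
  for (k in seq(2, 2 * floor(s / 2), by = 2)) {
    D <- sqrt(s * rmsd_target^2 / k)
    err <- abs(tm_of(k, D) - tm_target)
    if (err < best_err) { best_err <- err; best_k <- k }
  }
  k <- best_k
  build_apo <- function(k, D) {
    hv <- prot$heavy_coords
    ca <- prot$ca_coords
    for (p in seq_len(k / 2)) {
      i <- ord[2 * p - 1]; j <- ord[2 * p]
      v <- ca[i, ] - ca[j, ]
      v <- D * v / sqrt(sum(v^2))
      ri <- which(prot$atom_to_residue == i)
      rj <- which(prot$atom_to_residue == j)
      hv[ri, ] <- sweep(hv[ri, , drop = FALSE], 2, -v)
      hv[rj, ] <- sweep(hv[rj, , drop = FALSE], 2, v)
      ca[i, ] <- ca[i, ] + v
      ca[j, ] <- ca[j, ] - v
    }
    p2 <- protein_structure(prot$sequence, ca, hv, prot$atom_to_residue,
                            prot$chain_ids)
    complex_structure(p2, holo$ligand_coords, holo$ligand_graph, 0)
  }
  measure <- function(apo) {
    d <- apo_holo_filter(apo, holo, coupling_thresholds())
    c(tm = d$tm, rmsd = d$rmsd)
  }
  # outer loop: adjust the moved-residue count toward the measured
  # TM-score; inner loop: fixed point on the deviation magnitude so the
  # measured RMSD lands on target
  calibrate_D <- function(k) {
    D <- sqrt(s * rmsd_target^2 / k)
    for (it in 1:4) {
      m <- measure(build_apo(k, D))
      if (abs(m["rmsd"] - rmsd_target) < 1e-10) break
      D <- D * rmsd_target / m["rmsd"]
    }
    list(D = D, m = m)
  }
  cal <- calibrate_D(k)
  for (outer in 1:8) {
    tm_meas <- cal$m["tm"]
    if (abs(tm_meas - tm_target) < 0.003) break
    k_new <- 2 * round(k * (1 - tm_target) / (2 * (1 - tm_meas)))
    k_new <- min(max(k_new, 2), 2 * floor(s / 2))
    if (k_new == k) break
    k <- k_new
    cal <- calibrate_D(k)
  }
  apo <- build_apo(k, cal$D * (1 + rmsd_pad))
  m <- measure(apo)
  list(apo = apo, holo = holo, tm = unname(m["tm"]), rmsd = unname(m["rmsd"]))
}
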