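#' CondOT conditional path interpolation
#'
#' The conditional probability path between a prior sample `x0` and a data
#' sample `x1` is the straight line `xt = (1 - t) x0 + t x1`, the
#' conditional-optimal-transport (CondOT) path on Euclidean space.
#'
#' @param x0,x1 coordinate matrices of identical shape.
#' @param t scalar flow time in `[0, 1]`.
#' @return Matrix of the same shape as `x0`.
#' @export
condot_interpolate <- function(x0, x1, t) {
  if (!identical(dim(as.matrix(x0)), dim(as.matrix(x1)))) {
    stop_input("condot_interpolate: x0 and x1 shapes differ")
  }
  if (!is.numeric(t) || length(t) != 1 || t < 0 || t > 1) {
    stop_input("condot_interpolate: t must be a scalar in [0, 1]")
  }
  (1 - t) * x0 + t * x1
}

#' Endpoint-parametrized flow-matching loss
#'
#' Under the CondOT path the tractable regression target is the path
#' endpoint itself, so the field is an endpoint predictor and the loss is
#' the mean over (unmasked) atoms of the squared Euclidean deviation
#' `||pred_i - x1_i||^2`. The loss is deliberately frame-dependent: a
#' rigid motion applied to both arguments leaves it unchanged, applied to
#' one argument it does not.
#'
#' @param predicted,x1 n x 3 coordinate matrices.
#' @param mask logical per-atom vector; `FALSE` atoms are excluded.
#' @return Non-negative scalar; 0 iff `predicted == x1` on unmasked atoms.
#' @export
cfm_endpoint_loss <- function(predicted, x1, mask = NULL) {
  predicted <- as_coord_matrix(predicted, "predicted")
  x1 <- as_coord_matrix(x1, "x1")
  if (!identical(dim(predicted), dim(x1))) {
    stop_input("cfm_endpoint_loss: shapes differ")
  }
  if (is.null(mask)) mask <- rep(TRUE, nrow(x1))
  if (length(mask) != nrow(x1)) stop_input("cfm_endpoint_loss: mask length mismatch")
  if (!any(mask)) stop_input("cfm_endpoint_loss: empty mask")
  mean(rowSums((predicted - x1)^2)[mask])
}

#' Coupling thresholds for apo-holo pair filtering
#'
#' Thresholds of the unbalanced coupling: an apo-holo pair is kept only
#' if, after ligand-proximity-weighted superposition of the protein
#' C-alpha traces, the TM-score is at least `c_tm` and the RMSD is
#' strictly below `c_rmsd` (pairs with `rmsd >= c_rmsd` are rejected),
#' and the residue / ligand-atom counts fall inside the length bounds.
#'
#' @param c_tm TM-score lower bound in `(0, 1]` (default 0.7).
#' @param c_rmsd RMSD upper bound in Angstrom (default 5).
#' @param min_residues,max_residues protein length bounds (defaults 10, 2000).
#' @param min_ligand_atoms,max_ligand_atoms ligand size bounds (defaults 1, 200).
#' @return An object of class `coupling_thresholds`.
#' @export
coupling_thresholds <- function(c_tm = 0.7, c_rmsd = 5,
                                min_residues = 10, max_residues = 2000,
                                min_ligand_atoms = 1, max_ligand_atoms = 200) {
  if (c_tm <= 0 || c_tm > 1) stop_input("coupling_thresholds: c_tm must be in (0, 1]")
  if (c_rmsd <= 0) stop_input("coupling_thresholds: c_rmsd must be positive")
  structure(
    list(c_tm = c_tm, c_rmsd = c_rmsd,
         min_residues = min_residues, max_residues = max_residues,
         min_ligand_atoms = min_ligand_atoms,
         max_ligand_atoms = max_ligand_atoms),
    class = "coupling_thresholds"
  )
}

#' Coupling decision rule on measured similarity
#'
#' The decision kernel of the unbalanced coupling, applied to an already
#' measured (TM-score, RMSD) pair: reject if `tm < c_tm` (strict) or
#' `rmsd >= c_rmsd` (non-strict), or if length bounds fail. Exposed
#' separately from [apo_holo_filter()] so the inequality semantics can be
#' exercised at exact threshold values.
#'
#' @param tm measured TM-score.
#' @param rmsd measured RMSD in Angstrom.
#' @param n_residues,n_ligand_atoms sizes checked against length bounds.
#' @param thresholds a [coupling_thresholds()].
#' @return List with `accepted` (logical) and `reject_reason`, one of
#'   `"none"`, `"tm_below"`, `"rmsd_above"`, `"length"`.
#' @export
coupling_decide <- function(tm, rmsd, n_residues, n_ligand_atoms,
                            thresholds = coupling_thresholds()) {
  reason <- "none"
  if (n_residues < thresholds$min_residues ||
      n_residues > thresholds$max_residues ||
      n_ligand_atoms < thresholds$min_ligand_atoms ||
      n_ligand_atoms > thresholds$max_ligand_atoms) {
    reason <- "length"
  } else if (tm < thresholds$c_tm) {
    reason <- "tm_below"
  } else if (rmsd >= thresholds$c_rmsd) {
    reason <- "rmsd_above"
  }
  list(accepted = identical(reason, "none"), reject_reason = reason)
}

#' Unbalanced coupling filter for an apo-holo pair
#'
#' Superposes the apo protein onto the holo protein on C-alpha
#' correspondences with ligand-proximity weights (computed from the holo
#' ligand), measures TM-score (normalized by the holo chain length) and
#' unweighted C-alpha RMSD, then applies [coupling_decide()].
#'
#' @param apo,holo residue-matched [complex_structure()] objects.
#' @param thresholds a [coupling_thresholds()].
#' @param tm_optimal if `TRUE`, refine with an iterative TM-optimal
#'   superposition (repeatedly re-fitting on residues within `d0` weight)
#'   before scoring; default `FALSE` scores after the ligand-weighted
#'   alignment.
#' @return An object of class `coupling_decision`: list with `alignment`
#'   (an `alignment_result`), `tm`, `rmsd`, `accepted`, `reject_reason`.
#' @export
apo_holo_filter <- function(apo, holo, thresholds = coupling_thresholds(),
                            tm_optimal = FALSE) {
  stopifnot(inherits(apo, "complex_structure"),
            inherits(holo, "complex_structure"))
  s <- holo$protein$n_residues
  if (apo$protein$n_residues != s) {
    stop_input("apo_holo_filter: residue counts differ (%d vs %d)",
               apo$protein$n_residues, s)
  }
  w <- ligand_proximity_weights(holo$protein, holo$ligand_coords)
  aln <- weighted_kabsch(apo$protein$ca_coords, holo$protein$ca_coords,
                         weights = w, norm_length = s)
  if (tm_optimal) aln <- tm_refine(apo$protein$ca_coords,
                                   holo$protein$ca_coords, aln, s)
  dec <- coupling_decide(aln$tm_score, aln$rmsd, s, holo$ligand_graph$n_atoms,
                         thresholds)
  structure(
    list(alignment = aln, tm = aln$tm_score, rmsd = aln$rmsd,
         accepted = dec$accepted, reject_reason = dec$reject_reason),
    class = "coupling_decision"
  )
}

# Iterative TM-flavoured refinement: re-fit with weights 1/(1+(d/d0)^2)
# from the previous superposition until the TM-score stops improving.
tm_refine <- function(mobile_ca, reference_ca, aln, norm_length,
                      max_iter = 20) {
  d0 <- tm_d0(norm_length)
  best <- aln
  for (it in seq_len(max_iter)) {
    moved <- best$transform(mobile_ca)
    wi <- 1 / (1 + rowSums((moved - reference_ca)^2) / d0^2)
    cand <- weighted_kabsch(mobile_ca, reference_ca, weights = wi,
                            norm_length = norm_length)
    if (cand$tm_score <= best$tm_score + 1e-12) break
    best <- cand
  }
  best
}

#' @export
print.coupling_decision <- function(x, ...) {
  cat(sprintf("coupling_decision: TM = %.3f, RMSD = %.3f A -> %s%s\n",
              x$tm, x$rmsd, if (x$accepted) "accepted" else "rejected",
              if (x$accepted) "" else paste0(" (", x$reject_reason, ")")))
  invisible(x)
}

#' Draw a training batch of conditional path samples
#'
#' Each element draws a pair uniformly from the accepted pool, applies
#' training noise (`N(0, sigma)` per coordinate to the apo and holo
#' protein atoms and the holo ligand atoms), replaces the apo ligand by a
#' harmonic prior draw centered at the apo ligand centroid, samples
#' `t ~ U(0, 1)`, and interpolates along the CondOT path. The regression
#' target of every sample is the (noised) holo coordinate matrix.
#'
#' @param pairs list of accepted pairs, each a list with elements `apo`
#'   and `holo` ([complex_structure()] objects).
#' @param batch_size number of path samples.
#' @param seed integer seed; the batch is reproducible given it.
#' @param noise_sigma training noise scale in Angstrom (default `1e-4`).
#' @param harmonic_ligand if `TRUE` (default) the t = 0 ligand is a
#'   harmonic prior sample; if `FALSE` the apo ligand coordinates are
#'   used directly.
#' @return List of `path_sample` objects: lists with `x0`, `x1`, `t`,
#'   `xt`, `target` (all stacked coordinate matrices; `target == x1`),
#'   `pair_index`, and `is_ligand` (per-row indicator).
#' @export
sample_training_batch <- function(pairs, batch_size, seed = 1L,
                                  noise_sigma = 1e-4,
                                  harmonic_ligand = TRUE) {
  if (length(pairs) == 0) {
    stop_input("sample_training_batch: empty accepted pool (thresholds too strict?)")
  }
  set.seed(substream_seed(seed, "batch"))
  lapply(seq_len(batch_size), function(b) {
    k <- sample.int(length(pairs), 1)
    apo <- pairs[[k]]$apo
    holo <- pairs[[k]]$holo
    np <- apo$protein$n_heavy
    nl <- apo$ligand_graph$n_atoms

    lig0 <- if (harmonic_ligand) {
      ctr <- colMeans(apo$ligand_coords)
      centers <- matrix(ctr, max(apo$ligand_graph$fragment_ids), 3,
                        byrow = TRUE)
      spec <- harmonic_prior_spec(apo$ligand_graph, centers)
      sample_harmonic(spec, 1, seed = sample.int(2^31 - 2, 1))[[1]]
    } else {
      apo$ligand_coords
    }
    noise <- function(m, sd) m + matrix(rnorm(length(m), sd = sd),
                                        nrow(m), 3)
    x0 <- rbind(noise(apo$protein$heavy_coords, noise_sigma), lig0)
    x1 <- rbind(noise(holo$protein$heavy_coords, noise_sigma),
                noise(holo$ligand_coords, noise_sigma))
    t <- runif(1)
    structure(
      list(x0 = x0, x1 = x1, t = t, xt = condot_interpolate(x0, x1, t),
           target = x1, pair_index = k,
           is_ligand = c(rep(FALSE, np), rep(TRUE, nl))),
      class = "path_sample"
    )
  })
}
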