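#' Graph Laplacian of a ligand bond graph
#'
#' Computes `L = D - A`, the degree matrix minus the adjacency matrix.
#' `L` is symmetric positive-semidefinite with one zero eigenvalue per
#' connected fragment, and is block-diagonal across fragments. It is the
#' precision matrix of the harmonic ligand prior.
#'
#' @param graph a [ligand_graph()].
#' @return An `n_atoms` x `n_atoms` numeric matrix.
#' @examples
#' graph_laplacian(ligand_graph(c("C", "C", "C"), rbind(c(1, 2), c(2, 3))))
#' @export
graph_laplacian <- function(graph) {
  if (!inherits(graph, "ligand_graph")) stop_input("graph_laplacian: need a ligand_graph")
  n <- graph$n_atoms
  if (n < 1) stop_input("graph_laplacian: empty graph")
  A <- matrix(0, n, n)
  if (nrow(graph$bonds) > 0) {
    A[graph$bonds] <- 1
    A[graph$bonds[, c(2, 1), drop = FALSE]] <- 1
  }
  diag(rowSums(A), nrow = n, ncol = n) - A
}

#' Weighted Kabsch superposition
#'
#' Closed-form weighted least-squares rigid superposition of two
#' corresponding point sets via SVD of the weighted cross-covariance,
#' with the usual determinant correction so the returned rotation is
#' proper (no reflection). The transform minimizes
#' `sum_i w_i ||R x_i + t - y_i||^2`; the reported RMSD is the plain
#' (unweighted) RMSD over all points after applying the transform.
#'
#' @param mobile n x 3 matrix of points to move.
#' @param reference n x 3 matrix of target points (same correspondence).
#' @param weights non-negative per-point weights; at least 3 must be
#'   strictly positive. Default uniform.
#' @param norm_length chain length used to normalize the TM-score reported
#'   alongside the alignment; defaults to `nrow(reference)`.
#' @return An object of class `alignment_result`: list with `rotation`
#'   (3 x 3, det +1), `translation` (length-3), `rmsd`, `tm_score`, and
#'   `transform(x)`, a function applying the fitted motion.
#' @export
weighted_kabsch <- function(mobile, reference, weights = NULL,
                            norm_length = nrow(reference)) {
  mobile <- as_coord_matrix(mobile, "mobile")
  reference <- as_coord_matrix(reference, "reference")
  n <- nrow(mobile)
  if (n != nrow(reference)) stop_input("weighted_kabsch: point counts differ (%d vs %d)", n, nrow(reference))
  if (n < 3) stop_input("weighted_kabsch: need at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0)) {
    stop_input("weighted_kabsch: weights must be non-negative, one per point")
  }
  if (sum(weights > 0) < 3) stop_input("weighted_kabsch: need >= 3 strictly positive weights")
  w <- weights / sum(weights)

  mu_m <- colSums(mobile * w)
  mu_r <- colSums(reference * w)
  xm <- sweep(mobile, 2, mu_m)
  xr <- sweep(reference, 2, mu_r)
  H <- t(xm * w) %*% xr
  sv <- svd(H)
  # smallest singular value near zero => degenerate (collinear/coincident)
  if (sv$d[1] <= 0 || sv$d[3] / max(sv$d[1], .Machine$double.eps) < 1e-10) {
    warning("weighted_kabsch: degenerate geometry; best-effort transform returned",
            call. = FALSE)
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(mu_r - R %*% mu_m)

  moved <- mobile %*% t(R) + matrix(tr, n, 3, byrow = TRUE)
  dev2 <- rowSums((moved - reference)^2)
  res <- structure(
    list(rotation = R, translation = tr,
         rmsd = sqrt(mean(dev2)),
         tm_score = tm_from_dev2(dev2, norm_length),
         transform = function(x) {
           x <- as_coord_matrix(x, "x")
           x %*% t(R) + matrix(tr, nrow(x), 3, byrow = TRUE)
         }),
    class = "alignment_result"
  )
  res
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("alignment_result: rmsd = %.4f A, TM-score = %.4f\n",
              x$rmsd, x$tm_score))
  invisible(x)
}

# d0 length scale of the TM-score, floored at 0.5 A.
tm_d0 <- function(norm_length) {
  max(1.24 * (max(norm_length, 16) - 15)^(1 / 3) - 1.8, 0.5)
}

tm_from_dev2 <- function(dev2, norm_length) {
  d0 <- tm_d0(norm_length)
  sum(1 / (1 + dev2 / d0^2)) / norm_length
}

#' TM-score of two superposed C-alpha traces
#'
#' Length-normalized structural similarity in `(0, 1]`:
#' `TM = (1/Lnorm) * sum_i 1 / (1 + (d_i/d0)^2)` with
#' `d0 = 1.24 (Lnorm - 15)^(1/3) - 1.8` (floored at 0.5 Angstrom),
#' evaluated on the coordinates as given -- no superposition is applied
#' here, so align first (e.g. with [weighted_kabsch()]).
#'
#' @param aligned_ca_a,aligned_ca_b n x 3 matrices of corresponding
#'   C-alpha coordinates, already superposed.
#' @param norm_length normalizing chain length (conventionally the
#'   holo/crystal chain length). Defaults to `nrow(aligned_ca_a)`.
#' @return Scalar in `(0, 1]`; exactly 1 iff all deviations are zero.
#' @export
tm_score <- function(aligned_ca_a, aligned_ca_b,
                     norm_length = nrow(aligned_ca_a)) {
  a <- as_coord_matrix(aligned_ca_a, "aligned_ca_a")
  b <- as_coord_matrix(aligned_ca_b, "aligned_ca_b")
  if (nrow(a) != nrow(b)) {
    stop_input("tm_score: chain lengths differ (%d vs %d)", nrow(a), nrow(b))
  }
  if (norm_length < 1) stop_input("tm_score: norm_length must be >= 1")
  tm_from_dev2(rowSums((a - b)^2), norm_length)
}

#' Ligand-proximity residue weights
#'
#' Per-residue alignment weights concentrating the superposition on the
#' binding pocket: `w_i` is proportional to `exp(-d_i / scale)` where
#' `d_i` is the minimum distance from residue i's C-alpha to any ligand
#' heavy atom. Weights are normalized to sum to 1, so they lie in
#' `(0, 1]` and are non-increasing in `d_i`.
#'
#' @param protein a [protein_structure()].
#' @param ligand_coords NL x 3 matrix of ligand heavy-atom coordinates.
#' @param scale decay length in Angstrom (default 4).
#' @return Numeric vector of length `n_residues`, summing to 1.
#' @export
ligand_proximity_weights <- function(protein, ligand_coords, scale = 4) {
  ligand_coords <- as_coord_matrix(ligand_coords, "ligand_coords")
  if (nrow(ligand_coords) < 1) stop_input("ligand_proximity_weights: empty ligand")
  if (scale <= 0) stop_input("ligand_proximity_weights: scale must be positive")
  dmin <- min_dist_to_set(protein$ca_coords, ligand_coords)
  w <- exp(-dmin / scale)
  w / sum(w)
}

# Row-wise minimum Euclidean distance from points `x` to the set `y`.
min_dist_to_set <- function(x, y) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(y))) +
    outer(rep(1, nrow(x)), rowSums(y^2)) - 2 * x %*% t(y)
  sqrt(pmax(apply(d2, 1, min), 0))
}
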