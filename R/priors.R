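#' Harmonic ligand prior specification
#'
#' The harmonic prior is a Gaussian over ligand coordinates with density
#' proportional to `exp(-1/2 x^T L x)` per axis, where `L` is the bond
#' graph's Laplacian. The Laplacian has one zero eigenvalue per fragment
#' (rigid translations), so the density is improper along those modes;
#' sampling draws the positive-eigenvalue modes with per-axis variance
#' `1/lambda` and pins each fragment's centroid to a supplied center.
#'
#' @param graph a [ligand_graph()].
#' @param fragment_centers k x 3 matrix (one row per fragment) of centroid
#'   positions, or a single length-3 vector recycled to every fragment.
#'   Default: origin.
#' @param rng_seed integer seed used by [sample_harmonic()].
#' @return An object of class `harmonic_prior_spec`.
#' @export
harmonic_prior_spec <- function(graph, fragment_centers = c(0, 0, 0),
                                rng_seed = 1L) {
  stopifnot(inherits(graph, "ligand_graph"))
  k <- max(graph$fragment_ids)
  if (is.null(dim(fragment_centers))) {
    fragment_centers <- matrix(fragment_centers, k, 3, byrow = TRUE)
  }
  fragment_centers <- as_coord_matrix(fragment_centers, "fragment_centers")
  if (nrow(fragment_centers) != k) {
    stop_input("harmonic_prior_spec: %d fragment centers for %d fragments",
               nrow(fragment_centers), k)
  }
  structure(
    list(graph = graph, laplacian = graph_laplacian(graph),
         fragment_centers = fragment_centers, rng_seed = as.integer(rng_seed)),
    class = "harmonic_prior_spec"
  )
}

#' Sample ligand conformations from the harmonic prior
#'
#' Draws coordinates from the Gaussian with the bond-graph Laplacian as
#' precision matrix (independently per axis), via eigendecomposition:
#' each eigenmode with eigenvalue `lambda > 0` gets an independent
#' `N(0, 1/lambda)` coefficient per axis; zero modes (fragment
#' translations) are excluded and each fragment's centroid is set exactly
#' to its requested center.
#'
#' @param spec a [harmonic_prior_spec()].
#' @param n_samples number of independent conformations.
#' @param seed optional seed overriding `spec$rng_seed`.
#' @return A list of `n_samples` matrices, each `n_atoms` x 3.
#' @export
sample_harmonic <- function(spec, n_samples = 1, seed = NULL) {
  stopifnot(inherits(spec, "harmonic_prior_spec"))
  L <- spec$laplacian
  if (any(abs(L - t(L)) > 1e-9)) stop_input("sample_harmonic: Laplacian not symmetric")
  eig <- eigen(L, symmetric = TRUE)
  if (min(eig$values) < -1e-8) stop_input("sample_harmonic: matrix is not positive-semidefinite")
  pos <- which(eig$values > 1e-10)
  n <- nrow(L)
  frag <- spec$graph$fragment_ids
  set.seed(seed %||% spec$rng_seed)

  lapply(seq_len(n_samples), function(dummy) {
    x <- matrix(0, n, 3)
    if (length(pos) > 0) {
      z <- matrix(rnorm(length(pos) * 3), length(pos), 3) /
        sqrt(eig$values[pos])
      x <- eig$vectors[, pos, drop = FALSE] %*% z
    }
    # pin fragment centroids exactly
    for (f in seq_len(max(frag))) {
      idx <- which(frag == f)
      x[idx, ] <- sweep(x[idx, , drop = FALSE], 2,
                        colMeans(x[idx, , drop = FALSE]) -
                          spec$fragment_centers[f, ])
    }
    x
  })
}

#' Noised apo protein prior specification
#'
#' The protein side of the prior is a user-supplied unbound (apo)
#' structure -- typically a structure-prediction output -- with small
#' i.i.d. Gaussian noise added per coordinate, which turns the apo point
#' mass into a narrow distribution. During training the same noise scale
#' is also applied to holo structures to avoid overfitting to coordinate
#' noise; at inference protein noising defaults to off. The noise is not
#' a substitute for a real conformational ensemble.
#'
#' @param apo_structure a [protein_structure()].
#' @param noise_sigma noise scale in Angstrom per axis (default `1e-4`).
#' @param rng_seed integer seed.
#' @return An object of class `protein_prior_spec`.
#' @export
protein_prior_spec <- function(apo_structure, noise_sigma = 1e-4,
                               rng_seed = 1L) {
  stopifnot(inherits(apo_structure, "protein_structure"))
  if (noise_sigma < 0) stop_input("protein_prior_spec: noise_sigma must be >= 0")
  structure(
    list(apo_structure = apo_structure, noise_sigma = noise_sigma,
         rng_seed = as.integer(rng_seed)),
    class = "protein_prior_spec"
  )
}

#' Sample a noised apo protein structure
#'
#' @param spec a [protein_prior_spec()].
#' @param seed optional seed overriding `spec$rng_seed`.
#' @return A [protein_structure()] with coordinates
#'   `apo + N(0, sigma)` per axis and the sequence unchanged.
#' @export
sample_protein_prior <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "protein_prior_spec"))
  p <- spec$apo_structure
  if (spec$noise_sigma == 0) return(p)
  set.seed(seed %||% spec$rng_seed)
  eps <- matrix(rnorm(p$n_heavy * 3, sd = spec$noise_sigma), p$n_heavy, 3)
  heavy <- p$heavy_coords + eps
  ca_idx <- ca_atom_indices(p)
  p$heavy_coords <- heavy
  p$ca_coords <- heavy[ca_idx, , drop = FALSE]
  p
}
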