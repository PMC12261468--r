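#' Rigid-motion-invariant complex descriptors
#'
#' Feature vector consumed by the confidence and affinity heads. Every
#' feature is a function of interatomic distances only, so the heads are
#' invariant under rigid motion of the whole complex.
#'
#' @param cs a [complex_structure()].
#' @param contact_cutoff contact distance (default 4.5 Angstrom).
#' @param clash_cutoff clash distance (default 2.2 Angstrom).
#' @return Named numeric vector: `contacts_total` (protein-ligand atom
#'   pairs within the contact cutoff), `contacts_per_atom` (the same per
#'   ligand atom), `clashes_per_atom`,
#'   `mean_min_dist` (mean over ligand atoms of the distance to the
#'   nearest protein atom, capped at 20 A), `burial` (mean number of
#'   protein atoms within 8 A of a ligand atom -- a coordination-number
#'   style pocket-burial measure), `bond_dev` (RMS deviation of ligand
#'   bond lengths from the 1.5 A bead rest length), `lig_rg` (ligand
#'   radius of gyration).
#' @export
complex_features <- function(cs, contact_cutoff = 4.5, clash_cutoff = 2.2) {
  p <- cs$protein$heavy_coords
  l <- cs$ligand_coords
  nl <- nrow(l)
  d2 <- outer(rowSums(l^2), rep(1, nrow(p))) +
    outer(rep(1, nl), rowSums(p^2)) - 2 * l %*% t(p)
  d2 <- pmax(d2, 0)
  dmin <- sqrt(apply(d2, 1, min))
  bonds <- cs$ligand_graph$bonds
  bond_dev <- if (nrow(bonds) > 0) {
    bl <- sqrt(rowSums((l[bonds[, 1], , drop = FALSE] -
                          l[bonds[, 2], , drop = FALSE])^2))
    sqrt(mean((bl - 1.5)^2))
  } else 0
  ctr <- colMeans(l)
  c(contacts_total = sum(d2 < contact_cutoff^2),
    contacts_per_atom = sum(d2 < contact_cutoff^2) / nl,
    clashes_per_atom = sum(d2 < clash_cutoff^2) / nl,
    mean_min_dist = mean(pmin(dmin, 20)),
    burial = sum(d2 < 64) / nl,
    bond_dev = bond_dev,
    lig_rg = sqrt(mean(rowSums(sweep(l, 2, ctr)^2))))
}

#' Train a ranking head (confidence or affinity)
#'
#' Least-squares fit of a scalar target on the invariant descriptors of
#' [complex_features()]. For a confidence head the conventional target
#' is negated ligand RMSD to the reference (higher = better); for an
#' affinity head, the pK-scale binding affinity.
#'
#' When `groups` is supplied (one label per structure, e.g. the system
#' each decoy pose came from), features and targets are demeaned within
#' each group before fitting -- the fixed-effects estimator. A
#' confidence head is used to rank alternative poses of one complex, so
#' only within-complex contrasts carry signal; demeaning removes the
#' between-system offsets that would otherwise dominate the fit.
#'
#' @param structures list of [complex_structure()] objects.
#' @param targets numeric target per structure.
#' @param kind `"confidence"` or `"affinity"` (label only).
#' @param groups optional grouping labels for within-group fitting.
#' @return An object of class `ranking_head`.
#' @export
train_ranking_head <- function(structures, targets,
                               kind = c("confidence", "affinity"),
                               groups = NULL) {
  kind <- match.arg(kind)
  if (length(structures) != length(targets) || length(targets) < 2) {
    stop_input("train_ranking_head: need matched structures and targets (>= 2)")
  }
  X <- t(vapply(structures, complex_features, numeric(7)))
  y <- targets
  mu_x <- colMeans(X)
  mu_y <- mean(y)
  if (!is.null(groups)) {
    if (length(groups) != length(targets)) {
      stop_input("train_ranking_head: groups length mismatch")
    }
    for (g in unique(groups)) {
      idx <- which(groups == g)
      X[idx, ] <- sweep(X[idx, , drop = FALSE], 2,
                        colMeans(X[idx, , drop = FALSE]))
      y[idx] <- y[idx] - mean(y[idx])
    }
    fit <- stats::lm(y ~ . - 1, data = data.frame(y = y, X))
  } else {
    fit <- stats::lm(y ~ ., data = data.frame(y = y, X))
  }
  coefs <- stats::coef(fit)
  coefs[is.na(coefs)] <- 0
  slopes <- coefs[colnames(X)]
  intercept <- if (is.null(groups)) {
    unname(coefs["(Intercept)"])
  } else {
    # anchor predictions at the global feature/target means
    mu_y - sum(slopes * mu_x)
  }
  structure(list(kind = kind, slopes = slopes, intercept = intercept,
                 feature_names = colnames(X)),
            class = "ranking_head")
}

head_predict <- function(head, structure) {
  stopifnot(inherits(head, "ranking_head"),
            inherits(structure, "complex_structure"))
  head$intercept + sum(head$slopes * complex_features(structure))
}

#' Predict structural confidence for a complex
#'
#' Deterministic scalar, higher = better. On synthetic data the trained
#' head's score correlates positively with negated ligand RMSD to the
#' reference pose.
#'
#' @param head a trained `"confidence"` [train_ranking_head()].
#' @param structure a [complex_structure()].
#' @return Scalar confidence.
#' @export
predict_confidence <- function(head, structure) head_predict(head, structure)

#' Predict binding affinity (pK units) for a complex
#'
#' @param head a trained `"affinity"` [train_ranking_head()].
#' @param structure a [complex_structure()].
#' @return Scalar affinity in pK units (-log10 molar).
#' @export
predict_affinity <- function(head, structure) head_predict(head, structure)

#' Regression metric report
#'
#' Pearson and Spearman correlation, RMSE, and MAE of predictions
#' against observations -- the standard affinity-regression report.
#'
#' @param predicted,observed numeric vectors of equal length.
#' @return Named list with `pearson`, `spearman`, `rmse`, `mae`, `n`.
#' @export
regression_metrics <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop_input("regression_metrics: length mismatch")
  }
  list(pearson = stats::cor(predicted, observed, method = "pearson"),
       spearman = stats::cor(predicted, observed, method = "spearman"),
       rmse = sqrt(mean((predicted - observed)^2)),
       mae = mean(abs(predicted - observed)),
       n = length(predicted))
}

#' Assemble a ranked prediction record
#'
#' @param structure a [complex_structure()] at t = 1.
#' @param confidence scalar confidence score.
#' @param affinity scalar affinity in pK units.
#' @return An object of class `ranked_prediction` (rank unset until
#'   [rank_samples()]).
#' @export
ranked_prediction <- function(structure, confidence, affinity) {
  structure(list(structure = structure, confidence = confidence,
                 affinity = affinity, rank = NA_integer_),
            class = "ranked_prediction")
}

#' Rank generated samples by confidence or affinity
#'
#' Stable sort, descending in the chosen key; ties keep the input order
#' (sample index), so equal-scoring samples stay in generation order.
#'
#' @param predictions list of [ranked_prediction()] objects.
#' @param key `"confidence"` (default) or `"affinity"`.
#' @return The same list reordered, with `rank` set to 1..n; element i of
#'   the result has rank i.
#' @export
rank_samples <- function(predictions, key = c("confidence", "affinity")) {
  key <- match.arg(key)
  if (length(predictions) == 0) stop_input("rank_samples: empty prediction list")
  scores <- vapply(predictions, function(p) as.numeric(p[[key]]), numeric(1))
  ord <- order(-scores)  # order() is stable: ties keep input order
  out <- predictions[ord]
  for (i in seq_along(out)) out[[i]]$rank <- i
  out
}

#' Ligand RMSD between two complexes
#'
#' Plain (no superposition, no symmetry correction) heavy-atom RMSD of
#' the ligand coordinates; the standard pose-accuracy measure for a
#' predicted complex against the crystal pose in a common frame.
#'
#' @param a,b [complex_structure()] objects with identical ligand size.
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(a, b) {
  if (nrow(a$ligand_coords) != nrow(b$ligand_coords)) {
    stop_input("ligand_rmsd: ligand sizes differ")
  }
  sqrt(mean(rowSums((a$ligand_coords - b$ligand_coords)^2)))
}
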