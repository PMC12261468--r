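#' Toy endpoint-field configuration
#'
#' Configures the small trainable endpoint predictor: an SE(3)-equivariant
#' message-passing model over a radius graph. Each atom carries a set of
#' geometric basis vectors (contraction to its own centroid, a softmin
#' pocket vector for ligand atoms, distance-gated neighbor means over
#' `n_layers` aggregation rounds, and a bonded-neighbor mean), and the
#' prediction is the current position plus a learned, time-embedded
#' linear combination of those vectors with separate coefficients for
#' protein and ligand atoms. Because the model is linear in its learned
#' coefficients, the endpoint loss is quadratic and gradients are exact.
#'
#' @param hidden_width number of Gaussian distance gates on the neighbor
#'   aggregation (default 4).
#' @param n_layers neighbor-aggregation rounds (default 2).
#' @param neighbor_cutoff radius-graph cutoff in Angstrom (default 10).
#' @param time_embedding_dim number of `(1 - t)^k` time features
#'   (default 3).
#' @param seed integer seed for initialization and training order.
#' @return An object of class `field_config`.
#' @export
field_config <- function(hidden_width = 4L, n_layers = 2L,
                         neighbor_cutoff = 10, time_embedding_dim = 3L,
                         seed = 1L) {
  stopifnot(hidden_width >= 1, n_layers >= 1, neighbor_cutoff > 0,
            time_embedding_dim >= 1)
  structure(
    list(hidden_width = as.integer(hidden_width),
         n_layers = as.integer(n_layers),
         neighbor_cutoff = neighbor_cutoff,
         time_embedding_dim = as.integer(time_embedding_dim),
         seed = as.integer(seed)),
    class = "field_config"
  )
}

n_basis <- function(config) 3L + config$hidden_width * config$n_layers + 1L

#' Initialize an endpoint field at zero
#'
#' At initialization all combination coefficients are zero, so the field
#' is the identity map (it predicts the current coordinates).
#'
#' @param config a [field_config()].
#' @return An object of class `endpoint_field` with coefficient array `W`
#'   of dimension `2 (atom types) x n_basis x time_embedding_dim`.
#' @export
init_field <- function(config = field_config()) {
  structure(
    list(config = config,
         W = array(0, c(2, n_basis(config), config$time_embedding_dim)),
         loss_curve = numeric(0)),
    class = "endpoint_field"
  )
}

# Geometric basis vectors for every atom: an N x 3 x K array.
# Column layout: [1] to-own-centroid, [2-3] soft-nearest-protein vectors
# (ligand only), [4 .. 3+H*Lyr] gated neighbor means, [last]
# bonded-neighbor mean.
field_basis <- function(coords, is_ligand, bonds, frag_ids, config) {
  n <- nrow(coords)
  K <- n_basis(config)
  B <- array(0, c(n, 3, K))
  prot_idx <- which(!is_ligand)
  lig_idx <- which(is_ligand)

  # 1: contraction toward own-entity centroid (fragment for ligand atoms)
  if (length(prot_idx) > 0) {
    pc <- colMeans(coords[prot_idx, , drop = FALSE])
    B[prot_idx, , 1] <- sweep(-coords[prot_idx, , drop = FALSE], 2, -pc)
  }
  for (f in unique(frag_ids)) {
    idx <- lig_idx[frag_ids == f]
    fc <- colMeans(coords[idx, , drop = FALSE])
    B[idx, , 1] <- sweep(-coords[idx, , drop = FALSE], 2, -fc)
  }

  # 2-3: per-ligand-atom soft-nearest-protein vectors at a short (2 A)
  # and a medium (6 A) scale: point toward the closest protein surface
  # (i.e. back into the pocket), with magnitude tracking the gap
  if (length(prot_idx) > 0 && length(lig_idx) > 0) {
    pm <- coords[prot_idx, , drop = FALSE]
    for (ii in seq_along(lig_idx)) {
      i <- lig_idx[ii]
      dv <- sweep(pm, 2, coords[i, ])
      di <- sqrt(rowSums(dv^2))
      for (slot in 1:2) {
        tau <- c(2, 6)[slot]
        wp <- exp(-(di - min(di)) / tau)
        wp <- wp / sum(wp)
        B[i, , 1 + slot] <- colSums(dv * wp)
      }
    }
  }

  # gated neighbor means over aggregation rounds
  d2 <- outer(rowSums(coords^2), rep(1, n)) +
    outer(rep(1, n), rowSums(coords^2)) - 2 * coords %*% t(coords)
  d <- sqrt(pmax(d2, 0))
  diag(d) <- Inf
  centers <- seq(0, config$neighbor_cutoff,
                 length.out = config$hidden_width + 1)[-1]
  width <- config$neighbor_cutoff / config$hidden_width
  col <- 4L
  layer_input <- coords
  for (lyr in seq_len(config$n_layers)) {
    agg <- matrix(0, n, 3)
    for (h in seq_len(config$hidden_width)) {
      G <- exp(-((d - centers[h]) / width)^2)
      G[d > config$neighbor_cutoff] <- 0
      denom <- rowSums(G) + 1e-8
      msg <- (G %*% layer_input) / denom - layer_input *
        (rowSums(G) / denom)
      B[, , col] <- msg
      agg <- agg + msg
      col <- col + 1L
    }
    layer_input <- layer_input + agg / config$hidden_width
  }

  # bonded-neighbor mean (ligand atoms; Laplacian smoothing direction)
  if (nrow(bonds) > 0) {
    deg <- numeric(n)
    acc <- matrix(0, n, 3)
    for (k in seq_len(nrow(bonds))) {
      i <- lig_idx[bonds[k, 1]]; j <- lig_idx[bonds[k, 2]]
      acc[i, ] <- acc[i, ] + coords[j, ] - coords[i, ]
      acc[j, ] <- acc[j, ] + coords[i, ] - coords[j, ]
      deg[i] <- deg[i] + 1; deg[j] <- deg[j] + 1
    }
    nz <- deg > 0
    B[nz, , K] <- acc[nz, , drop = FALSE] / deg[nz]
  }
  B
}

# powers (1-t)^1 .. (1-t)^k: no constant term, so the predicted
# displacement vanishes at t = 1 exactly as the CondOT endpoint target
# (x1 - xt) = (1-t)(x1 - x0) does
time_features <- function(t, config) (1 - t)^seq_len(config$time_embedding_dim)

#' Evaluate the endpoint field
#'
#' @param field an `endpoint_field`.
#' @param coords stacked (NP + NL) x 3 coordinates at time `t`.
#' @param t flow time.
#' @param is_ligand logical per-row indicator (protein rows `FALSE`).
#' @param ligand_graph the system's [ligand_graph()].
#' @return Predicted endpoint coordinates, same shape as `coords`.
#' @export
field_predict <- function(field, coords, t, is_ligand, ligand_graph) {
  stopifnot(inherits(field, "endpoint_field"))
  cfg <- field$config
  B <- field_basis(coords, is_ligand, ligand_graph$bonds,
                   ligand_graph$fragment_ids, cfg)
  phi <- time_features(t, cfg)
  type <- ifelse(is_ligand, 2L, 1L)
  coef <- matrix(0, nrow(coords), dim(B)[3])  # per-atom basis weights
  for (c_type in 1:2) {
    rows <- type == c_type
    if (any(rows)) {
      wk <- field$W[c_type, , , drop = FALSE]
      dim(wk) <- dim(field$W)[2:3]
      coef[rows, ] <- matrix(wk %*% phi, sum(rows), dim(B)[3], byrow = TRUE)
    }
  }
  delta <- matrix(0, nrow(coords), 3)
  for (k in seq_len(dim(B)[3])) delta <- delta + B[, , k] * coef[, k]
  coords + delta
}

#' Bind a field to one system as a `(coords, t)` closure
#'
#' @param field an `endpoint_field`.
#' @param template a [complex_structure()] supplying topology.
#' @return Function `(coords, t) -> coords` usable with
#'   [vd_ode_integrate()] and [euler_integrate()].
#' @export
field_closure <- function(field, template) {
  is_ligand <- c(rep(FALSE, template$protein$n_heavy),
                 rep(TRUE, template$ligand_graph$n_atoms))
  lg <- template$ligand_graph
  function(coords, t) field_predict(field, coords, t, is_ligand, lg)
}

#' Train the endpoint field by conditional flow matching
#'
#' Minimizes the endpoint loss over CondOT path samples drawn from the
#' accepted apo-holo pool with Adam. The model is linear in its
#' coefficients, so gradients are exact.
#'
#' @param pairs accepted pair pool (list of `list(apo=, holo=)`), as
#'   consumed by [sample_training_batch()].
#' @param config a [field_config()].
#' @param steps optimization steps (default 500).
#' @param batch_size path samples per step (default 4).
#' @param lr initial Adam step size (default 0.05), decayed as
#'   `lr / (1 + 2 step / steps)`; the returned coefficients are the
#'   Polyak average of the final quarter of iterates, which stabilizes
#'   the small-batch stochastic optimization.
#' @param seed training seed (defaults to `config$seed`).
#' @param verbose print the loss every 100 steps.
#' @return A trained `endpoint_field` with a recorded `loss_curve`.
#' @export
train_field <- function(pairs, config = field_config(), steps = 500,
                        batch_size = 4, lr = 0.05, seed = config$seed,
                        verbose = FALSE) {
  field <- init_field(config)
  W <- field$W
  m <- W * 0; v <- W * 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  losses <- numeric(steps)
  base_seed <- substream_seed(seed, "train")
  avg_from <- max(1, steps - floor(steps / 4) + 1)
  W_avg <- W * 0
  n_avg <- 0

  for (step in seq_len(steps)) {
    batch <- sample_training_batch(pairs, batch_size,
                                   seed = (base_seed + step) %% 2147483629)
    grad <- W * 0
    loss <- 0
    for (smp in batch) {
      lg <- pairs[[smp$pair_index]]$holo$ligand_graph
      B <- field_basis(smp$xt, smp$is_ligand, lg$bonds, lg$fragment_ids,
                       config)
      phi <- time_features(smp$t, config)
      pred <- smp$xt
      for (c_type in 1:2) {
        rows <- which((smp$is_ligand + 1L) == c_type)
        if (length(rows) == 0) next
        ck <- as.numeric(matrix(W[c_type, , ],
                                dim(W)[2], dim(W)[3]) %*% phi)
        for (k in seq_len(dim(B)[3])) {
          pred[rows, ] <- pred[rows, ] + B[rows, , k] * ck[k]
        }
      }
      r <- pred - smp$target
      n_atoms <- nrow(r)
      loss <- loss + mean(rowSums(r^2))
      for (c_type in 1:2) {
        rows <- which((smp$is_ligand + 1L) == c_type)
        if (length(rows) == 0) next
        # d loss / d W[c,k,m] = (2/N) sum_i <B[i,,k], r_i> * phi_m
        bk <- vapply(seq_len(dim(B)[3]), function(k) {
          sum(B[rows, , k] * r[rows, , drop = FALSE])
        }, numeric(1))
        grad[c_type, , ] <- grad[c_type, , ] +
          (2 / n_atoms) * outer(bk, phi)
      }
    }
    loss <- loss / length(batch)
    grad <- grad / length(batch)
    if (!is.finite(loss)) {
      stop_input("train_field: loss diverged (non-finite) at step %d", step)
    }
    losses[step] <- loss
    m <- b1 * m + (1 - b1) * grad
    v <- b2 * v + (1 - b2) * grad^2
    mh <- m / (1 - b1^step)
    vh <- v / (1 - b2^step)
    W <- W - (lr / (1 + 2 * step / steps)) * mh / (sqrt(vh) + eps)
    if (step >= avg_from) {
      W_avg <- W_avg + W
      n_avg <- n_avg + 1
    }
    if (verbose && step %% 100 == 0) {
      message(sprintf("step %5d  loss %.4f", step, loss))
    }
  }
  field$W <- W_avg / n_avg
  field$loss_curve <- losses
  field
}
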