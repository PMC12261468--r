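make_rigid_suite <- function(n, seed, heldout_fraction = 1 / 3) {
  suite <- generate_benchmark_suite(
    n, spec_ranges = list(modes = "rigid_ligand_shift"),
    seed = seed, heldout_fraction = heldout_fraction)
  systems <- lapply(seq_len(nrow(suite)), function(k)
    system_from_manifest(suite[k, ]))
  list(suite = suite, systems = systems,
       train = which(suite$split == "train"),
       heldout = which(suite$split == "heldout"))
}

prior_start <- function(sys, seed) {
  g <- sys$apo$ligand_graph
  ctr <- colMeans(sys$apo$ligand_coords)
  spec <- harmonic_prior_spec(g, matrix(ctr, max(g$fragment_ids), 3,
                                        byrow = TRUE), rng_seed = seed)
  complex_structure(sys$apo$protein, sample_harmonic(spec, 1)[[1]], g, t = 0)
}

test_that("field output keeps shape and an untrained field still integrates", {
  cs <- tiny_complex()
  field <- init_field(field_config())
  x <- complex_coords(cs)
  isl <- c(rep(FALSE, cs$protein$n_heavy), rep(TRUE, 2))
  pred <- field_predict(field, x, 0.3, isl, cs$ligand_graph)
  expect_identical(dim(pred), dim(x))
  expect_identical(pred, x)  # zero-initialized field is the identity

  traj <- vd_ode_integrate(cs, field_closure(field, cs),
                           solver_config(n_steps = 5))
  expect_length(traj$states, 6)
  expect_s3_class(trajectory_final(traj), "complex_structure")
})

test_that("training reduces the endpoint loss and moves ligands pocketward", {
  dat <- make_rigid_suite(12, seed = 61)
  pairs <- lapply(dat$systems[dat$train],
                  function(s) list(apo = s$apo, holo = s$holo))
  field <- train_field(pairs, field_config(), steps = 600, batch_size = 4,
                       seed = 3)
  init_loss <- mean(field$loss_curve[1:20])
  final_loss <- mean(tail(field$loss_curve, 50))
  expect_lt(final_loss, init_loss)
  expect_length(field$loss_curve, 600)

  # held-out transport: ligand centroid moves in the true shift direction
  cosines <- vapply(dat$heldout, function(k) {
    sys <- dat$systems[[k]]
    x0c <- prior_start(sys, seed = 400 + k)
    fin <- trajectory_final(vd_ode_integrate(x0c, field_closure(field, x0c),
                                             solver_config()))
    moved <- colMeans(fin$ligand_coords) - colMeans(x0c$ligand_coords)
    truth <- colMeans(sys$holo$ligand_coords) - colMeans(x0c$ligand_coords)
    sum(moved * truth) / sqrt(sum(moved^2) * sum(truth^2))
  }, numeric(1))
  expect_gt(median(cosines), 0.9)

  # both blocks of atoms are live outputs (flexible-receptor contract)
  sys <- dat$systems[[dat$heldout[1]]]
  x0c <- prior_start(sys, seed = 999)
  x <- complex_coords(x0c)
  isl <- c(rep(FALSE, sys$apo$protein$n_heavy),
           rep(TRUE, sys$apo$ligand_graph$n_atoms))
  pred <- field_predict(field, x, 0.1, isl, sys$apo$ligand_graph)
  expect_gt(max(abs((pred - x)[isl, ])), 0)
  expect_gt(max(abs((pred - x)[!isl, ])), 0)
})

test_that("training aborts on divergence with diagnostics", {
  cs0 <- tiny_complex(t = 0)
  cs1 <- tiny_complex(t = 1, lig_offset = c(0, 0, 1.5))
  pool <- list(list(apo = cs0, holo = cs1))
  expect_error(train_field(pool, field_config(), steps = 50,
                           lr = 1e200, seed = 1),
               "diverged")
})

test_that("confidence head ranks decoys by quality on held-out systems", {
  suite <- generate_benchmark_suite(24, seed = 71)
  systems <- lapply(seq_len(nrow(suite)), function(k)
    system_from_manifest(suite[k, ]))
  tr <- which(suite$split == "train")
  ho <- which(suite$split == "heldout")

  dec_tr <- lapply(systems[tr], sample_decoy_poses, n = 10, seed = 5)
  head <- train_ranking_head(
    do.call(c, lapply(dec_tr, `[[`, "structures")),
    -unlist(lapply(dec_tr, `[[`, "rmsd")),
    kind = "confidence",
    groups = rep(seq_along(dec_tr), each = 10))

  # the head's job is ranking alternative poses of one complex: score
  # held-out decoy sets system by system
  per_sys <- vapply(seq_along(ho), function(i) {
    d <- sample_decoy_poses(systems[[ho[i]]], n = 10, seed = 600 + i)
    sc <- vapply(d$structures, function(s) predict_confidence(head, s),
                 numeric(1))
    cor(sc, -d$rmsd, method = "spearman")
  }, numeric(1))
  expect_gt(length(per_sys) * 10, 30)
  expect_gt(mean(per_sys), 0.5)

  # duplicates score identically; scrambling a ligand lowers the score
  cs <- systems[[ho[1]]]$holo
  expect_identical(predict_confidence(head, cs), predict_confidence(head, cs))
  worse <- 0
  for (k in 1:30) {
    sys <- systems[[(k %% length(systems)) + 1]]
    set.seed(k)
    perm <- sample(nrow(sys$holo$ligand_coords))
    scr <- complex_structure(sys$holo$protein,
                             sys$holo$ligand_coords[perm, ],
                             sys$holo$ligand_graph, 1)
    if (predict_confidence(head, scr) < predict_confidence(head, sys$holo)) {
      worse <- worse + 1
    }
  }
  expect_gt(worse / 30, 0.8)
})

test_that("affinity head recovers the synthetic contact-based affinity", {
  suite <- generate_benchmark_suite(40, seed = 81)
  systems <- lapply(seq_len(nrow(suite)), function(k)
    system_from_manifest(suite[k, ]))
  tr <- which(suite$split == "train")
  ho <- which(suite$split == "heldout")
  head <- train_ranking_head(lapply(systems[tr], `[[`, "holo"),
                             vapply(systems[tr], `[[`, numeric(1),
                                    "true_affinity"),
                             kind = "affinity")
  pred <- vapply(systems[ho], function(s) predict_affinity(head, s$holo),
                 numeric(1))
  obs <- vapply(systems[ho], `[[`, numeric(1), "true_affinity")
  expect_gt(regression_metrics(pred, obs)$pearson, 0.8)

  # invariance under rigid motion of the whole complex
  cs <- systems[[ho[1]]]$holo
  ax <- c(1, 2, 2) / 3
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  R <- diag(3) + sin(1.1) * K + (1 - cos(1.1)) * K %*% K
  move <- function(m) m %*% t(R) + matrix(c(7, -4, 2), nrow(m), 3, byrow = TRUE)
  prot <- cs$protein
  prot$heavy_coords <- move(prot$heavy_coords)
  prot$ca_coords <- move(prot$ca_coords)
  moved <- complex_structure(prot, move(cs$ligand_coords), cs$ligand_graph, 1)
  expect_equal(predict_affinity(head, moved), predict_affinity(head, cs),
               tolerance = 1e-6)
})

test_that("metric reporter matches longhand formulas on a 5-point table", {
  pred <- c(5.1, 6.3, 4.2, 7.8, 5.9)
  obs <- c(5.0, 6.8, 3.9, 7.1, 6.2)
  m <- regression_metrics(pred, obs)
  o <- longhand_metrics(pred, obs)
  expect_equal(m$pearson, o$pearson, tolerance = 1e-12)
  expect_equal(m$spearman, o$spearman, tolerance = 1e-12)
  expect_equal(m$rmse, o$rmse, tolerance = 1e-12)
  expect_equal(m$mae, o$mae, tolerance = 1e-12)
  expect_equal(m$n, 5)
  expect_error(regression_metrics(pred, obs[-1]), "length mismatch")
})

test_that("rank_samples sorts stably by the chosen key", {
  cs <- tiny_complex()
  mk <- function(conf, aff) ranked_prediction(cs, conf, aff)

  r <- rank_samples(list(mk(0.2, 1), mk(0.9, 2), mk(0.5, 3)))
  expect_equal(vapply(r, `[[`, numeric(1), "confidence"), c(0.9, 0.5, 0.2))
  expect_equal(vapply(r, `[[`, integer(1), "rank"), 1:3)

  # all-equal scores preserve input order
  tie <- rank_samples(list(mk(1, 10), mk(1, 20), mk(1, 30)))
  expect_equal(vapply(tie, `[[`, numeric(1), "affinity"), c(10, 20, 30))

  # the two keys can disagree
  byc <- rank_samples(list(mk(0.9, 1), mk(0.1, 9)), key = "confidence")
  bya <- rank_samples(list(mk(0.9, 1), mk(0.1, 9)), key = "affinity")
  expect_equal(byc[[1]]$confidence, 0.9)
  expect_equal(bya[[1]]$affinity, 9)

  expect_error(rank_samples(list()), "empty")
})
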