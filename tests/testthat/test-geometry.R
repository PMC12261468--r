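test_that("graph Laplacian matches D - A on canonical graphs", {
  path3 <- ligand_graph(c("C", "C", "C"), rbind(c(1, 2), c(2, 3)))
  expect_equal(graph_laplacian(path3),
               rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)))

  expect_equal(graph_laplacian(ligand_graph("C")), matrix(0, 1, 1))

  two_frag <- ligand_graph(c("C", "C", "O", "O"),
                           rbind(c(1, 2), c(3, 4)))
  expect_equal(two_frag$fragment_ids, c(1, 1, 2, 2))
  blk <- rbind(c(1, -1), c(-1, 1))
  expect_equal(graph_laplacian(two_frag),
               rbind(cbind(blk, matrix(0, 2, 2)),
                     cbind(matrix(0, 2, 2), blk)))
})

test_that("Laplacian is PSD with one zero mode per fragment", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(2:12, 1)
    n_frag <- sample(1:min(3, n), 1)
    sizes <- diff(round(seq(0, n, length.out = n_frag + 1)))
    sizes[sizes < 1] <- 1
    bonds <- NULL
    off <- 0
    for (k in sizes) {
      if (k > 1) {
        for (a in 2:k) bonds <- rbind(bonds, c(off + sample.int(a - 1, 1), off + a))
      }
      off <- off + k
    }
    g <- ligand_graph(rep("C", sum(sizes)), bonds)
    ev <- eigen(graph_laplacian(g), symmetric = TRUE)$values
    expect_gte(min(ev), -1e-10)
    expect_equal(sum(abs(ev) < 1e-8), max(g$fragment_ids))
  }
})

test_that("ligand_graph rejects malformed inputs", {
  expect_error(ligand_graph(character(0)), "at least one atom")
  expect_error(ligand_graph(c("C", "C"), rbind(c(1, 3))), "out of range")
  expect_error(ligand_graph(c("C", "C"), rbind(c(2, 2))), "self-bond")
})

test_that("weighted Kabsch recovers exact rigid motions", {
  set.seed(7)
  x <- matrix(rnorm(30), 10, 3)

  id <- weighted_kabsch(x, x)
  expect_equal(id$rotation, diag(3), tolerance = 1e-10)
  expect_equal(id$rmsd, 0, tolerance = 1e-10)

  R90 <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))  # 90 deg about z
  y <- x %*% t(R90) + matrix(c(3, -2, 5), 10, 3, byrow = TRUE)
  fit <- weighted_kabsch(x, y)
  expect_equal(fit$rotation, R90, tolerance = 1e-10)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(fit$transform(x), y, tolerance = 1e-8)
})

test_that("weighted fit matches a brute-force axis-angle minimizer", {
  # oracle: direct minimization of the weighted objective over a
  # rotation-vector + translation parametrization
  weighted_ssd <- function(par, x, y, w) {
    theta <- sqrt(sum(par[1:3]^2))
    R <- if (theta < 1e-12) diag(3) else {
      a <- par[1:3] / theta
      K <- rbind(c(0, -a[3], a[2]), c(a[3], 0, -a[1]), c(-a[2], a[1], 0))
      diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
    }
    moved <- x %*% t(R) + matrix(par[4:6], nrow(x), 3, byrow = TRUE)
    sum(w * rowSums((moved - y)^2))
  }
  set.seed(11)
  for (rep in 1:4) {
    x <- matrix(rnorm(15), 5, 3)
    y <- matrix(rnorm(15), 5, 3)
    w <- runif(5, 0.1, 2)
    fit <- weighted_kabsch(x, y, w)
    fitted_obj <- sum(w * rowSums((fit$transform(x) - y)^2))
    oracle <- Inf
    for (start in 1:8) {
      o <- optim(c(rnorm(3), rnorm(3)), weighted_ssd, x = x, y = y, w = w,
                 method = "BFGS", control = list(maxit = 500))
      oracle <- min(oracle, o$value)
    }
    expect_lte(fitted_obj, oracle + 1e-6)
  }
})

test_that("weight concentration beats unweighted fit on the trusted points", {
  set.seed(3)
  x <- matrix(rnorm(15), 5, 3)
  motion_R <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  y <- x %*% t(motion_R) + matrix(c(1, 2, 3), 5, 3, byrow = TRUE)
  y[4:5, ] <- y[4:5, ] + matrix(rnorm(6, sd = 2), 2, 3)  # corrupt low-weight
  w <- c(1, 1, 1, 1e-6, 1e-6)
  res_w <- sum(rowSums((weighted_kabsch(x, y, w)$transform(x) - y)[1:3, ]^2))
  res_u <- sum(rowSums((weighted_kabsch(x, y)$transform(x) - y)[1:3, ]^2))
  expect_lte(res_w, res_u + 1e-12)
})

test_that("Kabsch rmsd is invariant to pre-rotation of the mobile set", {
  set.seed(19)
  x <- matrix(rnorm(24), 8, 3)
  y <- x + matrix(rnorm(24, sd = 0.3), 8, 3)
  base <- weighted_kabsch(x, y)$rmsd
  for (rep in 1:5) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, 0, pi)
    K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    x2 <- x %*% t(R) + matrix(rnorm(3), 8, 3, byrow = TRUE)
    expect_equal(weighted_kabsch(x2, y)$rmsd, base, tolerance = 1e-8)
  }
})

test_that("degenerate point sets warn but return a transform", {
  line <- cbind(1:5, 0, 0)
  expect_warning(fit <- weighted_kabsch(line, line + 1), "degenerate")
  expect_true(all(is.finite(fit$rotation)))
})

test_that("Kabsch input validation", {
  x <- matrix(rnorm(9), 3, 3)
  expect_error(weighted_kabsch(x, x[1:2, ]), "point counts differ")
  expect_error(weighted_kabsch(x[1:2, ], x[1:2, ]), "at least 3")
  expect_error(weighted_kabsch(x, x, c(1, 1, -1)), "non-negative")
  expect_error(weighted_kabsch(x, x, c(1, 1, 0)), "3 strictly positive")
})

test_that("TM-score equals the published sum and is exactly 1 on identity", {
  set.seed(5)
  a <- matrix(rnorm(150), 50, 3)
  expect_identical(tm_score(a, a), 1)

  # independent evaluation of the published formula
  b <- a + matrix(rnorm(150, sd = 2), 50, 3)
  d0 <- max(1.24 * (50 - 15)^(1 / 3) - 1.8, 0.5)
  direct <- mean(1 / (1 + rowSums((a - b)^2) / d0^2))
  expect_equal(tm_score(a, b), direct, tolerance = 1e-12)

  # far-apart chains score below 0.2 when deviations >= 10 d0
  far <- a + matrix(c(15 * d0, 0, 0), 50, 3, byrow = TRUE)
  expect_lt(tm_score(a, far), 0.2)
  expect_gt(tm_score(a, far), 0)
})

test_that("TM-score is symmetric and monotone under deviation scaling", {
  set.seed(6)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    a <- matrix(rnorm(3 * n), n, 3)
    dev <- matrix(rnorm(3 * n, sd = 0.8), n, 3)
    expect_equal(tm_score(a, a + dev), tm_score(a + dev, a, norm_length = n))
    scores <- vapply(c(0.5, 1, 2, 4, 8),
                     function(s) tm_score(a, a + s * dev), numeric(1))
    expect_true(all(diff(scores) < 0))
  }
  expect_error(tm_score(matrix(0, 3, 3), matrix(0, 4, 3)), "lengths differ")
})

test_that("ligand proximity weights follow the exponential kernel", {
  cs <- tiny_complex()
  w <- ligand_proximity_weights(cs$protein, cs$ligand_coords, scale = 4)
  expect_equal(sum(w), 1)
  expect_true(all(w > 0))

  # two-residue toy at distances 0 and 4 with scale 4: ratio e
  prot <- protein_structure("AA", rbind(c(0, 0, 0), c(4, 0, 0)))
  w2 <- ligand_proximity_weights(prot, matrix(c(0, 0, 0), 1, 3), scale = 4)
  expect_equal(w2[1] / w2[2], exp(1), tolerance = 1e-12)
  expect_equal(which.max(w2), 1L)

  # equidistant residues get uniform weights
  ring <- protein_structure("AAAA",
                            rbind(c(1, 0, 0), c(-1, 0, 0),
                                  c(0, 1, 0), c(0, -1, 0)))
  w3 <- ligand_proximity_weights(ring, matrix(0, 1, 3))
  expect_equal(w3, rep(0.25, 4))

  # weights nonincreasing in distance
  far <- protein_structure("AAA", rbind(c(1, 0, 0), c(5, 0, 0), c(9, 0, 0)))
  w4 <- ligand_proximity_weights(far, matrix(0, 1, 3))
  expect_true(all(diff(w4) < 0))
})
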