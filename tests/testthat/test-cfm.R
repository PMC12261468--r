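test_that("CondOT interpolation is exact linear blending", {
  x0 <- matrix(c(0, 0, 0), 1, 3)
  x1 <- matrix(c(2, 4, 6), 1, 3)
  expect_identical(condot_interpolate(x0, x1, 0), x0)
  expect_identical(condot_interpolate(x0, x1, 1), x1)
  expect_equal(condot_interpolate(x0, x1, 0.25),
               matrix(c(0.5, 1, 1.5), 1, 3))
  expect_error(condot_interpolate(x0, matrix(0, 2, 3), 0.5), "shapes differ")
  expect_error(condot_interpolate(x0, x1, 1.5), "in \\[0, 1\\]")
})

test_that("endpoint loss is the mean squared per-atom deviation", {
  set.seed(2)
  x1 <- matrix(rnorm(15), 5, 3)
  expect_identical(cfm_endpoint_loss(x1, x1), 0)

  shifted <- x1 + matrix(c(1, 0, 0), 5, 3, byrow = TRUE)
  expect_equal(cfm_endpoint_loss(shifted, x1), 1)

  # masking removes an atom's contribution entirely
  bad <- x1
  bad[3, ] <- bad[3, ] + 1e6
  mask <- rep(TRUE, 5); mask[3] <- FALSE
  expect_equal(cfm_endpoint_loss(bad, x1, mask),
               cfm_endpoint_loss(x1[-3, ], x1[-3, , drop = FALSE]))
  expect_error(cfm_endpoint_loss(x1, x1, rep(FALSE, 5)), "empty mask")
})

test_that("endpoint loss is frame-dependent by contract", {
  set.seed(4)
  pred <- matrix(rnorm(12), 4, 3)
  x1 <- matrix(rnorm(12), 4, 3)
  shift <- matrix(c(5, -3, 2), 4, 3, byrow = TRUE)
  expect_equal(cfm_endpoint_loss(pred + shift, x1 + shift),
               cfm_endpoint_loss(pred, x1))
  expect_false(isTRUE(all.equal(cfm_endpoint_loss(pred + shift, x1),
                                cfm_endpoint_loss(pred, x1))))
})

test_that("coupling decision applies the quoted inequality semantics", {
  th <- coupling_thresholds()  # c_tm = 0.7, c_rmsd = 5

  d <- coupling_decide(0.9, 5.0, 100, 10, th)
  expect_false(d$accepted); expect_equal(d$reject_reason, "rmsd_above")

  d <- coupling_decide(0.9, 4.999999, 100, 10, th)
  expect_true(d$accepted)

  d <- coupling_decide(0.7, 3, 100, 10, th)   # tm == c_tm is kept
  expect_true(d$accepted)

  d <- coupling_decide(0.699999, 3, 100, 10, th)
  expect_false(d$accepted); expect_equal(d$reject_reason, "tm_below")

  d <- coupling_decide(1, 0, 5, 10, th)       # too short a protein
  expect_false(d$accepted); expect_equal(d$reject_reason, "length")
  expect_equal(coupling_decide(1, 0, 100, 500, th)$reject_reason, "length")
})

test_that("filter accepts identical pairs and rejects calibrated deformations", {
  sys <- generate_system(toy_system_spec(n_residues = 50,
                                         deformation_scale = 0, seed = 8))
  d <- apo_holo_filter(sys$apo, sys$holo)
  expect_true(d$accepted)
  expect_equal(d$tm, 1)
  expect_equal(d$rmsd, 0, tolerance = 1e-9)

  base <- generate_system(toy_system_spec(n_residues = 80, seed = 15))
  heavy <- deform_to_similarity(base, 0.6, 3)
  expect_lt(heavy$tm, 0.7)
  dh <- apo_holo_filter(heavy$apo, heavy$holo)
  expect_false(dh$accepted)
  expect_equal(dh$reject_reason, "tm_below")

  wrong <- tiny_complex(n_res = 8)
  expect_error(apo_holo_filter(tiny_complex(n_res = 6), wrong),
               "residue counts differ")
})

test_that("filter acceptance is monotone in the thresholds", {
  base <- generate_system(toy_system_spec(n_residues = 60, seed = 23))
  pairs <- list(deform_to_similarity(base, 0.75, 3),
                deform_to_similarity(base, 0.65, 4),
                deform_to_similarity(base, 0.9, 5.5))
  for (p in pairs) {
    for (c_tm in c(0.9, 0.7, 0.5)) {
      for (c_rmsd in c(2, 5, 8)) {
        strict <- apo_holo_filter(p$apo, p$holo,
                                  coupling_thresholds(c_tm, c_rmsd))
        loose <- apo_holo_filter(p$apo, p$holo,
                                 coupling_thresholds(c_tm - 0.1, c_rmsd + 1))
        if (strict$accepted) expect_true(loose$accepted)
      }
    }
  }
})

test_that("training batches have uniform t and bit-exact interpolation", {
  cs0 <- tiny_complex(t = 0)
  cs1 <- tiny_complex(t = 1, lig_offset = c(0, 0, 1.5))
  pool <- list(list(apo = cs0, holo = cs1))

  b <- sample_training_batch(pool, 4, seed = 31)
  expect_length(b, 4)
  ts <- vapply(b, `[[`, numeric(1), "t")
  expect_equal(length(unique(ts)), 4)
  for (smp in b) {
    expect_identical(smp$xt, (1 - smp$t) * smp$x0 + smp$t * smp$x1)
    expect_identical(smp$target, smp$x1)
    expect_identical(dim(smp$x0), dim(smp$x1))
  }

  big <- sample_training_batch(pool, 10000, seed = 77)
  tbar <- mean(vapply(big, `[[`, numeric(1), "t"))
  expect_gte(tbar, 0.49); expect_lte(tbar, 0.51)

  expect_error(sample_training_batch(list(), 4), "empty accepted pool")
})

test_that("filter_pairs tabulates decisions over a pool", {
  base <- generate_system(toy_system_spec(n_residues = 60, seed = 40))
  pairs <- list(
    list(apo = base$apo, holo = base$holo),
    local({p <- deform_to_similarity(base, 0.5, 4); list(apo = p$apo, holo = p$holo)})
  )
  tab <- filter_pairs(pairs)
  expect_equal(nrow(tab), 2)
  expect_true(tab$accepted[1])
  expect_false(tab$accepted[2])
  expect_equal(tab$reason[2], "tm_below")
  expect_identical(filter_pairs(pairs), tab)  # deterministic
})
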