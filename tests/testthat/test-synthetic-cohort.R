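test_that("generated connectomes are symmetric integer graphs with flagged candidates", {
  cn <- generate_connectome(471, density = 0.1, candidate_frontal = 9,
                            candidate_parietal = 8, seed = 1)
  expect_equal(dim(cn$weights), c(471, 471))
  expect_identical(cn$weights, t(cn$weights))
  expect_true(all(cn$weights >= 0))
  expect_true(all(cn$weights == round(cn$weights)))
  expect_true(all(diag(cn$weights) == 0))
  expect_length(cn$candidate_frontal, 9)
  expect_length(cn$candidate_parietal, 8)
  expect_length(intersect(cn$candidate_frontal, cn$candidate_parietal), 0)

  full <- generate_connectome(5, density = 1, candidate_frontal = 1,
                              candidate_parietal = 1, seed = 2)
  off <- full$weights[upper.tri(full$weights)]
  expect_true(all(off > 0))
  expect_true(all(diag(full$weights) == 0))
})

test_that("connectome generation is a pure function of its seed", {
  a <- generate_connectome(60, density = 0.2, seed = 99)
  b <- generate_connectome(60, density = 0.2, seed = 99)
  expect_identical(a, b)
  c <- generate_connectome(60, density = 0.2, seed = 100)
  expect_false(identical(a$weights, c$weights))
})

test_that("degenerate connectome requests are rejected", {
  expect_error(generate_connectome(1), "at least 2")
  expect_error(generate_connectome(20, candidate_frontal = 0), "non-empty")
  expect_error(generate_connectome(5, candidate_frontal = 3,
                                   candidate_parietal = 3), "too small")
  expect_error(generate_connectome(20, density = 0), "density")
})

test_that("synthetic anatomy satisfies its geometric invariants", {
  an <- generate_anatomy(scalp_radius_mm = 95, cortex_radius_mm = 80,
                         n_sulci = 20, seed = 5)
  r_scalp <- sqrt(rowSums(an$scalp_mesh$vertices^2))
  expect_true(all(abs(r_scalp - 95) < 1e-9))
  expect_true(all(abs(sqrt(rowSums(an$scalp_mesh$normals^2)) - 1) < 1e-9))
  # scalp strictly encloses cortex for the concentric-sphere generator
  expect_true(max(sqrt(rowSums(an$cortex_mesh$vertices^2))) <
                min(r_scalp))
  # sulcal normals are unit length and near-tangential
  sn <- an$sulcal_points$normals
  sp <- an$sulcal_points$positions
  expect_true(all(abs(sqrt(rowSums(sn^2)) - 1) < 1e-9))
  radial <- sp / sqrt(rowSums(sp^2))
  expect_true(all(abs(rowSums(sn * radial)) <= 0.5))
  # affine is invertible and round-trips
  aff <- an$mni_to_native_affine
  expect_true(max(abs(solve(aff) %*% aff - diag(4))) < 1e-9)
  expect_error(generate_anatomy(scalp_radius_mm = 70, cortex_radius_mm = 80),
               "scalp_radius")
})

test_that("observer accuracy is monotone in set size and hits the curve midpoint", {
  ob <- observer_model(threshold_s0 = 6, slope_k = 1.2, lapse = 0,
                       task_shift = c(DRAT = 0, DRMT = 0))
  p <- predicted_accuracy(ob, 1:12)
  expect_true(all(diff(p) <= 0))
  # at s = s0 with gamma = 0.5 and no lapse, accuracy is 0.75
  expect_equal(predicted_accuracy(ob, 6), 0.75)
  # small set sizes approach the lapse-free ceiling
  expect_gt(predicted_accuracy(ob, 1), 0.99)
  expect_error(observer_model(guess_gamma = 1), "guess_gamma")
  expect_error(observer_model(lapse = 0.5), "lapse")
})

test_that("injected stimulation effects shift empirical accuracy by the stated amount", {
  em <- data.frame(target = "DLPFC", task = "DRAT", stimulation = "active",
                   shift = 0.05)
  ob <- observer_model(threshold_s0 = 6, effect_map = em)
  n <- 10000
  withr::with_seed(11, {
    active <- simulate_response(ob, rep(6, n), task = "DRAT",
                                target = "DLPFC", stimulation = "active")
    sham <- simulate_response(ob, rep(6, n), task = "DRAT",
                              target = "DLPFC", stimulation = "sham")
  })
  diff <- mean(active$correct) - mean(sham$correct)
  expect_true(abs(diff - 0.05) < 0.01)
  expect_true(all(active$rt_ms >= 200))
})

test_that("the coil field is exactly linear in drive and decays with distance", {
  fm <- field_model()
  withr::with_seed(3, {
    for (i in 1:5) {
      pose <- list(center_mm = rnorm(3, sd = 50))
      x <- matrix(rnorm(30, sd = 40), ncol = 3)
      d1 <- runif(1, 10, 60)
      d2 <- runif(1, 10, 60)
      e1 <- fm$magnitude(x, pose, d1)
      e2 <- fm$magnitude(x, pose, d2)
      expect_equal(e2 / e1, rep(d2 / d1, nrow(x)))
    }
  })
  pose <- list(center_mm = c(0, 0, 0))
  near <- fm$magnitude(matrix(c(0, 0, 10), 1), pose, 50)
  far <- fm$magnitude(matrix(c(0, 0, 40), 1), pose, 50)
  expect_gt(near, far)
})

test_that("synthetic BOLD carries the designed signal and only the noise varies with seed", {
  rois <- make_candidate_rois(n_frontal = 2, n_parietal = 2)
  des <- block_design(2, 60, data.frame(
    condition = rep(c("DRAT", "DRMT"), 3),
    onset_s = seq(6, 106, by = 20), duration_s = 12
  ))
  b1 <- generate_activation(rois$rois, active_labels = 1, effect_size = 2,
                            design = des, seed = 1)
  b2 <- generate_activation(rois$rois, active_labels = 1, effect_size = 2,
                            design = des, seed = 2)
  expect_false(identical(b1$data, b2$data))
  # noise differs but the signal component is shared: the difference of the
  # two datasets has zero design-locked structure
  x <- build_design_matrix(des)
  beta_diff <- qr.coef(qr(x), b1$data - b2$data)
  expect_lt(max(abs(colMeans(t(beta_diff))[1:2])), 0.2)
  expect_error(generate_activation(rois$rois, active_labels = 99,
                                   effect_size = 1, design = des),
               "active_labels")
})

test_that("subject bundles are reproducible from (id, seed)", {
  a <- generate_subject("sub-007", cohort = 2, seed = 123)
  b <- generate_subject("sub-007", cohort = 2, seed = 123)
  expect_identical(a$connectome, b$connectome)
  expect_identical(a$rmt_pct_mso, b$rmt_pct_mso)
  expect_identical(a$observer$threshold_s0, b$observer$threshold_s0)
  expect_true(a$rmt_pct_mso > 0 && a$rmt_pct_mso <= 100)
  expect_gte(a$hair_mm, 0)
})
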