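# registration tests run at small grid sizes to stay fast; capture-range
# checks with more seeds live in test-acceptance.R

test_that("ssd is the plain sum of squared differences", {
  g <- unit_grid(c(2, 1, 1))
  a <- binary_volume(array(c(1L, 0L), c(2, 1, 1)), g)
  b <- binary_volume(array(c(0L, 1L), c(2, 1, 1)), g)
  expect_equal(ssd(a, a), 0)
  expect_equal(ssd(a, b), 2)
  v <- random_blob(c(6, 6, 6))
  w <- v
  w$data[2, 2, 2] <- 1L - w$data[2, 2, 2]
  expect_equal(ssd(v, w), 1)
  b2 <- ball_volume(c(6, 6, 6), 2, spacing = c(2, 1, 1))
  expect_error(ssd(v, b2), "frame")
})

test_that("parameter vectors have the printed dimensionalities", {
  expect_equal(n_free_params(rigid_params()), 6)
  expect_equal(n_free_params(similarity_params()), 7)
  expect_equal(n_free_params(affine_params()), 12)
})

test_that("registering a shape to itself recovers the identity", {
  b <- ball_volume(c(20, 20, 20), 5)
  # make it asymmetric so the optimum is unique
  b$data[13:16, 9:12, 9:12] <- 1L
  rr <- register(b, b, "rigid")
  expect_true(rr$converged)
  expect_true(all(abs(rr$params$angles) < 1e-2))
  expect_true(all(abs(rr$params$translation) < 1e-2))
})

test_that("known translations and homothety are recovered", {
  set.seed(33)
  # 1.5 mm voxels: the mm translation is a whole number of voxels, so the
  # nearest-neighbour-resampled ground truth is unambiguous
  b <- ball_volume(c(24, 24, 24), 7.5, spacing = c(1.5, 1.5, 1.5))
  b$data[16:18, 11:14, 11:14] <- 1L
  truth <- rigid_params(c(0, 0, 0), c(3.0, -4.5, 1.5))
  fixed <- apply_known_transform(b, truth)
  rr <- register(b, fixed, "rigid")
  # within 0.5 voxel = 0.75 mm per axis
  expect_true(all(abs(rr$params$translation - truth$translation) < 0.75))
  sm <- apply_known_transform(b, similarity_params(k_h = 1.2))
  rs <- register(b, sm, "similarity")
  expect_lt(abs(rs$params$k_h - 1.2), 0.05)
})

test_that("energy never increases versus the identity transform", {
  set.seed(5)
  pair <- replicate(2, random_blob(c(14, 14, 14), frac = 0.2),
                    simplify = FALSE)
  for (m in c("rigid", "similarity", "affine")) {
    rr <- register(pair[[1]], pair[[2]], m)
    expect_lte(rr$final_ssd, rr$initial_ssd)
    expect_equal(n_free_params(rr$params),
                 c(rigid = 6, similarity = 7, affine = 12)[[m]])
  }
})

test_that("registering an empty shape is a content error", {
  g <- unit_grid(c(6, 6, 6))
  e <- binary_volume(array(0L, c(6, 6, 6)), g)
  b <- ball_volume(c(6, 6, 6), 2)
  expect_error(register(e, b, "rigid"), "empty")
  expect_error(register_demons(b, e), "empty")
})

test_that("demons on identical inputs is numerically the identity field", {
  b <- ball_volume(c(16, 16, 16), 5)
  dr <- register_demons(b, b, reg_opts(iterations = 10))
  mag <- sqrt(dr$field$ux^2 + dr$field$uy^2 + dr$field$uz^2)
  expect_lt(max(mag), 0.1) # voxel units = mm here
})

test_that("zero demons iterations give the identity field", {
  b <- ball_volume(c(12, 12, 12), 4)
  w <- ball_volume(c(12, 12, 12), 3)
  dr <- register_demons(w, b, reg_opts(iterations = 0))
  expect_equal(max(abs(dr$field$ux)), 0)
  expect_equal(dr$result$final_ssd, dr$result$initial_ssd)
})

test_that("demons warps nested balls onto each other", {
  fixedb <- ball_volume(c(24, 24, 24), 8)
  moving <- ball_volume(c(24, 24, 24), 5)
  dr <- register_demons(moving, fixedb)
  warped <- apply_params(moving, dr$field)
  expect_gte(dice(warped, fixedb), 0.95)
  expect_lte(dr$result$final_ssd, dr$result$initial_ssd)
})

test_that("select_reference averages SSD and breaks ties by lowest index", {
  dg <- degenerate_sample(3, dims = c(12, 12, 12), r = 4)
  sel <- select_reference(dg, "rigid", reg_opts(maxit = 60))
  expect_equal(sel$index, 1L)
  expect_true(all(is.na(diag(sel$ssd_matrix))))
  # single shape
  s1 <- select_reference(dg[1], "rigid")
  expect_equal(s1$index, 1L)
  # two similar balls plus one heavily warped: reference among the balls
  set.seed(9)
  sp <- population_spec(n_cases = 1,
                        grid = volume_grid(c(24, 24, 24),
                                           spacing = c(1.5, 1.5, 1.5)),
                        base_radius = 7, lobe_count = 4, pose_sd = c(0, 0),
                        scale_sd = 0, affine_sd = 0, warp_amp = 4,
                        warp_smoothness = 6, seed = 21)
  warped <- make_population(sp)[[1]]
  b <- ball_volume(c(24, 24, 24), 5, spacing = c(1.5, 1.5, 1.5))
  sel3 <- select_reference(list(b, b, warped), "rigid", reg_opts(maxit = 60))
  expect_true(sel3$index %in% c(1L, 2L))
})

test_that("coregistration re-overlaps rigidly displaced shapes", {
  set.seed(17)
  b <- ball_volume(c(24, 24, 24), 5)
  b$data[16:18, 11:13, 11:13] <- 1L
  sample3 <- list(
    b,
    apply_known_transform(b, rigid_params(c(0, 0, 0), c(2, 1, -1.5))),
    apply_known_transform(b, rigid_params(c(0.1, 0, 0), c(-1.5, 2, 0))))
  co <- coregister_sample(sample3, "rigid", reference = 1)
  expect_identical(co$aligned[[1]]$data, b$data)
  prs <- combn(3, 2)
  dices <- apply(prs, 2, function(ij)
    dice(co$aligned[[ij[1]]], co$aligned[[ij[2]]]))
  expect_gte(mean(dices), 0.9)
})

test_that("identical shapes coregister to themselves", {
  dg <- degenerate_sample(3, dims = c(12, 12, 12), r = 4)
  co <- coregister_sample(dg, "rigid", reference = 1, reg_opts(maxit = 80))
  for (v in co$aligned)
    expect_gte(dice(v, dg[[1]]), 0.98)
})
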