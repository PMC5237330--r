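test_that("equatorial landmarks of a ball sit on the analytic circle", {
  b <- ball_volume(c(24, 24, 24), 8)
  ls <- extract_semilandmarks(b, slices_per_axis = c(0, 0, 1), counts = 4L)
  expect_equal(nrow(ls$points), 4)
  ctr <- (c(24, 24, 24) - 1) / 2
  r <- sqrt(rowSums((ls$points[, 1:2] - matrix(ctr[1:2], 4, 2,
                                               byrow = TRUE))^2))
  expect_true(all(abs(r - 8) <= 1)) # within one voxel of the circle
  ang <- sort(atan2(ls$points[, 2] - ctr[2], ls$points[, 1] - ctr[1]))
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  expect_true(all(abs(gaps - pi / 2) < 0.2)) # ~90 degree spacing
})

test_that("landmark extraction is deterministic and layout is shared", {
  set.seed(3)
  sp <- population_spec(n_cases = 2,
                        grid = volume_grid(c(24, 24, 24),
                                           spacing = c(1.5, 1.5, 1.5)),
                        base_radius = 8, pose_sd = c(0.05, 1), scale_sd = 0.03,
                        affine_sd = 0, warp_amp = 1, warp_smoothness = 8,
                        seed = 4)
  pop <- make_population(sp)
  l1 <- extract_semilandmarks(pop[[1]], c(4, 4, 4))
  l2 <- extract_semilandmarks(pop[[1]], c(4, 4, 4))
  expect_identical(l1$points, l2$points)
  sets <- landmark_population(pop, c(4, 4, 4))
  expect_identical(sets[[1]]$layout, sets[[2]]$layout)
})

test_that("fit_shape_model has PCA's structure", {
  set.seed(8)
  mk <- function(pts) structure(
    list(points = pts, layout = data.frame(axis = 1L, slice = 1L,
                                           npts = nrow(pts))),
    class = "landmark_set")
  pts <- matrix(rnorm(30), 10, 3)
  # identical sets: zero variance
  m0 <- fit_shape_model(list(mk(pts), mk(pts), mk(pts)))
  expect_equal(m0$mean, as.vector(t(pts)))
  expect_true(all(m0$eigenvalues <= 1e-10))
  # two sets: mean is the midpoint, single mode along the difference
  pts2 <- pts + matrix(rnorm(30, sd = 0.5), 10, 3)
  m2 <- fit_shape_model(list(mk(pts), mk(pts2)))
  expect_equal(m2$mean, as.vector(t((pts + pts2) / 2)))
  expect_equal(length(m2$eigenvalues), 1)
  dirv <- as.vector(t(pts2 - pts))
  align <- abs(sum(m2$modes[, 1] * dirv / sqrt(sum(dirv^2))))
  expect_equal(align, 1, tolerance = 1e-8)
  # full-rank reconstruction
  sets <- lapply(1:5, function(i) mk(pts + matrix(rnorm(30), 10, 3)))
  mf <- fit_shape_model(sets)
  X <- do.call(rbind, lapply(sets, function(s) as.vector(t(s$points))))
  for (i in 1:5) {
    ctrd <- X[i, ] - mf$mean
    rec <- mf$mean + mf$modes %*% (t(mf$modes) %*% ctrd)
    expect_lt(max(abs(rec - X[i, ])), 1e-6)
  }
  # orthonormal modes, ordered eigenvalues
  gram <- t(mf$modes) %*% mf$modes
  expect_lt(max(abs(gram - diag(ncol(mf$modes)))), 1e-8)
  expect_true(all(diff(mf$eigenvalues) <= 1e-12))
  # layout mismatch
  bad <- mk(pts[1:5, ])
  expect_error(fit_shape_model(list(mk(pts), bad)), "layout")
})

test_that("viscous reconstruction fills a ball from its centre", {
  dims <- c(26, 26, 26)
  ball <- ball_volume(dims, 9)
  seed <- array(0L, dims); seed[13, 13, 13] <- 1L
  seedv <- binary_volume(seed, ball$grid)
  rec <- viscous_reconstruction(ball, seedv, opening_radius = 1)
  expect_true(all(rec$data <= ball$data)) # never exceeds the constraint
  expect_lte(abs(sum(rec$data) - sum(ball$data)) / sum(ball$data), 0.15)
  # underestimation direction
  expect_lte(sum(rec$data), sum(ball$data))
})

test_that("viscous reconstruction degenerate cases", {
  dims <- c(16, 16, 16)
  ball <- ball_volume(dims, 4)
  # constraint = seed: the growth is trapped between the opened seed and
  # the constraint, and reaches its fixpoint at once
  rec <- viscous_reconstruction(ball, ball, opening_radius = 1,
                                max_iters = 5)
  opened <- shapeatlas:::open_vox(ball$data, dims, 1)
  expect_true(all(opened <= rec$data))
  expect_true(all(rec$data <= ball$data))
  rec50 <- viscous_reconstruction(ball, ball, opening_radius = 1,
                                  max_iters = 50)
  expect_identical(rec50$data, rec$data) # fixpoint reached early
  # max_iters = 0: opened (pre-dilated) seed only
  rec0 <- viscous_reconstruction(ball, ball, opening_radius = 1,
                                 max_iters = 0)
  expect_identical(rec0$data, opened)
  emptyv <- binary_volume(array(0L, dims), ball$grid)
  expect_error(viscous_reconstruction(ball, emptyv), "empty")
})

test_that("statistical atlas on near-degenerate balls recovers the ball", {
  # radius 10 voxels: the reconstruction's half-voxel boundary bias is
  # small relative to the shape at this resolution
  dims <- c(32, 32, 32)
  b <- ball_volume(dims, 10)
  sta <- statistical_atlas(list(b, b, b), slices_per_axis = c(6, 6, 6))
  expect_gte(dice(sta$atlas, b), 0.9)
  # sandwich: inner <= atlas <= outer
  expect_true(all(sta$inner$data <= sta$atlas$data))
  expect_true(all(sta$atlas$data <= sta$outer$data))
})

test_that("statistical atlas is permutation invariant and sandwiched", {
  set.seed(6)
  sp <- population_spec(n_cases = 3,
                        grid = volume_grid(c(32, 32, 32),
                                           spacing = c(1.5, 1.5, 1.5)),
                        base_radius = 10, pose_sd = c(0.05, 1.5),
                        scale_sd = 0.04, affine_sd = 0, warp_amp = 1.5,
                        warp_smoothness = 8, seed = 31)
  pop <- make_population(sp)
  s1 <- statistical_atlas(pop, slices_per_axis = c(6, 6, 6))
  s2 <- statistical_atlas(pop[c(2, 3, 1)], slices_per_axis = c(6, 6, 6))
  expect_identical(s1$atlas$data, s2$atlas$data)
  expect_true(all(s1$inner$data <= s1$atlas$data))
  expect_true(all(s1$atlas$data <= s1$outer$data))
})
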