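test_that("tricube kernel matches its closed form", {
  expect_equal(tricube(0), 70 / 81)
  expect_equal(tricube(1), 0)
  expect_equal(tricube(-1), 0)
  expect_equal(tricube(0.5), (70 / 81) * (7 / 8)^3)
  expect_equal(tricube(2), 0)
  expect_true(all(tricube(seq(-2, 2, by = 0.1)) >= 0))
})

test_that("local_weights composes distance with the kernel", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 3, 0))
  w <- local_weights(c(0, 0, 0), pts, h = 2)
  expect_equal(w[1], 70 / 81)
  expect_equal(w[2], tricube(0.5))
  expect_equal(w[3], 0) # at distance >= h
  expect_equal(local_weights(c(9, 9, 9), pts, h = 1), c(0, 0, 0))
})

test_that("glm_config validates its fields", {
  expect_error(glm_config(span = 0), "span")
  expect_error(glm_config(bandwidth = -1), "bandwidth")
  expect_error(glm_config(order = 3), "order")
  expect_error(glm_config(eps = 0.7), "eps")
})

# 1-D lattice of distance values with Bernoulli coverage drawn from a known
# logistic curve; returns the dstar volume and indicator volumes
logistic_lattice <- function(beta0, beta1, n_shapes, L = 81, step = 0.25) {
  g <- volume_grid(c(L, 1, 1))
  d <- (seq_len(L) - (L + 1) / 2) * step
  dst <- distance_volume(array(d, c(L, 1, 1)), g)
  p <- stats::plogis(beta0 + beta1 * d)
  ind <- lapply(seq_len(n_shapes), function(i)
    binary_volume(array(stats::rbinom(L, 1, p), c(L, 1, 1)), g))
  list(dstar = dst, indicators = ind, d = d, p = p)
}

test_that("local logistic fit recovers a generating curve", {
  set.seed(77)
  lat <- logistic_lattice(beta0 = 0.5, beta1 = -0.9, n_shapes = 400)
  cfg <- glm_config(bandwidth = 1e6, band_halfwidth = 1e6)
  fit <- fit_local_logistic(c(10, 0, 0), lat$dstar, lat$indicators, cfg)
  expect_true(fit$converged)
  expect_lt(abs(fit$beta[1] - 0.5) / 0.5, 0.1)
  expect_lt(abs(fit$beta[2] - (-0.9)) / 0.9, 0.1)
  expect_lt(fit$beta[2], 0) # sign consistency: coverage decreasing in d*
})

test_that("pure-label neighbourhoods short-circuit to the eps clamps", {
  dg <- degenerate_sample(4, dims = c(12, 12, 12), r = 4)
  dst <- mean_distance(dg)
  cfg <- glm_config(bandwidth = 2)
  centre <- c(5.5, 5.5, 5.5) # deep inside all shapes
  fit <- fit_local_logistic(centre, dst, dg, cfg)
  expect_equal(fit$prob, 1 - cfg$eps)
  # a corner sees only background-pure band points with a wider kernel
  corner <- c(0, 0, 0)
  fit2 <- fit_local_logistic(corner, dst, dg, glm_config(bandwidth = 4))
  expect_equal(fit2$prob, cfg$eps)
  # no grid points inside the kernel support is a domain error
  expect_error(fit_local_logistic(corner, dst, dg, glm_config(bandwidth = 2)),
               "kernel support")
})

test_that("exact fit agrees with a generic optimizer on the same loglik", {
  set.seed(55)
  g <- unit_grid(c(8, 8, 8))
  sample3 <- replicate(3, random_blob(c(8, 8, 8), frac = 0.4),
                       simplify = FALSE)
  dst <- mean_distance(sample3)
  cfg <- glm_config(bandwidth = 4, band_halfwidth = 3)
  x0 <- c(3, 3, 3)
  fit <- fit_local_logistic(x0, dst, sample3, cfg)
  expect_false(anyNA(fit$beta)) # must not short-circuit for this fixture
  # independent route: generic Nelder-Mead on the weighted loglikelihood
  bp <- shapeatlas:::band_points(dst, 3)
  d2 <- colSums((t(bp$pts) - x0)^2)
  w <- tricube(sqrt(d2) / 4)
  keep <- w > 0
  cov <- Reduce(`+`, lapply(sample3, function(v) v$data[bp$sel][keep]))
  negll <- function(b) {
    mu <- stats::plogis(b[1] + b[2] * bp$d[keep])
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    -sum(w[keep] * (cov * log(mu) + (3 - cov) * log(1 - mu)))
  }
  ref <- stats::optim(c(0, 0), negll, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  ref <- stats::optim(ref$par, negll, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  expect_lt(max(abs(fit$beta - ref$par)), 1e-4)
})

test_that("binned band engine matches exact per-voxel fits on a small grid", {
  set.seed(91)
  sample4 <- replicate(4, random_blob(c(10, 10, 10), frac = 0.35),
                       simplify = FALSE)
  cfg <- glm_config(bandwidth = 3.5, band_halfwidth = 2.5, nbins = 2048)
  atlas <- glm_atlas(sample4, cfg)
  dst <- mean_distance(sample4)
  sel <- which(abs(dst$data) <= 2.5)
  idx <- arrayInd(sel, dim(dst$data))
  worst <- 0
  for (r in sample(seq_along(sel), 25)) {
    x0 <- (idx[r, ] - 1) * 1.0
    fit <- fit_local_logistic(x0, dst, sample4, cfg)
    worst <- max(worst, abs(fit$prob - atlas$data[sel[r]]))
  }
  expect_lt(worst, 1e-3)
})

test_that("glm_atlas output lies in [0,1] and is permutation invariant", {
  set.seed(23)
  sample3 <- replicate(3, random_blob(c(10, 10, 10), frac = 0.35),
                       simplify = FALSE)
  a1 <- glm_atlas(sample3, glm_config(bandwidth = 3))
  a2 <- glm_atlas(sample3[c(3, 1, 2)], glm_config(bandwidth = 3))
  expect_true(all(a1$data >= 0 & a1$data <= 1))
  expect_equal(a1$data, a2$data)
})

test_that("degenerate sample: 0.5-threshold recovers the shape, IProb high", {
  dg <- degenerate_sample(4, dims = c(16, 16, 16), r = 5)
  atlas <- glm_atlas(dg)
  rec <- threshold_atlas(atlas, 0.5)
  # recovery up to a one-voxel boundary band
  bnd <- signed_distance(dg[[1]])$data
  core <- bnd < -1.01
  outside <- bnd > 1.01
  expect_true(all(rec$data[core] == 1L))
  expect_true(all(rec$data[outside] == 0L))
  expect_gte(iprob(atlas, dg[[1]]), 0.98)
})

test_that("the band shortcut changes nothing beyond eps", {
  set.seed(41)
  sample3 <- replicate(3, random_blob(c(9, 9, 9), frac = 0.35),
                       simplify = FALSE)
  cfgs <- list(narrow = glm_config(bandwidth = 3, band_halfwidth = 2.5),
               wide = glm_config(bandwidth = 3, band_halfwidth = 100))
  a_nar <- glm_atlas(sample3, cfgs$narrow)
  a_wid <- glm_atlas(sample3, cfgs$wide)
  dst <- mean_distance(sample3)
  off_band <- abs(dst$data) > 2.5
  # outside the narrow band the wide computation must sit at the clamps
  expect_lt(max(abs(a_nar$data[off_band] - a_wid$data[off_band])), 0.05)
})

test_that("glm atlas is smoother than the NCF atlas", {
  set.seed(63)
  sp <- population_spec(n_cases = 5,
                        grid = volume_grid(c(24, 24, 24),
                                           spacing = c(1.5, 1.5, 1.5)),
                        base_radius = 8, pose_sd = c(0, 2), scale_sd = 0.05,
                        affine_sd = 0, warp_amp = 2, warp_smoothness = 8,
                        seed = 13)
  pop <- make_population(sp)
  tv <- function(a) {
    sum(abs(diff(a))) + sum(abs(aperm(apply(a, c(1, 3), diff)))) +
      sum(abs(apply(a, c(1, 2), diff)))
  }
  expect_lte(tv(glm_atlas(pop)$data), tv(ncf_atlas(pop)$data))
})

test_that("glm probabilities are monotone along d* on monotone data", {
  set.seed(29)
  sp <- population_spec(n_cases = 6,
                        grid = volume_grid(c(24, 24, 24),
                                           spacing = c(1.5, 1.5, 1.5)),
                        base_radius = 8, pose_sd = c(0, 1.5), scale_sd = 0.04,
                        affine_sd = 0, warp_amp = 1.5, warp_smoothness = 8,
                        seed = 19)
  pop <- make_population(sp)
  atlas <- glm_atlas(pop)
  dst <- mean_distance(pop)
  h <- attr(atlas, "diagnostics")$mean_bandwidth
  sel <- sample(length(dst$data), 4000)
  da <- dst$data[sel]; pa <- atlas$data[sel]
  ord <- order(da)
  da <- da[ord]; pa <- pa[ord]
  # pairs separated by more than the bandwidth must be ordered
  lo <- pa[da < min(da) + 1]
  hi <- pa[da > max(da) - 1]
  expect_true(min(lo) >= max(hi))
})
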