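test_that("dice and jaccard match direct counts and their identity", {
  g <- unit_grid(c(10, 1, 1))
  A <- binary_volume(array(c(rep(1L, 4), rep(0L, 6)), c(10, 1, 1)), g)
  B <- binary_volume(array(c(0L, rep(1L, 6), rep(0L, 3)), c(10, 1, 1)), g)
  # |A|=4, |B|=6, |A&B|=3, |A|B|=7
  expect_equal(dice(A, B), 0.6)
  expect_equal(jaccard(A, B), 3 / 7)
  expect_equal(dice(A, A), 1)
  expect_equal(jaccard(B, B), 1)
  disj <- binary_volume(array(c(rep(0L, 8), 1L, 1L), c(10, 1, 1)), g)
  expect_equal(dice(A, disj), 0)
  empty <- binary_volume(array(0L, c(10, 1, 1)), g)
  expect_error(dice(empty, empty), "empty")
  expect_error(jaccard(empty, empty), "empty")
  set.seed(2)
  for (i in 1:10) {
    v <- random_blob(c(8, 8, 8)); w <- random_blob(c(8, 8, 8))
    dc <- dice(v, w); jc <- jaccard(v, w)
    expect_lte(jc, dc)
    expect_equal(jc, dc / (2 - dc), tolerance = 1e-12)
  }
})

test_that("hausdorff matches the two-point case and brute force", {
  g <- unit_grid(c(8, 8, 8))
  a <- array(0L, c(8, 8, 8)); a[2, 2, 2] <- 1L
  b <- array(0L, c(8, 8, 8)); b[5, 2, 2] <- 1L
  A <- binary_volume(a, g); B <- binary_volume(b, g)
  expect_equal(hausdorff(A, B), 3)
  expect_equal(hausdorff(A, A), 0)
  empty <- binary_volume(array(0L, c(8, 8, 8)), g)
  expect_error(hausdorff(A, empty), "empty")
  set.seed(14)
  for (i in 1:10) {
    sp <- runif(3, 0.8, 1.8)
    v <- random_blob(c(8, 8, 8), spacing = sp)
    w <- random_blob(c(8, 8, 8), spacing = sp)
    expect_equal(hausdorff(v, w), brute_hausdorff(v, w), tolerance = 1e-12)
  }
})

test_that("hausdorff and 1-jaccard behave as metrics on random triples", {
  set.seed(27)
  for (i in 1:6) {
    v <- random_blob(c(8, 8, 8)); w <- random_blob(c(8, 8, 8))
    u <- random_blob(c(8, 8, 8))
    expect_equal(hausdorff(v, w), hausdorff(w, v))
    expect_lte(hausdorff(v, u), hausdorff(v, w) + hausdorff(w, u) + 1e-12)
    dj <- function(a, b) 1 - jaccard(a, b)
    expect_lte(dj(v, u), dj(v, w) + dj(w, u) + 1e-12)
  }
})

test_that("iprob extremes, zero point and antisymmetry", {
  S <- ball_volume(c(12, 12, 12), 4)
  g <- S$grid
  indS <- probability_volume(array(as.double(S$data), c(12, 12, 12)), g)
  expect_equal(iprob(indS, S), 1)
  half <- probability_volume(array(0.5, c(12, 12, 12)), g)
  expect_equal(iprob(half, S), 0)
  comp <- probability_volume(array(1 - as.double(S$data), c(12, 12, 12)), g)
  expect_equal(iprob(comp, S), -1)
  set.seed(19)
  for (i in 1:6) {
    P <- probability_volume(array(runif(12^3), c(12, 12, 12)), g)
    Pc <- probability_volume(1 - P$data, g)
    expect_equal(iprob(P, S) + iprob(Pc, S), 0, tolerance = 1e-12)
    expect_gte(iprob(P, S), -1)
    expect_lte(iprob(P, S), 1)
  }
  expect_error(iprob(half, binary_volume(array(0L, c(12, 12, 12)), g)),
               "undefined")
  expect_error(iprob(half, binary_volume(array(1L, c(12, 12, 12)), g)),
               "undefined")
})

test_that("best_threshold_eval optimizes per measure with the tie rule", {
  S <- ball_volume(c(12, 12, 12), 4)
  g <- S$grid
  indS <- probability_volume(array(as.double(S$data), c(12, 12, 12)), g)
  bt <- best_threshold_eval(indS, S)
  expect_equal(bt$value[bt$measure == "dice"], 1)
  expect_equal(bt$value[bt$measure == "hausdorff"], 0)
  expect_equal(bt$threshold, c(0, 0, 0)) # ties resolved to the lowest t
  # NCF of a 2-shape sample vs one of them: exhaustive over both levels
  set.seed(10)
  v <- random_blob(c(10, 10, 10)); w <- random_blob(c(10, 10, 10))
  P <- ncf_atlas(list(v, w))
  bt2 <- best_threshold_eval(P, v)
  union_shape <- threshold_atlas(P, 0)
  inter_shape <- threshold_atlas(P, 0.5)
  cand <- c(dice(union_shape, v),
            if (sum(inter_shape$data) > 0) dice(inter_shape, v))
  expect_equal(bt2$value[bt2$measure == "dice"], max(cand))
})

test_that("paired t tests match the closed form and handle degeneracy", {
  rec <- function(method, vals) data.frame(
    case_id = seq_along(vals), method = method, dice = vals,
    jaccard = vals, hausdorff = 1 - vals, iprob = vals)
  x <- c(0.7, 0.8, 0.75, 0.9)
  y <- c(0.6, 0.85, 0.7, 0.8)
  cm <- compare_methods(rbind(rec("A", x), rec("B", y)), adjust = "none")
  d <- x - y
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  got <- cm$tests[cm$tests$measure == "dice", ]
  expect_equal(got$statistic, t_manual, tolerance = 1e-10)
  # identical per-case values: t = 0, p = 1, no flag
  cm2 <- compare_methods(rbind(rec("A", x), rec("B", x)))
  expect_true(all(cm2$tests$statistic == 0))
  expect_true(all(cm2$tests$p == 1))
  expect_false(any(cm2$tests$significant))
})

test_that("the 3x4 method grid yields 12 labels and 66 paired tests", {
  set.seed(3)
  methods <- as.vector(outer(c("NCF", "GLM", "STA"),
                             c("R", "TRS", "A", "D"), paste, sep = "-"))
  records <- do.call(rbind, lapply(methods, function(m) {
    data.frame(case_id = 1:5, method = m, dice = runif(5),
               jaccard = runif(5), hausdorff = runif(5), iprob = runif(5))
  }))
  cm <- compare_methods(records)
  expect_equal(cm$n_methods, 12)
  expect_equal(cm$n_pairs, 66)
  expect_equal(nrow(cm$tests), 66 * 4)
  expect_true(all(cm$tests$p >= 0 & cm$tests$p <= 1))
  expect_true(all(cm$tests$p_adjusted >= cm$tests$p - 1e-12))
})

test_that("leave-one-out on a degenerate population is ideal and honest", {
  dg <- degenerate_sample(3, dims = c(16, 16, 16), r = 5)
  rec <- leave_one_out(dg, patient_ids = c("p1", "p2", "p3"), "NCF", "rigid",
                       reference = 1, opts = reg_opts(maxit = 80))
  expect_equal(nrow(rec), 3)
  expect_true(all(rec$dice == 1))
  expect_true(all(rec$iprob >= 0.99))
  expect_true(all(rec$method == "NCF-R"))
})

test_that("the held-out patient's explorations never enter the atlas", {
  # two explorations for one patient: distinguishable shapes let us audit
  # the exclusion by value
  g <- volume_grid(c(16, 16, 16))
  b1 <- ball_volume(c(16, 16, 16), 5)
  b2 <- ball_volume(c(16, 16, 16), 4)
  b3 <- ball_volume(c(16, 16, 16), 3)
  sample4 <- list(b1, b1, b2, b3)
  ids <- c("p1", "p1", "p2", "p3")
  rec <- leave_one_out(sample4, ids, "NCF", "rigid", reference = 1,
                       opts = reg_opts(maxit = 40))
  # for case 1 (patient p1) the atlas is built from b2, b3 only: its
  # support must not exceed the union of b2 and b3
  atlas_support <- threshold_atlas(ncf_atlas(list(b2, b3)), 0)
  expect_lt(rec$dice[1], 1) # b1 is not its own atlas
  expect_equal(rec$dice[1], dice(atlas_support, b1))
})

test_that("STA records carry no iprob and no thresholds", {
  dims <- c(24, 24, 24)
  b <- ball_volume(dims, 8, spacing = c(1.5, 1.5, 1.5))
  rec <- leave_one_out(list(b, b, b), c("a", "b", "c"), "STA", "rigid",
                       reference = 1, opts = reg_opts(maxit = 40),
                       sta_args = list(slices_per_axis = c(6, 6, 6)))
  expect_true(all(is.na(rec$iprob)))
  expect_true(all(is.na(rec$threshold_dice)))
  expect_true(all(rec$dice > 0.8))
})
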