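# Morphological helpers on the voxel lattice (voxel units, EDT-based;
# outside the window counts as background for dilation and as foreground
# for erosion, so structures may hug the window faces).

dilate_vox <- function(mask, dims, r) {
  if (r <= 0) return(mask)
  d <- .edt_cpp(as.integer(mask), dims, c(1, 1, 1))
  array(as.integer(d <= r), dim = dims)
}

erode_vox <- function(mask, dims, r) {
  if (r <= 0) return(mask)
  d <- .edt_cpp(as.integer(mask == 0L), dims, c(1, 1, 1))
  array(as.integer(mask != 0L & d > r), dim = dims)
}

open_vox <- function(mask, dims, r) {
  dilate_vox(erode_vox(mask, dims, r), dims, r)
}

#' Viscous morphological reconstruction
#'
#' Grows a shape from a seed inside an allowed region by iterating
#' \{dilate by 1 voxel; open with a ball of `opening_radius` voxels;
#' intersect with the allowed region\} until a fixpoint (or `max_iters`).
#' The opening prunes thin tendrils, so the growth cannot leak through
#' narrow gaps in the allowed region — which is what lets a sparse landmark
#' shell act as a barrier. The result never exceeds the allowed region and
#' tends to underestimate the enclosed shape slightly (the front stops about
#' one opening radius short inside gaps).
#'
#' The seed is first dilated by `opening_radius + 1` voxels (clipped to the
#' allowed region) so that a single-voxel seed survives the opening;
#' `max_iters = 0` returns the opened initial seed.
#'
#' @param marker a [binary_volume()]: the allowed region the growth may
#'   occupy.
#' @param seed a non-empty [binary_volume()]: where the growth starts.
#' @param opening_radius ball radius (voxels) of the opening.
#' @param max_iters iteration cap.
#' @return A [binary_volume()].
#' @export
viscous_reconstruction <- function(marker, seed, opening_radius = 2,
                                   max_iters = 200) {
  assert_common_frame(list(marker, seed))
  if (sum(seed$data) == 0L) stop("seed is empty", call. = FALSE)
  dims <- marker$grid$dims
  allowed <- marker$data
  x <- dilate_vox(seed$data, dims, opening_radius + 1) * allowed
  x <- open_vox(x, dims, opening_radius) * allowed
  if (max_iters > 0) {
    for (it in seq_len(max_iters)) {
      nxt <- dilate_vox(x, dims, 1)
      nxt <- open_vox(nxt, dims, opening_radius)
      nxt <- nxt * allowed
      if (identical(nxt, x)) break
      x <- nxt
    }
  }
  binary_volume(x, marker$grid)
}

#' Ordered semi-landmarks of a binary shape
#'
#' Slices the shape along each axis at equal fractions of its own bounding
#' extent (so slice placement is normalized to the shape's length, width and
#' height), finds per slice the longest closed boundary contour of the
#' shape, and samples it at equal arclength fractions. Traversal is
#' deterministic: the start point is the contour vertex with the smallest
#' second (then first) in-slice coordinate, and orientation is
#' counter-clockwise in the in-slice plane, so the i-th landmark of every
#' case in a population corresponds to a geometrically equivalent point.
#'
#' The number of points of each slice is `max(3, round(density * L))` with
#' `L` the contour length; in a population the counts must be shared, so
#' [landmark_population()] derives them from the population-mean contour
#' lengths and passes them through `counts`.
#'
#' @param shape a non-empty [binary_volume()].
#' @param slices_per_axis integer triple: slices along x, y, z.
#' @param density landmarks per mm of contour length; `NULL` (default)
#'   resolves to one landmark per voxel of contour (`1/min(spacing)`), which
#'   keeps the rasterized shell watertight with respect to the opening ball
#'   at any resolution.
#' @param counts optional integer vector of per-slice point counts (layout
#'   contract across a population); `NULL` derives counts from this shape
#'   alone.
#' @return A `landmark_set`: `points` (P x 3 mm), `layout` (data frame with
#'   axis, slice, npts) and the slicing settings.
#' @export
extract_semilandmarks <- function(shape, slices_per_axis = c(8, 8, 8),
                                  density = NULL, counts = NULL) {
  if (is.null(density)) density <- 1 / min(shape$grid$spacing)
  cont <- slice_contours(shape, slices_per_axis)
  if (length(cont) == 0L)
    stop("shape produced no closed slice contours (too thin for slicing)",
         call. = FALSE)
  lens <- vapply(cont, function(cc) cc$length, 0)
  if (is.null(counts)) counts <- pmax(3L, as.integer(round(density * lens)))
  if (length(counts) != length(cont))
    stop("counts length does not match the slice layout", call. = FALSE)
  pts <- do.call(rbind, lapply(seq_along(cont), function(i)
    sample_contour(cont[[i]], counts[i])))
  layout <- data.frame(
    axis = vapply(cont, function(cc) cc$axis, 0L),
    slice = vapply(cont, function(cc) cc$slice, 0L),
    npts = as.integer(counts))
  structure(list(points = pts, layout = layout,
                 slices_per_axis = as.integer(slices_per_axis),
                 density = density),
            class = "landmark_set")
}

# closed boundary contours per slice: for each axis and slice fraction,
# the longest closed 0.5-level curve of the in-slice mask
slice_contours <- function(shape, slices_per_axis) {
  stopifnot(inherits(shape, "binary_volume"))
  if (sum(shape$data) == 0L) stop("shape is empty", call. = FALSE)
  g <- shape$grid
  ax <- grid_axes(g)
  out <- list()
  for (a in 1:3) {
    m <- slices_per_axis[a]
    if (m < 1) next
    idx <- which(apply(shape$data, a, sum) > 0)
    lo <- min(idx); hi <- max(idx)
    others <- setdiff(1:3, a)
    for (s in seq_len(m)) {
      frac <- (s - 0.5) / m
      plane <- lo + round(frac * (hi - lo))
      slab <- switch(a,
                     shape$data[plane, , ],
                     shape$data[, plane, ],
                     shape$data[, , plane])
      cl <- grDevices::contourLines(x = ax[[others[1]]], y = ax[[others[2]]],
                                    z = slab + 0, levels = 0.5)
      cl <- Filter(function(cc) {
        closed <- abs(cc$x[1] - cc$x[length(cc$x)]) < 1e-9 &&
          abs(cc$y[1] - cc$y[length(cc$y)]) < 1e-9
        closed && length(cc$x) >= 4
      }, cl)
      if (length(cl) == 0L) next
      lens <- vapply(cl, function(cc)
        sum(sqrt(diff(cc$x)^2 + diff(cc$y)^2)), 0)
      best <- cl[[which.max(lens)]]
      out[[length(out) + 1L]] <- list(
        axis = a, slice = s, u = best$x, v = best$y,
        w = ax[[a]][plane], length = max(lens))
    }
  }
  out
}

# equal-arclength samples of a closed contour, deterministic start and
# counter-clockwise traversal; returns npts x 3 physical points
sample_contour <- function(cc, npts) {
  u <- cc$u; v <- cc$v
  # drop the duplicated closing vertex, orient CCW (shoelace > 0)
  u <- u[-length(u)]; v <- v[-length(v)]
  area2 <- sum(u * c(v[-1], v[1]) - c(u[-1], u[1]) * v)
  if (area2 < 0) {
    u <- rev(u); v <- rev(v)
  }
  # start at smallest (v, then u)
  st <- order(v, u)[1]
  if (st > 1) {
    u <- c(u[st:length(u)], u[seq_len(st - 1)])
    v <- c(v[st:length(v)], v[seq_len(st - 1)])
  }
  uu <- c(u, u[1]); vv <- c(v, v[1])
  seg <- sqrt(diff(uu)^2 + diff(vv)^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  targets <- (seq_len(npts) - 1) / npts * total
  iu <- stats::approx(s, uu, xout = targets, rule = 2)$y
  iv <- stats::approx(s, vv, xout = targets, rule = 2)$y
  others <- setdiff(1:3, cc$axis)
  pts <- matrix(0, npts, 3)
  pts[, others[1]] <- iu
  pts[, others[2]] <- iv
  pts[, cc$axis] <- cc$w
  pts
}

#' Semi-landmarks for a whole population
#'
#' Extracts per-case contours, derives the shared per-slice point counts
#' from the population-mean contour lengths (`max(3, round(density *
#' mean_L))`), and returns landmark sets with identical layout for every
#' case. Errors if the cases disagree on which slices produced contours.
#'
#' @param shapes list of [binary_volume()]s on a common frame.
#' @inheritParams extract_semilandmarks
#' @return List of `landmark_set`s with identical layout.
#' @export
landmark_population <- function(shapes, slices_per_axis = c(8, 8, 8),
                                density = NULL) {
  assert_common_frame(shapes)
  if (is.null(density)) density <- 1 / min(shapes[[1]]$grid$spacing)
  conts <- lapply(shapes, slice_contours, slices_per_axis = slices_per_axis)
  key <- function(cont) vapply(cont, function(cc)
    paste(cc$axis, cc$slice), "")
  k0 <- key(conts[[1]])
  for (i in seq_along(conts))
    if (!identical(key(conts[[i]]), k0))
      stop("case ", i, " produced a different slice layout; adjust ",
           "slices_per_axis", call. = FALSE)
  lens <- sapply(conts, function(cont) vapply(cont, function(cc) cc$length, 0))
  mean_len <- if (is.matrix(lens)) rowMeans(lens) else mean(lens)
  counts <- pmax(3L, as.integer(round(density * mean_len)))
  lapply(shapes, extract_semilandmarks, slices_per_axis = slices_per_axis,
         density = density, counts = counts)
}

#' Fit a PCA shape model to landmark sets
#'
#' Stacks each case's landmark coordinates into one vector, averages them
#' into the mean shape, and extracts orthonormal modes of variation and
#' eigenvalues from the covariance by singular value decomposition.
#'
#' @param sets list of >= 2 `landmark_set`s with identical layout.
#' @return A `shape_model`: `mean` (coordinate vector), `modes` (columns,
#'   orthonormal), `eigenvalues` (non-increasing), `layout`.
#' @export
fit_shape_model <- function(sets) {
  if (length(sets) < 2L) stop("need >= 2 landmark sets", call. = FALSE)
  lay0 <- sets[[1]]$layout
  for (i in seq_along(sets))
    if (!identical(sets[[i]]$layout, lay0))
      stop("landmark set ", i, " has a different layout", call. = FALSE)
  X <- do.call(rbind, lapply(sets, function(s) as.vector(t(s$points))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  keep <- sv$d > 1e-12 * max(sv$d, 1e-300)
  structure(list(mean = mu,
                 modes = sv$v[, keep, drop = FALSE],
                 eigenvalues = sv$d[keep]^2 / (nrow(X) - 1),
                 layout = lay0),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("<shape_model> %d landmarks, %d modes; leading eigenvalues %s\n",
              length(x$mean) / 3, length(x$eigenvalues),
              paste(signif(utils::head(x$eigenvalues, 3), 3), collapse = ", ")))
  invisible(x)
}

# coordinate vector -> P x 3 matrix
model_mean_points <- function(model) {
  matrix(model$mean, ncol = 3, byrow = TRUE)
}

#' Statistical (landmark/PCA) atlas
#'
#' Builds the comparison statistical atlas: ordered semi-landmarks for every
#' case, a PCA shape model, and a binary mean shape reconstructed from the
#' mean landmarks. The mean landmarks are rasterized and dilated by 1 voxel
#' into a barrier shell; viscous reconstruction is run twice in the shell's
#' complement — from an inner seed (the voxel nearest the landmark
#' centroid) and from an outer seed (a window corner), the latter inverted —
#' and the final atlas is the Baddeley-Molchanov mean of the inner and
#' outer (inverted) reconstructions, which it is sandwiched between.
#'
#' @param aligned list of >= 2 coregistered [binary_volume()]s.
#' @param slices_per_axis,density see [extract_semilandmarks()].
#' @param opening_radius,max_iters see [viscous_reconstruction()].
#' @return A list with `atlas` (a [binary_volume()]), `model` (the
#'   `shape_model`), `landmarks` (per-case sets), `inner`, `outer`
#'   (the two reconstructions; `outer` is already inverted).
#' @export
statistical_atlas <- function(aligned, slices_per_axis = c(8, 8, 8),
                              density = NULL, opening_radius = 2,
                              max_iters = 200) {
  assert_common_frame(aligned)
  if (length(aligned) < 2L) stop("need >= 2 shapes", call. = FALSE)
  g <- aligned[[1]]$grid
  sets <- landmark_population(aligned, slices_per_axis, density)
  model <- fit_shape_model(sets)
  mp <- model_mean_points(model)
  # rasterize the mean landmarks into a barrier shell
  idx <- round(sweep(sweep(mp, 2, g$origin), 2, g$spacing, `/`)) + 1
  idx <- pmin(pmax(idx, 1), matrix(g$dims, nrow(idx), 3, byrow = TRUE))
  shell <- array(0L, dim = g$dims)
  shell[idx] <- 1L
  shell <- dilate_vox(shell, g$dims, 1)
  allowed <- binary_volume(1L - shell, g)
  # inner seed: allowed voxel nearest the landmark centroid
  cvox <- round((colMeans(mp) - g$origin) / g$spacing) + 1
  cvox <- pmin(pmax(cvox, 1), g$dims)
  seed_in <- array(0L, dim = g$dims)
  seed_in[cvox[1], cvox[2], cvox[3]] <- 1L
  if (shell[cvox[1], cvox[2], cvox[3]] == 1L)
    stop("landmark centroid falls on the barrier shell; increase grid ",
         "resolution", call. = FALSE)
  inner <- viscous_reconstruction(allowed, binary_volume(seed_in, g),
                                  opening_radius, max_iters)
  seed_out <- array(0L, dim = g$dims)
  seed_out[1, 1, 1] <- 1L
  grown_out <- viscous_reconstruction(allowed, binary_volume(seed_out, g),
                                      opening_radius, max_iters)
  outer <- binary_volume(1L - grown_out$data, g)
  atlas <- mean_shape_bm(list(inner, outer))
  list(atlas = atlas, model = model, landmarks = sets, inner = inner,
       outer = outer)
}
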