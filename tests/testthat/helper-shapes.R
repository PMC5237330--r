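# Shared fixture builders and brute-force oracles. Everything is generated
# in code; no binary fixtures.

unit_grid <- function(dims, spacing = c(1, 1, 1)) {
  volume_grid(dims, spacing = spacing)
}

# digital ball of radius r (physical units) centred in the grid
ball_volume <- function(dims, r, spacing = c(1, 1, 1), center = NULL) {
  g <- volume_grid(dims, spacing = spacing)
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) * spacing[a])
  if (is.null(center)) center <- (dims - 1) / 2 * spacing
  X <- array(ax[[1]], dim = dims)
  Y <- array(rep(ax[[2]], each = dims[1]), dim = dims)
  Z <- array(rep(ax[[3]], each = dims[1] * dims[2]), dim = dims)
  d2 <- (X - center[1])^2 + (Y - center[2])^2 + (Z - center[3])^2
  binary_volume(array(as.integer(d2 <= r^2), dim = dims), g)
}

# random non-empty, non-full blob: thresholded smoothed noise
random_blob <- function(dims, spacing = c(1, 1, 1), frac = 0.3) {
  g <- volume_grid(dims, spacing = spacing)
  repeat {
    noise <- array(stats::rnorm(prod(dims)), dim = dims)
    sm <- array(shapeatlas:::.gauss_smooth_cpp(noise, as.integer(dims),
                                               c(1.5, 1.5, 1.5)), dim = dims)
    occ <- array(as.integer(sm > stats::quantile(sm, 1 - frac)), dim = dims)
    n <- sum(occ)
    if (n > 0 && n < prod(dims)) return(binary_volume(occ, g))
  }
}

voxel_centers_mm <- function(vol) {
  idx <- which(vol$data >= 0, arr.ind = TRUE) # all voxels, in array order
  t(t(idx - 1) * vol$grid$spacing + vol$grid$origin)
}

# O(N^2) brute-force signed distance (voxel-centre convention)
brute_signed_distance <- function(vol) {
  g <- vol$grid
  pts <- voxel_centers_mm(vol)
  fg <- vol$data == 1L
  fg_pts <- pts[as.vector(fg), , drop = FALSE]
  bg_pts <- pts[!as.vector(fg), , drop = FALSE]
  mindist <- function(from, to) {
    apply(from, 1, function(p)
      sqrt(min(colSums((t(to) - p)^2))))
  }
  out <- numeric(nrow(pts))
  out[as.vector(fg)] <- -mindist(fg_pts, bg_pts)
  out[!as.vector(fg)] <- mindist(bg_pts, fg_pts)
  array(out, dim = g$dims)
}

# O(|A||B|) brute-force Hausdorff between voxel sets
brute_hausdorff <- function(A, B) {
  pa <- voxel_centers_mm(A)[as.vector(A$data == 1L), , drop = FALSE]
  pb <- voxel_centers_mm(B)[as.vector(B$data == 1L), , drop = FALSE]
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * pa %*% t(pb)
  dmat <- sqrt(pmax(d2, 0))
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

# small degenerate population (identical copies)
degenerate_sample <- function(n, dims = c(16, 16, 16), r = 5) {
  v <- ball_volume(dims, r)
  replicate(n, v, simplify = FALSE)
}

# strongly asymmetric ellipsoid-plus-bumps blob: every rotation axis and
# affine direction is identifiable, for registration-recovery tests
ellipsoid_blob <- function(dims, semi_axes, bump1, bump2) {
  g <- volume_grid(dims)
  c0 <- (dims - 1) / 2
  X <- array(0:(dims[1] - 1), dim = dims)
  Y <- array(rep(0:(dims[2] - 1), each = dims[1]), dim = dims)
  Z <- array(rep(0:(dims[3] - 1), each = dims[1] * dims[2]), dim = dims)
  q <- ((X - c0[1]) / semi_axes[1])^2 + ((Y - c0[2]) / semi_axes[2])^2 +
    ((Z - c0[3]) / semi_axes[3])^2
  occ <- q <= 1
  for (b in list(bump1, bump2))
    occ[((X - c0[1] - b[1])^2 + (Y - c0[2] - b[2])^2 +
         (Z - c0[3] - b[3])^2) <= b[4]^2] <- TRUE
  binary_volume(array(as.integer(occ), dims), g)
}

# geodesic angle (degrees) between two Z.Y.X-composed rotations
rotation_geodesic_deg <- function(a1, a2) {
  Rd <- shapeatlas:::rotation_matrix_zyx(a1) %*%
    t(shapeatlas:::rotation_matrix_zyx(a2))
  acos(pmin(pmax((sum(diag(Rd)) - 1) / 2, -1), 1)) * 180 / pi
}
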