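#' Signed Euclidean distance to a binary shape
#'
#' Exact two-sided voxel-centre distance transform, spacing-aware (mm):
#' background voxels get the positive Euclidean distance to the nearest
#' foreground voxel centre, foreground voxels the negative distance to the
#' nearest background voxel centre. On a voxel lattice no voxel is exactly
#' "the boundary": the zero level lives between voxel layers, so foreground
#' voxels adjacent to background get `-min(spacing)` and no voxel gets
#' exactly 0.
#'
#' @param shape a non-empty, non-full [binary_volume()].
#' @return A [distance_volume()] on the same grid.
#' @export
signed_distance <- function(shape) {
  stopifnot(inherits(shape, "binary_volume"))
  nfg <- sum(shape$data)
  if (nfg == 0L) stop("signed distance undefined: shape is empty",
                      call. = FALSE)
  if (nfg == length(shape$data))
    stop("signed distance undefined: shape fills the whole window",
         call. = FALSE)
  g <- shape$grid
  d <- .signed_distance_cpp(shape$data, g$dims, g$spacing)
  distance_volume(array(d, dim = g$dims), g)
}

# unsigned distance (mm by default; voxel units with spacing = c(1,1,1)),
# Inf everywhere when the mask is empty
distance_to_set <- function(mask, dims, spacing) {
  array(.edt_cpp(mask, dims, spacing), dim = dims)
}

#' Normalized coverage function (NCF) atlas
#'
#' The classical probabilistic atlas: per voxel, the fraction of sample
#' shapes covering it, `p(x) = (1/n) * sum_i 1_{phi_i}(x)`. Values lie on
#' the lattice `{0, 1/n, ..., 1}`; the estimate at each voxel uses only the
#' data at that voxel.
#'
#' @param aligned non-empty list of coregistered [binary_volume()]s on one
#'   common frame.
#' @return A [probability_volume()].
#' @export
ncf_atlas <- function(aligned) {
  assert_common_frame(aligned)
  n <- length(aligned)
  acc <- Reduce(`+`, lapply(aligned, function(v) as.double(v$data)))
  g <- aligned[[1]]$grid
  probability_volume(array(acc / n, dim = g$dims), g)
}

#' Mean signed distance function
#'
#' The per-voxel average of the sample shapes' signed distance functions,
#' `d*(x) = (1/n) * sum_i d_{phi_i}(x)`. Smooth in space, and the basis of
#' both the GLM atlas predictor and the Baddeley-Molchanov mean shape.
#'
#' @inheritParams ncf_atlas
#' @return A [distance_volume()].
#' @export
mean_distance <- function(aligned) {
  assert_common_frame(aligned)
  acc <- Reduce(`+`, lapply(aligned, function(v) signed_distance(v)$data))
  g <- aligned[[1]]$grid
  distance_volume(acc / length(aligned), g)
}

#' Baddeley-Molchanov mean shape
#'
#' The mean signed distance function thresholded at 0 (voxel is foreground
#' iff `d*(x) < 0`); a smooth notion of the sample's mean shape.
#'
#' @inheritParams ncf_atlas
#' @return A [binary_volume()].
#' @export
mean_shape_bm <- function(aligned) {
  d <- mean_distance(aligned)
  binary_volume(array(as.integer(d$data < 0), dim = d$grid$dims), d$grid)
}
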