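#' Voxel grid geometry
#'
#' A `volume_grid` records the geometry shared by all volume types: the number
#' of voxels per axis, the physical voxel spacing in millimetres and the
#' physical position (mm) of the centre of voxel `(1,1,1)`. The physical
#' position of voxel `(i,j,k)` (1-based R indices) is
#' `origin + (i-1, j-1, k-1) * spacing`, i.e. voxel-centre convention. Two
#' grids are *compatible* iff `dims`, `spacing` and `origin` agree
#' element-wise; all multi-volume operations in the package require
#' compatible grids and refuse to resample.
#'
#' @param dims integer vector of length 3, voxels per axis (all >= 1).
#' @param spacing numeric vector of length 3, mm per voxel (all > 0).
#' @param origin numeric vector of length 3, mm position of the first voxel
#'   centre. Defaults to `c(0,0,0)`.
#' @return An object of class `volume_grid`.
#' @examples
#' g <- volume_grid(c(64, 64, 64), spacing = c(1.46, 1.46, 1.5))
#' @export
volume_grid <- function(dims, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(dims) != 3L || anyNA(dims) || any(dims < 1L))
    stop("`dims` must be 3 integers >= 1", call. = FALSE)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop("`spacing` must be 3 positive reals (mm)", call. = FALSE)
  if (length(origin) != 3L || anyNA(origin))
    stop("`origin` must be 3 finite reals (mm)", call. = FALSE)
  structure(list(dims = dims, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %dx%dx%d voxels, spacing %.4gx%.4gx%.4g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @rdname volume_grid
#' @param a,b two `volume_grid` objects.
#' @export
grids_compatible <- function(a, b) {
  identical(a$dims, b$dims) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-9))
}

# Physical mm volume of one voxel.
voxel_volume <- function(grid) prod(grid$spacing)

# Physical coordinates (mm) of voxel centres along each axis.
grid_axes <- function(grid) {
  lapply(1:3, function(a)
    grid$origin[a] + (seq_len(grid$dims[a]) - 1) * grid$spacing[a])
}

new_volume <- function(data, grid, class) {
  stopifnot(inherits(grid, "volume_grid"))
  data <- as.array(data)
  if (length(dim(data)) != 3L || !all(dim(data) == grid$dims))
    stop("data dimensions do not match grid dims", call. = FALSE)
  structure(list(grid = grid, data = data),
            class = c(class, "shape_volume"))
}

#' Volume containers
#'
#' Three thin containers couple a 3D array with its [volume_grid()]:
#' `binary_volume` holds a `{0,1}` occupancy mask (one realization of a random
#' compact set), `probability_volume` holds per-voxel probabilities in
#' `[0,1]` (an atlas), and `distance_volume` holds a signed distance in mm
#' (negative inside the shape, positive outside).
#'
#' @param data numeric/logical/integer 3D array matching `grid$dims`.
#' @param grid a [volume_grid()].
#' @return The corresponding volume object; all inherit class `shape_volume`.
#' @seealso [signed_distance()], [ncf_atlas()], [threshold_atlas()]
#' @export
binary_volume <- function(data, grid) {
  data <- as.array(data)
  storage.mode(data) <- "integer"
  if (anyNA(data) || !all(data == 0L | data == 1L))
    stop("binary_volume occupancy must be strictly 0/1", call. = FALSE)
  new_volume(data, grid, "binary_volume")
}

#' @rdname binary_volume
#' @export
probability_volume <- function(data, grid) {
  data <- as.array(data)
  storage.mode(data) <- "double"
  if (anyNA(data) || any(data < 0) || any(data > 1))
    stop("probability_volume values must lie in [0,1]", call. = FALSE)
  new_volume(data, grid, "probability_volume")
}

#' @rdname binary_volume
#' @export
distance_volume <- function(data, grid) {
  data <- as.array(data)
  storage.mode(data) <- "double"
  if (anyNA(data) || any(!is.finite(data)))
    stop("distance_volume values must be finite", call. = FALSE)
  new_volume(data, grid, "distance_volume")
}

#' @export
print.shape_volume <- function(x, ...) {
  kind <- class(x)[1]
  cat(sprintf("<%s> %dx%dx%d voxels, spacing %.4gx%.4gx%.4g mm",
              kind, x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              x$grid$spacing[1], x$grid$spacing[2], x$grid$spacing[3]))
  if (kind == "binary_volume") {
    cat(sprintf(", V = %.5g mm^3 (%d fg voxels)",
                shape_volume_mm3(x), sum(x$data)))
  } else {
    cat(sprintf(", range [%.4g, %.4g]", min(x$data), max(x$data)))
  }
  cat("\n")
  invisible(x)
}

#' Physical volume of a binary shape
#'
#' `V(S)` = foreground voxel count times the voxel volume, in cubic mm.
#'
#' @param vol a `binary_volume`.
#' @return Non-negative scalar, mm^3.
#' @export
shape_volume_mm3 <- function(vol) {
  stopifnot(inherits(vol, "binary_volume"))
  sum(vol$data) * voxel_volume(vol$grid)
}

#' Assert that volumes share one frame
#'
#' All atlas and evaluation operations assume the shapes are referred to a
#' common frame. This checks every grid against the first and raises an error
#' naming the offending list index and field (`dims`, `spacing` or `origin`).
#'
#' @param vols non-empty list of volume objects (any type).
#' @return Invisibly `TRUE` on success.
#' @export
assert_common_frame <- function(vols) {
  if (!is.list(vols) || length(vols) == 0L)
    stop("`vols` must be a non-empty list of volumes", call. = FALSE)
  ref <- vols[[1]]$grid
  for (i in seq_along(vols)) {
    g <- vols[[i]]$grid
    for (field in c("dims", "spacing", "origin")) {
      if (!isTRUE(all.equal(as.numeric(ref[[field]]),
                            as.numeric(g[[field]]), tolerance = 1e-9)))
        stop(sprintf("frame mismatch at index %d: field \"%s\" differs",
                     i, field), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Threshold a probabilistic atlas into a binary shape
#'
#' Returns the strict superlevel set `p(x) > t`. The inequality is strict so
#' that `t = 0` selects the *support* of the atlas (the union of the sample
#' under the coverage estimator) rather than the whole window; this matches
#' the evaluation sweep over thresholds `0, 0.1, ..., 0.9`.
#'
#' @param atlas a `probability_volume`.
#' @param t threshold in `[0, 1)`.
#' @return A `binary_volume` on the same grid.
#' @export
threshold_atlas <- function(atlas, t) {
  stopifnot(inherits(atlas, "probability_volume"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0 || t >= 1)
    stop("threshold `t` must lie in [0, 1)", call. = FALSE)
  binary_volume(array(as.integer(atlas$data > t), dim = atlas$grid$dims),
                atlas$grid)
}
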