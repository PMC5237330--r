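#' Geometric transformation parameters
#'
#' Parameter containers for the four registration models. `rigid_params`
#' holds three rotation angles (radians, about z, y, x — composed as
#' `Rz %*% Ry %*% Rx` applied to the point) and a translation in mm (6 free
#' parameters). `similarity_params` adds the homothety constant `k_h`
#' (uniform scaling, 7 parameters). `affine_params` holds an unrestricted
#' non-singular 3x3 matrix plus translation (12 parameters).
#'
#' The transform maps a physical point `x` to
#' `K * R * (x - c) + c + t` (rigid/similarity, rotation and scaling about
#' the pivot `c`, by default the volume-window centre) or
#' `M * (x - c) + c + t` (affine).
#'
#' @param angles rotation angles `(phi, vphi, psi)` in radians about z, y, x;
#'   stored wrapped into `(-pi, pi]`.
#' @param translation translation vector, mm.
#' @param rigid a `rigid_params` object.
#' @param k_h positive homothety (global scale) constant.
#' @param matrix non-singular 3x3 matrix.
#' @return An object of class `rigid_params`, `similarity_params` or
#'   `affine_params` (all inherit `transform_params`).
#' @export
rigid_params <- function(angles = c(0, 0, 0), translation = c(0, 0, 0)) {
  angles <- as.numeric(angles); translation <- as.numeric(translation)
  stopifnot(length(angles) == 3L, length(translation) == 3L,
            all(is.finite(angles)), all(is.finite(translation)))
  angles <- ((angles + pi) %% (2 * pi)) - pi
  angles[angles == -pi] <- pi
  structure(list(angles = angles, translation = translation),
            class = c("rigid_params", "transform_params"))
}

#' @rdname rigid_params
#' @export
similarity_params <- function(rigid = rigid_params(), k_h = 1) {
  stopifnot(inherits(rigid, "rigid_params"), is.numeric(k_h),
            length(k_h) == 1L, is.finite(k_h), k_h > 0)
  structure(list(rigid = rigid, k_h = as.numeric(k_h)),
            class = c("similarity_params", "transform_params"))
}

#' @rdname rigid_params
#' @export
affine_params <- function(matrix = diag(3), translation = c(0, 0, 0)) {
  matrix <- base::matrix(as.numeric(matrix), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3L, all(is.finite(matrix)),
            all(is.finite(translation)))
  if (abs(det(matrix)) <= 1e-8)
    stop("affine matrix is singular", call. = FALSE)
  structure(list(matrix = matrix, translation = translation),
            class = c("affine_params", "transform_params"))
}

#' Number of free parameters of a transformation model
#' @param params a `transform_params` object.
#' @return 6 (rigid), 7 (similarity) or 12 (affine).
#' @export
n_free_params <- function(params) {
  length(params_to_vector(params))
}

# flatten / unflatten for the optimizer -------------------------------------

params_to_vector <- function(params) {
  if (inherits(params, "rigid_params"))
    c(params$angles, params$translation)
  else if (inherits(params, "similarity_params"))
    c(params$rigid$angles, params$rigid$translation, params$k_h)
  else if (inherits(params, "affine_params"))
    c(as.vector(params$matrix), params$translation)
  else stop("not a transform_params object", call. = FALSE)
}

vector_to_params <- function(theta, model) {
  switch(model,
    rigid = rigid_params(theta[1:3], theta[4:6]),
    similarity = similarity_params(rigid_params(theta[1:3], theta[4:6]),
                                   theta[7]),
    affine = affine_params(matrix(theta[1:9], 3, 3), theta[10:12]),
    stop("unknown model ", model, call. = FALSE))
}

rotation_matrix_zyx <- function(angles) {
  phi <- angles[1]; vphi <- angles[2]; psi <- angles[3]
  rz <- rbind(c(cos(phi), -sin(phi), 0), c(sin(phi), cos(phi), 0), c(0, 0, 1))
  ry <- rbind(c(cos(vphi), 0, sin(vphi)), c(0, 1, 0),
              c(-sin(vphi), 0, cos(vphi)))
  rx <- rbind(c(1, 0, 0), c(0, cos(psi), -sin(psi)), c(0, sin(psi), cos(psi)))
  rz %*% ry %*% rx
}

grid_center <- function(grid) {
  grid$origin + (grid$dims - 1) / 2 * grid$spacing
}

# forward 4x4 homogeneous matrix in physical coordinates, pivot at `center`
transform_matrix <- function(params, center = c(0, 0, 0)) {
  if (inherits(params, "rigid_params")) {
    A <- rotation_matrix_zyx(params$angles)
    t <- params$translation
  } else if (inherits(params, "similarity_params")) {
    A <- params$k_h * rotation_matrix_zyx(params$rigid$angles)
    t <- params$rigid$translation
  } else if (inherits(params, "affine_params")) {
    A <- params$matrix
    t <- params$translation
  } else stop("not a transform_params object", call. = FALSE)
  m <- diag(4)
  m[1:3, 1:3] <- A
  m[1:3, 4] <- center - A %*% center + t
  m
}

#' Dense deformation field
#'
#' A per-voxel displacement in mm. The convention is pull-back: a volume is
#' warped by sampling the input at `y + u(y)` for every output voxel centre
#' `y`, which is the native output of the demons registration.
#'
#' @param grid a [volume_grid()].
#' @param ux,uy,uz 3D arrays of mm displacements matching `grid$dims`.
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(grid, ux, uy, uz) {
  stopifnot(inherits(grid, "volume_grid"))
  dm <- grid$dims
  for (u in list(ux, uy, uz)) {
    if (!all(dim(as.array(u)) == dm) || any(!is.finite(u)))
      stop("displacement components must be finite arrays on the grid",
           call. = FALSE)
  }
  structure(list(grid = grid, ux = as.array(ux) * 1.0,
                 uy = as.array(uy) * 1.0, uz = as.array(uz) * 1.0),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(x$ux^2 + x$uy^2 + x$uz^2)
  cat(sprintf("<deformation_field> %dx%dx%d, |u| max %.3g mm, mean %.3g mm\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              max(mag), mean(mag)))
  invisible(x)
}

#' Apply a transformation to a volume
#'
#' Resamples the volume under parametric transform parameters (rigid,
#' similarity, affine; rotation/scaling pivot at the volume-window centre) or
#' warps it by a dense [deformation_field()]. Binary volumes are resampled
#' with nearest-neighbour interpolation so binarity is preserved; real-valued
#' volumes use trilinear interpolation.
#'
#' @param vol a volume object.
#' @param params `transform_params`, `deformation_field` or a
#'   `registration_result`.
#' @return A volume of the same class on the same grid.
#' @export
apply_params <- function(vol, params) {
  stopifnot(inherits(vol, "shape_volume"))
  if (inherits(params, "registration_result")) params <- params$params
  g <- vol$grid
  binary <- inherits(vol, "binary_volume")
  data <- array(as.double(vol$data), dim = g$dims)
  if (inherits(params, "deformation_field")) {
    if (!grids_compatible(g, params$grid))
      stop("deformation field grid does not match the volume", call. = FALSE)
    out <- .warp_field_cpp(data, g$dims, g$spacing, g$origin,
                           params$ux, params$uy, params$uz, binary, 0)
  } else if (inherits(params, "transform_params")) {
    fwd <- transform_matrix(params, grid_center(g))
    out <- .resample_affine_cpp(data, g$dims, g$spacing, g$origin,
                                solve(fwd), binary, 0)
  } else stop("unsupported transform object", call. = FALSE)
  out <- array(out, dim = g$dims)
  if (binary) binary_volume(array(as.integer(out > 0.5), dim = g$dims), g)
  else if (inherits(vol, "probability_volume"))
    probability_volume(pmin(pmax(out, 0), 1), g)
  else distance_volume(out, g)
}
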