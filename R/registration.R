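#' Sum of squared differences between two volumes
#'
#' Voxel-wise `sum((fixed - moving)^2)` on whatever values the volumes carry.
#' During registration the cost is evaluated on Gaussian-smoothed float
#' copies of the binary masks (see [register()]); this function is the plain
#' evaluation used both there and for reporting.
#'
#' @param moving,fixed volumes on a common frame.
#' @return Non-negative scalar.
#' @export
ssd <- function(moving, fixed) {
  assert_common_frame(list(moving, fixed))
  sum((as.double(fixed$data) - as.double(moving$data))^2)
}

#' Registration optimizer settings
#'
#' @param sigma Gaussian smoothing (voxel units) applied to the binary masks
#'   before the SSD optimization; smoothing gives the cost a usable slope
#'   (raw binary SSD is a staircase in the parameters).
#' @param maxit Nelder-Mead iteration budget per optimization stage.
#' @param reltol relative convergence tolerance.
#' @param cycles number of rigid/homothety batches for the similarity model.
#' @param iterations demons iterations.
#' @param sigma_field Gaussian regularization (voxel units) of the demons
#'   displacement field, applied every iteration.
#' @param sigma_fluid optional fluid-like Gaussian smoothing (voxel units)
#'   of each demons update increment before it is added to the field; 0
#'   disables it.
#' @return A list of settings for [register()] / [register_demons()].
#' @export
reg_opts <- function(sigma = 1, maxit = 500, reltol = 1e-8, cycles = 2,
                     iterations = 50, sigma_field = 0.5, sigma_fluid = 1.5) {
  list(sigma = sigma, maxit = maxit, reltol = reltol, cycles = cycles,
       iterations = iterations, sigma_field = sigma_field,
       sigma_fluid = sigma_fluid)
}

smoothed_float <- function(vol, sigma) {
  g <- vol$grid
  d <- array(as.double(vol$data), dim = g$dims)
  if (sigma > 0)
    d <- array(.gauss_smooth_cpp(d, g$dims, rep(sigma, 3)), dim = g$dims)
  d
}

centroid_mm <- function(vol) {
  idx <- which(vol$data != 0, arr.ind = TRUE)
  vol$grid$origin + (colMeans(idx) - 1) * vol$grid$spacing
}

new_registration_result <- function(params, model, final_ssd, initial_ssd,
                                    converged, iterations) {
  structure(list(params = params, model = model, final_ssd = final_ssd,
                 initial_ssd = initial_ssd, converged = converged,
                 iterations = iterations),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> model %s: SSD %.6g -> %.6g (%s, %d evals)\n",
              x$model, x$initial_ssd, x$final_ssd,
              if (x$converged) "converged" else "not converged",
              x$iterations))
  invisible(x)
}

#' Register one binary shape to another
#'
#' Estimates rigid (6), similarity (7) or affine (12) transform parameters
#' minimizing the sum of squared differences between the fixed mask and the
#' transformed moving mask, both Gaussian-smoothed. The optimizer is
#' derivative-free (Nelder-Mead) started from identity angles plus the
#' centroid-difference translation; the similarity model alternates batches
#' of a 6-parameter rigid stage and a 1-parameter homothety line search.
#' The rotation/scaling pivot is the volume-window centre.
#'
#' The returned transform never increases the smoothed SSD relative to the
#' identity transform: if the optimizer ends worse than the identity, the
#' identity is returned with `converged = FALSE`.
#'
#' @param moving,fixed non-empty [binary_volume()]s on a common frame.
#' @param model `"rigid"`, `"similarity"` or `"affine"`.
#' @param opts settings from [reg_opts()].
#' @return A `registration_result` with fields `params`, `final_ssd`,
#'   `initial_ssd`, `converged` (the optimizer terminated by its own
#'   tolerance, or successive restarts agreed to 1e-6 relative), and
#'   `iterations` (cost evaluations spent).
#' @export
register <- function(moving, fixed, model = c("rigid", "similarity", "affine"),
                     opts = reg_opts()) {
  model <- match.arg(model)
  assert_common_frame(list(moving, fixed))
  if (sum(moving$data) == 0L || sum(fixed$data) == 0L)
    stop("cannot register an empty shape", call. = FALSE)
  g <- moving$grid
  M <- smoothed_float(moving, opts$sigma)
  F <- smoothed_float(fixed, opts$sigma)
  ctr <- grid_center(g)
  cost_of <- function(params) {
    fwd <- transform_matrix(params, ctr)
    .ssd_affine_cpp(M, F, g$dims, g$spacing, g$origin, solve(fwd))
  }
  cost_vec <- function(theta, mdl) cost_of(vector_to_params(theta, mdl))
  t0 <- centroid_mm(fixed) - centroid_mm(moving)
  id_cost <- cost_of(rigid_params())
  evals <- 0L
  run_nm <- function(theta, mdl, parscale) {
    res <- stats::optim(theta, cost_vec, mdl = mdl, method = "Nelder-Mead",
                        control = list(maxit = opts$maxit,
                                       reltol = opts$reltol,
                                       parscale = parscale))
    evals <<- evals + res$counts[["function"]]
    res
  }
  sc_ang <- rep(0.05, 3)
  sc_tr <- pmax(g$spacing, 1)
  ok <- TRUE
  stable <- function(a, b) abs(a - b) <= 1e-6 * max(1, abs(a))
  if (model == "rigid") {
    res <- run_nm(c(0, 0, 0, t0), "rigid", c(sc_ang, sc_tr))
    # restart with a tighter simplex; Nelder-Mead stalls on 6 parameters
    res2 <- run_nm(res$par, "rigid", c(sc_ang / 5, sc_tr / 5))
    ok <- res2$convergence == 0L || stable(res$value, res2$value)
    res <- if (res2$value < res$value) res2 else res
    params <- vector_to_params(res$par, "rigid")
    final <- res$value
  } else if (model == "similarity") {
    theta6 <- c(0, 0, 0, t0)
    kh <- 1
    final <- NULL
    prev_final <- Inf
    for (cy in seq_len(opts$cycles)) {
      cost6 <- function(th) cost_of(
        similarity_params(rigid_params(th[1:3], th[4:6]), kh))
      scale6 <- c(sc_ang, sc_tr) / cy # tighter simplex in later cycles
      res6 <- stats::optim(theta6, cost6, method = "Nelder-Mead",
                           control = list(maxit = opts$maxit,
                                          reltol = opts$reltol,
                                          parscale = scale6))
      evals <- evals + res6$counts[["function"]]
      theta6 <- res6$par
      ok <- res6$convergence == 0L
      resk <- stats::optimize(function(k) cost_of(
        similarity_params(rigid_params(theta6[1:3], theta6[4:6]), k)),
        interval = c(0.4, 2.5), tol = 1e-6)
      kh <- resk$minimum
      final <- resk$objective
      ok <- ok || stable(prev_final, final)
      prev_final <- final
      evals <- evals + 30L
    }
    params <- similarity_params(rigid_params(theta6[1:3], theta6[4:6]), kh)
  } else { # affine
    theta <- c(as.vector(diag(3)), t0)
    res <- run_nm(theta, "affine", c(rep(0.03, 9), sc_tr))
    # restarts with shrinking simplices; 12-dim Nelder-Mead stalls easily
    ok <- res$convergence == 0L
    for (shrink in c(3, 10, 30)) {
      res2 <- run_nm(res$par, "affine", c(rep(0.03, 9), sc_tr) / shrink)
      ok <- res2$convergence == 0L || stable(res$value, res2$value)
      if (res2$value < res$value) res <- res2
    }
    params <- vector_to_params(res$par, "affine")
    final <- res$value
  }
  if (final > id_cost) {
    id <- switch(model,
                 rigid = rigid_params(),
                 similarity = similarity_params(),
                 affine = affine_params())
    return(new_registration_result(id, model, id_cost, id_cost, FALSE, evals))
  }
  new_registration_result(params, model, final, id_cost, ok, evals)
}

#' Demons deformable registration
#'
#' Symmetric-forces demons on Gaussian-smoothed float copies of the two
#' masks, with Gaussian regularization applied every iteration: the update
#' increment is smoothed with `sigma_fluid` (fluid-like) and the accumulated
#' field with `sigma_field`. Pure field smoothing at a comparable width
#' stalls about half a voxel short of convergence on nested smooth shapes,
#' so the default puts most of the regularization on the update. Returns the dense displacement field (mm, pull-back
#' convention) plus a `registration_result`; the field with the best SSD
#' seen over the iterations is kept, so the warped moving shape's SSD to the
#' fixed shape never exceeds the unregistered SSD.
#'
#' @inheritParams register
#' @return A list with elements `field` (a [deformation_field()]) and
#'   `result` (a `registration_result`).
#' @export
register_demons <- function(moving, fixed, opts = reg_opts()) {
  assert_common_frame(list(moving, fixed))
  if (sum(moving$data) == 0L || sum(fixed$data) == 0L)
    stop("cannot register an empty shape", call. = FALSE)
  g <- moving$grid
  M <- smoothed_float(moving, opts$sigma)
  F <- smoothed_float(fixed, opts$sigma)
  out <- .demons_cpp(M, F, g$dims, g$spacing, g$origin,
                     as.integer(opts$iterations), opts$sigma_field,
                     opts$sigma_fluid %||% 0)
  fld <- deformation_field(g, array(out$ux, g$dims), array(out$uy, g$dims),
                           array(out$uz, g$dims))
  res <- new_registration_result(fld, "demons", out$final_ssd,
                                 out$initial_ssd,
                                 out$final_ssd <= out$initial_ssd,
                                 out$iterations)
  list(field = fld, result = res)
}

#' Select the reference case of a sample
#'
#' Registers every shape to every candidate reference under the given model
#' and picks the candidate with the smallest mean final SSD (self-terms
#' excluded; ties broken by lowest index).
#'
#' @param sample non-empty list of [binary_volume()]s on a common frame.
#' @param model `"rigid"`, `"similarity"`, `"affine"` or `"demons"`.
#' @param opts settings from [reg_opts()].
#' @return A list with `index` (chosen reference) and `ssd_matrix`
#'   (`n x n`, entry `[i, r]` = final SSD of registering shape `i` to
#'   candidate reference `r`; diagonal `NA`).
#' @export
select_reference <- function(sample, model, opts = reg_opts()) {
  assert_common_frame(sample)
  n <- length(sample)
  for (i in seq_len(n))
    if (sum(sample[[i]]$data) == 0L)
      stop("shape ", i, " is empty", call. = FALSE)
  mat <- matrix(NA_real_, n, n)
  if (n > 1) {
    for (r in seq_len(n)) {
      for (i in seq_len(n)) {
        if (i == r) next
        mat[i, r] <- if (model == "demons")
          register_demons(sample[[i]], sample[[r]], opts)$result$final_ssd
        else register(sample[[i]], sample[[r]], model, opts)$final_ssd
      }
    }
  }
  means <- colMeans(mat, na.rm = TRUE)
  if (all(is.nan(means))) means[] <- 0 # single shape
  list(index = which.min(means), ssd_matrix = mat)
}

#' Coregister a shape sample
#'
#' Registers every non-reference shape to the reference (chosen
#' automatically by [select_reference()] unless an index is given) and
#' resamples it into the reference frame; the reference is returned
#' unchanged.
#'
#' @inheritParams select_reference
#' @param reference `"auto"` or the 1-based index of the reference case.
#' @return A list with `aligned` (list of [binary_volume()]s), `reference`
#'   (index) and `results` (per-case `registration_result`, `NULL` for the
#'   reference).
#' @export
coregister_sample <- function(sample, model, reference = "auto",
                              opts = reg_opts()) {
  assert_common_frame(sample)
  if (length(sample) < 2L) stop("need at least 2 shapes", call. = FALSE)
  ref <- if (identical(reference, "auto"))
    select_reference(sample, model, opts)$index
  else as.integer(reference)
  fixed <- sample[[ref]]
  aligned <- vector("list", length(sample))
  results <- vector("list", length(sample))
  for (i in seq_along(sample)) {
    if (i == ref) {
      aligned[[i]] <- sample[[i]]
      next
    }
    if (model == "demons") {
      dr <- register_demons(sample[[i]], fixed, opts)
      results[[i]] <- dr$result
      aligned[[i]] <- apply_params(sample[[i]], dr$field)
    } else {
      rr <- register(sample[[i]], fixed, model, opts)
      results[[i]] <- rr
      aligned[[i]] <- apply_params(sample[[i]], rr$params)
    }
  }
  list(aligned = aligned, reference = ref, results = results)
}
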