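#' Control parameters for Demons registration
#'
#' Collects every solver knob of [register_demons()] with the defaults of
#' the method's reference configuration: 3 multiresolution levels, up to 50
#' iterations per level, filter window radius `r = 5`, `epsilon = 0.1`,
#' SLIC compactness `m = 24` with `K = 3750` supervoxels and `M = 3`
#' guidance channels.
#'
#' @param levels pyramid depth (>= 1).
#' @param iter_max maximum iterations per level (>= 1).
#' @param similarity force model: `"ssd"` (symmetric SSD, one-to-one
#'   intensity mapping) or `"lcc"` (local correlation coefficient, robust
#'   to local affine intensity changes).
#' @param regularizer `"rnd-gif"` (guided filtering, random-perturbation
#'   supervoxel guidance), `"mls-gif"` (guided filtering, multiscale
#'   supervoxel guidance) or `"iso-dem"` (isotropic Gaussian baseline).
#' @param r guided-filter window radius in voxels.
#' @param epsilon guided-filter edge-preservation parameter (> 0, on
#'   `[0, 1]`-normalized guidance).
#' @param K target supervoxel count at full resolution; coarser pyramid
#'   levels scale `K` with the voxel count so the supervoxel size in
#'   voxels stays constant.
#' @param m SLIC compactness weight (see [slic_cluster()]).
#' @param M number of random-guidance channels.
#' @param K_ladder supervoxel counts for multiscale guidance; default
#'   `K * c(1, 1/2, 1/4)`.
#' @param sigma_z seed-perturbation standard deviation in voxels
#'   (default `S / 4`).
#' @param mu_z seed-perturbation mean in voxels.
#' @param slic_iter SLIC iteration cap.
#' @param lambda Demons step-control weight (> 0); the per-voxel step is
#'   bounded by `1 / (2 sqrt(lambda))` voxels.
#' @param denom_floor stability floor for force denominators (> 0).
#' @param lcc_radius LCC window radius in voxels.
#' @param gaussian_sigma Gaussian standard deviation (voxels) of the
#'   `iso-dem` baseline regularizer; `NULL` (default) matches the guided
#'   filter's homogeneous-region bandwidth, `sqrt(2 r (r + 1) / 3)`
#'   (about 4.5 voxels at `r = 5`), so that the two regularizers differ in
#'   structure-adaptivity rather than smoothing strength.
#' @param tol convergence threshold: mean voxel-wise Euclidean norm of the
#'   field update below which a level stops (voxels, > 0).
#' @param seed integer seed controlling the random SLIC perturbations;
#'   identical seeds give bit-identical registrations.
#' @return A list of class `demons_control`.
#' @export
demons_control <- function(levels = 3, iter_max = 50,
                           similarity = c("ssd", "lcc"),
                           regularizer = c("rnd-gif", "mls-gif", "iso-dem"),
                           r = 5, epsilon = 0.1, K = 3750, m = 24, M = 3,
                           K_ladder = NULL, sigma_z = NULL, mu_z = 0,
                           slic_iter = 10, lambda = 1, denom_floor = 1e-9,
                           lcc_radius = 4, gaussian_sigma = NULL, tol = 0.01,
                           seed = 1L) {
  similarity <- match.arg(similarity)
  regularizer <- match.arg(regularizer)
  stopifnot(levels >= 1, iter_max >= 1, r >= 1, epsilon > 0, K >= 1, m > 0,
            M >= 1, lambda > 0, denom_floor > 0, lcc_radius >= 1, tol > 0)
  if (is.null(K_ladder)) K_ladder <- pmax(1, round(K * c(1, 1 / 2, 1 / 4)))
  # bandwidth-matched baseline: in homogeneous regions the guided filter
  # reduces to a double box mean of radius r, whose variance 2 r (r + 1) / 3
  # fixes the standard deviation of an equally strong Gaussian. Matching the
  # two isolates structure-adaptivity when regularizers are compared.
  if (is.null(gaussian_sigma)) gaussian_sigma <- sqrt(2 * r * (r + 1) / 3)
  stopifnot(gaussian_sigma >= 0)
  structure(list(levels = as.integer(levels), iter_max = as.integer(iter_max),
                 similarity = similarity, regularizer = regularizer,
                 r = as.integer(r), epsilon = epsilon, K = K, m = m,
                 M = as.integer(M), K_ladder = K_ladder, sigma_z = sigma_z,
                 mu_z = mu_z, slic_iter = as.integer(slic_iter),
                 lambda = lambda, denom_floor = denom_floor,
                 lcc_radius = as.integer(lcc_radius),
                 gaussian_sigma = gaussian_sigma, tol = tol,
                 seed = as.integer(seed)),
            class = "demons_control")
}

compute_force <- function(fixed, moving, u, control) {
  if (control$similarity == "ssd") {
    ssd_symmetric_force(fixed, moving, u, control$lambda, control$denom_floor)
  } else {
    lcc_force(fixed, moving, u, control$lambda, control$denom_floor,
              control$lcc_radius)
  }
}

#' One Demons iteration: force, composition, regularization
#'
#' Computes the similarity force, composes it under the current field
#' (`u' = u o f`) and regularizes the result — by guided filtering with the
#' supplied guidance for the `gif` regularizers, or by Gaussian smoothing
#' for `iso-dem`.
#'
#' @param fixed,moving [volume3d()] objects on one grid.
#' @param u current [displacement_field()].
#' @param guidance a [guidance_image()] (required unless
#'   `control$regularizer == "iso-dem"`).
#' @param control a [demons_control()] object.
#' @return The updated [displacement_field()].
#' @export
demons_iteration <- function(fixed, moving, u, guidance = NULL, control) {
  f <- compute_force(fixed, moving, u, control)
  u1 <- compose_fields(u, f)
  if (control$regularizer == "iso-dem") {
    gaussian_smooth_field(u1, control$gaussian_sigma)
  } else {
    if (is.null(guidance))
      stop("regularizer '", control$regularizer, "' requires a guidance image")
    regularize_field(u1, guidance, control$r, control$epsilon)
  }
}

#' Convergence test on the field update
#'
#' @param u_new,u_old [displacement_field()] objects on one grid.
#' @param tol threshold in voxels (> 0).
#' @return `TRUE` iff the mean voxel-wise Euclidean norm of
#'   `u_new - u_old` is below `tol`.
#' @export
has_converged <- function(u_new, u_old, tol) {
  stopifnot(is_field(u_new), is_field(u_old), tol > 0)
  if (!identical(dim(u_new$v), dim(u_old$v)))
    stop("fields are on different grids")
  d <- u_new$v - u_old$v
  mean(sqrt(d[, , , 1]^2 + d[, , , 2]^2 + d[, , , 3]^2)) < tol
}

build_level_guidance <- function(fixed_level, control, level) {
  N_level <- prod(dim(fixed_level$data))
  if (control$regularizer == "rnd-gif") {
    K_l <- max(27, round(control$K * N_level / control$N_full))
    build_random_guidance(fixed_level, K = K_l, M = control$M, m = control$m,
                          sigma_z = control$sigma_z, mu_z = control$mu_z,
                          i_max = control$slic_iter,
                          seed = control$seed + 97L * level)
  } else if (control$regularizer == "mls-gif") {
    ladder <- pmax(27, round(control$K_ladder * N_level / control$N_full))
    ladder <- ladder[!duplicated(ladder)]
    build_multiscale_guidance(fixed_level, K_ladder = ladder, m = control$m,
                              i_max = control$slic_iter)
  } else NULL
}

#' Demons registration with guided-filter or Gaussian regularization
#'
#' Estimates the displacement field aligning `moving` to `fixed` by
#' compositive Demons iterations within a coarse-to-fine multiresolution
#' pyramid. At each level the similarity force ([ssd_symmetric_force()] or
#' [lcc_force()]) is composed onto the current field and the field is
#' regularized — classically by isotropic Gaussian smoothing
#' (`regularizer = "iso-dem"`), or by guided image filtering steered by
#' supervoxel guidance built from the fixed image
#' (`"rnd-gif"`, `"mls-gif"`), which preserves sliding-motion
#' discontinuities at intensity interfaces without prior segmentation.
#'
#' Both volumes should be preprocessed onto a shared intensity scale
#' (e.g. [normalize_intensity()]); they must live on the same grid
#' (use [resample_isotropic()] first otherwise).
#'
#' @param fixed reference [volume3d()].
#' @param moving source [volume3d()] to be aligned onto `fixed`.
#' @param control a [demons_control()] object.
#' @param verbose print per-iteration progress.
#' @return An object of class `demons_reg` with components `field` (the
#'   estimated [displacement_field()] on the fixed grid, pull-back
#'   convention: `warp_volume(moving, field)` is aligned with `fixed`),
#'   `control`, `log` (per-iteration data frame with mean update norms and
#'   residuals), `fixed`, `moving` and `converged`. Methods:
#'   [predict.demons_reg()], [residuals.demons_reg()],
#'   [summary.demons_reg()], [plot.demons_reg()], `coef()`.
#' @examples
#' ph <- make_sliding_phantom(shape = c(24, 24, 24), slide_voxels = 2,
#'                            n_landmarks = 4, margin = 5, seed = 7)
#' ctl <- demons_control(levels = 1, iter_max = 5, regularizer = "iso-dem",
#'                       K = 200)
#' fit <- register_demons(ph$fixed, ph$moving, ctl)
#' fit
#' @export
register_demons <- function(fixed, moving, control = demons_control(),
                            verbose = FALSE) {
  stopifnot(is_volume(fixed), is_volume(moving),
            inherits(control, "demons_control"))
  if (!same_grid(fixed, moving))
    stop("fixed and moving volumes must share one grid; ",
         "resample the moving volume first")
  if (max(abs(fixed$spacing - moving$spacing)) > 1e-6)
    stop("fixed and moving volumes have different voxel spacing")
  t0 <- proc.time()[["elapsed"]]
  control$N_full <- prod(dim(fixed$data))
  pf <- build_pyramid(fixed, control$levels)
  pm <- build_pyramid(moving, control$levels)
  logs <- list()
  converged <- logical(control$levels)
  u <- NULL
  for (level in control$levels:1) {
    fl <- pf[[level]]
    ml <- pm[[level]]
    dl <- dim(fl$data)
    u <- if (is.null(u)) zero_field(fl) else upsample_field(u, dl)
    guidance <- build_level_guidance(fl, control, level)
    for (it in seq_len(control$iter_max)) {
      u_new <- demons_iteration(fl, ml, u, guidance, control)
      dnorm <- {
        dd <- u_new$v - u$v
        mean(sqrt(dd[, , , 1]^2 + dd[, , , 2]^2 + dd[, , , 3]^2))
      }
      u <- u_new
      mag <- mean(sqrt(u$v[, , , 1]^2 + u$v[, , , 2]^2 + u$v[, , , 3]^2))
      if (mag > max(dl) / 3)
        stop("registration diverged at level ", level, ", iteration ", it,
             ": mean |u| = ", signif(mag, 4), " voxels exceeds a third of ",
             "the image extent")
      logs[[length(logs) + 1L]] <- data.frame(level = level, iter = it,
                                              mean_update = dnorm,
                                              mean_mag = mag)
      if (verbose)
        message(sprintf("level %d iter %3d  mean update %.5f  mean |u| %.4f",
                        level, it, dnorm, mag))
      if (dnorm < control$tol) { converged[level] <- TRUE; break }
    }
  }
  res <- warp_volume(moving, u)
  structure(list(field = u, control = control,
                 log = do.call(rbind, logs),
                 fixed = fixed, moving = moving, warped = res,
                 converged = converged,
                 elapsed = proc.time()[["elapsed"]] - t0),
            class = "demons_reg")
}

#' @export
print.demons_reg <- function(x, ...) {
  d <- dim(x$field$v)[1:3]
  mag <- sqrt(x$field$v[, , , 1]^2 + x$field$v[, , , 2]^2 +
                x$field$v[, , , 3]^2)
  cat("Demons registration (", x$control$similarity, " force, ",
      x$control$regularizer, " regularizer)\n", sep = "")
  cat("  grid: ", paste(d, collapse = " x "), " voxels, ",
      x$control$levels, " level(s), ", nrow(x$log), " iterations total\n",
      sep = "")
  cat("  displacement |u|: mean ", signif(mean(mag), 4), ", max ",
      signif(max(mag), 4), " voxels\n", sep = "")
  cat("  mean |residual|: ",
      signif(mean(abs(x$fixed$data - x$warped$data)), 4),
      " (before: ", signif(mean(abs(x$fixed$data - x$moving$data)), 4),
      ")\n", sep = "")
  invisible(x)
}

#' @export
coef.demons_reg <- function(object, ...) object$field

#' Residual image of a registration
#'
#' @param object a `demons_reg` fit.
#' @param ... unused.
#' @return A [volume3d()] of `fixed - warped moving` intensities.
#' @export
residuals.demons_reg <- function(object, ...) {
  volume3d(object$fixed$data - object$warped$data,
           object$fixed$spacing, object$fixed$origin)
}

#' Apply a fitted registration to a volume or to landmarks
#'
#' With a volume, resamples it through the estimated field (pull-back onto
#' the fixed grid). With landmarks (data frame with `x`, `y`, `z` in mm),
#' maps fixed-image points to their moving-image positions
#' `p + u(p) * spacing`.
#'
#' @param object a `demons_reg` fit.
#' @param newdata a [volume3d()] or a landmark data frame; defaults to the
#'   moving volume of the fit.
#' @param ... unused.
#' @return A warped [volume3d()] or a transformed landmark data frame.
#' @export
predict.demons_reg <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$warped)
  if (is_volume(newdata)) return(warp_volume(newdata, object$field))
  if (is.data.frame(newdata)) return(transform_landmarks(newdata, object$field))
  stop("newdata must be a volume or a landmark data frame")
}

#' @export
summary.demons_reg <- function(object, ...) {
  jac <- jacobian_determinant(object$field)$data
  res_after <- abs(object$fixed$data - object$warped$data)
  res_before <- abs(object$fixed$data - object$moving$data)
  out <- list(control = object$control,
              iterations = nrow(object$log),
              converged = object$converged,
              residual_before = mean(res_before),
              residual_after = mean(res_after),
              jacobian_range = range(jac),
              frac_nonpositive_jacobian = mean(jac <= 0),
              elapsed = object$elapsed)
  class(out) <- "summary.demons_reg"
  out
}

#' @export
print.summary.demons_reg <- function(x, ...) {
  cat("Demons registration summary\n")
  cat("  similarity: ", x$control$similarity, ", regularizer: ",
      x$control$regularizer, "\n", sep = "")
  cat("  iterations: ", x$iterations, " (levels converged: ",
      paste(which(rev(x$converged)), collapse = ", "), ")\n", sep = "")
  cat("  mean |residual|: ", signif(x$residual_after, 4), " (before ",
      signif(x$residual_before, 4), ")\n", sep = "")
  cat("  Jacobian determinant range: [", signif(x$jacobian_range[1], 4),
      ", ", signif(x$jacobian_range[2], 4), "], non-positive fraction ",
      signif(x$frac_nonpositive_jacobian, 4), "\n", sep = "")
  cat("  elapsed: ", signif(x$elapsed, 3), " s\n", sep = "")
  invisible(x)
}

#' Convergence trace of a registration
#'
#' Plots the mean field-update norm per iteration, one curve segment per
#' pyramid level.
#'
#' @param x a `demons_reg` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.demons_reg <- function(x, ...) {
  lg <- x$log
  graphics::plot(seq_len(nrow(lg)), lg$mean_update, type = "l",
                 xlab = "iteration (all levels)",
                 ylab = "mean update norm (voxels)",
                 main = "Demons convergence", ...)
  lv_breaks <- which(diff(lg$level) != 0) + 0.5
  if (length(lv_breaks))
    graphics::abline(v = lv_breaks, lty = 3, col = "grey50")
  invisible(x)
}

#' Map landmarks through a displacement field
#'
#' @param landmarks data frame with `x`, `y`, `z` in mm (fixed image space).
#' @param field a [displacement_field()].
#' @return The data frame with coordinates moved by `u(p) * spacing`;
#'   points outside the field domain are returned unchanged with a warning.
#' @export
transform_landmarks <- function(landmarks, field) {
  stopifnot(is_field(field))
  d <- dim(field$v)[1:3]
  vox <- sweep(sweep(as.matrix(landmarks[, c("x", "y", "z")]), 2,
                     field$origin, "-"), 2, field$spacing, "/")
  inside <- vox[, 1] >= 0 & vox[, 1] <= d[1] - 1 &
    vox[, 2] >= 0 & vox[, 2] <= d[2] - 1 &
    vox[, 3] >= 0 & vox[, 3] <= d[3] - 1
  if (any(!inside))
    warning(sum(!inside), " landmark(s) outside the field domain left unchanged")
  out <- landmarks
  cols <- c("x", "y", "z")
  for (c in 1:3) {
    u_c <- cpp_trilinear(as.vector(field$v[, , , c]), d,
                         vox[, 1], vox[, 2], vox[, 3])
    out[[cols[c]]] <- landmarks[[cols[c]]] +
      ifelse(inside, u_c * field$spacing[c], 0)
  }
  out
}
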