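# Synthetic sliding-motion phantom and landmark-based evaluation.
#
# The phantom emulates the situation the guided-filter regularizer is built
# for: two textured, high-contrast regions separated by a planar interface
# (think lung against liver/abdominal wall) where the motion is tangentially
# discontinuous — one region slides along the interface while the other
# stays put. Landmarks are kept away from the interface so TRE measures
# motion recovery, not interface ambiguity.

# smooth band-limited texture with unit standard deviation
band_limited_noise <- function(dims, sigma, seed = NULL) {
  n <- with_seed(seed, array(stats::rnorm(prod(dims)), dims))
  s <- gaussian_smooth_volume(n, sigma)
  s / stats::sd(s)
}

# taper from 0 at the volume faces to 1 at `margin` voxels inside
border_taper <- function(dims, margin) {
  ramp1 <- function(n) {
    i <- seq_len(n) - 1
    pmin(1, pmin(i, n - 1 - i) / margin)
  }
  array(outer(outer(ramp1(dims[1]), ramp1(dims[2])), ramp1(dims[3])), dims)
}

# fixed-point inversion of a displacement field: returns g with
# x + g(x) + u(x + g(x)) = x, i.e. warp(fixed, g) realizes the push-forward
# of fixed through phi(x) = x + u(x) (up to the iteration tolerance)
invert_field <- function(u, iterations = 10) {
  g <- displacement_field(-u$v, u$spacing, u$origin)
  d <- dim(u$v)[1:3]
  for (it in seq_len(iterations)) {
    co <- displaced_coords(g)
    gv <- g$v
    for (c in 1:3) {
      gv[, , , c] <- -array(cpp_trilinear(as.vector(u$v[, , , c]), d,
                                          co$xs, co$ys, co$zs), d)
    }
    g <- displacement_field(gv, u$spacing, u$origin)
  }
  g
}

#' Synthetic sliding-motion phantom
#'
#' Builds a pair of volumes with known ground truth: the fixed image is a
#' band-limited random texture overlaid on two high-contrast regions
#' separated by a planar interface; the true displacement translates one
#' region by `slide_voxels` tangentially to the interface (the other region
#' does not move), giving a motion discontinuity of `slide_voxels` across
#' the plane. The displacement tapers to zero within `margin` voxels of the
#' outer borders of the sliding region. The moving image is the fixed image
#' resampled through the (fixed-point-inverted) true field, optionally
#' degraded by a multiplicative low-frequency bias field (emulating
#' contrast change) and additive Gaussian noise.
#'
#' `true_field` is the fixed-to-moving correspondence field: a fixed-image
#' point `p` corresponds to moving-image point `p + u(p) * spacing`, which
#' is also the convention of the field estimated by [register_demons()]
#' and consumed by [compute_tre()]. Landmark pairs are sampled at least
#' `interface_clear` voxels from the interface and `margin` voxels from the
#' borders, in both regions.
#'
#' @param shape grid dimensions (>= 32 per axis for benchmark use; smaller
#'   grids are fine for unit tests).
#' @param interface_axis axis (1-3) normal to the sliding interface.
#' @param slide_voxels tangential shift magnitude `t` in voxels (>= 0).
#' @param texture_scale Gaussian smoothing sigma of the random texture
#'   (voxels).
#' @param contrast intensity offset between the two regions (on `[0, 1]`).
#' @param bias_amplitude relative amplitude of the multiplicative
#'   low-frequency bias applied to the moving image (0 disables it).
#' @param noise_sd additive Gaussian noise standard deviation (0 disables).
#' @param n_landmarks landmarks per region.
#' @param margin border margin in voxels (taper width and landmark
#'   exclusion zone).
#' @param interface_clear minimum landmark distance from the interface
#'   (voxels).
#' @param landmark_band maximum landmark distance from the interface
#'   (voxels); landmarks concentrate in the sliding-relevant band, as lung
#'   landmarks do around sliding surfaces.
#' @param spacing voxel spacing in mm.
#' @param seed RNG seed (texture, noise and landmark placement).
#' @return A list with `fixed`, `moving` ([volume3d()]), `true_field`
#'   ([displacement_field()]), `fixed_landmarks`, `moving_landmarks`
#'   (`gf_landmarks` data frames, mm), and the geometry entries
#'   `interface_axis`, `interface_position` (0-based voxel index of the
#'   first sliding slice), `slide_voxels`, `margin`.
#' @export
make_sliding_phantom <- function(shape = c(64, 64, 64), interface_axis = 3,
                                 slide_voxels = 6, texture_scale = 2,
                                 contrast = 0.8, bias_amplitude = 0,
                                 noise_sd = 0.02, n_landmarks = 20, margin = 8,
                                 interface_clear = 3, landmark_band = 16,
                                 spacing = c(1, 1, 1), seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L), slide_voxels >= 0,
            interface_axis %in% 1:3, contrast >= 0, contrast <= 1)
  d <- shape
  ax <- interface_axis
  tangent_axis <- if (ax == 1L) 2L else 1L
  z0 <- d[ax] %/% 2L # 0-based: slices z >= z0 slide
  # region indicator along the interface axis, broadcast to 3-D
  axcoord <- function(axis) {
    switch(axis,
           array(rep(seq_len(d[1]) - 1, times = d[2] * d[3]), d),
           array(rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]), d),
           array(rep(seq_len(d[3]) - 1, each = d[1] * d[2]), d))
  }
  zc <- axcoord(ax)
  upper <- zc >= z0
  base <- (1 - contrast) / 2 + contrast * upper
  # parenchyma-like content: faint texture everywhere plus strong sparse
  # vessel/airway-like features
  tex <- band_limited_noise(d, texture_scale, seed = seed)
  blobs <- band_limited_noise(d, 2 * texture_scale, seed = seed + 3L)
  thr <- stats::quantile(blobs, c(0.65, 0.80), names = FALSE)
  structure_mask <- pmin(pmax((blobs - thr[1]) / (thr[2] - thr[1]), 0), 1)
  fixed_data <- base + 0.04 * tex + 0.15 * tex * structure_mask
  fixed_data <- array(pmin(pmax(fixed_data, 0), 1), d)
  fixed <- volume3d(fixed_data, spacing)
  # true field: tangential slide of the upper region. The slide decays to
  # zero near the two volume faces it points at (content would otherwise
  # have no source inside the field of view); along the other axes the
  # slide runs right up to the border, as sliding organs do in a cropped
  # scan.
  ramp1 <- pmin(1, pmin(seq_len(d[tangent_axis]) - 1,
                        d[tangent_axis] - seq_len(d[tangent_axis])) / margin)
  taper <- switch(tangent_axis,
                  array(rep(ramp1, times = d[2] * d[3]), d),
                  array(rep(rep(ramp1, each = d[1]), times = d[3]), d))
  u <- array(0, c(d, 3L))
  u[, , , tangent_axis] <- slide_voxels * upper * taper
  true_field <- displacement_field(u, spacing, fixed$origin)
  if (slide_voxels > 0) {
    gen <- invert_field(true_field)
    moving_data <- warp_volume(fixed, gen)$data
  } else {
    moving_data <- fixed_data
  }
  if (bias_amplitude > 0) {
    bias <- 1 + bias_amplitude *
      cos(pi * axcoord(1) / d[1]) * cos(pi * axcoord(2) / d[2]) *
      cos(pi * axcoord(3) / d[3])
    moving_data <- moving_data * bias
  }
  if (noise_sd > 0) {
    moving_data <- moving_data +
      with_seed(seed + 1L, array(stats::rnorm(prod(d), 0, noise_sd), d))
  }
  moving <- volume3d(moving_data, spacing)
  # landmark placement: inside the taper plateau, clear of the interface
  lo <- rep(margin, 3)
  hi <- d - 1 - margin
  lo[ax] <- max(lo[ax], 0)
  regions <- list(lower = c(max(margin, z0 - 1 - landmark_band),
                            z0 - 1 - interface_clear),
                  upper = c(z0 + interface_clear,
                            min(d[ax] - 1 - margin, z0 + landmark_band)))
  pts <- with_seed(seed + 2L, {
    res <- list()
    for (rg in names(regions)) {
      zr <- regions[[rg]]
      if (zr[2] < zr[1])
        stop("region '", rg, "' too thin to place landmarks ",
             interface_clear, " voxels from the interface and ", margin,
             " voxels from the borders")
      p <- matrix(0, n_landmarks, 3)
      for (a in 1:3) {
        rng <- if (a == ax) zr else c(margin, d[a] - 1 - margin)
        p[, a] <- sample(seq(rng[1], rng[2]), n_landmarks, replace = TRUE)
      }
      res[[rg]] <- p
    }
    res
  })
  vox <- rbind(pts$lower, pts$upper)
  labels <- c(sprintf("lower_%02d", seq_len(n_landmarks)),
              sprintf("upper_%02d", seq_len(n_landmarks)))
  mm <- sweep(sweep(vox, 2, spacing, "*"), 2, fixed$origin, "+")
  fixed_lm <- data.frame(x = mm[, 1], y = mm[, 2], z = mm[, 3],
                         label = labels, stringsAsFactors = FALSE)
  class(fixed_lm) <- c("gf_landmarks", "data.frame")
  moving_lm <- transform_landmarks(fixed_lm, true_field)
  class(moving_lm) <- c("gf_landmarks", "data.frame")
  list(fixed = fixed, moving = moving, true_field = true_field,
       fixed_landmarks = fixed_lm, moving_landmarks = moving_lm,
       interface_axis = ax, interface_position = z0,
       slide_voxels = slide_voxels, margin = margin,
       interface_clear = interface_clear)
}

#' Target registration error of paired landmarks
#'
#' For each landmark pair, the fixed-image point is mapped through the
#' field (`p_F + u(p_F) * spacing`, `u` interpolated trilinearly) and the
#' Euclidean distance in mm to the true moving-image point is reported.
#' Landmarks outside the field domain are excluded with a warning.
#'
#' @param fixed_landmarks,moving_landmarks paired data frames with
#'   `x`, `y`, `z` in mm (equal row counts, aligned ordering).
#' @param field a [displacement_field()] on the fixed grid; pass
#'   `zero_field(fixed)` for the initial (pre-registration) TRE.
#' @param spacing,origin grid metadata; default taken from `field`.
#' @return A list with `mean`, `sd`, `per_point` (mm) and `n_excluded`.
#' @export
compute_tre <- function(fixed_landmarks, moving_landmarks, field,
                        spacing = field$spacing, origin = field$origin) {
  stopifnot(is_field(field),
            nrow(fixed_landmarks) == nrow(moving_landmarks))
  d <- dim(field$v)[1:3]
  pf <- as.matrix(fixed_landmarks[, c("x", "y", "z")])
  pm <- as.matrix(moving_landmarks[, c("x", "y", "z")])
  vox <- sweep(sweep(pf, 2, origin, "-"), 2, spacing, "/")
  inside <- vox[, 1] >= 0 & vox[, 1] <= d[1] - 1 &
    vox[, 2] >= 0 & vox[, 2] <= d[2] - 1 &
    vox[, 3] >= 0 & vox[, 3] <= d[3] - 1
  if (any(!inside))
    warning(sum(!inside), " landmark(s) outside the field domain excluded")
  mapped <- pf
  for (c in 1:3) {
    u_c <- cpp_trilinear(as.vector(field$v[, , , c]), d,
                         vox[, 1], vox[, 2], vox[, 3])
    mapped[, c] <- pf[, c] + u_c * spacing[c]
  }
  err <- sqrt(rowSums((mapped - pm)^2))[inside]
  list(mean = mean(err), sd = stats::sd(err), per_point = err,
       n_excluded = sum(!inside))
}

#' Displacement jump across a planar interface
#'
#' Measures the recovered tangential discontinuity: the mean difference of
#' one displacement component between slices `offsets` voxels above and
#' below the interface plane, averaged over the central in-plane window
#' (`core` fraction per axis, avoiding the tapered borders).
#'
#' @param field a [displacement_field()].
#' @param axis axis normal to the interface (1-3).
#' @param position 0-based index of the first slice above the interface.
#' @param component displacement component to difference (1-3).
#' @param offsets voxel offsets from the interface used on both sides.
#' @param core central fraction of the in-plane extent to average over.
#' @return Mean jump of the component across the interface (voxels).
#' @export
interface_jump <- function(field, axis, position, component,
                           offsets = 2:4, core = 0.5) {
  stopifnot(is_field(field), axis %in% 1:3, component %in% 1:3)
  d <- dim(field$v)[1:3]
  sel <- lapply(1:3, function(a) {
    n <- d[a]
    w <- max(1L, floor(n * core / 2))
    (n %/% 2 - w):(n %/% 2 + w) + 1L
  })
  slab <- function(slices) {
    sel2 <- sel
    sel2[[axis]] <- slices + 1L # to 1-based
    comp <- field$v[, , , component]
    mean(comp[sel2[[1]], sel2[[2]], sel2[[3]]])
  }
  above <- slab(pmin(position + offsets, d[axis] - 1L))
  below <- slab(pmax(position - 1L - offsets, 0L))
  above - below
}

#' Benchmark registration configurations on a sliding phantom
#'
#' Registers the phantom's volume pair under each configuration and
#' tabulates initial and final TRE (mean and sd, mm), the mean absolute
#' intensity residual, the fraction of non-positive Jacobian determinants
#' in the region interiors (at least `interface_clear` voxels from the
#' interface, 2 voxels from the borders), and the recovered tangential
#' jump across the interface. A configuration that aborts is recorded with
#' `NA` results and the run continues.
#'
#' @param phantom output of [make_sliding_phantom()].
#' @param configs named list of [demons_control()] objects.
#' @param out_csv optional path; when given, the table is written as CSV.
#' @param verbose print progress.
#' @return A data frame with one row per configuration plus an `initial`
#'   row.
#' @export
run_benchmark <- function(phantom, configs, out_csv = NULL, verbose = FALSE) {
  stopifnot(length(configs) >= 1)
  if (is.null(names(configs)) || any(names(configs) == ""))
    names(configs) <- paste0("config", seq_along(configs))
  ax <- phantom$interface_axis
  tangent_axis <- if (ax == 1L) 2L else 1L
  d <- dim(phantom$fixed$data)
  interior <- interior_mask(d, ax, phantom$interface_position,
                            phantom$interface_clear)
  tre0 <- compute_tre(phantom$fixed_landmarks, phantom$moving_landmarks,
                      zero_field(phantom$fixed))
  rows <- list(data.frame(
    method = "initial", tre_mean_mm = tre0$mean, tre_sd_mm = tre0$sd,
    mean_abs_residual = mean(abs(phantom$fixed$data - phantom$moving$data)),
    frac_nonpos_jacobian = 0,
    interface_jump_voxels = 0, error = "", stringsAsFactors = FALSE))
  for (nm in names(configs)) {
    if (verbose) message("benchmark: ", nm)
    fit <- tryCatch(register_demons(phantom$fixed, phantom$moving,
                                    configs[[nm]]),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[length(rows) + 1L]] <- data.frame(
        method = nm, tre_mean_mm = NA_real_, tre_sd_mm = NA_real_,
        mean_abs_residual = NA_real_, frac_nonpos_jacobian = NA_real_,
        interface_jump_voxels = NA_real_, error = conditionMessage(fit),
        stringsAsFactors = FALSE)
      next
    }
    tre <- compute_tre(phantom$fixed_landmarks, phantom$moving_landmarks,
                       fit$field)
    jac <- jacobian_determinant(fit$field)$data
    rows[[length(rows) + 1L]] <- data.frame(
      method = nm, tre_mean_mm = tre$mean, tre_sd_mm = tre$sd,
      mean_abs_residual = mean(abs(fit$fixed$data - fit$warped$data)),
      frac_nonpos_jacobian = mean(jac[interior] <= 0),
      interface_jump_voxels = interface_jump(fit$field, ax,
                                             phantom$interface_position,
                                             tangent_axis),
      error = "", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

# voxels at least `clear` voxels from the interface plane and 2 voxels from
# the outer borders
interior_mask <- function(dims, axis, position, clear) {
  coord <- switch(axis,
                  array(rep(seq_len(dims[1]) - 1, times = dims[2] * dims[3]), dims),
                  array(rep(rep(seq_len(dims[2]) - 1, each = dims[1]),
                            times = dims[3]), dims),
                  array(rep(seq_len(dims[3]) - 1, each = dims[1] * dims[2]), dims))
  away <- coord <= position - 1 - clear | coord >= position + clear
  brd <- border_taper(dims, 2) >= 1
  away & brd
}
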