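#' Displacement field on a reference grid
#'
#' A `gf_field` stores one 3-vector per voxel of the reference grid, in
#' voxel units (the physical displacement of voxel `x` is
#' `v[x, ] * spacing` mm). The transformation represented is the pull-back
#' map `phi(x) = x + u(x)`: a moving image is resampled at `x + u(x)` to
#' bring it onto the reference grid (see [warp_volume()]).
#'
#' @param v numeric 4-D array of dimension `c(nx, ny, nz, 3)` holding the
#'   x, y, z displacement components in voxel units.
#' @param spacing,origin grid metadata inherited from the reference volume.
#' @return An object of class `gf_field` with fields `v`, `spacing`, `origin`.
#' @export
displacement_field <- function(v, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  v <- as.array(v)
  if (length(dim(v)) != 4L || dim(v)[4] != 3L)
    stop("displacement field must be a (nx, ny, nz, 3) array")
  storage.mode(v) <- "double"
  if (any(!is.finite(v))) stop("displacement components must be finite")
  structure(list(v = v, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "gf_field")
}

#' Zero displacement field matching a volume's grid
#'
#' @param volume a [volume3d()] object (or a 3-D array).
#' @return A [displacement_field()] of zeros on `volume`'s grid.
#' @export
zero_field <- function(volume) {
  d <- dim(vol_data(volume))
  sp <- if (is_volume(volume)) volume$spacing else c(1, 1, 1)
  og <- if (is_volume(volume)) volume$origin else c(0, 0, 0)
  displacement_field(array(0, c(d, 3L)), sp, og)
}

#' @export
print.gf_field <- function(x, ...) {
  d <- dim(x$v)[1:3]
  mag <- sqrt(x$v[, , , 1]^2 + x$v[, , , 2]^2 + x$v[, , , 3]^2)
  cat("<gf_field> ", paste(d, collapse = " x "),
      " voxels; |u| mean ", signif(mean(mag), 4),
      ", max ", signif(max(mag), 4), " voxels\n", sep = "")
  invisible(x)
}

is_field <- function(x) inherits(x, "gf_field")

# grid coordinates (0-based) displaced by the field, as three long vectors
displaced_coords <- function(field) {
  d <- dim(field$v)[1:3]
  gx <- seq_len(d[1]) - 1
  gy <- seq_len(d[2]) - 1
  gz <- seq_len(d[3]) - 1
  list(
    xs = rep(gx, times = d[2] * d[3]) + as.vector(field$v[, , , 1]),
    ys = rep(rep(gy, each = d[1]), times = d[3]) + as.vector(field$v[, , , 2]),
    zs = rep(gz, each = d[1] * d[2]) + as.vector(field$v[, , , 3])
  )
}

#' Warp a volume through a displacement field
#'
#' Pull-back resampling: `output(x) = moving(x + u(x))` with trilinear
#' interpolation and edge clamping for out-of-bounds samples. The output
#' lives on the field's (reference) grid.
#'
#' @param moving a [volume3d()] object to be resampled.
#' @param field a [displacement_field()] whose grid matches `moving`.
#' @return The warped [volume3d()].
#' @export
warp_volume <- function(moving, field) {
  stopifnot(is_volume(moving), is_field(field))
  if (!identical(dim(moving$data), dim(field$v)[1:3]))
    stop("field grid (", paste(dim(field$v)[1:3], collapse = "x"),
         ") does not match moving volume grid (",
         paste(dim(moving$data), collapse = "x"), ")")
  co <- displaced_coords(field)
  vals <- cpp_trilinear(as.vector(moving$data), dim(moving$data),
                        co$xs, co$ys, co$zs)
  volume3d(array(vals, dim(moving$data)), field$spacing, field$origin)
}

#' Compose two displacement fields
#'
#' Returns the field of the composed map `phi_u o phi_f`, i.e.
#' `(u o f)(x) = f(x) + u(x + f(x))`, with `u` sampled trilinearly
#' (edge-clamped). This is the update rule of compositive Demons: the
#' current field `u` is composed with the update `f`.
#'
#' @param u,f [displacement_field()] objects on the same grid.
#' @return The composed [displacement_field()].
#' @export
compose_fields <- function(u, f) {
  stopifnot(is_field(u), is_field(f))
  if (!identical(dim(u$v), dim(f$v))) stop("fields are on different grids")
  d <- dim(u$v)[1:3]
  co <- displaced_coords(f)
  out <- f$v
  for (c in 1:3) {
    out[, , , c] <- out[, , , c] +
      array(cpp_trilinear(as.vector(u$v[, , , c]), d, co$xs, co$ys, co$zs), d)
  }
  displacement_field(out, u$spacing, u$origin)
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian smoothing of a displacement field
#'
#' Each vector component is convolved with a separable, unit-sum sampled
#' Gaussian (kernel radius `ceiling(3 * sigma)`, replicated edges). This is
#' the isotropic-diffusion baseline regularizer of Demons registration;
#' `sigma = 0` is the identity.
#'
#' @param field a [displacement_field()].
#' @param sigma Gaussian standard deviation in voxels (>= 0).
#' @return The smoothed [displacement_field()].
#' @export
gaussian_smooth_field <- function(field, sigma) {
  stopifnot(is_field(field), sigma >= 0)
  if (sigma == 0) return(field)
  k <- gaussian_kernel_1d(sigma)
  d <- dim(field$v)[1:3]
  out <- field$v
  for (c in 1:3) {
    out[, , , c] <- array(cpp_sep_convolve(as.vector(field$v[, , , c]), d, k), d)
  }
  displacement_field(out, field$spacing, field$origin)
}

#' Gaussian smoothing of a scalar volume
#'
#' Separable convolution with a unit-sum sampled Gaussian, replicated edges.
#'
#' @param volume a [volume3d()] or 3-D array.
#' @param sigma standard deviation in voxels (`0` is the identity).
#' @return Same type as the input.
#' @export
gaussian_smooth_volume <- function(volume, sigma) {
  if (sigma == 0) return(volume)
  a <- vol_data(volume)
  k <- gaussian_kernel_1d(sigma)
  sm <- array(cpp_sep_convolve(as.vector(a), dim(a), k), dim(a))
  if (is_volume(volume)) volume3d(sm, volume$spacing, volume$origin) else sm
}

#' Multiresolution pyramid of a volume
#'
#' Level 1 is the original volume; each subsequent level is smoothed with a
#' Gaussian of 1 voxel and decimated by a factor of 2 per axis (voxels at
#' even 0-based indices are kept, so level-`l` voxel `i` sits at level-1
#' voxel `2^(l-1) * i`). Spacing doubles per level.
#'
#' @param volume a [volume3d()] object.
#' @param levels number of levels (>= 1); the coarsest level must keep at
#'   least 4 voxels per axis.
#' @return A list of [volume3d()] objects, finest first.
#' @export
build_pyramid <- function(volume, levels) {
  stopifnot(is_volume(volume), levels >= 1)
  d <- dim(volume$data)
  if (any(ceiling(d / 2^(levels - 1)) < 4))
    stop("too many pyramid levels (", levels, ") for a ",
         paste(d, collapse = "x"), " volume: coarsest level would drop ",
         "below 4 voxels per axis")
  out <- vector("list", levels)
  out[[1]] <- volume
  for (l in seq_len(levels - 1L)) {
    prev <- out[[l]]
    sm <- gaussian_smooth_volume(prev, 1)
    dp <- dim(prev$data)
    idx <- lapply(dp, function(n) seq(1L, n, by = 2L))
    out[[l + 1]] <- volume3d(sm$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
                             prev$spacing * 2, prev$origin)
  }
  out
}

#' Upsample a displacement field to the next finer pyramid level
#'
#' Components are trilinearly interpolated onto the target grid (fine voxel
#' `i` maps to coarse coordinate `i / 2`) and vector magnitudes are doubled,
#' converting voxel units from the coarse to the fine grid.
#'
#' @param field a [displacement_field()] at the coarser level.
#' @param target_shape integer length-3, dimensions of the finer grid
#'   (approximately twice the source dimensions).
#' @return A [displacement_field()] on the finer grid.
#' @export
upsample_field <- function(field, target_shape) {
  stopifnot(is_field(field), length(target_shape) == 3L)
  d <- dim(field$v)[1:3]
  nd <- as.integer(target_shape)
  ax <- lapply(1:3, function(a) (seq_len(nd[a]) - 1) / 2)
  xs <- rep(ax[[1]], times = nd[2] * nd[3])
  ys <- rep(rep(ax[[2]], each = nd[1]), times = nd[3])
  zs <- rep(ax[[3]], each = nd[1] * nd[2])
  out <- array(0, c(nd, 3L))
  for (c in 1:3) {
    out[, , , c] <- 2 * array(cpp_trilinear(as.vector(field$v[, , , c]), d,
                                            xs, ys, zs), nd)
  }
  displacement_field(out, field$spacing / 2, field$origin)
}

# finite differences along one axis: central interior, one-sided borders
diff_axis <- function(a, axis) {
  d <- dim(a)
  n <- d[axis]
  idx_p <- pmin(seq_len(n) + 1L, n)
  idx_m <- pmax(seq_len(n) - 1L, 1L)
  den <- idx_p - idx_m # 2 interior, 1 at the two borders
  pick <- function(i) {
    switch(axis,
           a[i, , , drop = FALSE],
           a[, i, , drop = FALSE],
           a[, , i, drop = FALSE])
  }
  g <- (pick(idx_p) - pick(idx_m))
  sweepden <- switch(axis,
                     array(rep(den, times = d[2] * d[3]), d),
                     array(rep(rep(den, each = d[1]), times = d[3]), d),
                     array(rep(den, each = d[1] * d[2]), d))
  array(g, d) / sweepden
}

#' Spatial gradient of a volume
#'
#' Central differences in the interior, one-sided at the borders, in
#' voxel units (intensity change per voxel step).
#'
#' @param volume a [volume3d()] or 3-D array.
#' @return A 4-D array `c(dim, 3)` with the x, y, z derivative components.
#' @export
spatial_gradient <- function(volume) {
  a <- vol_data(volume)
  d <- dim(a)
  out <- array(0, c(d, 3L))
  for (axis in 1:3) out[, , , axis] <- diff_axis(a, axis)
  out
}

#' Jacobian determinant of the transformation carried by a field
#'
#' Computes `det(grad phi)` with `phi(x) = x + u(x)` (finite differences in
#' voxel units). Values of 1 indicate local volume preservation; values
#' less than or equal to 0 indicate folding.
#'
#' @param field a [displacement_field()].
#' @return A [volume3d()] of determinant values.
#' @export
jacobian_determinant <- function(field) {
  stopifnot(is_field(field))
  d <- dim(field$v)[1:3]
  J <- vector("list", 9L)
  for (comp in 1:3) {
    for (axis in 1:3) {
      g <- diff_axis(field$v[, , , comp], axis)
      if (comp == axis) g <- g + 1
      J[[(comp - 1L) * 3L + axis]] <- g
    }
  }
  # rows = component, cols = derivative axis
  det <- J[[1]] * (J[[5]] * J[[9]] - J[[6]] * J[[8]]) -
    J[[2]] * (J[[4]] * J[[9]] - J[[6]] * J[[7]]) +
    J[[3]] * (J[[4]] * J[[8]] - J[[5]] * J[[7]])
  volume3d(det, field$spacing, field$origin)
}

#' Read/write displacement fields
#'
#' Fields are persisted as 4-D volumes with three components: NIfTI stores
#' an `(nx, ny, nz, 3)` array; MetaImage stores a 3-channel image
#' (`ElementNumberOfChannels = 3`). Components are in voxel units.
#'
#' @param path file path (`.nii`, `.nii.gz`, `.mha`, `.mhd`).
#' @return [read_field()] returns a [displacement_field()];
#'   [write_field()] returns `path` invisibly.
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- file_format(path)
  raw <- if (fmt == "nifti") nifti_read_raw(path) else meta_read_raw(path)
  a <- raw$data
  d <- dim(a)
  if (length(d) == 5L && d[4] == 1L) { # NIfTI vector convention nx,ny,nz,1,3
    a <- array(a, c(d[1:3], d[5]))
    d <- dim(a)
  }
  if (length(d) != 4L || d[4] != 3L)
    stop("expected a 3-component vector field in '", path, "', got dims ",
         paste(dim(raw$data), collapse = " x "))
  displacement_field(a, raw$spacing[1:3], raw$origin[1:3])
}

#' @rdname read_field
#' @param field a [displacement_field()].
#' @export
write_field <- function(field, path) {
  stopifnot(is_field(field))
  fmt <- file_format(path)
  if (fmt == "nifti") {
    nifti_write_raw(field$v, field$spacing, field$origin, path)
  } else {
    meta_write_raw(field$v, field$spacing, field$origin, path, nchannels = 3L)
  }
  invisible(path)
}
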