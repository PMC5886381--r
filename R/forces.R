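#' Symmetric SSD Demons force
#'
#' The compositive-Demons update direction for the (normalized) sum of
#' squared differences,
#' `f = (I_F - I_M o phi) / (||grad I||^2 + lambda kappa^2) * grad I`,
#' where `grad I = (grad I_F + grad(I_M o phi)) / 2` is the symmetric
#' gradient and `kappa = I_F - I_M o phi` acts as a local noise estimate.
#' The per-voxel step is bounded by `1 / (2 sqrt(lambda))` voxels. Voxels
#' whose denominator falls below `denom_floor` get zero force.
#'
#' @param fixed,moving [volume3d()] objects on one grid, intensity-
#'   normalized to a shared scale (see [normalize_intensity()]).
#' @param u current [displacement_field()] estimate.
#' @param lambda step-control weight (> 0).
#' @param denom_floor stability threshold for the denominator (> 0).
#' @return A [displacement_field()] holding the update (voxel units).
#' @export
ssd_symmetric_force <- function(fixed, moving, u, lambda = 1,
                                denom_floor = 1e-9) {
  stopifnot(is_volume(fixed), is_volume(moving), is_field(u),
            lambda > 0, denom_floor > 0)
  if (!same_grid(fixed, moving) ||
      !identical(dim(fixed$data), dim(u$v)[1:3]))
    stop("fixed, moving and field must share one grid")
  warped <- warp_volume(moving, u)
  res <- fixed$data - warped$data
  g <- (spatial_gradient(fixed$data) + spatial_gradient(warped$data)) / 2
  gn2 <- g[, , , 1]^2 + g[, , , 2]^2 + g[, , , 3]^2
  den <- gn2 + lambda * res^2
  s <- ifelse(den < denom_floor, 0, res / den)
  f <- g
  for (c in 1:3) f[, , , c] <- s * g[, , , c]
  displacement_field(f, u$spacing, u$origin)
}

#' Local-correlation-coefficient Demons force
#'
#' Similarity force for data with spatially varying intensity relations
#' (e.g. contrast-enhanced MRI): both images are standardized within cubic
#' box windows of radius `radius` (local mean subtracted, local standard
#' deviation divided out) and the pseudo-residual
#' `rho_residual = F_hat - rho * J_hat`, with `rho` the local correlation
#' coefficient, replaces the SSD residual in the Demons step
#' normalization. The force vanishes wherever the warped moving image is a
#' local affine function of the fixed image (LCC invariance), and shares
#' the `1 / (2 sqrt(lambda))` per-voxel bound with the SSD force. Voxels
#' with local variance below `denom_floor` in either image get zero force.
#'
#' This is an LCC-Demons-style ascent direction on the local correlation;
#' the exact windowed statistics are box means (truncated at borders).
#'
#' @inheritParams ssd_symmetric_force
#' @param radius LCC window radius in voxels (>= 1).
#' @return A [displacement_field()] holding the update (voxel units).
#' @export
lcc_force <- function(fixed, moving, u, lambda = 1, denom_floor = 1e-9,
                      radius = 4) {
  stopifnot(is_volume(fixed), is_volume(moving), is_field(u), radius >= 1,
            lambda > 0, denom_floor > 0)
  if (!same_grid(fixed, moving) ||
      !identical(dim(fixed$data), dim(u$v)[1:3]))
    stop("fixed, moving and field must share one grid")
  warped <- warp_volume(moving, u)
  Fv <- fixed$data
  Jv <- warped$data
  muF <- box_mean(Fv, radius); muJ <- box_mean(Jv, radius)
  vF <- box_mean(Fv^2, radius) - muF^2
  vJ <- box_mean(Jv^2, radius) - muJ^2
  cFJ <- box_mean(Fv * Jv, radius) - muF * muJ
  ok <- vF > denom_floor & vJ > denom_floor
  sF <- sqrt(pmax(vF, denom_floor))
  sJ <- sqrt(pmax(vJ, denom_floor))
  Fh <- (Fv - muF) / sF
  Jh <- (Jv - muJ) / sJ
  rho <- cFJ / (sF * sJ)
  res <- ifelse(ok, Fh - rho * Jh, 0)
  g <- (spatial_gradient(Fh) + spatial_gradient(Jh)) / 2
  gn2 <- g[, , , 1]^2 + g[, , , 2]^2 + g[, , , 3]^2
  den <- gn2 + lambda * res^2
  s <- ifelse(den < denom_floor, 0, res / den)
  f <- g
  for (c in 1:3) f[, , , c] <- s * g[, , , c]
  displacement_field(f, u$spacing, u$origin)
}
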