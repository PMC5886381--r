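#' Box mean over a cubic window
#'
#' Mean over the `(2r+1)^3` cube centred at each voxel, truncated at the
#' volume borders and normalized by the true in-bounds count. Computed in
#' O(N) by axis-wise running sums; this is the primitive that makes guided
#' filtering linear-time.
#'
#' @param volume a [volume3d()] or numeric 3-D array.
#' @param r window radius in voxels (>= 1 for filtering; `0` is allowed and
#'   is the identity).
#' @return Same type as the input.
#' @export
box_mean <- function(volume, r) {
  a <- vol_data(volume)
  stopifnot(length(dim(a)) == 3L, r >= 0)
  if (r == 0) return(volume)
  s <- array(cpp_box_sum(as.vector(a), dim(a), as.integer(r)), dim(a))
  m <- s / box_counts(dim(a), r)
  if (is_volume(volume)) volume3d(m, volume$spacing, volume$origin) else m
}

# number of in-bounds voxels in each truncated window (outer product of
# per-axis counts)
box_counts <- function(dims, r) {
  cnt1 <- function(n) {
    i <- seq_len(n) - 1
    pmin(i + r, n - 1) - pmax(i - r, 0) + 1
  }
  cx <- cnt1(dims[1]); cy <- cnt1(dims[2]); cz <- cnt1(dims[3])
  array(outer(outer(cx, cy), cz), dims)
}

#' Multichannel guidance image
#'
#' Bundles `M >= 1` scalar channels (each a 3-D array on a common grid,
#' values in `[0, 1]`) that jointly shape the guided-filter kernels. Channels
#' typically come from supervoxel mean-intensity renderings
#' ([build_random_guidance()], [build_multiscale_guidance()]), but any
#' `[0, 1]` volume can serve.
#'
#' @param channels a list of 3-D arrays or [volume3d()] objects with equal
#'   dimensions and values in `[0, 1]`, or a single such array/volume.
#' @param spacing,origin grid metadata (defaults taken from the first
#'   channel when it is a volume).
#' @return An object of class `gf_guidance` with fields `channels`
#'   (list of arrays), `spacing`, `origin`. Filter statistics are cached
#'   internally per `(r, epsilon)`.
#' @export
guidance_image <- function(channels, spacing = NULL, origin = NULL) {
  if (!is.list(channels)) channels <- list(channels)
  if (length(channels) < 1L) stop("guidance needs at least one channel")
  if (is.null(spacing))
    spacing <- if (is_volume(channels[[1]])) channels[[1]]$spacing else c(1, 1, 1)
  if (is.null(origin))
    origin <- if (is_volume(channels[[1]])) channels[[1]]$origin else c(0, 0, 0)
  arrs <- lapply(channels, vol_data)
  d <- dim(arrs[[1]])
  for (a in arrs) {
    if (!identical(dim(a), d)) stop("guidance channels must share one grid")
    if (any(!is.finite(a))) stop("guidance channels must be finite")
    if (min(a) < -1e-9 || max(a) > 1 + 1e-9)
      stop("guidance channels must be normalized to [0, 1]")
  }
  structure(list(channels = arrs, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), cache = new.env(parent = emptyenv())),
            class = "gf_guidance")
}

#' @export
print.gf_guidance <- function(x, ...) {
  cat("<gf_guidance> ", length(x$channels), " channel(s), ",
      paste(dim(x$channels[[1]]), collapse = " x "), " voxels\n", sep = "")
  invisible(x)
}

is_guidance <- function(x) inherits(x, "gf_guidance")

as_guidance <- function(x) {
  if (is_guidance(x)) x else guidance_image(x)
}

# Window statistics of a guidance image that do not depend on the filter
# input: channel means and the per-voxel inverse of (Sigma + epsilon I).
# Cached on the guidance object since registration filters the same
# guidance hundreds of times.
gif_stats <- function(g, r, epsilon) {
  key <- paste0("r", r, "_e", format(epsilon, digits = 17))
  if (!is.null(g$cache[[key]])) return(g$cache[[key]])
  M <- length(g$channels)
  d <- dim(g$channels[[1]])
  n <- prod(d)
  mu <- lapply(g$channels, function(ch) as.vector(box_mean(ch, r)))
  chv <- lapply(g$channels, as.vector)
  if (M == 1L) {
    var1 <- as.vector(box_mean(array(chv[[1]]^2, d), r)) - mu[[1]]^2
    st <- list(M = 1L, d = d, mu = mu, ch = chv, inv = 1 / (var1 + epsilon))
  } else {
    A <- matrix(0, n, M * M)
    for (k in seq_len(M)) {
      for (l in k:M) {
        cov_kl <- as.vector(box_mean(array(chv[[k]] * chv[[l]], d), r)) -
          mu[[k]] * mu[[l]]
        if (k == l) cov_kl <- cov_kl + epsilon
        A[, (l - 1L) * M + k] <- cov_kl
        if (l != k) A[, (k - 1L) * M + l] <- cov_kl
      }
    }
    inv <- cpp_invert_batch(A, M)
    st <- list(M = M, d = d, mu = mu, ch = chv, inv = inv)
  }
  g$cache[[key]] <- st
  st
}

gif_filter_stats <- function(st, p, r, epsilon) {
  d <- st$d
  pv <- as.vector(vol_data(p))
  mp <- as.vector(box_mean(array(pv, d), r))
  M <- st$M
  if (M == 1L) {
    cov1 <- as.vector(box_mean(array(st$ch[[1]] * pv, d), r)) - st$mu[[1]] * mp
    a <- cov1 * st$inv
    b <- mp - a * st$mu[[1]]
    out <- as.vector(box_mean(array(a, d), r)) * st$ch[[1]] +
      as.vector(box_mean(array(b, d), r))
    return(array(out, d))
  }
  covs <- vector("list", M)
  for (l in seq_len(M)) {
    covs[[l]] <- as.vector(box_mean(array(st$ch[[l]] * pv, d), r)) -
      st$mu[[l]] * mp
  }
  b <- mp
  out <- 0
  for (k in seq_len(M)) {
    a_k <- 0
    for (l in seq_len(M)) a_k <- a_k + st$inv[, (l - 1L) * M + k] * covs[[l]]
    b <- b - a_k * st$mu[[k]]
    out <- out + as.vector(box_mean(array(a_k, d), r)) * st$ch[[k]]
  }
  out <- out + as.vector(box_mean(array(b, d), r))
  array(out, d)
}

#' Guided image filtering (single- or multichannel guidance)
#'
#' Edge-preserving linear-time filter: within every window the output is the
#' best local linear function of the guidance,
#' `gamma = cov(g, p) / (var(g) + epsilon)`, `beta = mean(p) - gamma mean(g)`
#' (multichannel: `Gamma = (Sigma + epsilon U)^{-1} cov(g, p)`), and the
#' per-voxel output averages `gamma g(x) + beta` over all windows containing
#' the voxel. Windows are truncated at borders with true-count
#' normalization, so kernel weights always sum to 1 and constants are fixed
#' points.
#'
#' @param guidance a [guidance_image()], [volume3d()] or 3-D array
#'   (values in `[0, 1]`).
#' @param input a [volume3d()] or 3-D array to be filtered (same grid).
#' @param r window radius in voxels (window width `2r + 1`).
#' @param epsilon regularization / edge-preservation parameter (> 0);
#'   small values preserve guidance edges, large values approach a plain
#'   double box mean.
#' @return Same type as `input`.
#' @export
guided_filter <- function(guidance, input, r, epsilon) {
  stopifnot(r >= 1, epsilon > 0)
  g <- as_guidance(guidance)
  d <- dim(vol_data(input))
  if (!identical(d, dim(g$channels[[1]])))
    stop("guidance grid does not match input grid")
  st <- gif_stats(g, r, epsilon)
  out <- gif_filter_stats(st, input, r, epsilon)
  if (is_volume(input)) volume3d(out, input$spacing, input$origin) else out
}

#' Explicit guided-filter kernel weights at one voxel
#'
#' Direct evaluation of the aggregated kernel
#' `W(x, y) = (1/N_x) * sum over windows w containing both x and y of
#' (1/|w|) * (1 + (g(x) - mu_w) (g(y) - mu_w) / (sigma_w^2 + epsilon))`
#' (multichannel: quadratic form with `(Sigma_w + epsilon U)^{-1}`), where
#' `N_x` is the number of windows containing `x`. This is the slow,
#' explicit form of the filter that [guided_filter()] computes via box
#' filters; the weights at any voxel sum to 1.
#'
#' @param guidance a [guidance_image()], [volume3d()] or 3-D array.
#' @param x integer length-3, 1-based voxel index.
#' @param r window radius in voxels.
#' @param epsilon regularization parameter (> 0).
#' @return A 3-D array of weights (zero outside the `2r`-reachable
#'   neighbourhood of `x`).
#' @export
explicit_kernel_weights <- function(guidance, x, r, epsilon) {
  g <- as_guidance(guidance)
  d <- dim(g$channels[[1]])
  x <- as.integer(x)
  stopifnot(length(x) == 3L, all(x >= 1L), all(x <= d))
  M <- length(g$channels)
  W <- array(0, d)
  gx <- vapply(g$channels, function(ch) ch[x[1], x[2], x[3]], numeric(1))
  # window centers k whose (truncated) window contains x: |k - x| <= r
  kr <- lapply(1:3, function(a) max(1L, x[a] - r):min(d[a], x[a] + r))
  Nx <- length(kr[[1]]) * length(kr[[2]]) * length(kr[[3]])
  for (k3 in kr[[3]]) for (k2 in kr[[2]]) for (k1 in kr[[1]]) {
    w1 <- max(1L, k1 - r):min(d[1], k1 + r)
    w2 <- max(1L, k2 - r):min(d[2], k2 + r)
    w3 <- max(1L, k3 - r):min(d[3], k3 + r)
    nw <- length(w1) * length(w2) * length(w3)
    vals <- lapply(g$channels, function(ch) as.vector(ch[w1, w2, w3]))
    mu <- vapply(vals, mean, numeric(1))
    if (M == 1L) {
      s2 <- mean(vals[[1]]^2) - mu[1]^2
      q <- (gx[1] - mu[1]) * (vals[[1]] - mu[1]) / (s2 + epsilon)
    } else {
      Sig <- matrix(0, M, M)
      for (a in seq_len(M)) for (b in seq_len(M))
        Sig[a, b] <- mean(vals[[a]] * vals[[b]]) - mu[a] * mu[b]
      inv <- solve(Sig + epsilon * diag(M))
      dx <- gx - mu
      dy <- do.call(rbind, lapply(seq_len(M), function(a) vals[[a]] - mu[a]))
      q <- as.vector((dx %*% inv) %*% dy)
    }
    W[w1, w2, w3] <- W[w1, w2, w3] +
      array((1 + q) / (Nx * nw), c(length(w1), length(w2), length(w3)))
  }
  W
}

#' Guided-filter regularization of a displacement field
#'
#' Filters the three displacement components independently with
#' [guided_filter()], transferring the guidance's structure (e.g. supervoxel
#' boundaries at a sliding interface) into the field while smoothing
#' homogeneous regions. This replaces the Gaussian convolution step of
#' classical Demons.
#'
#' @param u a [displacement_field()].
#' @param guidance a [guidance_image()] (or single volume) on `u`'s grid.
#' @param r window radius in voxels.
#' @param epsilon edge-preservation parameter (> 0).
#' @return The regularized [displacement_field()].
#' @export
regularize_field <- function(u, guidance, r, epsilon) {
  stopifnot(is_field(u))
  g <- as_guidance(guidance)
  if (!identical(dim(u$v)[1:3], dim(g$channels[[1]])))
    stop("guidance grid does not match field grid")
  st <- gif_stats(g, r, epsilon)
  out <- u$v
  for (c in 1:3) {
    out[, , , c] <- gif_filter_stats(st, u$v[, , , c], r, epsilon)
  }
  displacement_field(out, u$spacing, u$origin)
}
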