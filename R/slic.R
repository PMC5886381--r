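#' SLIC joint spatial-intensity distance
#'
#' `D = sqrt((d_xw / S)^2 + (d_I / m)^2)`: the spatial distance is
#' normalized by the sampling interval `S` and the intensity distance by
#' the compactness weight `m`. Larger `m` yields more compact (spatially
#' regular) clusters; smaller `m` makes clusters follow intensity edges.
#'
#' @param d_xw Euclidean spatial distance to the cluster center (voxels).
#' @param d_I absolute intensity difference to the cluster center.
#' @param S sampling interval `(N / K)^(1/3)` (voxels, > 0).
#' @param m compactness weight (> 0), on the same scale as `d_I`.
#' @return The combined distance (vectorized over the inputs).
#' @export
slic_distance <- function(d_xw, d_I, S, m) {
  stopifnot(S > 0, m > 0)
  sqrt((d_xw / S)^2 + (d_I / m)^2)
}

# evaluate expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.gf_slic <- function(x, ...) {
  cat("<gf_slic> ", max(x$labels), " supervoxels over ",
      paste(dim(x$labels), collapse = " x "), " voxels (S = ",
      signif(x$S, 4), ")\n", sep = "")
  invisible(x)
}

#' SLIC supervoxel clustering of a 3-D volume
#'
#' k-means-like clustering in joint spatial + intensity space
#' ([slic_distance()]): seeds start on a regular grid with interval
#' `S = (N / K)^(1/3)`, are optionally perturbed by
#' `N(mu_z, sigma_z^2)` per coordinate, and are snapped to the
#' lowest-gradient voxel of their 3x3x3 neighbourhood. Voxels are assigned
#' to the nearest center within a `2S` search window, centers (position and
#' mean intensity) are recomputed, and iterations stop when labels no
#' longer change or after `i_max` iterations. Connectivity of each label is
#' enforced afterwards ([enforce_connectivity()]).
#'
#' Intensities are min-max rescaled to `[0, 255]` internally so that the
#' compactness weight `m` keeps its conventional SLIC meaning regardless of
#' the volume's intensity scale (for a `[0, 1]`-normalized volume, `m = 24`
#' weighs an intensity difference of ~9.4% of the range like one sampling
#' interval of spatial distance).
#'
#' @param volume a [volume3d()] object.
#' @param K target number of supervoxels (1 <= K <= number of voxels).
#' @param m compactness weight on the internal 0-255 intensity scale
#'   (> 0; default 24).
#' @param i_max maximum number of assignment/update iterations.
#' @param sigma_z standard deviation (voxels) of the random seed
#'   perturbation; `0` disables it.
#' @param mu_z mean (voxels) of the seed perturbation.
#' @param seed integer RNG seed for the perturbation (`NULL` uses the
#'   current RNG state). With `sigma_z = 0` the result is deterministic
#'   regardless of seed.
#' @return An object of class `gf_slic`: `labels` (3-D integer array,
#'   values `1..K'`), `centers` (data frame with 0-based voxel coordinates
#'   `x`, `y`, `z` and mean `intensity` on the input scale), `S`, `K`,
#'   `spacing`, `origin`, `iterations`, `converged` (labels stopped
#'   changing before `i_max`), and `center_move` (largest center
#'   displacement, in voxels, of the final update — a convergence
#'   diagnostic; 0 when `converged`).
#' @export
slic_cluster <- function(volume, K, m = 24, i_max = 10, sigma_z = 0,
                         mu_z = 0, seed = NULL) {
  stopifnot(is_volume(volume), K >= 1, m > 0, i_max >= 1, sigma_z >= 0)
  d <- dim(volume$data)
  N <- prod(d)
  if (K > N) stop("K (", K, ") exceeds the number of voxels (", N, ")")
  rng <- range(volume$data)
  I255 <- if (rng[2] > rng[1])
    (volume$data - rng[1]) / (rng[2] - rng[1]) * 255 else
      array(0, d)
  S <- (N / K)^(1 / 3)
  nseed <- pmax(1L, as.integer(round(d / S)))
  pos <- lapply(1:3, function(a) (seq_len(nseed[a]) - 0.5) * d[a] / nseed[a] - 0.5)
  seeds <- as.matrix(expand.grid(pos[[1]], pos[[2]], pos[[3]]))
  if (sigma_z > 0) {
    seeds <- with_seed(seed, {
      seeds + matrix(stats::rnorm(length(seeds), mu_z, sigma_z), nrow(seeds), 3L)
    })
  }
  for (a in 1:3) seeds[, a] <- pmin(pmax(seeds[, a], 0), d[a] - 1)
  # snap each seed to the strictly lowest-gradient voxel of the 3^3 cube
  # around its nearest voxel; seeds keep their continuous position when no
  # neighbour strictly improves (ties must not shift the seed lattice)
  gmag <- {
    gr <- spatial_gradient(I255)
    sqrt(gr[, , , 1]^2 + gr[, , , 2]^2 + gr[, , , 3]^2)
  }
  for (s in seq_len(nrow(seeds))) {
    cc <- pmin(pmax(round(seeds[s, ]), 0), d - 1) + 1 # 1-based nearest voxel
    best <- gmag[cc[1], cc[2], cc[3]]
    bpos <- NULL
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      p <- cc + c(dx, dy, dz)
      if (any(p < 1) || any(p > d)) next
      v <- gmag[p[1], p[2], p[3]]
      if (v < best - 1e-12) { best <- v; bpos <- p }
    }
    if (!is.null(bpos)) seeds[s, ] <- bpos - 1
  }
  sidx <- pmin(pmax(round(seeds), 0), matrix(d - 1, nrow(seeds), 3,
                                             byrow = TRUE)) + 1
  centers0 <- cbind(seeds, I255[cbind(sidx[, 1], sidx[, 2], sidx[, 3])])
  res <- cpp_slic(as.vector(I255), d, centers0, S, m, as.integer(i_max))
  labels <- array(res$labels, d)
  min_size <- max(1L, as.integer(floor(S^3 / 4)))
  labels <- array(cpp_enforce_connectivity(as.vector(labels), d, min_size), d)
  out <- relabel_and_centers(labels, volume, S, K)
  out$iterations <- res$iterations
  out$converged <- res$converged
  out$center_move <- res$center_move
  out
}

# compact labels to 1..L (preserving order of label values) and recompute
# centers (mean 0-based position, mean intensity on the input scale)
relabel_and_centers <- function(labels, volume, S, K) {
  u <- sort(unique(as.vector(labels)))
  lab <- array(match(labels, u), dim(labels))
  d <- dim(lab)
  idx <- as.vector(lab)
  gx <- rep(seq_len(d[1]) - 1, times = d[2] * d[3])
  gy <- rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3])
  gz <- rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  cnt <- tabulate(idx, nbins = length(u))
  centers <- data.frame(
    x = as.vector(rowsum(gx, idx)) / cnt,
    y = as.vector(rowsum(gy, idx)) / cnt,
    z = as.vector(rowsum(gz, idx)) / cnt,
    intensity = as.vector(rowsum(as.vector(volume$data), idx)) / cnt
  )
  structure(list(labels = lab, centers = centers, S = S, K = K,
                 spacing = volume$spacing, origin = volume$origin),
            class = "gf_slic")
}

#' Enforce 26-connectivity of a supervoxel labeling
#'
#' Splits disconnected labels: the largest 26-connected component of each
#' label keeps it; fragments smaller than `S^3 / 4` voxels are merged into
#' the neighbouring component with the largest face contact; larger
#' detached fragments receive fresh labels. The partition property is
#' preserved and the operation is idempotent on connected labelings.
#'
#' @param labeling a `gf_slic` object (from [slic_cluster()]), or a 3-D
#'   integer array of labels.
#' @param volume the clustered [volume3d()] (required when `labeling` is a
#'   bare array, to recompute centers).
#' @param min_size fragment-size threshold; defaults to `S^3 / 4` for a
#'   `gf_slic` input.
#' @return A `gf_slic` object with connected labels (or a bare array when
#'   the input was one and `volume` is `NULL`).
#' @export
enforce_connectivity <- function(labeling, volume = NULL, min_size = NULL) {
  if (inherits(labeling, "gf_slic")) {
    if (is.null(min_size)) min_size <- max(1L, as.integer(floor(labeling$S^3 / 4)))
    d <- dim(labeling$labels)
    lab <- array(cpp_enforce_connectivity(as.vector(labeling$labels), d,
                                          as.integer(min_size)), d)
    vol <- volume %||% volume3d(array(0, d), labeling$spacing, labeling$origin)
    out <- relabel_and_centers(lab, vol, labeling$S, labeling$K)
    if (!is.null(volume)) return(out)
    out$centers$intensity <- NULL
    return(out)
  }
  a <- vol_data(labeling)
  if (is.null(min_size)) min_size <- 1L
  lab <- array(cpp_enforce_connectivity(as.integer(as.vector(a)), dim(a),
                                        as.integer(min_size)), dim(a))
  u <- sort(unique(as.vector(lab)))
  lab <- array(match(lab, u), dim(a))
  if (is.null(volume)) return(lab)
  relabel_and_centers(lab, volume, S = (length(a) / max(lab))^(1 / 3),
                      K = max(lab))
}

#' Render a supervoxel mean-intensity channel
#'
#' Replaces every voxel by the mean intensity of its supervoxel,
#' producing the piecewise-constant pseudo-segmentation image used as a
#' guidance channel. If the input volume lies outside `[0, 1]` it is
#' min-max rescaled first so the channel is always a valid guidance
#' channel.
#'
#' @param volume a [volume3d()] object.
#' @param labeling a `gf_slic` object (or 3-D integer label array) on the
#'   same grid.
#' @return A [volume3d()] with values in `[0, 1]`.
#' @export
render_channel <- function(volume, labeling) {
  stopifnot(is_volume(volume))
  lab <- if (inherits(labeling, "gf_slic")) labeling$labels else vol_data(labeling)
  if (!identical(dim(lab), dim(volume$data)))
    stop("labeling grid does not match volume grid")
  a <- volume$data
  rng <- range(a)
  if (rng[1] < 0 || rng[2] > 1) {
    a <- if (rng[2] > rng[1]) (a - rng[1]) / (rng[2] - rng[1]) else
      array(0, dim(a))
  }
  idx <- as.vector(lab)
  L <- max(idx)
  means <- as.vector(rowsum(as.vector(a), idx)) / tabulate(idx, nbins = L)
  volume3d(array(means[idx], dim(a)), volume$spacing, volume$origin)
}

#' Random-perturbation multichannel supervoxel guidance
#'
#' Runs SLIC `M` times with randomly perturbed initial cluster centers
#' (channel `i` uses seed `seed + i - 1`) and renders each run's
#' mean-intensity image as one guidance channel. In homogeneous regions the
#' channels disagree (so no single spurious supervoxel edge survives the
#' ensemble), while strong image edges are clustered consistently and are
#' preserved by the filter.
#'
#' @param volume a [volume3d()] object (typically the fixed image).
#' @param K target supervoxel count per channel.
#' @param M number of channels.
#' @param m compactness weight (see [slic_cluster()]).
#' @param sigma_z perturbation standard deviation in voxels; default
#'   `S / 4` where `S = (N / K)^(1/3)`.
#' @param mu_z perturbation mean in voxels.
#' @param i_max SLIC iteration cap.
#' @param seed base RNG seed; channel order is deterministic given `seed`.
#' @return A [guidance_image()] with `M` channels.
#' @export
build_random_guidance <- function(volume, K, M = 3, m = 24, sigma_z = NULL,
                                  mu_z = 0, i_max = 10, seed = 1L) {
  stopifnot(M >= 1)
  if (is.null(sigma_z)) sigma_z <- (prod(dim(volume$data)) / K)^(1 / 3) / 4
  chans <- vector("list", M)
  for (i in seq_len(M)) {
    cl <- slic_cluster(volume, K = K, m = m, i_max = i_max,
                       sigma_z = sigma_z, mu_z = mu_z,
                       seed = if (is.null(seed)) NULL else seed + i - 1L)
    chans[[i]] <- render_channel(volume, cl)
  }
  guidance_image(chans, volume$spacing, volume$origin)
}

#' Multiscale supervoxel guidance
#'
#' One unperturbed SLIC run per entry of `K_ladder`; each run's
#' mean-intensity rendering is one channel. Small-`K` channels encode
#' large, segmentation-like regions (global motion), large-`K` channels
#' encode fine structure, so filtering with the stack yields piecewise
#' smooth displacement fields across scales.
#'
#' @param volume a [volume3d()] object.
#' @param K_ladder strictly monotone vector of supervoxel counts, e.g.
#'   `c(3750, 1875, 937)`.
#' @param m compactness weight.
#' @param i_max SLIC iteration cap.
#' @return A [guidance_image()] with `length(K_ladder)` channels.
#' @export
build_multiscale_guidance <- function(volume, K_ladder, m = 24, i_max = 10) {
  stopifnot(length(K_ladder) >= 1)
  dk <- diff(K_ladder)
  if (length(dk) && !(all(dk > 0) || all(dk < 0)))
    stop("K_ladder must be strictly increasing or decreasing")
  chans <- lapply(K_ladder, function(K) {
    render_channel(volume, slic_cluster(volume, K = K, m = m, i_max = i_max,
                                        sigma_z = 0))
  })
  guidance_image(chans, volume$spacing, volume$origin)
}
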