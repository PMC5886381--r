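# Independent, deliberately naive reference implementations used as oracles.
# They share no code with the package's fast paths.

naive_box_mean <- function(a, r) {
  d <- dim(a)
  out <- array(0, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    out[i, j, k] <- mean(a[max(1, i - r):min(d[1], i + r),
                           max(1, j - r):min(d[2], j + r),
                           max(1, k - r):min(d[3], k + r)])
  }
  out
}

# trilinear interpolation at one 0-based coordinate with edge clamping
naive_trilinear1 <- function(a, x, y, z) {
  d <- dim(a)
  x <- min(max(x, 0), d[1] - 1)
  y <- min(max(y, 0), d[2] - 1)
  z <- min(max(z, 0), d[3] - 1)
  i0 <- min(floor(x), d[1] - 2); j0 <- min(floor(y), d[2] - 2)
  k0 <- min(floor(z), d[3] - 2)
  i0 <- max(i0, 0); j0 <- max(j0, 0); k0 <- max(k0, 0)
  fx <- x - i0; fy <- y - j0; fz <- z - k0
  acc <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    acc <- acc + w * a[i0 + dx + 1, j0 + dy + 1, k0 + dz + 1]
  }
  acc
}

# number of 26-connected components of each label, by breadth-first search
label_component_counts <- function(labels) {
  d <- dim(labels)
  seen <- array(FALSE, d)
  counts <- integer(max(labels))
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  idx_all <- which(!seen)
  for (start in seq_along(labels)) {
    if (seen[start]) next
    lab <- labels[start]
    counts[lab] <- counts[lab] + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ci <- arrayInd(cur, d)
      for (n in seq_len(nrow(nb))) {
        p <- ci + nb[n, ]
        if (any(p < 1) || any(p > d)) next
        li <- p[1] + (p[2] - 1) * d[1] + (p[3] - 1) * d[1] * d[2]
        if (!seen[li] && labels[li] == lab) {
          seen[li] <- TRUE
          queue <- c(queue, li)
        }
      }
    }
  }
  counts
}

# band-limited random volume normalized to [0, 1]
smooth_volume <- function(dims, sigma = 2, seed = 1) {
  set.seed(seed)
  a <- gaussian_smooth_volume(array(rnorm(prod(dims)), dims), sigma)
  volume3d((a - min(a)) / (max(a) - min(a)))
}

rand_volume <- function(dims, seed = 1) {
  set.seed(seed)
  volume3d(array(runif(prod(dims)), dims))
}

rand_field <- function(dims, scale = 1, sigma = 2, seed = 1) {
  set.seed(seed)
  v <- array(rnorm(prod(dims) * 3), c(dims, 3L))
  for (c in 1:3) v[, , , c] <- gaussian_smooth_volume(v[, , , c], sigma) * scale
  displacement_field(v / max(abs(v)) * scale)
}
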