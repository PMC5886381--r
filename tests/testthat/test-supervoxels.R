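test_that("SLIC distance combines normalized spatial and intensity terms", {
  expect_equal(sqrt(sum((c(3, 4, 0) - c(0, 0, 0))^2)), 5) # d_xw of the 3-4-5 case
  expect_equal(slic_distance(5, 0, S = 5, m = 2), 1)
  expect_equal(slic_distance(0, 4, S = 5, m = 2), 2)
  expect_equal(slic_distance(5, 4, S = 5, m = 2), sqrt(5), tolerance = 1e-12)
  expect_equal(slic_distance(5, 4, S = 5, m = 2), 2.2361, tolerance = 1e-4)
})

test_that("constant volume with K = 8 recovers the 2x2x2 block grid", {
  v <- volume3d(array(0.5, c(24, 24, 24)))
  cl <- slic_cluster(v, K = 8, m = 24)
  sizes <- tabulate(cl$labels)
  expect_equal(length(sizes), 8L)
  expect_true(all(abs(sizes - 1728) <= 0.1 * 1728))
})

test_that("labels partition the volume and clusters stay compact with huge m", {
  tv <- rand_volume(c(20, 20, 20), seed = 50)
  cl <- slic_cluster(tv, K = 27, m = 1e6)
  expect_true(all(tabulate(cl$labels) > 0))
  expect_equal(sum(tabulate(cl$labels)), 20^3)
  S <- cl$S
  for (l in seq_len(max(cl$labels))) {
    w <- which(cl$labels == l, arr.ind = TRUE)
    expect_lte(max(apply(w, 2, function(x) diff(range(x)) + 1)), 2 * S + 1)
  }
})

test_that("strong edges are never crossed for small compactness weights", {
  d <- c(24, 24, 24)
  z <- array(0, d); z[, , 13:24] <- 1
  v <- volume3d(z)
  cl <- slic_cluster(v, K = 64, m = 24) # m ~ 9.4% of the intensity range
  spans <- vapply(split(as.vector(z), as.vector(cl$labels)),
                  function(x) length(unique(x)), integer(1))
  expect_true(all(spans == 1L))
  # boundary recall: every interface voxel lies on a supervoxel boundary
  lab <- cl$labels
  boundary <- lab[, , 12] != lab[, , 13]
  expect_true(all(boundary))
})

test_that("SLIC center movement settles within the iteration budget", {
  tv <- smooth_volume(c(20, 20, 20), seed = 51)
  one <- slic_cluster(tv, K = 27, m = 24, i_max = 1)
  ten <- slic_cluster(tv, K = 27, m = 24, i_max = 10)
  expect_gt(one$center_move, 0.5) # a single sweep has not settled
  expect_lt(ten$center_move, 0.5) # residual movement after the default budget
  # with a generous budget the labels stop changing entirely
  full <- slic_cluster(tv, K = 27, m = 24, i_max = 60)
  expect_true(full$converged)
  expect_identical(full$labels,
                   slic_cluster(tv, K = 27, m = 24, i_max = 80)$labels)
})

test_that("connectivity enforcement yields one 26-connected component per label", {
  # already-connected labelings are unchanged
  lab <- array(1L, c(8, 8, 8)); lab[5:8, , ] <- 2L
  expect_identical(enforce_connectivity(lab, min_size = 8), lab)
  # a 2-voxel orphan island is absorbed by its surrounding label
  lab2 <- lab
  lab2[2:3, 2, 2] <- 2L
  fixed <- enforce_connectivity(lab2, min_size = 8)
  expect_identical(fixed, lab)
  # arbitrary noisy labelings come out connected (flood-fill oracle)
  set.seed(52)
  noisy <- array(sample(1:4, 12^3, TRUE), c(12, 12, 12))
  out <- enforce_connectivity(noisy, min_size = 10)
  expect_true(all(label_component_counts(out) == 1L))
  expect_equal(sum(tabulate(out) > 0), max(out)) # compact label ids
})

test_that("render_channel replaces voxels by supervoxel means", {
  v <- smooth_volume(c(10, 10, 10), seed = 53)
  one <- array(1L, c(10, 10, 10))
  rc <- render_channel(v, one)
  expect_equal(rc$data, array(mean(v$data), c(10, 10, 10)), tolerance = 1e-12)
  # two constant regions perfectly clustered reproduce the input
  d <- c(8, 8, 8)
  two <- volume3d(array(rep(c(0.2, 0.8), each = 256), d))
  lab <- array(rep(c(1L, 2L), each = 256), d)
  expect_equal(render_channel(two, lab)$data, two$data, tolerance = 1e-12)
  # group-by oracle on a real clustering
  cl <- slic_cluster(v, K = 20, m = 24)
  rc2 <- render_channel(v, cl)
  means <- tapply(as.vector(v$data), as.vector(cl$labels), mean)
  expect_equal(as.vector(rc2$data),
               as.vector(means[as.vector(cl$labels)]), tolerance = 1e-10)
})

test_that("random guidance: deterministic seeds, perturbation-driven diversity", {
  v <- smooth_volume(c(18, 18, 18), seed = 54)
  # sigma_z = 0 makes all channels identical
  g0 <- build_random_guidance(v, K = 27, M = 3, sigma_z = 0, seed = 5)
  expect_identical(g0$channels[[1]], g0$channels[[2]])
  expect_identical(g0$channels[[1]], g0$channels[[3]])
  expect_equal(length(g0$channels), 3L)
  # identical seeds are bit-exact
  g1 <- build_random_guidance(v, K = 27, M = 2, seed = 9)
  g2 <- build_random_guidance(v, K = 27, M = 2, seed = 9)
  expect_identical(g1$channels, g2$channels)
  # on a homogeneous noise volume, perturbed channels differ...
  hv <- rand_volume(c(18, 18, 18), seed = 55)
  gh <- build_random_guidance(hv, K = 27, M = 2, seed = 9)
  expect_false(identical(gh$channels[[1]], gh$channels[[2]]))
  # ...but a strong edge is clustered consistently in every channel
  d <- c(18, 18, 18)
  z <- array(0, d); z[, , 10:18] <- 1
  ge <- build_random_guidance(volume3d(z), K = 27, M = 2, seed = 9)
  for (ch in ge$channels) {
    expect_true(all(ch[, , 9] < 0.5) && all(ch[, , 10] > 0.5))
  }
})

test_that("multiscale guidance has one channel per K with decreasing granularity", {
  v <- smooth_volume(c(18, 18, 18), seed = 56)
  g1 <- build_multiscale_guidance(v, K_ladder = 40)
  expect_equal(length(g1$channels), 1L)
  ref <- render_channel(v, slic_cluster(v, K = 40, m = 24, sigma_z = 0))
  expect_identical(g1$channels[[1]], ref$data)
  g3 <- build_multiscale_guidance(v, K_ladder = c(64, 27, 8))
  counts <- vapply(g3$channels, function(ch) length(unique(as.vector(ch))),
                   integer(1))
  expect_true(all(diff(counts) < 0))
  cst <- volume3d(array(0.4, c(18, 18, 18)))
  gc <- build_multiscale_guidance(cst, K_ladder = c(27, 8))
  for (ch in gc$channels) expect_equal(length(unique(as.vector(ch))), 1L)
  expect_error(build_multiscale_guidance(v, K_ladder = c(10, 30, 20)),
               "monotone|increasing|decreasing")
})
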