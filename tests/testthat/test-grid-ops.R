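test_that("warping with the zero field is the identity", {
  v <- rand_volume(c(7, 8, 6), seed = 1)
  expect_identical(warp_volume(v, zero_field(v))$data, v$data)
})

test_that("warping a ramp by a constant displacement shifts it", {
  d <- c(10, 6, 6)
  ramp <- volume3d(array(rep(0:9, times = 36), d))
  f <- zero_field(ramp)
  f$v[, , , 1] <- 2
  w <- warp_volume(ramp, f)
  expect_equal(w$data[1:8, , ], ramp$data[1:8, , ] + 2, tolerance = 1e-12)
})

test_that("warp and composition match a naive per-voxel oracle", {
  v <- smooth_volume(c(9, 8, 7), seed = 4)
  u <- rand_field(c(9, 8, 7), scale = 1.5, seed = 5)
  w <- warp_volume(v, u)
  f2 <- rand_field(c(9, 8, 7), scale = 1.2, seed = 6)
  comp <- compose_fields(u, f2)
  set.seed(7)
  pts <- cbind(sample(1:9, 25, TRUE), sample(1:8, 25, TRUE),
               sample(1:7, 25, TRUE))
  for (p in seq_len(nrow(pts))) {
    i <- pts[p, 1]; j <- pts[p, 2]; k <- pts[p, 3]
    x <- i - 1 + u$v[i, j, k, 1]
    y <- j - 1 + u$v[i, j, k, 2]
    z <- k - 1 + u$v[i, j, k, 3]
    expect_equal(w$data[i, j, k], naive_trilinear1(v$data, x, y, z),
                 tolerance = 1e-6)
    xf <- i - 1 + f2$v[i, j, k, 1]
    yf <- j - 1 + f2$v[i, j, k, 2]
    zf <- k - 1 + f2$v[i, j, k, 3]
    for (c in 1:3) {
      expect_equal(comp$v[i, j, k, c],
                   f2$v[i, j, k, c] + naive_trilinear1(u$v[, , , c], xf, yf, zf),
                   tolerance = 1e-6)
    }
  }
})

test_that("composition has the zero field as identity and adds translations", {
  u <- rand_field(c(6, 6, 6), scale = 1, seed = 8)
  z <- zero_field(volume3d(array(0, c(6, 6, 6))))
  expect_equal(compose_fields(u, z)$v, u$v, tolerance = 0)
  a <- z; a$v[, , , 1] <- 1
  b <- z; b$v[, , , 1] <- 2
  expect_equal(compose_fields(a, b)$v[, , , 1],
               array(3, c(6, 6, 6)), tolerance = 0)
})

test_that("Gaussian field smoothing: identity at 0, constants fixed, impulse matches kernel", {
  u <- rand_field(c(6, 6, 6), seed = 9)
  expect_identical(gaussian_smooth_field(u, 0)$v, u$v)
  cst <- zero_field(volume3d(array(0, c(8, 8, 8))))
  cst$v[, , , 2] <- 4.5
  sm <- gaussian_smooth_field(cst, 1.7)
  expect_equal(sm$v, cst$v, tolerance = 1e-6)
  # unit impulse reproduces the separable sampled Gaussian
  d <- c(11, 11, 11)
  imp <- zero_field(volume3d(array(0, d)))
  imp$v[6, 6, 6, 1] <- 1
  sm2 <- gaussian_smooth_field(imp, 1)
  r <- 3L
  k1 <- exp(-(-r:r)^2 / 2); k1 <- k1 / sum(k1)
  expected <- outer(outer(k1, k1), k1)
  expect_equal(sm2$v[3:9, 3:9, 3:9, 1], expected, tolerance = 1e-4)
  expect_equal(max(abs(sm2$v[, , , 2])), 0)
})

test_that("pyramids halve dimensions and preserve constants", {
  v <- smooth_volume(c(32, 32, 32), seed = 10)
  expect_identical(build_pyramid(v, 1)[[1]]$data, v$data)
  p <- build_pyramid(v, 3)
  expect_equal(dim(p[[2]]$data), c(16, 16, 16))
  expect_equal(dim(p[[3]]$data), c(8, 8, 8))
  expect_equal(p[[3]]$spacing, v$spacing * 4)
  cst <- volume3d(array(0.3, c(16, 16, 16)))
  pc <- build_pyramid(cst, 2)
  expect_equal(pc[[2]]$data, array(0.3, c(8, 8, 8)), tolerance = 1e-12)
  expect_error(build_pyramid(cst, 4), "levels")
})

test_that("field upsampling doubles vectors and reconstructs smooth fields", {
  z <- zero_field(volume3d(array(0, c(6, 6, 6))))
  up <- upsample_field(z, c(12, 12, 12))
  expect_equal(max(abs(up$v)), 0)
  cst <- z; cst$v[, , , 1] <- 1
  upc <- upsample_field(cst, c(12, 12, 12))
  expect_equal(upc$v[, , , 1], array(2, c(12, 12, 12)), tolerance = 1e-12)
  # down-then-up of a band-limited field stays close
  u <- rand_field(c(16, 16, 16), scale = 2, sigma = 4, seed = 11)
  down <- displacement_field(u$v[seq(1, 16, 2), seq(1, 16, 2), seq(1, 16, 2), ,
                                  drop = FALSE] / 2)
  rec <- upsample_field(down, c(16, 16, 16))
  core <- 3:13
  rel <- max(abs(rec$v[core, core, core, ] - u$v[core, core, core, ])) /
    max(abs(u$v))
  expect_lt(rel, 0.1)
})

test_that("spatial gradients are exact for affine images and match finite differences", {
  cst <- array(2.5, c(6, 6, 6))
  expect_equal(max(abs(spatial_gradient(cst))), 0)
  d <- c(10, 7, 7)
  ramp <- array(rep(0:9 * 3, times = 49), d)
  g <- spatial_gradient(ramp)
  expect_equal(g[2:9, , , 1], array(3, c(8, 7, 7)), tolerance = 1e-12)
  expect_equal(max(abs(g[, , , 2:3])), 0)
  set.seed(12)
  a <- array(rnorm(6^3), c(6, 6, 6))
  ga <- spatial_gradient(a)
  # interior central difference, border one-sided
  expect_equal(ga[3, 4, 5, 1], (a[4, 4, 5] - a[2, 4, 5]) / 2)
  expect_equal(ga[1, 4, 5, 1], a[2, 4, 5] - a[1, 4, 5])
  expect_equal(ga[6, 4, 5, 1], a[6, 4, 5] - a[5, 4, 5])
  expect_equal(ga[3, 4, 2, 3], (a[3, 4, 3] - a[3, 4, 1]) / 2)
})

test_that("Jacobian determinant: 1 for translations, closed form for linear fields", {
  z <- zero_field(volume3d(array(0, c(7, 7, 7))))
  expect_equal(jacobian_determinant(z)$data, array(1, c(7, 7, 7)))
  tr <- z; tr$v[, , , 1] <- 3; tr$v[, , , 3] <- -1
  expect_equal(jacobian_determinant(tr)$data, array(1, c(7, 7, 7)),
               tolerance = 1e-12)
  lin <- z
  for (c in 1:3) lin$v[, , , c] <- 0.1 * (slice.index(lin$v[, , , c], c) - 1)
  jd <- jacobian_determinant(lin)$data
  expect_equal(jd[2:6, 2:6, 2:6], array(1.1^3, c(5, 5, 5)), tolerance = 1e-9)
})
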