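small_pair <- function(seed = 60, shift = 1.5) {
  fixed <- smooth_volume(c(20, 20, 20), sigma = 2, seed = seed)
  gen <- zero_field(fixed)
  gen$v[, , , 1] <- -shift
  moving <- warp_volume(fixed, gen)
  list(fixed = fixed, moving = moving, shift = shift)
}

test_that("one Demons iteration factorizes into force, composition, filtering", {
  p <- small_pair()
  u <- rand_field(c(20, 20, 20), scale = 0.5, seed = 61)
  ctl_iso <- demons_control(levels = 1, iter_max = 1, regularizer = "iso-dem",
                            K = 30)
  f <- ssd_symmetric_force(p$fixed, p$moving, u, ctl_iso$lambda,
                           ctl_iso$denom_floor)
  byhand_iso <- gaussian_smooth_field(compose_fields(u, f),
                                      ctl_iso$gaussian_sigma)
  expect_identical(demons_iteration(p$fixed, p$moving, u, NULL, ctl_iso)$v,
                   byhand_iso$v)
  g <- build_random_guidance(p$fixed, K = 30, M = 2, seed = 3)
  ctl_gif <- demons_control(levels = 1, iter_max = 1, regularizer = "rnd-gif",
                            K = 30)
  byhand_gif <- regularize_field(compose_fields(u, f), g, ctl_gif$r,
                                 ctl_gif$epsilon)
  expect_identical(demons_iteration(p$fixed, p$moving, u, g, ctl_gif)$v,
                   byhand_gif$v)
  expect_error(demons_iteration(p$fixed, p$moving, u, NULL, ctl_gif),
               "guidance")
})

test_that("identical inputs give a zero field; one iteration moves with the shift", {
  p <- small_pair()
  ctl <- demons_control(levels = 1, iter_max = 3, regularizer = "iso-dem")
  fit0 <- register_demons(p$fixed, p$fixed, ctl)
  expect_equal(max(abs(fit0$field$v)), 0)
  u1 <- demons_iteration(p$fixed, p$moving, zero_field(p$fixed), NULL, ctl)
  expect_gt(mean(u1$v[5:16, 5:16, 5:16, 1]), 0) # pulls toward +x, the true shift
})

test_that("convergence test thresholds the mean update norm", {
  z <- zero_field(volume3d(array(0, c(6, 6, 6))))
  expect_true(has_converged(z, z, tol = 1e-12))
  a <- z; a$v[, , , 1] <- 0.5
  expect_false(has_converged(a, z, tol = 0.1))
  b <- z; b$v[, , , 1] <- 0.005
  expect_true(has_converged(b, z, tol = 0.01))
})

test_that("multiresolution registration recovers a small translation", {
  p <- small_pair(seed = 62, shift = 1.5)
  ctl <- demons_control(levels = 2, iter_max = 20, regularizer = "iso-dem",
                        gaussian_sigma = 1.5)
  fit <- register_demons(p$fixed, p$moving, ctl)
  interior <- 5:16
  epe <- sqrt((fit$field$v[, , , 1] - p$shift)^2 +
                fit$field$v[, , , 2]^2 + fit$field$v[, , , 3]^2)
  expect_lt(mean(epe[interior, interior, interior]), 0.5)
  # residual shrinks
  expect_lt(mean(abs(residuals(fit)$data)),
            mean(abs(p$fixed$data - p$moving$data)))
})

test_that("fit methods expose field, warp, landmarks and diagnostics", {
  p <- small_pair(seed = 63)
  ctl <- demons_control(levels = 1, iter_max = 8, regularizer = "rnd-gif",
                        K = 40, r = 2)
  fit <- register_demons(p$fixed, p$moving, ctl)
  expect_s3_class(coef(fit), "gf_field")
  expect_identical(predict(fit)$data, fit$warped$data)
  expect_identical(predict(fit, p$moving)$data, fit$warped$data)
  lm <- data.frame(x = c(5, 10), y = c(10, 10), z = c(10, 5))
  moved <- predict(fit, lm)
  expect_equal(nrow(moved), 2L)
  expect_false(all(moved$x == lm$x))
  s <- summary(fit)
  expect_lt(s$residual_after, s$residual_before)
  expect_output(print(fit), "Demons registration")
  expect_output(print(s), "Jacobian")
  # plotting runs silently to a null device
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
})

test_that("mismatched grids and missing preprocessing are rejected", {
  a <- smooth_volume(c(12, 12, 12), seed = 64)
  b <- smooth_volume(c(12, 12, 14), seed = 64)
  expect_error(register_demons(a, b, demons_control(levels = 1)), "grid")
  c2 <- a; c2$spacing <- c(2, 2, 2)
  expect_error(register_demons(a, c2, demons_control(levels = 1)), "spacing")
})

test_that("registration is bit-reproducible for a fixed seed", {
  ph <- make_sliding_phantom(shape = c(32, 32, 32), slide_voxels = 3,
                             margin = 5, landmark_band = 8, n_landmarks = 5,
                             seed = 77)
  ctl <- demons_control(levels = 2, iter_max = 8, regularizer = "rnd-gif",
                        K = 60, seed = 42)
  f1 <- register_demons(ph$fixed, ph$moving, ctl)
  f2 <- register_demons(ph$fixed, ph$moving, ctl)
  expect_identical(f1$field$v, f2$field$v)
})
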