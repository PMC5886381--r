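test_that("the identity phantom has coinciding volumes and landmarks", {
  ph <- make_sliding_phantom(shape = c(32, 32, 32), slide_voxels = 0,
                             noise_sd = 0, bias_amplitude = 0, margin = 5,
                             landmark_band = 8, n_landmarks = 6, seed = 70)
  expect_identical(ph$moving$data, ph$fixed$data)
  expect_equal(as.matrix(ph$moving_landmarks[, 1:3]),
               as.matrix(ph$fixed_landmarks[, 1:3]), tolerance = 1e-12)
  expect_equal(max(abs(ph$true_field$v)), 0)
})

test_that("the true field carries the prescribed tangential discontinuity", {
  ph <- make_sliding_phantom(shape = c(48, 48, 48), slide_voxels = 6,
                             margin = 6, landmark_band = 10, n_landmarks = 6,
                             seed = 71)
  z0 <- ph$interface_position
  jump <- ph$true_field$v[24, 24, z0 + 1, 1] - ph$true_field$v[24, 24, z0, 1]
  expect_equal(jump, 6)
  expect_equal(max(abs(ph$true_field$v[, , , 2:3])), 0)
  expect_equal(interface_jump(ph$true_field, 3, z0, 1), 6, tolerance = 1e-12)
})

test_that("warping the moving volume through the true field recovers the fixed volume", {
  ph <- make_sliding_phantom(shape = c(48, 48, 48), slide_voxels = 5,
                             noise_sd = 0, margin = 6, landmark_band = 10,
                             n_landmarks = 6, seed = 72)
  w <- warp_volume(ph$moving, ph$true_field)
  # away from the interface mixing zone and the tapered inflow bands
  msk <- array(TRUE, c(48, 48, 48))
  z0 <- ph$interface_position
  msk[, , (z0 - 1):(z0 + 2)] <- FALSE
  msk[c(1:8, 41:48), , ] <- FALSE
  expect_lt(max(abs(w$data - ph$fixed$data)[msk]), 1e-6)
})

test_that("TRE reproduces hand values and the phantom's self-consistency", {
  vol <- volume3d(array(0, c(16, 16, 16)))
  z <- zero_field(vol)
  fl <- data.frame(x = 0, y = 0, z = 0, label = "a")
  ml <- data.frame(x = 3, y = 4, z = 0, label = "a")
  tre <- compute_tre(fl, ml, z)
  expect_equal(tre$mean, 5)
  expect_equal(tre$sd, NA_real_) # single point has no spread
  # a field mapping every landmark exactly has zero error
  f <- zero_field(vol); f$v[, , , 1] <- 3; f$v[, , , 2] <- 4
  expect_equal(compute_tre(fl, ml, f)$mean, 0, tolerance = 1e-12)
  # the phantom's own field on its own landmark pairs
  ph <- make_sliding_phantom(shape = c(40, 40, 40), slide_voxels = 4,
                             margin = 6, landmark_band = 9, n_landmarks = 10,
                             seed = 73)
  self <- compute_tre(ph$fixed_landmarks, ph$moving_landmarks, ph$true_field)
  expect_lt(self$mean, 0.25 * max(ph$fixed$spacing))
})

test_that("initial TRE equals the slide magnitude on the moving side", {
  ph <- make_sliding_phantom(shape = c(48, 48, 48), slide_voxels = 5,
                             margin = 6, landmark_band = 10, n_landmarks = 8,
                             seed = 74)
  tre0 <- compute_tre(ph$fixed_landmarks, ph$moving_landmarks,
                      zero_field(ph$fixed))
  moving_side <- grepl("upper", ph$fixed_landmarks$label)
  expect_equal(mean(tre0$per_point[moving_side]),
               5 * max(ph$fixed$spacing), tolerance = 1e-9)
  expect_equal(mean(tre0$per_point[!moving_side]), 0, tolerance = 1e-12)
})

test_that("landmarks outside the field domain are excluded with a warning", {
  vol <- volume3d(array(0, c(10, 10, 10)))
  z <- zero_field(vol)
  fl <- data.frame(x = c(2, 50), y = c(2, 2), z = c(2, 2))
  ml <- fl
  expect_warning(tre <- compute_tre(fl, ml, z), "excluded")
  expect_equal(length(tre$per_point), 1L)
  expect_equal(tre$n_excluded, 1L)
})

test_that("landmark placement fails loudly when a region is too thin", {
  expect_error(make_sliding_phantom(shape = c(24, 24, 24), margin = 10,
                                    interface_clear = 3, n_landmarks = 4),
               "too thin")
})

test_that("the benchmark table has one row per configuration plus the initial state", {
  ph <- make_sliding_phantom(shape = c(32, 32, 32), slide_voxels = 3,
                             margin = 5, landmark_band = 8, n_landmarks = 5,
                             seed = 75)
  configs <- list(
    iso = demons_control(levels = 1, iter_max = 5, regularizer = "iso-dem"),
    gif = demons_control(levels = 1, iter_max = 5, regularizer = "rnd-gif",
                         K = 60))
  csv <- file.path(tempdir(), "bench.csv")
  res <- run_benchmark(ph, configs, out_csv = csv)
  expect_equal(nrow(res), 3L)
  expect_equal(res$method, c("initial", "iso", "gif"))
  expect_true(all(res$tre_mean_mm[2:3] <= res$tre_mean_mm[1]))
  expect_true(file.exists(csv))
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), 3L)
  # failing configurations are recorded, not fatal
  bad <- list(boom = demons_control(levels = 6, iter_max = 2))
  res2 <- run_benchmark(ph, bad)
  expect_equal(nrow(res2), 2L)
  expect_true(is.na(res2$tre_mean_mm[2]))
  expect_match(res2$error[2], "levels")
})
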