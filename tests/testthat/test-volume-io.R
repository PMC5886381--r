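test_that("volumes round-trip through NIfTI and MetaImage losslessly", {
  set.seed(1)
  v <- volume3d(array(rnorm(8^3), c(8, 8, 8)),
                spacing = c(0.98, 0.98, 2.5), origin = c(10, -5, 2.5))
  for (ext in c("nii", "nii.gz", "mha", "mhd")) {
    path <- file.path(tempdir(), paste0("rt.", ext))
    write_volume(v, path)
    b <- read_volume(path)
    expect_equal(b$data, v$data, tolerance = 0, info = ext)
    expect_equal(b$spacing, v$spacing, tolerance = 1e-6, info = ext)
    expect_equal(b$origin, v$origin, tolerance = 1e-6, info = ext)
  }
})

test_that("NIfTI and MetaImage encodings of one array are voxel-identical", {
  v <- volume3d(array(seq_len(6^3) / 6^3, c(6, 6, 6)), spacing = c(2, 2, 2))
  p1 <- file.path(tempdir(), "x.nii.gz")
  p2 <- file.path(tempdir(), "x.mha")
  write_volume(v, p1)
  write_volume(v, p2)
  a <- read_volume(p1)
  b <- read_volume(p2)
  expect_identical(a$data, b$data)
  expect_equal(a$spacing, b$spacing)
})

test_that("non-finite intensities and wrong dimensionality are rejected", {
  expect_error(volume3d(array(c(NA, rep(0, 26)), c(3, 3, 3))), "finite")
  v <- volume3d(array(0, c(4, 4, 4)))
  v$data[1] <- NaN
  expect_error(write_volume(v, file.path(tempdir(), "bad.nii")), "finite")
  # a 3-component field file is not a scalar volume
  f <- zero_field(volume3d(array(0, c(5, 5, 5))))
  pf <- file.path(tempdir(), "field.nii.gz")
  write_field(f, pf)
  expect_error(read_volume(pf), "3-D|vector")
})

test_that("displacement fields round-trip as vector volumes", {
  f <- rand_field(c(6, 7, 5), scale = 2, seed = 3)
  for (ext in c("nii.gz", "mha")) {
    path <- file.path(tempdir(), paste0("f.", ext))
    write_field(f, path)
    g <- read_field(path)
    expect_equal(g$v, f$v, tolerance = 0, info = ext)
  }
})

test_that("landmark files parse with comments, commas and labels", {
  p <- file.path(tempdir(), "lm.txt")
  writeLines(c("# header comment", "0 0 0", "3, 4, 0 ankle", "", "1 2 3"), p)
  lm <- read_landmarks(p)
  expect_equal(nrow(lm), 3L)
  expect_equal(lm$x, c(0, 3, 1))
  expect_equal(lm$label[2], "ankle")
  # ~50 landmarks per case
  writeLines(sprintf("%d %d %d", 1:50, 51:100, 1:50), p)
  expect_equal(nrow(read_landmarks(p)), 50L)
  # parse errors report the offending line
  writeLines(c("1 2 3", "4 x 6"), p)
  expect_error(read_landmarks(p), "line 2")
})

test_that("landmarks round-trip through write_landmarks", {
  lm <- data.frame(x = c(1.5, 2), y = c(0, -3.25), z = c(9, 1),
                   label = c("a", "b"))
  p <- file.path(tempdir(), "lm2.txt")
  write_landmarks(lm, p)
  back <- read_landmarks(p)
  expect_equal(back$x, lm$x)
  expect_equal(back$z, lm$z)
  expect_equal(back$label, lm$label)
})

test_that("isotropic resampling preserves content and is idempotent", {
  # identity at the target spacing
  v <- smooth_volume(c(10, 10, 10), seed = 2)
  v$spacing <- c(2, 2, 2)
  r <- resample_isotropic(v, 2)
  expect_equal(r$data, v$data, tolerance = 1e-6)
  # dimension arithmetic: 10^3 at 4 mm -> about 20^3 at 2 mm
  v4 <- volume3d(array(0, c(10, 10, 10)), spacing = c(4, 4, 4))
  r2 <- resample_isotropic(v4, 2)
  expect_true(all(abs(dim(r2$data) - 20) <= 1))
  expect_equal(r2$spacing, c(2, 2, 2))
  # trilinear reproduces affine functions exactly
  d <- c(9, 9, 9)
  ramp <- volume3d(array(rep(0:8 * 3, times = 81), d), spacing = c(4, 4, 4))
  rr <- resample_isotropic(ramp, 2)
  expected <- (seq_len(dim(rr$data)[1]) - 1) * 2 / 4 * 3
  expect_equal(rr$data[, 3, 3], expected, tolerance = 1e-9)
  # second application changes nothing
  r3 <- resample_isotropic(rr, 2)
  expect_equal(r3$data, rr$data, tolerance = 1e-6)
})

test_that("intensity normalization clips to percentiles and maps to [0, 1]", {
  d <- c(5, 5, 4)
  v <- volume3d(array(0:99, d))
  n <- normalize_intensity(v, 0, 100)
  expect_equal(n$data, array(0:99 / 99, d))
  expect_true(min(n$data) >= 0 && max(n$data) <= 1)
  # constant volume degenerates to zeros with a warning
  expect_warning(z <- normalize_intensity(volume3d(array(7, c(4, 4, 4)))),
                 "degenerate")
  expect_true(all(z$data == 0))
  # hand-computed type-7 percentile: P75 of {0, 50, 100, 1000} is 325
  w <- volume3d(array(c(0, 50, 100, 1000, 0, 50, 100, 1000), c(2, 2, 2)))
  nw <- normalize_intensity(w, 0, 75)
  expect_equal(max(nw$data), 1) # 1000 clipped to 325 then mapped to 1
  expect_equal(sort(unique(as.vector(nw$data))),
               c(0, 50, 100, 325) / 325, tolerance = 1e-12)
})
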