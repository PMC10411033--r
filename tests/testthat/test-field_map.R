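test_that("field_map validates its invariants", {
  expect_error(field_map(matrix(1, 2, 2), spacing = c(1, -1)), "spacing")
  expect_error(field_map(matrix(c(-1, 1, 2, 3), 2, 2), modality = "SAR"),
               "negative")
  expect_error(field_map(matrix(1, 2, 2), mask = matrix(TRUE, 3, 3)),
               "shape")
  # NaN voxels drop out of the default mask
  v <- matrix(c(1, NaN, 3, 4), 2, 2)
  fm <- field_map(v, modality = "SAR")
  expect_equal(sum(fm$mask), 3L)
  expect_equal(mask_max(fm), 4)
  # temperature maps may be negative
  expect_silent(field_map(matrix(c(-3, 0, 2, 5), 2, 2), modality = "TEMP"))
})

test_that("tsv reader parses matrices, masks NaN, rejects bad input", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1 2", "3 4"), p)
  fm <- read_field_map(p, modality = "SAR")
  expect_equal(fm$values, matrix(c(1, 3, 2, 4), 2, 2))
  expect_true(all(fm$mask))
  expect_equal(mask_max(fm), 4)

  writeLines(c("1 2", "NaN 4"), p)
  fm <- read_field_map(p, modality = "SAR")
  expect_equal(sum(fm$mask), 3L)
  expect_false(fm$mask[2, 1])

  writeLines(c("1 2 3", "4 5"), p)
  expect_error(read_field_map(p, modality = "SAR"), "rectangular")

  writeLines(c("1 -2", "3 4"), p)
  expect_error(read_field_map(p, modality = "SAR"), "negative")
  expect_error(read_field_map(tempfile(), modality = "SAR"), "no such file")
})

test_that("write/read round-trips preserve values in both formats", {
  set.seed(101)
  v <- matrix(runif(256, 0, 9), 16, 16)
  fm <- field_map(v, spacing = c(2.88, 2.88), modality = "B1",
                  norm_power = 8)
  for (ext in c(".tsv", ".nii", ".nii.gz")) {
    p <- withr::local_tempfile(fileext = ext)
    write_field_map(fm, p)
    back <- read_field_map(p, modality = "B1", spacing = fm$spacing)
    expect_equal(back$values, v, tolerance = 1e-6)
    expect_true(all(back$mask))
  }
  # NIfTI header carries the spacing
  p <- withr::local_tempfile(fileext = ".nii")
  write_field_map(fm, p)
  expect_equal(read_field_map(p, modality = "B1")$spacing, c(2.88, 2.88),
               tolerance = 1e-6)
})

test_that("3D NIfTI volumes round-trip", {
  set.seed(7)
  v <- array(runif(16 * 12 * 3), dim = c(16, 12, 3))
  p <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(v, p, spacing = c(1.5, 1.5, 10))
  back <- read_nifti(p)
  expect_equal(dim(back), dim(v))
  expect_equal(as.vector(back), as.vector(v), tolerance = 1e-6)
  expect_equal(attr(back, "spacing"), c(1.5, 1.5, 10), tolerance = 1e-6)
})

test_that("block-average resampling conserves means and constants", {
  # constant map stays constant under any integer factor
  cm <- field_map(matrix(5, 12, 12), modality = "SAR")
  for (f in c(2, 3, 4)) {
    r <- resample_to_grid(cm, factor = f)
    expect_equal(unique(as.vector(r$values)), 5)
    expect_equal(dim(r$values), dim(cm$values) / f)
    expect_equal(r$spacing, cm$spacing * f)
  }
  # checkerboard halves to 0.5
  cb <- field_map(outer(1:4, 1:4, function(i, j) (i + j) %% 2),
                  modality = "SAR")
  expect_equal(as.vector(resample_to_grid(cb, factor = 2)$values),
               rep(0.5, 4))
  # full-mask mean conservation on random maps
  set.seed(11)
  for (rep in 1:5) {
    v <- matrix(runif(64), 8, 8)
    r <- resample_to_grid(field_map(v, modality = "SAR"), factor = 2)
    expect_equal(mean(r$values), mean(v), tolerance = 1e-12)
  }
})

test_that("resampling refuses upsampling and handles masks", {
  fm <- field_map(matrix(1, 8, 8), spacing = c(2, 2), modality = "SAR")
  expect_error(resample_to_grid(fm, factor = 0.5), "upsampling")
  # a masked source voxel excludes its target block from the mask
  v <- matrix(1, 8, 8)
  m <- matrix(TRUE, 8, 8); m[1, 1] <- FALSE
  r <- resample_to_grid(field_map(v, mask = m, modality = "SAR"), factor = 2)
  expect_false(r$mask[1, 1])
  expect_true(all(r$mask[-1]))
})

test_that("linear resampling approximates smooth fields on uneven grids", {
  v <- outer(seq_len(30), seq_len(30), function(i, j) i + 2 * j)
  fm <- field_map(v, spacing = c(1, 1), modality = "SAR")
  r <- resample_to_grid(fm, target = list(shape = c(13, 13),
                                          spacing = c(30 / 13, 30 / 13)))
  expect_equal(dim(r$values), c(13L, 13L))
  # linear field reproduced exactly away from clamped borders
  interior <- r$values[3:11, 3:11]
  expect_equal(max(abs(diff(interior[, 1]))), 30 / 13, tolerance = 1e-6)
  expect_equal(mean(r$values), mean(v), tolerance = 0.05)
})

test_that("erosion matches the brute-force neighborhood oracle", {
  expect_equal(erode_mask(matrix(TRUE, 10, 10), 0), matrix(TRUE, 10, 10))
  expect_equal(sum(erode_mask(matrix(TRUE, 10, 10), 1)), 64L)
  expect_equal(sum(erode_mask(matrix(TRUE, 3, 3), 2)), 0L)
  set.seed(21)
  for (rep in 1:10) {
    m <- matrix(runif(16 * 16) > 0.35, 16, 16)
    for (d in 1:2)
      expect_equal(erode_mask(m, d), erode_oracle(m, d),
                   info = sprintf("rep %d depth %d", rep, d))
  }
})

test_that("erosion composes: erode(erode(m, a), b) == erode(m, a + b)", {
  set.seed(31)
  for (rep in 1:8) {
    m <- matrix(runif(32 * 32) > 0.3, 32, 32)
    expect_equal(erode_mask(erode_mask(m, 1), 2), erode_mask(m, 3))
    expect_equal(erode_mask(erode_mask(m, 2), 1), erode_mask(m, 3))
  }
})

test_that("gaussian smoothing preserves constants, mass and range", {
  cm <- field_map(matrix(7, 9, 9), modality = "TEMP")
  expect_equal(mask_values(gaussian_smooth(cm)), rep(7, 81))
  # impulse mass conservation away from edges (kernel sums to 1)
  imp <- matrix(0, 9, 9); imp[5, 5] <- 3.5
  expect_equal(sum(gaussian_smooth(imp)), 3.5, tolerance = 1e-12)
  # variance never increases; output stays within input range
  set.seed(41)
  for (rep in 1:100) {
    v <- matrix(runif(100), 10, 10)
    sv <- gaussian_smooth(v)
    expect_lte(stats::var(as.vector(sv)), stats::var(as.vector(v)))
    expect_gte(min(sv), min(v))
    expect_lte(max(sv), max(v))
  }
  expect_error(gaussian_smooth(field_map(matrix(1, 2, 2), modality = "TEMP"),
                               kernel_size = 5), "larger")
  expect_error(gaussian_smooth(matrix(1, 5, 5), kernel_size = 4), "odd")
})

test_that("mask-aware smoothing ignores out-of-mask voxels", {
  v <- matrix(1, 7, 7)
  v[4, 4] <- 1000            # poisoned voxel, masked out
  m <- matrix(TRUE, 7, 7); m[4, 4] <- FALSE
  sm <- gaussian_smooth(field_map(v, mask = m, modality = "TEMP"))
  expect_equal(range(mask_values(sm)), c(1, 1))
})
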