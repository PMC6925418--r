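test_that("cohorts are a pure function of spec and seed", {
  spec <- cohort_spec(n_per_class = 3, seed = 7)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(lapply(a, function(x) x$image$voxels),
                   lapply(b, function(x) x$image$voxels))
  expect_identical(lapply(a, function(x) x$mask$voxels),
                   lapply(b, function(x) x$mask$voxels))
  expect_identical(vapply(a, function(x) x$split, character(1)),
                   vapply(b, function(x) x$split, character(1)))
  # a different seed changes the cohort
  c2 <- generate_cohort(cohort_spec(n_per_class = 3, seed = 8))
  expect_false(identical(a[[1]]$image$voxels, c2[[1]]$image$voxels))
})

test_that("lesions respect the dilation margin and stay star-shaped slices", {
  cases <- small_cohort(n_per_class = 3, seed = 2)
  for (cs in cases) {
    m <- cs$mask$voxels
    idx <- which(m, arr.ind = TRUE)
    d <- dim(m)
    # at least 7 voxels of in-plane margin so Dilation7 never clips
    expect_gte(min(idx[, 1]) - 1, 7)
    expect_gte(min(idx[, 2]) - 1, 7)
    expect_gte(d[1] - max(idx[, 1]), 7)
    expect_gte(d[2] - max(idx[, 2]), 7)
    # every occupied slice has foreground and slices form one contiguous range
    occ <- which(apply(m, 3, any))
    expect_identical(occ, seq(min(occ), max(occ)))
  }
})

test_that("oversized lesions are rejected with an explicit message", {
  expect_error(cohort_spec(n_per_class = 2, image_shape = c(32, 32, 12),
                           lesion_radius_range_vox = c(10, 14)),
               "cannot fit")
})

test_that("intensity effect shifts class-mean lesion intensity as configured", {
  spec <- cohort_spec(n_per_class = 30, intensity_effect = 3, seed = 11)
  cases <- generate_cohort(spec)
  mns <- vapply(cases, function(cs) mean(cs$image$voxels[cs$mask$voxels]),
                numeric(1))
  lab <- vapply(cases, function(cs) cs$class_label, integer(1))
  diff_sd <- (mean(mns[lab == 1]) - mean(mns[lab == 0])) / spec$noise_sd
  # the point-spread blur attenuates the shift a little at the lesion rim,
  # and n = 30 per class leaves Monte-Carlo error; both fit inside +/- 0.6
  expect_lt(abs(diff_sd - 3), 0.6)
})

test_that("zero effects make the classes exchangeable in lesion statistics", {
  cases <- generate_cohort(cohort_spec(n_per_class = 30, seed = 13))
  mns <- vapply(cases, function(cs) mean(cs$image$voxels[cs$mask$voxels]),
                numeric(1))
  lab <- vapply(cases, function(cs) cs$class_label, integer(1))
  expect_lt(abs(mean(mns[lab == 1]) - mean(mns[lab == 0])),
            3 * stats::sd(mns) / sqrt(15))
})

test_that("stratified split honours the validation fraction", {
  cases <- generate_cohort(cohort_spec(n_per_class = 20, seed = 3))
  split <- vapply(cases, function(x) x$split, character(1))
  lab <- vapply(cases, function(x) x$class_label, integer(1))
  for (l in 0:1)
    expect_equal(sum(split == "validation" & lab == l), 5)  # 0.25 * 20
  cases33 <- generate_cohort(cohort_spec(n_per_class = 12, seed = 3,
                                         validation_fraction = 0.33))
  split33 <- vapply(cases33, function(x) x$split, character(1))
  expect_equal(sum(split33 == "validation"), 8)  # round(0.33*12) per class
})

test_that("written cohorts round-trip through NIfTI and the manifest", {
  cases <- small_cohort(n_per_class = 2, seed = 5)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(cases, dir)
  man <- read.csv(manifest)
  expect_equal(nrow(man), 4)  # 2 * n_per_class
  back <- read_cohort(manifest)
  expect_equal(back[[1]]$image$voxels, cases[[1]]$image$voxels)
  expect_identical(back[[1]]$mask$voxels, cases[[1]]$mask$voxels)
  # spacing survives at NIfTI header (single) precision
  expect_equal(back[[1]]$image$spacing_mm, cases[[1]]$image$spacing_mm,
               tolerance = 1e-6)
  expect_identical(back[[1]]$split, cases[[1]]$split)
})
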