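test_that("geometric features recover analytic shapes", {
  mc <- array(FALSE, c(14, 14, 14))
  mc[3:12, 3:12, 3:12] <- TRUE
  g1 <- geometric_features(voi_mask(mc))
  expect_equal(unname(g1["volume_mm3"]), 1000)      # count x voxel volume
  expect_equal(unname(g1["solidity"]), 1)           # digital cube is convex
  expect_equal(unname(g1["eccentricity"]), 0)
  g2 <- geometric_features(voi_mask(mc, spacing_mm = c(2, 1, 1)))
  expect_equal(unname(g2["volume_mm3"]), 2000)      # spacing scaling
  # digital ball, radius 12, isotropic 1 mm
  gr <- expand.grid(x = 1:27, y = 1:27, z = 1:27)
  ball <- array((gr$x - 14)^2 + (gr$y - 14)^2 + (gr$z - 14)^2 <= 144,
                c(27, 27, 27))
  gb <- geometric_features(voi_mask(ball))
  expect_gte(unname(gb["solidity"]), 0.95)
  expect_lte(unname(gb["solidity"]), 1)
  expect_lte(unname(gb["eccentricity"]), 0.15)
  expect_equal(unname(gb["size_mm"]), 24, tolerance = 0.05)  # diameter 2r
})

test_that("degenerate coplanar masks fall back to solidity 1 with warning", {
  flat <- array(FALSE, c(6, 6, 3))
  flat[2:5, 2:5, 2] <- TRUE
  expect_warning(g <- geometric_features(voi_mask(flat)), "degenerate")
  expect_equal(unname(g["solidity"]), 1)
})

test_that("resampling at the native isotropic scale preserves values", {
  set.seed(10)
  arr <- array(rnorm(12^3), c(12, 12, 12))
  msk <- array(FALSE, c(12, 12, 12)); msk[4:9, 4:9, 4:9] <- TRUE
  res <- resample_isotropic(image_volume(arr), voi_mask(msk), 1)
  # the target grid lands on source voxel centers: values are copied
  expect_true(all(res$image$voxels %in% arr))
  expect_equal(sum(res$mask$voxels), sum(msk))
  # a constant lesion stays constant at any scale
  arr2 <- array(3.5, c(12, 12, 12))
  res2 <- resample_isotropic(image_volume(arr2), voi_mask(msk), 1.7)
  expect_true(all(abs(res2$image$voxels - 3.5) < 1e-12))
  # coarser grid shrinks the bounding box accordingly
  res3 <- resample_isotropic(image_volume(arr), voi_mask(msk), 2)
  expect_lte(max(abs(dim(res3$mask$voxels) - dim(res$mask$voxels) / 2)), 1)
})

test_that("quantization algorithms honour their bin definitions", {
  set.seed(2)
  v <- rnorm(100)  # 100 distinct values
  img <- image_volume(array(v, c(100, 1, 1)))
  msk <- voi_mask(array(TRUE, c(100, 1, 1)))
  qu <- quantize(img, msk, "Uniform", 8)
  expect_equal(qu$levels[which.min(v)], 1L)
  expect_equal(qu$levels[which.max(v)], 8L)
  qe <- quantize(img, msk, "Equal", 4)
  expect_true(all(abs(tabulate(qe$levels[qe$levels > 0], 4) - 25) <= 1))
  # Lloyd fixed point for two point masses: split at the midpoint
  x2 <- c(rep(1, 10), rep(5, 14))
  img2 <- image_volume(array(x2, c(24, 1, 1)))
  msk2 <- voi_mask(array(TRUE, c(24, 1, 1)))
  ql <- quantize(img2, msk2, "Lloyd", 2)
  expect_identical(as.integer(ql$levels[x2 == 1]), rep(1L, 10))
  expect_identical(as.integer(ql$levels[x2 == 5]), rep(2L, 14))
  # constant intensities: all level 1, with a warning
  imgc <- image_volume(array(2, c(10, 1, 1)))
  expect_warning(qc <- quantize(imgc, voi_mask(array(TRUE, c(10, 1, 1))),
                                "Uniform", 4), "constant")
  expect_true(all(qc$levels == 1L))
})

test_that("texture matrices match hand enumeration on minimal volumes", {
  q <- as_qvoi(array(c(1L, 2L), c(1, 1, 2)), 2)
  m <- build_texture_matrices(q)
  expect_equal(m$glcm, matrix(c(0, 0.5, 0.5, 0), 2))
  f <- texture_features(m, c(0, 1))
  expect_equal(unname(f["glcm.contrast"]), 1)
  expect_equal(unname(f["glcm.dissimilarity"]), 1)
  # constant-level VOI: single diagonal GLCM cell
  qc <- as_qvoi(array(1L, c(3, 3, 1)), 2)
  mc <- build_texture_matrices(qc)
  expect_equal(sum(mc$glcm), 1)
  expect_equal(mc$glcm[1, 1], 1)
  fc <- texture_features(mc, rep(2, 9))
  expect_equal(unname(fc["glcm.energy"]), 1)
  expect_equal(unname(fc["glcm.entropy"]), 0)
  expect_equal(unname(fc["glcm.contrast"]), 0)
  # single voxel: no pairs
  expect_error(build_texture_matrices(as_qvoi(array(1L, c(1, 1, 1)), 2)),
               "no voxel pairs")
})

test_that("run matrix along one direction matches the hand-counted runs", {
  q <- as_qvoi(array(c(1L, 1L, 1L, 2L), c(1, 1, 4)), 2)
  dz <- matrix(c(0L, 0L, 1L), 1)
  m <- build_texture_matrices(q, directions = dz)
  # one run of level 1, length 3; one run of level 2, length 1
  expected <- matrix(0L, 2, 3)
  expected[1, 3] <- 1L; expected[2, 1] <- 1L
  expect_equal(m$glrlm, expected)
  f <- texture_features(m, c(0, 0, 0, 1))
  expect_equal(unname(f["glrlm.sre"]), 0.5 / 9 + 0.5)  # from the 2-run matrix
  expect_equal(unname(f["glrlm.rp"]), 2 / 4)
})

test_that("compiled matrices equal brute-force enumeration oracles", {
  for (seed in 1:20) {
    rv <- random_level_volume(seed)
    q <- as_qvoi(rv$lev, rv$ng)
    m <- build_texture_matrices(q)
    og <- oracle_glcm(rv$lev, rv$ng)
    expect_equal(m$glcm, og, tolerance = 1e-12)
    orl <- oracle_glrlm(rv$lev, rv$ng)
    k <- max(ncol(orl), ncol(m$glrlm))
    expect_identical(pad_cols(m$glrlm, k), pad_cols(orl, k))
    osz <- oracle_glszm(rv$lev, rv$ng)
    k <- max(ncol(osz), ncol(m$glszm))
    expect_identical(pad_cols(m$glszm, k), pad_cols(osz, k))
    ond <- oracle_ngtdm(rv$lev, rv$ng)
    expect_equal(m$ngtdm$s, ond$s, tolerance = 1e-12)
    expect_identical(m$ngtdm$n, ond$n)
  }
})

test_that("GLCM is symmetric and normalized on every extraction", {
  for (seed in 21:25) {
    rv <- random_level_volume(seed)
    p <- build_texture_matrices(as_qvoi(rv$lev, rv$ng))$glcm
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(p, t(p), tolerance = 1e-12)
  }
})

test_that("feature vectors have the advertised length and are deterministic", {
  cs <- small_cohort(n_per_class = 1, seed = 6)[[1]]
  g1 <- extraction_grid(scales_mm = 2, algorithms = "Uniform",
                        gray_levels = 8)
  fv <- extract_features(cs$image, cs$mask, g1)
  expect_length(fv, 47)  # 4 geometric + 1 combination x 43
  expect_identical(names(fv), feature_names(g1))
  expect_true(all(is.finite(fv)))
  fv2 <- extract_features(cs$image, cs$mask, g1)
  expect_identical(fv, fv2)
})

test_that("features are invariant to whole-voxel translations", {
  cs <- small_cohort(n_per_class = 1, seed = 8)[[1]]
  arr <- cs$image$voxels
  msk <- cs$mask$voxels
  shift <- function(a, fill) {
    out <- array(fill, dim(a))
    out[4:dim(a)[1], 3:dim(a)[2], ] <- a[1:(dim(a)[1] - 3),
                                         1:(dim(a)[2] - 2), ]
    out
  }
  g <- accept_grid()
  f0 <- extract_features(cs$image, cs$mask, g)
  f1 <- extract_features(image_volume(shift(arr, 0), cs$image$spacing_mm),
                         voi_mask(shift(msk, FALSE), cs$mask$spacing_mm), g)
  expect_equal(f0, f1, tolerance = 1e-9)
})

test_that("texture features ignore constant intensity shifts", {
  cs <- small_cohort(n_per_class = 1, seed = 12)[[1]]
  g <- extraction_grid(scales_mm = c(1, 3), gray_levels = c(8, 16))
  f0 <- extract_features(cs$image, cs$mask, g)
  f1 <- extract_features(image_volume(cs$image$voxels + 100,
                                      cs$image$spacing_mm), cs$mask, g)
  expect_equal(f0, f1, tolerance = 1e-8)
})
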