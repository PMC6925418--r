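disk_mask <- function(r, n = 2 * r + 17, nz = 1) {
  g <- expand.grid(x = 1:n, y = 1:n)
  sl <- matrix((g$x - (n + 1) / 2)^2 + (g$y - (n + 1) / 2)^2 <= r^2, n, n)
  voi_mask(array(sl, c(n, n, nz)))
}

test_that("single-voxel dilation reproduces the exact Euclidean disk", {
  m <- array(FALSE, c(11, 11, 1))
  m[6, 6, 1] <- TRUE
  base <- voi_mask(m)
  d3 <- perturb_mask(base, "dilate", 3)
  expect_equal(sum(d3$voxels), 29)  # |{dx^2+dy^2 <= 9}| enumerated
  expect_equal(volume_ratio(d3, base), 29)
  expect_identical(d3$variant, "Dilation")
  # offsets are the same set the structuring element definition gives
  off <- expand.grid(dx = -3:3, dy = -3:3)
  expect_equal(sum(off$dx^2 + off$dy^2 <= 9), 29)
})

test_that("erosion with a disk larger than the slice empties it", {
  m <- array(TRUE, c(5, 5, 1))
  expect_warning(e <- perturb_mask(voi_mask(m), "erode", 3), "emptied")
  expect_equal(sum(e$voxels), 0)
  expect_true(isTRUE(attr(e, "empty_after_erosion")))
})

test_that("smoothing a constant slice is the identity", {
  m <- array(TRUE, c(9, 9, 2))
  s <- perturb_mask(voi_mask(m), "smooth")
  expect_identical(s$voxels, m)
  expect_identical(s$variant, "Smoothing")
})

test_that("smoothing perturbs large disks less (ratio -> 1 with radius)", {
  devs <- vapply(c(5, 10, 20), function(r) {
    b <- disk_mask(r)
    abs(volume_ratio(perturb_mask(b, "smooth"), b) - 1)
  }, numeric(1))
  expect_true(all(diff(devs) <= 0))
})

test_that("variants nest and volume ratios are monotone on synthetic cases", {
  for (cs in small_cohort(n_per_class = 1, seed = 4)) {
    v <- voi_variants(cs$mask)
    expect_true(all(v$Erosion$voxels <= v$Baseline$voxels))
    expect_true(all(v$Baseline$voxels <= v$Dilation$voxels))
    expect_true(all(v$Dilation$voxels <= v$Dilation5$voxels))
    expect_true(all(v$Dilation5$voxels <= v$Dilation7$voxels))
    r <- vapply(v, volume_ratio, numeric(1), baseline = cs$mask)
    expect_equal(unname(r["Baseline"]), 1)
    expect_lte(r["Erosion"], 1)
    expect_true(all(diff(r[c("Baseline", "Dilation", "Dilation5",
                             "Dilation7")]) >= 0))
  }
})

test_that("perturbation acts on each slice independently", {
  cs <- small_cohort(n_per_class = 1, seed = 9)[[1]]
  m <- cs$mask$voxels
  perm <- rev(seq_len(dim(m)[3]))
  permuted <- voi_mask(m[, , perm], cs$mask$spacing_mm)
  d_then_perm <- perturb_mask(cs$mask, "dilate", 5)$voxels[, , perm]
  perm_then_d <- perturb_mask(permuted, "dilate", 5)$voxels
  expect_identical(d_then_perm, perm_then_d)
})

test_that("margin distances read the bounding-rectangle edges", {
  b <- disk_mask(6)
  expect_true(all(as.matrix(margin_distances(b, b)[, -1]) == 0))
  d3 <- perturb_mask(b, "dilate", 3)
  md <- margin_distances(b, d3)
  expect_true(all(as.matrix(md[, c("up", "down", "left", "right")]) == 3))
  # a pure 2-pixel shift along the second axis moves only left/right
  m <- b$voxels
  shifted <- voi_mask(array(cbind(matrix(FALSE, nrow(m), 2),
                                  m[, 1:(ncol(m) - 2), 1]),
                           dim(m)))
  ms <- margin_distances(b, shifted)
  expect_true(all(ms$left == 2) && all(ms$right == 2))
  expect_true(all(ms$up == 0) && all(ms$down == 0))
})

test_that("margin distances require a shared nonempty slice", {
  a <- array(FALSE, c(6, 6, 2)); a[2:3, 2:3, 1] <- TRUE
  b <- array(FALSE, c(6, 6, 2)); b[2:3, 2:3, 2] <- TRUE
  expect_error(margin_distances(voi_mask(a), voi_mask(b)), "no slice")
})
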