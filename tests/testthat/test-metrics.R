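test_that("Dice matches set arithmetic on constructed and random masks", {
  dims <- c(6, 4, 3)
  a_arr <- array(0L, dims); a_arr[2:3, 2:3, 2] <- 1L # 2x2x1 block
  b_arr <- array(0L, dims); b_arr[3:4, 2:3, 2] <- 1L # shifted 1 voxel in x
  a <- label_volume(a_arr, c(1, 1, 1)); b <- label_volume(b_arr, c(1, 1, 1))
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 0.5)
  disjoint <- label_volume(array(c(rep(0L, 71), 1L), dims), c(1, 1, 1))
  expect_equal(dice(a, disjoint), 0)
  empty <- label_volume(array(0L, dims), c(1, 1, 1))
  expect_error(dice(empty, empty), "both masks are empty")
  for (s in 1:10) {
    x <- rand_mask(c(9, 8, 7), 0.3, seed = s)
    y <- rand_mask(c(9, 8, 7), 0.3, seed = s + 100)
    expect_equal(dice(x, y), brute_dice(x, y))
    expect_equal(dice(x, y), dice(y, x))
  }
})

test_that("Hausdorff distance agrees with direct and all-pairs oracles", {
  dims <- c(9, 3, 3)
  a_arr <- array(0L, dims); a_arr[2, 2, 2] <- 1L
  b_arr <- array(0L, dims); b_arr[7, 2, 2] <- 1L
  a <- label_volume(a_arr, c(1, 1, 1)); b <- label_volume(b_arr, c(1, 1, 1))
  expect_equal(hausdorff(a, a, "voxels"), 0)
  expect_equal(hausdorff(a, b, "voxels"), 5)

  # nested spheres radius 10 and 8: HD ~ 2 up to discretization
  big <- sphere_mask(c(25, 25, 25), c(13, 13, 13), 10)
  small <- sphere_mask(c(25, 25, 25), c(13, 13, 13), 8)
  hd <- hausdorff(big, small, "voxels")
  expect_lt(abs(hd - 2), 1)
  expect_equal(hd, brute_hd(big, small))

  empty <- label_volume(array(0L, dims), c(1, 1, 1))
  expect_error(hausdorff(a, empty), "empty mask")
})

test_that("average Hausdorff distance equals the brute-force oracle", {
  a_arr <- array(0L, c(9, 3, 3)); a_arr[2, 2, 2] <- 1L
  b_arr <- array(0L, c(9, 3, 3)); b_arr[7, 2, 2] <- 1L
  a <- label_volume(a_arr, c(1, 1, 1)); b <- label_volume(b_arr, c(1, 1, 1))
  expect_equal(average_hausdorff(a, a), 0)
  expect_equal(average_hausdorff(a, b), 5)
  x <- rand_mask(c(12, 12, 12), 0.25, seed = 3)
  y <- rand_mask(c(12, 12, 12), 0.25, seed = 103)
  expect_equal(average_hausdorff(x, y, "voxels"), brute_ahd(x, y),
               tolerance = 1e-12)
  # symmetric-mean variant is the mean of the two directed means
  expect_lte(average_hausdorff(x, y, combine = "mean"),
             average_hausdorff(x, y, combine = "max"))
})

test_that("distance metrics respect spacing and stay stable under dilation", {
  x <- rand_mask(c(10, 10, 10), 0.2, seed = 5, spacing = c(2, 2, 2))
  y <- rand_mask(c(10, 10, 10), 0.2, seed = 105, spacing = c(2, 2, 2))
  expect_equal(hausdorff(x, y, "mm"), 2 * hausdorff(x, y, "voxels"))
  expect_equal(average_hausdorff(x, y, "mm"),
               2 * average_hausdorff(x, y, "voxels"))
  # anisotropic mm distances match the all-pairs oracle
  xa <- rand_mask(c(10, 9, 8), 0.25, seed = 6, spacing = c(0.5, 0.5, 2))
  ya <- rand_mask(c(10, 9, 8), 0.25, seed = 106, spacing = c(0.5, 0.5, 2))
  expect_equal(hausdorff(xa, ya, "mm"), brute_hd(xa, ya, c(0.5, 0.5, 2)),
               tolerance = 1e-12)
  # dilating one argument by a voxel moves HD by at most the largest step
  hd0 <- hausdorff(x, y, "mm")
  hd1 <- hausdorff(x, dilate1(y), "mm")
  expect_lte(abs(hd1 - hd0), max(x$spacing) + 1e-9)
})

test_that("HD percentile and all-voxel support options behave sensibly", {
  x <- rand_mask(c(12, 12, 12), 0.3, seed = 9)
  y <- rand_mask(c(12, 12, 12), 0.3, seed = 109)
  expect_lte(hausdorff(x, y, percentile = 0.95), hausdorff(x, y))
  expect_gte(hausdorff(x, y, support = "all"), 0)
})

test_that("slicewise metrics average per-slice values with the stated policy", {
  dims <- c(6, 6, 4)
  a_arr <- array(0L, dims); b_arr <- array(0L, dims)
  a_arr[2:3, 2:3, 2] <- 1L; b_arr[2:3, 2:3, 2] <- 1L   # slice 2: DSC 1
  a_arr[2:3, 2:3, 3] <- 1L; b_arr[3:4, 2:3, 3] <- 1L   # slice 3: DSC 0.5
  a <- label_volume(a_arr, c(1, 1, 1)); b <- label_volume(b_arr, c(1, 1, 1))
  expect_equal(slicewise_metric(a, b, "DSC"), 0.75)
  expect_equal(slicewise_metric(a, a, "DSC"), 1)
  expect_equal(slicewise_metric(a, a, "HD"), 0)
  # single-slice volumes reduce to the 2D metric
  a1 <- label_volume(a_arr[, , 3, drop = FALSE], c(1, 1, 1))
  b1 <- label_volume(b_arr[, , 3, drop = FALSE], c(1, 1, 1))
  expect_equal(slicewise_metric(a1, b1, "DSC"), dice(a1, b1))
  expect_equal(slicewise_metric(a1, b1, "HD"), hausdorff(a1, b1))
  # a slice present in only one mask pulls DSC down but is skipped for HD
  c_arr <- b_arr; c_arr[2:3, 2:3, 4] <- 1L
  cc <- label_volume(c_arr, c(1, 1, 1))
  expect_equal(slicewise_metric(a, cc, "DSC"), mean(c(1, 0.5, 0)))
  expect_equal(slicewise_metric(a, cc, "HD"), mean(c(0, 1)))
  # no overlapping slices at all
  d_arr <- array(0L, dims); d_arr[2, 2, 4] <- 1L
  expect_error(slicewise_metric(a, label_volume(d_arr, c(1, 1, 1)), "DSC"),
               "no axial slice")
})
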