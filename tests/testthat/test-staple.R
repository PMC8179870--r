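test_that("unanimous raters return their mask with near-perfect performance", {
  m <- sphere_mask(c(14, 14, 14), c(7, 7, 7), 4)
  res <- staple(list(a = m, b = m, c = m))
  expect_identical(res$consensus$voxels, m$voxels)
  expect_true(all(res$per_rater$sensitivity >= 1 - 1e-4))
  expect_true(all(res$per_rater$specificity >= 1 - 1e-4))
  expect_true(res$converged)
  expect_equal(compare_to_consensus(m, res, "DSC"), 1)
  expect_equal(compare_to_consensus(m, res, "HD"), 0)
})

test_that("posterior favours unanimity over disagreement voxels", {
  # 120 voxels: 50 both-1, 50 both-0, 20 disagreements split 10/10
  v1 <- c(rep(1L, 50), rep(0L, 50), rep(1L, 10), rep(0L, 10))
  v2 <- c(rep(1L, 50), rep(0L, 50), rep(0L, 10), rep(1L, 10))
  a <- label_volume(array(v1, c(120, 1, 1)), c(1, 1, 1))
  b <- label_volume(array(v2, c(120, 1, 1)), c(1, 1, 1))
  res <- staple(list(a = a, b = b), margin = 0)
  post <- as.vector(res$posterior)
  expect_gt(min(post[1:50]), max(post[101:120]))
  expect_gt(min(post[1:50]), 0.9)
  # symmetric disagreement: the two disagreement blocks get equal posterior
  expect_equal(post[101:110], post[111:120], tolerance = 1e-6)
})

test_that("consensus recovers the truth better than individual raters", {
  spec <- test_spec(n_cases = 2, seed = 11, raters = uniform_raters(1),
                    volume_range_cm3 = c(25, 60))
  for (ci in 1:2) {
    truth <- make_truth(spec, ci)
    masks <- lapply(seq_len(7), function(ri)
      simulate_rater(truth, spec$raters[ri, ], "WG",
                     raterseg:::derive_seed(spec$seed, ci, 300 + ri)))
    names(masks) <- spec$raters$rater_id
    res <- staple(masks)
    cons_dsc <- dice(res$consensus, truth$true_wg)
    rater_dsc <- vapply(masks, function(m) dice(m, truth$true_wg), numeric(1))
    expect_gt(cons_dsc, mean(rater_dsc))
  }
})

test_that("the consensus is invariant to rater order and improves with less noise", {
  spec <- test_spec(n_cases = 1, seed = 13, volume_range_cm3 = c(30, 30))
  truth <- make_truth(spec, 1)
  sim7 <- function(noise) {
    rr <- uniform_raters(noise)
    masks <- lapply(seq_len(7), function(ri)
      simulate_rater(truth, rr[ri, ], "WG", 40L + ri))
    names(masks) <- rr$rater_id
    masks
  }
  masks <- sim7(1.5)
  r1 <- staple(masks)
  r2 <- staple(rev(masks))
  expect_equal(max(abs(r1$posterior - r2$posterior)), 0, tolerance = 1e-6)
  expect_identical(r1$consensus$voxels, r2$consensus$voxels)
  # monotone recovery as noise shrinks
  d_lo <- dice(staple(sim7(0.5))$consensus, truth$true_wg)
  d_hi <- dice(staple(sim7(2.5))$consensus, truth$true_wg)
  expect_gt(d_lo, d_hi)
  expect_gt(d_lo, 0.97)
})

test_that("per-rater consensus DSC usually exceeds the rater's worst pairwise DSC", {
  spec <- test_spec(n_cases = 4, seed = 11, volume_range_cm3 = c(20, 80))
  coh <- simulate_cohort(spec)
  ok <- 0; tot <- 0
  for (cs in coh$cases) {
    masks <- lapply(cs$raters, `[[`, "WG")
    res <- staple(masks)
    for (i in seq_along(masks)) {
      cons <- dice(masks[[i]], res$consensus)
      worst <- min(vapply(seq_along(masks)[-i],
                          function(j) dice(masks[[i]], masks[[j]]),
                          numeric(1)))
      tot <- tot + 1
      if (cons >= worst) ok <- ok + 1
    }
  }
  expect_gte(ok / tot, 0.9)
})

test_that("degenerate and malformed STAPLE inputs are rejected", {
  m <- sphere_mask(c(10, 10, 10), c(5, 5, 5), 3)
  empty <- label_volume(array(0L, c(10, 10, 10)), c(1, 1, 1))
  expect_error(staple(list(m)), "at least 2")
  expect_error(staple(list(empty, empty)), "all rater masks are empty")
  other <- sphere_mask(c(12, 10, 10), c(5, 5, 5), 3)
  expect_error(staple(list(m, other)), "different array dimensions")
  expect_warning(staple(list(a = m, b = dilate1(m)), max_iter = 1L),
                 "did not converge")
})

test_that("the consensus mask agrees with an independent STAPLE implementation", {
  sitk <- "import SimpleITK as sitk"
  have_py <- nzchar(Sys.which("python")) &&
    system2("python", c("-c", shQuote(sitk)), stdout = FALSE, stderr = FALSE) == 0
  if (!have_py) {
    fail("python with SimpleITK unavailable for the cross-check")
  }
  spec <- test_spec(n_cases = 1, seed = 17, volume_range_cm3 = c(30, 30))
  truth <- make_truth(spec, 1)
  masks <- lapply(seq_len(7), function(ri)
    simulate_rater(truth, spec$raters[ri, ], "WG", 90L + ri))
  names(masks) <- spec$raters$rater_id
  td <- withr::local_tempdir()
  for (i in seq_along(masks))
    write_volume(masks[[i]], file.path(td, sprintf("m%d.nii.gz", i)))
  out <- file.path(td, "sitk_consensus.nii.gz")
  script <- sprintf(
    "import SimpleITK as sitk
imgs = [sitk.ReadImage('%s/m%%d.nii.gz' %% i, sitk.sitkUInt8) for i in range(1, 8)]
st = sitk.STAPLEImageFilter()
st.SetForegroundValue(1)
post = st.Execute(imgs)
sitk.WriteImage(sitk.Cast(post >= 0.5, sitk.sitkUInt8), '%s')", td, out)
  sf <- file.path(td, "staple_ref.py")
  writeLines(script, sf)
  expect_equal(system2("python", sf, stdout = FALSE, stderr = FALSE), 0)
  ref <- read_label_volume(out)
  ours <- staple(masks)$consensus
  expect_gte(dice(ours, ref), 0.99)
})
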