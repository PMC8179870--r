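test_that("label volumes round-trip bit-exactly through all three formats", {
  vol <- rand_mask(c(16, 16, 16), p = 0.3, seed = 7,
                   spacing = c(0.5, 0.5, 1.25))
  for (ext in c("nii.gz", "nii", "nrrd", "mha")) {
    f <- file.path(withr::local_tempdir(), paste0("mask.", ext))
    write_volume(vol, f)
    back <- read_label_volume(f)
    expect_identical(back$voxels, vol$voxels, label = ext)
    expect_equal(back$spacing, vol$spacing, tolerance = 1e-12, label = ext)
  }
})

test_that("intensity volumes round-trip with full precision in NRRD/MHA", {
  set.seed(3)
  img <- intensity_volume(array(rnorm(10 * 12 * 8, 100, 25), c(10, 12, 8)),
                          c(0.6, 0.6, 1.2))
  for (ext in c("nrrd", "mha")) {
    f <- file.path(withr::local_tempdir(), paste0("img.", ext))
    write_volume(img, f)
    back <- read_intensity_volume(f)
    expect_identical(back$voxels, img$voxels, label = ext)
  }
})

test_that("multi-valued label files are binarized, with a warning when labels mix", {
  td <- withr::local_tempdir()
  v255 <- array(c(0, 255), c(4, 4, 4))
  f <- file.path(td, "v255.nrrd")
  write_volume(intensity_volume(v255, c(1, 1, 1)), f)
  lab <- read_label_volume(f)
  expect_setequal(unique(as.vector(lab$voxels)), c(0L, 1L))
  expect_equal(sum(lab$voxels), sum(v255 != 0))

  vmix <- array(c(0, 1, 2, 0), c(4, 4, 4))
  fm <- file.path(td, "vmix.nrrd")
  write_volume(intensity_volume(vmix, c(1, 1, 1)), fm)
  expect_warning(read_label_volume(fm), "distinct nonzero labels")

  fr <- file.path(td, "frac.nrrd")
  write_volume(intensity_volume(array(0.5, c(4, 4, 4)), c(1, 1, 1)), fr)
  expect_error(read_label_volume(fr), "not integer-coded")
})

test_that("unreadable or spacing-less headers fail loudly", {
  td <- withr::local_tempdir()
  f <- file.path(td, "nospacing.nrrd")
  writeBin(c(charToRaw(paste0(
    "NRRD0004\ntype: uint8\ndimension: 3\nsizes: 2 2 2\nencoding: raw\n\n")),
    as.raw(rep(1, 8))), f)
  expect_error(read_label_volume(f), "spacing")
  expect_error(read_label_volume(file.path(td, "absent.nii")), "does not exist")
  fx <- file.path(td, "bad.xyz")
  writeLines("not a volume", fx)
  expect_error(read_label_volume(fx), "unsupported")
})

test_that("PZ subtraction obeys set arithmetic and nesting checks", {
  dims <- c(8, 8, 8)
  wg_arr <- array(0L, dims); wg_arr[2:6, 2:6, 2:5] <- 1L # 100 voxels
  tz_arr <- array(0L, dims); tz_arr[2:5, 2:6, 3:4] <- 1L # 40 voxels nested in WG
  wg <- label_volume(wg_arr, c(1, 1, 1))
  tz <- label_volume(tz_arr, c(1, 1, 1))
  expect_equal(sum(wg$voxels), 100)
  expect_equal(sum(tz$voxels), 40)
  pz <- derive_pz(wg, tz)
  expect_equal(sum(pz$voxels), 60)
  expect_equal(sum(pz$voxels) + sum(tz$voxels & wg$voxels), sum(wg$voxels))
  # idempotence: subtracting TZ again changes nothing
  expect_identical(derive_pz(pz, label_volume(array(0L, dims), c(1, 1, 1)))$voxels,
                   pz$voxels)
  # WG == TZ -> empty; TZ empty -> PZ == WG
  expect_equal(sum(derive_pz(wg, wg)$voxels), 0)
  expect_identical(derive_pz(wg, label_volume(array(0L, dims), c(1, 1, 1)))$voxels,
                   wg$voxels)
  # TZ voxels outside WG are rejected with a count
  bad <- tz_arr; bad[8, 8, 8] <- 1L
  expect_error(derive_pz(wg, label_volume(bad, c(1, 1, 1))),
               "1 TZ voxel")
  # ... unless within tolerance
  expect_silent(derive_pz(wg, label_volume(bad, c(1, 1, 1)), tolerance = 0.1))
})

test_that("cohort manifests are schema-validated and loaded", {
  td <- withr::local_tempdir()
  vol <- rand_mask(c(8, 8, 8), seed = 1)
  rows <- list()
  for (cid in c("c1", "c2")) for (r in c("r1", "r2")) for (st in c("WG", "TZ")) {
    fn <- sprintf("%s_%s_%s.nii.gz", cid, r, st)
    write_volume(vol, file.path(td, fn))
    rows[[length(rows) + 1]] <- data.frame(
      case_id = cid, rater_id = r,
      experience_group = ifelse(r == "r1", "expert", "junior"),
      structure = st, sequence_type = "3D_T2W", path = fn)
  }
  man <- do.call(rbind, rows)
  mf <- file.path(td, "manifest.csv")
  write.csv(man, mf, row.names = FALSE)
  coh <- suppressMessages(load_cohort(mf))
  expect_s3_class(coh, "rater_cohort")
  expect_named(coh$volumes, c("c1", "c2"))
  expect_named(coh$volumes$c1$WG, c("r1", "r2"))
  expect_equal(unname(coh$rater_groups[["r1"]]), "expert")

  # missing TZ for one (case, rater) is named in the error
  write.csv(man[-2, ], mf, row.names = FALSE)
  expect_error(suppressMessages(load_cohort(mf)), "lacks TZ")

  # inconsistent experience group per rater
  man2 <- man
  man2$experience_group[man2$rater_id == "r1"] <- c("expert", "senior",
                                                    "expert", "expert")
  write.csv(man2, mf, row.names = FALSE)
  expect_error(suppressMessages(load_cohort(mf)), "not constant")

  # inconsistent shapes within a case
  man3 <- man
  write_volume(rand_mask(c(6, 8, 8), seed = 2), file.path(td, "odd.nii.gz"))
  man3$path[1] <- "odd.nii.gz"
  write.csv(man3, mf, row.names = FALSE)
  expect_error(suppressMessages(load_cohort(mf)), "shapes differ")
})
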