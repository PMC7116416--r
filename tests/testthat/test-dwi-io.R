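test_that("shell grouping clusters effective b-values onto nominal shells", {
  g <- group_shells(c(0, 0, 495, 505, 1000), tolerance = 50)
  expect_equal(g$scheme$bvalues, c(0, 500, 1000))
  expect_equal(g$scheme$counts, c(2L, 2L, 1L))
  expect_equal(g$shell_index, c(1L, 1L, 2L, 2L, 3L))

  g2 <- group_shells(c(0, 1000), tolerance = 50)
  expect_equal(g2$scheme$bvalues, c(0, 1000))
  expect_equal(g2$scheme$counts, c(1L, 1L))

  expect_error(group_shells(c(0, 40, 80), tolerance = 50), "ambiguous")
})

test_that("scheme constructor enforces its invariants", {
  s <- shell_scheme(c(0, 400, 1000, 2600), c(20, 64, 88, 128))
  expect_equal(s$n_total, 300L)
  expect_error(shell_scheme(c(400, 0), c(1, 1)), "increasing")
  expect_error(shell_scheme(c(0, 400), c(0, 1)), "at least one")
})

test_that("dataset validation catches count mismatches and b=0 convention", {
  vols <- array(1, c(2, 2, 1, 6))
  bvecs <- rbind(c(0, 1, 0, 0, 1, 0), c(0, 0, 1, 0, 0, 1),
                 c(0, 0, 0, 1, 0, 0))
  mask <- array(TRUE, c(2, 2, 1))
  ds <- dwi_dataset(vols, c(0, rep(1000, 5)), bvecs, mask)
  expect_s3_class(ds, "dwi_dataset")

  expect_error(dwi_dataset(vols, c(0, rep(1000, 4)), bvecs, mask),
               "bval count mismatch")
  expect_error(dwi_dataset(vols, c(0, rep(1000, 5)), bvecs[, 1:5], mask),
               "bvec count mismatch")
  badv <- vols; badv[1] <- NaN
  expect_error(dwi_dataset(badv, c(0, rep(1000, 5)), bvecs, mask),
               "non-finite")
})

test_that("NIfTI round trip through read_dwi preserves the dataset", {
  skip_if_not_installed("RNifti")
  dwi <- mixed_fibre_dwi()
  prefix <- file.path(tempdir(), "phantom")
  paths <- write_dwi(dwi$dataset, prefix)
  ds <- read_dwi(paths["image"], paths["bval"], paths["bvec"], paths["mask"])
  expect_equal(dim(ds$volumes), dim(dwi$dataset$volumes))
  expect_equal(ds$bvals, dwi$dataset$bvals)
  expect_equal(unname(ds$bvecs), unname(dwi$dataset$bvecs), tolerance = 1e-6)
  expect_equal(max(abs(ds$volumes - dwi$dataset$volumes)), 0,
               tolerance = 1e-5)
  expect_error(read_dwi(paths["image"], paths["bval"], paths["bvec"],
                        "nonexistent.nii"), "not found")
})

test_that("shell means average volumes and recover known constants", {
  # shell with volumes of value 2 and 4 at every voxel -> mean 3
  vols <- array(0, c(2, 2, 1, 4))
  vols[, , , 1] <- 10
  vols[, , , 2] <- 2
  vols[, , , 3] <- 4
  vols[, , , 4] <- 10
  bvecs <- rbind(c(0, 1, 0, 1), c(0, 0, 1, 0), c(0, 0, 0, 0))
  ds <- dwi_dataset(vols, c(0, 1000, 1000, 0), bvecs, array(TRUE, c(2, 2, 1)))
  ms <- shell_mean_signal(ds)
  expect_equal(unname(ms$D[1, ]), rep(10, 4))
  expect_equal(unname(ms$D[2, ]), rep(3, 4))

  # permutation of volumes within shells leaves the means unchanged
  perm <- c(4, 3, 2, 1)
  ds2 <- dwi_dataset(vols[, , , perm, drop = FALSE], c(0, 1000, 1000, 0)[perm],
                     bvecs[, perm], ds$mask)
  expect_equal(shell_mean_signal(ds2)$D, ms$D)

  expect_error(shell_mean_signal(
    dwi_dataset(vols, c(0, 1000, 1000, 0), bvecs,
                array(FALSE, c(2, 2, 1)))), "empty mask")
})

test_that("synthetic dataset with known per-shell constants is recovered", {
  dwi <- make_dwi(phantom_config(n_voxels = 8,
    compartments = list(list(d = 1e-3)),
    bvalues = c(0, 1000), counts = c(2L, 12L), sigma = 0, seed = 4))
  ms <- shell_mean_signal(dwi$dataset)
  expect_equal(unname(ms$D[1, ]), rep(100, 8), tolerance = 1e-12)
  expect_equal(unname(ms$D[2, ]), rep(100 * exp(-1), 8), tolerance = 1e-12)
})

test_that("pooling concatenates voxels and is associative", {
  a <- two_compartment_means(n_voxels = 10)$data
  b <- two_compartment_means(n_voxels = 20, seed = 5)$data
  c3 <- two_compartment_means(n_voxels = 5, seed = 9)$data
  ab <- pool_subjects(a, b)
  expect_equal(ncol(ab$D), 30)
  expect_equal(pool_subjects(pool_subjects(a, b), c3)$D,
               pool_subjects(a, b, c3)$D)
  expect_equal(pool_subjects(list(a))$D, a$D)

  other <- make_shell_means(phantom_config(n_voxels = 5,
    bvalues = c(0, 700, 1500), counts = c(2L, 10L, 10L)))$data
  expect_error(pool_subjects(a, other), "mismatched shell schemes")
})

test_that("mean-signal CSV round trip preserves matrix and scheme", {
  ms <- two_compartment_means(n_voxels = 12)$data
  path <- file.path(tempdir(), "means.csv")
  write_mean_signal(ms, path)
  back <- read_mean_signal(path)
  expect_equal(unname(back$D), unname(ms$D), tolerance = 1e-12)
  expect_equal(back$scheme$bvalues, ms$scheme$bvalues)
  expect_equal(back$scheme$counts, ms$scheme$counts)
})
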