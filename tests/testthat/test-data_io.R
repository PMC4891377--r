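test_that("a written synthetic session round-trips through the manifest", {
  dir <- withr::local_tempdir()
  sim <- quick_sim(grid = c(8, 8, 4), n_runs = 10, seed = 7)
  manifest <- write_synth_session(sim, dir)
  ses <- load_session(manifest)
  expect_s3_class(ses, "fmri_session")
  expect_equal(ses$n_runs, 10)
  expect_equal(dim(ses$runs[[1]]$data), c(8, 8, 4, 56))
  expect_equal(ses$tr, 2.5)
  # order-preserving assembly: run k is manifest position k
  expect_equal(vapply(ses$runs, `[[`, integer(1), "run_id"), 1:10)
  for (k in c(1, 5, 10)) {
    expect_lt(max(abs(ses$runs[[k]]$data - sim$session$runs[[k]]$data)), 1e-2)
  }
  # mask written by the generator covers the ground-truth brain exactly
  expect_identical(ses$mask, sim$session$mask)
  expect_true(all(ses$mask[sim$truth$active_mask]))
  # design carried through
  expect_equal(ses$design$onsets, c(20, 60, 100))
  expect_equal(ses$design$total_duration, 140)
})

test_that("grid or volume-count mismatches and missing files are fatal", {
  dir <- withr::local_tempdir()
  a <- array(1000 + rnorm(4 * 4 * 2 * 8), c(4, 4, 2, 8))
  b <- array(1000 + rnorm(4 * 4 * 2 * 9), c(4, 4, 2, 9))
  RNifti::writeNifti(RNifti::asNifti(a), file.path(dir, "a.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(b), file.path(dir, "b.nii.gz"))
  man <- list(runs = c("a.nii.gz", "b.nii.gz"), tr_seconds = 2)
  expect_error(load_session(man, base_dir = dir), "volume count")
  man$runs <- c("a.nii.gz", "nope.nii.gz")
  expect_error(load_session(man, base_dir = dir), "missing")
  man$runs <- "a.nii.gz"
  expect_error(load_session(man, base_dir = dir), "at least 2")
  c4 <- array(1000 + rnorm(3 * 4 * 2 * 8), c(3, 4, 2, 8))
  RNifti::writeNifti(RNifti::asNifti(c4), file.path(dir, "c.nii.gz"))
  man$runs <- c("a.nii.gz", "c.nii.gz")
  expect_error(load_session(man, base_dir = dir), "grid")
})

test_that("intensity-quantile brain mask separates phantom foreground", {
  tt <- seq_len(16)
  vol <- array(0, c(6, 6, 3, 16))
  brain <- array(FALSE, c(6, 6, 3))
  brain[2:5, 2:5, 1:2] <- TRUE
  for (i in which(brain)) {
    vol[arrayInd(i, dim(brain))[1], arrayInd(i, dim(brain))[2],
        arrayInd(i, dim(brain))[3], ] <- 1000 + sin(tt)
  }
  # one in-brain voxel is made constant: zero temporal SD excludes it
  vol[3, 3, 1, ] <- 1000
  run <- run_series(vol, tr = 1)
  m <- compute_brain_mask(run)
  want <- brain
  want[3, 3, 1] <- FALSE
  expect_identical(m, want)
  expect_error(compute_brain_mask(run_series(array(0, c(4, 4, 2, 8)), tr = 1)),
               "empty mask")
})

test_that("save_map writes float32 values and propagates reference geometry", {
  dir <- withr::local_tempdir()
  a <- array(1000 + rnorm(6 * 5 * 3 * 8), c(6, 5, 3, 8))
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- c(1.7, 1.7, 3.3, 2.5)
  p_run <- file.path(dir, "ref.nii.gz")
  RNifti::writeNifti(img, p_run)
  man <- list(runs = c("ref.nii.gz", "ref.nii.gz"), tr_seconds = 2.5)
  ses <- load_session(man, base_dir = dir)

  map <- array(rnorm(6 * 5 * 3), c(6, 5, 3))
  p_map <- file.path(dir, "map.nii.gz")
  save_map(map, ses$runs[[1]], p_map)
  back <- RNifti::readNifti(p_map)
  expect_lt(max(abs(as.array(back) - map)), 1e-6)
  expect_equal(RNifti::pixdim(back)[1:3], c(1.7, 1.7, 3.3), tolerance = 1e-6)

  save_map(array(0, c(6, 5, 3)), ses$runs[[1]], p_map)
  expect_equal(sum(as.array(RNifti::readNifti(p_map))), 0)
  expect_error(save_map(array(0, c(2, 2, 2)), ses$runs[[1]], p_map), "shape")
})

test_that("QC reports serialise passes and good runs and parse back", {
  dir <- withr::local_tempdir()
  rep <- structure(list(
    excluded = 3L, good_runs = c(1L, 2L, 4L, 5L),
    passes = data.frame(pass = c(1L, 1L), run_id = c(2L, 3L),
                        welch_t = c(0.4, 3.9), welch_dof = c(55.2, 60.1),
                        p_one_sided = c(0.3, 1e-4), alpha_corrected = 0.01,
                        decision = c("kept", "excluded")),
    activation_mask = NULL, tested = TRUE, alpha = 0.05,
    selection = "mean_t"), class = "bad_run_report")
  p <- file.path(dir, "qc.tsv")
  write_qc_report(rep, p)
  back <- read_qc_report(p)
  expect_equal(back$excluded, 3L)
  expect_equal(back$good_runs, c(1L, 2L, 4L, 5L))
  expect_equal(back$passes$decision, c("kept", "excluded"))
  expect_equal(back$passes$run_id[back$passes$decision == "excluded"], 3L)
  expect_equal(back$passes$welch_t, c(0.4, 3.9))

  # no-exclusion report: header plus final good-run list only
  sim <- quick_sim(grid = c(6, 6, 3), n_runs = 2, seed = 2)
  res <- run_unbiased(sim$session)
  write_qc_report(res$bad_runs, p)
  back <- read_qc_report(p)
  expect_equal(back$good_runs, 1:2)
  expect_equal(nrow(back$passes), 0)
})
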