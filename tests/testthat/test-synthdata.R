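test_that("standard designs reproduce the acquisition timing", {
  mo <- make_design("motor_ababab")
  expect_equal(mo$n_volumes, 56)
  expect_equal(mo$tr, 2.5)
  expect_equal(mo$design$onsets, c(20, 60, 100))
  expect_equal(mo$design$durations, rep(20, 3))
  expect_equal(mo$design$total_duration, 140)
  vi <- make_design("visuomotor")
  expect_equal(vi$n_volumes, 160)
  expect_equal(vi$tr, 1)
  expect_equal(length(vi$design$onsets), 5)
  expect_equal(vi$design$durations, rep(10, 5))
  expect_error(make_design("oddball"), "arg")
  expect_error(make_design("motor_ababab", tr = 3), "divide")
})

test_that("response templates honour shape, sign and delay", {
  des <- make_design("motor_ababab")
  mk <- function(shape, ...) region_spec(cube_voxels(1, 1, 1), shape = shape, ...)
  can <- response_template(mk("canonical"), des$design, 56, 2.5)
  expect_equal(max(abs(can)), 4)          # peak equals default amplitude (%)
  expect_equal(response_template(mk("none"), des$design, 56, 2.5), rep(0, 56))
  expect_equal(response_template(mk("negative"), des$design, 56, 2.5), -can)
  del <- response_template(mk("delayed", delay = 2.5), des$design, 56, 2.5)
  # a one-TR delay is a one-volume shift away from block boundaries
  expect_equal(del[10:56], can[9:55], tolerance = 1e-9)
  tra <- response_template(mk("transient_onset_offset"), des$design, 56, 2.5)
  # transients live at block starts and ends, so the mid-block plateau of the
  # sustained response is absent
  plateau <- which(can > 0.95 * max(can))
  expect_lt(max(tra[plateau]) / max(tra), 0.8)
})

test_that("generation is reproducible from the seed alone", {
  cfg <- synth_config(grid = c(8, 8, 4), n_runs = 3, seed = 42)
  a <- generate_session(cfg)
  b <- generate_session(synth_config(grid = c(8, 8, 4), n_runs = 3, seed = 42))
  for (r in 1:3) expect_identical(a$session$runs[[r]]$data,
                                  b$session$runs[[r]]$data)
  c2 <- generate_session(synth_config(grid = c(8, 8, 4), n_runs = 3, seed = 43))
  expect_false(identical(a$session$runs[[1]]$data, c2$session$runs[[1]]$data))
})

test_that("the noiseless drift-free limit gives identical runs and full reliability", {
  sim <- quick_sim(grid = c(10, 10, 4), n_runs = 3, seed = 1, noise_sd = 0,
                   drift_coeff_sd = c(0, 0, 0))
  expect_identical(sim$session$runs[[1]]$data, sim$session$runs[[2]]$data)
  res <- run_unbiased(sim$session, exclude_bad = FALSE)
  expect_true(all(res$reliability$values[sim$truth$active_mask] == 100))
})

test_that("achieved temporal SNR tracks the target", {
  sim <- generate_session(synth_config(grid = c(14, 14, 6), n_runs = 4,
                                       tsnr_target = 70, seed = 5))
  ses <- detrend_session(sim$session)
  bg <- sim$session$mask & !sim$truth$active_mask
  sds <- vapply(ses$runs, function(r) {
    m <- matrix(r$data, ncol = 56)[which(bg), ]
    mean(apply(m, 1, sd))
  }, numeric(1))
  achieved <- 1000 / mean(sds)
  expect_lt(abs(achieved - 70) / 70, 0.1)
})

test_that("quadratic drift is injected per run and fully removable", {
  sim <- quick_sim(grid = c(8, 8, 4), n_runs = 3, seed = 9, noise_sd = 0)
  # without noise, in-brain background voxels carry baseline + drift only
  bg <- which(sim$session$mask & !sim$truth$active_mask)
  v1 <- matrix(sim$session$runs[[1]]$data, ncol = 56)[bg[1], ]
  v2 <- matrix(sim$session$runs[[2]]$data, ncol = 56)[bg[1], ]
  drift_power <- var(v1)
  expect_gt(drift_power, 0)
  expect_false(isTRUE(all.equal(v1, v2)))   # fresh coefficients per run
  det <- detrend_poly2(sim$session$runs[[1]], sim$session$mask)
  resid <- matrix(det$data, ncol = 56)[bg[1], ]
  expect_lt(var(resid), 0.01 * drift_power)
})

test_that("bad runs are generated without task modulation", {
  cfg <- synth_config(grid = c(12, 12, 4), n_runs = 4, bad_runs = 2L, seed = 33,
                      noise_sd = 0, drift_coeff_sd = c(0, 0, 0))
  sim <- generate_session(cfg)
  expect_equal(sim$truth$bad_runs, 2L)
  act <- which(sim$truth$active_mask)
  good_course <- matrix(sim$session$runs[[1]]$data, ncol = 56)[act[1], ]
  bad_course <- matrix(sim$session$runs[[2]]$data, ncol = 56)[act[1], ]
  expect_gt(diff(range(good_course)), 1)
  expect_equal(bad_course, rep(1000, 56))
  expect_error(synth_config(grid = c(8, 8, 4), n_runs = 3, bad_runs = 9L),
               "bad_runs")
  expect_error(synth_config(grid = c(8, 8, 4), regions = list(
    region_spec(cube_voxels(1:20, 1, 1)))), "outside the grid")
})
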