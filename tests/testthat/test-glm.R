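test_that("canonical HRF has the expected double-gamma geometry", {
  h <- canonical_hrf(dt = 0.001)
  expect_equal(h$samples[1], 0)
  expect_equal(max(h$samples), 1)
  # oracle: maximise the closed-form difference directly
  f <- function(t) dgamma(t, 6, 1) - dgamma(t, 16, 1) / 6
  opt <- optimize(f, c(0, 10), maximum = TRUE)
  peak_t <- (which.max(h$samples) - 1) * 0.001
  expect_equal(peak_t, opt$maximum, tolerance = 1e-3)
  expect_equal(peak_t, 5.0, tolerance = 0.05)
  # undershoot: negative minimum after the peak
  imin <- which.min(h$samples)
  expect_gt(imin, which.max(h$samples))
  expect_lt(h$samples[imin], 0)
  expect_error(canonical_hrf(dt = 0), "positive")
})

test_that("block regressor is the centred HRF-convolved boxcar", {
  des <- make_design("motor_ababab")
  reg <- block_regressor(des$design, des$n_volumes, des$tr)
  expect_length(reg, 56)
  expect_equal(mean(reg), 0, tolerance = 1e-12)
  # three response lobes: contiguous runs above half maximum
  above <- reg > 0.5 * max(reg)
  expect_equal(sum(diff(c(FALSE, above)) == 1), 3)

  # empty design -> all-zero regressor
  empty <- design_spec(numeric(0), numeric(0), 140)
  expect_equal(block_regressor(empty, 56, 2.5), rep(0, 56))

  # delta-like kernel (single unit sample) returns the centred boxcar
  delta <- structure(list(samples = 1, dt = 2.5, duration = 0),
                     class = "hrf_kernel")
  reg_d <- block_regressor(des$design, 56, 2.5, hrf = delta)
  tt <- (0:55) * 2.5
  box <- as.numeric((tt >= 20 & tt < 40) | (tt >= 60 & tt < 80) |
                    (tt >= 100 & tt < 120))
  expect_equal(reg_d, box - mean(box), tolerance = 1e-12)

  bad <- design_spec(c(10), 30, 200)
  expect_error(block_regressor(bad, 10, 2), "exceeds run duration")
})

test_that("GLM fit matches hand OLS and the squared-correlation identity", {
  mask <- array(TRUE, c(3, 1, 1))
  reg <- c(0, 1, 2, 3)
  m <- rbind(2 * reg + 7,            # exact fit
             c(1, -1, 1, -1) - mean(c(1, -1, 1, -1)),  # low-correlation probe
             c(0, 1, 2, 4))
  g <- glm_fit_run(run_from_matrix(m), reg, mask)
  expect_equal(g$r2[1, 1, 1], 1)
  expect_equal(g$beta[1, 1, 1], 2)
  expect_equal(g$r2[3, 1, 1], 1 - 0.30 / 8.75, tolerance = 1e-9)
  # orthogonal signal: beta and R^2 exactly zero
  orth <- c(1, -1, -1, 1)  # sum(orth * (reg - mean(reg))) == 0
  g2 <- glm_fit_run(run_from_matrix(rbind(orth, orth, orth)), reg, mask)
  expect_equal(g2$beta[1, 1, 1], 0)
  expect_equal(g2$r2[1, 1, 1], 0)
  set.seed(31)
  y <- matrix(rnorm(20 * 30), 20, 30)
  x <- rnorm(30)
  gr <- glm_fit_run(run_from_matrix(y), x, array(TRUE, c(20, 1, 1)))
  expect_equal(as.numeric(gr$r2),
               apply(y, 1, function(v) cor(v, x)^2), tolerance = 1e-8)
  expect_error(glm_fit_run(run_from_matrix(y), rep(1, 30),
                           array(TRUE, c(20, 1, 1))), "constant regressor")
})

test_that("model-free R^2 averages pairwise fit quality", {
  set.seed(41)
  m <- matrix(rnorm(30 * 16), 30, 16)
  ses <- session_from_matrices(list(m, m, m))
  ps <- all_pair_fits(ses)
  expect_equal(as.numeric(r2_unbiased(ps)), rep(1, 30), tolerance = 1e-12)

  ps2 <- fake_pair_stats(beta = matrix(0, 1, 1), n_runs = 2,
                         r2 = matrix(0.8, 1, 1))
  ps3 <- fake_pair_stats(beta = matrix(0, 1, 3), n_runs = 3,
                         r2 = matrix(c(0.8, 0.6, 0.7), 1, 3))
  expect_equal(r2_unbiased(ps3, good_runs = c(1, 2, 3))[1, 1, 1],
               0.7, tolerance = 1e-12)

  # independent noise: mean pairwise r^2 is 1/(T-1)
  set.seed(43)
  mats <- replicate(4, matrix(rnorm(500 * 56), 500, 56), simplify = FALSE)
  psn <- all_pair_fits(session_from_matrices(mats))
  expect_equal(mean(psn$r2), 1 / 55, tolerance = 0.15)
})

test_that("fit-comparison map and positive clusters behave as defined", {
  expect_equal(rug_map(array(0.9, c(2, 2, 2)), array(0.9, c(2, 2, 2))),
               array(0, c(2, 2, 2)))
  expect_equal(rug_map(array(0.5, c(1, 1, 1)), array(0, c(1, 1, 1)))[1],  1)
  expect_equal(rug_map(array(0.2, c(1, 1, 1)), array(0.6, c(1, 1, 1)))[1], -0.5)
  expect_equal(rug_map(array(0, c(1, 1, 1)), array(0, c(1, 1, 1)))[1], 0)

  d <- c(12, 12, 12)
  mask <- array(TRUE, d)
  rug <- array(-0.1, d)
  expect_length(positive_rug_clusters(rug, mask), 0)
  rug[3:6, 3:6, 3:6] <- 0.5                      # 64 voxels
  rug[9:11, 9:11, 9:11] <- 0.2                   # 27 voxels
  cl <- positive_rug_clusters(rug, mask, min_size = 10)
  expect_length(cl, 2)
  expect_equal(cl[[1]]$size, 64)
  expect_equal(cl[[1]]$centroid, c(4.5, 4.5, 4.5))
  expect_equal(cl[[2]]$size, 27)
  # oracle: connected components from an independent graph construction
  pos <- which(rug > 0)
  co <- arrayInd(pos, d)
  adj <- which(as.matrix(dist(co, method = "maximum")) == 1, arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(apply(adj, 2, as.integer), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(co) - igraph::vcount(g)))
  comp <- igraph::components(g)
  expect_equal(sort(comp$csize, decreasing = TRUE), c(64, 27))
})

test_that("cubic ROI time courses average space, not time", {
  sim <- quick_sim(grid = c(9, 9, 5), n_runs = 2, seed = 3, noise_sd = 0,
                   drift_coeff_sd = c(0, 0, 0))
  ses <- sim$session
  roi <- roi_mean_timecourse(ses, center = c(5, 5, 3), edge = 3)
  expect_equal(dim(roi$mean), c(56, 2))
  # edge 1 returns the centre voxel's own course
  roi1 <- roi_mean_timecourse(ses, center = c(5, 5, 3), edge = 1)
  expect_equal(roi1$mean[, 1], ses$runs[[1]]$data[5, 5, 3, ])
  expect_equal(roi1$sd[, 1], rep(0, 56))
  expect_message(roi_mean_timecourse(ses, center = c(1, 1, 1), edge = 5),
                 "clipped")
  expect_error(roi_mean_timecourse(ses, center = c(50, 1, 1)), "outside")
})

test_that("transient ROI courses match the generator's template shape", {
  reg <- region_spec(cube_voxels(4:8, 4:8, 2:6), shape = "transient_onset_offset",
                     amplitude = 4)
  sim <- generate_session(synth_config(
    grid = c(12, 12, 8), n_runs = 10, regions = list(reg),
    tsnr_target = 100, seed = 19))
  ses <- detrend_session(sim$session)
  roi <- roi_mean_timecourse(ses, center = c(6, 6, 4), edge = 5)
  tmpl <- sim$truth$templates[[1]]
  expect_gt(cor(roi$avg_mean, tmpl - mean(tmpl)), 0.9)
})
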