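# Reference single-regressor GLM on identically preprocessed data, and the
# goodness-of-fit comparison between the model-based and model-free routes.

#' Canonical double-gamma HRF
#'
#' The usual canonical hemodynamic response: a gamma density peaking near 5 s
#' minus a later, smaller gamma for the undershoot,
#' `g(t; 6, 1) - g(t; 16, 1)/6`, sampled on `[0, duration]` at spacing `dt`
#' and peak-normalised to 1. The value at t = 0 is exactly 0.
#'
#' @param dt sample spacing in seconds (default 0.1).
#' @param duration kernel support in seconds (default 32).
#' @return An `hrf_kernel`: list with `samples`, `dt`, `duration`.
#' @export
canonical_hrf <- function(dt = 0.1, duration = 32) {
  if (dt <= 0) stop("dt must be positive")
  tt <- seq(0, duration, by = dt)
  h <- stats::dgamma(tt, shape = 6, rate = 1) -
       stats::dgamma(tt, shape = 16, rate = 1) / 6
  structure(list(samples = h / max(h), dt = dt, duration = duration),
            class = "hrf_kernel")
}

# Boxcar(s) convolved with the HRF on a fine grid, sampled at volume times
# t = v * tr, v = 0..T-1. No centering or normalisation here.
convolve_boxcar <- function(onsets, durations, total_duration, n_volumes, tr, hrf) {
  dt <- hrf$dt
  durations <- rep_len(durations, length(onsets))
  nfine <- as.integer(round(total_duration / dt))
  tim <- (seq_len(nfine) - 1) * dt
  box <- numeric(nfine)
  for (i in seq_along(onsets)) {
    box[tim >= onsets[i] & tim < onsets[i] + durations[i]] <- 1
  }
  conv <- stats::convolve(box, rev(hrf$samples), type = "open")[seq_len(nfine)]
  vidx <- 1 + round((seq_len(n_volumes) - 1) * tr / dt)
  if (any(vidx > nfine)) stop("design does not cover the run duration")
  conv[vidx]
}

#' Task regressor for a block design
#'
#' A boxcar (1 during task blocks) built on a fine time grid, convolved with
#' the HRF, sampled at the volume acquisition times and mean-centred.
#'
#' @param design a [design_spec()].
#' @param n_volumes number of volumes T.
#' @param tr repetition time in seconds.
#' @param hrf an [canonical_hrf()] kernel.
#' @return Numeric vector of length `n_volumes`.
#' @export
block_regressor <- function(design, n_volumes, tr, hrf = canonical_hrf()) {
  stopifnot(inherits(design, "design_spec"))
  if (length(design$onsets) &&
      any(design$onsets + design$durations > n_volumes * tr + 1e-9))
    stop("design exceeds run duration")
  x <- convolve_boxcar(design$onsets, design$durations,
                       max(design$total_duration, n_volumes * tr),
                       n_volumes, tr, hrf)
  x - mean(x)
}

#' Voxelwise GLM fit of one run
#'
#' Per masked voxel, ordinary least squares of the (detrended) signal on an
#' intercept plus the task regressor; `t = beta / SE(beta)` with `T - 2`
#' degrees of freedom and `R^2 = 1 - SSres/SStot` (SStot about the voxel's
#' temporal mean).
#'
#' @param run a [run_series()], normally detrended.
#' @param regressor numeric vector of length T, non-constant.
#' @param mask logical 3D array.
#' @return A `glm_result`: 3D `beta`, `t`, `r2` grids and `dof`.
#' @export
glm_fit_run <- function(run, regressor, mask) {
  stopifnot(inherits(run, "run_series"))
  TT <- n_volumes(run)
  if (length(regressor) != TT) stop("regressor length must equal volume count")
  if (stats::sd(regressor) == 0) stop("constant regressor")
  idx <- which(mask)
  y <- masked_matrix(run, idx)
  yc <- y - rowMeans(y)
  xc <- matrix(regressor - mean(regressor), length(idx), TT, byrow = TRUE)
  fit <- inter_run_ols(xc, yc)
  sp <- spatial_dim(run)
  grid <- function(v) { out <- array(0, sp); out[idx] <- v; out }
  structure(list(beta = grid(fit$beta), t = grid(fit$t), r2 = grid(fit$r2),
                 dof = fit$dof),
            class = "glm_result")
}

#' GLM maps averaged over the runs of a session
#'
#' Fits [glm_fit_run()] to each run and averages beta, t and R-squared
#' voxelwise across the chosen runs. The per-run fitting keeps the degrees of
#' freedom comparable with the pairwise inter-run fits. By display convention
#' only positive t values are of interest; the raw average is returned and
#' `pmax(t, 0)` is left to the caller.
#'
#' @param session an [fmri_session()] (runs as given; detrend first).
#' @param regressor optional; defaults to [block_regressor()] from the
#'   session's design.
#' @param runs run indices to include (default: all).
#' @return A `glm_result` with averaged 3D `beta`, `t`, `r2` and per-run
#'   `dof`.
#' @export
glm_session <- function(session, regressor = NULL, runs = seq_len(session$n_runs)) {
  stopifnot(inherits(session, "fmri_session"))
  TT <- n_volumes(session$runs[[1]])
  if (is.null(regressor)) {
    if (is.null(session$design)) stop("no regressor given and session has no design")
    regressor <- block_regressor(session$design, TT, session$tr)
  }
  fits <- lapply(session$runs[runs], glm_fit_run, regressor = regressor,
                 mask = session$mask)
  avg <- function(field) Reduce(`+`, lapply(fits, `[[`, field)) / length(fits)
  structure(list(beta = avg("beta"), t = avg("t"), r2 = avg("r2"),
                 dof = TT - 2, n_runs = length(runs)),
            class = "glm_result")
}

#' Goodness of fit of the model-free route
#'
#' Per voxel, the mean over good pairs of the pairwise inter-run R-squared
#' (`1 - SSres/SStot` of each inter-run regression). With `pooled = TRUE`
#' the residual and total sums of squares are instead pooled over pairs
#' before forming the ratio.
#'
#' @param pairs a `pair_stats` from [all_pair_fits()].
#' @param good_runs run indices to use.
#' @param pooled pool sums of squares across pairs instead of averaging
#'   per-pair R-squared (default FALSE).
#' @return 3D R-squared grid in `[0, 1]`.
#' @export
r2_unbiased <- function(pairs, good_runs = seq_len(pairs$n_runs), pooled = FALSE) {
  stopifnot(inherits(pairs, "pair_stats"))
  if (length(good_runs) < 2) stop("need at least 2 good runs")
  sel <- pair_selector(pairs, good_runs)
  if (pooled) {
    tot <- rowSums(pairs$sstot[, sel, drop = FALSE])
    res <- rowSums(pairs$ssres[, sel, drop = FALSE])
    v <- ifelse(tot > 0, pmin(pmax(1 - res / tot, 0), 1), 0)
  } else {
    v <- rowMeans(pairs$r2[, sel, drop = FALSE])
  }
  vec_to_grid(pairs, v)
}

#' Normalised goodness-of-fit difference map
#'
#' `r = (R2_consistency - R2_glm) / (R2_consistency + R2_glm)`, elementwise;
#' 0 where both are 0. Positive values mark voxels whose signal is better
#' explained by its own time course in other runs than by the model
#' regressor - the signature of consistent but non-model-conform responses.
#'
#' @param r2_unbiased,r2_glm 3D grids in `[0, 1]` on the same grid.
#' @return 3D grid in `[-1, 1]`.
#' @export
rug_map <- function(r2_unbiased, r2_glm) {
  if (!identical(dim(r2_unbiased), dim(r2_glm))) stop("shape mismatch")
  den <- r2_unbiased + r2_glm
  out <- array(0, dim(r2_unbiased))
  pos <- den > 0
  out[pos] <- (r2_unbiased[pos] - r2_glm[pos]) / den[pos]
  out
}

#' Clusters of positive fit advantage
#'
#' Connected components (26-connectivity) of the voxels where the comparison
#' map is positive, restricted to the mask, with a minimum size.
#'
#' @param rug 3D comparison map (e.g. from [rug_map()]).
#' @param mask logical 3D array.
#' @param min_size minimum cluster size in voxels (default 10).
#' @return list of clusters sorted by size (descending), each with `voxels`
#'   (n x 3 index matrix), `size`, `centroid`; the label array is attached as
#'   attribute `labels`.
#' @export
positive_rug_clusters <- function(rug, mask, min_size = 10) {
  stopifnot(identical(dim(rug), dim(mask)))
  lab <- label_components(rug > 0 & mask)
  ids <- setdiff(unique(as.integer(lab)), 0L)
  clusters <- list()
  for (id in ids) {
    idx <- which(lab == id)
    if (length(idx) < min_size) next
    vox <- arrayInd(idx, dim(rug))
    clusters[[length(clusters) + 1]] <-
      list(voxels = vox, size = nrow(vox), centroid = colMeans(vox))
  }
  ord <- order(vapply(clusters, `[[`, numeric(1), "size"), decreasing = TRUE)
  structure(clusters[ord], labels = lab)
}

#' Mean time course in a cubic ROI
#'
#' Spatial mean and SD across the voxels of an `edge^3` cube centred on a
#' voxel, per time point and per run, plus the across-run average time
#' course. The cube is clipped at the volume borders (with a message).
#'
#' @param session an [fmri_session()].
#' @param center integer voxel index triple (1-based).
#' @param edge cube edge in voxels (default 5).
#' @return list with `mean` and `sd` (T x N matrices, one column per run),
#'   `avg_mean` and `avg_sd` (length-T across-run averages), `n_voxels`,
#'   `clipped`.
#' @export
roi_mean_timecourse <- function(session, center, edge = 5) {
  stopifnot(inherits(session, "fmri_session"), length(center) == 3)
  sp <- spatial_dim(session$runs[[1]])
  center <- as.integer(round(center))
  if (any(center < 1) || any(center > sp)) stop("center outside volume")
  h <- (edge - 1) %/% 2
  lo <- center - h
  hi <- center + (edge - 1) - h
  clipped <- any(lo < 1) || any(hi > sp)
  if (clipped) message("ROI cube clipped at the volume border")
  lo <- pmax(lo, 1); hi <- pmin(hi, sp)
  TT <- n_volumes(session$runs[[1]])
  N <- session$n_runs
  mn <- matrix(0, TT, N); sdv <- matrix(0, TT, N)
  for (r in seq_len(N)) {
    block <- session$runs[[r]]$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], ,
                                    drop = FALSE]
    m <- matrix(block, ncol = TT)   # voxels x T
    mn[, r] <- colMeans(m)
    sdv[, r] <- if (nrow(m) > 1) apply(m, 2, stats::sd) else 0
  }
  list(mean = mn, sd = sdv,
       avg_mean = rowMeans(mn), avg_sd = rowMeans(sdv),
       n_voxels = prod(hi - lo + 1), clipped = clipped)
}
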