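# Pairwise inter-run regression: the heart of the method. Each voxel's
# "model" is its own time course in another run; consistent responses of any
# shape give reproducible positive slopes.

# Simple-regression statistics for row-matched series. xc, yc are
# mean-centred V x T matrices (predictor, response). Returns beta (slope),
# t (beta / SE, dof = T - 2), and R^2 of the intercept+slope fit.
# Degeneracies: zero predictor or response variance -> beta = t = r2 = 0;
# an (essentially) zero residual -> |t| clamped at T_CLAMP.
inter_run_ols <- function(xc, yc) {
  TT <- ncol(xc)
  dof <- TT - 2
  Sxx <- rowSums(xc^2)
  Syy <- rowSums(yc^2)
  Sxy <- rowSums(xc * yc)
  ok <- Sxx > 0 & Syy > 0
  beta <- ifelse(ok, Sxy / ifelse(Sxx > 0, Sxx, 1), 0)
  ssres <- pmax(Syy - beta * Sxy, 0)
  r2 <- ifelse(ok, pmin(pmax(beta * Sxy / ifelse(Syy > 0, Syy, 1), 0), 1), 0)
  se <- sqrt(ssres / (dof * ifelse(Sxx > 0, Sxx, 1)))
  tval <- numeric(length(beta))
  good_se <- ok & se > 0
  tval[good_se] <- beta[good_se] / se[good_se]
  exact <- ok & ssres <= 1e-12 * Syy
  tval[exact] <- sign(beta[exact]) * T_CLAMP
  tval <- pmin(pmax(tval, -T_CLAMP), T_CLAMP)
  list(beta = beta, t = tval, r2 = r2, ssres = ssres, sstot = Syy, dof = dof)
}

masked_matrix <- function(run, idx) {
  matrix(run$data, ncol = n_volumes(run))[idx, , drop = FALSE]
}

#' Inter-run fit for one pair of runs
#'
#' Ordinary least squares of run `k`'s voxel time course on run `j`'s
#' (with intercept): per masked voxel, `s_k(t) = a + beta * s_j(t) + e`.
#' The t value is `beta / SE(beta)` with `T - 2` residual degrees of freedom.
#' With the intercept in the model, t is symmetric in (j, k). Runs should be
#' detrended first (see [detrend_poly2()]).
#'
#' @param run_j,run_k [run_series()] objects on the same grid with equal T.
#' @param mask logical 3D array.
#' @return A `pair_fit`: list with 3D `beta` and `t` grids (zero outside the
#'   mask), run indices `j`, `k`, and `dof = T - 2`.
#' @export
pair_fit <- function(run_j, run_k, mask) {
  stopifnot(inherits(run_j, "run_series"), inherits(run_k, "run_series"))
  if (!identical(dim(run_j$data), dim(run_k$data)))
    stop("runs must share grid and volume count")
  if (run_j$run_id == run_k$run_id) stop("pair must consist of non-identical runs")
  sp <- spatial_dim(run_j)
  stopifnot(identical(dim(mask), sp))
  idx <- which(mask)
  x <- masked_matrix(run_j, idx)
  y <- masked_matrix(run_k, idx)
  fit <- inter_run_ols(x - rowMeans(x), y - rowMeans(y))
  grid <- function(v) { out <- array(0, sp); out[idx] <- v; out }
  structure(list(beta = grid(fit$beta), t = grid(fit$t), r2 = grid(fit$r2),
                 j = run_j$run_id, k = run_k$run_id, dof = fit$dof),
            class = "pair_fit")
}

#' Pairwise fits over all non-identical run combinations
#'
#' Computes [pair_fit()] statistics for every unordered pair `j < k`,
#' producing the per-voxel triangular beta/t matrices the rest of the analysis
#' consumes. For N runs there are exactly `N*(N-1)/2` pairs.
#'
#' @param session an [fmri_session()]; runs are used as-is (detrend first,
#'   e.g. via [detrend_session()]).
#' @return A `pair_stats` object: masked-voxel by pair matrices `beta`, `t`,
#'   `r2`, `ssres`, `sstot`; `pairs` (data frame with columns `j`, `k`);
#'   `dof`; the mask and grid geometry.
#' @export
all_pair_fits <- function(session) {
  stopifnot(inherits(session, "fmri_session"))
  N <- session$n_runs
  if (N < 2) stop("need at least 2 runs")
  idx <- which(session$mask)
  TT <- n_volumes(session$runs[[1]])
  cm <- lapply(session$runs, function(r) {
    m <- masked_matrix(r, idx)
    m - rowMeans(m)
  })
  pr <- utils::combn(N, 2)
  P <- ncol(pr)
  V <- length(idx)
  beta <- matrix(0, V, P); tval <- matrix(0, V, P); r2 <- matrix(0, V, P)
  ssres <- matrix(0, V, P); sstot <- matrix(0, V, P)
  for (p in seq_len(P)) {
    fit <- inter_run_ols(cm[[pr[1, p]]], cm[[pr[2, p]]])
    beta[, p] <- fit$beta; tval[, p] <- fit$t; r2[, p] <- fit$r2
    ssres[, p] <- fit$ssres; sstot[, p] <- fit$sstot
  }
  structure(list(beta = beta, t = tval, r2 = r2, ssres = ssres, sstot = sstot,
                 pairs = data.frame(j = pr[1, ], k = pr[2, ]),
                 dof = TT - 2, n_runs = N, n_volumes = TT,
                 mask = session$mask, voxels = idx,
                 dim = spatial_dim(session$runs[[1]]), tr = session$tr),
            class = "pair_stats")
}

#' @export
print.pair_stats <- function(x, ...) {
  cat(sprintf("pair_stats: %d runs, %d pairs, %d mask voxels, dof %d\n",
              x$n_runs, nrow(x$pairs), length(x$voxels), x$dof))
  invisible(x)
}

pair_selector <- function(ps, included_runs) {
  ps$pairs$j %in% included_runs & ps$pairs$k %in% included_runs
}

vec_to_grid <- function(ps, v) {
  out <- array(0, ps$dim)
  out[ps$voxels] <- v
  out
}

# One-sample t over pair betas, on masked voxels; returns a vector.
subject_t_vec <- function(ps, included_runs) {
  sel <- pair_selector(ps, included_runs)
  P <- sum(sel)
  if (P < 2) stop("subject t-map needs at least 2 pairs among included runs")
  bb <- ps$beta[, sel, drop = FALSE]
  mu <- rowMeans(bb)
  sdv <- sqrt(rowSums((bb - mu)^2) / (P - 1))
  tval <- numeric(length(mu))
  pos <- sdv > 0
  tval[pos] <- mu[pos] * sqrt(P) / sdv[pos]
  tval[!pos] <- sign(mu[!pos]) * T_CLAMP
  pmin(pmax(tval, -T_CLAMP), T_CLAMP)
}

#' Subject-level t-map from pair betas
#'
#' Per voxel, the one-sample t statistic of the pair beta values over all
#' pairs whose two runs are both included:
#' `t = mean(beta) * sqrt(P) / sd(beta)`. A zero across-pair SD is clamped
#' (sign of the mean times 1e6; exactly zero when the mean is also zero).
#'
#' @param pairs a `pair_stats` from [all_pair_fits()].
#' @param included_runs run indices to keep (default: all).
#' @return 3D t grid, zero outside the mask.
#' @export
subject_t_map <- function(pairs, included_runs = seq_len(pairs$n_runs)) {
  stopifnot(inherits(pairs, "pair_stats"))
  vec_to_grid(pairs, subject_t_vec(pairs, included_runs))
}

#' Mean pair beta map
#'
#' Arithmetic mean of the pairwise fit slopes over all good pairs; useful for
#' distinguishing true activation (beta near 1) from artefacts when few runs
#' are available.
#'
#' @inheritParams subject_t_map
#' @param good_runs run indices treated as good (default: all).
#' @return 3D grid of mean betas.
#' @export
mean_beta_map <- function(pairs, good_runs = seq_len(pairs$n_runs)) {
  stopifnot(inherits(pairs, "pair_stats"))
  if (length(good_runs) < 2) stop("need at least 2 good runs")
  sel <- pair_selector(pairs, good_runs)
  vec_to_grid(pairs, rowMeans(pairs$beta[, sel, drop = FALSE]))
}
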