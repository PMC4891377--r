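# The final activation measure: per-voxel percentage of good run pairs whose
# inter-run t value clears an uncorrected p < 0.001 threshold.

#' Reliability map
#'
#' Converts the per-voxel pair t values into the percentage of good run pairs
#' in which the voxel is "activated": pairs with `t > t_threshold`, where the
#' threshold is the upper-tail Student quantile at `p_threshold` with
#' `T - 2` degrees of freedom. Only the positive tail is counted: consistent
#' responses of either sign produce positive inter-run slopes, while negative
#' slopes mean anti-correlated (inconsistent) behaviour. Both runs of a
#' counted pair must be good, and the denominator is the number of good
#' pairs, so with `N_g` good runs the attainable levels are multiples of
#' `100 / (N_g*(N_g-1)/2)` (just {0, 100} for two runs).
#'
#' @param pairs a `pair_stats` from [all_pair_fits()].
#' @param good_runs run indices to use (default: all; normally the good set
#'   from [detect_bad_runs()]).
#' @param p_threshold uncorrected per-pair p threshold (default 0.001).
#' @return A `reliability_map`: list with `values` (3D percentages, zero
#'   outside the mask), `n_good_runs`, `n_pairs`, `t_threshold`,
#'   `p_threshold`.
#' @export
reliability_map <- function(pairs, good_runs = seq_len(pairs$n_runs),
                            p_threshold = 0.001) {
  stopifnot(inherits(pairs, "pair_stats"))
  if (length(good_runs) < 2) stop("need at least 2 good runs")
  thr <- stats::qt(1 - p_threshold, df = pairs$dof)
  sel <- pair_selector(pairs, good_runs)
  P <- sum(sel)
  m <- rowSums(pairs$t[, sel, drop = FALSE] > thr)
  structure(list(values = vec_to_grid(pairs, 100 * m / P),
                 n_good_runs = length(good_runs), n_pairs = P,
                 t_threshold = thr, p_threshold = p_threshold),
            class = "reliability_map")
}

#' @export
print.reliability_map <- function(x, ...) {
  cat(sprintf("reliability_map: %d good runs (%d pairs), t threshold %.3f (p < %g)\n",
              x$n_good_runs, x$n_pairs, x$t_threshold, x$p_threshold))
  cat(sprintf("  max reliability %.1f%%, voxels at 100%%: %d\n",
              max(x$values), sum(x$values == 100)))
  invisible(x)
}

#' Full model-free analysis of a session
#'
#' Convenience pipeline: per-run quadratic detrending, pairwise fits over all
#' non-identical run combinations, automatic bad-run exclusion, and the final
#' reliability, mean-beta and subject t-maps over the good runs.
#'
#' @param session an [fmri_session()] of raw (realigned) runs.
#' @param detrend apply [detrend_poly2()] per run first (default TRUE).
#' @param exclude_bad run [detect_bad_runs()] (default TRUE).
#' @param p_threshold per-pair threshold for the reliability map.
#' @param alpha significance level of the bad-run Welch tests.
#' @param top_percentile,smooth_fwhm_vox activation-mask parameters.
#' @return list with `reliability` ([reliability_map()]), `mean_beta`,
#'   `subject_t` (3D grids), `bad_runs` (report or NULL), `good_runs`,
#'   `pairs` (the `pair_stats`).
#' @export
run_unbiased <- function(session, detrend = TRUE, exclude_bad = TRUE,
                         p_threshold = 0.001, alpha = 0.05,
                         top_percentile = 0.01, smooth_fwhm_vox = 2) {
  stopifnot(inherits(session, "fmri_session"))
  if (detrend) session <- detrend_session(session)
  ps <- all_pair_fits(session)
  report <- NULL
  good <- seq_len(ps$n_runs)
  if (exclude_bad) {
    report <- detect_bad_runs(ps, alpha = alpha, top_percentile = top_percentile,
                              smooth_fwhm_vox = smooth_fwhm_vox)
    good <- report$good_runs
  }
  list(reliability = reliability_map(ps, good, p_threshold = p_threshold),
       mean_beta = mean_beta_map(ps, good),
       subject_t = if (length(good) >= 3) subject_t_map(ps, good) else NULL,
       bad_runs = report, good_runs = good, pairs = ps)
}
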