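# Automatic identification of low-quality ("bad") runs. Runs affected by poor
# task performance or artefacts depress the subject-level t values in the main
# activation foci; removing such a run raises the leave-one-out t-map, which a
# one-sided Welch test detects.

#' Activation mask from a subject t-map
#'
#' Binarises the voxels whose t value exceeds the top percentile of in-mask
#' values (strict inequality, linear-interpolation quantile), smooths the
#' binary map with a 3D Gaussian and re-binarises at > 0.5, then intersects
#' with the brain mask. If smoothing empties the set, the unsmoothed
#' top-percentile set is used instead (with a message). If even the strict cut
#' is empty (a constant map), ties at the threshold are admitted.
#'
#' @param t_map 3D statistic grid.
#' @param brain_mask logical 3D array.
#' @param top_percentile fraction of in-mask voxels to select (default 0.01,
#'   i.e. the top 1 percentile).
#' @param smooth_fwhm_vox Gaussian FWHM in voxels (default 2; 0 disables
#'   smoothing).
#' @return Logical 3D array.
#' @export
activation_mask <- function(t_map, brain_mask, top_percentile = 0.01,
                            smooth_fwhm_vox = 2) {
  stopifnot(identical(dim(t_map), dim(brain_mask)))
  vals <- t_map[brain_mask]
  if (!all(is.finite(vals))) stop("t-map must be finite inside the mask")
  thr <- stats::quantile(vals, 1 - top_percentile, names = FALSE)
  raw <- t_map > thr & brain_mask
  if (!any(raw)) {
    message("top-percentile cut is empty (ties at the threshold); including ties")
    raw <- t_map >= thr & brain_mask
  }
  if (smooth_fwhm_vox <= 0) return(raw)
  sm <- gaussian_smooth3(raw * 1, smooth_fwhm_vox) > 0.5 & brain_mask
  if (!any(sm)) {
    message("activation mask empty after smoothing; falling back to unsmoothed set")
    return(raw)
  }
  sm
}

#' One-sided Welch two-sample t test
#'
#' Tests the alternative `mean(b) > mean(a)` without assuming equal
#' variances: `t = (mean(b) - mean(a)) / sqrt(var(a)/na + var(b)/nb)` with
#' Welch-Satterthwaite degrees of freedom. When both samples are constant the
#' statistic is defined as 0 (equal means) or +/-Inf.
#'
#' @param a,b numeric vectors with at least 2 elements each.
#' @return list with `t`, `dof`, `p` (one-sided).
#' @export
welch_one_sided <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("both samples need at least 2 elements")
  va <- stats::var(a); vb <- stats::var(b)
  dm <- mean(b) - mean(a)
  if (va == 0 && vb == 0) {
    t <- if (dm == 0) 0 else sign(dm) * Inf
    return(list(t = t, dof = na + nb - 2,
                p = if (dm == 0) 0.5 else if (dm > 0) 0 else 1))
  }
  se2 <- va / na + vb / nb
  t <- dm / sqrt(se2)
  dof <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, dof = dof, p = stats::pt(t, dof, lower.tail = FALSE))
}

#' Iterative exclusion of bad runs
#'
#' Each pass: (1) the subject t-map over the current good runs is computed;
#' (2) an [activation_mask()] is derived from it; (3) for every candidate run
#' n, the leave-one-out subject t-map (excluding n) is compared to the
#' all-good-runs map inside the activation mask with a one-sided Welch test
#' (alternative: excluding n *raises* the t values); (4) runs with
#' `p < alpha / n_tested` (Bonferroni over the runs tested this pass) are
#' flagged; (5) if any are flagged, exactly one run is excluded and the pass
#' repeats. The loop stops when nothing is flagged or fewer than 4 good runs
#' remain (a leave-one-out map needs at least 3 runs to yield 2 or more
#' pairs, so sessions with 2 or 3 runs cannot be tested and are reported
#' untested).
#'
#' When several runs are flagged in one pass, the default `selection =
#' "mean_t"` excludes the run with the smallest mean subject-level t inside
#' the pass's activation mask, where that run's subject t is computed from
#' only the pairs involving it (bad runs show the lowest t values in the
#' activation foci). `selection = "welch"` instead excludes the flagged run
#' with the largest Welch statistic (the largest improvement on removal).
#'
#' @param pairs a `pair_stats` from [all_pair_fits()].
#' @param alpha per-pass significance level before Bonferroni correction
#'   (default 0.05).
#' @param selection tie-break rule among multiply-flagged runs.
#' @param top_percentile,smooth_fwhm_vox passed to [activation_mask()].
#' @return A `bad_run_report`: `excluded` (in exclusion order), `good_runs`,
#'   `passes` (one row per run tested per pass), `activation_mask` (from the
#'   final pass), `tested` (logical).
#' @export
detect_bad_runs <- function(pairs, alpha = 0.05,
                            selection = c("mean_t", "welch"),
                            top_percentile = 0.01, smooth_fwhm_vox = 2) {
  stopifnot(inherits(pairs, "pair_stats"))
  selection <- match.arg(selection)
  all_runs <- seq_len(pairs$n_runs)
  good <- all_runs
  excluded <- integer(0)
  rows <- list()
  amask <- NULL
  pass <- 0L
  if (length(good) < 4) {
    message("fewer than 4 runs: bad-run testing not performed")
  } else {
    repeat {
      pass <- pass + 1L
      t_all <- subject_t_vec(pairs, good)
      amask <- activation_mask(vec_to_grid(pairs, t_all), pairs$mask,
                               top_percentile, smooth_fwhm_vox)
      sel <- amask[pairs$voxels]
      a <- t_all[sel]
      n_tested <- length(good)
      corr_alpha <- alpha / n_tested
      wres <- lapply(good, function(n) {
        t_ex <- subject_t_vec(pairs, setdiff(good, n))
        welch_one_sided(a, t_ex[sel])
      })
      pvals <- vapply(wres, `[[`, numeric(1), "p")
      flagged <- good[pvals < corr_alpha]
      out <- if (length(flagged) == 0) NA_integer_
             else if (length(flagged) == 1) flagged
             else if (selection == "welch") {
               flagged[which.max(vapply(wres[match(flagged, good)], `[[`,
                                        numeric(1), "t"))]
             } else {
               score <- vapply(flagged, function(n) {
                 inv <- pairs$pairs$j == n | pairs$pairs$k == n
                 ok <- inv & pair_selector(pairs, good)
                 bb <- pairs$beta[, ok, drop = FALSE]
                 mu <- rowMeans(bb)
                 sdv <- sqrt(rowSums((bb - mu)^2) / (ncol(bb) - 1))
                 tn <- ifelse(sdv > 0, mu * sqrt(ncol(bb)) / sdv,
                              sign(mu) * T_CLAMP)
                 mean(tn[sel])
               }, numeric(1))
               flagged[which.min(score)]
             }
      dec <- rep("kept", n_tested)
      dec[good %in% flagged] <- "flagged"
      if (!is.na(out)) dec[good == out] <- "excluded"
      rows[[pass]] <- data.frame(
        pass = pass, run_id = good,
        welch_t = vapply(wres, `[[`, numeric(1), "t"),
        welch_dof = vapply(wres, `[[`, numeric(1), "dof"),
        p_one_sided = pvals, alpha_corrected = corr_alpha,
        decision = dec)
      if (is.na(out)) break
      excluded <- c(excluded, out)
      good <- setdiff(good, out)
      if (length(good) < 4) break
    }
  }
  structure(list(excluded = excluded, good_runs = good,
                 passes = if (length(rows)) do.call(rbind, rows)
                          else data.frame(pass = integer(0), run_id = integer(0),
                                          welch_t = numeric(0), welch_dof = numeric(0),
                                          p_one_sided = numeric(0),
                                          alpha_corrected = numeric(0),
                                          decision = character(0)),
                 activation_mask = amask,
                 tested = length(all_runs) >= 4,
                 alpha = alpha, selection = selection),
            class = "bad_run_report")
}

#' @export
print.bad_run_report <- function(x, ...) {
  if (!x$tested) cat("bad_run_report: not tested (fewer than 4 runs)\n")
  else if (!length(x$excluded)) cat("bad_run_report: no runs excluded\n")
  else cat("bad_run_report: excluded run(s)", paste(x$excluded, collapse = ", "), "\n")
  cat("  good runs:", paste(x$good_runs, collapse = ", "), "\n")
  invisible(x)
}
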