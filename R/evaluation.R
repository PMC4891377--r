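# Assessment experiments: split-half congruence with count-matched GLM
# thresholds, and sensitivity of both analyses to global timing shifts.

#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)` between two binary masks. Two empty masks are
#' defined to overlap perfectly (Dice 1) so threshold tables stay total; the
#' case is flagged via the `both_empty` attribute.
#'
#' @param a,b logical arrays of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(structure(1, both_empty = TRUE))
  2 * sum(a & b) / (na + nb)
}

#' Count-matched threshold of a statistic map
#'
#' Selects the `n` in-mask voxels with the largest values, which matches a
#' model-based map's activation extent to a reliability level's voxel count.
#' Ties at the cut are broken deterministically by lexicographic voxel index
#' (x, then y, then z).
#'
#' @param t_map 3D statistic grid.
#' @param mask logical 3D array.
#' @param n number of voxels to select, `0 <= n <= sum(mask)`.
#' @return Logical 3D array with exactly `n` TRUE voxels.
#' @export
match_count_threshold <- function(t_map, mask, n) {
  stopifnot(identical(dim(t_map), dim(mask)))
  idx <- which(mask)
  if (n > length(idx)) stop("n exceeds the mask size")
  out <- array(FALSE, dim(mask))
  if (n == 0) return(out)
  ai <- arrayInd(idx, dim(mask))
  ord <- order(-t_map[idx], ai[, 1], ai[, 2], ai[, 3])
  out[idx[ord[seq_len(n)]]] <- TRUE
  out
}

#' Split-half consistency of the model-free and GLM analyses
#'
#' Runs are split by 1-based acquisition position into odd and even halves,
#' each analysed separately with the model-free pipeline and with the
#' per-run GLM. At every reliability level r (0 to 100 in steps of
#' `reliability_step`) the model-free mask is `{reliability >= r}` per half,
#' the GLM mask is the count-matched top-t set ([match_count_threshold()])
#' with that half's model-free voxel count, and odd/even congruence is
#' scored with [dice()] per method. Bad-run exclusion is off inside halves
#' by default so both halves keep matched pair counts.
#'
#' @param session an [fmri_session()] with at least 4 runs and a design.
#' @param reliability_step threshold step in percent (default 5).
#' @param display_threshold reliability level for the congruence label maps
#'   (default 50).
#' @param exclude_bad run bad-run exclusion within each half (default FALSE).
#' @param detrend detrend runs before analysis (default TRUE).
#' @return A `split_half_result`: `odd_reliability`, `even_reliability`
#'   (reliability maps), `odd_glm_t`, `even_glm_t` (3D grids),
#'   `dice_table` (threshold, dice_unbiased, dice_glm, n_voxels_odd,
#'   n_voxels_even, both_empty), and congruence label grids
#'   (0 none, 1 both, 2 odd-only, 3 even-only) per method.
#' @export
split_half <- function(session, reliability_step = 5, display_threshold = 50,
                       exclude_bad = FALSE, detrend = TRUE) {
  stopifnot(inherits(session, "fmri_session"))
  N <- session$n_runs
  if (N < 4) stop("split-half needs at least 4 runs")
  halves <- list(odd = seq(1, N, by = 2), even = seq(2, N, by = 2))
  sub <- lapply(halves, function(ix)
    fmri_session(lapply(seq_along(ix), function(i) {
      r <- session$runs[[ix[i]]]
      r$run_id <- i
      r
    }), mask = session$mask, design = session$design))
  ub <- lapply(sub, run_unbiased, detrend = detrend, exclude_bad = exclude_bad)
  gl <- lapply(sub, function(s) {
    if (detrend) s <- detrend_session(s)
    glm_session(s)
  })
  mask <- session$mask
  thresholds <- seq(0, 100, by = reliability_step)
  rows <- lapply(thresholds, function(r) {
    mo <- ub$odd$reliability$values >= r & mask
    me <- ub$even$reliability$values >= r & mask
    du <- dice(mo, me)
    go <- match_count_threshold(gl$odd$t, mask, sum(mo))
    ge <- match_count_threshold(gl$even$t, mask, sum(me))
    dg <- dice(go, ge)
    data.frame(threshold = r, dice_unbiased = as.numeric(du),
               dice_glm = as.numeric(dg),
               n_voxels_odd = sum(mo), n_voxels_even = sum(me),
               both_empty = isTRUE(attr(du, "both_empty")))
  })
  congruence <- function(mo, me) {
    lab <- array(0L, dim(mask))
    lab[mo & me] <- 1L
    lab[mo & !me] <- 2L
    lab[!mo & me] <- 3L
    lab
  }
  mo <- ub$odd$reliability$values >= display_threshold & mask
  me <- ub$even$reliability$values >= display_threshold & mask
  go <- match_count_threshold(gl$odd$t, mask, sum(mo))
  ge <- match_count_threshold(gl$even$t, mask, sum(me))
  structure(list(odd_reliability = ub$odd$reliability,
                 even_reliability = ub$even$reliability,
                 odd_glm_t = gl$odd$t, even_glm_t = gl$even$t,
                 dice_table = do.call(rbind, rows),
                 congruence_unbiased = congruence(mo, me),
                 congruence_glm = congruence(go, ge),
                 display_threshold = display_threshold),
            class = "split_half_result")
}

#' Sensitivity of both analyses to global timing shifts
#'
#' Applies the same circular time shift to every run and re-runs both
#' analyses, tabulating the mean GLM t and the mean reliability inside an
#' ROI. Because the shift is global and circular and is applied to the
#' detrended series, the pairwise fits see identical point sets, so the
#' reliability column is constant across shifts, whereas the GLM's
#' regressor-to-response alignment (and hence its t values) changes.
#'
#' @param session an [fmri_session()] with a design.
#' @param shifts_volumes signed integer shifts (default -3:3).
#' @param roi logical 3D array over which means are taken.
#' @param detrend detrend before shifting (default TRUE).
#' @param exclude_bad run bad-run exclusion at each shift (default FALSE).
#' @param p_threshold reliability pair threshold.
#' @return A data frame (`shift_table`) with columns `shift_volumes`,
#'   `shift_seconds`, `mean_glm_t_in_roi`, `mean_reliability_in_roi`.
#' @export
shift_sensitivity <- function(session, shifts_volumes = -3:3, roi,
                              detrend = TRUE, exclude_bad = FALSE,
                              p_threshold = 0.001) {
  stopifnot(inherits(session, "fmri_session"))
  stopifnot(identical(dim(roi), spatial_dim(session$runs[[1]])))
  if (detrend) session <- detrend_session(session)
  TT <- n_volumes(session$runs[[1]])
  if (any(abs(shifts_volumes) >= TT)) stop("shift out of range")
  regressor <- block_regressor(session$design, TT, session$tr)
  rows <- lapply(shifts_volumes, function(s) {
    sh <- shift_session(session, s)
    ps <- all_pair_fits(sh)
    good <- seq_len(ps$n_runs)
    if (exclude_bad) good <- detect_bad_runs(ps)$good_runs
    rel <- reliability_map(ps, good, p_threshold = p_threshold)
    gt <- glm_session(sh, regressor = regressor, runs = good)
    data.frame(shift_volumes = s, shift_seconds = s * session$tr,
               mean_glm_t_in_roi = mean(gt$t[roi]),
               mean_reliability_in_roi = mean(rel$values[roi]))
  })
  structure(do.call(rbind, rows), class = c("shift_table", "data.frame"))
}
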