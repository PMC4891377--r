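# Baseline drift removal and circular temporal shifting.

poly2_residual_maker <- function(TT) {
  tt <- 0:(TT - 1)
  X <- cbind(1, tt, tt^2)
  diag(TT) - X %*% solve(crossprod(X), t(X))
}

#' Remove second-order polynomial baseline drift
#'
#' For each voxel the least-squares quadratic `a0 + a1*t + a2*t^2` in the
#' volume index `t = 0..T-1` is subtracted from the time course, removing
#' scanner drift and the mean. Voxels outside the mask are zeroed. Each run is
#' detrended independently.
#'
#' @param run a [run_series()] with at least 4 volumes.
#' @param mask optional logical 3D array; default all voxels.
#' @return A detrended `run_series`.
#' @export
detrend_poly2 <- function(run, mask = NULL) {
  stopifnot(inherits(run, "run_series"))
  TT <- n_volumes(run)
  if (TT < 4) stop("detrending needs at least 4 volumes")
  R <- poly2_residual_maker(TT)
  m <- matrix(run$data, ncol = TT)
  if (!is.null(mask)) {
    idx <- which(mask)
    out <- matrix(0, nrow(m), TT)
    out[idx, ] <- m[idx, , drop = FALSE] %*% R
  } else {
    out <- m %*% R
  }
  dim(out) <- dim(run$data)
  run$data <- out
  run
}

#' Detrend every run of a session
#'
#' @param session an [fmri_session()].
#' @return The session with [detrend_poly2()] applied to each run (using the
#'   session mask).
#' @export
detrend_session <- function(session) {
  stopifnot(inherits(session, "fmri_session"))
  session$runs <- lapply(session$runs, detrend_poly2, mask = session$mask)
  session
}

#' Circularly shift a run in time
#'
#' A positive shift of `n` volumes moves the final `n` volumes to the
#' beginning of the time series; a negative shift moves the first `|n|`
#' volumes to the end. Shifting by 0 is the identity.
#'
#' @param run a [run_series()].
#' @param n_volumes signed integer shift, `|n| < T`.
#' @return The shifted `run_series`.
#' @export
circular_shift <- function(run, n_volumes) {
  stopifnot(inherits(run, "run_series"))
  TT <- dim(run$data)[4]
  n <- as.integer(n_volumes)
  if (abs(n) >= TT) stop("|shift| must be smaller than the number of volumes")
  if (n == 0) return(run)
  ord <- ((seq_len(TT) - 1 - n) %% TT) + 1
  run$data <- run$data[, , , ord, drop = FALSE]
  run
}

#' Apply the same circular shift to every run of a session
#'
#' @param session an [fmri_session()].
#' @param n_volumes signed integer shift passed to [circular_shift()].
#' @return The shifted session.
#' @export
shift_session <- function(session, n_volumes) {
  session$runs <- lapply(session$runs, circular_shift, n_volumes = n_volumes)
  session
}
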