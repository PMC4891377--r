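# Small numerical helpers shared across modules.

# t statistics from degenerate (zero-residual) fits are clamped to this
# magnitude so that downstream Welch tests and percentiles stay finite.
T_CLAMP <- 1e6

`%||%` <- function(a, b) if (is.null(a)) b else a

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Shift a 3D array by `o` voxels along `axis`, zero-filling the vacated slab.
shift_zero <- function(a, axis, o) {
  if (o == 0) return(a)
  d <- dim(a)
  n <- d[axis]
  if (abs(o) >= n) return(array(0, d))
  out <- array(0, d)
  src <- seq_len(n - abs(o))
  if (o > 0) dst <- src + o else { dst <- src; src <- src + abs(o) }
  io <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  ii <- io
  io[[axis]] <- dst
  ii[[axis]] <- src
  out[io[[1]], io[[2]], io[[3]]] <- a[ii[[1]], ii[[2]], ii[[3]]]
  out
}

# Separable 3D Gaussian smoothing with zero-padded borders. The kernel is
# truncated at 3 sigma and renormalised, so a constant field far from the
# border stays constant.
gaussian_smooth3 <- function(vol, fwhm) {
  stopifnot(length(dim(vol)) == 3)
  if (fwhm <= 0) return(vol)
  sigma <- fwhm_to_sigma(fwhm)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  vol <- vol * 1
  for (axis in 1:3) {
    out <- array(0, dim(vol))
    for (o in seq(-r, r)) out <- out + k[o + r + 1] * shift_zero(vol, axis, o)
    vol <- out
  }
  vol
}

# Connected components of a logical 3D array under 26-connectivity.
# Returns an integer array of labels (0 = background), labelled in first-found
# order. Plain stack-based flood fill; grids here are modest.
label_components <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  d <- dim(mask)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  lab <- array(0L, d)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    lab[start] <- cur
    stack <- start
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      ci <- arrayInd(v, d)
      nb <- sweep(off, 2, as.integer(ci), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
            nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      new <- lin[mask[lin] & lab[lin] == 0L]
      lab[new] <- cur
      stack <- c(stack, new)
    }
  }
  lab
}
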