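# In-code fixtures shared across test files.

# A run_series from a voxels-by-time matrix laid out on a (V, 1, 1) grid.
run_from_matrix <- function(m, tr = 1, run_id = 1L) {
  run_series(array(m, c(nrow(m), 1, 1, ncol(m))), tr = tr, run_id = run_id)
}

# A session of runs given as V x T matrices on a (V, 1, 1) grid.
session_from_matrices <- function(mats, tr = 1, design = NULL) {
  runs <- lapply(seq_along(mats), function(i) run_from_matrix(mats[[i]], tr, i))
  fmri_session(runs, mask = array(TRUE, c(nrow(mats[[1]]), 1, 1)),
               design = design)
}

# A hand-built pair_stats object for forced-arithmetic tests: beta (and
# optionally t) as V x P matrices over an all-true (V, 1, 1) mask.
fake_pair_stats <- function(beta, t = beta, n_runs, dof = 54, r2 = NULL) {
  beta <- as.matrix(beta); t <- as.matrix(t)
  pr <- utils::combn(n_runs, 2)
  stopifnot(ncol(beta) == ncol(pr))
  V <- nrow(beta)
  structure(list(beta = beta, t = t,
                 r2 = r2 %||% matrix(0, V, ncol(beta)),
                 ssres = matrix(0, V, ncol(beta)),
                 sstot = matrix(1, V, ncol(beta)),
                 pairs = data.frame(j = pr[1, ], k = pr[2, ]),
                 dof = dof, n_runs = n_runs, n_volumes = dof + 2,
                 mask = array(TRUE, c(V, 1, 1)), voxels = seq_len(V),
                 dim = c(V, 1, 1), tr = 1),
            class = "pair_stats")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Closed-form simple regression with intercept: slope, t and R^2.
ols_closed_form <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  beta <- sxy / sxx
  ssres <- syy - beta * sxy
  se <- sqrt(ssres / ((n - 2) * sxx))
  list(beta = beta, t = beta / se, r2 = sxy^2 / (sxx * syy))
}

# Small default synthetic session (fast; study-condition defaults otherwise).
quick_sim <- function(grid = c(20, 20, 6), n_runs = 6, seed = 1, ...) {
  generate_session(synth_config(grid = grid, n_runs = n_runs, seed = seed, ...))
}
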