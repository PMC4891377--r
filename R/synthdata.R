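# Synthetic multi-run BOLD sessions with known ground truth. The generator
# emulates block-design sessions as acquired for presurgical mapping at 7 T:
# a stable baseline, task responses of configurable shape and amplitude
# (percent signal change), per-run quadratic scanner drift, and white
# Gaussian noise at a target temporal SNR.

#' Standard block designs
#'
#' Two designs are available. `motor_ababab`: four rest and three task
#' phases of 20 s each in an ABABABA pattern (total 140 s; 56 volumes at
#' TR 2.5 s). `visuomotor`: 10 s initial rest, then five repetitions of 10 s
#' task + 20 s rest (total 160 s; 160 volumes at TR 1 s).
#'
#' @param kind `"motor_ababab"` or `"visuomotor"`.
#' @param tr repetition time in seconds; defaults to 2.5 (motor) or 1
#'   (visuomotor). Must divide the total duration evenly.
#' @return list with `design` (a [design_spec()]) and `n_volumes`.
#' @export
make_design <- function(kind = c("motor_ababab", "visuomotor"), tr = NULL) {
  kind <- match.arg(kind)
  if (kind == "motor_ababab") {
    tr <- tr %||% 2.5
    design <- design_spec(onsets = c(20, 60, 100), durations = 20,
                          total_duration = 140, label = "motor_ababab")
  } else {
    tr <- tr %||% 1
    design <- design_spec(onsets = c(10, 40, 70, 100, 130), durations = 10,
                          total_duration = 160, label = "visuomotor")
  }
  TT <- design$total_duration / tr
  if (abs(TT - round(TT)) > 1e-9) stop("TR must divide the total duration")
  list(design = design, n_volumes = as.integer(round(TT)), tr = tr)
}

#' Voxel indices of an axis-aligned block
#'
#' @param x,y,z integer index ranges (e.g. `13:20`).
#' @return n x 3 integer matrix of voxel indices.
#' @export
cube_voxels <- function(x, y, z) {
  as.matrix(expand.grid(x = as.integer(x), y = as.integer(y), z = as.integer(z)))
}

#' Specification of one responding region
#'
#' @param voxels n x 3 integer matrix of voxel indices (see [cube_voxels()]).
#' @param shape response shape: `"canonical"` (boxcar convolved with the
#'   canonical HRF), `"delayed"` (same with onsets shifted by `delay`),
#'   `"transient_onset_offset"` (brief responses at each block start and
#'   end), `"negative"` (sign-flipped canonical), `"none"` (no response).
#' @param amplitude peak signal change in percent of baseline (default 4, a
#'   strong primary motor/visual response at 7 T).
#' @param delay onset delay in seconds (for `"delayed"`).
#' @param transient_width width of the onset/offset impulses in seconds.
#' @return A `region_spec`.
#' @export
region_spec <- function(voxels, shape = c("canonical", "delayed",
                                          "transient_onset_offset",
                                          "negative", "none"),
                        amplitude = 4, delay = 0, transient_width = 2) {
  shape <- match.arg(shape)
  voxels <- as.matrix(voxels)
  stopifnot(ncol(voxels) == 3, amplitude >= 0, is.finite(delay),
            transient_width > 0)
  structure(list(voxels = voxels, shape = shape, amplitude = amplitude,
                 delay = delay, transient_width = transient_width),
            class = "region_spec")
}

#' Noiseless response template for a region
#'
#' The region's response time course at the volume sampling times, in percent
#' signal change (peak magnitude equals the region's amplitude).
#'
#' @param region a [region_spec()].
#' @param design a [design_spec()].
#' @param n_volumes,tr sampling grid.
#' @param hrf HRF kernel (default [canonical_hrf()]).
#' @return Numeric vector of length `n_volumes`.
#' @export
response_template <- function(region, design, n_volumes, tr,
                              hrf = canonical_hrf()) {
  stopifnot(inherits(region, "region_spec"), inherits(design, "design_spec"))
  total <- max(design$total_duration, n_volumes * tr)
  x <- switch(region$shape,
    none = numeric(n_volumes),
    canonical = convolve_boxcar(design$onsets, design$durations, total,
                                n_volumes, tr, hrf),
    negative = -convolve_boxcar(design$onsets, design$durations, total,
                                n_volumes, tr, hrf),
    delayed = convolve_boxcar(design$onsets + region$delay, design$durations,
                              total, n_volumes, tr, hrf),
    transient_onset_offset = {
      on <- sort(c(design$onsets, design$onsets + design$durations))
      convolve_boxcar(on, region$transient_width, total, n_volumes, tr, hrf)
    })
  m <- max(abs(x))
  if (m > 0) x <- x / m * region$amplitude
  x
}

#' Configuration of a synthetic session
#'
#' Defaults describe a typical 7 T presurgical motor session: 10 runs of the
#' ABABABA design on a 32 x 32 x 8 grid, baseline 1000 units, temporal SNR 70
#' (noise SD ~14.3), one centrally placed canonical region at 4 percent peak
#' signal change, and gentle per-run quadratic drift.
#'
#' @param grid spatial dimensions (X, Y, Z).
#' @param design_kind passed to [make_design()].
#' @param tr repetition time; `NULL` uses the design's default.
#' @param n_runs number of runs (>= 2).
#' @param regions list of [region_spec()]; `NULL` gives one canonical cube
#'   spanning the central quarter of the grid in x/y and central half in z.
#' @param brain logical 3D array; `NULL` gives a centred box with a 15
#'   percent margin in x/y and one-voxel margin in z. Outside the brain the
#'   signal is exactly zero.
#' @param baseline baseline intensity in arbitrary units.
#' @param tsnr_target temporal SNR (baseline / noise SD); ignored when
#'   `noise_sd` is given.
#' @param noise_sd Gaussian noise SD in signal units (overrides
#'   `tsnr_target`).
#' @param drift_coeff_sd SDs of the per-run quadratic drift coefficients
#'   (constant, linear, quadratic term per volume index).
#' @param bad_runs run indices generated with zero task amplitude.
#' @param seed integer seed; the full session is reproducible from it.
#' @return A `synth_config`.
#' @export
synth_config <- function(grid = c(32, 32, 8), design_kind = "motor_ababab",
                         tr = NULL, n_runs = 10, regions = NULL, brain = NULL,
                         baseline = 1000, tsnr_target = 70, noise_sd = NULL,
                         drift_coeff_sd = c(10, 0.5, 0.01),
                         bad_runs = integer(0), seed = 1) {
  stopifnot(length(grid) == 3, n_runs >= 2, baseline > 0,
            length(drift_coeff_sd) == 3, all(drift_coeff_sd >= 0))
  if (is.null(noise_sd)) noise_sd <- baseline / tsnr_target
  stopifnot(noise_sd >= 0)
  grid <- as.integer(grid)
  if (is.null(brain)) {
    m <- pmax(1L, as.integer(round(grid * 0.15)))
    m[3] <- 1L
    brain <- array(FALSE, grid)
    brain[(m[1] + 1):(grid[1] - m[1]), (m[2] + 1):(grid[2] - m[2]),
          (m[3] + 1):(grid[3] - m[3])] <- TRUE
  }
  stopifnot(identical(dim(brain), grid), any(brain))
  if (is.null(regions)) {
    q <- pmax(1L, grid %/% 8L)
    ctr <- grid %/% 2L
    regions <- list(region_spec(cube_voxels(
      (ctr[1] - q[1] + 1):(ctr[1] + q[1]),
      (ctr[2] - q[2] + 1):(ctr[2] + q[2]),
      (ctr[3] - grid[3] %/% 4L + 1):(ctr[3] + grid[3] %/% 4L))))
  }
  lin <- lapply(regions, function(rg) {
    v <- rg$voxels
    if (any(v < 1) || any(v[, 1] > grid[1]) || any(v[, 2] > grid[2]) ||
        any(v[, 3] > grid[3]))
      stop("region voxels outside the grid")
    v[, 1] + (v[, 2] - 1) * grid[1] + (v[, 3] - 1) * grid[1] * grid[2]
  })
  if (anyDuplicated(unlist(lin))) stop("region voxel sets must be disjoint")
  if (length(bad_runs) && (any(bad_runs < 1) || any(bad_runs > n_runs)))
    stop("bad_runs outside 1..n_runs")
  structure(list(grid = grid, design_kind = design_kind, tr = tr,
                 n_runs = as.integer(n_runs), regions = regions,
                 region_lin = lin, brain = brain, baseline = baseline,
                 noise_sd = noise_sd, drift_coeff_sd = drift_coeff_sd,
                 bad_runs = as.integer(bad_runs), seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic multi-run session with ground truth
#'
#' Per run r and voxel v inside the brain:
#' `signal = baseline * (1 + template_v/100) + drift_r(t) + noise`, where
#' `drift_r` is a quadratic in the volume index with coefficients drawn
#' fresh per run from `Normal(0, drift_coeff_sd)`, and the noise is white
#' Gaussian, independent across runs, voxels and time. Runs listed in
#' `bad_runs` have their task templates zeroed (the paradigm was "not
#' performed"). Noise and drift draws come from a per-run seed stream derived
#' from the master seed, so the same seed always reproduces the identical
#' session and editing the region list does not perturb the noise.
#'
#' @param config a [synth_config()].
#' @return list with `session` (an [fmri_session()] whose mask is the true
#'   brain) and `truth`: `active_mask`, `shape_label` (0 background/none,
#'   1 canonical, 2 delayed, 3 transient, 4 negative), `templates` (per
#'   region, percent signal change), `bad_runs`, `noise_sd`, `tsnr`.
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  des <- make_design(cf$design_kind, cf$tr)
  TT <- des$n_volumes
  tr <- des$tr
  hrf <- canonical_hrf()
  tmpl <- lapply(cf$regions, response_template, design = des$design,
                 n_volumes = TT, tr = tr, hrf = hrf)
  set.seed(cf$seed)
  noise_seeds <- sample.int(.Machine$integer.max - 1L, cf$n_runs)
  drift_seeds <- sample.int(.Machine$integer.max - 1L, cf$n_runs)
  bidx <- which(cf$brain)
  nb <- length(bidx)
  nvox <- prod(cf$grid)
  tvec <- 0:(TT - 1)
  runs <- vector("list", cf$n_runs)
  for (r in seq_len(cf$n_runs)) {
    m <- matrix(0, nvox, TT)
    m[bidx, ] <- cf$baseline
    if (!(r %in% cf$bad_runs)) {
      for (i in seq_along(cf$regions)) {
        add <- cf$baseline * tmpl[[i]] / 100
        m[cf$region_lin[[i]], ] <- m[cf$region_lin[[i]], , drop = FALSE] +
          matrix(add, length(cf$region_lin[[i]]), TT, byrow = TRUE)
      }
    }
    set.seed(drift_seeds[r])
    co <- stats::rnorm(3) * cf$drift_coeff_sd
    drift <- co[1] + co[2] * tvec + co[3] * tvec^2
    m[bidx, ] <- m[bidx, ] + matrix(drift, nb, TT, byrow = TRUE)
    set.seed(noise_seeds[r])
    if (cf$noise_sd > 0)
      m[bidx, ] <- m[bidx, ] + matrix(stats::rnorm(nb * TT, sd = cf$noise_sd),
                                      nb, TT)
    dim(m) <- c(cf$grid, TT)
    runs[[r]] <- run_series(m, tr = tr, run_id = r)
  }
  shape_code <- c(canonical = 1L, delayed = 2L, transient_onset_offset = 3L,
                  negative = 4L, none = 0L)
  shape_label <- array(0L, cf$grid)
  active <- array(FALSE, cf$grid)
  for (i in seq_along(cf$regions)) {
    shape_label[cf$region_lin[[i]]] <- shape_code[[cf$regions[[i]]$shape]]
    if (cf$regions[[i]]$shape != "none") active[cf$region_lin[[i]]] <- TRUE
  }
  session <- fmri_session(runs, mask = cf$brain, design = des$design)
  list(session = session,
       truth = list(active_mask = active, shape_label = shape_label,
                    templates = tmpl, bad_runs = cf$bad_runs,
                    noise_sd = cf$noise_sd,
                    tsnr = cf$baseline / max(cf$noise_sd, .Machine$double.eps),
                    config = cf))
}

#' Write a synthetic session to disk as a loadable dataset
#'
#' Writes per-run NIfTI files, the brain mask, ground-truth maps
#' (`active_mask`, `shape_label`), a `manifest.yaml` understood by
#' [load_session()], and a `params.json` record of the generation settings.
#'
#' @param sim result of [generate_session()].
#' @param dir output directory (created if needed).
#' @return Path to the written manifest.
#' @export
write_synth_session <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  session <- sim$session
  run_files <- sprintf("run%02d.nii.gz", seq_len(session$n_runs))
  for (i in seq_len(session$n_runs)) {
    RNifti::writeNifti(RNifti::asNifti(session$runs[[i]]$data),
                       file.path(dir, run_files[i]), datatype = "float")
  }
  RNifti::writeNifti(RNifti::asNifti(session$mask * 1L),
                     file.path(dir, "mask.nii.gz"), datatype = "uint8")
  RNifti::writeNifti(RNifti::asNifti(sim$truth$active_mask * 1L),
                     file.path(dir, "active_mask.nii.gz"), datatype = "uint8")
  RNifti::writeNifti(RNifti::asNifti(sim$truth$shape_label),
                     file.path(dir, "shape_label.nii.gz"), datatype = "int16")
  de <- session$design
  manifest <- list(runs = as.list(run_files),
                   tr_seconds = session$tr,
                   mask = "mask.nii.gz",
                   design = list(onsets = de$onsets, durations = de$durations,
                                 total_duration = de$total_duration,
                                 label = de$label))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  cf <- sim$truth$config
  params <- list(grid = cf$grid, design_kind = cf$design_kind,
                 n_runs = cf$n_runs, baseline = cf$baseline,
                 noise_sd = cf$noise_sd, drift_coeff_sd = cf$drift_coeff_sd,
                 bad_runs = cf$bad_runs, seed = cf$seed,
                 regions = lapply(cf$regions, function(rg)
                   list(shape = rg$shape, amplitude = rg$amplitude,
                        delay = rg$delay, transient_width = rg$transient_width,
                        n_voxels = nrow(rg$voxels))))
  jsonlite::write_json(params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  file.path(dir, "manifest.yaml")
}
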