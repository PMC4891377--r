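# Session assembly and NIfTI/TSV input-output.

#' A single fMRI run
#'
#' Container for one run's 4D BOLD signal on a fixed spatial grid. Values are
#' in arbitrary scanner units; spatial correspondence across runs is by voxel
#' index, so runs must already be realigned to a common grid.
#'
#' @param data 4D numeric array (X, Y, Z, T). Non-finite values are zero-filled
#'   with a message.
#' @param tr repetition time in seconds (> 0).
#' @param run_id integer label, by convention the 1-based acquisition position.
#' @param source_path optional path the run was loaded from.
#' @param reference optional `RNifti` header used to propagate geometry when
#'   derived maps are written with [save_map()].
#' @return An object of class `run_series`.
#' @export
run_series <- function(data, tr, run_id = 1L, source_path = NA_character_,
                       reference = NULL) {
  if (length(dim(data)) != 4)
    stop("run data must be a 4D array (X, Y, Z, T)")
  if (dim(data)[4] < 4)
    stop("run must have at least 4 volumes")
  if (!is.numeric(tr) || length(tr) != 1 || tr <= 0)
    stop("tr must be a positive scalar (seconds)")
  bad <- !is.finite(data)
  if (any(bad)) {
    message(sum(bad), " non-finite values zero-filled in run ", run_id)
    data[bad] <- 0
  }
  structure(list(data = data, tr = as.numeric(tr), run_id = as.integer(run_id),
                 source_path = source_path, reference = reference),
            class = "run_series")
}

n_volumes <- function(run) dim(run$data)[4]
spatial_dim <- function(run) dim(run$data)[1:3]

#' Block-design timing specification
#'
#' @param onsets task-block onsets in seconds, strictly increasing.
#' @param durations block durations in seconds (recycled to `length(onsets)`).
#' @param total_duration run duration in seconds.
#' @param label free-text description.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(onsets, durations, total_duration, label = "") {
  durations <- rep_len(durations, length(onsets))
  if (length(onsets) && any(diff(onsets) <= 0))
    stop("onsets must be strictly increasing")
  if (any(onsets < 0) || any(durations <= 0))
    stop("onsets must be >= 0 and durations > 0")
  if (any(onsets + durations > total_duration + 1e-9))
    stop("design exceeds run duration")
  structure(list(onsets = as.numeric(onsets), durations = as.numeric(durations),
                 total_duration = as.numeric(total_duration), label = label),
            class = "design_spec")
}

#' A multi-run fMRI session
#'
#' Ordered collection of co-registered runs with identical grid, volume count
#' and TR, together with a brain mask and (optionally) the task design.
#'
#' @param runs list of [run_series()] objects, in acquisition order.
#' @param mask logical 3D array; if `NULL` it is derived with
#'   [compute_brain_mask()].
#' @param design a [design_spec()] or `NULL`.
#' @return An object of class `fmri_session`.
#' @export
fmri_session <- function(runs, mask = NULL, design = NULL) {
  if (length(runs) < 2) stop("a session needs at least 2 runs")
  if (!all(vapply(runs, inherits, logical(1), "run_series")))
    stop("runs must be run_series objects")
  d0 <- dim(runs[[1]]$data)
  tr0 <- runs[[1]]$tr
  for (r in runs) {
    if (!identical(dim(r$data), d0)) {
      if (!identical(dim(r$data)[1:3], d0[1:3]))
        stop("inconsistent spatial grid across runs")
      stop("inconsistent volume count across runs")
    }
    if (abs(r$tr - tr0) > 1e-9) stop("inconsistent TR across runs")
  }
  if (is.null(mask)) {
    s <- structure(list(runs = runs, mask = NULL, design = design,
                        n_runs = length(runs), tr = tr0), class = "fmri_session")
    mask <- compute_brain_mask(s)
  }
  if (!is.logical(mask) || !identical(dim(mask), d0[1:3]))
    stop("mask must be a logical array matching the spatial grid")
  if (!any(mask)) stop("empty mask")
  if (!is.null(design) && !inherits(design, "design_spec"))
    stop("design must be a design_spec")
  structure(list(runs = runs, mask = mask, design = design,
                 n_runs = length(runs), tr = tr0),
            class = "fmri_session")
}

#' @export
print.fmri_session <- function(x, ...) {
  d <- dim(x$runs[[1]]$data)
  cat(sprintf("fmri_session: %d runs, grid %dx%dx%d, %d volumes, TR %.3g s, %d mask voxels\n",
              x$n_runs, d[1], d[2], d[3], d[4], x$tr, sum(x$mask)))
  invisible(x)
}

#' Derive a brain mask from signal intensity
#'
#' A voxel is in the mask if its temporal mean reaches the given quantile of
#' the nonzero temporal means and its temporal standard deviation is positive
#' in every run (constant voxels carry no usable time course). The comparison
#' at the quantile is inclusive so that an exactly separable phantom (uniform
#' foreground over zero background) is recovered in full.
#'
#' @param x a `run_series` or `fmri_session`. For a session the temporal mean
#'   is averaged over runs and the minimum temporal SD over runs is used.
#' @param intensity_quantile quantile of nonzero temporal means (default 0.25).
#' @return Logical 3D array.
#' @export
compute_brain_mask <- function(x, intensity_quantile = 0.25) {
  if (inherits(x, "run_series")) x <- list(runs = list(x))
  sp <- spatial_dim(x$runs[[1]])
  tmean <- array(0, sp)
  tsd <- NULL
  for (r in x$runs) {
    m <- matrix(r$data, ncol = n_volumes(r))
    mu <- rowMeans(m)
    sdv <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
    tmean <- tmean + array(mu, sp)
    tsd <- if (is.null(tsd)) sdv else pmin(tsd, sdv)
  }
  tmean <- tmean / length(x$runs)
  nz <- tmean[tmean != 0]
  if (!length(nz)) stop("empty mask: input is all zero")
  thr <- stats::quantile(nz, intensity_quantile, names = FALSE)
  mask <- tmean >= thr & array(tsd > 0, sp)
  if (!any(mask)) stop("empty mask")
  mask
}

read_manifest <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}

#' Load a session from a manifest
#'
#' The manifest (YAML or JSON) lists the run files, the TR, optionally a mask
#' file, and the block design:
#' \preformatted{
#' runs: [run01.nii.gz, run02.nii.gz]
#' tr_seconds: 2.5
#' mask: mask.nii.gz            # optional
#' design:                      # optional
#'   onsets: [20, 60, 100]
#'   durations: [20, 20, 20]
#'   total_duration: 140
#' }
#' Relative paths are resolved against the manifest's directory. All runs must
#' share the same grid and volume count (at least 8 volumes); any mismatch is
#' fatal. Without a mask entry, [compute_brain_mask()] is applied.
#'
#' @param manifest path to a YAML/JSON manifest, or an equivalent list.
#' @param base_dir directory against which relative paths are resolved
#'   (defaults to the manifest's directory).
#' @return An [fmri_session()].
#' @export
load_session <- function(manifest, base_dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  base_dir <- base_dir %||% "."
  resolve <- function(p) {
    ifelse(file.exists(p) | grepl("^/", p), p, file.path(base_dir, p))
  }
  paths <- resolve(unlist(manifest$runs))
  if (length(paths) < 2) stop("manifest must list at least 2 runs")
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("missing run file(s): ", paste(missing, collapse = ", "))
  tr <- manifest$tr_seconds
  if (is.null(tr)) stop("manifest must give tr_seconds")
  runs <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    img <- RNifti::readNifti(paths[i])
    a <- as.array(img)
    if (length(dim(a)) == 3) dim(a) <- c(dim(a), 1L)
    if (dim(a)[4] < 8) stop("run ", paths[i], " has fewer than 8 volumes")
    runs[[i]] <- run_series(a, tr = tr, run_id = i, source_path = paths[i],
                            reference = RNifti::niftiHeader(img))
  }
  d0 <- dim(runs[[1]]$data)
  for (r in runs) {
    if (!identical(dim(r$data)[1:3], d0[1:3])) stop("inconsistent grid across runs")
    if (dim(r$data)[4] != d0[4]) stop("inconsistent volume count across runs")
  }
  mask <- NULL
  if (!is.null(manifest$mask)) {
    mask <- as.array(RNifti::readNifti(resolve(manifest$mask))) != 0
    dim(mask) <- d0[1:3]
  }
  design <- NULL
  if (!is.null(manifest$design)) {
    de <- manifest$design
    design <- design_spec(unlist(de$onsets), unlist(de$durations),
                          de$total_duration, de$label %||% "")
  }
  fmri_session(runs, mask = mask, design = design)
}

#' Write a 3D map as NIfTI alongside a reference run
#'
#' The reference run's header geometry (affine, voxel dimensions) is copied so
#' derived maps overlay the EPI data. Values are stored as 32-bit float.
#'
#' @param map numeric or logical 3D array matching the reference spatial grid.
#' @param reference a [run_series()] (its source header is used when present)
#'   or an `RNifti` image/header.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
save_map <- function(map, reference, path) {
  if (is.logical(map)) map <- map * 1
  ref <- reference
  if (inherits(reference, "run_series")) {
    if (!identical(dim(map), spatial_dim(reference)))
      stop("map shape does not match reference spatial grid")
    ref <- reference$reference
  }
  img <- if (is.null(ref)) RNifti::asNifti(map)
         else RNifti::asNifti(map, reference = ref)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Write a bad-run QC report as TSV
#'
#' One row per run tested in each exclusion pass (Welch statistic, dof,
#' one-sided p, Bonferroni-corrected alpha, decision), preceded by a comment
#' line with the final good-run list.
#'
#' @param report a `bad_run_report` from [detect_bad_runs()].
#' @param path output TSV path.
#' @seealso [read_qc_report()]
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "bad_run_report"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# good_runs: ", paste(report$good_runs, collapse = ",")), con)
  writeLines(paste0("# excluded: ", paste(report$excluded, collapse = ",")), con)
  utils::write.table(report$passes, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a QC report written by [write_qc_report()]
#'
#' @param path TSV path.
#' @return list with `passes` (data frame), `good_runs`, `excluded`.
#' @export
read_qc_report <- function(path) {
  hdr <- readLines(path, n = 2)
  parse_ids <- function(line) {
    x <- sub("^# [a-z_]+: ?", "", line)
    if (!nzchar(x)) integer(0) else as.integer(strsplit(x, ",")[[1]])
  }
  passes <- utils::read.delim(path, comment.char = "#")
  list(passes = passes,
       good_runs = parse_ids(hdr[1]),
       excluded = parse_ids(hdr[2]))
}
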