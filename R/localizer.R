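#' Construct a voxel-level contrast map
#'
#' Holds a per-voxel t statistic for a localizer contrast together with its
#' degrees of freedom, a gray-matter mask, and one or more parcel masks that
#' constrain where subject-specific fROIs may fall. Voxels are addressed by
#' storage-order linear index (1-based); any spatial affine is an I/O
#' concern only.
#'
#' @param t_values numeric vector of t statistics, one per voxel.
#' @param df degrees of freedom of the contrast.
#' @param gm_mask logical vector, TRUE for gray-matter voxels.
#' @param parcel_masks named list of logical vectors, one per parcel/fROI.
#' @param dim optional integer grid dimensions (prod(dim) == length(t_values)).
#' @return an object of class `voxel_contrast_map`.
#' @export
voxel_contrast_map <- function(t_values, df, gm_mask, parcel_masks, dim = NULL) {
  stopifnot(is.numeric(t_values), length(t_values) > 0)
  if (missing(df) || is.null(df) || !is.finite(df) || df <= 0) {
    stop("df must be a positive finite number (needed to convert t to p)")
  }
  nv <- length(t_values)
  stopifnot(is.logical(gm_mask), length(gm_mask) == nv,
            is.list(parcel_masks), length(parcel_masks) > 0,
            !is.null(names(parcel_masks)))
  for (nm in names(parcel_masks)) {
    if (!is.logical(parcel_masks[[nm]]) || length(parcel_masks[[nm]]) != nv) {
      stop("parcel mask '", nm, "' does not match the t-map's voxel grid")
    }
  }
  if (!is.null(dim) && prod(dim) != nv) stop("dim inconsistent with t_values")
  structure(list(t_values = t_values, df = df, gm_mask = gm_mask,
                 parcel_masks = parcel_masks, dim = dim),
            class = "voxel_contrast_map")
}

#' Simulate a localizer contrast t-map with a planted signal block
#'
#' Builds a parcel-sized voxel grid whose t values are background noise
#' (mean 0) except for a contiguous block of `n_signal_voxels` (consecutive
#' storage-order indices) centred on `signal_t`. Serves as ground truth for
#' top-percentile fROI selection: with `noise_sd = 0` and a block equal to
#' 10% of the parcel, selection must recover the block exactly.
#'
#' @param parcel_shape integer grid dimensions, e.g. `c(10, 10, 10)`.
#' @param n_signal_voxels size of the planted block.
#' @param signal_t mean t value inside the block.
#' @param noise_sd sd of the t noise (applied everywhere).
#' @param seed integer seed.
#' @param df degrees of freedom recorded for the contrast.
#' @param gm_exclude_frac fraction of voxels *outside* the block marked
#'   non-gray-matter (default 0).
#' @param parcel_name name of the single parcel covering the grid.
#' @return a `voxel_contrast_map` with attribute `"signal_indices"`.
#' @export
simulate_tmap <- function(parcel_shape, n_signal_voxels, signal_t,
                          noise_sd = 1, seed = 1L, df = 100,
                          gm_exclude_frac = 0, parcel_name = "IFG") {
  nv <- prod(parcel_shape)
  if (n_signal_voxels > nv) stop("impossible geometry: block larger than parcel")
  if (n_signal_voxels < 1) stop("n_signal_voxels must be >= 1")
  set.seed(stream_seed(seed, "tmap"))
  start <- sample.int(nv - n_signal_voxels + 1L, 1L)
  signal_idx <- seq(start, length.out = n_signal_voxels)
  t_values <- stats::rnorm(nv, 0, noise_sd)
  t_values[signal_idx] <- t_values[signal_idx] + signal_t
  gm_mask <- rep(TRUE, nv)
  if (gm_exclude_frac > 0) {
    bg <- setdiff(seq_len(nv), signal_idx)
    set.seed(stream_seed(seed, "tmap-gm"))
    drop <- sample(bg, round(gm_exclude_frac * length(bg)))
    gm_mask[drop] <- FALSE
  }
  parcel_masks <- stats::setNames(list(rep(TRUE, nv)), parcel_name)
  out <- voxel_contrast_map(t_values, df, gm_mask, parcel_masks,
                            dim = as.integer(parcel_shape))
  attr(out, "signal_indices") <- signal_idx
  out
}

#' Localizer data quality check
#'
#' Counts voxels within the union of the parcels (after gray-matter
#' masking) whose one-tailed p value falls below `alpha`, i.e. whose t
#' exceeds the upper-tail t quantile at the map's df. The participant fails
#' when fewer than `min_voxels` voxels survive; exactly `min_voxels` passes.
#'
#' @param map a `voxel_contrast_map`.
#' @param alpha uncorrected one-tailed threshold (default 0.001).
#' @param min_voxels minimum suprathreshold count (default 100).
#' @return list with `pass` (logical), `n_suprathreshold`, and the t
#'   `threshold` used.
#' @export
qc_localizer <- function(map, alpha = 0.001, min_voxels = 100) {
  stopifnot(inherits(map, "voxel_contrast_map"), alpha > 0, alpha < 1)
  thr <- stats::qt(1 - alpha, df = map$df)
  in_parcels <- Reduce(`|`, map$parcel_masks)
  eligible <- in_parcels & map$gm_mask
  n_supra <- sum(map$t_values[eligible] > thr)
  list(pass = n_supra >= min_voxels, n_suprathreshold = n_supra,
       threshold = thr)
}

#' Define a subject-specific functional ROI
#'
#' Within one parcel, after gray-matter masking, selects the top
#' `ceil(fraction * m)` voxels by t value (m = eligible voxel count). Ties
#' at the cutoff are broken by lower linear index, making the selection a
#' deterministic function of the map.
#'
#' @param map a `voxel_contrast_map`.
#' @param froi parcel name to define the fROI in.
#' @param fraction proportion of eligible voxels selected (default 0.10).
#' @return an object of class `froi_definition`: list with `froi`,
#'   `voxel_indices` (sorted), `fraction`, `n_parcel_voxels`.
#' @export
define_froi <- function(map, froi, fraction = 0.10) {
  stopifnot(inherits(map, "voxel_contrast_map"),
            fraction > 0, fraction <= 1)
  if (!froi %in% names(map$parcel_masks)) stop("unknown parcel: ", froi)
  eligible <- which(map$parcel_masks[[froi]] & map$gm_mask)
  m <- length(eligible)
  if (m == 0) stop("parcel '", froi, "' has no gray-matter voxels")
  k <- ceiling(fraction * m)
  ord <- eligible[order(-map$t_values[eligible], eligible)]
  structure(list(froi = froi,
                 voxel_indices = sort(ord[seq_len(k)]),
                 fraction = fraction,
                 n_parcel_voxels = m),
            class = "froi_definition")
}

#' @export
print.froi_definition <- function(x, ...) {
  cat(sprintf("fROI '%s': %d of %d voxels (fraction %.3g)\n",
              x$froi, length(x$voxel_indices), x$n_parcel_voxels, x$fraction))
  invisible(x)
}

#' Extract an fROI-average time course from voxel-level series
#'
#' Each selected voxel's series is temporally z-scored (mean 0, unit n-1
#' sd) and the z-scored series are averaged across voxels. Constant-valued
#' voxels carry no signal and are excluded with a warning; if every
#' selected voxel is constant the extraction fails.
#'
#' @param voxel_series numeric matrix, time x voxels, columns indexed by
#'   voxel linear index (i.e. column `j` is voxel `j` of the map's grid).
#' @param def a `froi_definition`.
#' @return numeric vector, the fROI-average z-scored series.
#' @export
extract_froi_timecourse <- function(voxel_series, def) {
  stopifnot(is.matrix(voxel_series), inherits(def, "froi_definition"))
  if (max(def$voxel_indices) > ncol(voxel_series)) {
    stop("voxel_series has fewer columns than the fROI's largest voxel index")
  }
  sel <- voxel_series[, def$voxel_indices, drop = FALSE]
  sds <- apply(sel, 2, stats::sd)
  if (all(sds == 0)) stop("all selected voxels are constant; nothing to extract")
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant voxel(s) excluded from fROI '",
            def$froi, "'")
    sel <- sel[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  z <- sweep(sweep(sel, 2, colMeans(sel)), 2, sds, `/`)
  rowMeans(z)
}

#' Write a froi_definition as JSON
#' @param def a `froi_definition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_froi <- function(def, path) {
  stopifnot(inherits(def, "froi_definition"))
  jsonlite::write_json(unclass(def), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read or write a t-map as NIfTI (optional; requires RNifti)
#'
#' @param map a `voxel_contrast_map` with `dim` set.
#' @param path NIfTI file path (.nii or .nii.gz).
#' @return `path` (write) / numeric array (read).
#' @export
write_tmap_nifti <- function(map, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("RNifti is required for NIfTI output")
  }
  stopifnot(inherits(map, "voxel_contrast_map"), !is.null(map$dim))
  RNifti::writeNifti(array(map$t_values, dim = map$dim), path)
  invisible(path)
}
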