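#' Gaussian smoothing of an SNR volume
#'
#' In-plane (per-slice) 2-D Gaussian filtering with SD `sd_px` pixels,
#' replicate boundary. Slices are thick and gapped relative to the in-plane
#' resolution, so smoothing is 2-D by default; `in_plane = FALSE` adds a
#' 1-D Gaussian pass along the slice axis with the same SD (in slices).
#'
#' @param vol 3-D numeric array.
#' @param sd_px Gaussian SD in pixels (> 0). The conventional "3 pixel
#'   kernel width" of common tools corresponds to SD = 3.
#' @param in_plane Smooth only within slices (default) or also across them.
#' @return Smoothed array, same dimensions.
#' @export
smooth_snr <- function(vol, sd_px = 3, in_plane = TRUE) {
  stopifnot(is.array(vol), length(dim(vol)) == 3L, sd_px > 0)
  size <- 2L * as.integer(ceiling(3 * sd_px)) + 1L
  size <- min(size, 2L * (min(dim(vol)[1:2]) %/% 2L) - 1L)
  brush <- EBImage::makeBrush(size, shape = "gaussian", sigma = sd_px)
  out <- vol
  for (k in seq_len(dim(vol)[3]))
    out[, , k] <- EBImage::filter2(vol[, , k], brush, boundary = "replicate")
  if (!in_plane) {
    r <- as.integer(ceiling(3 * sd_px))
    kern <- exp(-(seq(-r, r))^2 / (2 * sd_px^2))
    kern <- kern / sum(kern)
    nz <- dim(vol)[3]
    zz <- pmin.int(pmax.int(rep(seq_len(nz), each = 2L * r + 1L) +
                              seq(-r, r), 1L), nz)
    sm <- array(0, dim(out))
    idx <- matrix(zz, nrow = 2L * r + 1L)
    for (t in seq_len(2L * r + 1L))
      sm <- sm + kern[t] * out[, , idx[t, ], drop = FALSE]
    out <- sm
  }
  out
}

#' Preprocessed SNR series
#'
#' SNR volumes per TR on the anatomical grid with a validity mask and the
#' provenance (noise estimate, smoothing SD, threshold) that produced them.
#'
#' @param snr_volumes List of 3-D SNR arrays, one per TR.
#' @param tr_ms Repetition times (ms), increasing.
#' @param geometry [grid_geometry()] of the SNR volumes.
#' @param validity_mask Logical array; voxels kept for analysis.
#' @param provenance Named list (sigma_m, sigma_g, smooth_sd, snr_threshold,
#'   interp_order, ...).
#' @return Object of class `"snr_series"`.
#' @export
snr_series <- function(snr_volumes, tr_ms, geometry, validity_mask = NULL,
                       provenance = list()) {
  stopifnot(is.list(snr_volumes), length(snr_volumes) == length(tr_ms))
  ord <- order(tr_ms)
  snr_volumes <- snr_volumes[ord]
  tr_ms <- as.numeric(tr_ms)[ord]
  for (v in snr_volumes)
    stopifnot(all(dim(v) == geometry$dim))
  structure(list(snr_volumes = snr_volumes, tr_ms = tr_ms, geometry = geometry,
                 validity_mask = validity_mask, provenance = provenance),
            class = "snr_series")
}

#' @export
print.snr_series <- function(x, ...) {
  cat("snr_series:", length(x$tr_ms), "TRs on",
      paste(x$geometry$dim, collapse = " x "), "grid")
  if (!is.null(x$validity_mask))
    cat(";", sum(x$validity_mask), "valid voxels")
  cat("\n")
  invisible(x)
}

#' Validity mask from the least T1-weighted image
#'
#' Voxels whose (smoothed) SNR on the longest-TR image falls below
#' `threshold` are excluded from all further analysis; the mask keeps
#' `SNR >= threshold`.
#'
#' @param series An [snr_series()] (smoothed).
#' @param threshold SNR threshold (default 5).
#' @param tr_target TR of the reference image in ms (default 5000).
#' @return Logical array.
#' @export
build_validity_mask <- function(series, threshold = 5, tr_target = 5000) {
  stopifnot(inherits(series, "snr_series"))
  i <- which(abs(series$tr_ms - tr_target) < 0.5)
  if (length(i) != 1L)
    stop("build_validity_mask: series lacks the TR = ", tr_target, " ms image")
  series$snr_volumes[[i]] >= threshold
}

#' ROI mean SNR per TR
#'
#' Mean SNR over the intersection of a placenta ROI with the validity mask,
#' per TR. An empty intersection flags the placenta unusable (it is excluded
#' from fitting) rather than raising an error.
#'
#' @param series An [snr_series()] with a validity mask.
#' @param labels Integer label array on the series grid.
#' @param label Placenta label to measure.
#' @return List: `snr_mean` (per TR), `tr_ms`, `n_voxels`, `usable`.
#' @export
roi_mean_snr <- function(series, labels, label) {
  stopifnot(inherits(series, "snr_series"), all(dim(labels) == series$geometry$dim))
  mask <- labels == label
  if (!is.null(series$validity_mask)) mask <- mask & series$validity_mask
  n <- sum(mask)
  if (n == 0L)
    return(list(snr_mean = rep(NA_real_, length(series$tr_ms)),
                tr_ms = series$tr_ms, n_voxels = 0L, usable = FALSE))
  list(snr_mean = vapply(series$snr_volumes, function(v) mean(v[mask]), 0),
       tr_ms = series$tr_ms, n_voxels = n, usable = TRUE)
}

#' Preprocess one session: magnitude series to masked SNR series
#'
#' The fixed order of operations is: (1) estimate the Gaussian noise SD from
#' the signal-free ROI on the native magnitude image, (2) convert every TR
#' volume to noise-corrected SNR on the native grid, (3) interpolate the SNR
#' volumes up to the anatomical grid, (4) Gaussian-smooth in plane, (5) build
#' the validity mask from the smoothed longest-TR image. ROIs stay on the
#' anatomical grid; only the background noise ROI is transported (nearest
#' neighbour) down to the native grid.
#'
#' @param series A [magnitude_series()] (native 19F grid).
#' @param rois A [roi_set()] on the anatomical grid.
#' @param target_geometry Anatomical [grid_geometry()]; defaults to the ROI
#'   grid.
#' @param smooth_sd Gaussian SD in anatomical pixels (default 3).
#' @param snr_threshold Validity threshold on the TR = 5 s image (default 5).
#' @param interp_order Interpolation order for the native-to-anatomical
#'   resampling (default 3, cubic).
#' @param noise_per_tr Estimate sigma separately per TR instead of once from
#'   the longest-TR image (default FALSE: identical receiver settings within
#'   a series).
#' @return An [snr_series()] on the anatomical grid with validity mask and
#'   provenance.
#' @export
preprocess_session <- function(series, rois, target_geometry = NULL,
                               smooth_sd = 3, snr_threshold = 5,
                               interp_order = 3L, noise_per_tr = FALSE) {
  stopifnot(inherits(series, "magnitude_series"), inherits(rois, "roi_set"))
  if (is.null(target_geometry)) target_geometry <- rois$geometry
  bg_native <- resample_labels(rois$labels, rois$geometry, series$geometry)
  bg_mask <- bg_native == rois$background_label
  n_tr <- length(series$tr_ms)
  i_ref <- n_tr  # longest TR
  noise_ref <- estimate_noise(series$volumes[[i_ref]], bg_mask)
  snr_anat <- vector("list", n_tr)
  sigmas <- numeric(n_tr)
  for (i in seq_len(n_tr)) {
    ne <- if (noise_per_tr) estimate_noise(series$volumes[[i]], bg_mask) else noise_ref
    sigmas[i] <- ne$sigma_g
    snr_native <- magnitude_to_snr(series$volumes[[i]], ne$sigma_g)
    up <- resample_between_grids(snr_native, series$geometry, target_geometry,
                                 order = interp_order, fill = 0)
    up[up < 0] <- 0  # cubic overshoot below zero has no SNR meaning
    snr_anat[[i]] <- smooth_snr(up, sd_px = smooth_sd, in_plane = TRUE)
  }
  out <- snr_series(snr_anat, series$tr_ms, target_geometry,
                    provenance = list(sigma_m = noise_ref$sigma_m,
                                      sigma_g = noise_ref$sigma_g,
                                      sigma_g_per_tr = sigmas,
                                      noise_voxels = noise_ref$n_voxels,
                                      smooth_sd = smooth_sd,
                                      snr_threshold = snr_threshold,
                                      interp_order = interp_order))
  out$validity_mask <- build_validity_mask(out, threshold = snr_threshold)
  out
}

#' Write an SNR series with a JSON provenance sidecar
#'
#' @param series An [snr_series()].
#' @param dir Output directory.
#' @param prefix File prefix.
#' @return Paths written, invisibly.
#' @export
write_snr_series <- function(series, dir, prefix = "snr") {
  stopifnot(inherits(series, "snr_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("%s_tr%04d.nii", prefix,
                                  as.integer(round(series$tr_ms))))
  for (i in seq_along(paths))
    write_volume(series$snr_volumes[[i]], series$geometry, paths[i])
  if (!is.null(series$validity_mask)) {
    mpath <- file.path(dir, paste0(prefix, "_validity.nii"))
    write_volume(series$validity_mask + 0L, series$geometry, mpath)
    paths <- c(paths, mpath)
  }
  jsonlite::write_json(c(series$provenance, list(tr_ms = series$tr_ms)),
                       file.path(dir, paste0(prefix, "_provenance.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
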