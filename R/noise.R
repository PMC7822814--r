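#' Draw Rician-distributed magnitude samples
#'
#' Magnitude MRI noise: `|A + n1 + i n2|` with independent Gaussian channel
#' noise of SD `sigma_g`. With `signal = 0` this is the Rayleigh background
#' distribution whose mean is `sigma_g * sqrt(pi/2)` and whose SD is
#' `sigma_g * sqrt(2 - pi/2)`.
#'
#' @param n Number of draws.
#' @param signal True (noiseless) signal amplitude, scalar or length `n`.
#' @param sigma_g Gaussian channel noise SD, > 0.
#' @return Numeric vector of magnitudes.
#' @export
rrician <- function(n, signal = 0, sigma_g = 1) {
  stopifnot(sigma_g > 0)
  sqrt((signal + rnorm(n, 0, sigma_g))^2 + rnorm(n, 0, sigma_g)^2)
}

#' Estimate Gaussian noise from a signal-free region
#'
#' The SD of the magnitude signal in a signal-free ROI, `sigma_m`, is
#' related to the underlying Gaussian channel noise by
#' `sigma_g = sigma_m / sqrt(2 - pi/2)` (Rayleigh statistics).
#'
#' @param volume 3-D magnitude array (native units).
#' @param background_mask Logical array of the same dimensions marking the
#'   signal-free ROI; at least `min_voxels` voxels.
#' @param min_voxels Minimum ROI size accepted.
#' @return Object of class `"noise_estimate"`: `sigma_m`, `sigma_g`,
#'   `n_voxels`.
#' @export
estimate_noise <- function(volume, background_mask, min_voxels = 10L) {
  stopifnot(is.array(volume), is.array(background_mask) || is.logical(background_mask))
  if (!all(dim(volume) == dim(background_mask)))
    stop("estimate_noise: mask dimensions do not match volume")
  vals <- volume[background_mask != 0]
  if (length(vals) < min_voxels)
    stop("estimate_noise: background ROI has ", length(vals),
         " voxels; need >= ", min_voxels)
  sigma_m <- sd(vals)
  if (!is.finite(sigma_m) || sigma_m <= 0)
    stop("estimate_noise: background ROI has zero variance")
  structure(list(sigma_m = sigma_m,
                 sigma_g = sigma_m / sqrt(2 - pi / 2),
                 n_voxels = length(vals)),
            class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf("noise_estimate: sigma_m = %.4g, sigma_g = %.4g (n = %d voxels)\n",
              x$sigma_m, x$sigma_g, x$n_voxels))
  invisible(x)
}

#' Convert magnitude to noise-corrected SNR
#'
#' Gudbjartsson-Patz correction for the Rician bias of low-SNR magnitude
#' images: `SNR = sqrt(SI_m^2 - sigma_g^2) / sigma_g`. Voxels with
#' `SI_m < sigma_g` (negative radicand) sit below the noise floor and are
#' clamped to SNR 0; the downstream TR4 threshold would exclude them anyway.
#'
#' @param volume Magnitude array or vector (native units).
#' @param sigma_g Gaussian noise SD (native units), > 0.
#' @return SNR values, same shape as `volume`.
#' @export
magnitude_to_snr <- function(volume, sigma_g) {
  if (!is.numeric(sigma_g) || length(sigma_g) != 1L || !is.finite(sigma_g) ||
      sigma_g <= 0)
    stop("magnitude_to_snr: sigma_g must be a positive scalar")
  sqrt(pmax(volume^2 - sigma_g^2, 0)) / sigma_g
}

#' Naive (uncorrected) SNR
#'
#' `SI_m / sigma_g`, kept for the bias comparison against
#' [magnitude_to_snr()]; biased upward at low SNR because the Rician mean
#' exceeds the true amplitude.
#'
#' @inheritParams magnitude_to_snr
#' @export
naive_snr <- function(volume, sigma_g) {
  stopifnot(sigma_g > 0)
  volume / sigma_g
}
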