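#' Oxygen calibration for PFCE relaxometry
#'
#' The longitudinal relaxation rate R1 = 1/T1 of perfluoro-15-crown-5-ether
#' increases linearly with dissolved oxygen, so PO2 is affine in R1:
#' `PO2 = a / T1 - b` with slope `a` in mmHg*s and intercept `b` in mmHg.
#' The defaults are the in vitro calibration constants used throughout the
#' pipeline; they are taken as given, not re-estimated.
#'
#' @param slope Calibration slope `a` (mmHg*s).
#' @param intercept Calibration intercept `b` (mmHg).
#' @return An object of class `"oxygen_calibration"`.
#' @examples
#' cal <- oxygen_calibration()
#' t1_to_po2(1.0, cal)          # 270.67 mmHg
#' po2_to_t1(0, cal)            # T1 at zero oxygen, a/b
#' @export
oxygen_calibration <- function(slope = 470.81, intercept = 200.14) {
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope), slope > 0,
            is.numeric(intercept), length(intercept) == 1L, is.finite(intercept))
  structure(list(slope = slope, intercept = intercept),
            class = "oxygen_calibration")
}

#' @export
print.oxygen_calibration <- function(x, ...) {
  cat("PFCE oxygen calibration: PO2 [mmHg] =", x$slope, "/ T1 [s] -",
      x$intercept, "\n")
  cat("  zero-oxygen T1:", format(x$slope / x$intercept, digits = 6), "s\n")
  invisible(x)
}

#' Convert T1 to oxygen partial pressure
#'
#' Evaluates `PO2 = a/T1 - b`. Values below 0 or above 760 mmHg are
#' physically impossible but are returned unclipped; downstream code flags
#' them instead of censoring (see [placenta_qc_flags()]).
#'
#' @param t1 Longitudinal relaxation time(s) in seconds; must be > 0.
#' @param calib An [oxygen_calibration()].
#' @return PO2 in mmHg, same length as `t1`.
#' @export
t1_to_po2 <- function(t1, calib = oxygen_calibration()) {
  stopifnot(inherits(calib, "oxygen_calibration"), is.numeric(t1))
  if (any(!is.finite(t1)) || any(t1 <= 0))
    stop("t1_to_po2: T1 must be finite and positive")
  calib$slope / t1 - calib$intercept
}

#' Convert oxygen partial pressure to T1
#'
#' Algebraic inverse of [t1_to_po2()]: `T1 = a/(PO2 + b)`, defined for
#' `PO2 > -b`. Used by the phantom generator to derive ground-truth T1 from
#' a target PO2.
#'
#' @param po2 Oxygen partial pressure(s) in mmHg; must exceed `-intercept`.
#' @inheritParams t1_to_po2
#' @return T1 in seconds.
#' @export
po2_to_t1 <- function(po2, calib = oxygen_calibration()) {
  stopifnot(inherits(calib, "oxygen_calibration"), is.numeric(po2))
  if (any(!is.finite(po2)) || any(po2 <= -calib$intercept))
    stop("po2_to_t1: PO2 must be finite and > ", -calib$intercept, " mmHg")
  calib$slope / (po2 + calib$intercept)
}

#' QC flags for a placenta record
#'
#' Flags physiologically impossible PO2 (< 0 or > 760 mmHg, one atmosphere)
#' and non-converged or unusable fits. Values are retained, never censored.
#'
#' @param po2 PO2 in mmHg (may be NA).
#' @param converged Logical, did the saturation-recovery fit converge.
#' @param usable Logical, did the ROI retain any valid voxels.
#' @return Character vector of semicolon-separated flags ("" when clean).
#' @export
placenta_qc_flags <- function(po2, converged = TRUE, usable = TRUE) {
  n <- max(length(po2), length(converged), length(usable))
  po2 <- rep_len(po2, n)
  converged <- rep_len(converged, n)
  usable <- rep_len(usable, n)
  out <- character(n)
  for (i in seq_len(n)) {
    fl <- character(0)
    if (!isTRUE(usable[i])) fl <- c(fl, "unusable")
    else if (!isTRUE(converged[i])) fl <- c(fl, "no_convergence")
    else {
      if (is.finite(po2[i]) && po2[i] < 0) fl <- c(fl, "po2_below_0")
      if (is.finite(po2[i]) && po2[i] > 760) fl <- c(fl, "po2_above_760")
    }
    out[i] <- paste(fl, collapse = ";")
  }
  out
}
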