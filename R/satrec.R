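#' Fit the saturation-recovery signal model
#'
#' Two-parameter nonlinear least squares for
#' `SNR(TR) = S0 * (1 - exp(-TR / T1))`: `S0` is the equilibrium SNR
#' (proportional to local 19F agent concentration) and `T1` the longitudinal
#' relaxation time in seconds. Fitting uses Levenberg-Marquardt with box
#' bounds (S0 > 0, T1 in [0.05, 30] s by default — far beyond any
#' physiological range, present only to stop pathological excursions) and
#' the initialisation S0 = SNR at the longest TR, T1 = 1.5 s. Ordinary
#' (unweighted) least squares by default; supply `weights` for
#' inverse-variance weighting.
#'
#' A failed or degenerate fit returns a flagged object (`converged = FALSE`)
#' rather than raising, so one bad placenta never aborts a study.
#'
#' @param tr_ms Repetition times in milliseconds (>= 3 values).
#' @param snr Mean ROI SNR at each TR.
#' @param start Optional named list/vector with `S0` and `T1` (seconds).
#' @param lower,upper Box bounds on `c(S0, T1_s)`.
#' @param weights Optional nonnegative fit weights per TR.
#' @param calib An [oxygen_calibration()] used by `summary()`/records.
#' @return Object of class `"satrec"` with `coefficients` (`S0`, `T1`
#'   seconds), `fitted.values`, `residuals`, `rss`, `converged`, `data`.
#' @examples
#' tr <- c(318, 719, 1398, 5000)
#' y <- 10 * (1 - exp(-tr / 2000))
#' fit <- satrec(tr, y)
#' coef(fit)
#' @export
satrec <- function(tr_ms, snr, start = NULL,
                   lower = c(S0 = 1e-9, T1 = 0.05),
                   upper = c(S0 = Inf, T1 = 30),
                   weights = NULL, calib = oxygen_calibration()) {
  cl <- match.call()
  tr_ms <- as.numeric(tr_ms)
  snr <- as.numeric(snr)
  ok <- is.finite(tr_ms) & is.finite(snr)
  if (length(tr_ms) != length(snr))
    stop("satrec: tr_ms and snr lengths differ")
  if (sum(ok) < 3L)
    stop("satrec: need at least 3 finite (TR, SNR) pairs")
  tr_ms <- tr_ms[ok]; snr <- snr[ok]
  if (!is.null(weights)) weights <- as.numeric(weights)[ok]
  tr_s <- tr_ms / 1000
  failed <- function(msg) {
    structure(list(coefficients = c(S0 = NA_real_, T1 = NA_real_),
                   fitted.values = rep(NA_real_, length(tr_s)),
                   residuals = rep(NA_real_, length(tr_s)),
                   rss = NA_real_, converged = FALSE, message = msg,
                   data = data.frame(tr_ms = tr_ms, snr = snr),
                   calib = calib, call = cl),
              class = "satrec")
  }
  if (all(snr == 0)) return(failed("all SNR values are zero"))
  if (is.null(start)) {
    s0_init <- snr[which.max(tr_s)]
    if (!is.finite(s0_init) || s0_init <= 0) s0_init <- max(snr, 1e-3)
    start <- list(S0 = s0_init, T1 = 1.5)
  }
  fit_args <- list(snr ~ S0 * (1 - exp(-tr_s / T1)),
                   data = data.frame(tr_s = tr_s, snr = snr),
                   start = as.list(start),
                   lower = unname(lower), upper = unname(upper),
                   control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!is.null(weights)) fit_args$weights <- weights
  fit <- tryCatch(do.call(minpack.lm::nlsLM, fit_args), error = function(e) e)
  if (inherits(fit, "error")) return(failed(conditionMessage(fit)))
  co <- coef(fit)
  fitted_v <- co[["S0"]] * (1 - exp(-tr_s / co[["T1"]]))
  res <- snr - fitted_v
  structure(list(coefficients = c(S0 = unname(co[["S0"]]), T1 = unname(co[["T1"]])),
                 fitted.values = fitted_v, residuals = res,
                 rss = sum(res^2), converged = TRUE, message = "converged",
                 data = data.frame(tr_ms = tr_ms, snr = snr),
                 calib = calib, call = cl),
            class = "satrec")
}

#' @rdname satrec
#' @param snr_means,tr_list_ms Pipeline-facing aliases for `snr` and `tr_ms`.
#' @param ... Passed to [satrec()].
#' @export
fit_saturation_recovery <- function(snr_means, tr_list_ms, ...) {
  satrec(tr_list_ms, snr_means, ...)
}

#' @export
print.satrec <- function(x, digits = 4, ...) {
  cat("Saturation-recovery fit: SNR = S0 * (1 - exp(-TR/T1))\n")
  if (x$converged) {
    cat(sprintf("  S0 = %.*g, T1 = %.*g s (RSS %.3g, n = %d)\n",
                digits, x$coefficients[["S0"]], digits, x$coefficients[["T1"]],
                x$rss, nrow(x$data)))
  } else {
    cat("  fit failed:", x$message, "\n")
  }
  invisible(x)
}

#' @export
summary.satrec <- function(object, ...) {
  out <- object[c("coefficients", "rss", "converged", "message")]
  if (object$converged) {
    out$po2_mmhg <- t1_to_po2(object$coefficients[["T1"]], object$calib)
    out$qc_flags <- placenta_qc_flags(out$po2_mmhg)
  } else {
    out$po2_mmhg <- NA_real_
    out$qc_flags <- placenta_qc_flags(NA_real_, converged = FALSE)
  }
  out$n <- nrow(object$data)
  class(out) <- "summary.satrec"
  out
}

#' @export
print.summary.satrec <- function(x, ...) {
  cat("Saturation-recovery fit (n =", x$n, "TRs)\n")
  if (x$converged) {
    cat(sprintf("  S0  = %.4g\n  T1  = %.4g s\n  PO2 = %.4g mmHg%s\n",
                x$coefficients[["S0"]], x$coefficients[["T1"]], x$po2_mmhg,
                if (nzchar(x$qc_flags)) paste0("  [", x$qc_flags, "]") else ""))
  } else cat("  fit failed:", x$message, "\n")
  invisible(x)
}

#' @export
coef.satrec <- function(object, ...) object$coefficients

#' @export
residuals.satrec <- function(object, ...) object$residuals

#' @export
fitted.satrec <- function(object, ...) object$fitted.values

#' @export
predict.satrec <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("predict.satrec: fit did not converge")
  tr_ms <- if (is.null(newdata)) object$data$tr_ms
           else if (is.data.frame(newdata)) newdata$tr_ms else as.numeric(newdata)
  co <- object$coefficients
  co[["S0"]] * (1 - exp(-(tr_ms / 1000) / co[["T1"]]))
}

#' @export
plot.satrec <- function(x, main = "Saturation recovery", ...) {
  d <- x$data
  plot(d$tr_ms, d$snr, xlab = "TR [ms]", ylab = "mean SNR", pch = 19,
       main = main, ylim = range(0, d$snr, na.rm = TRUE), ...)
  if (x$converged) {
    tr_grid <- seq(0, max(d$tr_ms) * 1.05, length.out = 200)
    lines(tr_grid, predict(x, tr_grid), col = "red3")
    legend("bottomright", bty = "n", legend = c(
      sprintf("S0 = %.3g", x$coefficients[["S0"]]),
      sprintf("T1 = %.3g s", x$coefficients[["T1"]]),
      sprintf("PO2 = %.3g mmHg", t1_to_po2(x$coefficients[["T1"]], x$calib))))
  }
  invisible(x)
}

#' @export
simulate.satrec <- function(object, nsim = 1, seed = NULL, sigma_g = NULL, ...) {
  if (!object$converged) stop("simulate.satrec: fit did not converge")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sigma_g)) {
    sigma_g <- sqrt(object$rss / max(1L, nrow(object$data) - 2L))
    if (!is.finite(sigma_g) || sigma_g <= 0) sigma_g <- 1e-6
  }
  mu <- object$fitted.values
  out <- replicate(nsim, rrician(length(mu), signal = mu, sigma_g = sigma_g))
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  attr(out, "tr_ms") <- object$data$tr_ms
  out
}

#' Fit a multi-compartment saturation-recovery model
#'
#' Least squares for `SNR(TR) = sum_c S0_c * (1 - exp(-TR / T1_c))`, the
#' placental three-pool picture (maternal blood, fetal blood, trophoblast).
#' With `fractions` fixed, `S0_c = S0_total * f_c` and the free parameters
#' are `S0_total` and the per-compartment T1s; otherwise all `2 n` parameters
#' are free, which requires at least `2 n + 1` data points. Compartments are
#' reported sorted by T1. Optional residual-bootstrap confidence intervals
#' expose the (non-)identifiability of the fit: at in vivo SNR on four TRs
#' the intervals are expected to be non-informative.
#'
#' @param snr_means Mean SNR per TR.
#' @param tr_list_ms Repetition times (ms).
#' @param n_compartments Number of exponential pools.
#' @param fractions Optional fixed signal fractions (sum to 1).
#' @param n_boot Residual-bootstrap replicates (0 = none).
#' @param t1_start Optional starting T1s (seconds).
#' @param seed Optional RNG seed for the bootstrap.
#' @return Object of class `"satrec_multi"`: data frame `compartments`
#'   (`s0`, `t1`, optional CI columns), `rss`, `converged`, `boot_ci_width`.
#' @export
fit_multiexponential <- function(snr_means, tr_list_ms, n_compartments = 3L,
                                 fractions = NULL, n_boot = 0L,
                                 t1_start = NULL, seed = NULL) {
  tr_s <- as.numeric(tr_list_ms) / 1000
  y <- as.numeric(snr_means)
  n_c <- as.integer(n_compartments)
  stopifnot(length(tr_s) == length(y), n_c >= 1L)
  if (!is.null(fractions)) {
    fractions <- as.numeric(fractions)
    stopifnot(length(fractions) == n_c)
    if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-12)
      stop("fit_multiexponential: fractions must be nonnegative and sum to 1")
    n_par <- n_c + 1L
  } else {
    n_par <- 2L * n_c
    if (length(y) < 2L * n_c + 1L)
      stop("fit_multiexponential: need >= ", 2L * n_c + 1L,
           " points for ", n_c, " free compartments (or fix fractions)")
  }
  if (length(y) < n_par)
    stop("fit_multiexponential: under-determined configuration")
  if (n_c == 1L && is.null(fractions)) {
    base <- satrec(tr_list_ms, snr_means)
    comp <- data.frame(s0 = base$coefficients[["S0"]],
                       t1 = base$coefficients[["T1"]])
    return(structure(list(compartments = comp, rss = base$rss,
                          converged = base$converged, fractions = NULL,
                          boot_ci_width = NULL,
                          data = data.frame(tr_ms = tr_list_ms, snr = y)),
                     class = "satrec_multi"))
  }
  if (is.null(t1_start))
    t1_start <- exp(seq(log(0.3), log(4), length.out = n_c))
  model_fun <- function(par) {
    if (!is.null(fractions)) {
      s0 <- par[1L] * fractions
      t1 <- par[-1L]
    } else {
      s0 <- par[seq_len(n_c)]
      t1 <- par[n_c + seq_len(n_c)]
    }
    colSums(s0 * (1 - exp(-outer(1 / t1, tr_s))))
  }
  fit_once <- function(yy) {
    if (!is.null(fractions)) {
      par0 <- c(max(yy[which.max(tr_s)], 1e-3), t1_start)
      lowr <- c(1e-9, rep(0.05, n_c)); uppr <- c(Inf, rep(30, n_c))
    } else {
      par0 <- c(rep(max(yy) / n_c, n_c), t1_start)
      lowr <- c(rep(1e-9, n_c), rep(0.05, n_c))
      uppr <- c(rep(Inf, n_c), rep(30, n_c))
    }
    tryCatch(minpack.lm::nls.lm(par = par0, lower = lowr, upper = uppr,
                                fn = function(p) yy - model_fun(p),
                                control = minpack.lm::nls.lm.control(maxiter = 500)),
             error = function(e) NULL)
  }
  fit <- fit_once(y)
  if (is.null(fit))
    return(structure(list(compartments = NULL, rss = NA_real_,
                          converged = FALSE, fractions = fractions,
                          boot_ci_width = NULL,
                          data = data.frame(tr_ms = tr_list_ms, snr = y)),
                     class = "satrec_multi"))
  par <- fit$par
  if (!is.null(fractions)) {
    s0 <- par[1L] * fractions; t1 <- par[-1L]
  } else {
    s0 <- par[seq_len(n_c)]; t1 <- par[n_c + seq_len(n_c)]
  }
  ord <- order(t1)
  comp <- data.frame(s0 = s0[ord], t1 = t1[ord])
  resid0 <- y - model_fun(par)
  boot_ci <- NULL
  if (n_boot > 0L) {
    if (!is.null(seed)) set.seed(seed)
    bt <- matrix(NA_real_, n_boot, n_c)
    for (b in seq_len(n_boot)) {
      yb <- model_fun(par) + sample(resid0, length(y), replace = TRUE)
      fb <- fit_once(yb)
      if (!is.null(fb)) {
        t1b <- if (!is.null(fractions)) fb$par[-1L] else fb$par[n_c + seq_len(n_c)]
        bt[b, ] <- sort(t1b)
      }
    }
    lo <- apply(bt, 2, quantile, 0.025, na.rm = TRUE)
    hi <- apply(bt, 2, quantile, 0.975, na.rm = TRUE)
    comp$t1_ci_lo <- lo
    comp$t1_ci_hi <- hi
    boot_ci <- (hi - lo) / comp$t1
  }
  structure(list(compartments = comp, rss = sum(resid0^2), converged = TRUE,
                 fractions = if (is.null(fractions)) NULL else fractions[ord],
                 boot_ci_width = boot_ci,
                 data = data.frame(tr_ms = tr_list_ms, snr = y)),
            class = "satrec_multi")
}

#' @export
print.satrec_multi <- function(x, ...) {
  cat("Multi-compartment saturation-recovery fit\n")
  if (!x$converged) { cat("  fit failed\n"); return(invisible(x)) }
  print(round(x$compartments, 5))
  cat("  RSS:", format(x$rss, digits = 4), "\n")
  if (!is.null(x$boot_ci_width))
    cat("  bootstrap 95% CI width / T1:",
        paste(round(x$boot_ci_width, 2), collapse = ", "), "\n")
  invisible(x)
}
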