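#' Monte-Carlo study of the genotype tests
#'
#' Repeatedly simulates record-level studies at the in vivo design (via
#' [simulate_records()]) and collects, per replicate, the p-values of the
#' full-model genotype and genotype-by-oxygen tests and of the post-hoc
#' genotype test at the lowest oxygen level. With the KO offsets at zero
#' this measures the type-I error calibration of the nested model; with the
#' study-like deficit injected at 30% O2 it measures power.
#'
#' @param n_reps Number of simulated studies.
#' @param ko_offsets Named per-oxygen-level KO PO2 shifts (mmHg); zero for
#'   a null simulation.
#' @param measurement_sd Per-record PO2 measurement SD (mmHg).
#' @param config Base [phantom_config()]; its `ko_offsets` are replaced.
#' @param seed RNG seed for the whole run.
#' @return Data frame with columns `p_genotype`, `p_interaction`,
#'   `p_posthoc_low` (one row per replicate).
#' @export
genotype_test_simulation <- function(n_reps = 200L,
                                     ko_offsets = c(`30` = 0, `60` = 0, `100` = 0),
                                     measurement_sd = 25,
                                     config = phantom_config(),
                                     seed = NULL) {
  cfg <- config
  cfg$ko_offsets <- ko_offsets
  low <- min(cfg$oxygen_levels)
  if (!is.null(seed)) set.seed(seed)
  out <- data.frame(p_genotype = rep(NA_real_, n_reps),
                    p_interaction = NA_real_, p_posthoc_low = NA_real_)
  for (b in seq_len(n_reps)) {
    rec <- simulate_records(cfg, measurement_sd = measurement_sd)
    full <- tryCatch(
      suppressWarnings(fit_full_model(rec, "po2_mmhg", emmeans = FALSE)),
      error = function(e) NULL)
    if (!is.null(full) && !full$degenerate) {
      out$p_genotype[b] <- full$tests$p[full$tests$source == "Genotype"]
      out$p_interaction[b] <- full$tests$p[full$tests$source == "Genotype x Oxygen"]
    }
    ph <- tryCatch(
      suppressWarnings(fit_posthoc_model(
        rec[rec$oxygen_percent == low, , drop = FALSE],
        "po2_mmhg", emmeans = FALSE)),
      error = function(e) NULL)
    if (!is.null(ph)) out$p_posthoc_low[b] <- ph$tests$p[1L]
  }
  out
}

#' Monte-Carlo recovery of the saturation-recovery fit
#'
#' Simulates ROI-mean SNR curves at the study TRs from known (S0, T1),
#' adds magnitude-domain Rician noise scaled so the equilibrium SNR lands
#' in `snr_range`, refits each curve and reports the recovery errors.
#' Measures the fitting stage in isolation (no imaging chain).
#'
#' @param n_curves Number of simulated curves.
#' @param t1_range True T1 sampled uniformly from this range (seconds).
#' @param snr4_range SNR at the longest TR sampled uniformly from this
#'   range; the true S0 follows from the recovery factor.
#' @param tr_list_ms Repetition times (ms).
#' @param n_voxels Effective ROI size; the SD of a mean-SNR point is
#'   approximately `1/sqrt(n_voxels)`.
#' @param seed RNG seed.
#' @return Data frame: `true_s0`, `true_t1`, `fit_s0`, `fit_t1`, `converged`.
#' @export
fit_recovery_simulation <- function(n_curves = 200L,
                                    t1_range = c(1.0, 2.5),
                                    snr4_range = c(10, 30),
                                    tr_list_ms = c(318, 719, 1398, 5000),
                                    n_voxels = 40L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr_s <- tr_list_ms / 1000
  true_t1 <- runif(n_curves, t1_range[1], t1_range[2])
  snr4 <- runif(n_curves, snr4_range[1], snr4_range[2])
  out <- data.frame(true_s0 = snr4 / (1 - exp(-max(tr_s) / true_t1)),
                    true_t1 = true_t1,
                    fit_s0 = NA_real_, fit_t1 = NA_real_, converged = FALSE)
  se <- 1 / sqrt(n_voxels)  # SE of a mean of unit-noise SNR voxels
  for (b in seq_len(n_curves)) {
    mu <- out$true_s0[b] * (1 - exp(-tr_s / out$true_t1[b]))
    snr <- mu + rnorm(length(mu), 0, se)
    fit <- satrec(tr_list_ms, snr)
    out$converged[b] <- fit$converged
    if (fit$converged) {
      out$fit_s0[b] <- coef(fit)[["S0"]]
      out$fit_t1[b] <- coef(fit)[["T1"]]
    }
  }
  out
}
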