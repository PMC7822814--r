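#' Fit every placenta of a study
#'
#' Runs preprocessing and ROI saturation-recovery fitting for every session
#' of an in-memory study, producing the canonical placenta-record table:
#' one row per placenta x oxygen condition with mean SNR per TR, S0, T1,
#' PO2 and QC flags. PO2 and T1 are linked exactly by the calibration;
#' out-of-range PO2 is flagged, never censored.
#'
#' @param study A `"phantom_study"` (or a list with the same fields:
#'   `sessions`, `rois`, `design`).
#' @param smooth_sd,snr_threshold,interp_order Preprocessing knobs, see
#'   [preprocess_session()].
#' @param calib An [oxygen_calibration()].
#' @param verbose Print per-session progress.
#' @return Data frame of placenta records.
#' @export
fit_study <- function(study, smooth_sd = 3, snr_threshold = 5,
                      interp_order = 3L, calib = oxygen_calibration(),
                      verbose = FALSE) {
  design <- study$design
  records <- list()
  for (r in seq_len(nrow(design))) {
    sid <- design$session_id[r]
    mother <- design$mother_id[r]
    series <- study$sessions[[sid]]
    rois <- study$rois[[mother]]
    if (is.null(series) || is.null(rois))
      stop("fit_study: session or ROI set missing for session '", sid, "'")
    snr <- tryCatch(
      preprocess_session(series, rois, smooth_sd = smooth_sd,
                         snr_threshold = snr_threshold,
                         interp_order = interp_order),
      error = function(e)
        stop("fit_study: preprocessing failed for session '", sid, "': ",
             conditionMessage(e), call. = FALSE))
    if (verbose) message("fitted session ", sid)
    for (pl in rois$label_map$label) {
      roi <- roi_mean_snr(snr, rois$labels, pl)
      if (!roi$usable) {
        rec <- data.frame(mother_id = mother, genotype = design$genotype[r],
                          placenta_id = pl, oxygen_percent = design$oxygen_percent[r],
                          n_voxels = 0L, snr_tr1 = NA, snr_tr2 = NA,
                          snr_tr3 = NA, snr_tr4 = NA, s0 = NA_real_,
                          t1_s = NA_real_, po2_mmhg = NA_real_,
                          converged = FALSE,
                          qc_flags = placenta_qc_flags(NA, usable = FALSE))
      } else {
        fit <- satrec(roi$tr_ms, roi$snr_mean, calib = calib)
        t1 <- unname(coef(fit)[["T1"]])
        po2 <- if (fit$converged) t1_to_po2(t1, calib) else NA_real_
        snrs <- as.list(roi$snr_mean)
        names(snrs) <- paste0("snr_tr", seq_along(snrs))
        rec <- cbind(data.frame(mother_id = mother,
                                genotype = design$genotype[r],
                                placenta_id = pl,
                                oxygen_percent = design$oxygen_percent[r],
                                n_voxels = roi$n_voxels),
                     as.data.frame(snrs),
                     data.frame(s0 = unname(coef(fit)[["S0"]]), t1_s = t1,
                                po2_mmhg = po2, converged = fit$converged,
                                qc_flags = placenta_qc_flags(po2, fit$converged)))
      }
      records[[length(records) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}

#' Run the full pipeline
#'
#' Sequences the whole analysis under a single configuration: simulate (or
#' load) a study, preprocess every session, fit every placenta, run the
#' nested mixed-effects inference and write all outputs with provenance.
#' Synthetic mode is bit-stable for a fixed config and seed. Any stage
#' failure aborts with the stage name and the offending input id.
#'
#' @param config Either a [phantom_config()] (synthetic mode) or a named
#'   list / path to a `study.yaml` describing a real-data run with per-
#'   session NIfTI paths.
#' @param out_dir Output directory; created if needed. `NULL` keeps
#'   everything in memory.
#' @param smooth_sd,snr_threshold,interp_order Preprocessing knobs.
#' @param posthoc_all Run post-hoc models for every outcome (not only where
#'   the interaction is significant).
#' @param verbose Print stage progress.
#' @return Object of class `"pipeline_result"`: `records`, `inference`,
#'   `truth` (synthetic mode), `config`, `paths`.
#' @export
run_pipeline <- function(config = phantom_config(), out_dir = NULL,
                         smooth_sd = 3, snr_threshold = 5, interp_order = 3L,
                         posthoc_all = FALSE, verbose = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.character(config) && length(config) == 1L)
    config <- stage("config", read_study_config(config))
  if (inherits(config, "phantom_config")) {
    study <- stage("simulate", generate_study(config))
    calib <- config$calib
    truth <- study$truth
  } else if (is.list(config) && identical(config$mode, "real")) {
    study <- stage("load", load_real_study(config))
    calib <- do.call(oxygen_calibration,
                     config$calibration %||% list())
    truth <- NULL
  } else stop("run_pipeline: config must be a phantom_config or a real-mode list")
  records <- stage("fit", fit_study(study, smooth_sd = smooth_sd,
                                    snr_threshold = snr_threshold,
                                    interp_order = interp_order,
                                    calib = calib, verbose = verbose))
  usable <- records[!is.na(records$po2_mmhg), , drop = FALSE]
  inference <- stage("stats", run_inference(usable, posthoc_all = posthoc_all))
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    rec_path <- file.path(out_dir, "placenta_records.csv")
    write.csv(records, rec_path, row.names = FALSE)
    paths <- c(records = rec_path,
               write_inference_tables(inference, out_dir))
    if (!is.null(truth)) {
      tr_path <- file.path(out_dir, "truth.csv")
      write.csv(truth, tr_path, row.names = FALSE)
      paths <- c(paths, truth = tr_path)
    }
    prov <- list(calibration = list(slope = calib$slope,
                                    intercept = calib$intercept,
                                    formula = "PO2[mmHg] = slope/T1[s] - intercept"),
                 snr_formula = "SNR = sqrt(SI_m^2 - sigma_g^2)/sigma_g",
                 sigma_formula = "sigma_g = sigma_m/sqrt(2 - pi/2)",
                 smooth_sd = smooth_sd, snr_threshold = snr_threshold,
                 interp_order = interp_order,
                 seed = if (inherits(config, "phantom_config")) config$seed else NULL,
                 mode = if (inherits(config, "phantom_config")) "synthetic" else "real")
    write_study_config(prov, file.path(out_dir, "provenance.yaml"))
  }
  structure(list(records = records, inference = inference, truth = truth,
                 config = config, paths = paths),
            class = "pipeline_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Assemble a study object from a real-mode config list:
## config$sessions: list of (session_id, mother_id, genotype, oxygen_percent,
## paths (NIfTI per TR), roi_labels, roi_map); config$tr_list_ms.
load_real_study <- function(config) {
  stopifnot(is.list(config$sessions), length(config$sessions) >= 1L)
  sessions <- list()
  rois <- list()
  rows <- list()
  for (s in config$sessions) {
    sid <- s$session_id %||% stop("real-mode session without session_id")
    if (is.null(s$paths) || !all(file.exists(unlist(s$paths))))
      stop("missing volume file(s) for session '", sid, "'")
    sessions[[sid]] <- load_series(unlist(s$paths), config$tr_list_ms)
    if (is.null(rois[[s$mother_id]])) {
      if (is.null(s$roi_labels) || !file.exists(s$roi_labels))
        stop("missing ROI file for session '", sid, "'")
      rois[[s$mother_id]] <- read_roi_set(s$roi_labels, s$roi_map)
    }
    rows[[sid]] <- data.frame(mother_id = s$mother_id, genotype = s$genotype,
                              oxygen_percent = s$oxygen_percent,
                              session_id = sid)
  }
  list(sessions = sessions, rois = rois,
       design = design_table(do.call(rbind, rows)))
}

#' @export
print.pipeline_result <- function(x, ...) {
  rec <- x$records
  cat("pipeline_result:", nrow(rec), "placenta records (",
      sum(!is.na(rec$po2_mmhg)), "usable )\n")
  for (oxy in sort(unique(rec$oxygen_percent))) {
    sub <- rec[rec$oxygen_percent == oxy & !is.na(rec$po2_mmhg), ]
    cat(sprintf("  %3d%% O2: mean PO2 %7.1f mmHg (n = %d)\n", oxy,
                mean(sub$po2_mmhg), nrow(sub)))
  }
  invisible(x)
}

#' Human-readable study report
#'
#' Writes a PDF with per-placenta saturation-recovery curves, descriptive
#' group panels (mean, 95% CI and SD per genotype and oxygen level),
#' truth-versus-estimate recovery scatter (synthetic mode) and a QC section
#' listing flagged records, plus the test tables as text.
#'
#' @param result A `"pipeline_result"`.
#' @param file Output PDF path.
#' @param max_curves Maximum number of example fit curves drawn.
#' @return `file`, invisibly.
#' @export
make_report <- function(result, file = "fluorox_report.pdf", max_curves = 12L) {
  stopifnot(inherits(result, "pipeline_result"))
  rec <- result$records
  pdf(file, width = 9, height = 7)
  on.exit(dev.off(), add = TRUE)
  if (is.null(rec) || nrow(rec) == 0L) {
    plot.new(); title("fluorox report"); text(0.5, 0.5, "no records")
    return(invisible(file))
  }
  usable <- rec[!is.na(rec$po2_mmhg), , drop = FALSE]
  # 1. example fit curves
  snr_cols <- grep("^snr_tr", names(rec), value = TRUE)
  tr_ms <- if (inherits(result$config, "phantom_config"))
    result$config$tr_list_ms else c(318, 719, 1398, 5000)[seq_along(snr_cols)]
  if (nrow(usable) && length(snr_cols)) {
    take <- head(seq_len(nrow(usable)), max_curves)
    par(mfrow = c(3, 4), mar = c(4, 4, 2, 1))
    for (i in take) {
      fit <- satrec(tr_ms, as.numeric(usable[i, snr_cols]))
      plot(fit, main = sprintf("%s p%d %d%%", usable$mother_id[i],
                               usable$placenta_id[i], usable$oxygen_percent[i]))
    }
  }
  # 2. group panels
  par(mfrow = c(2, 2), mar = c(4, 4, 3, 1))
  for (out in intersect(c("snr_tr1", "s0", "t1_s", "po2_mmhg"), names(usable))) {
    ds <- descriptive_summary(usable, out)
    plot_group_panel(usable, ds, out)
  }
  # 3. truth recovery (synthetic)
  if (!is.null(result$truth)) {
    par(mfrow = c(1, 1))
    key_r <- paste(usable$mother_id, usable$placenta_id, usable$oxygen_percent)
    key_t <- paste(result$truth$mother_id, result$truth$placenta_id,
                   result$truth$oxygen_percent)
    idx <- match(key_r, key_t)
    truth_po2 <- result$truth$true_po2_mmhg[idx]
    err <- usable$po2_mmhg - truth_po2
    plot(truth_po2, usable$po2_mmhg, pch = 19, col = "#00000088",
         xlab = "true PO2 [mmHg]", ylab = "estimated PO2 [mmHg]",
         main = sprintf("PO2 recovery: median |err| %.1f mmHg, bias %.1f mmHg",
                        median(abs(err), na.rm = TRUE), mean(err, na.rm = TRUE)))
    abline(0, 1, col = "red3")
  }
  # 4. QC + test tables
  par(mfrow = c(1, 1), mar = c(1, 1, 2, 1))
  plot.new(); title("QC and fixed-effect tests")
  flagged <- rec[nzchar(rec$qc_flags), , drop = FALSE]
  lines_txt <- c(sprintf("records: %d total, %d usable, %d flagged",
                         nrow(rec), nrow(usable), nrow(flagged)),
                 if (nrow(flagged)) sprintf("  %s p%d %d%%: %s",
                                            flagged$mother_id, flagged$placenta_id,
                                            flagged$oxygen_percent, flagged$qc_flags),
                 "", "Full-model tests:",
                 utils::capture.output(print(
                   format(result$inference$table_full, digits = 3),
                   row.names = FALSE)))
  lines_txt <- head(lines_txt, 40L)
  text(0, seq(0.97, by = -0.025, length.out = length(lines_txt)),
       lines_txt, adj = c(0, 1), cex = 0.7, family = "mono")
  invisible(file)
}

plot_group_panel <- function(records, ds, outcome) {
  oxys <- sort(unique(ds$oxygen_percent))
  xg <- function(oxy, geno) match(oxy, oxys) + ifelse(geno == "WT", -0.15, 0.15)
  x <- xg(records$oxygen_percent, records$genotype)
  y <- as.numeric(records[[outcome]])
  plot(x + runif(length(x), -0.04, 0.04), y, pch = 21,
       bg = ifelse(records$genotype == "WT", "black", "grey70"),
       xaxt = "n", xlab = "% O2 in breathing air", ylab = outcome,
       main = outcome, xlim = c(0.5, length(oxys) + 0.5))
  axis(1, at = seq_along(oxys), labels = oxys)
  for (r in seq_len(nrow(ds))) {
    xc <- xg(ds$oxygen_percent[r], ds$genotype[r])
    lines(xc + c(-0.1, 0.1), rep(ds$mean[r], 2), col = "red3", lwd = 2)
    if (is.finite(ds$ci_lo[r]))
      arrows(xc, ds$ci_lo[r], xc, ds$ci_hi[r], angle = 90, code = 3,
             length = 0.03, col = "red3")
  }
  legend("topleft", pch = 21, pt.bg = c("black", "grey70"),
         legend = c("WT", "KO"), bty = "n")
}
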