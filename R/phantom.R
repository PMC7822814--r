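#' Synthetic study configuration
#'
#' Defines the simulated study: group sizes matching the in vivo design
#' (WT 3 mothers / 19 placentas, KO 4 / 17), three within-subject oxygen
#' conditions (30/60/100% O2), the four-TR saturation-recovery protocol
#' (318/719/1398/5000 ms) and the two-grid acquisition geometry. Per
#' placenta and condition a ground-truth PO2 is drawn around the condition
#' baseline (plus the KO offset) with mother- and placenta-level random
#' intercepts and placenta-by-condition jitter; the calibration converts it
#' exactly into the ground-truth T1 that drives the signal model. Noise is
#' Rician: the magnitude of the noiseless signal plus complex Gaussian
#' channel noise of SD `sigma_g`.
#'
#' @param n_mothers Named integer vector, mothers per genotype.
#' @param n_placentas Named integer vector, total placentas per genotype
#'   (distributed as evenly as possible across that genotype's mothers).
#' @param oxygen_levels Oxygen conditions in percent, distinct.
#' @param tr_list_ms Repetition times in ms, positive.
#' @param sigma_g Gaussian channel noise SD in native image units, > 0.
#' @param s0_range Range of equilibrium SNR (S0) per placenta; the native
#'   signal amplitude is `S0 * s0_scale`.
#' @param s0_scale Native signal units per SNR unit; defaults to `sigma_g`,
#'   making `s0_range` the true equilibrium SNR. Fix it to decouple the
#'   signal amplitude from the noise level (e.g. for zero-noise limits).
#' @param baseline_po2 Named numeric: mean PO2 (mmHg) per oxygen level (WT).
#' @param ko_offsets Named numeric: additive KO PO2 shift per oxygen level.
#' @param mother_sd,placenta_sd SDs (mmHg) of mother and placenta random
#'   intercepts on PO2.
#' @param jitter_sd SD (mmHg) of placenta-by-condition PO2 jitter.
#' @param roi_voxel_range Target placenta ROI size range in 19F-grid voxels.
#' @param background_label Label of the signal-free noise ROI box.
#' @param geometry Output of [default_geometry()] (or same shape).
#' @param calib An [oxygen_calibration()].
#' @param seed Integer RNG seed.
#' @return Object of class `"phantom_config"`.
#' @export
phantom_config <- function(n_mothers = c(WT = 3L, KO = 4L),
                           n_placentas = c(WT = 19L, KO = 17L),
                           oxygen_levels = c(30, 60, 100),
                           tr_list_ms = c(318, 719, 1398, 5000),
                           sigma_g = 40,
                           s0_range = c(6, 12),
                           s0_scale = NULL,
                           baseline_po2 = c(`30` = 100, `60` = 150, `100` = 250),
                           ko_offsets = c(`30` = -64, `60` = 0, `100` = 0),
                           mother_sd = 15, placenta_sd = 15, jitter_sd = 20,
                           roi_voxel_range = c(20, 80),
                           background_label = 999L,
                           geometry = default_geometry(),
                           calib = oxygen_calibration(),
                           seed = 1L) {
  stopifnot(all(c("WT", "KO") %in% names(n_mothers)),
            all(c("WT", "KO") %in% names(n_placentas)),
            all(n_mothers >= 1L), all(n_placentas >= n_mothers[names(n_placentas)]))
  oxygen_levels <- as.numeric(oxygen_levels)
  if (anyDuplicated(oxygen_levels)) stop("phantom_config: oxygen levels must be distinct")
  tr_list_ms <- sort(as.numeric(tr_list_ms))
  if (any(tr_list_ms <= 0)) stop("phantom_config: all TRs must be > 0")
  if (!(is.numeric(sigma_g) && sigma_g > 0)) stop("phantom_config: sigma_g must be > 0")
  stopifnot(length(s0_range) == 2L, s0_range[1] > 0, diff(s0_range) >= 0)
  lv <- as.character(oxygen_levels)
  if (!all(lv %in% names(baseline_po2)))
    stop("phantom_config: baseline_po2 must name every oxygen level")
  if (!all(lv %in% names(ko_offsets)))
    stop("phantom_config: ko_offsets must name every oxygen level")
  implied <- c(baseline_po2[lv], baseline_po2[lv] + ko_offsets[lv])
  if (any(implied <= -calib$intercept))
    stop("phantom_config: group-mean PO2 of ", min(implied),
         " mmHg implies a nonpositive T1 (needs PO2 > ", -calib$intercept, ")")
  stopifnot(mother_sd >= 0, placenta_sd >= 0, jitter_sd >= 0,
            length(roi_voxel_range) == 2L, roi_voxel_range[1] >= 4)
  if (is.null(s0_scale)) s0_scale <- sigma_g
  stopifnot(is.numeric(s0_scale), s0_scale > 0)
  structure(list(n_mothers = n_mothers, n_placentas = n_placentas,
                 oxygen_levels = oxygen_levels, tr_list_ms = tr_list_ms,
                 sigma_g = sigma_g, s0_range = as.numeric(s0_range),
                 s0_scale = s0_scale,
                 baseline_po2 = baseline_po2, ko_offsets = ko_offsets,
                 mother_sd = mother_sd, placenta_sd = placenta_sd,
                 jitter_sd = jitter_sd,
                 roi_voxel_range = as.numeric(roi_voxel_range),
                 background_label = as.integer(background_label),
                 geometry = geometry, calib = calib, seed = as.integer(seed)),
            class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("phantom_config:",
      sprintf("WT %d/%d, KO %d/%d (mothers/placentas);", x$n_mothers[["WT"]],
              x$n_placentas[["WT"]], x$n_mothers[["KO"]], x$n_placentas[["KO"]]),
      "O2", paste0(x$oxygen_levels, "%", collapse = "/"), "\n")
  cat("  TRs [ms]:", paste(x$tr_list_ms, collapse = ", "),
      "; sigma_g =", x$sigma_g, "; S0 range", paste(x$s0_range, collapse = "-"), "\n")
  invisible(x)
}

## Even split of n placentas over m mothers: first (n mod m) mothers get one more.
split_placentas <- function(n, m) {
  base <- n %/% m
  extra <- n %% m
  base + (seq_len(m) <= extra)
}

## Deterministic non-overlapping slot lattice for up to 8 placentas per
## mother, in mm, inside the shared FOV and the thinner 19F stack.
placenta_slots <- function() {
  cbind(x = rep(c(-7, 7), 4),
        y = rep(c(-15, -5, 5, 15), each = 2),
        z = rep(c(-2.4, 2.4), 4))
}

#' Ground-truth table for a synthetic study
#'
#' One row per placenta x oxygen condition with the true S0, T1 and PO2
#' (linked exactly by the calibration). Used by [generate_study()] and
#' directly by record-level simulations.
#'
#' @param config A [phantom_config()]. The caller manages the RNG seed.
#' @return Data frame of class `"phantom_truth"`: `mother_id`, `genotype`,
#'   `placenta_id`, `oxygen_percent`, `true_s0`, `true_t1_s`, `true_po2_mmhg`,
#'   `sigma_g`.
#' @export
phantom_truth <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  rows <- list()
  floor_po2 <- -config$calib$intercept + 10  # keep implied T1 positive/bounded
  for (g in c("WT", "KO")) {
    m <- config$n_mothers[[g]]
    per <- split_placentas(config$n_placentas[[g]], m)
    for (im in seq_len(m)) {
      mother <- sprintf("%s%d", g, im)
      b_mother <- rnorm(1, 0, config$mother_sd)
      for (ip in seq_len(per[im])) {
        b_pl <- rnorm(1, 0, config$placenta_sd)
        s0 <- runif(1, config$s0_range[1], config$s0_range[2])
        for (oxy in config$oxygen_levels) {
          lv <- as.character(oxy)
          mu <- config$baseline_po2[[lv]] +
            if (g == "KO") config$ko_offsets[[lv]] else 0
          po2 <- mu + b_mother + b_pl + rnorm(1, 0, config$jitter_sd)
          po2 <- max(po2, floor_po2)
          rows[[length(rows) + 1L]] <- data.frame(
            mother_id = mother, genotype = g, placenta_id = ip,
            oxygen_percent = oxy, true_s0 = s0,
            true_t1_s = po2_to_t1(po2, config$calib),
            true_po2_mmhg = po2, sigma_g = config$sigma_g)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("phantom_truth", "data.frame")
  out
}

#' Three-compartment placental signal model
#'
#' Volume fractions for the maternal blood, fetal blood and trophoblast
#' pools (defaults 64.4% / 23.7% / 11.9%), per-compartment T1 and relative
#' 19F concentration weights. Fractions must be nonnegative and sum to 1
#' within 1e-12.
#'
#' @param fractions Named numeric (maternal, fetal, trophoblast).
#' @param t1_s Per-compartment T1 in seconds.
#' @param weights Per-compartment relative 19F concentration.
#' @return Object of class `"compartment_model"`.
#' @export
compartment_model <- function(fractions = c(maternal = 0.644, fetal = 0.237,
                                            trophoblast = 0.119),
                              t1_s = c(maternal = 1.5, fetal = 0.8,
                                       trophoblast = 2.5),
                              weights = c(maternal = 1, fetal = 1,
                                          trophoblast = 1)) {
  fractions <- as.numeric(fractions)
  t1_s <- as.numeric(t1_s)
  weights <- as.numeric(weights)
  stopifnot(length(t1_s) == length(fractions),
            length(weights) == length(fractions))
  if (any(fractions < 0)) stop("compartment_model: fractions must be nonnegative")
  if (abs(sum(fractions) - 1) > 1e-12)
    stop("compartment_model: fractions must sum to 1 (got ", sum(fractions), ")")
  if (any(t1_s <= 0) || any(weights < 0))
    stop("compartment_model: T1s must be positive, weights nonnegative")
  structure(list(fractions = fractions, t1_s = t1_s, weights = weights),
            class = "compartment_model")
}

#' Noiseless multi-compartment saturation-recovery signal
#'
#' `S(TR) = S0_total * sum_c w_c f_c (1 - exp(-TR/T1_c))`. Reduces to the
#' single-compartment model when one fraction is 1 or all T1s coincide
#' (with unit weights).
#'
#' @param model A [compartment_model()].
#' @param tr_ms Repetition times (ms).
#' @param s0_total Overall equilibrium amplitude.
#' @return Numeric signal vector, one value per TR.
#' @export
mix_compartments <- function(model, tr_ms, s0_total = 1) {
  stopifnot(inherits(model, "compartment_model"))
  tr_s <- as.numeric(tr_ms) / 1000
  sig <- vapply(tr_s, function(t)
    sum(model$weights * model$fractions * (1 - exp(-t / model$t1_s))), 0)
  s0_total * sig
}

## Ellipsoid semi-axes (a, a, c) hitting a target 19F-voxel count.
ellipsoid_axes <- function(n_voxels, voxel_volume, c_mm) {
  v <- n_voxels * voxel_volume
  a <- sqrt(3 * v / (4 * pi * c_mm))
  c(a, a, c_mm)
}

## Mask of an axis-aligned ellipsoid evaluated at the grid's voxel centres.
ellipsoid_mask <- function(geom, center, axes) {
  d <- geom$dim
  ax <- voxel_to_world(geom, cbind(seq_len(d[1]) - 1L, 0, 0))[, 1]
  ay <- voxel_to_world(geom, cbind(0, seq_len(d[2]) - 1L, 0))[, 2]
  az <- voxel_to_world(geom, cbind(0, 0, seq_len(d[3]) - 1L))[, 3]
  ex <- ((ax - center[1]) / axes[1])^2
  ey <- ((ay - center[2]) / axes[2])^2
  ez <- ((az - center[3]) / axes[3])^2
  outer(outer(ex, ey, `+`), ez, `+`) < 1
}

## Background noise box (mm) in a signal-free corner of the shared FOV,
## clear of every placenta slot and inside the 19F stack.
background_box <- function(geom) {
  d <- geom$dim
  ax <- voxel_to_world(geom, cbind(seq_len(d[1]) - 1L, 0, 0))[, 1]
  ay <- voxel_to_world(geom, cbind(0, seq_len(d[2]) - 1L, 0))[, 2]
  az <- voxel_to_world(geom, cbind(0, 0, seq_len(d[3]) - 1L))[, 3]
  inx <- ax >= 13 & ax <= 18
  iny <- ay >= 18 & ay <= 24.5
  inz <- az >= -5 & az <= 5
  outer(outer(inx, iny, `&`), inz, `&`)
}

#' Generate a complete synthetic study
#'
#' Builds, per mother x oxygen condition, a four-TR 19F magnitude series on
#' the 19F grid. Each placenta is a homogeneous axis-aligned ellipsoid
#' (placed on a fixed non-overlapping lattice, sized to 20-80 19F voxels)
#' whose noiseless voxel signal is `S0 * sigma_g * (1 - exp(-TR/T1))`;
#' background voxels carry zero signal; every voxel receives Rician noise of
#' SD `sigma_g`. ROI labels are drawn on the anatomical grid, with the
#' signal-free noise box as its own label. Fully deterministic under
#' `config$seed`.
#'
#' @param config A [phantom_config()].
#' @param dir Optional output directory; when given, all volumes (NIfTI),
#'   tables (CSV) and the config (YAML) are written there.
#' @return Object of class `"phantom_study"`: `sessions` (named list of
#'   [magnitude_series()], one per mother x condition), `rois` (named list of
#'   [roi_set()] per mother), `design` ([design_table()]), `truth`
#'   ([phantom_truth()] table), `config`.
#' @export
generate_study <- function(config = phantom_config(), dir = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  truth <- phantom_truth(config)
  g_anat <- config$geometry$anat
  g_f19 <- config$geometry$f19
  vox_vol_f19 <- abs(det(g_f19$affine[1:3, 1:3]))
  slots <- placenta_slots()
  mothers <- unique(truth$mother_id)
  rois <- list()
  sessions <- list()
  design_rows <- list()
  bg_anat <- background_box(g_anat)
  for (mother in mothers) {
    tm <- truth[truth$mother_id == mother, ]
    pls <- unique(tm$placenta_id)
    if (length(pls) > nrow(slots))
      stop("generate_study: more placentas than lattice slots for ", mother)
    lab_anat <- array(0L, g_anat$dim)
    geom_info <- list()
    for (ip in seq_along(pls)) {
      nv <- runif(1, config$roi_voxel_range[1], config$roi_voxel_range[2])
      c_mm <- runif(1, 2.4, 3.6)
      axes <- ellipsoid_axes(nv, vox_vol_f19, c_mm)
      center <- slots[ip, ] + runif(3, -0.5, 0.5)
      geom_info[[ip]] <- list(center = center, axes = axes)
      lab_anat[ellipsoid_mask(g_anat, center, axes)] <- pls[ip]
    }
    lab_anat[bg_anat] <- config$background_label
    map <- data.frame(label = pls, mother_id = mother, placenta_id = pls)
    rois[[mother]] <- roi_set(lab_anat, g_anat, map,
                              background_label = config$background_label)
    # per-placenta masks on the 19F grid (consistent world-space ellipsoids)
    f_masks <- lapply(geom_info, function(gi)
      ellipsoid_mask(g_f19, gi$center, gi$axes))
    genotype <- tm$genotype[1L]
    for (oxy in config$oxygen_levels) {
      vols <- vector("list", length(config$tr_list_ms))
      noiseless <- lapply(seq_along(config$tr_list_ms), function(i)
        array(0, g_f19$dim))
      for (ip in seq_along(pls)) {
        tr_row <- tm[tm$placenta_id == pls[ip] & tm$oxygen_percent == oxy, ]
        amp <- tr_row$true_s0 * config$s0_scale
        sig <- amp * (1 - exp(-(config$tr_list_ms / 1000) / tr_row$true_t1_s))
        for (i in seq_along(sig))
          noiseless[[i]][f_masks[[ip]]] <- sig[i]
      }
      for (i in seq_along(config$tr_list_ms)) {
        n_vox <- prod(g_f19$dim)
        vols[[i]] <- array(rrician(n_vox, signal = as.vector(noiseless[[i]]),
                                   sigma_g = config$sigma_g), g_f19$dim)
      }
      sid <- sprintf("%s_o%03d", mother, as.integer(oxy))
      sessions[[sid]] <- magnitude_series(vols, config$tr_list_ms, g_f19,
                                          meta = list(mother_id = mother,
                                                      oxygen_percent = oxy))
      design_rows[[sid]] <- data.frame(mother_id = mother, genotype = genotype,
                                       oxygen_percent = oxy, session_id = sid)
    }
  }
  design <- design_table(do.call(rbind, design_rows))
  rownames(design) <- NULL
  study <- structure(list(sessions = sessions, rois = rois, design = design,
                          truth = truth, config = config),
                     class = "phantom_study")
  if (!is.null(dir)) write_phantom_study(study, dir)
  study
}

#' @export
print.phantom_study <- function(x, ...) {
  cat("phantom_study:", length(x$rois), "mothers,",
      length(unique(paste(x$truth$mother_id, x$truth$placenta_id))),
      "placentas,", length(x$sessions), "sessions\n")
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Volumes as NIfTI, design and truth tables as CSV, configuration as YAML,
#' in the layout [run_pipeline()] reads back.
#'
#' @param study A `"phantom_study"`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_phantom_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  design <- study$design
  design$session_dir <- file.path("sessions", design$session_id)
  for (sid in names(study$sessions))
    write_series(study$sessions[[sid]], file.path(dir, "sessions", sid))
  for (mother in names(study$rois))
    write_roi_set(study$rois[[mother]], file.path(dir, "rois"), prefix = mother)
  write.csv(design, file.path(dir, "design.csv"), row.names = FALSE)
  write.csv(study$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  cfg <- study$config
  write_study_config(list(
    mode = "synthetic", seed = cfg$seed, sigma_g = cfg$sigma_g,
    oxygen_levels = cfg$oxygen_levels, tr_list_ms = cfg$tr_list_ms,
    calibration = list(slope = cfg$calib$slope, intercept = cfg$calib$intercept),
    background_label = cfg$background_label),
    file.path(dir, "study.yaml"))
  invisible(dir)
}

#' Record-level study simulation
#'
#' Draws placenta-record tables (the statistics module's input) directly
#' from the phantom's PO2 model plus a measurement-error term that stands in
#' for the image-noise-plus-fitting chain, so mixed-model Monte-Carlo
#' studies run in milliseconds per replicate. The caller controls the seed
#' via `set.seed()`.
#'
#' @param config A [phantom_config()].
#' @param measurement_sd SD (mmHg) of the per-record PO2 measurement error.
#' @return Data frame with `mother_id`, `genotype`, `placenta_id`,
#'   `oxygen_percent`, `po2_mmhg` (measured), `t1_s`, `true_po2_mmhg`.
#' @export
simulate_records <- function(config = phantom_config(), measurement_sd = 25) {
  truth <- phantom_truth(config)
  po2 <- truth$true_po2_mmhg + rnorm(nrow(truth), 0, measurement_sd)
  po2 <- pmax(po2, -config$calib$intercept + 5)
  data.frame(mother_id = truth$mother_id, genotype = truth$genotype,
             placenta_id = truth$placenta_id,
             oxygen_percent = truth$oxygen_percent,
             po2_mmhg = po2, t1_s = po2_to_t1(po2, config$calib),
             true_po2_mmhg = truth$true_po2_mmhg)
}
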