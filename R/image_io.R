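#' Multi-TR magnitude series
#'
#' Container for one session's saturation-recovery acquisition: one 3-D
#' magnitude volume per repetition time, all sharing a grid and affine.
#' Volumes are sorted by TR on construction.
#'
#' @param volumes List of 3-D numeric arrays (one per TR).
#' @param tr_ms Numeric vector of repetition times in ms, same length.
#' @param geometry A [grid_geometry()] shared by all volumes.
#' @param nucleus Acquisition nucleus label (metadata only).
#' @param meta Optional named list of extra acquisition metadata.
#' @return Object of class `"magnitude_series"`.
#' @export
magnitude_series <- function(volumes, tr_ms, geometry, nucleus = "19F",
                             meta = list()) {
  stopifnot(is.list(volumes), length(volumes) == length(tr_ms),
            length(volumes) >= 1L, inherits(geometry, "grid_geometry"))
  tr_ms <- as.numeric(tr_ms)
  if (any(!is.finite(tr_ms)) || any(tr_ms <= 0))
    stop("magnitude_series: TRs must be positive")
  if (anyDuplicated(tr_ms)) stop("magnitude_series: duplicate TRs")
  ord <- order(tr_ms)
  volumes <- volumes[ord]
  tr_ms <- tr_ms[ord]
  for (v in volumes) {
    if (!is.array(v) || length(dim(v)) != 3L || !all(dim(v) == geometry$dim))
      stop("magnitude_series: all volumes must be 3-D arrays on the series grid")
    if (any(v < 0)) stop("magnitude_series: magnitude intensities must be >= 0")
  }
  structure(list(volumes = volumes, tr_ms = tr_ms, geometry = geometry,
                 nucleus = nucleus, meta = meta),
            class = "magnitude_series")
}

#' @export
print.magnitude_series <- function(x, ...) {
  cat("magnitude_series (", x$nucleus, "): ",
      paste(x$geometry$dim, collapse = " x "), " voxels, TRs [ms]: ",
      paste(x$tr_ms, collapse = ", "), "\n", sep = "")
  invisible(x)
}

nifti_from_array <- function(arr, geometry) {
  spacing <- sqrt(colSums(geometry$affine[1:3, 1:3]^2))
  img <- RNifti::asNifti(arr, pixdim = spacing)
  aff <- structure(geometry$affine, code = 2L)
  RNifti::`sform<-`(img, aff)
}

geometry_from_nifti <- function(img) {
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  grid_geometry(dim(img)[1:3], affine = unclass(aff)[1:4, 1:4])
}

#' Write a volume as NIfTI
#'
#' Volumes are written as NIfTI-2 so the affine round-trips at double
#' precision.
#'
#' @param vol 3-D array.
#' @param geometry A [grid_geometry()].
#' @param path Output file (`.nii`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, geometry, path) {
  img <- nifti_from_array(vol, geometry)
  RNifti::writeNifti(img, path, version = 2)
  invisible(path)
}

#' Read a volume and its geometry from NIfTI
#'
#' @param path NIfTI file.
#' @return List with `data` (3-D array) and `geometry` ([grid_geometry()]).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim = dim(img)[1:3]),
       geometry = geometry_from_nifti(img))
}

#' Load a multi-TR series from NIfTI files
#'
#' @param paths Character vector of NIfTI files, one volume per TR.
#' @param tr_ms Repetition times in ms matching `paths`.
#' @param affine_tol Maximum absolute per-entry affine mismatch tolerated
#'   between volumes (mm).
#' @inheritParams magnitude_series
#' @return A [magnitude_series()].
#' @export
load_series <- function(paths, tr_ms, nucleus = "19F", affine_tol = 1e-4) {
  stopifnot(length(paths) == length(tr_ms), length(paths) >= 1L)
  missing <- !file.exists(paths)
  if (any(missing))
    stop("load_series: missing file(s): ", paste(paths[missing], collapse = ", "))
  vols <- lapply(paths, read_volume)
  ref <- vols[[1L]]$geometry
  for (v in vols[-1L]) {
    if (!all(v$geometry$dim == ref$dim))
      stop("load_series: volumes have mismatched matrix sizes")
    if (max(abs(v$geometry$affine - ref$affine)) > affine_tol)
      stop("load_series: volume affines disagree beyond tolerance ", affine_tol)
  }
  magnitude_series(lapply(vols, `[[`, "data"), tr_ms, ref, nucleus = nucleus)
}

#' Write a magnitude series to a directory
#'
#' One NIfTI per TR (`<prefix>_tr<ms>.nii`) plus a JSON sidecar with TRs and
#' nucleus.
#'
#' @param series A [magnitude_series()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of volume paths, invisibly.
#' @export
write_series <- function(series, dir, prefix = "f19") {
  stopifnot(inherits(series, "magnitude_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("%s_tr%04d.nii", prefix,
                                  as.integer(round(series$tr_ms))))
  for (i in seq_along(paths))
    write_volume(series$volumes[[i]], series$geometry, paths[i])
  side <- list(tr_ms = series$tr_ms, nucleus = series$nucleus,
               files = basename(paths))
  jsonlite::write_json(side, file.path(dir, paste0(prefix, "_series.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Region-of-interest label set
#'
#' Integer label volume on the anatomical grid: 0 = outside, positive
#' labels = placentas, plus one designated background (signal-free) label
#' used for noise estimation. Label -1 is reserved and never used.
#'
#' @param labels Integer 3-D array.
#' @param geometry [grid_geometry()] of the label volume.
#' @param label_map Data frame with columns `label`, `mother_id`,
#'   `placenta_id` for the placenta labels.
#' @param background_label Integer label of the signal-free noise ROI.
#' @return Object of class `"roi_set"`.
#' @export
roi_set <- function(labels, geometry, label_map, background_label = 999L) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L,
            inherits(geometry, "grid_geometry"),
            all(dim(labels) == geometry$dim),
            is.data.frame(label_map),
            all(c("label", "mother_id", "placenta_id") %in% names(label_map)))
  storage.mode(labels) <- "integer"
  if (any(labels == -1L)) stop("roi_set: label -1 is reserved")
  present <- setdiff(unique(as.vector(labels)), c(0L, as.integer(background_label)))
  unknown <- setdiff(present, label_map$label)
  if (length(unknown))
    stop("roi_set: labels without map entry: ", paste(unknown, collapse = ", "))
  structure(list(labels = labels, geometry = geometry, label_map = label_map,
                 background_label = as.integer(background_label)),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("roi_set:", nrow(x$label_map), "placenta label(s), background label",
      x$background_label, "\n")
  invisible(x)
}

#' Write / read an ROI label set
#'
#' Writes the label volume (`<prefix>_labels.nii`), the background ROI as
#' its own binary label volume (`<prefix>_background.nii`) and the label map
#' CSV.
#'
#' @param rois A [roi_set()].
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_roi_set <- function(rois, dir, prefix = "rois") {
  stopifnot(inherits(rois, "roi_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, paste0(prefix, "_labels.nii"))
  p2 <- file.path(dir, paste0(prefix, "_background.nii"))
  p3 <- file.path(dir, paste0(prefix, "_map.csv"))
  write_volume(rois$labels, rois$geometry, p1)
  bg <- array(0L, dim(rois$labels))
  bg[rois$labels == rois$background_label] <- 1L
  write_volume(bg, rois$geometry, p2)
  map <- rois$label_map
  map$background_label <- rois$background_label
  write.csv(map, p3, row.names = FALSE)
  invisible(c(labels = p1, background = p2, map = p3))
}

#' @rdname write_roi_set
#' @param labels_path,map_path Paths written by [write_roi_set()].
#' @export
read_roi_set <- function(labels_path, map_path) {
  v <- read_volume(labels_path)
  lab <- v$data
  storage.mode(lab) <- "integer"
  map <- read.csv(map_path)
  bg <- as.integer(map$background_label[1L])
  roi_set(lab, v$geometry, map[, c("label", "mother_id", "placenta_id")],
          background_label = bg)
}

#' Study design table
#'
#' One row per mother x oxygen condition with genotype and session paths.
#' Validates that (mother, oxygen) pairs are unique and genotype is constant
#' within mother.
#'
#' @param df Data frame with columns `mother_id`, `genotype` ("WT"/"KO"),
#'   `oxygen_percent`, and optionally `session_dir`.
#' @return The validated data frame, classed `"design_table"`.
#' @export
design_table <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("mother_id", "genotype", "oxygen_percent") %in% names(df)))
  if (!all(df$genotype %in% c("WT", "KO")))
    stop("design_table: genotype must be WT or KO")
  key <- paste(df$mother_id, df$oxygen_percent)
  if (anyDuplicated(key))
    stop("design_table: duplicate (mother, oxygen) rows")
  gpm <- tapply(df$genotype, df$mother_id, function(g) length(unique(g)))
  if (any(gpm > 1L))
    stop("design_table: genotype must be constant within mother")
  class(df) <- c("design_table", "data.frame")
  df
}

#' Read / write study configuration YAML
#'
#' `study.yaml` holds the per-session entries and tunables used by
#' [run_pipeline()]. Plain wrappers over the yaml package so all config I/O
#' goes through one place.
#'
#' @param config Named list.
#' @param path YAML file.
#' @return `read_study_config` returns the named list.
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("read_study_config: no such file: ", path)
  yaml::read_yaml(path)
}
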