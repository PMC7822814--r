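test_that("voxel/world mappings invert each other", {
  g <- grid_geometry(c(64, 84, 8), c(39.2 / 64, 51.2 / 84, 2.4))
  ijk <- cbind(c(0, 10, 63), c(0, 41, 83), c(0, 3, 7))
  expect_equal(world_to_voxel(g, voxel_to_world(g, ijk)), ijk,
               tolerance = 1e-12, ignore_attr = TRUE)
  # default grids share the world-space stack centre
  geo <- default_geometry()
  c_anat <- voxel_to_world(geo$anat, (geo$anat$dim - 1) / 2)
  c_f19 <- voxel_to_world(geo$f19, (geo$f19$dim - 1) / 2)
  expect_equal(c_anat, c_f19, tolerance = 1e-12)
  expect_error(grid_geometry(c(4, 4, 4), affine = matrix(0, 4, 4)), "singular")
})

test_that("resampling preserves constants and the identity transform", {
  g <- grid_geometry(c(12, 14, 5), c(1, 1, 2))
  v <- array(7, g$dim)
  for (ord in c(0L, 1L, 3L)) {
    expect_equal(resample_between_grids(v, g, g, order = ord), v,
                 tolerance = 1e-12)
  }
  g2 <- grid_geometry(c(23, 27, 9), c(0.5, 0.5, 1))
  out <- resample_between_grids(v, g, g2, order = 1L)
  expect_equal(out[5:19, 5:23, 3:7], array(7, c(15, 19, 5)), tolerance = 1e-12)
  r <- array(rnorm(prod(g$dim)), g$dim)
  expect_equal(resample_between_grids(r, g, g, order = 3L), r, tolerance = 1e-9)
})

test_that("upsampling a linear ramp preserves it away from edges", {
  g <- grid_geometry(c(20, 10, 5), c(2, 2, 2))
  x_mm <- voxel_to_world(g, cbind(seq_len(20) - 1, 0, 0))[, 1]
  ramp <- array(rep(3 * x_mm + 1, 10 * 5), g$dim)
  g2 <- grid_geometry(c(40, 20, 10), c(1, 1, 1))
  for (ord in c(1L, 3L)) {
    out <- resample_between_grids(ramp, g, g2, order = ord)
    x2 <- voxel_to_world(g2, cbind(seq_len(40) - 1, 0, 0))[, 1]
    expected <- 3 * x2 + 1
    interior <- 5:36
    err <- abs(sweep(out[interior, 5:16, 3:8], 1, expected[interior]))
    expect_lt(max(err), 1e-6)
  }
})

test_that("oblique (non-axis-aligned) grids interpolate linear fields exactly", {
  g <- grid_geometry(c(16, 16, 6), c(1, 1, 2))
  th <- 0.3
  R <- diag(4)
  R[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  gr <- grid_geometry(g$dim, affine = R %*% g$affine)
  w <- grid_world_coords(gr)
  lin <- array(2 * w[, 1] - w[, 2] + 0.5 * w[, 3], gr$dim)
  gt <- grid_geometry(c(8, 8, 3), c(1, 1, 2))
  out <- resample_between_grids(lin, gr, gt, order = 1L)
  wt <- grid_world_coords(gt)
  expected <- array(2 * wt[, 1] - wt[, 2] + 0.5 * wt[, 3], gt$dim)
  # interior only: edge clamping and FOV fill affect the border
  expect_equal(out[3:6, 3:6, 2], expected[3:6, 3:6, 2], tolerance = 1e-9)
})

test_that("magnitude series validates grids, TRs and intensities", {
  g <- grid_geometry(c(4, 4, 2), c(1, 1, 1))
  vols <- list(array(1, g$dim), array(2, g$dim))
  s <- magnitude_series(vols[2:1], c(5000, 318), g)
  expect_equal(s$tr_ms, c(318, 5000))  # sorted on construction
  expect_equal(s$volumes[[1]], array(1, g$dim))  # TR follows its volume
  expect_error(magnitude_series(vols, c(318, 318), g), "duplicate")
  expect_error(magnitude_series(vols, c(-1, 318), g), "positive")
  expect_error(magnitude_series(list(array(1, c(3, 4, 2)), vols[[2]]),
                                c(318, 719), g), "grid")
  expect_error(magnitude_series(list(array(-1, g$dim), vols[[2]]),
                                c(318, 719), g), ">= 0")
})

test_that("NIfTI series round-trips data and affine", {
  g <- grid_geometry(c(10, 12, 4), c(0.6125, 51.2 / 84, 2.4))
  set.seed(7)
  vols <- lapply(1:4, function(i) array(abs(rnorm(prod(g$dim))), g$dim))
  s <- magnitude_series(vols, c(318, 719, 1398, 5000), g)
  d <- withr::local_tempdir()
  paths <- write_series(s, d)
  s2 <- load_series(paths, s$tr_ms)
  for (i in 1:4) expect_equal(s2$volumes[[i]], s$volumes[[i]], tolerance = 1e-12)
  expect_lt(max(abs(s2$geometry$affine - g$affine)), 1e-6)
  expect_error(load_series(c(paths[1], "nope.nii"), c(318, 719)), "missing")
  # mismatched grids across files must be rejected
  g3 <- grid_geometry(c(10, 12, 4), c(1, 1, 1))
  p3 <- file.path(d, "other.nii")
  write_volume(vols[[1]], g3, p3)
  expect_error(load_series(c(paths[1], p3), c(318, 719)), "affine|matrix")
})

test_that("ROI sets validate labels and round-trip through disk", {
  g <- grid_geometry(c(12, 12, 4), c(1, 1, 2))
  lab <- array(0L, g$dim)
  lab[3:5, 3:5, 2] <- 1L
  lab[8:10, 8:10, 3] <- 999L
  map <- data.frame(label = 1L, mother_id = "WT1", placenta_id = 1L)
  rs <- roi_set(lab, g, map)
  d <- withr::local_tempdir()
  paths <- write_roi_set(rs, d)
  rs2 <- read_roi_set(paths[["labels"]], paths[["map"]])
  expect_identical(rs2$labels, rs$labels)
  expect_equal(rs2$background_label, 999L)
  lab_bad <- lab
  lab_bad[1, 1, 1] <- 7L
  expect_error(roi_set(lab_bad, g, map), "without map")
  lab_res <- lab
  lab_res[2, 2, 1] <- -1L
  expect_error(roi_set(lab_res, g, map), "reserved")
})

test_that("design table enforces uniqueness and genotype constancy", {
  df <- data.frame(mother_id = c("m1", "m1", "m2"),
                   genotype = c("WT", "WT", "KO"),
                   oxygen_percent = c(30, 60, 30))
  expect_s3_class(design_table(df), "design_table")
  df_bad <- df
  df_bad$oxygen_percent[2] <- 30
  expect_error(design_table(df_bad), "duplicate")
  df_geno <- df
  df_geno$genotype[2] <- "KO"
  expect_error(design_table(df_geno), "constant within mother")
  df_lvl <- df
  df_lvl$genotype[3] <- "het"
  expect_error(design_table(df_lvl), "WT or KO")
})

test_that("ROI centroids keep their world position across grid transport", {
  cfg <- quick_config(seed = 11)
  study <- generate_study(cfg)
  g_anat <- cfg$geometry$anat
  g_f19 <- cfg$geometry$f19
  rois <- study$rois[[1]]
  f19_vox_mm <- sqrt(colSums(g_f19$affine[1:3, 1:3]^2))
  for (pl in rois$label_map$label) {
    m_anat <- which(rois$labels == pl, arr.ind = TRUE) - 1
    c_anat <- colMeans(voxel_to_world(g_anat, m_anat))
    lab_f <- resample_labels(rois$labels, g_anat, g_f19)
    m_f <- which(lab_f == pl, arr.ind = TRUE) - 1
    c_f <- colMeans(voxel_to_world(g_f19, m_f))
    expect_true(all(abs(c_anat - c_f) <= f19_vox_mm / 2))
  }
})
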