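test_that("phantom config validates its physical constraints", {
  expect_s3_class(phantom_config(), "phantom_config")
  expect_error(phantom_config(oxygen_levels = c(30, 30, 100)), "distinct")
  expect_error(phantom_config(tr_list_ms = c(-1, 719)), "> 0")
  expect_error(phantom_config(sigma_g = 0), "sigma_g")
  # a group mean at or below -intercept would imply nonpositive T1
  expect_error(phantom_config(baseline_po2 = c(`30` = -250, `60` = 150,
                                               `100` = 250)),
               "nonpositive T1")
  expect_error(phantom_config(baseline_po2 = c(`30` = 100, `60` = 150,
                                               `100` = 250),
                              ko_offsets = c(`30` = -310, `60` = 0, `100` = 0)),
               "nonpositive T1")
})

test_that("ground truth links T1 and PO2 exactly through the calibration", {
  cfg <- quick_config(seed = 2)
  set.seed(cfg$seed)
  truth <- phantom_truth(cfg)
  expect_equal(t1_to_po2(truth$true_t1_s, cfg$calib), truth$true_po2_mmhg,
               tolerance = 1e-9)
  expect_true(all(truth$true_t1_s > 0))
  # one row per placenta x condition; study totals honoured
  expect_equal(nrow(truth),
               sum(cfg$n_placentas) * length(cfg$oxygen_levels))
  per_geno <- table(unique(truth[, c("mother_id", "placenta_id", "genotype")])$genotype)
  expect_equal(as.integer(per_geno[c("WT", "KO")]),
               unname(cfg$n_placentas[c("WT", "KO")]))
})

test_that("the default design matches the in vivo study layout", {
  cfg <- phantom_config()
  set.seed(1)
  truth <- phantom_truth(cfg)
  mothers <- unique(truth[, c("mother_id", "genotype")])
  expect_equal(sum(mothers$genotype == "WT"), 3L)
  expect_equal(sum(mothers$genotype == "KO"), 4L)
  placentas <- unique(truth[, c("mother_id", "placenta_id", "genotype")])
  expect_equal(sum(placentas$genotype == "WT"), 19L)
  expect_equal(sum(placentas$genotype == "KO"), 17L)
  expect_equal(sort(unique(truth$oxygen_percent)), c(30, 60, 100))
  expect_equal(cfg$tr_list_ms, c(318, 719, 1398, 5000))
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_study(quick_config(seed = 31))
  b <- generate_study(quick_config(seed = 31))
  expect_identical(a$truth, b$truth)
  expect_identical(a$sessions[[1]]$volumes, b$sessions[[1]]$volumes)
  expect_identical(a$rois[[1]]$labels, b$rois[[1]]$labels)
  c2 <- generate_study(quick_config(seed = 32))
  expect_false(identical(a$sessions[[1]]$volumes, c2$sessions[[1]]$volumes))
  # byte-identical on disk as well
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_phantom_study(a, d1); write_phantom_study(b, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  sums1 <- tools::md5sum(file.path(d1, f1))
  sums2 <- tools::md5sum(file.path(d2, f1))
  expect_true(all(unname(sums1) == unname(sums2)))
})

test_that("zero-noise limit reproduces the pure saturation-recovery signal", {
  cfg <- quick_config(seed = 4,
                      n_mothers = c(WT = 2L, KO = 2L),
                      n_placentas = c(WT = 2L, KO = 2L),
                      sigma_g = 1e-7, s0_range = c(10, 10), s0_scale = 1,
                      baseline_po2 = c(`30` = 35.265, `60` = 150, `100` = 250),
                      mother_sd = 0, placenta_sd = 0, jitter_sd = 0)
  study <- generate_study(cfg)
  sess <- study$sessions[["WT1_o030"]]
  tru <- study$truth[study$truth$mother_id == "WT1" &
                       study$truth$placenta_id == 1 &
                       study$truth$oxygen_percent == 30, ]
  expect_equal(tru$true_t1_s, po2_to_t1(35.265), tolerance = 1e-12)
  lab_f <- resample_labels(study$rois[["WT1"]]$labels,
                           cfg$geometry$anat, cfg$geometry$f19)
  mask <- lab_f == 1L
  for (i in seq_along(sess$tr_ms)) {
    expected <- 10 * (1 - exp(-(sess$tr_ms[i] / 1000) / tru$true_t1_s))
    expect_equal(mean(sess$volumes[[i]][mask]), expected,
                 tolerance = 1e-5)
  }
  # the noise box carries no signal: pure Rician floor (label-0 voxels can
  # straddle placenta edges after nearest-neighbour transport, so test the
  # dedicated background ROI)
  bg <- lab_f == cfg$background_label
  expect_lt(mean(sess$volumes[[4]][bg]), 3 * cfg$sigma_g)
})

test_that("background voxels sit at the Rician noise floor", {
  cfg <- quick_config(seed = 6, sigma_g = 30)
  study <- generate_study(cfg)
  lab_f <- resample_labels(study$rois[[1]]$labels,
                           cfg$geometry$anat, cfg$geometry$f19)
  bg <- lab_f == 0L
  vals <- study$sessions[[1]]$volumes[[1]][bg]
  expect_equal(mean(vals), 30 * sqrt(pi / 2), tolerance = 0.02 * 30 * sqrt(pi / 2))
})

test_that("configured KO deficit appears in the truth-table group means", {
  cfg <- phantom_config(baseline_po2 = c(`30` = 100, `60` = 150, `100` = 250),
                        ko_offsets = c(`30` = -60, `60` = 0, `100` = 0),
                        seed = 13)
  set.seed(cfg$seed)
  truth <- phantom_truth(cfg)
  t30 <- truth[truth$oxygen_percent == 30, ]
  gap <- mean(t30$true_po2_mmhg[t30$genotype == "KO"]) -
    mean(t30$true_po2_mmhg[t30$genotype == "WT"])
  # sampling error of the group-mean difference given the mother/placenta/
  # jitter variance components: SD ~ 14 mmHg; allow 3 SD
  expect_lt(abs(gap - (-60)), 42)
})

test_that("compartment mixing matches brute-force summation and its limits", {
  trs <- c(318, 719, 1398, 5000)
  # degenerate mixture = single compartment
  one <- compartment_model(fractions = c(1, 0, 0), t1_s = c(2, 1, 1))
  expect_equal(mix_compartments(one, trs, s0_total = 10),
               10 * (1 - exp(-(trs / 1000) / 2)), tolerance = 1e-12)
  # equal rates collapse regardless of fractions
  eq <- compartment_model(fractions = c(0.644, 0.237, 0.119),
                          t1_s = c(1.8, 1.8, 1.8))
  expect_equal(mix_compartments(eq, trs),
               1 - exp(-(trs / 1000) / 1.8), tolerance = 1e-12)
  # general case against an independent term-by-term sum
  fr <- c(0.644, 0.237, 0.119); t1s <- c(1.5, 0.8, 2.5); w <- c(1, 0.9, 1.2)
  m <- compartment_model(fractions = fr, t1_s = t1s, weights = w)
  brute <- vapply(trs, function(tr) {
    acc <- 0
    for (c_i in 1:3)
      acc <- acc + w[c_i] * fr[c_i] * (1 - exp(-(tr / 1000) / t1s[c_i]))
    acc
  }, 0)
  expect_equal(mix_compartments(m, trs), brute, tolerance = 1e-12)
  expect_error(compartment_model(fractions = c(0.7, 0.2, 0.2)), "sum to 1")
  expect_error(compartment_model(fractions = c(-0.1, 0.9, 0.2)), "nonnegative")
})

test_that("record-level simulation preserves design and calibration links", {
  cfg <- quick_config(seed = 17)
  set.seed(17)
  rec <- simulate_records(cfg, measurement_sd = 25)
  expect_equal(nrow(rec), sum(cfg$n_placentas) * 3L)
  expect_equal(t1_to_po2(rec$t1_s, cfg$calib), rec$po2_mmhg, tolerance = 1e-9)
  expect_false(any(is.na(rec$po2_mmhg)))
})
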