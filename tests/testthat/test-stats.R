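test_that("descriptive summaries handle degenerate groups and hand values", {
  rec <- data.frame(mother_id = c("m1", "m1", "m2"),
                    genotype = c("WT", "WT", "KO"),
                    placenta_id = c(1, 2, 1),
                    oxygen_percent = 30,
                    po2_mmhg = c(0, 10, 55))
  ds <- descriptive_summary(rec)
  wt <- ds[ds$genotype == "WT", ]
  expect_equal(wt$mean, 5)
  expect_equal(wt$sd, 7.071, tolerance = 1e-3)
  ko <- ds[ds$genotype == "KO", ]
  expect_equal(ko$n, 1L)
  expect_true(is.na(ko$sd) && is.na(ko$ci_lo))
})

test_that("group means in simulated studies track the configured baselines", {
  cfg <- phantom_config(seed = 3)
  set.seed(cfg$seed)
  rec <- simulate_records(cfg, measurement_sd = 25)
  ds <- descriptive_summary(rec)
  for (oxy in c(30, 60, 100)) {
    wt <- ds[ds$genotype == "WT" & ds$oxygen_percent == oxy, ]
    mu <- cfg$baseline_po2[[as.character(oxy)]]
    # SE of a group mean dominated by the mother intercepts (~ 10-12 mmHg)
    expect_lt(abs(wt$mean - mu), 40)
  }
})

test_that("full model reports genotype, oxygen and interaction with nested df", {
  set.seed(101)
  rec <- make_records(mean_fun = function(g, oxy) {
    100 + 0.8 * oxy + ifelse(g == "KO" & oxy == 30, -64, 0)
  }, noise_sd = 15)
  res <- fit_full_model(rec)
  expect_s3_class(res, "mixed_model_result")
  expect_equal(res$tests$source, c("Genotype", "Oxygen", "Genotype x Oxygen"))
  expect_true(all(res$tests$num_df == c(1, 2, 2)))
  expect_true(all(res$tests$den_df > 0))
  expect_true(all(res$tests$F >= 0))
  # strong interaction injected at 30% only
  expect_lt(res$tests$p[3], 0.01)
  # estimated means come per genotype within oxygen level, CIs bracket them
  em <- res$emmeans
  expect_equal(nrow(em), 6L)
  expect_true(all(em$lower.CL <= em$estimate & em$estimate <= em$upper.CL))
  expect_output(print(res), "Genotype x Oxygen")
})

test_that("constant outcomes yield a degenerate-fit diagnostic", {
  rec <- make_records(mean_fun = function(g, oxy) 42, noise_sd = 0)
  res <- fit_full_model(rec)
  expect_true(res$degenerate)
  expect_match(res$message, "constant")
  expect_output(print(res), "degenerate")
})

test_that("full model demands the design it was built for", {
  set.seed(5)
  rec <- make_records(noise_sd = 5)
  expect_error(fit_full_model(rec[rec$oxygen_percent == 30, ]),
               ">= 2 oxygen levels")
  expect_error(fit_full_model(rec[rec$genotype == "WT" |
                                    rec$mother_id == "KO1", ]),
               "mothers per genotype")
  expect_error(fit_full_model(rec, outcome = "nope"), "not found")
})

test_that("post-hoc model recovers exact group means in the zero-variance limit", {
  rec <- make_records(oxygen = 30, mean_fun = function(g, oxy)
    ifelse(g == "KO", 38, 102), noise_sd = 0)
  # the perfect fit is the point here; lm warns about it
  res <- suppressWarnings(fit_posthoc_model(rec))
  em <- res$emmeans
  expect_equal(em$estimate[em$genotype == "KO"], 38, tolerance = 1e-6)
  expect_equal(em$estimate[em$genotype == "WT"], 102, tolerance = 1e-6)
  expect_error(fit_posthoc_model(make_records(noise_sd = 1)), "one oxygen")
  wt_only <- make_records(oxygen = 30, noise_sd = 1)
  expect_error(fit_posthoc_model(wt_only[wt_only$genotype == "WT", ]),
               "both genotypes")
})

test_that("with one placenta per mother the genotype test is the pooled t-test", {
  set.seed(202)
  rec <- make_records(n_mothers = c(WT = 8L, KO = 9L),
                      placentas_per_mother = 1L, oxygen = 30,
                      mean_fun = function(g, oxy) ifelse(g == "KO", 80, 100),
                      noise_sd = 20)
  res <- fit_posthoc_model(rec)
  expect_equal(res$method, "lm")
  tt <- t.test(po2_mmhg ~ genotype, data = rec, var.equal = TRUE)
  expect_lt(abs(res$tests$p - tt$p.value), 1e-3)
  expect_lt(abs(res$tests$den_df - unname(tt$parameter)), 1)
  expect_equal(res$tests$F, unname(tt$statistic)^2, tolerance = 1e-9)
})

test_that("post-hoc model recovers an injected genotype gap on average", {
  cfg <- phantom_config(ko_offsets = c(`30` = -64, `60` = 0, `100` = 0))
  set.seed(303)
  gaps <- replicate(200, {
    rec <- simulate_records(cfg, measurement_sd = 25)
    r30 <- rec[rec$oxygen_percent == 30, ]
    fit <- suppressWarnings(fit_posthoc_model(r30, emmeans = FALSE))
    if (fit$method == "lmer") unname(lme4::fixef(fit$model)[["genotypeKO"]])
    else unname(coef(fit$model)[["genotypeKO"]])
  })
  expect_lt(abs(mean(gaps) - (-64)), 10)
})

test_that("run_inference models outcomes independently and writes tables", {
  set.seed(404)
  rec <- make_records(mean_fun = function(g, oxy) {
    100 + oxy + ifelse(g == "KO" & oxy == 30, -80, 0)
  }, noise_sd = 12)
  rec$t1_s <- po2_to_t1(pmax(rec$po2_mmhg, -150))
  inf <- run_inference(rec, outcomes = c("po2_mmhg", "t1_s"), t_tests = TRUE)
  expect_named(inf$full, c("po2_mmhg", "t1_s"))
  expect_equal(nrow(inf$table_full), 6L)
  # the strong interaction triggers per-oxygen follow-up with t-test column
  expect_true("po2_mmhg" %in% names(inf$posthoc))
  expect_true("t_test_p" %in% names(inf$table_posthoc))
  d <- withr::local_tempdir()
  paths <- write_inference_tables(inf, d)
  expect_true(all(file.exists(paths)))
  tf <- read.csv(file.path(d, "tests_full_model.csv"))
  expect_equal(names(tf), c("outcome", "source", "num_df", "den_df", "F", "p"))
})

test_that("singular fits are flagged, not hidden", {
  # a pure fixed-effect structure with iid noise drives the mother and
  # placenta variance components to the zero boundary
  set.seed(11)
  rec <- make_records(mean_fun = function(g, oxy) 100 + oxy, noise_sd = 0.01)
  res <- suppressWarnings(fit_full_model(rec))
  expect_false(res$degenerate)
  expect_true(is.logical(res$singular) && !is.na(res$singular))
  expect_true(res$singular)
  expect_output(print(res), "singular")
  # variance components are reported alongside the flag
  expect_true(is.data.frame(res$varcomp))
  expect_setequal(res$varcomp$grp, c("mother_id", "placenta_uid", "Residual"))
})
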