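#' Nested mixed-effects model over genotype and oxygen challenge
#'
#' Fits, for one outcome, the repeated-measures linear mixed model
#' `outcome ~ genotype * oxygen + (1 | mother) + (1 | placenta-in-mother)`
#' by REML. Mothers are the independent statistical unit; placentas are
#' nested within mothers and each placenta is measured under every oxygen
#' condition, so both grouping levels get random intercepts. Fixed-effect
#' F tests use Satterthwaite denominator degrees of freedom (type III), and
#' estimated marginal means with 95% CIs are computed per genotype within
#' each oxygen level. Singular fits (a variance component estimated at
#' zero) are reported through the `singular` flag, never hidden; an outcome
#' with zero variance short-circuits to a degenerate-fit diagnostic.
#'
#' @param records Placenta-record data frame with columns `mother_id`,
#'   `genotype` (WT/KO), `placenta_id`, `oxygen_percent` and the outcome.
#' @param outcome Name of the outcome column (e.g. `"po2_mmhg"`, `"t1_s"`).
#' @param emmeans Compute estimated marginal means (switch off in Monte
#'   Carlo loops where only the F tests are needed).
#' @return Object of class `"mixed_model_result"`: `tests` (source,
#'   num_df, den_df, F, p), `emmeans` (genotype x oxygen estimates with 95%
#'   CI), `varcomp`, `singular`, `degenerate`, `model`.
#' @export
fit_full_model <- function(records, outcome = "po2_mmhg", emmeans = TRUE) {
  d <- prepare_records(records, outcome)
  if (length(unique(d$oxygen)) < 2L)
    stop("fit_full_model: need >= 2 oxygen levels")
  check_mothers_per_genotype(d, 2L)
  if (var(d$y) == 0)
    return(degenerate_result(outcome, "outcome constant across all rows"))
  fml <- y ~ genotype * oxygen + (1 | mother_id) + (1 | placenta_uid)
  fit <- suppressMessages(lmerTest::lmer(fml, data = d, REML = TRUE))
  a <- suppressMessages(anova(fit, type = 3, ddf = "Satterthwaite"))
  tests <- data.frame(outcome = outcome,
                      source = c("Genotype", "Oxygen", "Genotype x Oxygen"),
                      num_df = a[, "NumDF"], den_df = a[, "DenDF"],
                      F = a[, "F value"], p = a[, "Pr(>F)"],
                      row.names = NULL)
  em <- if (emmeans) emmeans_safe(fit, ~ genotype | oxygen) else NULL
  mixed_model_result(outcome, tests, em, fit, method = "lmer")
}

#' Post-hoc genotype model at one oxygen level
#'
#' For a single oxygen condition: `outcome ~ genotype + (1 | mother)`,
#' genotype F test with Satterthwaite df and estimated marginal means with
#' 95% CI per genotype. When the random intercept is unidentifiable — one
#' placenta per mother, or a degenerate (zero-residual) fit — the model
#' falls back to the fixed-effects `lm`, whose genotype F test is exactly
#' the pooled two-sample t-test; the `method` field records which route ran.
#'
#' @param records Placenta records restricted to one oxygen level.
#' @param outcome Outcome column name.
#' @inheritParams fit_full_model
#' @return A `"mixed_model_result"` (see [fit_full_model()]).
#' @export
fit_posthoc_model <- function(records, outcome = "po2_mmhg", emmeans = TRUE) {
  d <- prepare_records(records, outcome)
  if (length(unique(d$oxygen)) != 1L)
    stop("fit_posthoc_model: records must contain exactly one oxygen level")
  if (length(unique(d$genotype)) < 2L)
    stop("fit_posthoc_model: both genotypes must be present")
  one_per_mother <- all(tapply(d$placenta_uid, d$mother_id,
                               function(p) length(unique(p))) == 1L)
  # zero residual variance after the genotype effect makes the mixed model
  # unidentifiable; the fixed-effects route recovers the exact means
  resid_ss <- sum(residuals(lm(y ~ genotype, data = d))^2)
  fit <- NULL
  method <- "lmer"
  if (!one_per_mother && var(d$y) > 0 && resid_ss > 1e-8 * var(d$y) * nrow(d)) {
    fit <- tryCatch(
      suppressMessages(lmerTest::lmer(y ~ genotype + (1 | mother_id),
                                      data = d, REML = TRUE)),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    method <- "lm"
    fit <- lm(y ~ genotype, data = d)
    a <- anova(fit)
    tests <- data.frame(outcome = outcome, source = "Genotype",
                        num_df = a["genotype", "Df"],
                        den_df = a["Residuals", "Df"],
                        F = a["genotype", "F value"],
                        p = a["genotype", "Pr(>F)"], row.names = NULL)
  } else {
    a <- suppressMessages(anova(fit, type = 3, ddf = "Satterthwaite"))
    tests <- data.frame(outcome = outcome, source = "Genotype",
                        num_df = a[, "NumDF"], den_df = a[, "DenDF"],
                        F = a[, "F value"], p = a[, "Pr(>F)"],
                        row.names = NULL)
  }
  em <- if (emmeans) emmeans_safe(fit, ~ genotype) else NULL
  res <- mixed_model_result(outcome, tests, em, fit, method = method)
  res$oxygen_percent <- d$oxygen[1L]
  res
}

prepare_records <- function(records, outcome) {
  stopifnot(is.data.frame(records),
            all(c("mother_id", "genotype", "placenta_id", "oxygen_percent")
                %in% names(records)))
  if (!outcome %in% names(records))
    stop("outcome column not found: ", outcome)
  d <- data.frame(
    mother_id = factor(records$mother_id),
    genotype = factor(records$genotype, levels = c("WT", "KO")),
    placenta_uid = factor(paste(records$mother_id, records$placenta_id, sep = ":")),
    oxygen = factor(records$oxygen_percent,
                    levels = sort(unique(records$oxygen_percent))),
    y = as.numeric(records[[outcome]]))
  d <- d[is.finite(d$y), , drop = FALSE]
  if (nrow(d) == 0L) stop("no finite values for outcome ", outcome)
  droplevels(d)
}

check_mothers_per_genotype <- function(d, min_m) {
  mpg <- tapply(d$mother_id, d$genotype, function(m) length(unique(m)))
  if (any(is.na(mpg)) || any(mpg < min_m))
    stop("need >= ", min_m, " mothers per genotype")
}

emmeans_safe <- function(fit, spec) {
  em <- tryCatch({
    if (inherits(fit, "merMod"))
      emmeans::emmeans(fit, spec, lmer.df = "satterthwaite")
    else
      emmeans::emmeans(fit, spec)
  }, error = function(e) NULL)
  if (is.null(em)) return(NULL)
  s <- as.data.frame(summary(em, level = 0.95))
  names(s)[names(s) == "emmean"] <- "estimate"
  s
}

mixed_model_result <- function(outcome, tests, em, fit, method) {
  singular <- inherits(fit, "merMod") && lme4::isSingular(fit, tol = 1e-4)
  vc <- if (inherits(fit, "merMod"))
    as.data.frame(lme4::VarCorr(fit)) else NULL
  structure(list(outcome = outcome, tests = tests, emmeans = em,
                 varcomp = vc, singular = singular, degenerate = FALSE,
                 method = method, model = fit),
            class = "mixed_model_result")
}

degenerate_result <- function(outcome, msg) {
  structure(list(outcome = outcome,
                 tests = data.frame(outcome = character(0), source = character(0),
                                    num_df = numeric(0), den_df = numeric(0),
                                    F = numeric(0), p = numeric(0)),
                 emmeans = NULL, varcomp = NULL, singular = NA,
                 degenerate = TRUE, message = msg, method = "none",
                 model = NULL),
            class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat("Mixed-model tests of fixed effects --", x$outcome, "\n")
  if (x$degenerate) {
    cat("  degenerate fit:", x$message, "\n")
    return(invisible(x))
  }
  t <- x$tests
  t$F <- round(t$F, 3); t$p <- signif(t$p, 3); t$den_df <- round(t$den_df, 3)
  print(t[, c("source", "num_df", "den_df", "F", "p")], row.names = FALSE)
  if (isTRUE(x$singular))
    cat("  note: singular fit (a variance component estimated at zero)\n")
  if (x$method == "lm")
    cat("  note: random intercept unidentifiable; fixed-effects fallback\n")
  if (!is.null(x$emmeans)) {
    cat("  estimated marginal means (95% CI):\n")
    print(x$emmeans, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Descriptive group summaries
#'
#' Plain per-genotype x oxygen mean, SD and 95% confidence interval of the
#' mean (t-based), for plotting parity with the descriptive group figures —
#' deliberately not model-based. A group with a single value reports SD and
#' CI as missing.
#'
#' @param records Placenta records.
#' @param outcome Outcome column name.
#' @return Data frame: genotype, oxygen_percent, n, mean, sd, ci_lo, ci_hi.
#' @export
descriptive_summary <- function(records, outcome = "po2_mmhg") {
  d <- prepare_records(records, outcome)
  groups <- split(d$y, list(d$genotype, d$oxygen), drop = TRUE, sep = "|")
  rows <- lapply(names(groups), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
    y <- groups[[key]]
    n <- length(y)
    m <- mean(y)
    s <- if (n > 1L) sd(y) else NA_real_
    half <- if (n > 1L) qt(0.975, n - 1L) * s / sqrt(n) else NA_real_
    data.frame(genotype = parts[1L], oxygen_percent = as.numeric(parts[2L]),
               n = n, mean = m, sd = s, ci_lo = m - half, ci_hi = m + half)
  })
  out <- do.call(rbind, rows)
  out[order(out$oxygen_percent, out$genotype), , drop = FALSE]
}

#' Full inference over all outcomes
#'
#' Runs [fit_full_model()] for each outcome; where the genotype-by-oxygen
#' interaction is significant at `alpha`, follows up with
#' [fit_posthoc_model()] at every oxygen level (and, optionally, unpaired
#' two-tailed t-tests as an auxiliary report column). Each outcome is
#' treated independently; no cross-outcome multiplicity correction.
#'
#' @param records Placenta records.
#' @param outcomes Outcome column names to model.
#' @param alpha Significance level for following up the interaction.
#' @param posthoc_all Run post-hoc models for every outcome regardless of
#'   the interaction test (default FALSE).
#' @param t_tests Add unpaired t-test p-values to the post-hoc tables.
#' @return Object of class `"study_inference"`: `full` (named list of
#'   [fit_full_model()] results), `posthoc` (named list of lists by oxygen
#'   level), `table_full`, `table_posthoc` (stacked test data frames).
#' @export
run_inference <- function(records, outcomes = c("po2_mmhg", "t1_s",
                                                "snr_tr1", "snr_tr2",
                                                "snr_tr3", "snr_tr4", "s0"),
                          alpha = 0.05, posthoc_all = FALSE, t_tests = FALSE) {
  outcomes <- intersect(outcomes, names(records))
  full <- list()
  posthoc <- list()
  for (out in outcomes) {
    full[[out]] <- fit_full_model(records, out)
    inter_p <- with(full[[out]]$tests,
                    p[source == "Genotype x Oxygen"])
    if (posthoc_all || (length(inter_p) == 1L && is.finite(inter_p) &&
                        inter_p < alpha)) {
      posthoc[[out]] <- list()
      for (oxy in sort(unique(records$oxygen_percent))) {
        sub <- records[records$oxygen_percent == oxy, , drop = FALSE]
        ph <- tryCatch(fit_posthoc_model(sub, out), error = function(e) NULL)
        if (!is.null(ph) && t_tests) {
          tt <- tryCatch(t.test(as.numeric(sub[[out]]) ~ sub$genotype,
                                var.equal = TRUE),
                         error = function(e) NULL)
          ph$t_test_p <- if (is.null(tt)) NA_real_ else tt$p.value
        }
        posthoc[[out]][[as.character(oxy)]] <- ph
      }
    }
  }
  tf <- do.call(rbind, lapply(full, `[[`, "tests"))
  tp_rows <- unlist(lapply(names(posthoc), function(out)
    lapply(names(posthoc[[out]]), function(oxy) {
      ph <- posthoc[[out]][[oxy]]
      if (is.null(ph)) return(NULL)
      t <- ph$tests
      t$oxygen_percent <- as.numeric(oxy)
      if (!is.null(ph$t_test_p)) t$t_test_p <- ph$t_test_p
      t
    })), recursive = FALSE)
  tp <- if (length(tp_rows)) do.call(rbind, tp_rows) else NULL
  structure(list(full = full, posthoc = posthoc,
                 table_full = tf, table_posthoc = tp),
            class = "study_inference")
}

#' @export
print.study_inference <- function(x, ...) {
  cat("Study inference over", length(x$full), "outcome(s)\n\n")
  for (f in x$full) print(f)
  if (length(x$posthoc)) {
    cat("\nPost-hoc genotype models per oxygen level:\n")
    for (out in names(x$posthoc))
      for (oxy in names(x$posthoc[[out]]))
        if (!is.null(x$posthoc[[out]][[oxy]])) {
          cat(sprintf("\n[%s at %s%% O2]\n", out, oxy))
          print(x$posthoc[[out]][[oxy]])
        }
  }
  invisible(x)
}

#' Write inference tables as CSV
#'
#' Emits the full-model and post-hoc test tables (source, numerator df,
#' denominator df, F, p) plus the estimated-means table.
#'
#' @param inference A `"study_inference"`.
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_inference_tables <- function(inference, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "tests_full_model.csv")
  write.csv(inference$table_full, p1, row.names = FALSE)
  paths <- p1
  if (!is.null(inference$table_posthoc) && nrow(inference$table_posthoc)) {
    p2 <- file.path(dir, "tests_posthoc.csv")
    write.csv(inference$table_posthoc, p2, row.names = FALSE)
    paths <- c(paths, p2)
  }
  ems <- do.call(rbind, lapply(names(inference$full), function(out) {
    em <- inference$full[[out]]$emmeans
    if (is.null(em)) return(NULL)
    em$outcome <- out
    em
  }))
  if (!is.null(ems)) {
    p3 <- file.path(dir, "estimated_means.csv")
    write.csv(ems, p3, row.names = FALSE)
    paths <- c(paths, p3)
  }
  invisible(paths)
}
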