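# Reduced-resolution geometry sharing the real field of view and stack
# centre, so placenta slots and the background box stay valid while unit
# tests run in seconds.
quick_geometry <- function() {
  list(anat = grid_geometry(c(98L, 128L, 10L), c(0.4, 0.4, 2.4)),
       f19  = grid_geometry(c(32L, 42L, 8L), c(39.2 / 32, 51.2 / 42, 2.4)))
}

quick_config <- function(seed = 1L, n_mothers = c(WT = 2L, KO = 2L),
                         n_placentas = c(WT = 4L, KO = 4L), ...) {
  phantom_config(n_mothers = n_mothers, n_placentas = n_placentas,
                 geometry = quick_geometry(), seed = seed, ...)
}

# Nested record table with explicit group means and noise, for stats tests.
make_records <- function(n_mothers = c(WT = 3L, KO = 4L),
                         placentas_per_mother = 5L,
                         oxygen = c(30, 60, 100),
                         mean_fun = function(genotype, oxy) 100,
                         noise_sd = 0) {
  rows <- list()
  for (g in names(n_mothers)) for (im in seq_len(n_mothers[[g]])) {
    mother <- sprintf("%s%d", g, im)
    for (ip in seq_len(placentas_per_mother)) for (oxy in oxygen) {
      rows[[length(rows) + 1L]] <- data.frame(
        mother_id = mother, genotype = g, placenta_id = ip,
        oxygen_percent = oxy,
        po2_mmhg = mean_fun(g, oxy) + rnorm(1, 0, noise_sd))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
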