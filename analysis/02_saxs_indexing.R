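#!/usr/bin/env Rscript
# Index the simulated scattering profiles: detect Bragg peaks, assign the
# mesophase by spacing ratios, fit the lattice parameter with the intercept
# QC, and derive water-channel radii. Writes results/saxs_indexing.csv.

suppressPackageStartupMessages(library(llcchar))
dir.create("results", showWarnings = FALSE)

samples <- read.csv("results/inputs/samples.csv")
rows <- list()
for (i in seq_len(nrow(samples))) {
  prof <- read_saxs_profile(sprintf("results/inputs/saxs_%s.dat",
                                    samples$sample[i]))
  peaks <- detect_peaks(prof)
  ranking <- assign_phase(peaks, ratio_tolerance = 0.02)
  fit <- fit_lattice(ranking$assignments[[ranking$top]])
  geom <- water_channel_radius(ranking$top, fit$a, samples$l_c[i])
  rows[[i]] <- data.frame(
    sample = samples$sample[i],
    true_phase = samples$phase[i],
    assigned_phase = ranking$top,
    n_peaks = nrow(peaks),
    n_indexed = ranking$ranking$n_matched[1],
    a_true = samples$a[i],
    a_fit = fit$a,
    intercept = fit$intercept,
    qc_pass = fit$qc_pass,
    r_squared = fit$r_squared,
    l_c = samples$l_c[i],
    r_w = geom$r_w)
  cat(sprintf(
    "%s: %d peaks -> %s (intercept %.2e, QC %s), a = %.1f A, r_w = %.1f A\n",
    samples$sample[i], nrow(peaks), ranking$top, fit$intercept,
    ifelse(fit$qc_pass, "pass", "FAIL"), fit$a, geom$r_w))
}
out <- do.call(rbind, rows)
write.csv(out, "results/saxs_indexing.csv", row.names = FALSE)

stopifnot(all(out$assigned_phase == out$true_phase),
          all(abs(out$a_fit - out$a_true) / out$a_true < 0.01))
cat("All three compositions indexed to their generating phase;",
    "lattice parameters within 1% of truth.\n")
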