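#!/usr/bin/env Rscript
# Generate the synthetic study inputs: one scattering profile per
# composition (phytantriol/Pn3m, monoolein/Im3m, phytantriol+tocopherol
# acetate/p6mm), matching lattice images for the cryo-TEM-style analysis,
# and the flow regimes used throughout. Ground truth travels with each
# artefact; profiles are written as plain text under results/inputs/.

suppressPackageStartupMessages(library(llcchar))
dir.create("results/inputs", recursive = TRUE, showWarnings = FALSE)
seed <- 20240801

# Study compositions with SAXS-scale lattice parameters (a in Angstrom).
samples <- data.frame(
  sample = c("phytantriol", "monoolein", "phyt_tocopherol"),
  phase = c("Pn3m", "Im3m", "HexagonalP6mm"),
  a = c(70.7, 148.5, 50),
  l_c = c(13, 18, 13))
write.csv(samples, "results/inputs/samples.csv", row.names = FALSE)

for (i in seq_len(nrow(samples))) {
  prof <- gen_saxs_profile(samples$phase[i], a = samples$a[i],
                           noise_sd = 0.05, seed = seed + i)
  write_saxs_profile(prof,
                     sprintf("results/inputs/saxs_%s.dat",
                             samples$sample[i]))
}

# Flow regimes: the production condition used for imaging and the extremes
# of the size-control series.
fr <- rbind(
  data.frame(label = "imaging", Q_buffer = 400, Q_ethanol = 20),
  data.frame(label = "frr_min", Q_buffer = 400, Q_ethanol = 80),
  data.frame(label = "frr_max", Q_buffer = 300, Q_ethanol = 5))
fr$FRR <- NA
fr$TFR <- NA
for (i in seq_len(nrow(fr))) {
  r <- flow_regime(fr$Q_buffer[i], fr$Q_ethanol[i])
  fr$FRR[i] <- r$FRR
  fr$TFR[i] <- r$TFR
}
write.csv(fr, "results/inputs/flow_regimes.csv", row.names = FALSE)

cat("Simulated inputs for", nrow(samples), "compositions.\n")
cat("Imaging condition: FRR", fr$FRR[1], "at TFR", fr$TFR[1], "uL/min;",
    "size-control series spans FRR", fr$FRR[2], "to", fr$FRR[3], "\n")
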