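#!/usr/bin/env Rscript
# GUV payload-delivery study on a synthetic 64-vesicle cohort: two particle
# size classes with opposite lumen/background contrast, the inner-minus-
# outer intensity statistic per vesicle, and the pooled histogram with
# per-class delivered fractions. Writes results/fusion_deltaI.csv and
# results/fusion_histogram.csv.

suppressPackageStartupMessages(library(llcchar))
dir.create("results", showWarnings = FALSE)
seed <- 20240804

set.seed(seed)
measurements <- list()
groups <- character(0)
rows <- list()
for (i in 1:32) {
  # small particles deliver: lumen brighter than background
  g <- gen_guv_image(radius = 15, lumen_mean = rnorm(1, 180, 15),
                     background_mean = 100, membrane_amplitude = 40,
                     noise_sd = 10, seed = seed + i)
  m <- delta_i(g)
  measurements[[length(measurements) + 1]] <- m
  groups <- c(groups, "130nm")
  rows[[length(rows) + 1]] <- data.frame(
    group = "130nm", guv = i, inner = m$inner_mean, outer = m$outer_mean,
    delta_i = m$delta_i, delivered = m$delivered)
}
for (i in 1:32) {
  # large particles do not: lumen stays dimmer than the dye-rich exterior
  g <- gen_guv_image(radius = 15, lumen_mean = rnorm(1, 70, 10),
                     background_mean = 100, membrane_amplitude = 40,
                     noise_sd = 10, seed = seed + 500 + i)
  m <- delta_i(g)
  measurements[[length(measurements) + 1]] <- m
  groups <- c(groups, "310nm")
  rows[[length(rows) + 1]] <- data.frame(
    group = "310nm", guv = i, inner = m$inner_mean, outer = m$outer_mean,
    delta_i = m$delta_i, delivered = m$delivered)
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/fusion_deltaI.csv", row.names = FALSE)

h <- aggregate_histogram(measurements, group = groups)
hist_tab <- data.frame(bin_left = head(h$breaks, -1),
                       bin_right = tail(h$breaks, -1),
                       count_130nm = h$counts_by_group["130nm", ],
                       count_310nm = h$counts_by_group["310nm", ])
write.csv(hist_tab, "results/fusion_histogram.csv", row.names = FALSE)

cat(sprintf("Cohort of %d GUVs:\n", h$n))
cat(sprintf("  130 nm class: delivered fraction %.2f (mean dI %+.0f AU)\n",
            h$delivered_fraction[["130nm"]],
            mean(tab$delta_i[tab$group == "130nm"])))
cat(sprintf("  310 nm class: delivered fraction %.2f (mean dI %+.0f AU)\n",
            h$delivered_fraction[["310nm"]],
            mean(tab$delta_i[tab$group == "310nm"])))
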