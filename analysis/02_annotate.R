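#!/usr/bin/env Rscript
# Step 2 — annotate synthetic unipolar electrograms and verify recovery.
#
# Generates electrograms (1 kHz, SNR 20 dB, mixed T-wave polarity) from a
# known activation/repolarization field, annotates LAT by the steepest
# negative slope and LRT by the Wyatt maximum-upslope rule, screens isolated
# outliers, and reports how closely the annotations recover the truth.

suppressPackageStartupMessages(library(rvimap))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L
dir.create("results", showWarnings = FALSE)

mesh <- make_sheet_mesh(20, 10, 5)
lat <- planar_wave_lat(mesh, c(1, 0.2, 0), 0.8)
truth <- list(mesh = mesh, lat = lat,
              lrt = lat + 240 + 0.4 * mesh$vertices[, 2])
set <- synth_egm_set(truth, snr_db = 20, inverted = 0.5, seed = seed)

map <- annotate_map(set$egms, set$windows, mesh, smooth_ms = 5)
map <- flag_outliers(map, "lat", k = 5)$map
map <- flag_outliers(map, "lrt", k = 5)$map

err_lat <- abs(map$lat - truth$lat)[map$valid]
err_lrt <- abs(map$lrt - truth$lrt)[map$valid]
tab <- data.frame(
  quantity = c("LAT", "LRT"),
  n_valid = sum(map$valid),
  median_abs_err_ms = c(median(err_lat), median(err_lrt)),
  p95_abs_err_ms = c(quantile(err_lat, 0.95), quantile(err_lrt, 0.95)))
print(tab, row.names = FALSE)
utils::write.csv(tab, "results/annotation_recovery.csv", row.names = FALSE)
write_map(map, "results/annotated_map.json")

cat(sprintf(paste0(
  "\nAnnotated %d/%d sites (%d inverted T waves); median recovery error ",
  "%.2f ms (LAT) / %.2f ms (LRT) at 1 kHz sampling.\n"),
  sum(map$valid), length(set$egms), sum(set$inverted),
  median(err_lat), median(err_lrt)))
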