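#!/usr/bin/env Rscript
# Step 1 — simulate paired electroanatomical maps.
#
# Builds matched healthy-like (wt_s4) and severe-substrate (ts1_s4) S4 maps
# for a handful of seeds and writes them, with their ground truth, under
# results/maps/. Later steps read these files, so the whole workflow is
# reproducible from the seeds alone.

suppressPackageStartupMessages(library(rvimap))

args <- commandArgs(trailingOnly = TRUE)
seed0 <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L
seeds <- seed0 + 0:2
outdir <- "results/maps"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

for (preset in c("wt_s4", "ts1_s4")) {
  for (s in seeds) {
    sc <- build_scenario(scenario_config(preset, seed = s))
    stem <- file.path(outdir, sprintf("%s_seed%02d", preset, s))
    write_map(sc$map, paste0(stem, ".json"))
    jsonlite::write_json(
      list(speed_m_s = sc$truth$speed, lat_ms = sc$truth$lat,
           apd_ms = sc$truth$apd, lrt_ms = sc$truth$lrt,
           expected_block_area_cm2 = sc$truth$expected_block_area_cm2),
      paste0(stem, ".truth.json"), digits = I(17))
    cat(sprintf("%s: %d vertices, LAT range %.1f ms -> %s.json\n",
                preset, n_vertices(sc$map),
                summarize_map(sc$map)$lat_range_ms, stem))
  }
}
cat("\nSimulated", 2 * length(seeds), "maps; the severe preset halves",
    "conduction speed and adds 10-mm functional-block patches.\n")
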