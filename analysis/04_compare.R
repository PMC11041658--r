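#!/usr/bin/env Rscript
# Step 4 — before/after comparison of the severe substrate.
#
# Re-analyzes the severe (ts1_s4) baseline and a 'relieved' variant of the
# same scenario — conduction speed partially restored, slow patches and APD
# patches removed, as a favorable compound would act — and reports absolute
# and percent changes of the headline metrics with the improvement verdict
# (an algebraic increase of global RVI = less vulnerable substrate).

suppressPackageStartupMessages(library(rvimap))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L
dir.create("results", showWarnings = FALSE)

pre <- analyze_map(build_scenario(scenario_config("ts1_s4", seed = seed))$map)
post_cfg <- scenario_config("ts1_s4", seed = seed, base_speed = 0.7,
                            patches = list(), apd_patches = list(),
                            apd_gradient = c(0.5, 0.25, 0))
post <- analyze_map(build_scenario(post_cfg)$map)

cmp <- compare_maps(pre, post)
write_report(cmp, "results/comparison.json")

cat(sprintf("global RVI: %.1f -> %.1f ms (%+.1f%%), verdict: %s\n",
            cmp$global_rvi_ms$pre, cmp$global_rvi_ms$post,
            cmp$global_rvi_ms$percent, cmp$verdict))
cat(sprintf("LAT range:  %.1f -> %.1f ms (%+.1f%%)\n",
            cmp$lat_range_ms$pre, cmp$lat_range_ms$post,
            cmp$lat_range_ms$percent))
cat(sprintf("LRT range:  %.1f -> %.1f ms (%+.1f%%)\n",
            cmp$lrt_range_ms$pre, cmp$lrt_range_ms$post,
            cmp$lrt_range_ms$percent))
cat(sprintf("block area: %.2f -> %.2f cm^2\n",
            cmp$block_area_cm2$pre, cmp$block_area_cm2$post))
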