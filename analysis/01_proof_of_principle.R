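#!/usr/bin/env Rscript

# Proof-of-principle study: render the artificial object across all scenario
# families, score outline detectability with LEIA / HEI statistics and the
# mean luminance comparison, and tabulate the per-family optima.
#
# Writes results/exp1_results.csv, results/exp1_argmin.csv,
# results/exp1_config.csv. Fully deterministic (~10 min on one CPU).

library(fringecam)

dir.create("results", showWarnings = FALSE)

message("Running the six scenario families (77 images)...")
res <- run_experiment1(verbose = TRUE)

write.csv(res$results, "results/exp1_results.csv", row.names = FALSE)
write.csv(res$argmin, "results/exp1_argmin.csv", row.names = FALSE)
write.csv(grid_as_config(unlist(lapply(c("basic", "thickness", "transparency",
                                         "length", "background", "acuity"),
                                       scenario_grid), recursive = FALSE)),
          "results/exp1_config.csv", row.names = FALSE)

message(sprintf("HEI fraction q from the zero-appendage reference: %.3f%%",
                100 * res$q))
message("Appendage count with the lowest mean HEI edge intensity, per family:")
print(res$argmin)

# headline numbers: the basic family curve
basic <- subset(res$results, family == "basic")
message("Basic-family mean HEI by appendage count:")
print(basic[, c("count_stage", "count", "mean_hei", "coverage",
                "mean_appendage", "transition_score")], digits = 4)
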