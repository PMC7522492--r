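#!/usr/bin/env Rscript
# Generate the synthetic developmental dataset used by the downstream steps:
# a bursty birth-time catalog with L/R pairs, a strategy-driven synapse table
# at the observed conformity (0.75), and the planted ground truth.

suppressPackageStartupMessages(library(firstmover))

out_dir <- "results/synthetic"
spec <- generator_spec(n_cells = 120, seed = 20260925)
g <- generate(spec)
write_generated(g, out_dir)
write_graphml(g$synapses, g$catalog, file.path(out_dir, "network.graphml"))

message(sprintf("generated %d cells (%d classes) and %d synapses",
                nrow(g$catalog), length(unique(g$catalog$family)),
                nrow(g$synapses)))
message(sprintf("stability mix: %s",
                paste(capture.output(print(round(
                  table(g$synapses$stability) / nrow(g$synapses), 3))),
                  collapse = " ")))
message("written to ", out_dir)
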