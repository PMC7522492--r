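#!/usr/bin/env Rscript
# Staged views of the developing network: snapshot membership at the five
# sampling times, stage differencing with family counts, and the burst
# histogram of birth times (bins of 8 minutes).

suppressPackageStartupMessages(library(firstmover))

catalog <- load_catalog("results/synthetic/catalog.csv")

stage_times <- c(265, 280, 290, 300, 400)
sizes <- vapply(stage_times, function(t) length(snapshot(catalog, t)$members),
                integer(1))
stages <- data.frame(time_min = stage_times, n_cells = sizes)
write.csv(stages, "results/stage_sizes.csv", row.names = FALSE)
message("snapshot sizes: ", paste(sprintf("%d min: %d", stage_times, sizes),
                                  collapse = ", "))

new_cells <- snapshot_diff(catalog, 300, 400)
fam <- family_counts(new_cells, catalog = catalog)
write.csv(fam, "results/new_families_300_400.csv", row.names = FALSE)
message(sprintf("%d cells differentiate in (300, 400]; %d families",
                length(new_cells), nrow(fam)))

h <- burst_histogram(catalog$birth_time, bin_width = 8)
write.csv(data.frame(bin_lo = h$breaks[-length(h$breaks)],
                     bin_hi = h$breaks[-1], count = h$counts),
          "results/burst_histogram.csv", row.names = FALSE)
write.csv(h$bursts, "results/bursts.csv", row.names = FALSE)
message(sprintf("%d birth bursts; silent windows between them", nrow(h$bursts)))

# the published stage table, for comparison
fam_ref <- fixtures()$table_families
message(sprintf("reference stage table: %d new neurons across %d families",
                sum(fam_ref$count), nrow(fam_ref)))
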