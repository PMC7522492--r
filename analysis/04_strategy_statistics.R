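#!/usr/bin/env Rscript
# Population statistics, twice over: (a) from the bundled printed strategy
# lists, reproducing the published frequencies, overlaps and NSY-5 split;
# (b) from the synthetic classification, with stability composition, CDFs
# and synaptic densities. Figures are written when ggplot2 is available.

suppressPackageStartupMessages(library(firstmover))

fx <- fixtures()

freq_ref <- frequency_table(fx$strategies)
freq_ref$pct <- round(100 * freq_ref$fraction, 1)
write.csv(freq_ref, "results/frequencies_reference.csv", row.names = FALSE)
message("published-list frequencies (%): ",
        paste(sprintf("%s %.1f", freq_ref$strategy, freq_ref$pct),
              collapse = ", "))

ov <- rbind(
  data.frame(pair = "NP/XNOR", t(overlap(fx$strategies, "NP", "XNOR"))),
  data.frame(pair = "NP/XOR_FIRST", t(overlap(fx$strategies, "NP", "XOR_FIRST"))),
  data.frame(pair = "NP/XOR_SECOND", t(overlap(fx$strategies, "NP", "XOR_SECOND"))))
write.csv(ov, "results/overlaps.csv", row.names = FALSE)
message("overlaps shared/possible: ",
        paste(sprintf("%s %d/%d", ov$pair, ov$shared, ov$possible),
              collapse = ", "))

nsy5 <- subnetwork_strategy_split(fx$strategies, fx$nsy5$pn_classes)
message(sprintf("NSY-5 P-N split: %d cells from %d classes",
                nsy5$count[nsy5$strategy == "PN"], length(fx$nsy5$pn_classes)))

# synthetic-side statistics
catalog <- load_catalog("results/synthetic/catalog.csv")
synapses <- load_synapses("results/synthetic/synapses.csv", catalog = catalog)
assignments <- assign_all(synapses, catalog)
freq_syn <- frequency_table(assignments, synapses = synapses)
write.csv(freq_syn, "results/frequencies_synthetic.csv", row.names = FALSE)

dens <- rbind(cbind(role = "pre", synaptic_density(synapses, catalog, "pre")),
              cbind(role = "post", synaptic_density(synapses, catalog, "post")))
write.csv(dens, "results/synaptic_density.csv", row.names = FALSE)

cdfs <- birth_time_cdf(assignments, catalog)
cdf_tab <- do.call(rbind, lapply(names(cdfs), function(s) {
  x <- sort(stats::knots(cdfs[[s]]))
  data.frame(strategy = s, birth_time = x, cumulative = cdfs[[s]](x))
}))
write.csv(cdf_tab, "results/birth_time_cdfs.csv", row.names = FALSE)
message("synthetic frequency, density and CDF tables written under results/")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  ggplot2::ggsave("results/difference_histogram.png",
                  plot_difference_histogram(synapses, catalog),
                  width = 7, height = 4, dpi = 150)
  ggplot2::ggsave("results/birth_time_cdfs.png",
                  plot_birth_time_cdf(assignments, catalog),
                  width = 7, height = 4, dpi = 150)
  ggplot2::ggsave("results/synaptic_density.png",
                  plot_synaptic_density(synapses, catalog, "pre"),
                  width = 7, height = 4, dpi = 150)
  message("figures written under results/")
}
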