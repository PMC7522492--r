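# Optional ggplot2 figures mirroring the published panels. ggplot2 is a
# suggested dependency; each helper checks for it at call time.

need_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting; install it or skip the figures")
  }
}

#' Plot a per-class birth-time-difference histogram
#'
#' @param synapses A `synapse_table`.
#' @param catalog A `cell_catalog`.
#' @param bin_width Bin width in minutes.
#' @return A ggplot object.
#' @export
plot_difference_histogram <- function(synapses, catalog, bin_width = 10) {
  need_ggplot2()
  h <- difference_histogram(synapses, catalog, bin_width = bin_width)
  ggplot2::ggplot(h, ggplot2::aes(x = (bin_lo + bin_hi) / 2, y = count,
                                  fill = stability)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "birth time difference, pre - post (min)",
                  y = "connections", fill = "stability") +
    ggplot2::theme_minimal()
}

#' Plot per-strategy birth-time CDFs
#'
#' @param assignments Anything [assignment_labels()] accepts.
#' @param catalog A `cell_catalog`.
#' @return A ggplot object.
#' @export
plot_birth_time_cdf <- function(assignments, catalog) {
  need_ggplot2()
  cdfs <- birth_time_cdf(assignments, catalog)
  df <- do.call(rbind, lapply(names(cdfs), function(s) {
    x <- sort(unique(stats::knots(cdfs[[s]])))
    data.frame(strategy = s, birth_time = x, F = cdfs[[s]](x))
  }))
  ggplot2::ggplot(df, ggplot2::aes(birth_time, F, colour = strategy)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "birth time (min post-fertilization)",
                  y = "cumulative fraction of cells") +
    ggplot2::theme_minimal()
}

#' Plot normalized synaptic density by birth time
#'
#' @param synapses A `synapse_table`.
#' @param catalog A `cell_catalog`.
#' @param role `"pre"` or `"post"`.
#' @return A ggplot object.
#' @export
plot_synaptic_density <- function(synapses, catalog, role = c("pre", "post")) {
  need_ggplot2()
  role <- match.arg(role)
  d <- synaptic_density(synapses, catalog, role = role)
  ggplot2::ggplot(d, ggplot2::aes(factor(birth_time), density, fill = stability)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "birth time (min)", y = "connections per cell born",
                  fill = "stability",
                  title = paste0(role, "synaptic connections")) +
    ggplot2::theme_minimal()
}
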