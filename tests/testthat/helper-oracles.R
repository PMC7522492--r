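# Independent brute-force oracles. These deliberately avoid the package's
# delta bookkeeping: strategies are evaluated straight from partner birth-time
# comparisons with explicit loops, so agreement with the classifier is a real
# cross-check.

# Definitional-predicate classifier: for each cell, the mean of
# birth(pre) - birth(post) over incident edges fixes the base label (negative
# N-P, positive P-N, zero -> N-P by the default tie rule, no refinement);
# refinements hold when no incoming partner was born after the cell (XOR
# First), no outgoing partner before it (XOR Second), or both (XNOR).
oracle_classify <- function(edges, birth) {
  cells <- sort(unique(c(edges$pre, edges$post)))
  out <- list()
  for (cl in cells) {
    d <- c()
    in_after <- FALSE   # some presynaptic partner born after the cell
    out_before <- FALSE # some postsynaptic partner born before the cell
    for (i in seq_len(nrow(edges))) {
      p <- edges$pre[i]; q <- edges$post[i]
      if (p == cl) {
        d <- c(d, birth[[p]] - birth[[q]])
        if (birth[[q]] < birth[[cl]]) out_before <- TRUE
      }
      if (q == cl) {
        d <- c(d, birth[[p]] - birth[[q]])
        if (birth[[p]] > birth[[cl]]) in_after <- TRUE
      }
    }
    m <- mean(d)
    if (m > 0) {
      labels <- "PN"
    } else if (m == 0) {
      labels <- "NP"
    } else if (!in_after && !out_before) {
      labels <- c("NP", "XNOR")
    } else if (!in_after) {
      labels <- c("NP", "XOR_FIRST")
    } else if (!out_before) {
      labels <- c("NP", "XOR_SECOND")
    } else {
      labels <- "NP"
    }
    out[[cl]] <- labels
  }
  out
}

# All directed edge sets over `n` cells (no autapses), as index pairs.
all_directed_pairs <- function(n) {
  pairs <- expand.grid(pre = seq_len(n), post = seq_len(n))
  pairs[pairs$pre != pairs$post, , drop = FALSE]
}

# A random small synapse table plus catalog with births drawn from `times`.
random_small_network <- function(n_cells, times = 0:2) {
  nm <- LETTERS[seq_len(n_cells)]
  birth <- stats::setNames(sample(times, n_cells, replace = TRUE), nm)
  pairs <- all_directed_pairs(n_cells)
  keep <- stats::runif(nrow(pairs)) < 0.4
  if (!any(keep)) keep[sample.int(length(keep), 1L)] <- TRUE
  edges <- data.frame(pre = nm[pairs$pre[keep]], post = nm[pairs$post[keep]],
                      stringsAsFactors = FALSE)
  list(catalog = cell_catalog(nm, birth), birth = birth, edges = edges,
       synapses = synapse_table(edges$pre, edges$post,
                                rep("stable", nrow(edges))))
}

# Labels of an assign_all() row, as a character vector.
split_labels <- function(assignments) {
  stats::setNames(strsplit(assignments$labels, ";", fixed = TRUE),
                  assignments$cell)
}

# Planted-vs-recovered agreement for a generated dataset.
recovered_labels <- function(generated, policy = first_mover_policy()) {
  a <- assign_all(generated$synapses, generated$catalog, policy)
  lab <- vapply(strsplit(a$labels, ";", fixed = TRUE),
                function(x) x[length(x)], character(1))
  stats::setNames(lab, a$cell)
}

write_temp_csv <- function(df, ext = ".csv") {
  path <- tempfile(fileext = ext)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
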