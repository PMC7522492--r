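# Recompute the published desk-scale numbers from the bundled fixtures.

#' Verify bundled fixtures against the published numbers
#'
#' Recomputes, from the bundled fixtures alone: the five strategy population
#' frequencies (count over the 53-class union), the three N-P overlaps, the
#' NSY-5 P-N split (16 cells), the 300-to-400-minute stage totals (87 new
#' neurons; AV 14, RI 9, RM 7, UR 6), the profile conformity (0.75) and the
#' pairwise-matrix scale (53^2 = 2809 entries), and compares each against its
#' expected value.
#'
#' @return Data frame `check`, `expected`, `actual`, `pass`; attribute
#'   `all_pass`.
#' @export
verify_fixtures <- function() {
  fx <- fixtures()
  rows <- list()
  push <- function(check, expected, actual, tol = 0) {
    rows[[length(rows) + 1]] <<- data.frame(
      check = check, expected = expected, actual = actual,
      pass = is.finite(actual) && abs(actual - expected) <= tol,
      stringsAsFactors = FALSE)
  }

  freq <- frequency_table(fx$strategies)
  expect_pct <- fx$table_frequencies
  for (s in strategy_labels()) {
    push(paste0("frequency_", s),
         expect_pct$frequency_pct[expect_pct$strategy == s],
         round(100 * freq$fraction[freq$strategy == s], 1),
         tol = 0.05)
  }

  ov <- overlap(fx$strategies, "NP", "XNOR")
  push("overlap_NP_XNOR_shared", 5, ov[["shared"]])
  push("overlap_NP_XNOR_possible", 8, ov[["possible"]])
  ov <- overlap(fx$strategies, "NP", "XOR_FIRST")
  push("overlap_NP_XOR_FIRST_shared", 2, ov[["shared"]])
  push("overlap_NP_XOR_FIRST_possible", 4, ov[["possible"]])
  ov <- overlap(fx$strategies, "NP", "XOR_SECOND")
  push("overlap_NP_XOR_SECOND_shared", 8, ov[["shared"]])
  push("overlap_NP_XOR_SECOND_possible", 10, ov[["possible"]])

  split <- subnetwork_strategy_split(fx$strategies, fx$nsy5$pn_classes)
  push("nsy5_pn_cells", 16, split$count[split$strategy == "PN"])

  push("new_neurons_300_400", 87, sum(fx$table_families$count))
  for (fam in c("AV", "RI", "RM", "UR")) {
    expected <- c(AV = 14, RI = 9, RM = 7, UR = 6)[[fam]]
    push(paste0("family_", fam),
         expected, fx$table_families$count[fx$table_families$family == fam])
  }

  push("profile_conformity", 0.75, conformity(fx$profile))

  union_cells <- unique(unlist(fx$strategies))
  push("strategy_union_size", 53, length(union_cells))
  push("pairwise_matrix_entries", 2809,
       length(pairwise_matrix(
         cell_catalog(union_cells, seq(265, 400, length.out = length(union_cells))))))

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "all_pass") <- all(out$pass)
  out
}
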