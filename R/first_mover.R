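# Wiring-strategy classification from the signs of a cell's pre-role and
# post-role birth-time differences.
#
# Base label: sign of the mean delta over ALL incident connections
# (delta = birth(pre) - birth(post)); negative -> NP, positive -> PN.
# Refinements of NP use universal quantification over the cell's partners:
#   XNOR       every incoming partner born strictly before the cell AND every
#              outgoing partner born strictly after it
#   XOR_FIRST  every incoming partner born strictly before the cell
#   XOR_SECOND every outgoing partner born strictly after the cell
# XNOR is tested first and suppresses both XOR labels. Partners born at
# exactly the cell's birth time (bilateral pairs) count as neither born-first
# nor born-second: they are excluded from the universal tests but enter the
# mean as delta 0.

#' Classification policy
#'
#' @param tie Base label when the mean delta is exactly zero: `"NP"`
#'   (default), `"PN"` or `"none"` (cell left unlabelled). Ties are flagged in
#'   the output either way. A tied cell receives no exclusivity refinement.
#' @param exclusivity_tolerance Maximum number of violating (non-tie)
#'   connections a universal test may ignore; 0 (default) is the strict
#'   reading in which an exclusive strategy admits zero violations.
#' @return A `first_mover_policy` list.
#' @export
first_mover_policy <- function(tie = c("NP", "PN", "none"),
                               exclusivity_tolerance = 0L) {
  tie <- match.arg(tie)
  stopifnot(exclusivity_tolerance >= 0)
  structure(list(tie = tie,
                 exclusivity_tolerance = as.integer(exclusivity_tolerance)),
            class = "first_mover_policy")
}

#' Role-wise birth-time difference summary for one cell
#'
#' Splits the cell's incident records into its presynaptic role (records where
#' the cell is `pre`) and postsynaptic role (records where it is `post`), and
#' decomposes the deltas into negative and positive components.
#'
#' @param cell Cell name.
#' @param synapses A `synapse_table`.
#' @param catalog A `cell_catalog`.
#' @return A `role_summary` list: `cell`, `pre_role_deltas`,
#'   `post_role_deltas`, `mean_delta_all`, `neg_component`, `pos_component`
#'   (the component means are `NA` when the respective set is empty).
#' @export
role_summary <- function(cell, synapses, catalog) {
  is_pre <- synapses$pre == cell
  is_post <- synapses$post == cell
  if (!any(is_pre | is_post)) {
    stop("no incident connections for cell ", cell)
  }
  delta <- birth_time_difference(synapses, catalog)
  pre_d <- delta[is_pre]
  post_d <- delta[is_post]
  all_d <- c(pre_d, post_d)
  structure(list(
    cell = cell,
    pre_role_deltas = pre_d,
    post_role_deltas = post_d,
    mean_delta_all = mean(all_d),
    neg_component = if (any(all_d < 0)) mean(all_d[all_d < 0]) else NA_real_,
    pos_component = if (any(all_d > 0)) mean(all_d[all_d > 0]) else NA_real_
  ), class = "role_summary")
}

#' @export
print.role_summary <- function(x, ...) {
  cat("<role_summary>", x$cell, "- pre role:", length(x$pre_role_deltas),
      "post role:", length(x$post_role_deltas),
      "mean delta:", signif(x$mean_delta_all, 4), "min\n")
  invisible(x)
}

#' Classify one cell's wiring strategy
#'
#' @param summary A [role_summary()].
#' @param policy A [first_mover_policy()].
#' @return A `strategy_assignment` list: `cell`, `labels` (character vector),
#'   `tie` (logical: mean delta exactly zero).
#' @export
classify_strategy <- function(summary, policy = first_mover_policy()) {
  m <- summary$mean_delta_all
  tie <- m == 0
  if (tie) {
    labels <- switch(policy$tie, NP = "NP", PN = "PN", none = character(0))
    return(structure(list(cell = summary$cell, labels = labels, tie = TRUE),
                     class = "strategy_assignment"))
  }
  if (m > 0) {
    return(structure(list(cell = summary$cell, labels = "PN", tie = FALSE),
                     class = "strategy_assignment"))
  }
  tol <- policy$exclusivity_tolerance
  # Incoming partners: cell is post, delta = birth(partner) - birth(cell).
  # "Born strictly before the cell" is delta < 0; ties (delta 0) are skipped.
  in_d <- summary$post_role_deltas
  out_d <- summary$pre_role_deltas
  incoming_ok <- sum(in_d > 0) <= tol
  # Outgoing partners: cell is pre, delta = birth(cell) - birth(partner).
  # "Born strictly after the cell" is delta < 0.
  outgoing_ok <- sum(out_d > 0) <= tol
  labels <- "NP"
  if (incoming_ok && outgoing_ok) {
    labels <- c("NP", "XNOR")
  } else if (incoming_ok) {
    labels <- c("NP", "XOR_FIRST")
  } else if (outgoing_ok) {
    labels <- c("NP", "XOR_SECOND")
  }
  structure(list(cell = summary$cell, labels = labels, tie = FALSE),
            class = "strategy_assignment")
}

#' Classify every connected cell
#'
#' One assignment per cell incident to at least one record, deterministic in
#' the inputs and policy (record order does not matter). Per-cell failures are
#' collected, reported as a single warning, and the cells skipped.
#'
#' @param synapses A `synapse_table`.
#' @param catalog A `cell_catalog`.
#' @param policy A [first_mover_policy()].
#' @return Data frame with columns `cell`, `labels` (semicolon-joined, sorted
#'   refinement after base), `mean_delta`, `n_records`, `tie`; class
#'   `strategy_assignments`.
#' @export
assign_all <- function(synapses, catalog, policy = first_mover_policy()) {
  cells <- sort(unique(c(synapses$pre, synapses$post)))
  errs <- character(0)
  rows <- lapply(cells, function(cl) {
    res <- tryCatch({
      s <- role_summary(cl, synapses, catalog)
      a <- classify_strategy(s, policy)
      data.frame(cell = cl,
                 labels = paste(a$labels, collapse = ";"),
                 mean_delta = s$mean_delta_all,
                 n_records = length(s$pre_role_deltas) + length(s$post_role_deltas),
                 tie = a$tie,
                 stringsAsFactors = FALSE)
    }, error = function(e) conditionMessage(e))
    res
  })
  failed <- vapply(rows, is.character, logical(1))
  if (any(failed)) {
    warning("skipped ", sum(failed), " cell(s): ",
            paste(unlist(rows[failed]), collapse = "; "))
  }
  out <- do.call(rbind, rows[!failed])
  if (is.null(out)) {
    out <- data.frame(cell = character(0), labels = character(0),
                      mean_delta = numeric(0), n_records = integer(0),
                      tie = logical(0))
  }
  rownames(out) <- NULL
  class(out) <- c("strategy_assignments", "data.frame")
  out
}

#' Assignments in long (cell, label) form
#'
#' Accepts the output of [assign_all()] (semicolon-joined `labels` column) or
#' a list of per-strategy cell vectors such as the bundled printed lists.
#'
#' @param assignments A `strategy_assignments` data frame or a named list of
#'   character vectors keyed by strategy label.
#' @return Data frame with columns `cell`, `label`, one row per (cell, label).
#' @export
assignment_labels <- function(assignments) {
  if (is.data.frame(assignments)) {
    labs <- strsplit(assignments$labels, ";", fixed = TRUE)
    out <- data.frame(cell = rep(assignments$cell, lengths(labs)),
                      label = unlist(labs), stringsAsFactors = FALSE)
  } else if (is.list(assignments)) {
    bad <- setdiff(names(assignments), strategy_labels())
    if (length(bad)) stop("unknown strategy label(s): ", paste(bad, collapse = ", "))
    out <- data.frame(cell = unlist(assignments, use.names = FALSE),
                      label = rep(names(assignments), lengths(assignments)),
                      stringsAsFactors = FALSE)
  } else {
    stop("unsupported assignments representation")
  }
  out[nzchar(out$label), , drop = FALSE]
}

#' Write assignments to CSV
#'
#' @param assignments Output of [assign_all()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.csv(as.data.frame(assignments), path, row.names = FALSE)
  invisible(path)
}
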