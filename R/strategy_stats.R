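# Population-level summaries of strategy assignments.

#' Strategy frequency table
#'
#' Per-strategy counts and fractions of the assigned population. The
#' denominator is the number of distinct strategy-assigned cells, so counts
#' may sum to more than the denominator (NP overlaps its refinements). When a
#' synapse table and catalog are supplied, the per-strategy stability-class
#' composition is added: for each strategy, the proportions of
#' transient/developmental/stable records incident to its cells (each row of
#' proportions sums to 1).
#'
#' @param assignments Anything [assignment_labels()] accepts.
#' @param synapses Optional `synapse_table` for stability composition.
#' @param catalog Optional `cell_catalog` (unused unless needed to resolve
#'   endpoints; composition is computed from record incidence).
#' @return Data frame `strategy`, `count`, `fraction`, and (when `synapses`
#'   is given) `transient`, `developmental`, `stable`.
#' @export
frequency_table <- function(assignments, synapses = NULL, catalog = NULL) {
  long <- assignment_labels(assignments)
  if (!nrow(long)) stop("no strategy assignments")
  denom <- length(unique(long$cell))
  out <- data.frame(strategy = strategy_labels(), stringsAsFactors = FALSE)
  out$count <- vapply(out$strategy,
                      function(s) length(unique(long$cell[long$label == s])),
                      integer(1))
  out$fraction <- out$count / denom
  if (!is.null(synapses)) {
    comp <- t(vapply(out$strategy, function(s) {
      members <- unique(long$cell[long$label == s])
      hit <- synapses$pre %in% members | synapses$post %in% members
      if (!any(hit)) return(rep(NA_real_, 3))
      tab <- table(factor(synapses$stability[hit], levels = stability_classes()))
      as.numeric(tab) / sum(tab)
    }, numeric(3)))
    colnames(comp) <- stability_classes()
    out <- cbind(out, comp)
  }
  attr(out, "n_cells") <- denom
  rownames(out) <- NULL
  out
}

#' Overlap between two strategies
#'
#' `shared` is the number of cells carrying both labels; `possible` is the
#' size of the rarer label's set, so `shared <= possible` and the measure is
#' symmetric in its arguments.
#'
#' @param assignments Anything [assignment_labels()] accepts.
#' @param s1,s2 Strategy labels.
#' @return Named integer vector `c(shared =, possible =)`.
#' @export
overlap <- function(assignments, s1, s2) {
  ok <- c(s1, s2) %in% strategy_labels()
  if (!all(ok)) {
    stop("unknown strategy label(s): ", paste(c(s1, s2)[!ok], collapse = ", "))
  }
  long <- assignment_labels(assignments)
  set1 <- unique(long$cell[long$label == s1])
  set2 <- unique(long$cell[long$label == s2])
  c(shared = length(intersect(set1, set2)),
    possible = min(length(set1), length(set2)))
}

#' Strategy composition of a subnetwork
#'
#' Expands the member classes (and the assigned classes) to left/right cells
#' and counts, per strategy, the expanded member cells whose class carries the
#' label. Members with no assignment are reported in the `unassigned`
#' attribute.
#'
#' @param assignments Anything [assignment_labels()] accepts; cells are
#'   treated as class names and pair-expanded.
#' @param member_classes Character vector of subnetwork class names.
#' @param unpaired Class names that denote single cells (no L/R expansion).
#' @return Data frame `strategy`, `count` over expanded cells, with attribute
#'   `unassigned` (expanded member cells carrying no label).
#' @export
subnetwork_strategy_split <- function(assignments, member_classes,
                                      unpaired = character()) {
  long <- assignment_labels(assignments)
  members <- expand_pairs(member_classes, unpaired = unpaired)
  per_label <- lapply(strategy_labels(), function(s) {
    cells <- expand_pairs(unique(long$cell[long$label == s]), unpaired = unpaired)
    intersect(members, cells)
  })
  names(per_label) <- strategy_labels()
  out <- data.frame(strategy = strategy_labels(),
                    count = vapply(per_label, length, integer(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "unassigned") <- setdiff(members, unlist(per_label))
  out
}

#' Per-strategy empirical CDF of member birth times
#'
#' Each CDF is a right-continuous step function rising from 0 to 1 with a step
#' at each member's birth time (via [stats::ecdf()]).
#'
#' @param assignments Anything [assignment_labels()] accepts.
#' @param catalog A `cell_catalog` holding every assigned cell.
#' @return Named list of `ecdf` functions, one per strategy present.
#' @export
birth_time_cdf <- function(assignments, catalog) {
  long <- assignment_labels(assignments)
  labs <- intersect(strategy_labels(), unique(long$label))
  out <- lapply(labs, function(s) {
    cells <- unique(long$cell[long$label == s])
    stats::ecdf(birth_times(cells, catalog))
  })
  names(out) <- labs
  out
}

#' Normalized synaptic density by birth time
#'
#' For each catalogued birth time `t` and stability class: the number of
#' records whose role endpoint (`pre` or `post`) was born at `t`, divided by
#' the number of catalog cells born at `t` -- i.e. the mean number of
#' connections of that class per cell born at `t`.
#'
#' @param synapses A `synapse_table`.
#' @param catalog A `cell_catalog`.
#' @param role `"pre"` or `"post"`: which endpoint's birth time to group by.
#' @return Data frame `birth_time`, `stability`, `count`, `n_cells`,
#'   `density`, covering every catalogued birth time and class.
#' @export
synaptic_density <- function(synapses, catalog, role = c("pre", "post")) {
  role <- match.arg(role)
  times <- sort(unique(catalog$birth_time))
  n_cells <- vapply(times, function(t) sum(catalog$birth_time == t), integer(1))
  endpoint_birth <- birth_times(synapses[[role]], catalog)
  grid <- expand.grid(birth_time = times, stability = stability_classes(),
                      stringsAsFactors = FALSE)
  grid$count <- mapply(function(t, cls) {
    sum(endpoint_birth == t & synapses$stability == cls)
  }, grid$birth_time, grid$stability)
  grid$n_cells <- n_cells[match(grid$birth_time, times)]
  grid$density <- grid$count / grid$n_cells
  out <- grid[order(grid$birth_time, match(grid$stability, stability_classes())), ,
              drop = FALSE]
  rownames(out) <- NULL
  out
}
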