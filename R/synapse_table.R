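# Stability-classified directed chemical synapse tables and birth-time
# differences. Gap junctions are out of schema: only chemical synapses carry
# the pre/post distinction this analysis needs.

#' Construct a synapse table
#'
#' A synapse table is a data frame of directed chemical connections with one
#' row per `pre -> post` pair and a `stability` class (`transient`,
#' `developmental` or `stable`). Duplicate `(pre, post)` rows are collapsed to
#' one connection by default: the analysis is of cell-cell relationships, not
#' synapse counts.
#'
#' @param pre,post Character vectors of cell names.
#' @param stability Character vector of stability classes.
#' @param allow_autapses Permit `pre == post` rows (default `FALSE`).
#' @param collapse_duplicates Collapse duplicate `(pre, post)` rows
#'   (default `TRUE`).
#' @return A `synapse_table` data frame.
#' @export
synapse_table <- function(pre, post, stability,
                          allow_autapses = FALSE,
                          collapse_duplicates = TRUE) {
  pre <- as.character(pre)
  post <- as.character(post)
  stability <- as.character(stability)
  n <- length(pre)
  if (length(post) != n || length(stability) != n) {
    stop("`pre`, `post` and `stability` must have the same length")
  }
  bad_class <- setdiff(unique(stability), stability_classes())
  if (length(bad_class)) {
    stop("unknown stability label(s): ", paste(bad_class, collapse = ", "),
         " (expected ", paste(stability_classes(), collapse = "/"), ")")
  }
  if (!allow_autapses && any(pre == post)) {
    stop("autapse rows (pre == post) present: ",
         paste(unique(pre[pre == post]), collapse = ", "),
         "; set allow_autapses = TRUE to keep them")
  }
  out <- data.frame(pre = pre, post = post, stability = stability,
                    stringsAsFactors = FALSE)
  if (collapse_duplicates && n) {
    out <- out[!duplicated(out[c("pre", "post", "stability")]), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("synapse_table", "data.frame")
  out
}

#' Load a synapse edge table
#'
#' Reads a CSV/TSV with columns `pre,post,stability` and validates it. When a
#' catalog is given, every endpoint must resolve to a catalogued cell (either
#' directly or as `<class>L`/`<class>R` of a catalogued class).
#'
#' @param path Path to a CSV or TSV file.
#' @param catalog Optional `cell_catalog` used to check endpoints.
#' @param sep Optional field separator.
#' @inheritParams synapse_table
#' @return A `synapse_table`.
#' @export
load_synapses <- function(path, catalog = NULL, sep = NULL,
                          allow_autapses = FALSE,
                          collapse_duplicates = TRUE) {
  tab <- read_delim_auto(path, sep)
  if (nrow(tab) == 0 && ncol(tab) == 0) {
    return(synapse_table(character(0), character(0), character(0)))
  }
  need <- c("pre", "post", "stability")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("synapse table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  syn <- synapse_table(tab$pre, tab$post, tab$stability,
                       allow_autapses = allow_autapses,
                       collapse_duplicates = collapse_duplicates)
  if (!is.null(catalog)) {
    all_names <- unique(c(syn$pre, syn$post))
    unknown <- all_names[is.na(resolve_cells(all_names, catalog))]
    if (length(unknown)) {
      stop("synapse endpoint(s) not resolvable in catalog: ",
           paste(sort(unknown), collapse = ", "))
    }
  }
  syn
}

# Map a cell name to a catalog row index: direct match, or the catalogued
# class obtained by dropping a trailing L/R.
resolve_cells <- function(names, catalog) {
  idx <- match(names, catalog$name)
  miss <- is.na(idx)
  if (any(miss)) {
    stripped <- sub("[LR]$", "", names[miss])
    idx[miss] <- match(stripped, catalog$name)
  }
  idx
}

#' Look up birth times for cell names
#'
#' @param names Character vector of cell names.
#' @param catalog A `cell_catalog`.
#' @return Numeric vector of birth times in minutes.
#' @export
birth_times <- function(names, catalog) {
  idx <- resolve_cells(as.character(names), catalog)
  if (anyNA(idx)) {
    stop("no birth time for cell(s): ",
         paste(sort(unique(names[is.na(idx)])), collapse = ", "))
  }
  catalog$birth_time[idx]
}

#' Signed birth-time differences for synapses
#'
#' The convention throughout the package: `delta = birth(pre) - birth(post)`.
#' Negative values mean the presynaptic cell was born first; positive values
#' mean it was born second.
#'
#' @param synapses A `synapse_table`.
#' @param catalog A `cell_catalog` holding both endpoints of every record.
#' @return Numeric vector of deltas in minutes, one per record.
#' @export
birth_time_difference <- function(synapses, catalog) {
  birth_times(synapses$pre, catalog) - birth_times(synapses$post, catalog)
}

#' Pairwise birth-time difference matrix
#'
#' Entry `(i, j)` is `birth(i) - birth(j)`; the matrix is antisymmetric with a
#' zero diagonal, so `n` cells give `n^2` entries including the diagonal.
#'
#' @param catalog A `cell_catalog`.
#' @param cells Ordered character vector of cell names (default: all cells in
#'   the catalog).
#' @return A named numeric matrix of signed minutes.
#' @export
pairwise_matrix <- function(catalog, cells = catalog$name) {
  b <- birth_times(cells, catalog)
  m <- outer(b, b, "-")
  dimnames(m) <- list(cells, cells)
  m
}

#' Histogram of birth-time differences, per stability class
#'
#' Bins deltas into half-open intervals of width `bin_width`, optionally split
#' by stability class. Per-class counts conserve per-class record totals.
#'
#' @param synapses A `synapse_table`.
#' @param catalog A `cell_catalog`.
#' @param bin_width Bin width in minutes (default 10).
#' @param by_stability Split counts by stability class (default `TRUE`).
#' @return Data frame `stability`, `bin_lo`, `bin_hi`, `count` (stability is
#'   `"all"` when `by_stability = FALSE`).
#' @export
difference_histogram <- function(synapses, catalog, bin_width = 10,
                                 by_stability = TRUE) {
  if (bin_width <= 0) stop("bin_width must be positive")
  delta <- birth_time_difference(synapses, catalog)
  cls <- if (by_stability) synapses$stability else rep("all", length(delta))
  if (!length(delta)) {
    return(data.frame(stability = character(0), bin_lo = numeric(0),
                      bin_hi = numeric(0), count = integer(0)))
  }
  lo <- floor(min(delta) / bin_width) * bin_width
  breaks <- seq(lo, lo + bin_width * (floor((max(delta) - lo) / bin_width) + 1),
                by = bin_width)
  pieces <- lapply(split(delta, cls), function(d) {
    idx <- findInterval(d, breaks, rightmost.closed = FALSE)
    data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
               count = tabulate(idx, nbins = length(breaks) - 1))
  })
  out <- do.call(rbind, Map(function(cls_name, df) {
    cbind(stability = cls_name, df, stringsAsFactors = FALSE)
  }, names(pieces), pieces))
  rownames(out) <- NULL
  out
}

#' Export a synapse network as GraphML
#'
#' Writes a directed graph with a `stability` edge attribute and a
#' `birth_time` vertex attribute.
#'
#' @param synapses A `synapse_table`.
#' @param catalog A `cell_catalog` covering every endpoint.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(synapses, catalog, path) {
  cells <- sort(unique(c(synapses$pre, synapses$post)))
  vertices <- data.frame(name = cells,
                         birth_time = birth_times(cells, catalog),
                         stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    as.data.frame(synapses)[c("pre", "post", "stability")],
    directed = TRUE, vertices = vertices)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
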