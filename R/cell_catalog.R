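# Cell catalog: neuron identities, birth times, families, staged snapshots.

#' Strategy label vocabulary
#'
#' The five wiring strategies recognised by the classifier and the generator:
#' `NP` (N-P coupling: presynaptic partner born earlier on average),
#' `XOR_FIRST` and `XOR_SECOND` (exclusivity refinements of N-P), `XNOR`
#' (strictest refinement: presynaptic cell born first in every connection) and
#' `PN` (P-N coupling: presynaptic partner born later on average; a pure
#' strategy that never co-occurs with the others).
#'
#' @return Character vector of the five labels.
#' @export
strategy_labels <- function() {
  c("NP", "XOR_FIRST", "XOR_SECOND", "XNOR", "PN")
}

#' Stability class vocabulary
#'
#' @return Character vector: transient, developmental, stable.
#' @export
stability_classes <- function() {
  c("transient", "developmental", "stable")
}

# Minutes post-fertilization at hatch; birth times are validated against it.
HATCH_MIN <- 800

#' Construct a cell catalog
#'
#' A catalog is a data frame with one row per cell: `name`, `birth_time`
#' (minutes post-fertilization), `family` (nomenclature prefix, derived from
#' the name unless supplied) and `laterality` (one of `left`, `right`,
#' `unpaired`, `class`).
#'
#' @param name Character vector of unique cell names.
#' @param birth_time Numeric vector of birth times in minutes, in `[0, 800]`.
#' @param laterality Optional character vector; derived from names if `NULL`.
#' @param family Optional character vector; derived from names if `NULL`.
#' @return A `cell_catalog` data frame.
#' @examples
#' cell_catalog(c("RMEV", "ADFL"), c(265, 280))
#' @export
cell_catalog <- function(name, birth_time, laterality = NULL, family = NULL) {
  name <- as.character(name)
  birth_time <- as.numeric(birth_time)
  if (length(name) != length(birth_time)) {
    stop("`name` and `birth_time` must have the same length")
  }
  if (anyDuplicated(name)) {
    stop("duplicate cell names in catalog: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  bad <- which(is.na(birth_time) | birth_time < 0 | birth_time > HATCH_MIN)
  if (length(bad)) {
    stop("invalid birth time (must be in [0, ", HATCH_MIN, "] minutes) in row",
         if (length(bad) > 1) "s" else "", " ",
         paste(bad, collapse = ", "), " (", paste(name[bad], collapse = ", "), ")")
  }
  if (is.null(family)) family <- cell_family(name)
  if (is.null(laterality)) laterality <- derive_laterality(name)
  lat_ok <- laterality %in% c("left", "right", "unpaired", "class")
  if (!all(lat_ok)) {
    stop("unknown laterality value(s): ",
         paste(unique(laterality[!lat_ok]), collapse = ", "))
  }
  out <- data.frame(name = name, birth_time = birth_time,
                    family = as.character(family),
                    laterality = as.character(laterality),
                    stringsAsFactors = FALSE)
  class(out) <- c("cell_catalog", "data.frame")
  out
}

#' Load a birth-time table
#'
#' Reads a CSV/TSV with columns `name,birth_time` (optional `laterality`) and
#' returns a validated [cell_catalog()]. Family and laterality are derived
#' from the name where not supplied.
#'
#' @param path Path to a CSV or TSV file (separator inferred from extension,
#'   or forced with `sep`).
#' @param sep Optional field separator.
#' @return A `cell_catalog`.
#' @export
load_catalog <- function(path, sep = NULL) {
  tab <- read_delim_auto(path, sep)
  if (nrow(tab) == 0 && ncol(tab) == 0) {
    return(cell_catalog(character(0), numeric(0)))
  }
  need <- c("name", "birth_time")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("birth-time table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  lat <- if ("laterality" %in% names(tab)) as.character(tab$laterality) else NULL
  cell_catalog(tab$name, tab$birth_time, laterality = lat)
}

read_delim_auto <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) "\t" else ","
  }
  first <- readLines(path, n = 1L)
  if (length(first) == 0) {
    return(data.frame())
  }
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    strip.white = TRUE, comment.char = "")
}

# Characters treated as positional/laterality suffixes when deriving families.
FAMILY_SUFFIX_CHARS <- c("L", "R", "D", "V")

#' Derive nomenclature families from cell names
#'
#' The family is the name with trailing laterality/positional characters
#' (`L`, `R`, `D`, `V`) stripped greedily from the right, never below two
#' characters; a digit stops stripping, so numbered classes keep their number
#' (IL2DL -> IL2). An override table (shipped as a fixture) resolves prefixes
#' that pure suffix-stripping cannot, e.g. URY -> UR.
#'
#' @param names Character vector of cell names.
#' @param overrides Data frame with columns `from`, `to`; defaults to the
#'   bundled override table.
#' @return Character vector of family names.
#' @examples
#' cell_family(c("RMEV", "AVDL", "IL2DR", "URYDL"))
#' @export
cell_family <- function(names, overrides = family_overrides()) {
  names <- as.character(names)
  fam <- vapply(names, strip_family_suffix, character(1), USE.NAMES = FALSE)
  if (!is.null(overrides) && nrow(overrides)) {
    idx <- match(fam, overrides$from)
    hit <- !is.na(idx)
    fam[hit] <- overrides$to[idx[hit]]
  }
  fam
}

strip_family_suffix <- function(nm) {
  nm <- sub("/[LRDV]+$", "", nm)
  while (nchar(nm) > 2 &&
         substr(nm, nchar(nm), nchar(nm)) %in% FAMILY_SUFFIX_CHARS) {
    nm <- substr(nm, 1, nchar(nm) - 1)
  }
  nm
}

#' @keywords internal
family_overrides <- function() {
  path <- system.file("extdata", "family_overrides.csv", package = "firstmover")
  if (!nzchar(path)) return(NULL)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

derive_laterality <- function(names) {
  vapply(as.character(names), function(nm) {
    if (grepl("/", nm)) return("class")
    last <- substr(nm, nchar(nm), nchar(nm))
    if (nchar(nm) > 2 && last == "L") return("left")
    if (nchar(nm) > 2 && last == "R") return("right")
    "unpaired"
  }, character(1), USE.NAMES = FALSE)
}

#' Expand cell-class names to left/right cells
#'
#' Class names expand to `<name>L` and `<name>R`; names written with a pair
#' marker (`IL2L/R`) expand to both sides; names listed in `unpaired` are kept
#' as-is.
#'
#' @param names Character vector of class names.
#' @param unpaired Character vector of names that denote single cells.
#' @return Character vector of expanded cell names (unique, sorted).
#' @examples
#' expand_pairs(c("AWC", "IL2L/R", "RMEV"), unpaired = "RMEV")
#' @export
expand_pairs <- function(names, unpaired = character()) {
  out <- unlist(lapply(as.character(names), function(nm) {
    if (nm %in% unpaired) return(nm)
    if (grepl("/", nm)) {
      # pair marker, e.g. "IL2L/R" -> stem "IL2", sides L and R
      head <- sub("/.*$", "", nm)
      stem <- substr(head, 1, nchar(head) - 1)
      sides <- unique(c(substr(head, nchar(head), nchar(head)),
                        strsplit(sub("^.*/", "", nm), "")[[1]]))
      return(paste0(stem, sides))
    }
    paste0(nm, c("L", "R"))
  }))
  sort(unique(out))
}

#' Connectome snapshot at a developmental time
#'
#' Members are the cells born at or before `t` (birth at exactly `t` is
#' included, so the 265-min snapshot contains a cell born at 265).
#'
#' @param catalog A `cell_catalog`.
#' @param t Time in minutes post-fertilization (`t >= 0`).
#' @return A `stage_snapshot` list with `time` and sorted `members`.
#' @examples
#' cat <- cell_catalog(c("RMEV", "ADFL"), c(265, 280))
#' snapshot(cat, 265)$members
#' @export
snapshot <- function(catalog, t) {
  stopifnot(is.numeric(t), length(t) == 1)
  if (t < 0) stop("snapshot time must be non-negative")
  members <- sort(catalog$name[catalog$birth_time <= t])
  structure(list(time = t, members = members), class = "stage_snapshot")
}

#' @export
print.stage_snapshot <- function(x, ...) {
  cat("<stage_snapshot> t =", x$time, "min;", length(x$members), "cells\n")
  invisible(x)
}

#' Cells born in a developmental interval
#'
#' Returns the cells present at `t2` but not at `t1`, i.e. born in `(t1, t2]`.
#'
#' @param catalog A `cell_catalog`.
#' @param t1,t2 Interval bounds in minutes, `t1 < t2`.
#' @return Sorted character vector of cell names.
#' @export
snapshot_diff <- function(catalog, t1, t2) {
  if (!(t1 < t2)) stop("snapshot_diff requires t1 < t2 (got ", t1, " >= ", t2, ")")
  setdiff(snapshot(catalog, t2)$members, snapshot(catalog, t1)$members)
}

#' Count cells per nomenclature family
#'
#' @param cells Character vector of cell names.
#' @param catalog Optional `cell_catalog`; when given, every name must be
#'   present in it and the catalog's family column is used.
#' @param overrides Family override table, as in [cell_family()].
#' @return Data frame `family`, `count`, sorted by family; counts sum to
#'   `length(cells)`.
#' @export
family_counts <- function(cells, catalog = NULL, overrides = family_overrides()) {
  cells <- as.character(cells)
  if (!is.null(catalog)) {
    miss <- setdiff(cells, catalog$name)
    if (length(miss)) {
      stop("cell name(s) not in catalog: ", paste(miss, collapse = ", "))
    }
    fam <- catalog$family[match(cells, catalog$name)]
  } else {
    fam <- cell_family(cells, overrides = overrides)
  }
  if (!length(fam)) {
    return(data.frame(family = character(0), count = integer(0)))
  }
  tab <- table(fam)
  data.frame(family = names(tab), count = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Histogram of birth times with burst detection
#'
#' Bins are half-open `[lo, hi)` of width `bin_width`; the first bin starts at
#' the minimum observed time rounded down to a multiple of `bin_width`. Bursts
#' are maximal runs of consecutive non-empty bins separated by at least one
#' empty bin.
#'
#' @param birth_times Numeric vector of birth times in minutes.
#' @param bin_width Bin width in minutes (default 8).
#' @return A `burst_histogram` list: `breaks`, `counts` and a data frame
#'   `bursts` with columns `start`, `end` (bin-edge minutes).
#' @export
burst_histogram <- function(birth_times, bin_width = 8) {
  if (bin_width <= 0) stop("bin_width must be positive")
  birth_times <- as.numeric(birth_times)
  if (anyNA(birth_times)) stop("birth_times contains missing values")
  if (!length(birth_times)) {
    out <- list(breaks = numeric(0), counts = integer(0),
                bursts = data.frame(start = numeric(0), end = numeric(0)))
    class(out) <- "burst_histogram"
    return(out)
  }
  lo <- floor(min(birth_times) / bin_width) * bin_width
  hi <- max(birth_times)
  breaks <- seq(lo, lo + bin_width * (floor((hi - lo) / bin_width) + 1),
                by = bin_width)
  idx <- findInterval(birth_times, breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  nonempty <- counts > 0
  runs <- rle(nonempty)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values
  bursts <- data.frame(start = breaks[starts[keep]], end = breaks[ends[keep] + 1])
  out <- list(breaks = breaks, counts = counts, bursts = bursts)
  class(out) <- "burst_histogram"
  out
}

#' @export
print.burst_histogram <- function(x, ...) {
  cat("<burst_histogram>", length(x$counts), "bins,", sum(x$counts),
      "births,", nrow(x$bursts), "burst(s)\n")
  invisible(x)
}
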