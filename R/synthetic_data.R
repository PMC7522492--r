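# Synthetic catalogs and synapse tables with the statistical structure the
# analysis assumes: bursty birth schedules, left/right pairs with shared
# birth times, planted per-cell strategies with a stated conformity rate, and
# a transient/developmental/stable class mix.

#' Generator specification
#'
#' Defaults emulate the embryonic study conditions: three birth bursts
#' (210-285, 285-345 and 365-400 minutes, leaving 345-365 empty) weighted by
#' window width; about two thirds of cells created as left/right pairs with
#' equal birth times; planted strategies drawn from the observed population
#' frequencies (normalised to sum to 1, with plain N-P weighted by the
#' printed N-P frequency); conformity 0.75; stability mix 43/14/43.
#'
#' @param n_cells Number of cells to generate.
#' @param burst_windows Data frame `start`, `end`, `weight` (minutes); weights
#'   are normalised to sum to 1.
#' @param pair_fraction Fraction of cells belonging to L/R pairs.
#' @param planted_strategies Named probabilities over [strategy_labels()].
#' @param conformity Per-edge conformity probability.
#' @param class_mix Named probabilities for transient/developmental/stable.
#' @param attach_rate Mean edges initiated per entering cell.
#' @param seed Optional integer seed.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(n_cells = 60,
                           burst_windows = data.frame(
                             start = c(210, 285, 365),
                             end = c(285, 345, 400),
                             weight = c(75, 60, 35) / 170),
                           pair_fraction = 0.65,
                           planted_strategies = c(NP = 41.5, XOR_FIRST = 7.5,
                                                  XOR_SECOND = 18.9,
                                                  XNOR = 15.1,
                                                  PN = 45.3) / 128.3,
                           conformity = 0.75,
                           class_mix = c(transient = 0.43,
                                         developmental = 0.14,
                                         stable = 0.43),
                           attach_rate = 4,
                           seed = NULL) {
  stopifnot(n_cells >= 1, pair_fraction >= 0, pair_fraction <= 1,
            conformity >= 0, conformity <= 1, attach_rate >= 0)
  if (any(burst_windows$end <= burst_windows$start)) {
    stop("burst windows must have end > start")
  }
  if (any(burst_windows$weight < 0) || sum(burst_windows$weight) <= 0) {
    stop("burst weights must be non-negative with positive sum")
  }
  burst_windows$weight <- burst_windows$weight / sum(burst_windows$weight)
  if (any(planted_strategies < 0) || abs(sum(planted_strategies) - 1) > 1e-6) {
    stop("planted_strategies must be a probability distribution over labels")
  }
  bad <- setdiff(names(planted_strategies), strategy_labels())
  if (length(bad)) stop("unknown strategy label(s): ", paste(bad, collapse = ", "))
  if (abs(sum(class_mix) - 1) > 1e-9 || any(class_mix < 0)) {
    stop("class_mix must be non-negative and sum to 1")
  }
  structure(list(n_cells = n_cells, burst_windows = burst_windows,
                 pair_fraction = pair_fraction,
                 planted_strategies = planted_strategies,
                 conformity = conformity, class_mix = class_mix,
                 attach_rate = attach_rate, seed = seed),
            class = "generator_spec")
}

# Class-name stems that survive family derivation unchanged: no trailing
# L/R/D/V and no digits, so planted families can be recovered exactly.
SYNTH_STEMS <- c("AA", "AB", "AC", "BE", "BF", "CG", "CH", "DJ", "DK", "EM",
                 "EN", "FO", "FP", "GQ", "GS", "HT", "HU", "JW", "JX", "KY",
                 "KZ", "MB", "MC", "NE", "NF", "OG", "OH", "PJ", "PK", "QM",
                 "QN", "SO", "SP", "TQ", "TS", "UT", "UW", "WX", "WY", "XZ")

synth_class_names <- function(n) {
  suffix <- c("", LETTERS[!LETTERS %in% c("L", "R", "D", "V")])
  pool <- as.vector(t(outer(SYNTH_STEMS, suffix, paste0)))
  if (n > length(pool)) {
    pool <- as.vector(t(outer(pool, suffix, paste0)))
  }
  pool[seq_len(n)]
}

#' Generate a synthetic dataset with planted structure
#'
#' Draws a birth-time catalog (bursty schedule, L/R pairs sharing birth
#' times), plants a strategy on every cell, and grows a synapse table with
#' [simulate_growth()]. When `exact` (default: `conformity == 1`) the planted
#' labels are realised exactly and boundary-infeasible label draws (a label
#' requiring an older partner on the first-born cell, or a younger partner on
#' the last-born) are repaired by swapping labels between cells, which
#' preserves the drawn label counts.
#'
#' @param spec A [generator_spec()].
#' @param exact Passed to [simulate_growth()].
#' @return List with `catalog` (a `cell_catalog`), `synapses` (a
#'   `synapse_table`), `truth` (list: `labels` named by cell, `edges` the
#'   per-edge provenance table) and `spec`.
#' @export
generate <- function(spec = generator_spec(), exact = spec$conformity >= 1) {
  stopifnot(inherits(spec, "generator_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_cells
  n_pairs <- floor(round(spec$pair_fraction * n) / 2)
  n_single <- n - 2L * n_pairs
  n_classes <- n_pairs + n_single
  classes <- synth_class_names(n_classes)
  win <- spec$burst_windows
  draw_birth <- function(k) {
    w <- sample.int(nrow(win), k, replace = TRUE, prob = win$weight)
    floor(stats::runif(k, win$start[w], win$end[w]))
  }
  class_birth <- draw_birth(n_classes)
  paired <- seq_len(n_classes) <= n_pairs
  pair_names <- if (n_pairs) {
    paste0(rep(classes[paired], each = 2), c("L", "R"))
  } else {
    character(0)
  }
  name <- c(pair_names, classes[!paired])
  birth <- c(rep(class_birth[paired], each = 2), class_birth[!paired])
  names(birth) <- name

  # Plant one label per class (both cells of a pair share it), then repair
  # boundary infeasibilities by swapping labels between classes.
  class_label <- sample(names(spec$planted_strategies), n_classes,
                        replace = TRUE, prob = spec$planted_strategies)
  names(class_label) <- classes
  if (exact && n > 1) {
    class_label <- repair_boundary_labels(class_label, class_birth)
  }
  labels <- class_label[c(rep(which(paired), each = 2), which(!paired))]
  names(labels) <- name

  sim <- simulate_growth(birth, labels, conformity = spec$conformity,
                         attach_rate = spec$attach_rate,
                         class_mix = spec$class_mix,
                         exact = exact)
  catalog <- cell_catalog(name, birth)
  list(catalog = catalog, synapses = sim$synapses,
       truth = list(labels = labels, edges = sim$truth), spec = spec)
}

# Exact realisation constrains labels at the birth-order boundaries: labels
# needing a strictly older admissible partner (plain NP, XOR_FIRST) cannot
# sit on the earliest-born classes, labels needing a strictly younger one
# (plain NP, XOR_SECOND) cannot sit on the latest-born, and each boundary
# must hold at least one class whose label can RECEIVE the counter-order
# signature edges of later/earlier cells (PN or XOR_SECOND at the front, PN
# or XOR_FIRST at the back). Violating draws are swapped with the nearest
# feasible class, which preserves the drawn label counts.
repair_boundary_labels <- function(class_label, class_birth) {
  ord <- order(class_birth)
  need_older <- c("NP", "XOR_FIRST")
  need_younger <- c("NP", "XOR_SECOND")
  swap <- function(class_label, i, j) {
    tmp <- class_label[i]
    class_label[i] <- class_label[j]
    class_label[j] <- tmp
    class_label
  }
  swap_away <- function(class_label, at, banned, from_front) {
    pos <- if (from_front) ord else rev(ord)
    i <- match(at, pos)
    for (j in seq_along(pos)) {
      if (j <= i) next
      if (class_birth[pos[j]] == class_birth[at]) next  # still on the boundary
      if (!(class_label[pos[j]] %in% banned)) {
        return(swap(class_label, at, pos[j]))
      }
    }
    class_label
  }
  first_birth <- min(class_birth)
  last_birth <- max(class_birth)
  for (at in which(class_birth == first_birth)) {
    if (class_label[at] %in% need_older) {
      class_label <- swap_away(class_label, at, need_older, from_front = TRUE)
    }
  }
  for (at in which(class_birth == last_birth)) {
    if (class_label[at] %in% need_younger) {
      class_label <- swap_away(class_label, at, need_younger, from_front = FALSE)
    }
  }
  plant_anchor <- function(class_label, boundary, anchors, from_front) {
    at_boundary <- which(class_birth == boundary)
    if (any(class_label[at_boundary] %in% anchors)) return(class_label)
    pos <- if (from_front) ord else rev(ord)
    donor <- pos[which(class_label[pos] %in% anchors)[1]]
    if (is.na(donor)) return(class_label)  # no anchor label drawn at all
    swap(class_label, at_boundary[1], donor)
  }
  class_label <- plant_anchor(class_label, first_birth,
                              c("PN", "XOR_SECOND"), from_front = TRUE)
  class_label <- plant_anchor(class_label, last_birth,
                              c("PN", "XOR_FIRST"), from_front = FALSE)
  class_label
}

#' Write a generated dataset to disk
#'
#' Writes `catalog.csv`, `synapses.csv` and `truth.json` (planted labels plus
#' per-edge provenance) under `dir`.
#'
#' @param x Output of [generate()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_generated <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(x$catalog)[c("name", "birth_time")],
                   file.path(dir, "catalog.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(x$synapses),
                   file.path(dir, "synapses.csv"), row.names = FALSE)
  jsonlite::write_json(list(labels = as.list(x$truth$labels),
                            edges = x$truth$edges),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Bundled reference fixtures
#'
#' The in-text reference data shipped with the package: the five printed
#' strategy cell lists (22/4/10/8/24 class names, union 53), the 2x2
#' probabilistic strategy profile, the 300-to-400-minute family counts, the
#' published strategy frequencies, the NSY-5 gap-junction subnetwork class
#' lists, and the embryonic timeline constants.
#'
#' @return A list: `strategies` (named list of class-name vectors), `profile`
#'   (a [strategy_profile()]), `table_families` (data frame `family`,
#'   `count`), `table_frequencies` (data frame of percentages), `nsy5` (list
#'   `classes`, `pn_classes`), `timeline` (named list of minute marks).
#' @export
fixtures <- function() {
  path <- function(f) system.file("extdata", f, package = "firstmover")
  lists <- utils::read.csv(path("strategy_lists.csv"), stringsAsFactors = FALSE)
  strategies <- split(lists$cell, factor(lists$label, levels = strategy_labels()))
  prof <- jsonlite::read_json(path("first_mover_profile.json"),
                              simplifyVector = TRUE)
  list(
    strategies = strategies,
    profile = strategy_profile(prof$presynaptic$born_first,
                               prof$presynaptic$born_second,
                               prof$postsynaptic$born_first,
                               prof$postsynaptic$born_second),
    table_families = utils::read.csv(path("family_counts_300_400.csv"),
                                     stringsAsFactors = FALSE),
    table_frequencies = utils::read.csv(path("strategy_frequencies.csv"),
                                        stringsAsFactors = FALSE),
    nsy5 = jsonlite::read_json(path("nsy5_network.json"), simplifyVector = TRUE),
    timeline = jsonlite::read_json(path("timeline_constants.json"),
                                   simplifyVector = TRUE)
  )
}
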