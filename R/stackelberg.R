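# Leader-follower (Stackelberg) machinery: probabilistic strategy profiles,
# payoff utilities, and a sequential first-mover network-growth simulator.

NP_FAMILY <- c("NP", "XOR_FIRST", "XOR_SECOND", "XNOR")

#' Probabilistic strategy profile
#'
#' Joint probability over (synaptic role x birth order) for a focal cell's
#' connections: the chance that a connection finds the cell presynaptic or
#' postsynaptic to a partner born first or second. Entries are non-negative
#' and sum to 1.
#'
#' @param pre_first,pre_second,post_first,post_second Probabilities; the
#'   defaults are the bundled reference profile (0.375/0.125/0.125/0.375).
#' @return A `strategy_profile`: a 2x2 matrix with rows
#'   `presynaptic`/`postsynaptic` and columns `born_first`/`born_second`.
#' @export
strategy_profile <- function(pre_first = 0.375, pre_second = 0.125,
                             post_first = 0.125, post_second = 0.375) {
  p <- matrix(c(pre_first, pre_second, post_first, post_second),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("presynaptic", "postsynaptic"),
                              c("born_first", "born_second")))
  if (any(p < 0)) stop("profile entries must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) {
    stop("profile entries must sum to 1 (got ", sum(p), ")")
  }
  structure(p, class = c("strategy_profile", "matrix"))
}

#' Conformity probability of a profile
#'
#' The probability mass on the leader-follower heuristic: presynaptic partner
#' born first plus postsynaptic partner born second. The reference profile
#' gives 0.75.
#'
#' @param profile A [strategy_profile()] (or 2x2 matrix laid out the same way).
#' @return A probability.
#' @examples
#' conformity(strategy_profile())  # 0.75
#' @export
conformity <- function(profile) {
  if (any(profile < 0) || abs(sum(profile) - 1) > 1e-9) {
    stop("invalid strategy profile: entries must be non-negative and sum to 1")
  }
  unname(profile["presynaptic", "born_first"] +
           profile["postsynaptic", "born_second"])
}

#' Payoff matrix for a presynaptic cell
#'
#' Utilities for a presynaptic cell meeting another cell, parameterised by the
#' empirically observed frequency `FREQ`, a molecular-milieu estimate `M` and
#' a neurophysiological-milieu estimate `N`:
#' \describe{
#'   \item{(first, subsequent)}{`FREQ * (M + N)`}
#'   \item{(subsequent, first)}{`1 - FREQ * (M + N)`}
#'   \item{(first, random) and (random, first)}{`FREQ * 0.5`}
#'   \item{(subsequent, random) and (random, subsequent)}{`FREQ / 0.5` as
#'     printed (the default, `literal`); `subsequent_random = "product"`
#'     reads it as `FREQ * 0.5` instead}
#' }
#' The diagonal (self-play) is undefined. `M` and `N` are free parameters; a
#' warning is raised when `FREQ * (M + N) > 1` since utilities then leave
#' `[0, 1]`.
#'
#' @param FREQ Observed frequency in `[0, 1]`.
#' @param M,N Non-negative milieu estimates.
#' @param subsequent_random `"literal"` (default) or `"product"`.
#' @return A `payoff_matrix` object.
#' @export
payoff_matrix <- function(FREQ, M, N,
                          subsequent_random = c("literal", "product")) {
  subsequent_random <- match.arg(subsequent_random)
  stopifnot(FREQ >= 0, FREQ <= 1, M >= 0, N >= 0)
  if (FREQ * (M + N) > 1) {
    warning("FREQ * (M + N) = ", FREQ * (M + N),
            " > 1: utilities leave [0, 1]")
  }
  structure(list(FREQ = FREQ, M = M, N = N,
                 subsequent_random = subsequent_random),
            class = "payoff_matrix")
}

MOVER_TYPES <- c("first", "subsequent", "random")

#' Utility for a mover pairing
#'
#' @param matrix A [payoff_matrix()].
#' @param row,col Mover types of the focal (row) and opposing (col) cell:
#'   `"first"`, `"subsequent"` or `"random"`. `row == col` is undefined.
#' @return The utility value.
#' @export
payoff <- function(matrix, row, col) {
  row <- match.arg(row, MOVER_TYPES)
  col <- match.arg(col, MOVER_TYPES)
  if (row == col) stop("diagonal undefined: no self-play payoff")
  FREQ <- matrix$FREQ
  base <- FREQ * (matrix$M + matrix$N)
  sub_rand <- if (matrix$subsequent_random == "literal") FREQ / 0.5 else FREQ * 0.5
  key <- paste(row, col)
  switch(key,
         "first subsequent" = base,
         "subsequent first" = 1 - base,
         "first random" = FREQ * 0.5,
         "random first" = FREQ * 0.5,
         "subsequent random" = sub_rand,
         "random subsequent" = sub_rand)
}

#' Simulate strategy-driven network growth
#'
#' Cells enter the network in birth order; each entering cell initiates edges
#' to already-born cells. With probability `conformity` an edge conforms to
#' the entering cell's planted strategy: strategy-compatible partners are
#' preferred and the edge is directed so that N-P-family cells receive from
#' older cells and P-N cells project to older cells. Otherwise the direction
#' is reversed against the planted strategy (a violating edge). Stability
#' classes are drawn from `class_mix`.
#'
#' With `exact = TRUE` (the default when `conformity == 1`) the simulator
#' additionally realises each planted label's definitional predicate exactly:
#' it restricts partners to compatible strategies, adds the "signature" edges
#' that distinguish plain N-P, XOR First and XOR Second from XNOR (those
#' labels require at least one permitted counter-order connection), guarantees
#' every cell at least one connection, repairs mean-delta signs, and verifies
#' the result, so that classification recovers every planted label.
#'
#' @param birth Named numeric vector: cell name -> birth time (minutes).
#' @param strategies Named character vector: cell name -> planted label, one
#'   of [strategy_labels()] (plain `"NP"` means N-P with no refinement).
#' @param conformity Per-edge probability of conforming to the initiator's
#'   strategy, in `[0, 1]`.
#' @param attach_rate Mean number of edges initiated per entering cell
#'   (Poisson, floored at 1); must be non-negative.
#' @param class_mix Named probabilities for transient/developmental/stable.
#' @param seed Optional integer seed; a fixed seed makes output identical
#'   across runs.
#' @param exact Enforce exact planted structure (requires `conformity == 1`).
#' @param partner_kernel Optional function(candidates) -> one partner name;
#'   default uniform. Plug-in point for degree-preferential or
#'   fitness-weighted attachment.
#' @return List with `synapses` (a `synapse_table`), `truth` (one row per
#'   edge: `pre`, `post`, `initiator`, `conforming`, `phase`), `planted`
#'   (the strategies) and `birth`.
#' @export
simulate_growth <- function(birth, strategies, conformity = 0.75,
                            attach_rate = 4,
                            class_mix = c(transient = 0.43,
                                          developmental = 0.14,
                                          stable = 0.43),
                            seed = NULL,
                            exact = conformity >= 1,
                            partner_kernel = NULL) {
  if (!length(birth)) stop("birth schedule is empty")
  if (is.null(names(birth)) || anyNA(names(birth))) {
    stop("`birth` must be a named vector")
  }
  if (conformity < 0 || conformity > 1) stop("conformity must be in [0, 1]")
  if (attach_rate < 0) stop("attach_rate must be non-negative")
  if (exact && conformity < 1) {
    stop("exact planted structure requires conformity == 1")
  }
  miss <- setdiff(names(birth), names(strategies))
  if (length(miss)) {
    stop("no planted strategy for cell(s): ", paste(miss, collapse = ", "))
  }
  bad <- setdiff(unique(strategies), strategy_labels())
  if (length(bad)) stop("unknown strategy label(s): ", paste(bad, collapse = ", "))
  if (abs(sum(class_mix) - 1) > 1e-9 || any(class_mix < 0)) {
    stop("class_mix must be non-negative and sum to 1")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(partner_kernel)) {
    partner_kernel <- function(candidates) {
      candidates[sample.int(length(candidates), 1L)]
    }
  }

  ord <- names(birth)[order(birth, names(birth))]
  lab <- strategies[ord]
  b <- birth[ord]
  n <- length(ord)

  pre <- character(0); post <- character(0)
  initiator <- character(0); conf_flag <- logical(0); phase <- character(0)
  # Incremental bookkeeping keeps edge-existence checks O(1): `edge_keys`
  # holds directed "pre>post" keys, `adj` the undirected neighbour sets.
  edge_keys <- new.env(parent = emptyenv())
  adj <- new.env(parent = emptyenv())
  neighbours <- function(a) {
    if (is.null(adj[[a]])) character(0) else adj[[a]]
  }
  has_directed <- function(a, c2) !is.null(edge_keys[[paste0(a, ">", c2)]])
  add_edge <- function(p1, p2, init, conf, ph) {
    pre <<- c(pre, p1); post <<- c(post, p2)
    initiator <<- c(initiator, init); conf_flag <<- c(conf_flag, conf)
    phase <<- c(phase, ph)
    edge_keys[[paste0(p1, ">", p2)]] <- TRUE
    adj[[p1]] <- c(neighbours(p1), p2)
    adj[[p2]] <- c(neighbours(p2), p1)
  }
  is_np <- function(cells) lab[cells] %in% NP_FAMILY

  # Growth pass: each entering cell initiates edges to already-born cells.
  if (n >= 2 && attach_rate >= 0) {
    for (i in 2:n) {
      B <- ord[i]
      earlier <- ord[1:(i - 1)]
      m <- max(1L, stats::rpois(1L, attach_rate))
      for (k in seq_len(m)) {
        open <- setdiff(earlier, neighbours(B))
        if (!length(open)) break
        conf <- stats::runif(1) < conformity
        if (conf) {
          compatible <- open[is_np(open) == is_np(B)]
          if (!length(compatible)) {
            if (exact) next
            compatible <- open
          }
          A <- partner_kernel(compatible)
          if (is_np(B)) add_edge(A, B, B, TRUE, "growth")
          else add_edge(B, A, B, TRUE, "growth")
        } else {
          A <- partner_kernel(open)
          if (is_np(B)) add_edge(B, A, B, FALSE, "growth")
          else add_edge(A, B, B, FALSE, "growth")
        }
      }
    }
  }

  if (exact && n > 1) {
    # Signature pass: plain NP needs one outgoing-to-older and one
    # incoming-from-younger connection; XOR_FIRST needs outgoing-to-older;
    # XOR_SECOND needs incoming-from-younger. Targets/sources are restricted
    # to labels whose own predicate tolerates the counter-order edge.
    has_out_to_older <- function(B) any(b[post[pre == B]] < b[B])
    has_in_from_younger <- function(B) any(b[pre[post == B]] > b[B])
    need_out <- function(B) {
      cand <- ord[b < b[B] & lab %in% c("PN", "NP", "XOR_SECOND") & ord != B]
      cand <- cand[!vapply(cand, function(a) has_directed(B, a), logical(1))]
      if (!length(cand)) {
        stop("infeasible planted strategies: ", B, " (", lab[B],
             ") has no admissible older partner")
      }
      A <- cand[which.max(b[cand])]
      add_edge(B, A, B, TRUE, "signature")
    }
    need_in <- function(B) {
      cand <- ord[b > b[B] & lab %in% c("PN", "NP", "XOR_FIRST") & ord != B]
      cand <- cand[!vapply(cand, function(a) has_directed(a, B), logical(1))]
      if (!length(cand)) {
        stop("infeasible planted strategies: ", B, " (", lab[B],
             ") has no admissible younger partner")
      }
      A <- cand[which.min(b[cand])]
      add_edge(A, B, A, TRUE, "signature")
    }
    for (B in ord) {
      if (lab[B] %in% c("NP", "XOR_FIRST") && !has_out_to_older(B)) need_out(B)
      if (lab[B] %in% c("NP", "XOR_SECOND") && !has_in_from_younger(B)) need_in(B)
    }

    # Coverage pass: every cell must carry at least one connection. The
    # initiator recorded is always the younger endpoint (a cell cannot act
    # before it is born).
    for (B in ord) {
      if (length(neighbours(B))) next
      if (is_np(B)) {
        cand <- ord[ord != B & is_np(ord)]
      } else {
        cand <- ord[ord != B & !is_np(ord)]
      }
      cand <- setdiff(cand, neighbours(B))
      if (!length(cand)) {
        stop("infeasible planted strategies: ", B, " (", lab[B],
             ") has no compatible partner")
      }
      distinct <- cand[b[cand] != b[B]]
      A <- if (length(distinct)) distinct[which.min(abs(b[distinct] - b[B]))] else cand[1]
      init <- if (b[A] > b[B]) A else B
      if (is_np(B)) {
        if (b[A] <= b[B]) add_edge(A, B, init, TRUE, "coverage")
        else add_edge(B, A, init, TRUE, "coverage")
      } else {
        if (b[A] <= b[B]) add_edge(B, A, init, TRUE, "coverage")
        else add_edge(A, B, init, TRUE, "coverage")
      }
    }

    # Mean-repair pass: the base label reads the sign of the mean delta, so
    # counter-order signature edges must stay outweighed. Repairs use
    # same-family partners, which strictly improve both endpoints.
    for (iter in seq_len(20L * n)) {
      delta <- b[pre] - b[post]
      means <- vapply(ord, function(cl) {
        d <- delta[pre == cl | post == cl]
        if (length(d)) mean(d) else NA_real_
      }, numeric(1))
      bad_np <- ord[is_np(ord) & !is.na(means) & means >= 0]
      bad_pn <- ord[!is_np(ord) & !is.na(means) & means <= 0]
      if (!length(bad_np) && !length(bad_pn)) break
      B <- c(bad_np, bad_pn)[1]
      fam <- is_np(B)
      older <- ord[ord != B & is_np(ord) == fam & b < b[B]]
      younger <- ord[ord != B & is_np(ord) == fam & b > b[B]]
      if (fam) {
        older <- older[!vapply(older, function(a) has_directed(a, B), logical(1))]
        younger <- younger[!vapply(younger, function(a) has_directed(B, a), logical(1))]
      } else {
        older <- older[!vapply(older, function(a) has_directed(B, a), logical(1))]
        younger <- younger[!vapply(younger, function(a) has_directed(a, B), logical(1))]
      }
      if (fam) {
        if (length(older)) {
          A <- older[which.min(b[older])]
          add_edge(A, B, B, TRUE, "repair")
        } else if (length(younger)) {
          A <- younger[which.max(b[younger])]
          add_edge(B, A, A, TRUE, "repair")
        } else {
          stop("infeasible planted strategies: cannot repair mean for ", B)
        }
      } else {
        if (length(older)) {
          A <- older[which.min(b[older])]
          add_edge(B, A, B, TRUE, "repair")
        } else if (length(younger)) {
          A <- younger[which.max(b[younger])]
          add_edge(A, B, A, TRUE, "repair")
        } else {
          stop("infeasible planted strategies: cannot repair mean for ", B)
        }
      }
    }

    check <- check_planted(pre, post, b, lab)
    if (length(check)) {
      stop("exact simulation failed to realise planted strategies for: ",
           paste(check, collapse = ", "))
    }
  }

  stability <- if (length(pre)) {
    sample(names(class_mix), length(pre), replace = TRUE, prob = class_mix)
  } else {
    character(0)
  }
  syn <- synapse_table(pre, post, stability)
  truth <- data.frame(pre = pre, post = post, initiator = initiator,
                      conforming = conf_flag, phase = phase,
                      stringsAsFactors = FALSE)
  list(synapses = syn, truth = truth, planted = strategies, birth = birth)
}

# Which cells' incident edge sets fail their planted label's definitional
# predicate? (internal verification for exact simulations)
check_planted <- function(pre, post, b, lab) {
  bad <- character(0)
  for (cl in names(lab)) {
    d_out <- b[cl] - b[post[pre == cl]]
    d_in <- b[pre[post == cl]] - b[cl]
    d <- c(d_out, d_in)
    if (!length(d)) { bad <- c(bad, cl); next }
    m <- mean(d)
    ok <- switch(lab[[cl]],
                 PN = m > 0,
                 XNOR = m < 0 && !any(d_in > 0) && !any(d_out > 0),
                 XOR_FIRST = m < 0 && !any(d_in > 0) && any(d_out > 0),
                 XOR_SECOND = m < 0 && !any(d_out > 0) && any(d_in > 0),
                 NP = m < 0 && any(d_in > 0) && any(d_out > 0))
    if (!ok) bad <- c(bad, cl)
  }
  bad
}
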