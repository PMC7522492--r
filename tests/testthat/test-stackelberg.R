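test_that("conformity sums the leader-follower mass of a profile", {
  expect_equal(conformity(strategy_profile()), 0.75)
  expect_equal(conformity(strategy_profile(0.25, 0.25, 0.25, 0.25)), 0.5)
  expect_equal(conformity(strategy_profile(1, 0, 0, 0)), 1)
  expect_error(strategy_profile(0.5, 0.5, 0.5, 0.5), "sum to 1")
  bad <- strategy_profile()
  bad[1, 1] <- 0.9
  expect_error(conformity(bad), "invalid")
})

test_that("payoffs follow the utility formulas, including the literal cell", {
  pm <- payoff_matrix(0.5, 0.6, 0.4)
  expect_equal(payoff(pm, "first", "subsequent"), 0.5)
  expect_equal(payoff(pm, "subsequent", "first"), 0.5)
  expect_equal(payoff(pm, "first", "random"), 0.25)
  expect_equal(payoff(pm, "subsequent", "random"), 1)  # FREQ / 0.5
  expect_error(payoff(pm, "first", "first"), "diagonal")

  zero <- payoff_matrix(0, 0.6, 0.4)
  expect_equal(payoff(zero, "subsequent", "first"), 1)
  for (r in c("first", "subsequent", "random")) {
    for (co in setdiff(c("first", "subsequent", "random"), r)) {
      if (!(r == "subsequent" && co == "first")) {
        expect_equal(payoff(zero, r, co), 0)
      }
    }
  }

  set.seed(51)
  for (rep in 1:10) {
    FREQ <- runif(1); M <- runif(1); N <- runif(1, 0, 1 - M)
    pm <- payoff_matrix(FREQ, M, N)
    expect_equal(payoff(pm, "first", "subsequent"), FREQ * (M + N))
    expect_equal(payoff(pm, "subsequent", "first"), 1 - FREQ * (M + N))
    expect_equal(payoff(pm, "random", "first"), FREQ * 0.5)
    expect_equal(payoff(pm, "random", "subsequent"), FREQ / 0.5)
    alt <- payoff_matrix(FREQ, M, N, subsequent_random = "product")
    expect_equal(payoff(alt, "subsequent", "random"), FREQ * 0.5)
  }
  expect_warning(payoff_matrix(1, 2, 2), "leave")
})

test_that("growth respects temporal feasibility and seed determinism", {
  birth <- stats::setNames(c(100, 150, 200, 250, 300, 350), paste0("C", 1:6))
  strat <- stats::setNames(c("XNOR", "PN", "NP", "PN", "XOR_SECOND", "PN"),
                           names(birth))
  s1 <- simulate_growth(birth, strat, conformity = 0.6, seed = 99)
  s2 <- simulate_growth(birth, strat, conformity = 0.6, seed = 99)
  expect_identical(s1, s2)
  # the initiator of every edge is the younger (or co-born) endpoint
  partner <- ifelse(s1$truth$initiator == s1$truth$pre,
                    s1$truth$post, s1$truth$pre)
  expect_true(all(birth[partner] <= birth[s1$truth$initiator]))
  expect_error(simulate_growth(birth, strat, attach_rate = -1), "non-negative")
  expect_error(simulate_growth(birth, strat, conformity = 2), "\\[0, 1\\]")
})

test_that("two P-N cells at conformity one wire young-to-old", {
  birth <- c(early = 100, late = 200)
  strat <- c(early = "PN", late = "PN")
  sim <- simulate_growth(birth, strat, conformity = 1)
  expect_equal(nrow(sim$synapses), 1)
  expect_equal(sim$synapses$pre, "late")
  expect_equal(sim$synapses$post, "early")
})

test_that("exact growth realises planted labels for classification", {
  for (s in 1:20) {
    g <- generate(generator_spec(n_cells = 60, conformity = 1, seed = s))
    rec <- recovered_labels(g)
    expect_identical(rec[names(g$truth$labels)], g$truth$labels,
                     label = paste("seed", s))
  }
})

test_that("a partner kernel can bias attachment", {
  birth <- stats::setNames(seq(100, 190, by = 10), paste0("C", 1:10))
  strat <- stats::setNames(rep("NP", 10), names(birth))
  oldest_only <- function(cands) cands[which.min(birth[cands])]
  sim <- simulate_growth(birth, strat, conformity = 1, attach_rate = 1,
                         seed = 5, exact = FALSE, partner_kernel = oldest_only)
  grown <- sim$truth[sim$truth$phase == "growth", ]
  # every conforming growth edge connects to the oldest unconnected cell:
  # the very first partner choice is always C1
  expect_equal(grown$pre[1], "C1")
})
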