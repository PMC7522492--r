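test_that("role_summary partitions incident records by role", {
  cat <- cell_catalog(c("X", "Y", "Z"), c(120, 100, 125))
  syn <- synapse_table(c("X", "Z"), c("Y", "X"), c("stable", "stable"))
  s <- role_summary("X", syn, cat)
  expect_equal(s$pre_role_deltas, 20)   # X -> Y: 120 - 100
  expect_equal(s$post_role_deltas, 5)   # Z -> X: 125 - 120
  expect_equal(s$mean_delta_all, 12.5)
  expect_true(is.na(s$neg_component))
  expect_equal(s$pos_component, 12.5)
  expect_error(role_summary("W", syn, cat), "no incident connections")

  set.seed(31)
  for (rep in 1:10) {
    net <- random_small_network(6)
    cl <- sample(unique(c(net$edges$pre, net$edges$post)), 1)
    s <- role_summary(cl, net$synapses, net$catalog)
    d <- birth_time_difference(net$synapses, net$catalog)
    expect_equal(sort(s$pre_role_deltas), sort(d[net$synapses$pre == cl]))
    expect_equal(sort(s$post_role_deltas), sort(d[net$synapses$post == cl]))
    expect_equal(length(s$pre_role_deltas) + length(s$post_role_deltas),
                 sum(net$synapses$pre == cl) + sum(net$synapses$post == cl))
  }
})

test_that("classification follows the definitional predicates", {
  cat <- cell_catalog(c("old", "mid", "young"), c(100, 200, 300))
  # maximally conforming leader: receives from older, projects to younger
  syn <- synapse_table(c("old", "mid"), c("mid", "young"), rep("stable", 2))
  a <- classify_strategy(role_summary("mid", syn, cat))
  expect_equal(a$labels, c("NP", "XNOR"))
  # every incident delta positive -> pure P-N
  syn2 <- synapse_table(c("young", "mid"), c("mid", "old"), rep("stable", 2))
  expect_equal(classify_strategy(role_summary("mid", syn2, cat))$labels, "PN")
  # XOR Second: projects only to younger, but one presynaptic partner younger
  cat3 <- cell_catalog(c("X", "Y", "Z"), c(100, 200, 150))
  syn3 <- synapse_table(c("X", "Z"), c("Y", "X"), rep("stable", 2))
  expect_equal(classify_strategy(role_summary("X", syn3, cat3))$labels,
               c("NP", "XOR_SECOND"))
})

test_that("zero mean delta is a tie resolved by policy, without refinement", {
  cat <- cell_catalog(c("A", "B"), c(100, 100))
  syn <- synapse_table("A", "B", "stable")
  s <- role_summary("A", syn, cat)
  expect_equal(classify_strategy(s)$labels, "NP")
  expect_true(classify_strategy(s)$tie)
  expect_equal(classify_strategy(s, first_mover_policy(tie = "PN"))$labels, "PN")
  expect_length(classify_strategy(s, first_mover_policy(tie = "none"))$labels, 0)
})

test_that("exclusivity labels are mutually exclusive and PN is pure", {
  set.seed(32)
  for (rep in 1:30) {
    net <- random_small_network(sample(3:6, 1))
    a <- assign_all(net$synapses, net$catalog)
    for (labs in split_labels(a)) {
      if ("PN" %in% labs) expect_length(labs, 1)
      expect_lte(sum(c("XOR_FIRST", "XOR_SECOND", "XNOR") %in% labs), 1)
    }
  }
})

test_that("assignments are invariant to record order and deterministic", {
  set.seed(33)
  net <- random_small_network(6)
  a1 <- assign_all(net$synapses, net$catalog)
  perm <- sample(nrow(net$synapses))
  shuffled <- synapse_table(net$synapses$pre[perm], net$synapses$post[perm],
                            net$synapses$stability[perm])
  a2 <- assign_all(shuffled, net$catalog)
  expect_equal(a1, a2)
})

test_that("a single leader-ordered edge makes both endpoints strict leaders", {
  # one edge old -> young: the connection is N-P ordered for both cells,
  # and each cell's other side is vacuous, so both satisfy XNOR
  cat <- cell_catalog(c("old", "young"), c(100, 200))
  syn <- synapse_table("old", "young", "stable")
  a <- assign_all(syn, cat)
  labs <- split_labels(a)
  expect_equal(labs[["old"]], c("NP", "XNOR"))
  expect_equal(labs[["young"]], c("NP", "XNOR"))
})

test_that("classification agrees with the brute-force oracle on small networks", {
  set.seed(34)
  for (rep in 1:150) {
    net <- random_small_network(sample(3:6, 1))
    a <- assign_all(net$synapses, net$catalog)
    got <- split_labels(a)
    want <- oracle_classify(net$edges, net$birth)
    expect_identical(got[order(names(got))], want[order(names(want))])
  }
})

test_that("exclusivity tolerance admits the configured number of violations", {
  cat <- cell_catalog(c("X", "Y1", "Y2", "Y3", "Z"), c(100, 200, 210, 220, 90))
  # X projects to three younger cells and once to an older one
  syn <- synapse_table(c("X", "X", "X", "X"), c("Y1", "Y2", "Y3", "Z"),
                       rep("stable", 4))
  strict <- classify_strategy(role_summary("X", syn, cat))
  expect_equal(strict$labels, c("NP", "XOR_FIRST"))  # incoming side vacuous
  lax <- classify_strategy(role_summary("X", syn, cat),
                           first_mover_policy(exclusivity_tolerance = 1))
  expect_equal(lax$labels, c("NP", "XNOR"))
})
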