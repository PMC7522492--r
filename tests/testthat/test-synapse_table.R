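test_that("synapse_table validates classes, autapses and duplicates", {
  expect_error(synapse_table("A", "B", "sturdy"), "unknown stability")
  expect_error(synapse_table("A", "A", "stable"), "autapse")
  expect_equal(nrow(synapse_table("A", "A", "stable", allow_autapses = TRUE)), 1)

  dup <- synapse_table(c("A", "A"), c("B", "B"), c("stable", "stable"))
  expect_equal(nrow(dup), 1)
  kept <- synapse_table(c("A", "A"), c("B", "B"), c("stable", "stable"),
                        collapse_duplicates = FALSE)
  expect_equal(nrow(kept), 2)
})

test_that("load_synapses checks endpoints against the catalog", {
  cat <- cell_catalog(c("ADF", "AIY"), c(290, 400))
  path <- write_temp_csv(data.frame(pre = "ADF", post = "AIY",
                                    stability = "stable"))
  syn <- load_synapses(path, catalog = cat)
  expect_equal(nrow(syn), 1)

  # left/right cells resolve to their catalogued class
  path2 <- write_temp_csv(data.frame(pre = "ADFL", post = "AIYR",
                                     stability = "transient"))
  expect_equal(nrow(load_synapses(path2, catalog = cat)), 1)

  path3 <- write_temp_csv(data.frame(pre = "ADF", post = "NOPE",
                                     stability = "stable"))
  expect_error(load_synapses(path3, catalog = cat), "NOPE")

  empty <- tempfile(fileext = ".csv")
  file.create(empty)
  expect_equal(nrow(load_synapses(empty)), 0)
})

test_that("birth_time_difference follows the pre-minus-post convention", {
  cat <- cell_catalog(c("A", "B", "C"), c(280, 400, 280))
  expect_equal(birth_time_difference(synapse_table("A", "B", "stable"), cat), -120)
  expect_equal(birth_time_difference(synapse_table("A", "C", "stable"), cat), 0)
  # reversing pre and post negates the delta
  expect_equal(birth_time_difference(synapse_table("B", "A", "stable"), cat), 120)
})

test_that("pairwise_matrix is antisymmetric with zero diagonal", {
  one <- pairwise_matrix(cell_catalog("A", 100))
  expect_equal(unname(one), matrix(0, 1, 1))

  set.seed(21)
  for (rep in 1:5) {
    n <- sample(3:10, 1)
    cat <- cell_catalog(paste0("C", seq_len(n)), sample(0:800, n))
    m <- pairwise_matrix(cat)
    expect_equal(m, -t(m))
    expect_equal(unname(diag(m)), rep(0, n))
    brute <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      brute[i, j] <- cat$birth_time[i] - cat$birth_time[j]
    }
    expect_equal(unname(m), brute)
  }
})

test_that("difference_histogram conserves per-class totals", {
  cat <- cell_catalog(c("A", "B"), c(285, 300))
  one <- difference_histogram(synapse_table("A", "B", "stable"), cat)
  expect_equal(sum(one$count[one$stability == "stable"]), 1)
  hit <- one[one$count > 0, ]
  expect_true(hit$bin_lo <= -15 && -15 < hit$bin_hi)

  set.seed(22)
  n <- 40
  cat <- cell_catalog(paste0("C", 1:12), sample(200:400, 12))
  pre <- sample(cat$name, n, replace = TRUE)
  post <- sample(cat$name, n, replace = TRUE)
  keep <- pre != post
  cls <- sample(stability_classes(), sum(keep), replace = TRUE)
  syn <- synapse_table(pre[keep], post[keep], cls, collapse_duplicates = FALSE)
  h <- difference_histogram(syn, cat)
  for (s in unique(cls)) {
    expect_equal(sum(h$count[h$stability == s]), sum(syn$stability == s))
  }
})

test_that("GraphML export round-trips structure and attributes", {
  cat <- cell_catalog(c("A", "B", "C"), c(265, 280, 300))
  syn <- synapse_table(c("A", "B"), c("B", "C"), c("stable", "transient"))
  path <- tempfile(fileext = ".graphml")
  write_graphml(syn, cat, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::gorder(g), 3)
  expect_equal(igraph::gsize(g), 2)
  expect_setequal(igraph::edge_attr(g, "stability"), c("stable", "transient"))
  expect_setequal(igraph::vertex_attr(g, "birth_time"), c(265, 280, 300))
})
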