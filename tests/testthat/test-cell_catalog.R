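test_that("load_catalog validates and derives families and laterality", {
  path <- write_temp_csv(data.frame(name = c("RMEV", "ADFL", "AWBR"),
                                    birth_time = c(265, 280, 280)))
  cat <- load_catalog(path)
  expect_s3_class(cat, "cell_catalog")
  expect_equal(cat$birth_time[cat$name == "RMEV"], 265)
  expect_equal(cat$family[cat$name == "RMEV"], "RME")
  expect_equal(cat$laterality[cat$name == "RMEV"], "unpaired")
  expect_equal(cat$family[cat$name == "ADFL"], "ADF")
  expect_equal(cat$laterality[cat$name == "ADFL"], "left")
  expect_equal(cat$laterality[cat$name == "AWBR"], "right")

  dup <- write_temp_csv(data.frame(name = c("ADFL", "ADFL"),
                                   birth_time = c(280, 281)))
  expect_error(load_catalog(dup), "duplicate")
  neg <- write_temp_csv(data.frame(name = c("ADFL", "AWBR"),
                                   birth_time = c(280, -4)))
  expect_error(load_catalog(neg), "row.*2|2.*AWBR")

  empty <- tempfile(fileext = ".csv")
  file.create(empty)
  expect_equal(nrow(load_catalog(empty)), 0)
})

test_that("family derivation strips positional suffixes and applies overrides", {
  expect_equal(cell_family(c("RMEV", "AVDL", "AVDR", "AVL", "IL2DL", "IL2L/R",
                             "IL1VR", "URYDL", "URYVR", "OLQDL")),
               c("RME", "AV", "AV", "AV", "IL2", "IL2",
                 "IL1", "UR", "UR", "OLQ"))
})

test_that("pair expansion produces left/right cells and honours markers", {
  expect_equal(expand_pairs("AWC"), c("AWCL", "AWCR"))
  expect_equal(expand_pairs("IL2L/R"), c("IL2L", "IL2R"))
  expect_equal(expand_pairs(c("AWC", "RMEV"), unpaired = "RMEV"),
               c("AWCL", "AWCR", "RMEV"))
  # 8 classes expand to 16 cells
  expect_length(expand_pairs(fixtures()$nsy5$pn_classes), 16)
})

test_that("snapshots accrete monotonically and include births at t exactly", {
  cat <- cell_catalog(c("RMEV", "ADFL", "ADFR", "AWBL", "AWBR"),
                      c(265, 280, 280, 280, 280))
  expect_equal(snapshot(cat, 265)$members, "RMEV")
  expect_length(snapshot(cat, 280)$members, 5)
  expect_equal(snapshot(cat, 0)$members, character(0))
  expect_error(snapshot(cat, -1), "non-negative")

  set.seed(11)
  for (rep in 1:10) {
    rc <- cell_catalog(paste0("C", 1:30), sample(0:800, 30))
    ts <- sort(sample(0:800, 5))
    members <- lapply(ts, function(t) snapshot(rc, t)$members)
    for (i in 2:5) expect_true(all(members[[i - 1]] %in% members[[i]]))
  }
})

test_that("snapshot_diff equals the brute-force birth filter and partitions", {
  set.seed(12)
  rc <- cell_catalog(paste0("C", 1:40), sample(0:800, 40))
  for (rep in 1:10) {
    ts <- sort(sample(0:800, 2))
    if (ts[1] == ts[2]) next
    d <- snapshot_diff(rc, ts[1], ts[2])
    expect_setequal(d, rc$name[rc$birth_time > ts[1] & rc$birth_time <= ts[2]])
    expect_setequal(c(snapshot(rc, ts[1])$members, d), snapshot(rc, ts[2])$members)
    expect_length(intersect(snapshot(rc, ts[1])$members, d), 0)
  }
  expect_error(snapshot_diff(rc, 300, 300), "t1 < t2")
  expect_equal(snapshot_diff(cell_catalog("A", 100), 200, 300), character(0))
})

test_that("family_counts conserves totals and recovers planted prefixes", {
  expect_equal(family_counts("AVDL"),
               data.frame(family = "AV", count = 1L))
  set.seed(13)
  stems <- c("AB", "CE", "FG", "HJ", "KM")
  planted <- sample(stems, 50, replace = TRUE)
  names <- paste0(planted, rep_len(c("L", "R", "D", "V", ""), 50))
  # suffix stripping stops at two characters, so each name maps to its stem
  fc <- family_counts(names)
  expect_equal(sum(fc$count), 50)
  planted_tab <- table(planted)
  expect_equal(stats::setNames(fc$count, fc$family),
               stats::setNames(as.integer(planted_tab), names(planted_tab)))

  cat <- cell_catalog(c("AVDL", "AVDR"), c(290, 290))
  expect_error(family_counts(c("AVDL", "NOPE"), catalog = cat), "NOPE")
})

test_that("burst_histogram conserves counts and finds gap-separated bursts", {
  h1 <- burst_histogram(100)
  expect_equal(sum(h1$counts), 1)
  expect_equal(nrow(h1$bursts), 1)

  h0 <- burst_histogram(numeric(0))
  expect_equal(sum(h0$counts), 0)
  expect_equal(nrow(h0$bursts), 0)

  # three bursts separated by empty windows, the last one covering 345-365
  set.seed(14)
  times <- c(runif(40, 210, 270), runif(30, 290, 345), runif(20, 365, 400))
  h <- burst_histogram(times, bin_width = 8)
  expect_equal(sum(h$counts), 90)
  expect_equal(nrow(h$bursts), 3)
  gap_lo <- h$bursts$end[3 - 1]
  gap_hi <- h$bursts$start[3]
  expect_true(gap_lo <= 345 + 8 && gap_hi >= 365 - 8)

  # per-bin counts match a brute-force tally for arbitrary times
  for (rep in 1:5) {
    x <- runif(60, 0, 500)
    bw <- sample(c(5, 8, 16), 1)
    h <- burst_histogram(x, bin_width = bw)
    brute <- vapply(seq_len(length(h$breaks) - 1), function(i) {
      sum(x >= h$breaks[i] & x < h$breaks[i + 1])
    }, numeric(1))
    expect_equal(h$counts, as.integer(brute))
    expect_equal(sum(h$counts), 60)
  }
  expect_error(burst_histogram(1:3, bin_width = 0), "positive")
})
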