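test_that("DREAM4 time-series reader splits blank-line blocks and keeps header order", {
  genes <- c("G2", "G10", "G1")   # deliberately unsorted: order must survive
  b1 <- matrix(1:15 / 10, 5, 3)
  b2 <- matrix(16:30 / 10, 5, 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ts_fixture(path, list(b1, b2), genes, times = 0:4 * 10)

  out <- read_timeseries(path)
  expect_identical(out$genes, genes)
  expect_length(out$experiments, 2)
  expect_equal(out$experiments[[1]]$times, 0:4 * 10)
  expect_equal(unname(out$experiments[[2]]$values[, "G1"]), b2[, 3])
  expect_identical(colnames(out$experiments[[1]]$values), genes)
})

test_that("time-series reader rejects malformed input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Time\tG1\tG2", "0\t1\t2", "5\t1"), path)
  expect_error(read_timeseries(path), "ragged")

  writeLines(c("Time\tG1\tG2", "0\t1\t2", "5\t1\tfoo"), path)
  expect_error(read_timeseries(path), "non-numeric")

  writeLines(c("Time\tG1\tG2", "0\t1\t2", "5\t1\t2", "5\t1\t2"), path)
  expect_error(read_timeseries(path), "non-increasing")

  # a single 2-row block is minimal but valid
  writeLines(c("Time\tG1\tG2", "0\t1\t2", "10\t1\t2"), path)
  out <- read_timeseries(path)
  expect_length(out$experiments, 1)
  expect_equal(length(out$experiments[[1]]$times), 2)
})

test_that("steady-state reader handles bodies, empty bodies and header mismatch", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("G1\tG2\tG3", "1\t2\t3", "4\t5\t6"), path)
  out <- read_steadystate(path)
  expect_equal(dim(out$steady$values), c(2L, 3L))
  expect_identical(out$genes, c("G1", "G2", "G3"))

  writeLines("G1\tG2\tG3", path)
  out0 <- read_steadystate(path)
  expect_equal(nrow(out0$steady$values), 0L)

  expect_error(read_steadystate(path, genes = c("G1", "G3", "G2")),
               "does not match")
})

test_that("gold-standard reader applies set semantics and rejects self-edges", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("G1\tG2\t1", "G2\tG3\t0", "G1\tG2\t1"), path)
  gold <- read_gold_standard(path)
  expect_equal(nrow(gold$positive_edges), 1L)
  expect_equal(nrow(gold$known_negative_edges), 1L)

  writeLines("G1\tG1\t1", path)
  expect_error(read_gold_standard(path), "self-edge")

  writeLines("G1\tG2\t2", path)
  expect_error(read_gold_standard(path), "label")
})

test_that("ranked edge list round-trips through TSV byte-faithfully in order", {
  ranked <- data.frame(regulator = c("G1", "G3", "G2"),
                       target = c("G2", "G1", "G3"),
                       score = c(0.75, 0.5, 0.123456789))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ranked_edges(ranked, path)
  back <- read_ranked_edges(path)
  expect_identical(back$regulator, ranked$regulator)
  expect_identical(back$target, ranked$target)
  expect_equal(back$score, ranked$score, tolerance = 1e-7)

  write_ranked_edges(ranked[0, ], path)
  expect_equal(nrow(read_ranked_edges(path)), 0L)
})

test_that("dataset writers and readers are mutually inverse", {
  sim <- simulate_dataset(sample_network(6, 0.2, seed = 11),
                          n_ts_experiments = 2, T_points = 6, n_ss = 4,
                          seed = 11)
  tsp <- withr::local_tempfile(fileext = ".tsv")
  ssp <- withr::local_tempfile(fileext = ".tsv")
  gsp <- withr::local_tempfile(fileext = ".tsv")
  write_timeseries(sim$dataset$ts_experiments, tsp)
  write_steadystate(sim$dataset$steady, ssp)
  write_gold_standard(sim$gold, gsp)

  ts <- read_timeseries(tsp)
  ss <- read_steadystate(ssp)
  gold <- read_gold_standard(gsp)
  expect_identical(ts$genes, sim$dataset$genes)
  expect_length(ts$experiments, 2)
  expect_equal(ts$experiments[[1]]$values,
               sim$dataset$ts_experiments[[1]]$values, tolerance = 1e-6)
  expect_equal(ss$steady$values, sim$dataset$steady$values,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_setequal(paste(gold$positive_edges[, 1], gold$positive_edges[, 2]),
                  paste(sim$gold$positive_edges[, 1],
                        sim$gold$positive_edges[, 2]))
})

test_that("validators refuse NaN, duplicates and shape mismatches", {
  expect_error(timeseries_experiment(c(0, 1), matrix(c(1, NA, 1, 1), 2,
                                                     dimnames = list(NULL, c("a", "b")))),
               "finite")
  expect_error(expression_dataset(c("G1", "G1", "G2")), "duplicate")
  expect_error(expression_dataset(c("G1", "G2")), "must contain")
  expect_error(gold_standard(rbind(c("G1", "G1"))), "self-edge")
})
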