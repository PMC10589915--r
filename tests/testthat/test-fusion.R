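make_design <- function(X, y) {
  structure(list(features = X, responses = y,
                 provenance = rep("t", length(y))),
            class = "design_matrix")
}

test_that("a predictive feature out-ranks pure noise in both ensembles", {
  for (seed in c(1, 7, 19, 33, 55)) {
    set.seed(seed)
    X <- matrix(rnorm(400 * 2), 400, 2, dimnames = list(NULL, c("Gs", "Gn")))
    y <- X[, "Gs"] + rnorm(400, 0, 0.05)
    d <- make_design(X, y)
    vb <- fit_importances(d, "boosted", ensemble_config(seed = seed))
    vf <- fit_importances(d, "forest", ensemble_config(seed = seed))
    expect_gt(vb["Gs"], vb["Gn"])
    expect_gt(vf["Gs"], vf["Gn"])
    expect_true(all(vb >= 0) && all(vf >= 0))
  }
})

test_that("degenerate designs are handled per contract", {
  set.seed(2)
  X <- matrix(rnorm(50), 50, 1, dimnames = list(NULL, "Gs"))
  d1 <- make_design(X, X[, 1] * 2)
  expect_length(fit_importances(d1, "boosted"), 1)
  expect_gte(fit_importances(d1, "forest")[1], 0)
  dconst <- make_design(cbind(X, Gn = rnorm(50)), rep(1, 50))
  expect_warning(v <- fit_importances(dconst, "boosted"), "degenerate")
  expect_equal(unname(v), c(0, 0))
})

test_that("fusion is the elementwise product with zero annihilation", {
  expect_equal(fuse_scores(c(0.4, 0.1), c(0.9, 0.1)), c(0.36, 0.01))
  expect_equal(fuse_scores(c(0, 0.5), c(0.3, 0.5)), c(0, 0.25))
  expect_equal(fuse_scores(c(0.2, 0.7), c(1, 1)), c(0.2, 0.7))
  expect_equal(fuse_scores(c(0.3, 0.4), c(0.5, 0.6)),
               fuse_scores(c(0.5, 0.6), c(0.3, 0.4)))
  expect_error(fuse_scores(1, c(1, 2)), "length")
  expect_error(fuse_scores(-1, 1), "non-negative")
})

test_that("importance matrix honors regulator sets and composes from its factors", {
  dat <- toy_dataset(seed = 51, G = 5, T_points = 12, n_ss = 8)
  mm <- mic_matrix(dat)
  sets <- build_regulator_sets(mm, dat, 0.15, min_regulators = 2)
  ens <- ensemble_config(n_trees = 25, seed = 5)

  w <- build_importance_matrix(dat, sets, ens_cfg = ens, mode = "fused",
                               normalize = FALSE, keep_components = TRUE)
  expect_equal(diag(w$w), rep(0, 5), ignore_attr = TRUE)
  for (j in dat$genes) {
    outside <- setdiff(dat$genes, c(j, sets$sets[[j]]))
    expect_true(all(w$w[outside, j] == 0))
  }
  # fused = boosted * forest, elementwise, pre-normalization
  wb <- attr(w, "boosted")
  wf <- attr(w, "forest")
  expect_equal(w$w, wb * wf, tolerance = 1e-12)

  wb_only <- build_importance_matrix(dat, sets, ens_cfg = ens,
                                     mode = "boosted_only", normalize = FALSE)
  expect_equal(wb_only$w, wb, tolerance = 1e-12)
})

test_that("per-target normalization gives unit column sums where nonzero", {
  dat <- toy_dataset(seed = 61, G = 5)
  mm <- mic_matrix(dat)
  sets <- build_regulator_sets(mm, dat, 0.1)
  w <- build_importance_matrix(dat, sets,
                               ens_cfg = ensemble_config(n_trees = 20),
                               normalize = TRUE)
  cs <- colSums(w$w)
  expect_true(all(abs(cs[cs > 0] - 1) < 1e-12))
})

test_that("identical seeds give identical importance matrices", {
  dat <- toy_dataset(seed = 71, G = 5)
  mm <- mic_matrix(dat)
  sets <- build_regulator_sets(mm, dat, 0.15)
  ens <- ensemble_config(n_trees = 30, seed = 99)
  w1 <- build_importance_matrix(dat, sets, ens_cfg = ens)
  w2 <- build_importance_matrix(dat, sets, ens_cfg = ens)
  expect_identical(w1$w, w2$w)
})

test_that("edge ranking sorts by score with a lexicographic tie-break", {
  w <- matrix(0, 3, 3, dimnames = list(c("G1", "G2", "G3"),
                                       c("G1", "G2", "G3")))
  w["G2", "G1"] <- 0.9
  wm <- structure(list(w = w, genes = rownames(w), mode = "fused",
                       normalized = FALSE), class = "importance_matrix")
  r <- rank_edges(wm)
  expect_equal(nrow(r), 6)                       # all off-diagonal pairs
  expect_equal(r$regulator[1], "G2")
  expect_equal(r$target[1], "G1")
  # zero-score tail is pure lexicographic order
  tail_keys <- paste(r$regulator[-1], r$target[-1])
  expect_identical(tail_keys, sort(tail_keys))

  # distinct entries: full permutation matches a sort oracle
  set.seed(3)
  w2 <- matrix(runif(9), 3, 3, dimnames = dimnames(w))
  diag(w2) <- 0
  r2 <- rank_edges(w2)
  expect_equal(r2$score, sort(w2[row(w2) != col(w2)], decreasing = TRUE))
})

test_that("ranking is invariant to monotone transforms of the fused score", {
  dat <- toy_dataset(seed = 81, G = 5)
  mm <- mic_matrix(dat)
  sets <- build_regulator_sets(mm, dat, 0.1)
  w <- build_importance_matrix(dat, sets,
                               ens_cfg = ensemble_config(n_trees = 25),
                               normalize = FALSE)
  r1 <- rank_edges(w)
  wsqrt <- w
  wsqrt$w <- sqrt(w$w)
  r2 <- rank_edges(wsqrt)
  expect_identical(r1[c("regulator", "target")], r2[c("regulator", "target")])
})

test_that("importance matrix TSV round-trips", {
  dat <- toy_dataset(seed = 91, G = 4)
  mm <- mic_matrix(dat)
  sets <- build_regulator_sets(mm, dat, 0.1)
  w <- build_importance_matrix(dat, sets,
                               ens_cfg = ensemble_config(n_trees = 10))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_importance_matrix(w, path)
  back <- read_importance_matrix(path)
  expect_equal(back$w, w$w, tolerance = 1e-12)
})
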