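# Fixed 4-gene universe used by several ranking tests: 2 genes would give a
# 2-edge universe, too small for interesting curves.
toy_gold <- function() gold_standard(rbind(c("G1", "G2"), c("G1", "G3")))

ranked_df <- function(reg, tgt, score) {
  data.frame(regulator = reg, target = tgt, score = score)
}

test_that("confusion rates match their definitions with degenerate flags", {
  r <- confusion_rates(tp = 6, fp = 9, fn = 9, tn = 66)
  expect_equal(r$recall, 0.4)
  expect_equal(r$precision, 0.4)
  expect_equal(r$tpr, r$recall)
  expect_equal(r$fpr, 9 / 75)
  r0 <- confusion_rates(0, 0, 5, 10)
  expect_equal(r0$precision, 0)
  expect_true(r0$degenerate["precision"])
  rall <- confusion_rates(5, 10, 0, 0)
  expect_equal(rall$recall, 1)
  expect_error(confusion_rates(-1, 0, 0, 0), "non-negative")
})

test_that("AUROC equals exhaustive pair concordance, with tie half-credit", {
  genes <- c("A", "B", "C", "D")
  # the 4-edge toy: labels 1/0/1/0 at scores .9/.8/.7/.1 over a 4-edge strict
  # universe gives exactly 3 of 4 concordant pairs
  gold <- gold_standard(rbind(c("A", "B"), c("C", "D")),
                        rbind(c("B", "A"), c("D", "C")))
  ranked <- ranked_df(c("A", "B", "C", "D"), c("B", "A", "D", "C"),
                      c(0.9, 0.8, 0.7, 0.1))
  expect_equal(auroc(ranked, gold, genes, strict = TRUE), 0.75)

  # random instances: trapezoid-with-grouping equals Mann-Whitney enumeration
  set.seed(6)
  for (r in 1:20) {
    n <- 30
    labels <- rbinom(n, 1, 0.3)
    if (sum(labels) == 0 || sum(labels) == n) next
    scores <- round(runif(n), 2)     # rounding forces ties
    regs <- sprintf("R%d", seq_len(n))
    tgts <- rep("T0", n)
    genes_r <- c(regs, "T0")
    gold_r <- gold_standard(cbind(regs[labels == 1], "T0"),
                            cbind(regs[labels == 0], "T0"))
    a <- auroc(ranked_df(regs, tgts, scores), gold_r, genes_r, strict = TRUE)
    expect_equal(a, concordance_auroc(scores, labels), tolerance = 1e-12)
  }
})

test_that("perfect, reversed and constant rankings hit their closed forms", {
  genes <- c("G1", "G2", "G3")
  gold <- gold_standard(rbind(c("G1", "G2"), c("G2", "G3")))
  uni <- edge_universe(genes)
  key <- paste(uni$regulator, uni$target)
  pos <- key %in% c("G1 G2", "G2 G3")
  perfect <- ranked_df(uni$regulator, uni$target, ifelse(pos, 1, 0.1))
  reversed <- ranked_df(uni$regulator, uni$target, ifelse(pos, 0.1, 1))
  flat <- ranked_df(uni$regulator, uni$target, rep(0.5, nrow(uni)))
  expect_equal(auroc(perfect, gold, genes), 1)
  expect_equal(aupr(perfect, gold, genes), 1)
  expect_equal(auroc(reversed, gold, genes), 0)
  expect_equal(auroc(flat, gold, genes), 0.5)
  # a ranking and its reversal sum to 1 when scores are tie-free
  set.seed(9)
  sc <- runif(nrow(uni))
  a1 <- auroc(ranked_df(uni$regulator, uni$target, sc), gold, genes)
  a2 <- auroc(ranked_df(uni$regulator, uni$target, 1 - sc), gold, genes)
  expect_equal(a1 + a2, 1)
})

test_that("AUPR follows the threshold-sweep area and the prevalence baseline", {
  genes <- c("A", "B", "C", "D")
  gold <- gold_standard(rbind(c("A", "B"), c("C", "D")),
                        rbind(c("B", "A"), c("D", "C")))
  ranked <- ranked_df(c("A", "B", "C", "D"), c("B", "A", "D", "C"),
                      c(0.9, 0.8, 0.7, 0.1))
  # threshold cuts: (R, P) = (.5, 1), (.5, .5), (1, 2/3), (1, .5)
  expect_equal(aupr(ranked, gold, genes, strict = TRUE), 19 / 24)

  # many random scores: AUPR approaches positive prevalence
  set.seed(13)
  G <- 30
  genes_b <- sprintf("G%d", 1:G)
  uni <- edge_universe(genes_b)
  pos <- sample(nrow(uni), 150)
  gold_b <- gold_standard(cbind(uni$regulator[pos], uni$target[pos]))
  vals <- replicate(20, {
    aupr(ranked_df(uni$regulator, uni$target, runif(nrow(uni))),
         gold_b, genes_b)
  })
  prev <- 150 / nrow(uni)
  expect_lt(abs(mean(vals) - prev), 0.02)
})

test_that("overall score is the arithmetic mean", {
  expect_equal(overall_score(0.8, 0.4), 0.6)
  expect_equal(overall_score(1, 1), 1)
  expect_equal(overall_score(0, 0), 0)
})

test_that("early precision ratio matches its closed forms", {
  # n = 10 genes, k = 15 positives, 6 TPs in the top 15 -> EP .4, EPR 2.4
  n <- 10
  genes <- sprintf("G%d", 1:n)
  uni <- edge_universe(genes)
  set.seed(21)
  pos_idx <- sample(nrow(uni), 15)
  gold <- gold_standard(cbind(uni$regulator[pos_idx], uni$target[pos_idx]))
  scores <- numeric(nrow(uni))
  # put exactly 6 positives and 9 negatives in the top 15
  top <- c(pos_idx[1:6], setdiff(seq_len(nrow(uni)), pos_idx)[1:9])
  scores[top] <- seq(1, 0.9, length.out = 15)
  r <- early_precision_ratio(ranked_df(uni$regulator, uni$target, scores),
                             gold, n)
  expect_equal(r$ep, 0.4)
  expect_equal(r$epr, 0.4 / (15 / 90))
  expect_equal(r$epr, 2.4)

  # perfect top-k: EPR = n(n-1)/k
  scores2 <- numeric(nrow(uni))
  scores2[pos_idx] <- 1
  r2 <- early_precision_ratio(ranked_df(uni$regulator, uni$target, scores2),
                              gold, n)
  expect_equal(r2$epr, 90 / 15)

  # EPR is invariant to rescaling the scores
  r3 <- early_precision_ratio(ranked_df(uni$regulator, uni$target,
                                        scores * 100), gold, n)
  expect_equal(r3$epr, r$epr)
})

test_that("random permutations average EPR about 1", {
  n <- 10
  genes <- sprintf("G%d", 1:n)
  uni <- edge_universe(genes)
  set.seed(33)
  pos_idx <- sample(nrow(uni), 15)
  gold <- gold_standard(cbind(uni$regulator[pos_idx], uni$target[pos_idx]))
  n_rep <- 2000
  eprs <- replicate(n_rep, {
    early_precision_ratio(ranked_df(uni$regulator, uni$target,
                                    sample(nrow(uni))), gold, n)$epr
  })
  se <- sd(eprs) / sqrt(n_rep)
  expect_lt(abs(mean(eprs) - 1), 3 * se + 0.02)
})

test_that("metrics depend only on the ordering, not score magnitudes", {
  dat_genes <- sprintf("G%d", 1:6)
  uni <- edge_universe(dat_genes)
  set.seed(41)
  pos <- sample(nrow(uni), 6)
  gold <- gold_standard(cbind(uni$regulator[pos], uni$target[pos]))
  sc <- runif(nrow(uni))
  m1 <- evaluate_ranking(ranked_df(uni$regulator, uni$target, sc),
                         gold, dat_genes)
  m2 <- evaluate_ranking(ranked_df(uni$regulator, uni$target, sc^3),
                         gold, dat_genes)
  expect_equal(m1$auroc, m2$auroc)
  expect_equal(m1$aupr, m2$aupr)
  expect_equal(m1$epr, m2$epr)
  expect_equal(m1$overall, overall_score(m1$auroc, m1$aupr))
})

test_that("evaluate_ranking zero-pads pruned edges and reports serializably", {
  genes <- c("G1", "G2", "G3")
  gold <- gold_standard(rbind(c("G1", "G2")))
  # ranked list covers only 2 of the 6 potential edges
  ranked <- ranked_df(c("G1", "G2"), c("G2", "G1"), c(0.9, 0.5))
  m <- evaluate_ranking(ranked, gold, genes)
  expect_equal(m$n_positive + m$n_negative, 6)
  expect_equal(m$auroc, 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics(m, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$auroc, 1)
})

test_that("degenerate universes error", {
  genes <- c("G1", "G2")
  gold_all <- gold_standard(rbind(c("G1", "G2"), c("G2", "G1")))
  ranked <- ranked_df(c("G1", "G2"), c("G2", "G1"), c(1, 0.5))
  expect_error(auroc(ranked, gold_all, genes), "positive and one negative")
  expect_error(early_precision_ratio(ranked[0, ],
                                     gold_standard(rbind(c("G1", "G2"))), 2),
               "fewer than k")
})
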