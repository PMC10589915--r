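#' Confusion-matrix rates
#'
#' Recall = TP/(TP+FN) (identical to the true-positive rate), precision =
#' TP/(TP+FP) and false-positive rate = FP/(FP+TN). A zero denominator
#' yields a defined 0 with the corresponding `degenerate` flag set.
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return List with `recall`, `precision`, `tpr`, `fpr` and a logical
#'   `degenerate` vector flagging zero-denominator rates.
#' @export
confusion_rates <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("counts must be non-negative")
  safe <- function(num, den) if (den == 0) 0 else num / den
  list(recall = safe(tp, tp + fn),
       precision = safe(tp, tp + fp),
       tpr = safe(tp, tp + fn),
       fpr = safe(fp, fp + tn),
       degenerate = c(recall = (tp + fn) == 0,
                      precision = (tp + fp) == 0,
                      fpr = (fp + tn) == 0))
}

# Edge keys for fast set membership.
.edge_key <- function(reg, tgt) paste(reg, tgt, sep = "\r")

#' Evaluation edge universe
#'
#' All ordered non-self (regulator, target) pairs over the gene set,
#' restricted to regulators in the TF list when one defines the task.
#'
#' @param genes Character vector of genes.
#' @param tf_names Optional regulator restriction.
#' @return Data frame with columns `regulator`, `target`.
#' @export
edge_universe <- function(genes, tf_names = NULL) {
  regs <- if (is.null(tf_names)) genes else tf_names
  df <- expand.grid(regulator = regs, target = genes,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[df$regulator != df$target, , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Align a ranked list with a label universe: returns scores and 0/1 labels
# over the universe, with edges missing from the ranked list scored 0.
.align_ranking <- function(ranked, gold, genes, tf_names = NULL,
                           strict = FALSE, targets = NULL) {
  uni <- edge_universe(genes, tf_names)
  if (!is.null(targets)) uni <- uni[uni$target %in% targets, , drop = FALSE]
  key <- .edge_key(uni$regulator, uni$target)
  pos_key <- .edge_key(gold$positive_edges[, 1], gold$positive_edges[, 2])
  if (strict) {
    neg_key <- .edge_key(gold$known_negative_edges[, 1],
                         gold$known_negative_edges[, 2])
    keep <- key %in% c(pos_key, neg_key)
    uni <- uni[keep, , drop = FALSE]
    key <- key[keep]
  }
  labels <- as.integer(key %in% pos_key)
  scores <- numeric(length(key))
  m <- match(key, .edge_key(ranked$regulator, ranked$target))
  scores[!is.na(m)] <- ranked$score[m[!is.na(m)]]
  # deterministic full ordering: score desc, then regulator, target
  ord <- order(-scores, uni$regulator, uni$target)
  list(universe = uni[ord, , drop = FALSE], scores = scores[ord],
       labels = labels[ord])
}

# ROC / PR curve points with equal scores grouped into one threshold step.
.curve_points <- function(scores, labels) {
  P <- sum(labels == 1)
  Neg <- sum(labels == 0)
  grp <- cumsum(!duplicated(scores))     # scores arrive sorted descending
  ctp <- cumsum(labels)
  cfp <- cumsum(1 - labels)
  last <- which(!duplicated(grp, fromLast = TRUE))
  list(P = P, Neg = Neg, ctp = ctp[last], cfp = cfp[last])
}

.trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Area under the ROC curve of a ranked edge list
#'
#' Sweeps thresholds across the distinct scores (ties grouped into a single
#' step, which credits them exactly as Mann-Whitney half-credit), computes
#' the FPR/TPR points over the evaluation universe and integrates by
#' trapezoid. Edges of the universe absent from the ranked list are appended
#' with score 0.
#'
#' @param ranked Data frame (`regulator`, `target`, `score`).
#' @param gold A [gold_standard()].
#' @param genes Gene set defining the universe of potential edges.
#' @param tf_names Optional regulator restriction of the universe.
#' @param strict If `TRUE`, evaluate only explicitly labeled pairs;
#'   otherwise every unlabeled pair is a negative (DREAM convention).
#' @param targets Optional restriction of the universe to edges into these
#'   targets (used by cross-validation).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(ranked, gold, genes, tf_names = NULL, strict = FALSE,
                  targets = NULL) {
  al <- .align_ranking(ranked, gold, genes, tf_names, strict, targets)
  cp <- .curve_points(al$scores, al$labels)
  if (cp$P == 0 || cp$Neg == 0) {
    stop("universe must contain at least one positive and one negative edge")
  }
  .trapz(c(0, cp$cfp / cp$Neg), c(0, cp$ctp / cp$P))
}

#' Area under the precision-recall curve
#'
#' Same descending-threshold sweep with equal-score grouping; the curve is
#' anchored at recall 0 with the first cut's precision and integrated by
#' trapezoid across successive threshold points (segments that only lower
#' precision at constant recall contribute no area).
#'
#' @inheritParams auroc
#' @return AUPR in \[0, 1\].
#' @export
aupr <- function(ranked, gold, genes, tf_names = NULL, strict = FALSE,
                 targets = NULL) {
  al <- .align_ranking(ranked, gold, genes, tf_names, strict, targets)
  cp <- .curve_points(al$scores, al$labels)
  if (cp$P == 0 || cp$Neg == 0) {
    stop("universe must contain at least one positive and one negative edge")
  }
  rec <- cp$ctp / cp$P
  prec <- cp$ctp / (cp$ctp + cp$cfp)
  .trapz(c(0, rec), c(prec[1], prec))
}

#' Overall score
#'
#' Arithmetic mean of AUROC and AUPR.
#'
#' @param auroc,aupr Values in \[0, 1\].
#' @return `(auroc + aupr) / 2`.
#' @export
overall_score <- function(auroc, aupr) {
  stopifnot(auroc >= 0, auroc <= 1, aupr >= 0, aupr <= 1)
  (auroc + aupr) / 2
}

#' Early precision and early precision ratio
#'
#' With k the number of gold positives, early precision EP is the fraction
#' of true positives among the top-k ranked edges (deterministic tie-break
#' order). EPR divides EP by the expected precision of a random predictor,
#' the edge density `k / (n * (n - 1))` over the n-gene network; a perfect
#' top-k therefore scores `n * (n - 1) / k` and a random one about 1.
#'
#' @param ranked Ranked edge data frame.
#' @param gold A [gold_standard()].
#' @param n_genes Number of genes n defining the potential-edge count.
#' @param tf_density If `TRUE`, use `k / (|TF| * (n - 1))` as the random
#'   baseline instead (TF-restricted universes); default `FALSE`.
#' @param tf_names TF list, required when `tf_density = TRUE`.
#' @return List with `ep` and `epr`.
#' @export
early_precision_ratio <- function(ranked, gold, n_genes, tf_density = FALSE,
                                  tf_names = NULL) {
  k <- nrow(gold$positive_edges)
  if (k < 1) stop("gold standard has no positive edges")
  if (nrow(ranked) < k) stop("ranked list has fewer than k edges")
  ord <- order(-ranked$score, ranked$regulator, ranked$target)
  top <- ranked[ord[seq_len(k)], , drop = FALSE]
  pos_key <- .edge_key(gold$positive_edges[, 1], gold$positive_edges[, 2])
  tp <- sum(.edge_key(top$regulator, top$target) %in% pos_key)
  ep <- tp / k
  denom_pairs <- if (tf_density) {
    if (is.null(tf_names)) stop("tf_density = TRUE requires tf_names")
    length(tf_names) * (n_genes - 1)
  } else {
    n_genes * (n_genes - 1)
  }
  list(ep = ep, epr = ep / (k / denom_pairs))
}

#' Score a ranked edge list against a gold standard
#'
#' Composes the ranking metrics into one report: AUROC, AUPR, their mean
#' (overall score), early precision and early precision ratio, plus the
#' swept ROC and precision-recall curve points.
#'
#' @inheritParams auroc
#' @param tf_density Use the TF-restricted random baseline for EPR.
#' @return Object of class `grn_metrics`.
#' @export
evaluate_ranking <- function(ranked, gold, genes, tf_names = NULL,
                             strict = FALSE, targets = NULL,
                             tf_density = FALSE) {
  al <- .align_ranking(ranked, gold, genes, tf_names, strict, targets)
  cp <- .curve_points(al$scores, al$labels)
  if (cp$P == 0 || cp$Neg == 0) {
    stop("universe must contain at least one positive and one negative edge")
  }
  fpr <- cp$cfp / cp$Neg
  tpr <- cp$ctp / cp$P
  rec <- tpr
  prec <- cp$ctp / (cp$ctp + cp$cfp)
  au <- .trapz(c(0, fpr), c(0, tpr))
  ap <- .trapz(c(0, rec), c(prec[1], prec))
  # EP/EPR over the aligned (zero-padded) full ranking
  full <- data.frame(regulator = al$universe$regulator,
                     target = al$universe$target, score = al$scores)
  epx <- early_precision_ratio(full, gold, length(genes),
                               tf_density = tf_density, tf_names = tf_names)
  structure(list(auroc = au, aupr = ap, overall = overall_score(au, ap),
                 ep = epx$ep, epr = epx$epr,
                 n_positive = cp$P, n_negative = cp$Neg,
                 roc_curve = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)),
                 pr_curve = data.frame(recall = c(0, rec),
                                       precision = c(prec[1], prec))),
            class = "grn_metrics")
}

#' @export
print.grn_metrics <- function(x, ...) {
  cat("Network ranking metrics\n")
  cat(sprintf("  AUROC   %.4f\n  AUPR    %.4f\n  Overall %.4f\n",
              x$auroc, x$aupr, x$overall))
  cat(sprintf("  EP      %.4f\n  EPR     %.4f\n", x$ep, x$epr))
  cat(sprintf("  (%d positives / %d negatives evaluated)\n",
              x$n_positive, x$n_negative))
  invisible(x)
}

#' Serialize a metric report as JSON
#'
#' @param metrics A `grn_metrics` object.
#' @param path File path.
#' @param curves Include the ROC/PR point lists (default `FALSE`).
#' @export
write_metrics <- function(metrics, path, curves = FALSE) {
  stopifnot(inherits(metrics, "grn_metrics"))
  x <- metrics[c("auroc", "aupr", "overall", "ep", "epr",
                 "n_positive", "n_negative")]
  if (curves) x <- c(x, metrics[c("roc_curve", "pr_curve")])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
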