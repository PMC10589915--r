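# Independent oracles and small fixture builders shared across tests.

# Brute-force MIC: enumerate every admissible grid (m, n >= 2, m*n < N^alpha)
# and every placement of cut points between distinct sorted values, computing
# MI directly from a contingency table. Deliberately naive and separate from
# the package's search code.
brute_force_mic <- function(x, y, alpha = 0.6) {
  N <- length(x)
  bound <- N^alpha
  sx <- sort(unique(x))
  sy <- sort(unique(y))
  cutx <- (head(sx, -1) + tail(sx, -1)) / 2
  cuty <- (head(sy, -1) + tail(sy, -1)) / 2
  best <- 0
  for (m in 2:max(2, floor(bound / 2))) {
    for (n in 2:max(2, floor(bound / 2))) {
      if (m * n >= bound) next
      if (m - 1 > length(cutx) || n - 1 > length(cuty)) next
      cxs <- utils::combn(cutx, m - 1)
      cys <- utils::combn(cuty, n - 1)
      for (a in seq_len(ncol(cxs))) {
        xb <- findInterval(x, cxs[, a])
        for (b in seq_len(ncol(cys))) {
          yb <- findInterval(y, cys[, b])
          tb <- table(xb, yb)
          Nt <- sum(tb)
          px <- rowSums(tb) / Nt
          py <- colSums(tb) / Nt
          I <- 0
          for (i in seq_len(nrow(tb))) {
            for (j in seq_len(ncol(tb))) {
              p <- tb[i, j] / Nt
              if (p > 0) I <- I + p * log2(p / (px[i] * py[j]))
            }
          }
          v <- unname(I / log2(min(m, n)))
          if (v > best) best <- v
        }
      }
    }
  }
  best
}

# Mann-Whitney pairwise-concordance AUROC (ties get half credit).
concordance_auroc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(sp) * length(sn))
}

# A tiny deterministic dataset: 4 genes, one TS experiment + steady rows.
toy_dataset <- function(seed = 1, G = 4, T_points = 12, n_ss = 8) {
  set.seed(seed)
  genes <- sprintf("G%d", seq_len(G))
  vals <- matrix(runif(T_points * G, 0.1, 2), T_points, G,
                 dimnames = list(NULL, genes))
  ts <- timeseries_experiment(seq_len(T_points) - 1, vals)
  ss <- steadystate_matrix(matrix(runif(n_ss * G, 0.1, 2), n_ss, G,
                                  dimnames = list(NULL, genes)))
  expression_dataset(genes, list(ts), ss)
}

# DREAM4-dialect time-series text for tests that exercise the readers.
write_ts_fixture <- function(path, blocks, genes, times) {
  lines <- paste(c("Time", genes), collapse = "\t")
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    lines <- c(lines, vapply(seq_len(nrow(b)), function(i) {
      paste(c(times[i], b[i, ]), collapse = "\t")
    }, character(1)))
    if (k < length(blocks)) lines <- c(lines, "")
  }
  writeLines(lines, path)
  path
}
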