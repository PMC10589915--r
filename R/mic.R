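#' Mutual information of a discretized joint distribution
#'
#' Computes the mutual information, in bits, of the empirical joint
#' distribution given by a grid of cell counts:
#' \deqn{I(X;Y) = \sum_{x}\sum_{y} p(x,y) \log_2 \frac{p(x,y)}{p(x)p(y)},}
#' with the convention \eqn{0 \cdot \log(\cdot) = 0}. A grid with a single
#' non-empty row or column carries no dependence information and yields 0.
#'
#' @param joint_counts An m x n matrix of non-negative integer cell counts
#'   with total count at least 1.
#' @return Mutual information in bits (non-negative scalar).
#' @examples
#' mutual_information(matrix(c(2, 0, 0, 2), 2))  # 1 bit
#' mutual_information(matrix(1, 2, 2))           # 0 bits
#' @export
mutual_information <- function(joint_counts) {
  if (!is.matrix(joint_counts)) joint_counts <- as.matrix(joint_counts)
  if (!is.numeric(joint_counts) || any(!is.finite(joint_counts))) {
    stop("joint_counts must be a finite numeric matrix")
  }
  if (any(joint_counts < 0) || any(joint_counts != round(joint_counts))) {
    stop("joint_counts must contain non-negative integers")
  }
  n <- sum(joint_counts)
  if (n < 1) stop("joint_counts must have total count >= 1")
  p <- joint_counts / n
  px <- rowSums(p)
  py <- colSums(p)
  pe <- outer(px, py)
  nz <- p > 0
  val <- sum(p[nz] * log2(p[nz] / pe[nz]))
  max(val, 0)
}

# Run ids: rank of each sample among the distinct sorted values (ties share a
# run). Candidate grid cuts fall only between runs, so equal values are never
# split across bins.
.value_runs <- function(v) {
  sv <- sort(unique(v))
  list(id = match(v, sv), n = length(sv))
}

# Bin assignment for a cut set S (subset of run boundaries 1..D-1, "cut after
# run s"): bin = 1 + #{s in S : s < run}.
.bins_from_cuts <- function(run_id, cuts) {
  findInterval(run_id, cuts + 0.5) + 1L
}

# MI in bits from a flat cell-count vector, y index fastest (length m*n).
.mi_flat <- function(cnt, n_y) {
  N <- sum(cnt)
  cm <- matrix(cnt, nrow = n_y)
  px <- colSums(cm) / N
  py <- rowSums(cm) / N
  p <- cm / N
  nz <- which(p > 0)
  pe <- outer(py, px)
  sum(p[nz] * log2(p[nz] / pe[nz]))
}

# Exhaustive search over every admissible grid (m, n >= 2, m*n < bound) and
# every placement of cut points between distinct-value runs.
.mic_exact <- function(rx, ry, bound) {
  Dx <- rx$n
  Dy <- ry$n
  N <- length(rx$id)
  m_hi <- min(Dx, floor((bound - 1e-12) / 2))
  if (m_hi < 2) return(0)
  # precompute bin assignments for every axis / bin-count / cut placement
  axis_bins <- function(run, D, nb) {
    cuts <- utils::combn(D - 1L, nb - 1L)
    lapply(seq_len(ncol(cuts)), function(k) .bins_from_cuts(run, cuts[, k]))
  }
  best <- 0
  for (m in 2:m_hi) {
    n_hi <- min(Dy, floor((bound - 1e-12) / m))
    if (m * n_hi >= bound) n_hi <- n_hi - 1L
    if (n_hi < 2) next
    xb_all <- axis_bins(rx$id, Dx, m)
    for (n in 2:n_hi) {
      yb_all <- axis_bins(ry$id, Dy, n)
      norm <- log2(min(m, n))
      for (xb in xb_all) {
        xoff <- (xb - 1L) * n
        for (yb in yb_all) {
          cnt <- tabulate(xoff + yb, nbins = m * n)
          val <- .mi_flat(cnt, n) / norm
          if (val > best) best <- val
        }
      }
    }
  }
  best
}

# Equipartition run-respecting bins: assign value runs greedily to nb bins of
# ~N/nb samples each. Returns per-sample bin and the realized bin count.
.equipartition_bins <- function(run, nb) {
  tab <- tabulate(run$id, nbins = run$n)
  D <- run$n
  N <- sum(tab)
  cum <- cumsum(tab)
  bins <- integer(D)
  b <- 1L
  for (d in seq_len(D)) {
    bins[d] <- b
    if (b < nb && cum[d] >= b * N / nb) b <- b + 1L
  }
  list(sample_bins = bins[run$id], n_eff = bins[D])
}

# Dynamic-programming optimization of one axis against a fixed partition of
# the other. Points are taken in x order; candidate bin boundaries sit at
# distinct-x run ends. Each x-bin contributes additively
#   g(bin) = -(c/N) log2(c/N) + sum_y (c_y/N) log2(c_y/N)
# to H(X) - H(X,Y), so I = H(Y) + sum g is maximized by a prefix DP.
# Returns the best normalized score over k = 2..m_max x-bins.
.optimize_axis <- function(rx_ord, yb_ord, n_eff, m_max, max_boundaries) {
  N <- length(rx_ord)
  ends <- which(diff(rx_ord) != 0L)
  if (length(ends) + 1L > max_boundaries) {
    keep <- unique(round(seq(1, length(ends), length.out = max_boundaries - 1L)))
    ends <- ends[keep]
  }
  pos <- c(0L, ends, N)           # cumulative sample counts at boundaries
  B <- length(pos)
  if (B < 3) return(0)            # fewer than 2 possible bins
  m_max <- min(m_max, B - 1L)
  if (m_max < 2) return(0)

  ycum <- matrix(0, nrow = B, ncol = n_eff)
  for (j in seq_len(n_eff)) {
    ycum[, j] <- c(0, cumsum(yb_ord == j))[pos + 1L]
  }
  ytot <- ycum[B, ]
  py <- ytot / N
  Hy <- -sum(py[py > 0] * log2(py[py > 0]))

  plogp <- function(cm) {
    out <- matrix(0, nrow(cm), ncol(cm))
    ok <- cm > 0
    v <- cm[ok] / N
    out[ok] <- v * log2(v)
    out
  }
  Dtot <- -outer(pos, pos, "-")   # [a, b] = pos[b] - pos[a]
  G <- -plogp(Dtot)
  for (j in seq_len(n_eff)) {
    G <- G + plogp(-outer(ycum[, j], ycum[, j], "-"))
  }
  G[row(G) >= col(G)] <- -Inf     # only a < b defines a bin; -Inf propagates

  best <- 0
  cols <- seq_len(B)
  Fprev <- G[1, ]                 # k = 1 bins over prefix (0, pos[b]]
  for (k in 2:m_max) {
    M <- Fprev + G                # column recycling adds Fprev over rows (a)
    tM <- t(M)
    Fk <- tM[cbind(cols, max.col(tM, ties.method = "first"))]
    I_k <- Fk[B] + Hy
    val <- I_k / log2(min(k, n_eff))
    if (is.finite(val) && val > best) best <- val
    Fprev <- Fk
  }
  best
}

.mic_approx <- function(x, y, bound, max_boundaries) {
  best <- 0
  for (orient in 1:2) {
    if (orient == 2) {
      tmp <- x; x <- y; y <- tmp
    }
    rx <- .value_runs(x)
    ry <- .value_runs(y)
    if (rx$n < 2 || ry$n < 2) next
    ord <- order(x)
    rx_ord <- rx$id[ord]
    n_hi <- min(ry$n, floor((bound - 1e-12) / 2))
    if (n_hi < 2) next
    seen_neff <- integer(0)
    for (n in 2:n_hi) {
      eq <- .equipartition_bins(ry, n)
      n_eff <- eq$n_eff
      if (n_eff < 2 || n_eff %in% seen_neff) next
      seen_neff <- c(seen_neff, n_eff)
      m_max <- floor((bound - 1e-12) / n_eff)
      if (m_max < 2) next
      val <- .optimize_axis(rx_ord, eq$sample_bins[ord], n_eff, m_max,
                            max_boundaries)
      if (val > best) best <- val
    }
  }
  min(best, 1)
}

#' Maximal Information Coefficient between two vectors
#'
#' MIC is the maximum, over all grids with \eqn{m \ge 2} columns and
#' \eqn{n \ge 2} rows satisfying the size bound \eqn{m \times n < N^\alpha},
#' of the grid's mutual information normalized by \eqn{\log_2 \min(m, n)}.
#' Candidate cut points lie midway between consecutive distinct sorted sample
#' values, so tied values are never split across bins.
#'
#' For small samples (`length(x) <= exact_cutoff`) the search is exhaustive
#' over every admissible grid and cut placement. Above the cutoff one axis is
#' equipartitioned and the other optimized exactly by dynamic programming,
#' maximizing over both orientations and all admissible bin counts.
#'
#' Degenerate inputs are mapped to 0 rather than an error: a constant vector
#' has no dependence structure to measure, and a sample too small to admit
#' any 2 x 2 grid under the bound (\eqn{N^\alpha \le 4}) returns 0 with a
#' warning.
#'
#' @param x,y Numeric vectors of equal length N >= 4, all values finite.
#' @param alpha Grid-bound exponent; admissible grids satisfy
#'   `m * n < N^alpha`. Default 0.6.
#' @param exact_cutoff Largest N for which the exhaustive search is used
#'   (default 25).
#' @param max_boundaries Cap on candidate cut positions per axis in the
#'   approximate search; larger inputs are coarsened to this many boundaries.
#' @return MIC score in \[0, 1\]. Symmetric in `x` and `y`, and invariant
#'   under strictly increasing transformations of either argument.
#' @examples
#' mic(1:16, 1:16)              # 1: a median split is perfectly informative
#' mic(rnorm(50), rnorm(50))    # small: independent noise
#' @export
mic <- function(x, y, alpha = 0.6, exact_cutoff = 25, max_boundaries = 512) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (!is.numeric(x) || !is.numeric(y)) stop("x and y must be numeric")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("x and y must be finite (no NA/NaN/Inf)")
  }
  N <- length(x)
  if (N < 4) stop("need at least 4 samples")
  bound <- N^alpha
  if (bound <= 4) {
    warning("sample too small for any admissible grid (N^alpha <= 4); MIC = 0")
    return(0)
  }
  rx <- .value_runs(x)
  ry <- .value_runs(y)
  if (rx$n < 2 || ry$n < 2) return(0)   # constant marginal
  if (N <= exact_cutoff) {
    .mic_exact(rx, ry, bound)
  } else {
    .mic_approx(x, y, bound, max_boundaries)
  }
}

#' Pairwise MIC matrix over a dataset
#'
#' Pools each gene's expression into a single vector (all time points of all
#' time-series experiments in order, then all steady-state rows) and computes
#' MIC for every unordered gene pair in which at least one member is a
#' candidate regulator. Each pair is computed once and mirrored; the diagonal
#' is left `NA`.
#'
#' @param dataset An [expression_dataset()].
#' @param candidate_regulators Optional character vector of genes allowed as
#'   regulators (e.g. a transcription-factor list). Defaults to
#'   `dataset$tf_names`, or all genes when no TF list is attached. Pairs of
#'   two non-candidates are skipped and stay `NA`.
#' @param alpha,exact_cutoff,max_boundaries Passed to [mic()].
#' @param zscore If `TRUE`, each gene's pooled vector is standardized before
#'   MIC. MIC is invariant to monotone transforms so this only matters if a
#'   downstream consumer reuses the pooled vectors; default `FALSE`.
#' @return An object of class `mic_matrix`: list with `scores` (G x G
#'   symmetric matrix, `NA` diagonal) and `genes`.
#' @export
mic_matrix <- function(dataset, candidate_regulators = NULL, alpha = 0.6,
                       exact_cutoff = 25, max_boundaries = 512,
                       zscore = FALSE) {
  stopifnot(inherits(dataset, "expression_dataset"))
  genes <- dataset$genes
  G <- length(genes)
  pooled <- pooled_expression(dataset)
  if (nrow(pooled) < 4) stop("pooled sample count must be >= 4 for MIC")
  if (zscore) pooled <- scale(pooled)
  if (is.null(candidate_regulators)) {
    candidate_regulators <- if (is.null(dataset$tf_names)) genes else dataset$tf_names
  }
  bad <- setdiff(candidate_regulators, genes)
  if (length(bad)) stop("unknown candidate regulators: ", paste(bad, collapse = ", "))
  is_cand <- genes %in% candidate_regulators

  scores <- matrix(NA_real_, G, G, dimnames = list(genes, genes))
  for (i in seq_len(G - 1)) {
    for (j in (i + 1):G) {
      if (!is_cand[i] && !is_cand[j]) next
      s <- tryCatch(
        mic(pooled[, i], pooled[, j], alpha = alpha,
            exact_cutoff = exact_cutoff, max_boundaries = max_boundaries),
        error = function(e) {
          stop(sprintf("MIC failed for pair (%s, %s): %s",
                       genes[i], genes[j], conditionMessage(e)))
        })
      scores[i, j] <- s
      scores[j, i] <- s
    }
  }
  structure(list(scores = scores, genes = genes), class = "mic_matrix")
}

#' @export
print.mic_matrix <- function(x, ...) {
  v <- x$scores[upper.tri(x$scores)]
  v <- v[!is.na(v)]
  cat(sprintf("MIC matrix: %d genes, %d computed pairs\n",
              length(x$genes), length(v)))
  if (length(v)) {
    cat(sprintf("  scores: min %.3f / median %.3f / max %.3f\n",
                min(v), stats::median(v), max(v)))
  }
  invisible(x)
}

#' Write / read a MIC matrix as TSV (for caching)
#'
#' @param m A `mic_matrix`.
#' @param path File path.
#' @return `read_mic_matrix` returns a `mic_matrix`.
#' @export
write_mic_matrix <- function(m, path) {
  stopifnot(inherits(m, "mic_matrix"))
  df <- data.frame(gene = m$genes, m$scores, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mic_matrix
#' @export
read_mic_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  genes <- as.character(df[[1]])
  scores <- as.matrix(df[, -1, drop = FALSE])
  dimnames(scores) <- list(genes, genes)
  structure(list(scores = scores, genes = genes), class = "mic_matrix")
}
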