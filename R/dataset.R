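#' Time-series expression experiment
#'
#' One experiment: expression of G genes sampled at T strictly increasing
#' time points.
#'
#' @param times Numeric vector of strictly increasing time stamps (length T,
#'   arbitrary units).
#' @param values T x G numeric matrix of non-negative expression levels with
#'   gene names as column names.
#' @return Object of class `timeseries_experiment`.
#' @export
timeseries_experiment <- function(times, values) {
  values <- as.matrix(values)
  if (length(times) != nrow(values)) {
    stop("length(times) must equal nrow(values)")
  }
  if (any(!is.finite(times))) stop("times must be finite")
  if (length(times) >= 2 && any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  if (any(!is.finite(values))) stop("expression values must be finite (no NA)")
  if (any(values < 0)) stop("expression values must be non-negative")
  if (is.null(colnames(values))) stop("values must have gene names as colnames")
  structure(list(times = as.numeric(times), values = values),
            class = "timeseries_experiment")
}

#' Steady-state expression matrix
#'
#' @param values S x G numeric matrix (one row per perturbation condition)
#'   with gene names as column names; S may be 0.
#' @param condition_labels Optional character vector of length S.
#' @return Object of class `steadystate_matrix`.
#' @export
steadystate_matrix <- function(values, condition_labels = NULL) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("expression values must be finite (no NA)")
  if (any(values < 0)) stop("expression values must be non-negative")
  if (is.null(colnames(values))) stop("values must have gene names as colnames")
  if (!is.null(condition_labels) && length(condition_labels) != nrow(values)) {
    stop("condition_labels must match the number of rows")
  }
  structure(list(values = values, condition_labels = condition_labels),
            class = "steadystate_matrix")
}

.check_gene_index <- function(genes) {
  if (length(genes) < 2) stop("need at least 2 genes")
  if (anyDuplicated(genes)) stop("duplicate gene identifiers")
  if (any(!nzchar(genes)) || anyNA(genes)) stop("invalid gene identifiers")
  as.character(genes)
}

#' Expression dataset over a shared gene list
#'
#' Container combining zero or more time-series experiments and an optional
#' steady-state matrix over one canonical, ordered gene list. Gene order from
#' the constructor (or the first file header) is preserved verbatim and fixes
#' the column order of every derived matrix. Identifiers are case-sensitive.
#'
#' @param genes Character vector of unique gene identifiers (length G >= 2).
#' @param ts_experiments List of [timeseries_experiment()] objects (possibly
#'   empty); each must carry exactly the genes in `genes`, in that order.
#' @param steady Optional [steadystate_matrix()] over the same genes.
#' @param tf_names Optional character subset of `genes` permitted as
#'   regulators (transcription-factor list).
#' @return Object of class `expression_dataset`.
#' @export
expression_dataset <- function(genes, ts_experiments = list(), steady = NULL,
                               tf_names = NULL) {
  genes <- .check_gene_index(genes)
  for (e in ts_experiments) {
    stopifnot(inherits(e, "timeseries_experiment"))
    if (!identical(colnames(e$values), genes)) {
      stop("time-series experiment genes do not match the dataset gene index")
    }
  }
  if (!is.null(steady)) {
    stopifnot(inherits(steady, "steadystate_matrix"))
    if (!identical(colnames(steady$values), genes)) {
      stop("steady-state genes do not match the dataset gene index")
    }
  }
  n_ss <- if (is.null(steady)) 0L else nrow(steady$values)
  if (length(ts_experiments) == 0 && n_ss == 0) {
    stop("dataset must contain time-series experiments or steady-state rows")
  }
  if (!is.null(tf_names)) {
    tf_names <- as.character(tf_names)
    bad <- setdiff(tf_names, genes)
    if (length(bad)) stop("tf_names not in gene index: ", paste(bad, collapse = ", "))
  }
  structure(list(genes = genes, ts_experiments = ts_experiments,
                 steady = steady, tf_names = tf_names),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  n_ss <- if (is.null(x$steady)) 0L else nrow(x$steady$values)
  cat(sprintf("Expression dataset: %d genes\n", length(x$genes)))
  if (length(x$ts_experiments)) {
    cat(sprintf("  time-series: %d experiment(s), %s time points\n",
                length(x$ts_experiments),
                paste(vapply(x$ts_experiments, function(e) length(e$times),
                             integer(1)), collapse = "/")))
  }
  cat(sprintf("  steady-state conditions: %d\n", n_ss))
  if (!is.null(x$tf_names)) {
    cat(sprintf("  regulators restricted to %d TFs\n", length(x$tf_names)))
  }
  invisible(x)
}

#' Pooled per-gene expression matrix
#'
#' Stacks all time-series rows (experiments in order) and then all
#' steady-state rows into one N x G matrix; this pooled view feeds the MIC
#' computation. No rescaling is applied.
#'
#' @param dataset An [expression_dataset()].
#' @return N x G numeric matrix.
#' @export
pooled_expression <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  blocks <- lapply(dataset$ts_experiments, function(e) e$values)
  if (!is.null(dataset$steady) && nrow(dataset$steady$values) > 0) {
    blocks <- c(blocks, list(dataset$steady$values))
  }
  do.call(rbind, blocks)
}

#' Gold-standard edge labels
#'
#' @param positive_edges Two-column character matrix or data.frame of
#'   (regulator, target) pairs labeled 1.
#' @param known_negative_edges Optional pairs explicitly labeled 0.
#' @return Object of class `gold_standard` holding de-duplicated edge sets.
#' @export
gold_standard <- function(positive_edges, known_negative_edges = NULL) {
  norm <- function(x) {
    if (is.null(x) || NROW(x) == 0) {
      return(matrix(character(0), 0, 2,
                    dimnames = list(NULL, c("regulator", "target"))))
    }
    x <- as.matrix(x)
    storage.mode(x) <- "character"
    if (ncol(x) != 2) stop("edges must have two columns (regulator, target)")
    colnames(x) <- c("regulator", "target")
    if (any(x[, 1] == x[, 2])) stop("self-edges are not allowed in a gold standard")
    unique(x)
  }
  pos <- norm(positive_edges)
  neg <- norm(known_negative_edges)
  if (nrow(pos) && nrow(neg)) {
    key <- function(m) paste(m[, 1], m[, 2], sep = "\r")
    if (any(key(pos) %in% key(neg))) {
      stop("an edge cannot be both positive and known-negative")
    }
  }
  structure(list(positive_edges = pos, known_negative_edges = neg),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("Gold standard: %d positive, %d known-negative edges\n",
              nrow(x$positive_edges), nrow(x$known_negative_edges)))
  invisible(x)
}
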