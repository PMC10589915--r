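#' Read DREAM4-style time-series expression tables
#'
#' The `dream4` dialect is a tab-separated table whose header line starts
#' with a time-column label (any label is accepted) followed by gene names;
#' one or more blank lines separate successive experiments, each repeating
#' the same gene layout. The `tidy` dialect is the same format without blank
#' lines but with an extra leading `experiment` column.
#'
#' @param path Path to the file.
#' @param dialect `"dream4"` (default) or `"tidy"`.
#' @return A list with `experiments` (list of [timeseries_experiment()]) and
#'   `genes` (character vector, header order preserved verbatim).
#' @export
read_timeseries <- function(path, dialect = c("dream4", "tidy")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty time-series file: ", path)

  if (dialect == "tidy") {
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    genes <- .check_gene_index(header[-(1:2)])
    body <- lines[-1][nzchar(trimws(lines[-1]))]
    cells <- .parse_numeric_rows(body, length(header), path, skip_first = 1)
    exp_id <- vapply(body, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1],
                     character(1), USE.NAMES = FALSE)
    exps <- lapply(split(seq_along(exp_id), factor(exp_id, unique(exp_id))),
                   function(ix) {
                     m <- cells[ix, , drop = FALSE]
                     .make_ts_block(m, genes, path)
                   })
    return(list(experiments = unname(exps), genes = genes))
  }

  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 3) stop("header must list a time column and >= 2 genes")
  genes <- .check_gene_index(header[-1])
  body <- lines[-1]
  blank <- !nzchar(trimws(body))
  block_id <- cumsum(c(TRUE, blank[-length(blank)])) # grows at each blank run
  blocks <- split(body[!blank], block_id[!blank])
  if (!length(blocks)) stop("no data rows in ", path)
  exps <- lapply(blocks, function(bl) {
    m <- .parse_numeric_rows(bl, length(header), path)
    .make_ts_block(m, genes, path)
  })
  list(experiments = unname(exps), genes = genes)
}

.parse_numeric_rows <- function(lines, n_cols, path, skip_first = 0) {
  rows <- strsplit(lines, "\t", fixed = TRUE)
  lens <- lengths(rows)
  if (any(lens != n_cols)) {
    stop(sprintf("ragged row in %s: expected %d columns, found %d",
                 path, n_cols, lens[which(lens != n_cols)[1]]))
  }
  m <- matrix(NA_real_, length(rows), n_cols - skip_first)
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]][(skip_first + 1):n_cols]))
    if (anyNA(v)) stop("non-numeric cell in ", path, " at data row ", i)
    m[i, ] <- v
  }
  m
}

.make_ts_block <- function(m, genes, path) {
  times <- m[, 1]
  if (length(times) >= 2 && any(diff(times) <= 0)) {
    stop("non-increasing time stamps within an experiment in ", path)
  }
  vals <- m[, -1, drop = FALSE]
  colnames(vals) <- genes
  timeseries_experiment(times, vals)
}

#' Read a steady-state expression table
#'
#' Tab-separated matrix with a gene-name header and one row per perturbation
#' condition. A header-only file yields an S = 0 matrix.
#'
#' @param path Path to the file.
#' @param dialect Reserved; only the plain matrix dialect exists.
#' @param genes Optional gene index the header must match exactly (order
#'   included); a mismatch is an error.
#' @return A list with `steady` (a [steadystate_matrix()]) and `genes`.
#' @export
read_steadystate <- function(path, dialect = "dream4", genes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty steady-state file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  file_genes <- .check_gene_index(header)
  if (!is.null(genes) && !identical(file_genes, as.character(genes))) {
    stop("steady-state header does not match the supplied gene index")
  }
  body <- lines[-1][nzchar(trimws(lines[-1]))]
  if (length(body)) {
    m <- .parse_numeric_rows(body, length(header), path)
  } else {
    m <- matrix(numeric(0), 0, length(header))
  }
  colnames(m) <- file_genes
  list(steady = steadystate_matrix(m), genes = file_genes)
}

#' Read a transcription-factor list (one identifier per line)
#'
#' @param path Path to the file.
#' @return Character vector of unique identifiers, file order preserved.
#' @export
read_tf_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tf <- trimws(readLines(path))
  unique(tf[nzchar(tf)])
}

#' Read a gold-standard edge list
#'
#' Three tab-separated columns: regulator, target, label in {0, 1}. Label-1
#' rows become positive edges, label-0 rows known negatives; duplicates are
#' collapsed (set semantics).
#'
#' @param path Path to the file.
#' @return A [gold_standard()].
#' @export
read_gold_standard <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    stop("gold-standard file has no edges: ", path)
  }
  rows <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(rows) != 3)) stop("gold standard must have 3 tab-separated columns")
  m <- do.call(rbind, rows)
  lab <- m[, 3]
  if (!all(lab %in% c("0", "1"))) stop("gold-standard label outside {0,1} in ", path)
  if (any(m[, 1] == m[, 2])) stop("self-edge in gold standard: ", path)
  gold_standard(m[lab == "1", 1:2, drop = FALSE],
                m[lab == "0", 1:2, drop = FALSE])
}

#' Write / read a ranked edge list
#'
#' Ranked edges are written as three tab-separated columns
#' (regulator, target, score), descending score, scores with >= 6
#' significant digits; a write-then-read round trip preserves the ordering
#' exactly.
#'
#' @param ranked Data frame with columns `regulator`, `target`, `score`,
#'   already sorted (as produced by [rank_edges()]).
#' @param path File path.
#' @return `read_ranked_edges` returns the edge data frame.
#' @export
write_ranked_edges <- function(ranked, path) {
  stopifnot(is.data.frame(ranked),
            all(c("regulator", "target", "score") %in% names(ranked)))
  if (any(ranked$regulator == ranked$target)) stop("self-edges are not allowed")
  if (any(!is.finite(ranked$score)) || any(ranked$score < 0)) {
    stop("scores must be finite and non-negative")
  }
  lines <- sprintf("%s\t%s\t%s", ranked$regulator, ranked$target,
                   formatC(ranked$score, digits = 8, format = "g"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ranked_edges
#' @export
read_ranked_edges <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(regulator = character(0), target = character(0),
                      score = numeric(0)))
  }
  rows <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(rows) != 3)) stop("ranked edge file must have 3 columns")
  m <- do.call(rbind, rows)
  data.frame(regulator = m[, 1], target = m[, 2],
             score = as.numeric(m[, 3]))
}

#' Write a dataset in the DREAM4 dialect
#'
#' Companions to the readers, mainly used to materialize synthetic datasets:
#' `write_timeseries` emits blank-line-separated experiment blocks under a
#' `Time` + gene-name header, `write_steadystate` a plain matrix with a
#' gene-name header, and `write_gold_standard` the 3-column edge list
#' (positives first, then known negatives).
#'
#' @param experiments List of [timeseries_experiment()].
#' @param steady A [steadystate_matrix()].
#' @param gold A [gold_standard()].
#' @param path File path.
#' @export
write_timeseries <- function(experiments, path) {
  genes <- colnames(experiments[[1]]$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("Time", genes), collapse = "\t"), con)
  for (k in seq_along(experiments)) {
    e <- experiments[[k]]
    lines <- vapply(seq_along(e$times), function(i) {
      paste(formatC(c(e$times[i], e$values[i, ]), digits = 8, format = "g"),
            collapse = "\t")
    }, character(1))
    writeLines(lines, con)
    if (k < length(experiments)) writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_timeseries
#' @export
write_steadystate <- function(steady, path) {
  genes <- colnames(steady$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(genes, collapse = "\t"), con)
  if (nrow(steady$values)) {
    lines <- apply(steady$values, 1, function(r) {
      paste(formatC(r, digits = 8, format = "g"), collapse = "\t")
    })
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_timeseries
#' @export
write_gold_standard <- function(gold, path) {
  stopifnot(inherits(gold, "gold_standard"))
  lines <- c(sprintf("%s\t%s\t1", gold$positive_edges[, 1], gold$positive_edges[, 2]),
             sprintf("%s\t%s\t0", gold$known_negative_edges[, 1],
                     gold$known_negative_edges[, 2]))
  writeLines(lines, path)
  invisible(path)
}
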