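#' Select candidate regulators of one target by MIC thresholding
#'
#' Keeps every candidate regulator i != j whose MIC with the target strictly
#' exceeds the threshold, ordered by MIC descending (ties broken by gene
#' name). If fewer than `min_regulators` survive, the top candidates by MIC
#' are returned instead so that every target stays modelable: the screen is
#' meant to shrink the candidate set, not to drop targets.
#'
#' @param mic A [mic_matrix()].
#' @param target Target gene identifier.
#' @param threshold MIC threshold in \[0, 1\]; retention requires
#'   `MIC > threshold` (strict).
#' @param tf_restriction Optional character vector; candidates are limited to
#'   this set.
#' @param min_regulators Minimum number of regulators to return (default 3;
#'   capped at the number of available candidates).
#' @return Character vector of regulator names, MIC-descending.
#' @export
select_regulators <- function(mic, target, threshold, tf_restriction = NULL,
                              min_regulators = 3) {
  stopifnot(inherits(mic, "mic_matrix"))
  if (!target %in% mic$genes) stop("unknown target gene: ", target)
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  if (min_regulators < 1) stop("min_regulators must be >= 1")
  cand <- setdiff(mic$genes, target)
  if (!is.null(tf_restriction)) cand <- intersect(cand, tf_restriction)
  if (!length(cand)) stop("no candidate regulators available for ", target)
  s <- mic$scores[cand, target]
  if (anyNA(s)) stop("MIC undefined for some candidates of ", target)
  ord <- order(-s, cand)
  cand <- cand[ord]
  s <- s[ord]
  keep <- cand[s > threshold]
  if (length(keep) < min_regulators) {
    keep <- cand[seq_len(min(min_regulators, length(cand)))]
  }
  keep
}

#' Build pruned regulator sets for every target gene
#'
#' Applies [select_regulators()] to each gene in turn, using the dataset's
#' TF list (when present) as the candidate restriction.
#'
#' @param mic A [mic_matrix()].
#' @param dataset The [expression_dataset()] the MIC matrix was computed
#'   from (supplies gene order and the TF restriction).
#' @param threshold MIC threshold.
#' @param min_regulators Fallback minimum per target.
#' @return Object of class `regulator_sets`: named list of regulator vectors
#'   plus the threshold used.
#' @export
build_regulator_sets <- function(mic, dataset, threshold, min_regulators = 3) {
  stopifnot(inherits(dataset, "expression_dataset"))
  sets <- lapply(dataset$genes, function(j) {
    select_regulators(mic, j, threshold,
                      tf_restriction = dataset$tf_names,
                      min_regulators = min_regulators)
  })
  names(sets) <- dataset$genes
  structure(list(sets = sets, threshold_used = threshold),
            class = "regulator_sets")
}

#' @export
print.regulator_sets <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat(sprintf("Regulator sets for %d targets (MIC threshold %.3g)\n",
              length(sizes), x$threshold_used))
  cat(sprintf("  |R_j|: min %d / mean %.1f / max %d\n",
              min(sizes), mean(sizes), max(sizes)))
  invisible(x)
}

#' Serialize regulator sets as TSV (target, comma-joined regulators)
#'
#' @param sets A `regulator_sets` object.
#' @param path File path.
#' @export
write_regulator_sets <- function(sets, path) {
  stopifnot(inherits(sets, "regulator_sets"))
  lines <- sprintf("%s\t%s", names(sets$sets),
                   vapply(sets$sets, paste, character(1), collapse = ","))
  writeLines(lines, path)
  invisible(path)
}
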