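#' Pipeline configuration
#'
#' Bundles every tunable of the inference pipeline. Defaults target
#' dense/simulated expression profiles (DREAM4-like); sparse real networks
#' usually need a higher MIC threshold (searched in 0.2-0.7 by
#' [grid_search_cv()]).
#'
#' @param mic_threshold MIC retention threshold T_MIC (default 0.15, the
#'   recommended value for simulated 100-gene profiles).
#' @param alpha MIC grid-bound exponent (default 0.6).
#' @param decay,lag ODE decay constant and difference lag, see
#'   [ode_config()].
#' @param n_trees,max_depth,learning_rate,subsample,colsample,mtry,seed
#'   Ensemble hyperparameters, see [ensemble_config()].
#' @param mode `"fused"` (default) or an ablation arm: `"boosted_only"`,
#'   `"forest_only"`.
#' @param normalize Per-target unit-sum normalization of importance vectors
#'   before global ranking (default `TRUE`).
#' @param min_regulators Fallback regulator count per target (default 3).
#' @param mic_exact_cutoff,mic_max_boundaries MIC search controls, see
#'   [mic()].
#' @param zscore Standardize pooled vectors before MIC (default `FALSE`).
#' @return Object of class `grn_config`.
#' @export
grn_config <- function(mic_threshold = 0.15, alpha = 0.6, decay = 1, lag = 1L,
                       n_trees = 100, max_depth = 3, learning_rate = 0.1,
                       subsample = 1, colsample = 1, mtry = NULL, seed = 42,
                       mode = c("fused", "boosted_only", "forest_only"),
                       normalize = TRUE, min_regulators = 3,
                       mic_exact_cutoff = 25, mic_max_boundaries = 512,
                       zscore = FALSE) {
  mode <- match.arg(mode)
  if (mic_threshold < 0 || mic_threshold > 1) {
    stop("mic_threshold must be in [0, 1]")
  }
  structure(list(mic_threshold = mic_threshold, alpha = alpha, decay = decay,
                 lag = as.integer(lag), n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 learning_rate = learning_rate, subsample = subsample,
                 colsample = colsample, mtry = mtry, seed = as.integer(seed),
                 mode = mode, normalize = normalize,
                 min_regulators = as.integer(min_regulators),
                 mic_exact_cutoff = mic_exact_cutoff,
                 mic_max_boundaries = mic_max_boundaries, zscore = zscore),
            class = "grn_config")
}

.ode_cfg <- function(cfg) ode_config(decay = cfg$decay, lag = cfg$lag)
.ens_cfg <- function(cfg) {
  ensemble_config(n_trees = cfg$n_trees, max_depth = cfg$max_depth,
                  learning_rate = cfg$learning_rate, subsample = cfg$subsample,
                  colsample = cfg$colsample, mtry = cfg$mtry, seed = cfg$seed)
}

#' Infer a gene regulatory network
#'
#' The full pipeline: (1) compute pairwise MIC over pooled time-series +
#' steady-state expression, (2) prune each target's candidate regulators by
#' MIC threshold, (3) build the per-target ODE regression design, (4) fit
#' the boosted and forest ensembles and fuse their importances, (5) rank all
#' directed edges. Deterministic for fixed config and seed.
#'
#' @param dataset An [expression_dataset()].
#' @param config A [grn_config()].
#' @param targets Optional subset of genes to model; other targets keep
#'   zero columns (all potential edges are still ranked).
#' @param mic Optional precomputed [mic_matrix()] (reused by the
#'   cross-validation grid search, where it does not depend on the searched
#'   parameters).
#' @param keep_components Attach the raw per-model importance matrices (see
#'   [build_importance_matrix()]).
#' @param verbose Log per-stage counts to standard error.
#' @return Object of class `grn_fit` with elements `edges` (ranked edge data
#'   frame), `importance` (the `importance_matrix`), `regulator_sets`,
#'   `mic`, `config` and `stats`.
#' @examples
#' net <- sample_network(10, 0.15, seed = 7)
#' sim <- simulate_dataset(net, n_ts_experiments = 2, T_points = 11,
#'                         n_ss = 10, seed = 7)
#' fit <- infer_grn(sim$dataset, grn_config(n_trees = 20))
#' head(fit$edges)
#' @export
infer_grn <- function(dataset, config = grn_config(), targets = NULL,
                      mic = NULL, keep_components = FALSE, verbose = FALSE) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(config, "grn_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[3]
  G <- length(dataset$genes)
  pooled_n <- nrow(pooled_expression(dataset))
  say("stage mic: %d genes, pooled N = %d", G, pooled_n)
  if (is.null(mic)) {
    mic <- mic_matrix(dataset, alpha = config$alpha,
                      exact_cutoff = config$mic_exact_cutoff,
                      max_boundaries = config$mic_max_boundaries,
                      zscore = config$zscore)
  }
  reg_sets <- build_regulator_sets(mic, dataset, config$mic_threshold,
                                   min_regulators = config$min_regulators)
  say("stage regulators: mean |R_j| = %.1f (threshold %.3g)",
      mean(lengths(reg_sets$sets)), config$mic_threshold)
  w <- build_importance_matrix(dataset, reg_sets,
                               ode_cfg = .ode_cfg(config),
                               ens_cfg = .ens_cfg(config),
                               mode = config$mode,
                               normalize = config$normalize,
                               targets = targets,
                               keep_components = keep_components)
  edges <- rank_edges(w)
  say("stage rank: %d edges in %.1fs", nrow(edges), proc.time()[3] - t0)
  modeled <- if (is.null(targets)) dataset$genes else targets
  structure(list(edges = edges, importance = w, regulator_sets = reg_sets,
                 mic = mic, config = config,
                 stats = list(n_genes = G, pooled_n = pooled_n,
                              mean_regulators = mean(lengths(reg_sets$sets)),
                              targets_modeled = modeled,
                              elapsed = unname(proc.time()[3] - t0))),
            class = "grn_fit")
}

#' @export
print.grn_fit <- function(x, ...) {
  cat(sprintf("Inferred regulatory network (%s mode)\n", x$config$mode))
  cat(sprintf("  %d genes, %d ranked edges, mean |R_j| = %.1f\n",
              x$stats$n_genes, nrow(x$edges), x$stats$mean_regulators))
  cat("  top edges:\n")
  top <- utils::head(x$edges, 5)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("    %s -> %s  %.4g\n", top$regulator[i], top$target[i],
                top$score[i]))
  }
  invisible(x)
}

#' @export
summary.grn_fit <- function(object, ...) {
  sizes <- lengths(object$regulator_sets$sets)
  out <- list(n_genes = object$stats$n_genes,
              pooled_n = object$stats$pooled_n,
              mic_threshold = object$config$mic_threshold,
              regulators_per_target = summary(sizes),
              nonzero_edges = sum(object$edges$score > 0),
              total_edges = nrow(object$edges),
              mode = object$config$mode)
  class(out) <- "summary.grn_fit"
  out
}

#' @export
print.summary.grn_fit <- function(x, ...) {
  cat(sprintf("grn_fit: %d genes, pooled N = %d, mode = %s\n",
              x$n_genes, x$pooled_n, x$mode))
  cat(sprintf("  MIC threshold %.3g; regulators per target:\n",
              x$mic_threshold))
  print(x$regulators_per_target)
  cat(sprintf("  %d of %d potential edges have nonzero score\n",
              x$nonzero_edges, x$total_edges))
  invisible(x)
}

#' @describeIn infer_grn The fused importance matrix of a fit.
#' @param object,... S3 method arguments.
#' @export
coef.grn_fit <- function(object, ...) object$importance$w

#' @export
plot.grn_fit <- function(x, n = 20, ...) {
  top <- utils::head(x$edges[x$edges$score > 0, ], n)
  if (!nrow(top)) {
    warning("no nonzero-score edges to plot")
    return(invisible(x))
  }
  op <- graphics::par(mar = c(4, 8, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(top$score),
                    names.arg = rev(paste(top$regulator, "→", top$target)),
                    horiz = TRUE, las = 1, cex.names = 0.7,
                    xlab = "fused importance",
                    main = sprintf("Top %d inferred edges", nrow(top)))
  invisible(x)
}
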