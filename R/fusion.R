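#' Tree-ensemble configuration
#'
#' Hyperparameters for the two per-target regressors. The boosted model uses
#' total split-gain attribution for feature importance; the forest uses mean
#' impurity (node-purity) reduction — each library's canonical importance.
#'
#' @param n_trees Trees per model (default 100).
#' @param max_depth Maximum depth of boosted trees (default 3). The forest
#'   grows unpruned trees.
#' @param learning_rate Boosting shrinkage in (0, 1\] (default 0.1).
#' @param subsample Row subsampling fraction for the boosted model.
#' @param colsample Column subsampling fraction for the boosted model.
#' @param mtry Features tried per forest split; default `floor(sqrt(M))`.
#' @param seed Base random seed (default 42); per-target fits derive their
#'   own seeds from it so results do not depend on evaluation order.
#' @return Object of class `ensemble_config`.
#' @export
ensemble_config <- function(n_trees = 100, max_depth = 3, learning_rate = 0.1,
                            subsample = 1, colsample = 1, mtry = NULL,
                            seed = 42) {
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (learning_rate <= 0 || learning_rate > 1) {
    stop("learning_rate must be in (0, 1]")
  }
  structure(list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
                 learning_rate = learning_rate, subsample = subsample,
                 colsample = colsample, mtry = mtry, seed = as.integer(seed)),
            class = "ensemble_config")
}

#' Per-regulator feature importances from one tree ensemble
#'
#' Fits a gradient-boosted tree model (`model = "boosted"`) or a random
#' forest (`model = "forest"`) regressing the ODE response on the regulator
#' features, and returns one non-negative importance per regulator column.
#' Features never used in a split get importance 0. A zero-variance response
#' admits no split, so the importance vector is all zeros (with a warning).
#'
#' @param design A `design_matrix` with >= 2 rows and >= 1 feature.
#' @param model `"boosted"` or `"forest"`.
#' @param cfg An [ensemble_config()].
#' @return Named non-negative numeric vector, one entry per regulator, in
#'   design column order. Deterministic given the seed (single-threaded).
#' @export
fit_importances <- function(design, model = c("boosted", "forest"),
                            cfg = ensemble_config()) {
  model <- match.arg(model)
  stopifnot(inherits(design, "design_matrix"), inherits(cfg, "ensemble_config"))
  X <- design$features
  y <- design$responses
  if (nrow(X) < 2) stop("design needs at least 2 rows")
  if (ncol(X) < 1) stop("design needs at least 1 feature")
  out <- stats::setNames(numeric(ncol(X)), colnames(X))
  if (stats::var(y) == 0) {
    warning("degenerate (zero-variance) response; all importances are 0")
    return(out)
  }
  if (model == "boosted") {
    if (ncol(X) == 1) {
      # pad with an unsplittable constant so importance extraction sees >= 2
      # features (single-feature models trip the importance parser)
      X <- cbind(X, `.const.` = 0)
    }
    set.seed(cfg$seed)
    dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
    params <- list(objective = "reg:squarederror",
                   max_depth = cfg$max_depth,
                   eta = cfg$learning_rate,
                   subsample = cfg$subsample,
                   colsample_bytree = cfg$colsample,
                   nthread = 1,
                   seed = cfg$seed)
    fit <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = cfg$n_trees, verbose = 0)
    # pass feature names explicitly: the default getinfo(model,
    # "feature_name") path is unstable in long sessions with many boosters
    imp <- xgboost::xgb.importance(model = fit, feature_names = colnames(X))
    if (!is.null(imp) && nrow(imp)) {
      imp <- imp[imp$Feature %in% names(out), ]
      out[imp$Feature] <- imp$Gain
    }
  } else {
    mtry <- if (is.null(cfg$mtry)) max(1L, floor(sqrt(ncol(X)))) else
      min(cfg$mtry, ncol(X))
    set.seed(cfg$seed)
    fit <- randomForest::randomForest(x = X, y = y, ntree = cfg$n_trees,
                                      mtry = mtry, importance = FALSE)
    imp <- fit$importance[, "IncNodePurity", drop = FALSE]
    out[rownames(imp)] <- pmax(imp[, 1], 0)
  }
  out
}

#' Fuse two importance vectors multiplicatively
#'
#' The fused regulatory score is the elementwise product of the boosted and
#' forest importance vectors. A regulator found by only one model therefore
#' gets fused score 0 — the literal product semantics; ranking is unchanged
#' if the square root (geometric mean) is taken instead.
#'
#' @param score_boosted,score_forest Equal-length non-negative vectors.
#' @return Elementwise product.
#' @export
fuse_scores <- function(score_boosted, score_forest) {
  if (length(score_boosted) != length(score_forest)) {
    stop("importance vectors must have equal length")
  }
  if (any(score_boosted < 0) || any(score_forest < 0)) {
    stop("importances must be non-negative")
  }
  score_boosted * score_forest
}

#' Global fused importance matrix
#'
#' For each target gene: assemble its design matrix, fit the ensemble(s),
#' fuse the importances (or pass a single model through in the ablation
#' modes), optionally normalize the target's vector to unit sum, and write it
#' into the target's column of the G x G matrix `w`. Entries outside the
#' target's regulator set and the diagonal stay 0. A target whose design
#' cannot be built gets a zero column with a warning.
#'
#' @param dataset An [expression_dataset()].
#' @param reg_sets A [build_regulator_sets()] result.
#' @param ode_cfg An [ode_config()].
#' @param ens_cfg An [ensemble_config()].
#' @param mode `"fused"`, `"boosted_only"`, or `"forest_only"`.
#' @param normalize Normalize each target's importance vector to unit sum
#'   before ranking (default `TRUE`); raw products otherwise.
#' @param targets Optional subset of genes to model (others keep zero
#'   columns); used by the cross-validation driver.
#' @param keep_components If `TRUE` and `mode = "fused"`, the raw
#'   (pre-normalization) per-model matrices are attached as attributes
#'   `"boosted"` and `"forest"`.
#' @return Object of class `importance_matrix`: G x G matrix `w` with
#'   `w[i, j]` the fused importance of regulator i for target j.
#' @export
build_importance_matrix <- function(dataset, reg_sets,
                                    ode_cfg = ode_config(),
                                    ens_cfg = ensemble_config(),
                                    mode = c("fused", "boosted_only",
                                             "forest_only"),
                                    normalize = TRUE, targets = NULL,
                                    keep_components = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(reg_sets, "regulator_sets"))
  genes <- dataset$genes
  G <- length(genes)
  w <- matrix(0, G, G, dimnames = list(genes, genes))
  wb <- if (keep_components) w else NULL
  wf <- if (keep_components) w else NULL
  if (is.null(targets)) targets <- genes
  for (j in targets) {
    regs <- reg_sets$sets[[j]]
    design <- tryCatch(assemble_design(dataset, j, regs, ode_cfg),
                       error = function(e) NULL)
    if (is.null(design)) {
      warning("target ", j, " is unmodelable; zero column")
      next
    }
    tcfg <- ens_cfg
    tcfg$seed <- ens_cfg$seed + match(j, genes)
    vec <- switch(mode,
      boosted_only = fit_importances(design, "boosted", tcfg),
      forest_only = fit_importances(design, "forest", tcfg),
      fused = {
        vb <- fit_importances(design, "boosted", tcfg)
        vf <- fit_importances(design, "forest", tcfg)
        if (keep_components) {
          wb[regs, j] <- vb
          wf[regs, j] <- vf
        }
        fuse_scores(vb, vf)
      })
    if (normalize && sum(vec) > 0) vec <- vec / sum(vec)
    w[regs, j] <- vec
  }
  out <- structure(list(w = w, genes = genes, mode = mode,
                        normalized = normalize),
                   class = "importance_matrix")
  if (keep_components) {
    attr(out, "boosted") <- wb
    attr(out, "forest") <- wf
  }
  out
}

#' @export
print.importance_matrix <- function(x, ...) {
  nz <- sum(x$w > 0)
  cat(sprintf("Importance matrix (%s%s): %d genes, %d nonzero entries\n",
              x$mode, if (x$normalized) ", per-target normalized" else "",
              length(x$genes), nz))
  invisible(x)
}

#' Rank all potential edges of an importance matrix
#'
#' Flattens every off-diagonal (regulator, target) pair into a data frame
#' sorted by score descending. Ties — including the zero-score tail of edges
#' outside any regulator set, which are kept so that ranking metrics sweep
#' the full edge universe — are broken by (regulator, target) name,
#' lexicographic ascending, making the output byte-reproducible.
#'
#' @param w An `importance_matrix` (or plain G x G named matrix).
#' @return Data frame with columns `regulator`, `target`, `score`.
#' @export
rank_edges <- function(w) {
  if (inherits(w, "importance_matrix")) w <- w$w
  genes <- rownames(w)
  reg <- rep(genes, times = length(genes))
  tgt <- rep(genes, each = length(genes))
  keep <- reg != tgt
  df <- data.frame(regulator = reg[keep], target = tgt[keep],
                   score = as.vector(w)[keep])
  df <- df[order(-df$score, df$regulator, df$target), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Dump / load an importance matrix as TSV
#'
#' @param w An `importance_matrix`.
#' @param path File path.
#' @export
write_importance_matrix <- function(w, path) {
  stopifnot(inherits(w, "importance_matrix"))
  df <- data.frame(gene = w$genes, w$w, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_importance_matrix
#' @export
read_importance_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  genes <- as.character(df[[1]])
  w <- as.matrix(df[, -1, drop = FALSE])
  dimnames(w) <- list(genes, genes)
  structure(list(w = w, genes = genes, mode = "loaded", normalized = NA),
            class = "importance_matrix")
}
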