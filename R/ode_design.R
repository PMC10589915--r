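#' ODE model configuration
#'
#' The regression target for each gene follows a first-order kinetic model:
#' the rate of change of a target's expression plus a linear decay term
#' equals an unknown non-linear function of its regulators' expression.
#' Discrete time series approximate the derivative with a forward
#' difference over `lag` index steps; steady-state rows have zero derivative
#' so the target reduces to `decay * x`.
#'
#' @param decay Non-negative decay rate constant, shared across genes by
#'   default; a named numeric vector supplies per-gene overrides. Default 1.
#' @param lag Positive integer time-step lag b in index units. Default 1.
#' @return Object of class `ode_config`.
#' @export
ode_config <- function(decay = 1, lag = 1L) {
  if (any(decay < 0)) stop("decay must be non-negative")
  lag <- as.integer(lag)
  if (lag < 1) stop("lag must be >= 1")
  structure(list(decay = decay, lag = lag), class = "ode_config")
}

.decay_for <- function(cfg, target) {
  d <- cfg$decay
  if (!is.null(names(d)) && target %in% names(d)) unname(d[target]) else unname(d[1])
}

.design <- function(features, responses, provenance) {
  structure(list(features = features, responses = responses,
                 provenance = provenance),
            class = "design_matrix")
}

#' Time-series rows of the per-target design matrix
#'
#' For each time index k = 1..T-b the feature row holds the regulators'
#' expression at the earlier time t_k and the response is the forward
#' difference quotient plus decay:
#' `(x[k+b, j] - x[k, j]) / (t[k+b] - t[k]) + decay * x[k, j]`.
#'
#' @param exp A [timeseries_experiment()].
#' @param target Target gene name.
#' @param regulators Character vector of regulator names (column order of the
#'   design).
#' @param cfg An [ode_config()].
#' @param experiment_id Label used in row provenance.
#' @return A `design_matrix` with T - b rows (empty, with a warning, when
#'   T <= b).
#' @export
build_timeseries_rows <- function(exp, target, regulators, cfg = ode_config(),
                                  experiment_id = 1) {
  stopifnot(inherits(exp, "timeseries_experiment"), inherits(cfg, "ode_config"))
  b <- cfg$lag
  Tn <- length(exp$times)
  if (Tn <= b) {
    warning(sprintf("experiment has %d time points <= lag %d; no rows", Tn, b))
    return(.design(matrix(numeric(0), 0, length(regulators),
                          dimnames = list(NULL, regulators)),
                   numeric(0), character(0)))
  }
  k <- seq_len(Tn - b)
  dt <- exp$times[k + b] - exp$times[k]
  xj <- exp$values[, target]
  resp <- (xj[k + b] - xj[k]) / dt + .decay_for(cfg, target) * xj[k]
  feat <- exp$values[k, regulators, drop = FALSE]
  .design(feat, resp, sprintf("ts:%s:t%d", experiment_id, k))
}

#' Steady-state rows of the per-target design matrix
#'
#' At steady state the derivative vanishes, so the response is
#' `decay * x[e, j]` and the features are the regulators' expression in the
#' same condition; one row per condition.
#'
#' @param ss A [steadystate_matrix()].
#' @param target,regulators,cfg As in [build_timeseries_rows()].
#' @return A `design_matrix` with S rows.
#' @export
build_steadystate_rows <- function(ss, target, regulators, cfg = ode_config()) {
  stopifnot(inherits(ss, "steadystate_matrix"), inherits(cfg, "ode_config"))
  S <- nrow(ss$values)
  feat <- ss$values[, regulators, drop = FALSE]
  resp <- .decay_for(cfg, target) * ss$values[, target]
  labs <- if (!is.null(ss$condition_labels)) ss$condition_labels else
    as.character(seq_len(S))
  .design(feat, unname(resp), sprintf("ss:%s", labs))
}

#' Assemble the full design matrix for one target gene
#'
#' Vertically concatenates the time-series blocks (experiments in dataset
#' order) and then the steady-state block; the total row count is
#' `sum(T_e - lag) + S`. The target gene itself never appears among the
#' feature columns.
#'
#' @param dataset An [expression_dataset()].
#' @param target Target gene name.
#' @param regulators Regulator names; must not contain the target.
#' @param cfg An [ode_config()].
#' @return A `design_matrix`; an error if no source yields any rows.
#' @export
assemble_design <- function(dataset, target, regulators, cfg = ode_config()) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (target %in% regulators) stop("target cannot be its own regulator")
  bad <- setdiff(c(target, regulators), dataset$genes)
  if (length(bad)) stop("unknown genes: ", paste(bad, collapse = ", "))
  parts <- list()
  for (i in seq_along(dataset$ts_experiments)) {
    d <- withCallingHandlers(
      build_timeseries_rows(dataset$ts_experiments[[i]], target, regulators,
                            cfg, experiment_id = i),
      warning = function(w) invokeRestart("muffleWarning"))
    if (length(d$responses)) parts[[length(parts) + 1]] <- d
  }
  if (!is.null(dataset$steady) && nrow(dataset$steady$values) > 0) {
    parts[[length(parts) + 1]] <-
      build_steadystate_rows(dataset$steady, target, regulators, cfg)
  }
  if (!length(parts)) stop("no design rows for target ", target,
                           " (unmodelable)")
  .design(do.call(rbind, lapply(parts, `[[`, "features")),
          unlist(lapply(parts, `[[`, "responses"), use.names = FALSE),
          unlist(lapply(parts, `[[`, "provenance"), use.names = FALSE))
}

#' Dump a design matrix as TSV (provenance column included)
#'
#' @param design A `design_matrix`.
#' @param path File path.
#' @export
write_design_matrix <- function(design, path) {
  df <- data.frame(provenance = design$provenance,
                   response = design$responses,
                   design$features, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
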