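#' Scoring configuration for cell-type enrichment
#'
#' @param alpha Rank-weight exponent of the single-sample enrichment
#'   statistic (default 0.25, the ssGSEA convention).
#' @param calibration `"minmax"` (per-type min-max over the cohort to
#'   `[0, 1]`, the default cohort-relative calibration) or `"none"`.
#' @param spillover_matrix Optional cell-type x cell-type non-negative
#'   matrix with unit diagonal describing signature cross-talk; `NULL`
#'   disables spillover compensation.
#' @param kappa Spillover strength in `[0, 1]` (default 0.5).
#' @return A list of class `til_scoring_config`.
#' @export
scoring_config <- function(alpha = 0.25, calibration = c("minmax", "none"),
                           spillover_matrix = NULL, kappa = 0.5) {
  calibration <- match.arg(calibration)
  stopifnot(alpha >= 0, kappa >= 0, kappa <= 1)
  if (!is.null(spillover_matrix)) {
    if (nrow(spillover_matrix) != ncol(spillover_matrix)) {
      stop("spillover matrix must be square")
    }
    if (any(spillover_matrix < 0)) stop("spillover entries must be >= 0")
    if (any(abs(diag(spillover_matrix) - 1) > 1e-12)) {
      stop("spillover matrix diagonal must be 1")
    }
  }
  structure(list(alpha = alpha, calibration = calibration,
                 spillover_matrix = spillover_matrix, kappa = kappa),
            class = "til_scoring_config")
}

#' Rank-transform one sample's expression values
#'
#' Dense average ranks with the highest expression receiving rank `n`
#' (ties get the average of their ranks), the form the single-sample
#' enrichment statistic walks.
#'
#' @param x Numeric vector (named by gene) of one sample's expression.
#' @return Numeric vector of ranks, same names and length as `x`.
#' @export
rank_transform <- function(x) {
  if (length(x) < 2) stop("need >= 2 genes to rank")
  if (any(!is.finite(x))) stop("non-finite expression values")
  if (max(x) == min(x)) stop("all-constant expression: ranks undefined")
  rank(x, ties.method = "average")
}

#' Single-sample gene-set enrichment score
#'
#' Walks genes in decreasing rank order and accumulates the difference
#' between the weighted in-set cumulative distribution (in-set genes
#' weighted by `rank^alpha`, normalized to 1) and the uniform ECDF of
#' out-of-set genes:
#' `score = sum_i [ P_in^w(i) - P_out(i) ]`.
#'
#' @param ranks Named numeric vector of gene ranks (see [rank_transform()]).
#' @param gene_set Character vector of gene names.
#' @param alpha Rank-weight exponent (>= 0; 0 gives unweighted ECDFs).
#' @return A single finite numeric score.
#' @export
ssgsea_score <- function(ranks, gene_set, alpha = 0.25) {
  stopifnot(!is.null(names(ranks)), alpha >= 0)
  genes <- names(ranks)
  in_set <- genes %in% gene_set
  n_in <- sum(in_set)
  if (n_in == 0) stop("gene set has no overlap with the ranked universe")
  if (n_in == length(genes)) {
    stop("gene set covers the whole universe: out-of-set ECDF undefined")
  }
  # Deterministic walk order: decreasing rank, gene name as tiebreak.
  ord <- order(-ranks, genes)
  in_ord <- in_set[ord]
  w <- ifelse(in_ord, ranks[ord]^alpha, 0)
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_ord) / (length(genes) - n_in)
  sum(p_in - p_out)
}

#' Spillover-compensate a score matrix
#'
#' Models observed scores as `S_obs = S_true %*% (I + kappa * (K - I))`
#' where `K` is the unit-diagonal spillover matrix, solves the linear system
#' for `S_true`, and clamps negative solutions at 0 (clamped entries are
#' recorded in the `clamped` attribute).
#'
#' @param scores Samples x cell-types numeric matrix.
#' @param spillover_matrix Cell-type x cell-type matrix, unit diagonal,
#'   rows/columns ordered as the score columns.
#' @param kappa Spillover strength in `[0, 1]`; 0 returns `scores`
#'   unchanged.
#' @return Compensated matrix, same shape, with attribute `clamped`
#'   (number of entries clamped at 0).
#' @export
spillover_compensate <- function(scores, spillover_matrix, kappa = 0.5) {
  stopifnot(is.matrix(scores), kappa >= 0, kappa <= 1)
  if (kappa == 0) {
    attr(scores, "clamped") <- 0L
    return(scores)
  }
  k <- ncol(scores)
  if (!all(dim(spillover_matrix) == k)) {
    stop("spillover matrix must be ", k, " x ", k)
  }
  m <- diag(k) + kappa * (spillover_matrix - diag(k))
  if (abs(det(m)) < 1e-12) stop("singular spillover system at kappa = ", kappa)
  out <- scores %*% solve(m)
  clamped <- sum(out < 0)
  out[out < 0] <- 0
  dimnames(out) <- dimnames(scores)
  attr(out, "clamped") <- clamped
  out
}

calibrate_minmax <- function(scores) {
  apply(scores, 2, function(col) {
    rng <- max(col) - min(col)
    if (rng == 0) rep(0, length(col)) else (col - min(col)) / rng
  })
}

finalize_scores <- function(raw, config, estimator, samples) {
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = length(samples),
                                       dimnames = list(samples, colnames(raw)))
  cal <- switch(config$calibration,
                minmax = calibrate_minmax(raw),
                none = raw)
  if (is.matrix(cal) && nrow(raw) == 1) {
    # apply() drops to a vector for single samples; restore shape
    cal <- matrix(cal, nrow = 1, dimnames = dimnames(raw))
  }
  dimnames(cal) <- dimnames(raw)
  clamped <- 0L
  if (!is.null(config$spillover_matrix) && config$kappa > 0) {
    sp <- config$spillover_matrix[colnames(cal), colnames(cal)]
    cal <- spillover_compensate(cal, sp, config$kappa)
    clamped <- attr(cal, "clamped")
  }
  attr(cal, "provenance") <- list(estimator = estimator,
                                  alpha = config$alpha,
                                  kappa = if (is.null(config$spillover_matrix))
                                    0 else config$kappa,
                                  calibration = config$calibration,
                                  clamped = clamped)
  class(cal) <- c("til_score_matrix", class(cal))
  cal
}

#' Score cell types across a cohort by single-sample enrichment
#'
#' For each sample, rank-transforms the expression column, scores every
#' signature of every cell type with [ssgsea_score()], and averages a cell
#' type's signatures into its raw score. Raw scores are then calibrated
#' (per-type min-max over the cohort by default) and, when a spillover
#' matrix is configured, spillover-compensated.
#'
#' Signature genes absent from the expression matrix are intersected away;
#' cell types left with empty signatures are dropped with a warning.
#'
#' @param expression Genes x samples log2-scale matrix.
#' @param signatures Named list: cell type -> character vector of genes, or
#'   cell type -> list of such vectors (multiple signatures per type).
#' @param config A `til_scoring_config` (default [scoring_config()]).
#' @return A `til_score_matrix`: samples x cell types, non-negative after
#'   calibration, with a `provenance` attribute.
#' @export
score_cell_types <- function(expression, signatures, config = scoring_config()) {
  stopifnot(is.matrix(expression), length(signatures) >= 1,
            inherits(config, "til_scoring_config"))
  genes <- rownames(expression)
  samples <- colnames(expression)

  sig_list <- lapply(signatures, function(s) {
    if (!is.list(s)) s <- list(s)
    kept <- lapply(s, intersect, x = genes)
    kept[vapply(kept, length, 1L) > 0]
  })
  empty <- vapply(sig_list, length, 1L) == 0
  if (all(empty)) stop("no signature overlaps the expression gene universe")
  if (any(empty)) {
    warning("dropping cell types with no signature overlap: ",
            paste(names(sig_list)[empty], collapse = ", "))
    sig_list <- sig_list[!empty]
  }

  raw <- matrix(NA_real_, nrow = length(samples), ncol = length(sig_list),
                dimnames = list(samples, names(sig_list)))
  for (s in seq_along(samples)) {
    ranks <- rank_transform(expression[, s])
    names(ranks) <- genes
    for (ct in names(sig_list)) {
      vals <- vapply(sig_list[[ct]], function(gs)
        ssgsea_score(ranks, gs, alpha = config$alpha), numeric(1))
      raw[s, ct] <- mean(vals)
    }
  }
  finalize_scores(raw, config, estimator = "xcell-like", samples = samples)
}

#' Mean-of-marker-genes cell-type estimator
#'
#' A deliberately simple alternative estimator: a cell type's score is the
#' mean log2 expression of its signature genes. Calibration and spillover
#' follow the same configuration as [score_cell_types()], so the two
#' estimators can be compared head-to-head in the concordance analysis.
#'
#' @inheritParams score_cell_types
#' @return A `til_score_matrix` with estimator `"marker-mean"`.
#' @export
marker_mean_estimator <- function(expression, signatures,
                                  config = scoring_config()) {
  stopifnot(is.matrix(expression), length(signatures) >= 1)
  genes <- rownames(expression)
  samples <- colnames(expression)
  sig_list <- lapply(signatures, function(s) {
    if (is.list(s)) s <- unique(unlist(s))
    intersect(s, genes)
  })
  empty <- vapply(sig_list, length, 1L) == 0
  if (all(empty)) stop("no signature overlaps the expression gene universe")
  if (any(empty)) {
    warning("dropping cell types with no signature overlap: ",
            paste(names(sig_list)[empty], collapse = ", "))
    sig_list <- sig_list[!empty]
  }
  raw <- vapply(sig_list, function(gs) {
    colMeans(expression[gs, , drop = FALSE])
  }, numeric(length(samples)))
  if (is.null(dim(raw))) {
    raw <- matrix(raw, nrow = 1, dimnames = list(samples, names(sig_list)))
  }
  finalize_scores(raw, config, estimator = "marker-mean", samples = samples)
}

#' Default synthetic spillover matrix for a set of cell types
#'
#' Packaged stand-in for score cross-talk between related cell types: unit
#' diagonal, a constant off-diagonal level within the lymphocyte block
#' (closely related lymphocyte populations co-vary and their rank-based
#' scores bleed into each other) and zero elsewhere. Compensating with this
#' matrix (and clamping at zero) suppresses the shared-infiltration
#' component of each subset score.
#'
#' @param x A `til_reference_panel` or a character vector of cell types.
#' @param within_lymphocyte Off-diagonal spill level among lymphocyte types
#'   (default 0.1).
#' @return Cell-type x cell-type matrix with unit diagonal.
#' @export
default_spillover_matrix <- function(x, within_lymphocyte = 0.1) {
  ct <- if (inherits(x, "til_reference_panel")) x$cell_types else x
  k <- matrix(0, length(ct), length(ct), dimnames = list(ct, ct))
  lymph <- intersect(lymphocyte_types(), ct)
  k[lymph, lymph] <- within_lymphocyte
  diag(k) <- 1
  k
}
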