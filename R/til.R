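#' Composite intratumoral TIL score
#'
#' Sums the 19 lymphocyte cell-type scores into the per-sample TIL score and
#' attaches the log2 display transform `log2(raw + epsilon)`.
#'
#' @param scores Samples x cell-types matrix (e.g. from
#'   [score_cell_types()]); all configured lymphocyte types must be present
#'   and non-negative.
#' @param lymphocytes Character vector of lymphocyte cell types to sum
#'   (default [lymphocyte_types()], the 19-type panel).
#' @param epsilon Positive offset of the log2 display transform
#'   (default 1e-3).
#' @param subtype Optional character vector of per-sample subtypes (aligned
#'   to `rownames(scores)`); carried into the output for dichotomization.
#' @return Data frame of class `til_score_table`: `sample_id`, `raw`,
#'   `log2`, `subtype` (NA when not given), `group` (NA until
#'   [dichotomize_by_median()]).
#' @export
compute_til_score <- function(scores, lymphocytes = lymphocyte_types(),
                              epsilon = 1e-3, subtype = NULL) {
  stopifnot(is.matrix(scores) || is.data.frame(scores), epsilon > 0)
  scores <- as.matrix(scores)
  missing <- setdiff(lymphocytes, colnames(scores))
  if (length(missing)) {
    stop("score matrix is missing lymphocyte types: ",
         paste(missing, collapse = ", "))
  }
  sub <- scores[, lymphocytes, drop = FALSE]
  if (any(sub < 0)) stop("negative cell-type scores are not admissible")
  raw <- rowSums(sub)
  out <- data.frame(
    sample_id = rownames(scores) %||% as.character(seq_len(nrow(scores))),
    raw = unname(raw),
    log2 = unname(log2(raw + epsilon)),
    subtype = if (is.null(subtype)) NA_character_ else as.character(subtype),
    group = NA_character_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("til_score_table", class(out))
  out
}

#' Split TIL scores into high/low groups at the per-subtype median
#'
#' Within each subtype, samples whose score is greater than or equal to that
#' subtype's median go to the `high` group, the rest to `low`. With distinct
#' scores and odd n the high group gets `(n + 1) / 2` members; the split is
#' invariant under any strictly monotone transform of the scores.
#'
#' @param til A `til_score_table` from [compute_til_score()].
#' @param subtype Optional per-sample subtype vector overriding the table's
#'   `subtype` column.
#' @param value Which column to split on: `"raw"` (default) or `"log2"`
#'   (identical groups when scores are distinct).
#' @return The table with `group` filled in.
#' @export
dichotomize_by_median <- function(til, subtype = NULL, value = c("raw", "log2")) {
  stopifnot(inherits(til, "til_score_table"))
  value <- match.arg(value)
  st <- if (is.null(subtype)) til$subtype else as.character(subtype)
  if (anyNA(st)) stop("subtype must be known for every sample")
  x <- til[[value]]
  for (s in unique(st)) {
    i <- which(st == s)
    if (length(i) < 2) stop("subtype ", s, " has < 2 samples")
    med <- median(x[i])
    at_median <- sum(x[i] == med)
    if (at_median > 0.2 * length(i)) {
      warning("subtype ", s, ": ", at_median, "/", length(i),
              " scores tie at the median; high/low split is unstable")
    }
    til$group[i] <- ifelse(x[i] >= med, "high", "low")
  }
  til$subtype <- st
  til
}

#' Concordance of candidate TIL estimators with reference signals
#'
#' Spearman rank correlation (average-rank ties) of each candidate
#' per-sample summary against lymphocyte marker-gene expression (CD3D, CD4,
#' CD8A, FOXP3, PDCD1) and, when present in the clinical table, the
#' pathology TIL regional fraction.
#'
#' @param candidates Named list of per-sample numeric vectors (aligned to
#'   the expression columns).
#' @param expression Genes x samples matrix holding the marker genes.
#' @param clinical Optional clinical data.frame with `sample_id` and
#'   `path_til_fraction`.
#' @param marker_genes Reference marker genes (default the five lymphocyte
#'   markers).
#' @return Matrix of class `til_concordance` (candidates x reference
#'   signals) of Spearman correlations; attribute `dropped` records
#'   reference signals that were unavailable.
#' @export
estimator_concordance <- function(candidates, expression, clinical = NULL,
                                  marker_genes = c("CD3D", "CD4", "CD8A",
                                                   "FOXP3", "PDCD1")) {
  stopifnot(length(candidates) >= 1, !is.null(names(candidates)),
            is.matrix(expression), ncol(expression) >= 3)
  samples <- colnames(expression)
  refs <- list()
  dropped <- character(0)
  for (g in marker_genes) {
    if (g %in% rownames(expression)) refs[[g]] <- expression[g, ]
    else dropped <- c(dropped, g)
  }
  if (!is.null(clinical) && "path_til_fraction" %in% names(clinical)) {
    v <- clinical$path_til_fraction[match(samples, clinical$sample_id)]
    if (any(!is.na(v))) refs[["path_til_fraction"]] <- v
    else dropped <- c(dropped, "path_til_fraction")
  }
  if (!length(refs)) stop("no reference signal available")

  out <- matrix(NA_real_, nrow = length(candidates), ncol = length(refs),
                dimnames = list(names(candidates), names(refs)))
  for (cand in names(candidates)) {
    v <- candidates[[cand]]
    if (length(v) != length(samples)) {
      stop("candidate ", cand, " length differs from the sample set")
    }
    if (length(unique(v)) == 1) {
      stop("candidate ", cand, " is constant: Spearman undefined")
    }
    for (r in names(refs)) {
      ok <- !is.na(refs[[r]])
      out[cand, r] <- cor(v[ok], refs[[r]][ok], method = "spearman")
    }
  }
  attr(out, "dropped") <- dropped
  class(out) <- c("til_concordance", class(out))
  out
}

#' Select the best TIL estimator from a concordance matrix
#'
#' Picks the candidate with the highest mean correlation across reference
#' signals; ties broken lexicographically (reported via attribute `tied`).
#'
#' @param concordance Matrix from [estimator_concordance()].
#' @return Character scalar: the winning candidate name.
#' @export
select_estimator <- function(concordance) {
  stopifnot(nrow(concordance) >= 1)
  means <- rowMeans(concordance)
  best <- max(means)
  winners <- sort(names(means)[means == best])
  out <- winners[1]
  attr(out, "tied") <- if (length(winners) > 1) winners else character(0)
  attr(out, "row_means") <- means
  out
}

#' Build the standard candidate summaries for the concordance analysis
#'
#' Whole-lymphocyte and whole-T-cell sums for each supplied estimator's
#' score matrix.
#'
#' @param score_matrices Named list of samples x cell-types matrices
#'   (e.g. `list(xcell_like = ..., marker_mean = ...)`).
#' @return Named list of per-sample numeric vectors
#'   (`<estimator>_whole_lymphocytes`, `<estimator>_whole_tcells`).
#' @export
til_candidates <- function(score_matrices) {
  stopifnot(length(score_matrices) >= 1, !is.null(names(score_matrices)))
  out <- list()
  for (nm in names(score_matrices)) {
    m <- as.matrix(score_matrices[[nm]])
    ly <- intersect(lymphocyte_types(), colnames(m))
    tc <- intersect(tcell_types(), colnames(m))
    if (length(ly)) {
      out[[paste0(nm, "_whole_lymphocytes")]] <- rowSums(m[, ly, drop = FALSE])
    }
    if (length(tc)) {
      out[[paste0(nm, "_whole_tcells")]] <- rowSums(m[, tc, drop = FALSE])
    }
  }
  out
}
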