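#' Read a genes-x-samples expression matrix from TSV
#'
#' First column holds gene symbols; remaining columns are samples of
#' log2-scale normalized expression.
#'
#' @param path Path to TSV file.
#' @return Numeric matrix, genes in rows (rownames), samples in columns.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs a gene column plus >= 1 sample")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) stop("duplicated gene symbols in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Write a genes-x-samples expression matrix to TSV
#'
#' @param expr Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample clinical table from TSV
#'
#' @param path Path to TSV with at least a `sample_id` column; typically also
#'   `subtype`, `grade`, `pcr`, `os_months`, `os_event`, `path_til_fraction`
#'   and precomputed mutation-metric columns.
#' @return A data.frame, one row per sample.
#' @export
read_clinical <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("clinical table lacks sample_id column")
  df
}

#' Write a clinical table to TSV
#' @param clinical Data frame with a `sample_id` column.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_clinical <- function(clinical, path) {
  write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes within a set are dropped.
#'
#' @param path Path to GMT file.
#' @return Named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("malformed GMT line ", i, " in ", path,
           " (needs name, description, >= 1 gene)")
    }
    sets[[fields[1]]] <- unique(fields[-(1:2)])
  }
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions
#'   (recycled; defaults to `"na"`).
#' @return Invisibly `path`.
#' @export
write_gmt <- function(sets, path, descriptions = "na") {
  stopifnot(length(sets) >= 1, !is.null(names(sets)))
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a samples-x-cell-types score matrix with a provenance header
#'
#' @param scores A `til_score_matrix` (see [score_cell_types()]).
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_scores <- function(scores, path) {
  prov <- attr(scores, "provenance")
  header <- sprintf("# estimator=%s, alpha=%s, kappa=%s",
                    prov$estimator %||% "unknown",
                    prov$alpha %||% "NA", prov$kappa %||% "NA")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  df <- data.frame(sample_id = rownames(scores), unclass(scores),
                   check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score matrix written by [write_scores()]
#' @param path Path to scores TSV.
#' @return Numeric samples-x-cell-types matrix with `provenance` attribute.
#' @export
read_scores <- function(path) {
  first <- readLines(path, n = 1)
  skip <- if (startsWith(first, "#")) 1L else 0L
  df <- read.delim(path, skip = skip, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  if (skip) attr(m, "provenance") <- list(header = first)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
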