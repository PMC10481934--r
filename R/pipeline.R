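#' Configuration of a full pipeline run
#'
#' @param expression Path to the genes x samples expression TSV.
#' @param clinical Path to the clinical TSV.
#' @param signatures Path to the cell-type signature GMT.
#' @param pathways Optional path to a pathway GMT for GSEA (skipped when
#'   `NULL`).
#' @param out_dir Output directory for all result files.
#' @param scoring A `til_scoring_config`.
#' @param lymphocytes Lymphocyte types summed into the TIL score.
#' @param epsilon Offset of the log2 display transform.
#' @param n_perm GSEA permutations per subtype (default 200).
#' @param alpha Significance level for the comparison battery (default
#'   0.05).
#' @param seed Integer seed propagated to every stochastic stage.
#' @return List of class `til_run_config`.
#' @export
run_config <- function(expression, clinical, signatures, pathways = NULL,
                       out_dir, scoring = scoring_config(),
                       lymphocytes = lymphocyte_types(), epsilon = 1e-3,
                       n_perm = 200, alpha = 0.05, seed = 1) {
  structure(list(expression = expression, clinical = clinical,
                 signatures = signatures, pathways = pathways,
                 out_dir = out_dir, scoring = scoring,
                 lymphocytes = lymphocytes, epsilon = epsilon,
                 n_perm = n_perm, alpha = alpha, seed = as.integer(seed)),
            class = "til_run_config")
}

#' Validate pipeline inputs without mutating them
#'
#' Checks file existence, expression/clinical sample alignment, required
#' clinical columns, subtype vocabulary, positive survival times, and GMT
#' syntax. Violations are aggregated, not thrown.
#'
#' @param paths Named list/character with `expression`, `clinical`,
#'   `signatures`, optionally `pathways`.
#' @return Character vector of human-readable violations (empty when
#'   clean).
#' @export
validate_inputs <- function(paths) {
  v <- character(0)
  need <- c("expression", "clinical", "signatures")
  for (k in need) {
    if (is.null(paths[[k]])) v <- c(v, paste0("missing path: ", k))
    else if (!file.exists(paths[[k]])) {
      v <- c(v, paste0(k, " file not found: ", paths[[k]]))
    }
  }
  if (length(v)) return(v)

  expr <- tryCatch(read_expression(paths$expression), error = function(e) e)
  if (inherits(expr, "error")) {
    return(c(v, paste0("expression unreadable: ", conditionMessage(expr))))
  }
  clin <- tryCatch(read_clinical(paths$clinical), error = function(e) e)
  if (inherits(clin, "error")) {
    return(c(v, paste0("clinical unreadable: ", conditionMessage(clin))))
  }

  required_cols <- c("sample_id", "subtype", "os_months", "os_event", "pcr")
  miss <- setdiff(required_cols, names(clin))
  if (length(miss)) {
    v <- c(v, paste0("clinical table lacks column(s): ",
                     paste(miss, collapse = ", ")))
  }
  absent <- setdiff(clin$sample_id, colnames(expr))
  if (length(absent)) {
    v <- c(v, paste0("clinical sample(s) absent from expression: ",
                     paste(head(absent, 10), collapse = ", ")))
  }
  extra <- setdiff(colnames(expr), clin$sample_id)
  if (length(extra)) {
    v <- c(v, paste0("expression sample(s) absent from clinical: ",
                     paste(head(extra, 10), collapse = ", ")))
  }
  if ("subtype" %in% names(clin)) {
    bad <- setdiff(unique(clin$subtype), c("ER_HER2neg", "HER2pos", "TNBC"))
    if (length(bad)) {
      v <- c(v, paste0("unknown subtype label(s): ",
                       paste(bad, collapse = ", ")))
    }
  }
  if ("os_months" %in% names(clin) &&
      any(clin$os_months <= 0, na.rm = TRUE)) {
    v <- c(v, "non-positive survival times in os_months")
  }

  for (k in c("signatures", "pathways")) {
    if (is.null(paths[[k]])) next
    lines <- readLines(paths[[k]], warn = FALSE)
    lines <- lines[nzchar(lines)]
    for (i in seq_along(lines)) {
      if (length(strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]) < 3) {
        v <- c(v, paste0(k, " GMT line ", i, " malformed (< 3 fields)"))
      }
    }
  }
  v
}

stage <- function(report, name, fn) {
  res <- tryCatch(fn(), error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  report$stages[[name]] <- "ok"
  list(report = report, value = res)
}

#' Run the full TIL analysis pipeline
#'
#' simulate-free orchestration: reads the inputs, scores cell types with
#' the single-sample enrichment and marker-mean estimators, runs the
#' estimator-concordance selection, builds and dichotomizes the TIL score,
#' runs per-subtype GSEA of the supplied pathway collection, and the
#' outcome battery (CYT, myeloid/stromal/mutation comparisons, grade,
#' pCR, survival). All tables are written under `config$out_dir` together
#' with a machine-readable JSON report.
#'
#' @param config A `til_run_config` from [run_config()].
#' @return The run report (list): per-stage status, file manifest, and
#'   headline tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "til_run_config"))
  violations <- validate_inputs(config[c("expression", "clinical",
                                         "signatures", "pathways")])
  if (length(violations)) {
    stop("stage 'validate' failed:\n  ", paste(violations, collapse = "\n  "),
         call. = FALSE)
  }
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  report <- list(stages = list(validate = "ok"), manifest = character(0),
                 headline = list(),
                 version = as.character(packageVersion("tilquant")),
                 seed = config$seed)
  emit <- function(df, file) {
    path <- file.path(config$out_dir, file)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    report$manifest <<- c(report$manifest, path)
    path
  }

  expr <- read_expression(config$expression)
  clin <- read_clinical(config$clinical)
  clin <- clin[match(colnames(expr), clin$sample_id), ]
  sigs <- group_signatures(read_gmt(config$signatures))
  report$stages$read <- "ok"

  # -- scoring ------------------------------------------------------------
  # spillover compensation with the packaged synthetic matrix unless the
  # caller configured one (or explicitly set kappa = 0)
  if (is.null(config$scoring$spillover_matrix) && config$scoring$kappa > 0) {
    config$scoring$spillover_matrix <- default_spillover_matrix(names(sigs))
  }
  scores_ssgsea <- score_cell_types(expr, sigs, config$scoring)
  scores_marker <- marker_mean_estimator(expr, sigs, config$scoring)
  write_scores(scores_ssgsea, file.path(config$out_dir, "scores_ssgsea.tsv"))
  write_scores(scores_marker, file.path(config$out_dir, "scores_marker_mean.tsv"))
  report$manifest <- c(report$manifest,
                       file.path(config$out_dir, "scores_ssgsea.tsv"),
                       file.path(config$out_dir, "scores_marker_mean.tsv"))
  report$stages$score <- "ok"

  # -- estimator concordance ---------------------------------------------
  candidates <- til_candidates(list(xcell_like = scores_ssgsea,
                                    marker_mean = scores_marker))
  conc <- estimator_concordance(candidates, expr, clin)
  best <- select_estimator(conc)
  emit(data.frame(candidate = rownames(conc), unclass(conc),
                  row_mean = rowMeans(conc), check.names = FALSE),
       "concordance.tsv")
  report$headline$selected_estimator <- as.character(best)
  report$stages$concordance <- "ok"

  # -- TIL score + median split ------------------------------------------
  til <- compute_til_score(scores_ssgsea, lymphocytes = config$lymphocytes,
                           epsilon = config$epsilon, subtype = clin$subtype)
  til <- dichotomize_by_median(til)
  emit(til, "til_scores.tsv")
  groups <- setNames(til$group, til$sample_id)
  med_tbl <- vapply(split(til$log2, til$subtype), median, numeric(1))
  report$headline$median_log2_til <- as.list(med_tbl)
  report$stages$til_score <- "ok"

  # -- GSEA per subtype ---------------------------------------------------
  if (!is.null(config$pathways)) {
    pw <- read_gmt(config$pathways)
    gsea_all <- list()
    for (s in unique(til$subtype)) {
      i <- til$subtype == s
      res <- run_gsea(expr[, til$sample_id[i], drop = FALSE],
                      til$group[i], pw, n_perm = config$n_perm,
                      seed = config$seed)
      res$subtype <- s
      gsea_all[[s]] <- res
    }
    gsea_tbl <- do.call(rbind, gsea_all)
    emit(gsea_tbl, "gsea.tsv")
    report$headline$significant_gene_sets <- list(
      high = sum(gsea_tbl$significant & gsea_tbl$side == "high"),
      low = sum(gsea_tbl$significant & gsea_tbl$side == "low")
    )
    report$stages$gsea <- "ok"
  } else {
    report$stages$gsea <- "skipped"
  }

  # -- outcome battery ----------------------------------------------------
  meta <- clin
  meta$cyt <- tryCatch(cyt_score(expr)[meta$sample_id], error = function(e) NA)
  if ("MKI67" %in% rownames(expr)) meta$mki67 <- expr["MKI67", meta$sample_id]
  cell_cols <- intersect(c("Dendritic_cells", "Macrophages", "Monocytes",
                           "Mast_cells", "Adipocytes", "Endothelial_cells",
                           "Lymphatic_endothelial_cells", "Pericytes"),
                         colnames(scores_ssgsea))
  for (cc in cell_cols) meta[[cc]] <- scores_ssgsea[meta$sample_id, cc]
  mut_cols <- intersect(c("ith", "hrd", "silent_rate", "nonsilent_rate",
                          "snv_neoantigens", "indel_neoantigens"),
                        names(meta))
  vars <- c(intersect(c("cyt", "mki67"), names(meta)), cell_cols, mut_cols)
  comparisons <- compare_by_til_group(meta, groups, vars)
  emit(comparisons, "comparisons.tsv")

  # grade: TIL score across grades, per subtype
  grade_rows <- list()
  if ("grade" %in% names(meta)) {
    for (s in unique(meta$subtype)) {
      i <- meta$subtype == s & !is.na(meta$grade)
      if (length(unique(meta$grade[i])) >= 2) {
        grade_rows[[s]] <- kruskal_wallis(til$log2[i], meta$grade[i],
                                          variable = "til_log2_by_grade",
                                          subtype = s)
      }
    }
    if (length(grade_rows)) {
      emit(do.call(rbind, c(grade_rows, list(make.row.names = FALSE))),
           "grade_tests.tsv")
    }
  }

  pcr_tbl <- if ("pcr" %in% names(meta) && any(!is.na(meta$pcr))) {
    pcr_rate_comparison(meta, groups)
  } else NULL
  if (!is.null(pcr_tbl)) {
    emit(pcr_tbl, "pcr.tsv")
    report$headline$pcr <- pcr_tbl[, c("subtype", "rate_high", "rate_low",
                                       "p_value")]
  }

  surv <- survival_by_subtype(meta, groups)
  surv_tbl <- do.call(rbind, lapply(names(surv), function(s) {
    x <- surv[[s]]
    data.frame(subtype = s,
               n_high = x$n$high %||% 0, n_low = x$n$low %||% 0,
               events_high = x$events$high %||% 0,
               events_low = x$events$low %||% 0,
               logrank_chisq = x$logrank$chisq,
               logrank_p = x$logrank$p_value,
               hr = x$hazard_ratio$hr,
               hr_lower = x$hazard_ratio$ci_lower,
               hr_upper = x$hazard_ratio$ci_upper,
               stringsAsFactors = FALSE)
  }))
  emit(surv_tbl, "survival.tsv")
  report$headline$survival <- surv_tbl
  report$stages$outcomes <- "ok"

  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  report$manifest <- c(report$manifest, report_path)
  invisible(report)
}
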