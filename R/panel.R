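#' The 19 lymphocyte cell types that make up the TIL score
#'
#' The composite intratumoral TIL score is defined as the sum of the
#' enrichment scores of these 19 lymphocyte cell types (CD4/CD8 T-cell
#' subsets, regulatory and helper T cells, B-cell subsets, NK and NKT cells).
#'
#' @return Character vector of 19 cell-type identifiers.
#' @export
lymphocyte_types <- function() {
  c(
    "CD4_Tcells", "CD4_memory_Tcells", "CD4_naive_Tcells", "CD4_Tcm",
    "CD4_Tem", "CD8_Tcells", "CD8_naive_Tcells", "CD8_Tem", "CD8_Tcm",
    "Tregs", "Th1_cells", "Th2_cells",
    "B_cells", "pro_B_cells", "naive_B_cells", "Memory_B_cells",
    "Class_switched_memory_B_cells", "NK_cells", "NKT"
  )
}

#' Whole-T-cell subset of the lymphocyte panel
#'
#' CD4/CD8/regulatory/helper T-cell types; used to build the whole-T-cell
#' candidate summary in the estimator-concordance analysis.
#'
#' @return Character vector of 12 T-cell type identifiers.
#' @export
tcell_types <- function() {
  c(
    "CD4_Tcells", "CD4_memory_Tcells", "CD4_naive_Tcells", "CD4_Tcm",
    "CD4_Tem", "CD8_Tcells", "CD8_naive_Tcells", "CD8_Tem", "CD8_Tcm",
    "Tregs", "Th1_cells", "Th2_cells"
  )
}

# Non-lymphocyte cell types carried by the reference panel: the dominant
# cancer-cell population, four myeloid/immune populations compared between
# TIL groups, four stromal populations, and fibroblasts.
nonlymphocyte_types <- function() {
  c(
    "Cancer_cells", "Dendritic_cells", "Macrophages", "Monocytes",
    "Mast_cells", "Adipocytes", "Endothelial_cells",
    "Lymphatic_endothelial_cells", "Pericytes", "Fibroblasts"
  )
}

# Named marker genes and the cell type whose signature owns each of them.
marker_gene_owners <- function() {
  c(
    CD3D  = "CD4_Tcells",  # pan-T marker
    CD4   = "CD4_Tcells",
    CD8A  = "CD8_Tcells",
    FOXP3 = "Tregs",
    PDCD1 = "CD8_Tem",     # exhaustion/function marker on effector T cells
    GZMA  = "NK_cells",    # cytolytic effectors
    PRF1  = "CD8_Tcells",
    MKI67 = "Cancer_cells" # proliferation marker, dominated by tumor cells
  )
}

#' Generate a synthetic cell-type reference panel
#'
#' Builds a reference panel of 29 cell types (the 19 lymphocyte types of the
#' TIL score plus cancer, myeloid, mast, and stromal populations): a
#' cell-type-by-gene matrix of non-negative linear-scale mean expression
#' profiles and, per cell type, a marker gene set (genes overexpressed in
#' that type). Canonical lymphocyte/cytolytic/proliferation marker genes
#' (CD3D, CD4, CD8A, FOXP3, PDCD1, GZMA, PRF1, MKI67) are placed in the
#' signatures of their biological owners.
#'
#' Signature genes are disjoint across cell types by construction and are
#' lineage-specific the way real marker genes are: expressed around
#' `sig_expr` in their owning type and only at a low leak level in every
#' other type, while non-signature genes carry a shared moderate baseline.
#' Each type's mean profile over its signature genes exceeds its mean over
#' non-signature genes by at least `min_fold` (default 4; generated
#' profiles sit well above it).
#'
#' @param n_genes Total number of genes in the universe.
#' @param n_signature_genes Genes per signature (default 5).
#' @param n_signatures_per_type Signatures per cell type (default 3,
#'   mirroring the several independently derived signatures per type that
#'   enrichment-based deconvolution averages over).
#' @param seed Integer seed; fixed seed gives a byte-identical panel.
#' @param sig_expr Linear-scale expression of a signature gene in its
#'   owning cell type (default 10, drawn within +/- 25%).
#' @param leak_range Linear-scale expression range of a signature gene in
#'   non-owning types (default `c(0.02, 0.1)`).
#' @param min_fold Minimum admissible signature/background fold (default 4).
#' @return An object of class `til_reference_panel`: list with `cell_types`,
#'   `genes`, `profiles` (cell type x gene matrix), `signatures` (named list
#'   of gene-set character vectors), `marker_genes`.
#' @export
generate_reference_panel <- function(n_genes = 500, n_signature_genes = 5,
                                     n_signatures_per_type = 3,
                                     seed = 1, sig_expr = 10,
                                     leak_range = c(0.02, 0.1),
                                     min_fold = 4) {
  stopifnot(n_genes >= 1, n_signature_genes >= 1, n_signatures_per_type >= 1)
  cell_types <- c(lymphocyte_types(), nonlymphocyte_types())
  n_types <- length(cell_types)
  per_type <- n_signature_genes * n_signatures_per_type
  need <- n_types * per_type
  if (n_genes < need) {
    stop("n_genes = ", n_genes, " cannot host ", need,
         " disjoint signature genes (", n_types, " cell types x ",
         per_type, ")")
  }

  set.seed(as.integer(seed))
  genes <- sprintf("G%04d", seq_len(n_genes))

  # Carve disjoint marker-gene pools off the front of the universe.
  sig_idx <- split(seq_len(need), rep(seq_len(n_types), each = per_type))
  names(sig_idx) <- cell_types

  # Rename one slot in each owner's block to the canonical marker gene.
  owners <- marker_gene_owners()
  used_slot <- integer(0)
  for (m in names(owners)) {
    block <- sig_idx[[owners[[m]]]]
    slot <- setdiff(block, used_slot)[1]
    if (is.na(slot)) {
      stop("signature block of ", owners[[m]],
           " too small to host its marker genes; increase n_signature_genes")
    }
    genes[slot] <- m
    used_slot <- c(used_slot, slot)
  }

  # Non-signature genes: shared moderate baseline in every type.
  # Signature genes: high in the owning type, leak-level elsewhere --
  # the lineage specificity that makes a gene a marker in the first place.
  profiles <- matrix(runif(n_types * n_genes, min = 0.5, max = 2.0),
                     nrow = n_types, dimnames = list(cell_types, genes))
  all_sig <- unlist(sig_idx, use.names = FALSE)
  profiles[, all_sig] <- matrix(
    runif(n_types * length(all_sig), min = leak_range[1], max = leak_range[2]),
    nrow = n_types)
  for (ct in cell_types) {
    idx <- sig_idx[[ct]]
    profiles[ct, idx] <- sig_expr * runif(length(idx), 0.75, 1.25)
  }

  # Cytolytic effector genes are expressed across the cytotoxic compartment
  # (CD8 T, effector-memory T, NK, NKT), not by a single lineage: this is
  # the premise of the GZMA/PRF1 cytolytic activity score.
  cytotoxic <- c("CD8_Tcells", "CD8_Tem", "NK_cells", "NKT")
  for (m in c("GZMA", "PRF1")) {
    j <- match(m, genes)
    profiles[cytotoxic, j] <- sig_expr * runif(length(cytotoxic), 0.75, 1.25)
  }

  # Split each type's marker pool into its signatures.
  signatures <- lapply(sig_idx, function(i) {
    unname(split(genes[i], rep(seq_len(n_signatures_per_type),
                               each = n_signature_genes)))
  })
  panel <- structure(
    list(cell_types = cell_types, genes = genes, profiles = profiles,
         signatures = signatures, marker_genes = names(owners),
         n_signature_genes = n_signature_genes,
         n_signatures_per_type = n_signatures_per_type,
         seed = as.integer(seed)),
    class = "til_reference_panel"
  )
  validate_reference_panel(panel, min_fold = min_fold)
  panel
}

#' Validate a reference panel's structural invariants
#'
#' Checks that every signature gene is in the gene universe, that all profile
#' values are non-negative, and that each cell type's signature genes are on
#' average at least `min_fold`-fold above its non-signature genes.
#'
#' @param panel A `til_reference_panel`.
#' @param min_fold Minimum signature/background mean fold (default 4).
#' @return Invisibly `TRUE`; stops on violation.
#' @export
validate_reference_panel <- function(panel, min_fold = 4) {
  stopifnot(inherits(panel, "til_reference_panel"))
  if (any(panel$profiles < 0)) stop("profile values must be >= 0")
  for (ct in panel$cell_types) {
    sig <- unique(unlist(panel$signatures[[ct]]))
    if (!all(sig %in% panel$genes)) {
      stop("signature of ", ct, " contains genes outside the universe")
    }
    bg <- setdiff(panel$genes, sig)
    fold <- mean(panel$profiles[ct, sig]) / mean(panel$profiles[ct, bg])
    if (fold < min_fold) {
      stop("signature fold of ", ct, " is ", signif(fold, 3),
           " (< ", min_fold, ")")
    }
  }
  invisible(TRUE)
}

#' @export
print.til_reference_panel <- function(x, ...) {
  cat("Reference panel:", length(x$cell_types), "cell types,",
      length(x$genes), "genes,", x$n_signatures_per_type %||% 1,
      "signature(s) x", x$n_signature_genes, "genes per type\n")
  invisible(x)
}

#' Flatten a panel's per-type signature lists for GMT output
#'
#' Cell types with several signatures get names `<type>__1`, `<type>__2`,
#' ...; [group_signatures()] inverts the naming after [read_gmt()].
#'
#' @param signatures Named list: cell type -> gene vector or list of gene
#'   vectors.
#' @return Flat named list of gene vectors.
#' @export
flatten_signatures <- function(signatures) {
  out <- list()
  for (ct in names(signatures)) {
    s <- signatures[[ct]]
    if (!is.list(s)) s <- list(s)
    if (length(s) == 1) out[[ct]] <- s[[1]]
    else for (i in seq_along(s)) out[[paste0(ct, "__", i)]] <- s[[i]]
  }
  out
}

#' Regroup flat GMT signatures by cell type
#'
#' Inverse of [flatten_signatures()]: names carrying a `__<k>` suffix are
#' grouped under the prefix; plain names become single-signature types.
#'
#' @param sets Flat named list of gene vectors (e.g. from [read_gmt()]).
#' @return Named list: cell type -> list of gene vectors.
#' @export
group_signatures <- function(sets) {
  ct <- sub("__[0-9]+$", "", names(sets))
  lapply(split(unname(sets), ct)[unique(ct)], function(x) x)
}
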