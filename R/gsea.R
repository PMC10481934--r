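#' Signal-to-noise rank metric for two-class GSEA
#'
#' Per-gene signal-to-noise ratio
#' `(mu_pos - mu_neg) / (sigma_pos + sigma_neg)` with each group's standard
#' deviation floored at `max(0.2 * |mu|, 0.2)`, sorted descending with gene
#' name as a deterministic tiebreak.
#'
#' @param expression Genes x samples matrix.
#' @param groups Per-sample group labels (two levels).
#' @param positive The label treated as the positive class (default
#'   `"high"`).
#' @return Named numeric vector of per-gene statistics, sorted descending.
#' @export
rank_metric <- function(expression, groups, positive = "high") {
  stopifnot(is.matrix(expression))
  groups <- as.character(groups)
  if (length(groups) != ncol(expression)) {
    stop("groups length must match the sample columns")
  }
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two group labels required")
  if (!positive %in% lev) stop("positive label ", positive, " not in groups")
  negative <- setdiff(lev, positive)
  i_pos <- groups == positive
  i_neg <- groups == negative
  if (sum(i_pos) < 3 || sum(i_neg) < 3) stop("each group needs >= 3 samples")

  grp_stats <- function(m) {
    mu <- rowMeans(m)
    s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
    s <- pmax(s, pmax(0.2 * abs(mu), 0.2))
    list(mu = mu, s = s)
  }
  a <- grp_stats(expression[, i_pos, drop = FALSE])
  b <- grp_stats(expression[, i_neg, drop = FALSE])
  snr <- (a$mu - b$mu) / (a$s + b$s)
  snr[order(-snr, names(snr))]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Classic two-class GSEA statistic: genes are walked in metric order; hits
#' advance the running sum by `|w|^p` normalized over the set's weights,
#' misses decrease it by `1 / (N - |S|)`; the enrichment score is the
#' running-sum value of maximal absolute deviation. When the set's weights
#' are all zero the hit increments fall back to uniform.
#'
#' @param stats Named numeric vector of per-gene weights sorted in walk
#'   order (descending metric), e.g. from [rank_metric()].
#' @param gene_set Character vector of gene names.
#' @param p Weight exponent (default 1, the GSEA "weighted" scheme).
#' @return List with `es` (in `[-1, 1]`) and `running` (the running sum).
#' @export
enrichment_score <- function(stats, gene_set, p = 1) {
  stopifnot(!is.null(names(stats)), p >= 0)
  genes <- names(stats)
  hit <- genes %in% gene_set
  n_hit <- sum(hit)
  n <- length(genes)
  if (n_hit == 0) stop("gene set has no overlap with the ranked genes")
  if (n_hit == n) stop("gene set covers all ranked genes")
  w <- abs(stats)^p
  w[!hit] <- 0
  nr <- sum(w)
  if (nr == 0) {
    w[hit] <- 1
    nr <- n_hit
  }
  inc <- w / nr
  inc[!hit] <- -1 / (n - n_hit)
  running <- cumsum(inc)
  max_pos <- max(running)
  min_neg <- min(running)
  # equal magnitudes (to numerical precision) resolve to the positive
  # deviation
  tol <- 1e-12 * max(1, abs(max_pos), abs(min_neg))
  es <- if (max_pos >= -min_neg - tol) max_pos else min_neg
  list(es = unname(es), running = unname(running))
}

# ES for every set against one sorted stats vector.
es_for_sets <- function(stats, sets, p) {
  vapply(sets, function(s) enrichment_score(stats, s, p)$es, numeric(1))
}

#' Two-class GSEA with permutation NES and FDR q-values
#'
#' Runs the weighted-KS enrichment statistic for each gene set, normalizes
#' by permutation (NES = ES divided by the mean of same-sign permutation
#' ES), computes same-sign tail nominal p-values, and the GSEA
#' ratio-of-tails FDR q (clipped to 1 and made monotone non-decreasing in
#' ranked |NES| order within each enrichment side). Significance is called
#' at q < 0.25.
#'
#' Phenotype (label) permutation is used when both groups have at least 7
#' samples; otherwise the function falls back to gene-set permutation with
#' a warning.
#'
#' @param expression Genes x samples matrix.
#' @param groups Per-sample two-level labels (see [rank_metric()]).
#' @param gene_sets Named list of gene sets (e.g. from [read_gmt()]); sets
#'   are filtered to `[min_size, max_size]` genes after intersection with
#'   the gene universe.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @param p Weight exponent of [enrichment_score()].
#' @param min_size,max_size Set-size filter bounds (defaults 5 and 500).
#' @param positive Positive-class label (default `"high"`); sets with
#'   positive NES are enriched on this side.
#' @return Data frame: `name`, `size`, `es`, `nes`, `p_value`, `q_value`,
#'   `side` (`high`/`low`), `significant` (q < 0.25), `n_perm`, `seed`.
#' @export
run_gsea <- function(expression, groups, gene_sets, n_perm = 1000, seed = 1,
                     p = 1, min_size = 5, max_size = 500, positive = "high") {
  stopifnot(is.matrix(expression), length(gene_sets) >= 1,
            !is.null(names(gene_sets)), n_perm >= 1)
  genes <- rownames(expression)
  sets <- lapply(gene_sets, intersect, x = genes)
  sizes <- vapply(sets, length, 1L)
  keep <- sizes >= min_size & sizes <= max_size
  if (any(!keep)) {
    warning(sum(!keep), " gene set(s) outside size filter [", min_size,
            ", ", max_size, "] dropped: ",
            paste(names(sets)[!keep], collapse = ", "))
  }
  sets <- sets[keep]
  if (!length(sets)) stop("no gene set survives the size filter")

  obs_stats <- rank_metric(expression, groups, positive = positive)
  obs_es <- es_for_sets(obs_stats, sets, p)

  groups <- as.character(groups)
  min_group <- min(table(groups))
  phenotype <- min_group >= 7
  if (!phenotype) {
    warning("min group size ", min_group,
            " < 7: falling back to gene-set permutation")
  }

  set.seed(as.integer(seed))
  n_sets <- length(sets)
  perm_es <- matrix(NA_real_, nrow = n_sets, ncol = n_perm,
                    dimnames = list(names(sets), NULL))
  if (phenotype) {
    for (b in seq_len(n_perm)) {
      g <- sample(groups)
      perm_es[, b] <- es_for_sets(rank_metric(expression, g,
                                              positive = positive), sets, p)
    }
  } else {
    for (b in seq_len(n_perm)) {
      perm_es[, b] <- vapply(sets, function(s) {
        fake <- sample(genes, length(s))
        enrichment_score(obs_stats, fake, p)$es
      }, numeric(1))
    }
  }

  # Same-sign normalization constants per set.
  mean_pos <- apply(perm_es, 1, function(e) mean(e[e > 0]))
  mean_neg <- apply(perm_es, 1, function(e) mean(abs(e[e < 0])))
  normalize <- function(es, i) {
    if (is.na(es) || es == 0) return(0)
    if (es > 0) {
      if (is.na(mean_pos[i]) || mean_pos[i] == 0) return(NA_real_)
      es / mean_pos[i]
    } else {
      if (is.na(mean_neg[i]) || mean_neg[i] == 0) return(NA_real_)
      es / mean_neg[i]
    }
  }
  nes <- vapply(seq_len(n_sets), function(i) normalize(obs_es[i], i),
                numeric(1))
  nes_perm <- matrix(NA_real_, nrow = n_sets, ncol = n_perm)
  for (i in seq_len(n_sets)) {
    nes_perm[i, ] <- vapply(perm_es[i, ], normalize, numeric(1), i = i)
  }

  # Nominal p: same-sign permutation tail fraction.
  p_val <- vapply(seq_len(n_sets), function(i) {
    e <- obs_es[i]
    same <- perm_es[i, sign(perm_es[i, ]) == sign(e)]
    if (!length(same)) return(1 / n_perm)
    mean(abs(same) >= abs(e))
  }, numeric(1))

  # FDR q: ratio of permutation to observed NES tails, same sign.
  all_perm <- nes_perm[!is.na(nes_perm)]
  obs_nes_ok <- nes[!is.na(nes)]
  q_val <- vapply(seq_len(n_sets), function(i) {
    v <- nes[i]
    if (is.na(v)) return(NA_real_)
    if (v >= 0) {
      perm_pool <- all_perm[all_perm >= 0]
      obs_pool <- obs_nes_ok[obs_nes_ok >= 0]
      num <- if (length(perm_pool)) mean(perm_pool >= v) else 0
      den <- mean(obs_pool >= v)
    } else {
      perm_pool <- all_perm[all_perm <= 0]
      obs_pool <- obs_nes_ok[obs_nes_ok <= 0]
      num <- if (length(perm_pool)) mean(perm_pool <= v) else 0
      den <- mean(obs_pool <= v)
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))

  # Monotone enforcement within each side: walking up from the least
  # extreme |NES|, each set's q becomes the cumulative minimum, so q is
  # non-decreasing as |NES| drops (the BH-style step GSEA applies).
  side <- ifelse(nes >= 0, "high", "low")
  for (s in c("high", "low")) {
    i <- which(side == s & !is.na(q_val))
    if (length(i) > 1) {
      ord <- i[order(abs(nes[i]))]   # ascending |NES|
      q_val[ord] <- cummin(q_val[ord])
    }
  }

  data.frame(
    name = names(sets),
    size = vapply(sets, length, 1L),
    es = unname(obs_es),
    nes = unname(nes),
    p_value = p_val,
    q_value = q_val,
    side = side,
    significant = !is.na(q_val) & q_val < 0.25,
    n_perm = n_perm,
    seed = as.integer(seed),
    permutation = if (phenotype) "phenotype" else "gene_set",
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
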