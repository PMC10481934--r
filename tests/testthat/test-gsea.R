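# small two-class matrix with gene set "up" shifted in the high group
spiked_matrix <- function(n_genes = 100, n_per_group = 15, shift = 2,
                          n_up = 10, seed = 21) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  samples <- sprintf("s%02d", seq_len(2 * n_per_group))
  groups <- rep(c("high", "low"), each = n_per_group)
  m <- matrix(rnorm(n_genes * 2 * n_per_group, mean = 5),
              nrow = n_genes, dimnames = list(genes, samples))
  m[seq_len(n_up), groups == "high"] <- m[seq_len(n_up), groups == "high"] + shift
  list(expr = m, groups = groups, up = genes[seq_len(n_up)])
}

test_that("signal-to-noise metric matches hand-computed values, floors, and antisymmetry", {
  expr <- rbind(
    A = c(4, 5, 6, 1, 2, 3),   # means 5 vs 2, sds 1 vs 1 -> SNR 1.5
    B = c(1, 1, 1, 1, 1, 1)    # constant -> 0 after the sd floor
  )
  colnames(expr) <- paste0("s", 1:6)
  groups <- rep(c("high", "low"), each = 3)
  m <- rank_metric(expr, groups)
  expect_equal(m[["A"]], 1.5)
  expect_equal(m[["B"]], 0)
  expect_identical(names(m), c("A", "B"))  # sorted descending

  swapped <- rank_metric(expr, rep(c("low", "high"), each = 3))
  expect_equal(swapped[names(m)], -m[names(m)])

  expect_error(rank_metric(expr, c("high", "high", "low", "low", "low", "low")),
               ">= 3 samples")
})

test_that("enrichment score reproduces hand-evaluated cases", {
  # exact cover: all metric weight on the top-k set genes
  stats <- setNames(c(2, 1, 0, 0, 0), paste0("g", 1:5))
  expect_equal(enrichment_score(stats, c("g1", "g2"))$es, 1)

  # uniform weights, single set gene at position 3 of 5
  stats_u <- setNames(rep(1, 5), paste0("g", 1:5))
  expect_equal(enrichment_score(stats_u, "g3")$es, 0.5)

  expect_error(enrichment_score(stats, character(0)), "no overlap")
  expect_error(enrichment_score(stats, paste0("g", 1:5)), "all ranked genes")
})

test_that("enrichment score agrees with the brute-force running sum on random instances", {
  set.seed(7)
  for (i in 1:300) {
    n <- sample(5:100, 1)
    genes <- paste0("g", seq_len(n))
    stats <- setNames(sort(rnorm(n), decreasing = TRUE), genes)
    k <- sample(seq_len(n - 1), 1)
    gs <- sample(genes, k)
    p <- sample(c(0, 1, 1.5), 1)
    expect_equal(enrichment_score(stats, gs, p)$es, oracle_es(stats, gs, p),
                 tolerance = 1e-12)
  }
})

test_that("reversing the walk order negates the enrichment score", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(6:40, 1)
    genes <- paste0("g", seq_len(n))
    stats <- setNames(sort(rnorm(n), decreasing = TRUE), genes)
    gs <- sample(genes, sample(seq_len(n - 1), 1))
    expect_equal(enrichment_score(rev(stats), gs)$es,
                 -enrichment_score(stats, gs)$es, tolerance = 1e-12)
  }
})

test_that("run_gsea recovers a spiked gene set on the high side and is deterministic", {
  sp <- spiked_matrix()
  set.seed(31)
  sets <- list(up = sp$up)
  for (j in 1:6) sets[[paste0("null", j)]] <- sample(rownames(sp$expr), 12)
  res1 <- run_gsea(sp$expr, sp$groups, sets, n_perm = 200, seed = 5)
  res2 <- run_gsea(sp$expr, sp$groups, sets, n_perm = 200, seed = 5)
  expect_identical(res1, res2)

  up_row <- res1[res1$name == "up", ]
  expect_identical(up_row$side, "high")
  expect_true(up_row$significant)
  expect_lt(up_row$q_value, 0.25)

  # structural invariants
  nonzero <- res1$es != 0 & !is.na(res1$nes)
  expect_true(all(sign(res1$nes[nonzero]) == sign(res1$es[nonzero])))
  for (s in c("high", "low")) {
    rows <- res1[res1$side == s & !is.na(res1$q_value), ]
    if (nrow(rows) > 1) {
      ord <- order(-abs(rows$nes))
      expect_true(all(diff(rows$q_value[ord]) >= -1e-12))
    }
  }
})

test_that("run_gsea filters set sizes and falls back to gene-set permutation for tiny groups", {
  sp <- spiked_matrix(n_per_group = 5)
  sets <- list(up = sp$up, tiny = rownames(sp$expr)[1:2])
  expect_warning(
    expect_warning(
      res <- run_gsea(sp$expr, sp$groups, sets, n_perm = 50, seed = 2),
      "size filter"),
    "gene-set permutation")
  expect_identical(res$name, "up")
  expect_identical(unique(res$permutation), "gene_set")
})

test_that("null labels do not produce systematic enrichment calls", {
  set.seed(55)
  calls <- numeric(0)
  for (rep in 1:5) {
    n_genes <- 60
    genes <- sprintf("g%03d", seq_len(n_genes))
    m <- matrix(rnorm(n_genes * 20, mean = 5), nrow = n_genes,
                dimnames = list(genes, sprintf("s%02d", 1:20)))
    groups <- sample(rep(c("high", "low"), each = 10))
    sets <- lapply(1:8, function(i) sample(genes, 10))
    names(sets) <- paste0("set", 1:8)
    res <- run_gsea(m, groups, sets, n_perm = 100, seed = rep)
    calls <- c(calls, mean(res$significant))
  }
  # q < 0.25 on pure noise should not fire on most sets
  expect_lt(mean(calls), 0.4)
})
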