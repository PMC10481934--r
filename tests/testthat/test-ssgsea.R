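test_that("rank_transform follows the average-rank, highest-is-n convention", {
  expect_equal(unname(rank_transform(c(a = 5, b = 1, c = 3))), c(3, 1, 2))
  expect_equal(unname(rank_transform(c(a = 2, b = 2, c = 1))), c(2.5, 2.5, 1))
  x <- setNames(rnorm(50), paste0("g", 1:50))
  perm <- sample(50)
  expect_equal(rank_transform(x[perm]), rank_transform(x)[perm])
  expect_error(rank_transform(c(a = 1, b = 1)), "all-constant")
  expect_error(rank_transform(c(a = 1, b = NA)), "non-finite")
})

test_that("ssgsea_score reproduces hand-evaluated running sums", {
  ranks <- setNames(5:1, paste0("g", 1:5))  # g1 highest
  # set at the top: P_in = .5,1,1,1,1 ; P_out = 0,0,1/3,2/3,1
  expect_equal(ssgsea_score(ranks, c("g1", "g2"), alpha = 0), 2.5)
  # set at the bottom: antisymmetric construction
  expect_equal(ssgsea_score(ranks, c("g4", "g5"), alpha = 0), -2.5)
})

test_that("ssgsea_score is invariant to expression scaling and errors on degenerate sets", {
  x <- setNames(c(2, 9, 4, 7, 1, 5), paste0("g", 1:6))
  r1 <- rank_transform(x)
  r2 <- rank_transform(2 * x)
  expect_identical(ssgsea_score(r1, c("g2", "g4")), ssgsea_score(r2, c("g2", "g4")))
  expect_error(ssgsea_score(r1, character(0)), "no overlap")
  expect_error(ssgsea_score(r1, paste0("x", 1:3)), "no overlap")
  expect_error(ssgsea_score(r1, names(x)), "whole universe")
})

test_that("ssgsea_score agrees with the brute-force oracle on random instances", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(5:50, 1)
    genes <- paste0("g", seq_len(n))
    ranks <- setNames(rank(rnorm(n), ties.method = "average"), genes)
    k <- sample(seq_len(n - 1), 1)
    gs <- sample(genes, k)
    alpha <- sample(c(0, 0.25, 1), 1)
    expect_equal(ssgsea_score(ranks, gs, alpha),
                 oracle_ssgsea(ranks, gs, alpha), tolerance = 1e-12)
  }
})

test_that("a universe gene ranked below all set genes raises the score (alpha = 0)", {
  genes <- paste0("g", 1:10)
  x <- setNames(10:1, genes)
  gs <- c("g1", "g2", "g3")
  base <- ssgsea_score(rank_transform(x), gs, alpha = 0)
  bigger <- ssgsea_score(rank_transform(c(x, g11 = 0)), gs, alpha = 0)
  expect_gt(bigger, base)
})

test_that("spillover compensation inverts a known forward mixing and clamps at zero", {
  set.seed(3)
  k <- 4
  K <- matrix(runif(k * k, 0, 0.3), k, k); diag(K) <- 1
  s_true <- matrix(runif(12, 0, 1), nrow = 3, ncol = k)
  kappa <- 0.6
  s_obs <- s_true %*% (diag(k) + kappa * (K - diag(k)))
  rec <- spillover_compensate(s_obs, K, kappa)
  expect_equal(unname(rec), unname(s_true), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_identical(attr(rec, "clamped"), 0L)

  # kappa = 0 leaves scores untouched
  expect_equal(unname(spillover_compensate(s_obs, K, 0)), unname(s_obs),
               ignore_attr = TRUE)

  # forcing a negative solution triggers the clamp and the flag
  s_neg <- matrix(c(0, 1, 1, 1), nrow = 1)
  K2 <- matrix(1, 4, 4); diag(K2) <- 1
  out <- spillover_compensate(s_neg, matrix(c(1, 0.9, 0, 0,
                                              0.9, 1, 0, 0,
                                              0, 0, 1, 0,
                                              0, 0, 0, 1), 4, 4), 1)
  expect_true(all(out >= 0))
  expect_gt(attr(out, "clamped"), 0)
})

test_that("score_cell_types reduces to a calibrated single ssgsea score and rejects degenerate input", {
  genes <- paste0("g", 1:30)
  set.seed(8)
  expr <- matrix(rnorm(60, 5), nrow = 30, dimnames = list(genes, c("s1", "s2")))
  sig <- list(typeA = genes[1:5])
  sc <- score_cell_types(expr, sig, scoring_config(calibration = "none"))
  r1 <- rank_transform(expr[, 1])
  expect_equal(sc["s1", "typeA"], ssgsea_score(r1, genes[1:5], 0.25))

  expr_const <- expr; expr_const[, 1] <- 1
  expect_error(score_cell_types(expr_const, sig), "all-constant")
})

test_that("score_cell_types drops zero-overlap signatures with a warning and errors when all are dropped", {
  expr <- toy_expression(n_genes = 30, n_samples = 4)
  sig <- list(ok = rownames(expr)[1:4], gone = c("NOPE1", "NOPE2"))
  expect_warning(sc <- score_cell_types(expr, sig), "no signature overlap")
  expect_identical(colnames(sc), "ok")
  expect_error(score_cell_types(expr, list(g1 = "NOPE")), "no signature")
})

test_that("score_cell_types is permutation-equivariant in samples", {
  expr <- toy_expression(n_genes = 40, n_samples = 8)
  sig <- list(a = rownames(expr)[1:5], b = rownames(expr)[6:12])
  sc <- score_cell_types(expr, sig)
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  sc_perm <- score_cell_types(expr[, perm], sig)
  expect_equal(unclass(sc_perm), unclass(sc)[perm, ],
               ignore_attr = TRUE)
})

test_that("marker-mean estimator reduces to gene expression and shifts monotonically", {
  expr <- toy_expression(n_genes = 20, n_samples = 5)
  sc <- marker_mean_estimator(expr, list(t1 = rownames(expr)[3]),
                              scoring_config(calibration = "none"))
  expect_equal(unname(sc[, "t1"]), unname(expr[3, ]))
  expr2 <- expr
  expr2[3, ] <- expr2[3, ] + 1
  sc2 <- marker_mean_estimator(expr2, list(t1 = rownames(expr)[3]),
                               scoring_config(calibration = "none"))
  expect_true(all(sc2[, "t1"] > sc[, "t1"]))
})

test_that("cell-type scores recover true fractions on the simulated cohort", {
  co <- default_cohort()
  sc <- default_scores()
  truth <- co$truth
  rec <- vapply(lymphocyte_types(), function(ct) {
    cor(sc[, ct], truth[[paste0("frac_", ct)]], method = "spearman")
  }, numeric(1))
  # single-sample enrichment is a within-sample rank statistic, so closely
  # co-varying lymphocyte subsets cap per-type resolution; the composite
  # score is the quantity the analysis rests on and recovers much tighter
  expect_true(all(rec > 0.5))
  expect_gte(median(rec), 0.6)
  comp <- cor(rowSums(sc[, lymphocyte_types()]), truth$true_til_fraction,
              method = "spearman")
  expect_gte(comp, 0.8)
  mm <- marker_mean_estimator(co$expression, default_panel()$signatures)
  rec_mm <- cor(rowSums(mm[, lymphocyte_types()]), truth$true_til_fraction,
                method = "spearman")
  expect_gt(rec_mm, 0.7)  # the alternative estimator also tracks the truth
})
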