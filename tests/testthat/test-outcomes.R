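test_that("CYT score is the geometric mean of linear GZMA and PRF1", {
  expr <- rbind(GZMA = log2(1 + c(4, 2)), PRF1 = log2(1 + c(9, 2)))
  colnames(expr) <- c("s1", "s2")
  expect_equal(unname(cyt_score(expr, delta = 0)), c(6, 2))
  # equal expression c gives CYT = c + delta
  expect_equal(unname(cyt_score(expr, delta = 0.01)[2]), 2.01)
  # monotone in GZMA
  expr2 <- expr; expr2["GZMA", 1] <- expr2["GZMA", 1] + 0.5
  expect_gt(cyt_score(expr2)[1], cyt_score(expr)[1])
  expect_error(cyt_score(expr[1, , drop = FALSE]), "PRF1")
})

test_that("rank-sum test matches exact enumeration on small tie-free samples", {
  r <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 2 / 6, tolerance = 1e-12)

  set.seed(12)
  for (i in 1:25) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(seq_len(50), n1); y <- sample(setdiff(seq_len(50), x), n2)
    expect_equal(rank_sum_test(x, y)$p_value, oracle_ranksum_p(x, y),
                 tolerance = 1e-12)
  }

  # identical groups: maximal overlap
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("Kruskal-Wallis reduces to the squared rank-sum z for two tie-free groups", {
  set.seed(3)
  x <- rnorm(8); y <- rnorm(6)
  n1 <- 8; n2 <- 6; n <- n1 + n2
  u <- sum(rank(c(x, y))[1:n1]) - n1 * (n1 + 1) / 2
  z <- (u - n1 * n2 / 2) / sqrt(n1 * n2 * (n + 1) / 12)
  h <- kruskal_wallis(c(x, y), rep(c("a", "b"), c(n1, n2)))
  expect_equal(unname(h$statistic), z^2, tolerance = 1e-10)

  tied <- kruskal_wallis(rep(1, 6), rep(c("a", "b", "c"), 2))
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p_value, 1)
  expect_error(kruskal_wallis(1:3, rep("a", 3)), "categories")
})

test_that("TIL-linked grade shift in ER+/HER2- is detectable by Kruskal-Wallis", {
  panel <- default_panel()
  cfg <- sim_config(n_per_subtype = c(ER_HER2neg = 150, HER2pos = 10, TNBC = 10),
                    seed = 31)
  co <- simulate_cohort(panel, cfg)
  er <- co$truth[co$truth$subtype == "ER_HER2neg", ]
  res <- kruskal_wallis(er$true_til_fraction, er$grade,
                        variable = "til_by_grade", subtype = "ER_HER2neg")
  expect_lt(res$p_value, 0.05)
})

test_that("Fisher exact p equals the hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))$p_value,
               34 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))$p_value,
               2 / 252, tolerance = 1e-12)
  expect_error(fisher_exact(matrix(c(0, 0, 2, 3), 2, byrow = TRUE)), "margin")
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "negative")

  set.seed(17)
  for (i in 1:40) {
    tab <- matrix(rpois(4, 2), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p_value, oracle_fisher_p(tab),
                 tolerance = 1e-12)
  }
  # sample odds ratio is ad/bc
  expect_equal(fisher_exact(matrix(c(4, 2, 1, 3), 2, byrow = TRUE))$effect,
               (4 * 3) / (2 * 1))
})

test_that("pCR comparison reports rates per stratum and flags degenerate margins", {
  clin <- data.frame(
    sample_id = sprintf("s%02d", 1:40),
    subtype = rep(c("TNBC", "HER2pos"), each = 20),
    pcr = c(rep(c(1, 0), 10), rep(0, 20)),
    stringsAsFactors = FALSE
  )
  groups <- setNames(rep(rep(c("high", "low"), each = 10), 2),
                     clin$sample_id)
  res <- pcr_rate_comparison(clin, groups)
  tn <- res[res$subtype == "TNBC", ]
  expect_equal(tn$rate_high, tn$rate_low)
  expect_equal(tn$p_value, 1)
  h2 <- res[res$subtype == "HER2pos", ]
  expect_identical(h2$flag, "degenerate_pcr_margin")
  expect_equal(h2$p_value, 1)
  expect_true("pooled" %in% res$subtype)

  clin$pcr[1:2] <- NA
  res2 <- pcr_rate_comparison(clin, groups)
  expect_equal(res2$n_missing[res2$subtype == "TNBC"], 2)

  clin_bad <- clin[clin$subtype == "TNBC", ]
  g_bad <- setNames(rep("high", nrow(clin_bad)), clin_bad$sample_id)
  w <- testthat::capture_warnings(pcr_rate_comparison(clin_bad, g_bad))
  expect_true(any(grepl("empty TIL group", w)))
})

test_that("Kaplan-Meier estimates match hand-computed product limits", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival[km$n_event > 0], c(2 / 3, 1 / 3, 0))

  none <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(none$survival == 1))

  # censoring between events: 1(e), 2(c), 3(e), 4(c), 5(e)
  km2 <- km_estimate(c(1, 2, 3, 4, 5), c(1, 0, 1, 0, 1))
  ev <- km2[km2$n_event > 0, ]
  expect_equal(ev$survival, c(4 / 5, 4 / 5 * 2 / 3, 0), tolerance = 1e-12)
  expect_true(all(diff(km2$survival) <= 0))

  expect_error(km_estimate(c(-1, 2), c(1, 1)), "> 0")
})

test_that("KM without censoring equals the empirical survival function, and matches the oracle", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    times <- sample(1:30, n)
    events <- rbinom(n, 1, 0.7)
    if (sum(events) == 0) next
    km <- km_estimate(times, events)
    orc <- oracle_km(times, events)
    got <- km$survival[match(orc$time, km$time)]
    expect_equal(got, orc$survival, tolerance = 1e-12)
  }
  times <- c(3, 1, 4, 2, 5)
  km <- km_estimate(times, rep(1, 5))
  expect_equal(km$survival, 1 - ecdf(times)(km$time))
})

test_that("log-rank matches the hand-computed Mantel-Haenszel statistic and is label-symmetric", {
  # A: (1,e), (3,e); B: (2,e), (4,c)  ->  chi^2 = 8/13
  times <- c(1, 3, 2, 4); events <- c(1, 1, 1, 0)
  groups <- c("A", "A", "B", "B")
  lr <- logrank_test(times, events, groups)
  expect_equal(lr$chisq, 8 / 13, tolerance = 1e-12)
  expect_equal(lr$p_value, pchisq(8 / 13, 1, lower.tail = FALSE))

  swapped <- logrank_test(times, events, c("B", "B", "A", "A"))
  expect_equal(swapped$chisq, lr$chisq, tolerance = 1e-12)

  dup <- logrank_test(c(1, 2, 3, 1, 2, 3), c(1, 0, 1, 1, 0, 1),
                      rep(c("A", "B"), each = 3))
  expect_equal(dup$chisq, 0, tolerance = 1e-12)
  expect_equal(dup$p_value, 1)

  expect_warning(z <- logrank_test(c(1, 2), c(0, 0), c("A", "B")), "no events")
  expect_equal(z$p_value, 1)
})

test_that("hazard ratio: identity, reciprocity under label swap, and monotone-likelihood guard", {
  times <- c(1, 2, 3, 4, 5, 6, 7, 8)
  events <- c(1, 1, 0, 1, 1, 0, 1, 1)
  groups <- rep(c("high", "low"), 4)

  dup <- hazard_ratio(c(times, times), c(events, events),
                      rep(c("high", "low"), each = 8))
  expect_equal(dup$hr, 1, tolerance = 1e-8)

  hr1 <- hazard_ratio(times, events, groups)
  hr2 <- hazard_ratio(times, events, groups, positive = "low")
  expect_equal(hr1$hr, 1 / hr2$hr, tolerance = 1e-8)
  expect_true(hr1$ci_lower < hr1$hr & hr1$hr < hr1$ci_upper)

  mono <- hazard_ratio(c(1, 2, 3, 4), c(0, 0, 1, 1),
                       c("high", "high", "low", "low"))
  expect_identical(mono$flag, "monotone_likelihood")
  expect_equal(mono$hr, 0)
})

test_that("hazard ratio agrees with the O/E approximation on low-censoring data", {
  set.seed(41)
  n <- 100
  groups <- rep(c("high", "low"), each = n / 2)
  times <- rexp(n, rate = ifelse(groups == "high", 0.013, 0.01))
  events <- rep(1, n)
  hr <- hazard_ratio(times, events, groups)$hr
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  oe <- (sd$obs[1] / sd$exp[1]) / (sd$obs[2] / sd$exp[2])
  expect_lt(abs(hr - oe) / oe, 0.10)
})

test_that("TIL-high tumors show higher cytolytic activity in every subtype of the default cohort", {
  co <- default_cohort()
  til <- dichotomize_by_median(
    compute_til_score(default_scores(), subtype = co$truth$subtype))
  groups <- setNames(til$group, til$sample_id)
  meta <- truth_to_clinical(co$truth)
  meta$cyt <- cyt_score(co$expression)[meta$sample_id]
  res <- compare_by_til_group(meta, groups, "cyt")
  expect_equal(nrow(res), 3)
  expect_true(all(res$p_value < 0.05))
  expect_true(all(res$effect > 0))  # high-group median exceeds low
})
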