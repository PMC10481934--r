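#' Cytolytic activity (CYT) score
#'
#' Geometric mean of linear-scale GZMA and PRF1 expression,
#' `sqrt((GZMA + delta) * (PRF1 + delta))`, with the stored `log2(1 + x)`
#' transform undone first.
#'
#' @param expression Genes x samples log2-scale matrix containing rows
#'   `GZMA` and `PRF1`.
#' @param delta Pseudocount added on the linear scale (default 0.01).
#' @return Named per-sample numeric vector of CYT scores (>= 0).
#' @export
cyt_score <- function(expression, delta = 0.01) {
  need <- c("GZMA", "PRF1")
  missing <- setdiff(need, rownames(expression))
  if (length(missing)) {
    stop("expression matrix lacks gene(s): ", paste(missing, collapse = ", "))
  }
  lin <- 2^expression[need, , drop = FALSE] - 1
  sqrt((lin["GZMA", ] + delta) * (lin["PRF1", ] + delta))
}

significance_stars <- function(p) {
  ifelse(p <= 1e-4, "****",
         ifelse(p <= 1e-3, "***",
                ifelse(p <= 0.01, "**",
                       ifelse(p <= 0.05, "*", "ns"))))
}

comparison_row <- function(variable, subtype, test, statistic, p, effect,
                           n_groups) {
  data.frame(variable = variable, subtype = subtype, test = test,
             statistic = unname(statistic), p_value = unname(p),
             effect = unname(effect),
             n = paste(n_groups, collapse = "/"),
             stars = significance_stars(p),
             stringsAsFactors = FALSE)
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) comparison
#'
#' Exact p-value (via the null rank-sum distribution) for small tie-free
#' samples, normal approximation with tie and continuity correction
#' otherwise; two-sided. The effect summary is the difference of group
#' medians (`x` minus `y`).
#'
#' @param x,y Numeric vectors for the two groups.
#' @param variable,subtype Labels carried into the result row.
#' @return One-row data.frame (variable, subtype, test, statistic = U for
#'   `x`, p_value, effect, n, stars).
#' @export
rank_sum_test <- function(x, y, variable = "value", subtype = "all") {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  if (length(x) + length(y) < 3) stop("need >= 3 observations in total")
  res <- suppressWarnings(wilcox.test(x, y, exact = NULL, correct = TRUE))
  comparison_row(variable, subtype, "rank-sum", res$statistic, res$p.value,
                 median(x) - median(y), c(length(x), length(y)))
}

#' Kruskal-Wallis comparison across k groups
#'
#' Tie-corrected H statistic with a chi-squared reference on k - 1 degrees
#' of freedom.
#'
#' @param values Numeric vector of observations.
#' @param categories Grouping vector (k >= 2 non-empty levels).
#' @param variable,subtype Labels carried into the result row.
#' @return One-row data.frame as in [rank_sum_test()] with `effect = H`.
#' @export
kruskal_wallis <- function(values, categories, variable = "value",
                           subtype = "all") {
  categories <- as.factor(as.character(categories))
  if (any(table(categories) == 0) || nlevels(categories) < 2) {
    stop("need >= 2 non-empty categories")
  }
  if (length(values) < 3) stop("need >= 3 observations")
  if (length(unique(values)) == 1) {
    # all-tied input: H degenerates to 0 after the tie-correction guard
    return(comparison_row(variable, subtype, "Kruskal-Wallis", 0, 1, 0,
                          as.integer(table(categories))))
  }
  res <- kruskal.test(values, categories)
  comparison_row(variable, subtype, "Kruskal-Wallis", res$statistic,
                 res$p.value, unname(res$statistic),
                 as.integer(table(categories)))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' p is the sum of hypergeometric probabilities of all tables (fixed
#' margins) no more probable than the observed one; the effect is the
#' sample odds ratio `ad / bc` (infinite when `bc = 0`).
#'
#' @param counts 2x2 matrix of non-negative integer counts with positive
#'   row and column margins.
#' @param variable,subtype Labels carried into the result row.
#' @return One-row data.frame with `statistic` = observed top-left count,
#'   `effect` = odds ratio.
#' @export
fisher_exact <- function(counts, variable = "value", subtype = "all") {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == 2))
  if (any(counts < 0)) stop("negative counts are not admissible")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero margin: Fisher test undefined")
  }
  res <- fisher.test(counts)
  or <- (counts[1, 1] * counts[2, 2]) / (counts[1, 2] * counts[2, 1])
  comparison_row(variable, subtype, "Fisher-exact", counts[1, 1],
                 res$p.value, or, rowSums(counts))
}

#' Compare pCR rates between TIL-high and TIL-low groups
#'
#' Builds the 2x2 pCR-by-group table within each subtype and pooled,
#' runs the Fisher exact test per stratum, and reports group-wise pCR
#' rates. Samples with missing pCR are excluded and counted. Strata where
#' one group is empty are skipped with a warning; strata with no pCR event
#' in either group report p = 1 and are flagged.
#'
#' @param clinical Data frame with `sample_id`, `subtype` and `pcr`
#'   (0/1/NA).
#' @param groups Named character vector (`high`/`low`) indexed by sample
#'   id, e.g. from a dichotomized `til_score_table`.
#' @return Data frame, one row per stratum: `subtype`, `n_high`, `n_low`,
#'   `pcr_high`, `pcr_low`, `rate_high`, `rate_low`, `p_value`,
#'   `odds_ratio`, `n_missing`, `flag`, `stars`.
#' @export
pcr_rate_comparison <- function(clinical, groups) {
  stopifnot(all(c("sample_id", "subtype", "pcr") %in% names(clinical)))
  g <- groups[clinical$sample_id]
  strata <- c(unique(clinical$subtype), "pooled")
  rows <- list()
  for (s in strata) {
    in_s <- if (s == "pooled") rep(TRUE, nrow(clinical)) else clinical$subtype == s
    pcr <- clinical$pcr[in_s]
    grp <- g[in_s]
    n_missing <- sum(is.na(pcr) | is.na(grp))
    ok <- !is.na(pcr) & !is.na(grp)
    pcr <- pcr[ok]; grp <- grp[ok]
    n_h <- sum(grp == "high"); n_l <- sum(grp == "low")
    if (n_h == 0 || n_l == 0) {
      warning("stratum ", s, " has an empty TIL group; skipped")
      next
    }
    e_h <- sum(pcr[grp == "high"]); e_l <- sum(pcr[grp == "low"])
    flag <- ""
    if (e_h + e_l == 0 || e_h + e_l == n_h + n_l) {
      p <- 1; or <- NA_real_
      flag <- "degenerate_pcr_margin"
    } else {
      tab <- matrix(c(e_h, n_h - e_h, e_l, n_l - e_l), nrow = 2, byrow = TRUE)
      fr <- fisher_exact(tab, variable = "pcr", subtype = s)
      p <- fr$p_value; or <- fr$effect
    }
    rows[[s]] <- data.frame(
      subtype = s, n_high = n_h, n_low = n_l, pcr_high = e_h, pcr_low = e_l,
      rate_high = e_h / n_h, rate_low = e_l / n_l,
      p_value = p, odds_ratio = or, n_missing = n_missing, flag = flag,
      stars = significance_stars(p), stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times Positive survival times.
#' @param events 0/1 event indicators (1 = death observed).
#' @return Data frame: `time` (distinct observed times), `n_risk`,
#'   `n_event`, `n_censor`, `survival` (non-increasing, starts below 1 at
#'   the first event time).
#' @export
km_estimate <- function(times, events) {
  if (any(times <= 0)) stop("survival times must be > 0")
  stopifnot(length(times) == length(events), all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

#' Two-group log-rank (Mantel-Haenszel) test
#'
#' @param times Positive survival times.
#' @param events 0/1 event indicators.
#' @param groups Two-level group labels.
#' @return List with `chisq` and `p_value`; with zero events the test is
#'   undefined and `p_value = 1` is returned with a warning.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.character(groups)
  stopifnot(length(unique(groups)) == 2)
  if (sum(events) == 0) {
    warning("no events observed: log-rank undefined, returning p = 1")
    return(list(chisq = 0, p_value = 1))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  chisq <- unname(sd$chisq)
  list(chisq = chisq, p_value = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Hazard ratio of TIL-high versus TIL-low
#'
#' Single-binary-covariate proportional-hazards fit (Breslow tie handling);
#' `HR = exp(beta)` with a Wald 95% CI. When one group has no events the
#' partial likelihood is monotone; the function then reports `0` or `Inf`
#' with `flag = "monotone_likelihood"` instead of a diverging fit.
#'
#' @param times Positive survival times.
#' @param events 0/1 event indicators.
#' @param groups Two-level labels; the level named by `positive` is the
#'   numerator of the hazard ratio.
#' @param positive Numerator group label (default `"high"`).
#' @return List: `hr`, `ci_lower`, `ci_upper`, `beta`, `se`, `n`,
#'   `n_events`, `flag`.
#' @export
hazard_ratio <- function(times, events, groups, positive = "high") {
  groups <- as.character(groups)
  lev <- unique(groups)
  stopifnot(length(lev) == 2, positive %in% lev)
  x <- as.integer(groups == positive)
  ev_pos <- sum(events[x == 1])
  ev_neg <- sum(events[x == 0])
  if (ev_pos == 0 || ev_neg == 0) {
    hr <- if (ev_pos == 0) 0 else Inf
    return(list(hr = hr, ci_lower = NA_real_, ci_upper = NA_real_,
                beta = log(hr), se = NA_real_, n = length(times),
                n_events = ev_pos + ev_neg, flag = "monotone_likelihood"))
  }
  fit <- survival::coxph(survival::Surv(times, events) ~ x, ties = "breslow")
  beta <- unname(fit$coefficients)
  se <- sqrt(unname(fit$var[1, 1]))
  list(hr = exp(beta), ci_lower = exp(beta - 1.96 * se),
       ci_upper = exp(beta + 1.96 * se), beta = beta, se = se,
       n = length(times), n_events = ev_pos + ev_neg, flag = "")
}

#' Per-subtype survival summary for TIL groups
#'
#' Kaplan-Meier curves per group, log-rank test, and TIL-high vs TIL-low
#' hazard ratio within each subtype.
#'
#' @param clinical Data frame with `sample_id`, `subtype`, `os_months`,
#'   `os_event`.
#' @param groups Named `high`/`low` vector indexed by sample id.
#' @return List keyed by subtype; each element holds `km` (list of KM
#'   tables per group), `logrank`, `hazard_ratio`, `n`, `events`.
#' @export
survival_by_subtype <- function(clinical, groups) {
  stopifnot(all(c("sample_id", "subtype", "os_months", "os_event")
                %in% names(clinical)))
  g <- groups[clinical$sample_id]
  out <- list()
  for (s in unique(clinical$subtype)) {
    i <- clinical$subtype == s & !is.na(g)
    ti <- clinical$os_months[i]; ev <- clinical$os_event[i]; gi <- g[i]
    km <- lapply(split(seq_along(ti), gi), function(j)
      km_estimate(ti[j], ev[j]))
    out[[s]] <- list(
      km = km,
      logrank = logrank_test(ti, ev, gi),
      hazard_ratio = hazard_ratio(ti, ev, gi, positive = "high"),
      n = as.list(table(gi)),
      events = lapply(split(ev, gi), sum)
    )
  }
  out
}

#' TIL-group comparison battery over numeric variables
#'
#' Runs the rank-sum comparison of every listed variable between TIL-high
#' and TIL-low samples within each subtype (the boxplot-style analyses:
#' CYT, myeloid and stromal cell scores, MKI67, mutation metrics).
#'
#' @param data Data frame with `sample_id`, `subtype` and the variables.
#' @param groups Named `high`/`low` vector indexed by sample id.
#' @param variables Character vector of column names to compare.
#' @return Data frame of comparison rows (one per variable x subtype).
#' @export
compare_by_til_group <- function(data, groups, variables) {
  stopifnot(all(c("sample_id", "subtype") %in% names(data)),
            all(variables %in% names(data)))
  g <- groups[data$sample_id]
  rows <- list()
  for (s in unique(data$subtype)) {
    for (v in variables) {
      i <- data$subtype == s & !is.na(g) & !is.na(data[[v]])
      hi <- data[[v]][i & g == "high"]
      lo <- data[[v]][i & g == "low"]
      if (!length(hi) || !length(lo)) next
      rows[[paste(s, v)]] <- rank_sum_test(hi, lo, variable = v, subtype = s)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
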