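# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# ssGSEA running sum by explicit position-by-position evaluation.
oracle_ssgsea <- function(ranks, gene_set, alpha) {
  genes <- names(ranks)
  ord <- order(-ranks, genes)
  walk <- genes[ord]
  in_set <- walk %in% gene_set
  denom_in <- sum(ranks[walk[in_set]]^alpha)
  n_out <- sum(!in_set)
  total <- 0
  for (i in seq_along(walk)) {
    upto <- walk[seq_len(i)]
    p_in <- sum(ranks[upto[upto %in% gene_set]]^alpha) / denom_in
    p_out <- sum(!(upto %in% gene_set)) / n_out
    total <- total + (p_in - p_out)
  }
  total
}

# Weighted-KS enrichment score by explicit running sum.
oracle_es <- function(stats, gene_set, p = 1) {
  genes <- names(stats)
  hit <- genes %in% gene_set
  w <- abs(stats)^p
  nr <- sum(w[hit])
  if (nr == 0) { w[hit] <- 1; nr <- sum(hit) }
  run <- 0
  hi <- 0
  lo <- 0
  miss_inc <- 1 / (length(genes) - sum(hit))
  for (i in seq_along(genes)) {
    run <- run + if (hit[i]) unname(w[i]) / nr else -miss_inc
    if (run > hi) hi <- run
    if (run < lo) lo <- run
  }
  # ties (to numerical precision) resolve to the positive deviation
  if (hi >= -lo - 1e-12 * max(1, hi, -lo)) hi else lo
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments.
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(p, 1)
}

# Two-sided Fisher exact p by hypergeometric enumeration (same relative
# tolerance on "no more probable" as stats::fisher.test).
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  m <- a + cc; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Kaplan-Meier product-limit by hand at each distinct event time.
oracle_km <- function(times, events) {
  ord <- order(times)
  times <- times[ord]; events <- events[ord]
  ev_times <- sort(unique(times[events == 1]))
  s <- 1
  out <- data.frame(time = ev_times, survival = NA_real_)
  for (i in seq_along(ev_times)) {
    t0 <- ev_times[i]
    at_risk <- sum(times >= t0)
    d <- sum(times == t0 & events == 1)
    s <- s * (1 - d / at_risk)
    out$survival[i] <- s
  }
  out
}

# Shared fixtures, built once per test run.
.fixtures <- new.env()

default_panel <- function() {
  if (is.null(.fixtures$panel)) {
    .fixtures$panel <- generate_reference_panel(seed = 1)
  }
  .fixtures$panel
}

default_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- simulate_cohort(default_panel(), sim_config(seed = 11))
  }
  .fixtures$cohort
}

default_scores <- function() {
  if (is.null(.fixtures$scores)) {
    panel <- default_panel()
    .fixtures$scores <- score_cell_types(
      default_cohort()$expression, panel$signatures,
      scoring_config(spillover_matrix = default_spillover_matrix(panel)))
  }
  .fixtures$scores
}

# Small labelled expression matrix for statistics tests.
toy_expression <- function(n_genes = 40, n_samples = 20, seed = 5) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, mean = 5),
              nrow = n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}
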