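#' Simulation configuration for synthetic breast-cancer cohorts
#'
#' Defaults encode the statistical structure the analysis assumes: lymphocyte
#' abundance ordered TNBC > HER2+ > ER+/HER2-, a dominant cancer-cell
#' fraction (median >= 0.6, matching the tumor-cell-rich sampling the score's
#' intratumoral interpretation rests on), TIL-linked pCR odds, TIL-linked
#' grade in ER+/HER2-, and subtype-specific TIL-group survival hazards
#' (protective in HER2+ and TNBC, null in ER+/HER2-).
#'
#' @param n_per_subtype Named integer vector of sample counts for
#'   `ER_HER2neg`, `HER2pos`, `TNBC` (default 100/60/60).
#' @param lymph_alpha Named numeric: total Dirichlet concentration mass on
#'   the 19 lymphocyte types per subtype; must be ordered
#'   TNBC > HER2pos > ER_HER2neg.
#' @param til_dispersion Log-normal sdlog of a per-sample multiplier on the
#'   lymphocyte concentration mass (default 0.8). This overdispersion gives
#'   the wide, roughly bell-shaped log2 TIL distributions seen in real
#'   cohorts and makes total infiltration co-vary with every lymphocyte
#'   subset; 0 collapses to a plain per-subtype Dirichlet.
#' @param cancer_alpha Dirichlet concentration on the cancer-cell fraction.
#' @param other_alpha Concentration on each non-lymphocyte, non-cancer type.
#' @param noise_sd Log-normal noise sdlog applied multiplicatively to the
#'   mixed linear expression (default 0.3); 0 disables noise.
#' @param sample_scale_sd Log-normal sdlog of a per-sample global scaling
#'   factor (default 0.15), emulating residual normalization differences
#'   between samples; within-sample ranks are unaffected by it.
#' @param pcr_intercept Baseline pCR log-odds (default `qlogis(0.25)`).
#' @param pcr_log_odds pCR log-odds increase per 1-SD increase in true TIL
#'   fraction (default 1).
#' @param hazard_ratio Named numeric: TIL-high vs TIL-low hazard ratio per
#'   subtype (default 1 / 0.5 / 0.5 for ER+/HER2-, HER2+, TNBC).
#' @param baseline_hazard Exponential baseline hazard per month
#'   (default log(2)/100: 100-month median survival in the TIL-low group).
#' @param censoring_rate Target fraction of administratively censored
#'   samples under the baseline hazard (default 0.3).
#' @param grade_til_strength Log-odds slope linking true TIL fraction (1-SD
#'   units) to higher Nottingham grade in ER+/HER2- (default 1.5).
#' @param til_mutation_rho Gaussian-copula correlation between true TIL
#'   fraction and the simulated mutation metrics in ER+/HER2- (default 0.5;
#'   0 in the other subtypes).
#' @param path_til_noise_sd SD of the bounded noise added to the true TIL
#'   fraction to mimic pathological TIL assessment (default 0.02).
#' @param seed Integer seed; a fixed seed reproduces the cohort exactly.
#' @return A list of class `til_sim_config`.
#' @export
sim_config <- function(n_per_subtype = c(ER_HER2neg = 100, HER2pos = 60, TNBC = 60),
                       lymph_alpha = c(ER_HER2neg = 4, HER2pos = 8, TNBC = 14),
                       til_dispersion = 0.8,
                       cancer_alpha = 60,
                       other_alpha = 1,
                       noise_sd = 0.3,
                       sample_scale_sd = 0.15,
                       pcr_intercept = qlogis(0.25),
                       pcr_log_odds = 1,
                       hazard_ratio = c(ER_HER2neg = 1, HER2pos = 0.5, TNBC = 0.5),
                       baseline_hazard = log(2) / 100,
                       censoring_rate = 0.3,
                       grade_til_strength = 1.5,
                       til_mutation_rho = 0.5,
                       path_til_noise_sd = 0.02,
                       seed = 1) {
  subtypes <- c("ER_HER2neg", "HER2pos", "TNBC")
  stopifnot(all(subtypes %in% names(n_per_subtype)),
            all(subtypes %in% names(lymph_alpha)),
            all(subtypes %in% names(hazard_ratio)))
  if (any(n_per_subtype <= 0)) stop("all subtype sample counts must be > 0")
  if (any(lymph_alpha <= 0) || cancer_alpha <= 0 || other_alpha <= 0) {
    stop("Dirichlet concentration parameters must be > 0")
  }
  if (any(hazard_ratio <= 0)) stop("hazard ratios must be > 0")
  stopifnot(til_dispersion >= 0, noise_sd >= 0, sample_scale_sd >= 0,
            censoring_rate >= 0, censoring_rate < 1,
            baseline_hazard > 0, path_til_noise_sd >= 0,
            til_mutation_rho > -1, til_mutation_rho < 1)
  structure(
    list(n_per_subtype = n_per_subtype[subtypes],
         lymph_alpha = lymph_alpha[subtypes],
         til_dispersion = til_dispersion,
         cancer_alpha = cancer_alpha, other_alpha = other_alpha,
         noise_sd = noise_sd, sample_scale_sd = sample_scale_sd,
         pcr_intercept = pcr_intercept,
         pcr_log_odds = pcr_log_odds, hazard_ratio = hazard_ratio[subtypes],
         baseline_hazard = baseline_hazard, censoring_rate = censoring_rate,
         grade_til_strength = grade_til_strength,
         til_mutation_rho = til_mutation_rho,
         path_til_noise_sd = path_til_noise_sd, seed = as.integer(seed)),
    class = "til_sim_config"
  )
}

# One Dirichlet draw per row via normalized gamma variates; alpha may be a
# vector (shared) or an n x k matrix (per-sample concentrations).
rdirichlet_rows <- function(n, alpha) {
  if (!is.matrix(alpha)) alpha <- matrix(alpha, nrow = n, ncol = length(alpha),
                                         byrow = TRUE)
  k <- ncol(alpha)
  g <- matrix(rgamma(n * k, shape = alpha, rate = 1), nrow = n)
  sw <- rowSums(g)
  # Guard against all-zero rows at tiny concentrations.
  zero <- sw == 0
  if (any(zero)) {
    g[zero, which.max(alpha)] <- 1
    sw <- rowSums(g)
  }
  g / sw
}

# Administrative censoring horizon giving the target expected censoring
# fraction under an exponential hazard: solves (1 - exp(-l*tau))/(l*tau) = r.
censoring_horizon <- function(baseline_hazard, rate) {
  if (rate <= 0) return(Inf)
  f <- function(x) (1 - exp(-x)) / x - rate
  x <- uniroot(f, c(1e-8, 1e4))$root
  x / baseline_hazard
}

#' Simulate a synthetic breast-cancer cohort
#'
#' Draws per-sample cell-type fractions from subtype-specific Dirichlet
#' distributions, mixes the panel's linear-scale reference profiles by those
#' fractions, applies multiplicative log-normal noise, and stores expression
#' as `log2(1 + mixture)`. Clinical truth is simulated on top of the true
#' TIL fraction (the summed lymphocyte fractions): logistic pCR, grade
#' linked to TILs in ER+/HER2-, exponential survival with subtype-specific
#' TIL-group hazard ratios and uniform administrative censoring, a noisy
#' pathology TIL fraction, and TIL-correlated (ER+/HER2- only) stand-ins for
#' precomputed mutation metrics.
#'
#' @param panel A `til_reference_panel` from [generate_reference_panel()].
#' @param config A `til_sim_config` from [sim_config()].
#' @return List with `expression` (genes x samples, log2 scale) and `truth`
#'   (data.frame, one row per sample: `sample_id`, `subtype`, fraction
#'   columns `frac_*`, `true_til_fraction`, `true_til_group`, `grade`,
#'   `pcr`, `os_months`, `os_event`, `path_til_fraction`, `ith`, `hrd`,
#'   `silent_rate`, `nonsilent_rate`, `snv_neoantigens`, `indel_neoantigens`).
#' @export
simulate_cohort <- function(panel, config = sim_config()) {
  stopifnot(inherits(panel, "til_reference_panel"),
            inherits(config, "til_sim_config"))
  la <- config$lymph_alpha
  if (!(la[["TNBC"]] > la[["HER2pos"]] && la[["HER2pos"]] > la[["ER_HER2neg"]])) {
    stop("lymphocyte Dirichlet mass must be ordered TNBC > HER2pos > ER_HER2neg")
  }
  set.seed(config$seed)

  subtypes <- names(config$n_per_subtype)
  lymph <- lymphocyte_types()
  nonlymph_other <- setdiff(nonlymphocyte_types(), "Cancer_cells")
  cell_types <- panel$cell_types
  n_total <- sum(config$n_per_subtype)

  frac <- matrix(0, nrow = 0, ncol = length(cell_types),
                 dimnames = list(NULL, cell_types))
  subtype_vec <- character(0)
  for (st in subtypes) {
    n <- config$n_per_subtype[[st]]
    alpha <- matrix(0, nrow = n, ncol = length(cell_types),
                    dimnames = list(NULL, cell_types))
    alpha[, "Cancer_cells"] <- config$cancer_alpha
    alpha[, nonlymph_other] <- config$other_alpha
    # per-sample lymphocyte mass multiplier: wide infiltration spread
    m <- if (config$til_dispersion > 0)
      rlnorm(n, meanlog = 0, sdlog = config$til_dispersion) else rep(1, n)
    alpha[, lymph] <- (config$lymph_alpha[[st]] / length(lymph)) * m
    frac <- rbind(frac, rdirichlet_rows(n, alpha))
    subtype_vec <- c(subtype_vec, rep(st, n))
  }
  sample_id <- sprintf("S%04d", seq_len(n_total))
  rownames(frac) <- sample_id

  # Expression: linear mixture of profiles, multiplicative noise, log2(1+x).
  mix <- frac %*% panel$profiles             # samples x genes
  if (config$noise_sd > 0) {
    noise <- matrix(rlnorm(length(mix), meanlog = 0, sdlog = config$noise_sd),
                    nrow = nrow(mix))
    mix <- mix * noise
  }
  if (config$sample_scale_sd > 0) {
    mix <- mix * rlnorm(nrow(mix), meanlog = 0, sdlog = config$sample_scale_sd)
  }
  expression <- t(log2(1 + mix))             # genes x samples

  true_til <- rowSums(frac[, lymph, drop = FALSE])
  til_z <- as.numeric(scale(true_til))

  # Truth-level TIL group: per-subtype median split of the true fraction.
  true_group <- character(n_total)
  for (st in subtypes) {
    i <- subtype_vec == st
    true_group[i] <- ifelse(true_til[i] >= median(true_til[i]), "high", "low")
  }

  # pCR: logistic in standardized true TIL fraction.
  p_pcr <- plogis(config$pcr_intercept + config$pcr_log_odds * til_z)
  pcr <- rbinom(n_total, 1, p_pcr)

  # Grade 1-3: proportional-odds link to TILs in ER+/HER2-; TIL-independent
  # grade mix elsewhere (grade 1 rare outside ER+/HER2-).
  grade <- integer(n_total)
  for (i in seq_len(n_total)) {
    if (subtype_vec[i] == "ER_HER2neg") {
      eta <- config$grade_til_strength * til_z[i]
      # cumulative logits with cutpoints at -1 and 1
      p_le1 <- plogis(-1 - eta)
      p_le2 <- plogis(1 - eta)
      u <- runif(1)
      grade[i] <- if (u < p_le1) 1L else if (u < p_le2) 2L else 3L
    } else {
      grade[i] <- sample(1:3, 1, prob = c(0.05, 0.45, 0.5))
    }
  }

  # Survival: exponential hazards, TIL-high multiplied by the subtype HR.
  hr <- config$hazard_ratio[subtype_vec]
  lambda <- config$baseline_hazard * ifelse(true_group == "high", hr, 1)
  t_event <- rexp(n_total, rate = lambda)
  tau <- censoring_horizon(config$baseline_hazard, config$censoring_rate)
  t_cens <- if (is.finite(tau)) runif(n_total, 0, tau) else rep(Inf, n_total)
  os_months <- pmax(pmin(t_event, t_cens), 1e-6)
  os_event <- as.integer(t_event <= t_cens)

  path_til <- pmin(pmax(true_til + rnorm(n_total, 0, config$path_til_noise_sd),
                        0), 1)

  # Mutation metrics: Gaussian copula against the TIL fraction within
  # ER+/HER2-, independent in the other subtypes.
  rho <- ifelse(subtype_vec == "ER_HER2neg", config$til_mutation_rho, 0)
  copula_z <- function() {
    z_til <- qnorm(rank(true_til, ties.method = "average") / (n_total + 1))
    rho * z_til + sqrt(1 - rho^2) * rnorm(n_total)
  }
  ith <- pnorm(copula_z())                         # subclonal fraction in [0,1]
  hrd <- qgamma(pnorm(copula_z()), shape = 2, scale = 12)
  silent_rate <- qlnorm(pnorm(copula_z()), meanlog = -0.5, sdlog = 0.8)
  nonsilent_rate <- qlnorm(pnorm(copula_z()), meanlog = 0.5, sdlog = 0.8)
  snv_neo <- qnbinom(pnorm(copula_z()), mu = 40, size = 1.5)
  indel_neo <- qnbinom(pnorm(copula_z()), mu = 4, size = 1.2)

  truth <- data.frame(
    sample_id = sample_id, subtype = subtype_vec,
    frac, check.names = FALSE, stringsAsFactors = FALSE
  )
  names(truth)[match(cell_types, names(truth))] <- paste0("frac_", cell_types)
  truth$true_til_fraction <- true_til
  truth$true_til_group <- true_group
  truth$grade <- grade
  truth$pcr <- pcr
  truth$os_months <- os_months
  truth$os_event <- os_event
  truth$path_til_fraction <- path_til
  truth$ith <- ith
  truth$hrd <- hrd
  truth$silent_rate <- silent_rate
  truth$nonsilent_rate <- nonsilent_rate
  truth$snv_neoantigens <- snv_neo
  truth$indel_neoantigens <- indel_neo

  list(expression = expression, truth = truth)
}

#' Clinical columns of a simulated truth table
#'
#' Subsets a truth table to the columns a real clinical table would carry
#' (drops the unobservable true fractions and truth-level TIL group).
#'
#' @param truth Truth data.frame from [simulate_cohort()].
#' @return Data frame in the package's clinical-table layout.
#' @export
truth_to_clinical <- function(truth) {
  cols <- c("sample_id", "subtype", "grade", "pcr", "os_months", "os_event",
            "path_til_fraction", "ith", "hrd", "silent_rate",
            "nonsilent_rate", "snv_neoantigens", "indel_neoantigens")
  missing <- setdiff(cols, names(truth))
  if (length(missing)) stop("truth table lacks: ", paste(missing, collapse = ", "))
  truth[, cols]
}

#' Write a simulated cohort to disk
#'
#' Emits `expression.tsv` (genes x samples), `clinical.tsv`,
#' `truth.tsv` (full truth table including fractions), and, when a panel is
#' supplied, `signatures.gmt`. Round-trips losslessly through
#' [read_expression()] / [read_clinical()] / [read_gmt()].
#'
#' @param cohort List with `expression` and `truth` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @param panel Optional `til_reference_panel` whose signatures are written
#'   as GMT.
#' @param overwrite Overwrite existing files (default `FALSE`: refuses).
#' @return Invisibly, named character vector of the written paths.
#' @export
write_cohort <- function(cohort, dir, panel = NULL, overwrite = FALSE) {
  stopifnot(is.list(cohort), !is.null(cohort$expression), !is.null(cohort$truth))
  if (!identical(colnames(cohort$expression), cohort$truth$sample_id)) {
    stop("expression columns and truth sample_id disagree")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             truth = file.path(dir, "truth.tsv"))
  if (!is.null(panel)) paths["signatures"] <- file.path(dir, "signatures.gmt")
  exists <- file.exists(paths)
  if (any(exists) && !overwrite) {
    stop("refusing to overwrite: ", paste(paths[exists], collapse = ", "),
         " (use overwrite = TRUE)")
  }
  write_expression(cohort$expression, paths[["expression"]])
  write_clinical(truth_to_clinical(cohort$truth), paths[["clinical"]])
  write_clinical(cohort$truth, paths[["truth"]])
  if (!is.null(panel)) {
    write_gmt(flatten_signatures(panel$signatures), paths[["signatures"]],
              descriptions = "cell_type_signature")
  }
  invisible(paths)
}
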