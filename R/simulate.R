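#' Configuration for the synthetic case-control cohort generator
#'
#' Defines the generative model for a multi-dataset lung-cancer case-control
#' study instrumented by type-2-diabetes (T2DM) risk variants. Genotypes are
#' drawn per variant as Binomial(2, EAF), so Hardy-Weinberg equilibrium holds
#' by construction and instruments are mutually independent. A continuous
#' exposure liability is built from the true per-allele effects plus an
#' optional shared confounder and unit-variance noise; binary exposure status
#' follows a logistic link on the liability. The binary outcome is rare
#' (baseline prevalence ~1%) and logistic in the causal liability effect,
#' per-variant direct (pleiotropic) effects, the confounder, and smoking/age
#' covariate effects; case-control samples are accumulated by rejection
#' sampling from this superpopulation.
#'
#' @param n_variants Number of instrument SNPs (default 82).
#' @param n_datasets Number of independent case-control datasets (default 3).
#' @param n_cases_per_dataset,n_controls_per_dataset Requested counts, either
#'   a scalar recycled across datasets or a vector of length `n_datasets`.
#'   Defaults mirror a three-study design totalling ~13k cases and ~13k
#'   controls.
#' @param eaf_range Interval in (0,1) from which effect-allele frequencies are
#'   drawn uniformly.
#' @param beta_exposure_range Interval for per-SNP exposure log-odds effects
#'   (drawn uniformly; all positive, i.e. effect alleles are risk alleles).
#' @param causal_logor True causal effect of one unit of exposure liability on
#'   the outcome log-odds (default 0, the null).
#' @param confounder_strength Coefficient of a shared standard-normal
#'   confounder in both the exposure liability and the outcome log-odds.
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of per-variant direct
#'   effects on the outcome log-odds (directional pleiotropy when the mean is
#'   nonzero).
#' @param exposure_prevalence Marginal probability of binary exposure status at
#'   liability zero.
#' @param outcome_base_prevalence Outcome probability at the covariate/liability
#'   baseline. Kept small so that marginal per-allele odds ratios are
#'   effectively collapsible, as for a rare cancer outcome.
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   configuration. Per-dataset streams are derived by fixed offsets.
#' @param max_rounds Bound on rejection-sampling rounds per dataset before the
#'   requested case count is declared unreachable.
#'
#' @return An object of class `mr_sim_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
simulation_config <- function(n_variants = 82L,
                              n_datasets = 3L,
                              n_cases_per_dataset = c(10248L, 2126L, 953L),
                              n_controls_per_dataset = c(9298L, 3077L, 953L),
                              eaf_range = c(0.05, 0.95),
                              beta_exposure_range = c(0.10, 0.20),
                              causal_logor = 0,
                              confounder_strength = 0,
                              pleiotropy_mean = 0,
                              pleiotropy_sd = 0,
                              exposure_prevalence = 0.10,
                              outcome_base_prevalence = 0.01,
                              seed = 1L,
                              max_rounds = 30L) {
  n_variants <- as.integer(n_variants)
  n_datasets <- as.integer(n_datasets)
  stopifnot(n_variants > 0, n_datasets > 0, max_rounds > 0)
  recycle <- function(x, what) {
    x <- as.integer(x)
    if (length(x) == 1L) x <- rep(x, n_datasets)
    if (length(x) != n_datasets) {
      stop(sprintf("%s must have length 1 or n_datasets", what), call. = FALSE)
    }
    if (any(x <= 0L)) stop(sprintf("%s must be positive", what), call. = FALSE)
    x
  }
  n_cases_per_dataset <- recycle(n_cases_per_dataset, "n_cases_per_dataset")
  n_controls_per_dataset <- recycle(n_controls_per_dataset, "n_controls_per_dataset")
  stopifnot(
    length(eaf_range) == 2, eaf_range[1] > 0, eaf_range[2] < 1,
    eaf_range[1] <= eaf_range[2],
    length(beta_exposure_range) == 2,
    beta_exposure_range[1] <= beta_exposure_range[2],
    exposure_prevalence > 0, exposure_prevalence < 1,
    outcome_base_prevalence > 0, outcome_base_prevalence < 1
  )
  structure(list(
    n_variants = n_variants,
    n_datasets = n_datasets,
    n_cases_per_dataset = n_cases_per_dataset,
    n_controls_per_dataset = n_controls_per_dataset,
    eaf_range = as.numeric(eaf_range),
    beta_exposure_range = as.numeric(beta_exposure_range),
    causal_logor = as.numeric(causal_logor),
    confounder_strength = as.numeric(confounder_strength),
    pleiotropy_mean = as.numeric(pleiotropy_mean),
    pleiotropy_sd = as.numeric(pleiotropy_sd),
    exposure_prevalence = as.numeric(exposure_prevalence),
    outcome_base_prevalence = as.numeric(outcome_base_prevalence),
    seed = as.integer(seed),
    max_rounds = as.integer(max_rounds)
  ), class = "mr_sim_config")
}

# Fixed covariate effects on the outcome log-odds. Smoking is the dominant
# lung-cancer risk factor; age contributes moderately; sex and the synthetic
# ancestry PCs carry no direct effect.
.covariate_logors <- c(smoker = 0.7, age60 = 0.3, sex = 0)

# Non-complementary allele pairs so that default cohorts contain no
# palindromic variants (A/T, C/G ambiguity is exercised explicitly in tests).
.allele_pairs <- matrix(c(
  "A", "C", "A", "G", "C", "A", "C", "T",
  "G", "A", "G", "T", "T", "C", "T", "G"
), ncol = 2, byrow = TRUE)

#' Simulate a multi-dataset case-control cohort
#'
#' Draws instrument frequencies and effects once from the global seed, then
#' builds each dataset from its own derived stream by rejection sampling:
#' superpopulation individuals are generated in batches, their outcome is
#' realised from the logistic model, and cases/controls are retained until the
#' requested counts are reached. Age (>=60), sex and ever-smoking indicators
#' are Bernoulli(0.5); ten principal-component covariates are standard normal;
#' case histology is multinomial with adenocarcinoma the majority type.
#'
#' @param config An [simulation_config()] object.
#' @return An object of class `mr_cohort`: a list with elements
#'   * `genotypes`: samples x variants effect-allele dosage matrix (0/1/2),
#'   * `variants`: data frame of variant alleles (`rsid`, `a1`, `a2`); dosages
#'     count the `a2` (effect) allele,
#'   * `phenotypes`: per-sample outcome (`case`), exposure status (`t2d`),
#'     continuous `liability`, covariates, `histology` and `dataset`,
#'   * `instruments`: the true instrument table (published-weights analogue),
#'   * `truth`: every generated parameter, sufficient to reconstruct the
#'     cohort deterministically from the seed.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "mr_sim_config"))
  nv <- config$n_variants

  set.seed(config$seed)
  eaf <- stats::runif(nv, config$eaf_range[1], config$eaf_range[2])
  beta <- stats::runif(nv, config$beta_exposure_range[1], config$beta_exposure_range[2])
  alpha <- stats::rnorm(nv, config$pleiotropy_mean, config$pleiotropy_sd)
  pair <- .allele_pairs[sample.int(nrow(.allele_pairs), nv, replace = TRUE), , drop = FALSE]
  rsid <- sprintf("snp%03d", seq_len(nv))
  chrom <- sample(1:22, nv, replace = TRUE)
  pos <- sort(sample.int(2^28, nv))
  # Published-GWAS-style standard errors: genome-wide significant instruments
  # have |beta|/se well above 5.
  inst_se <- beta / stats::runif(nv, 6, 12)

  instruments <- data.frame(
    rsid = rsid, chr = as.character(chrom), pos = pos,
    ea = pair[, 2], oa = pair[, 1],
    beta = beta, se = inst_se, eaf = eaf,
    is_indel = FALSE, stringsAsFactors = FALSE
  )

  a0_x <- stats::qlogis(config$exposure_prevalence)
  a0_y <- stats::qlogis(config$outcome_base_prevalence)
  center_x <- sum(2 * eaf * beta)
  center_y <- sum(2 * eaf * alpha)

  geno_list <- list()
  pheno_list <- list()
  for (d in seq_len(config$n_datasets)) {
    set.seed(config$seed + 7919L * d)
    need_ca <- config$n_cases_per_dataset[d]
    need_co <- config$n_controls_per_dataset[d]
    got <- .sample_dataset(need_ca, need_co, eaf, beta, alpha,
                           a0_x, a0_y, center_x, center_y,
                           config$causal_logor, config$confounder_strength,
                           config$max_rounds)
    ids <- sprintf("d%d_s%05d", d, seq_len(nrow(got$pheno)))
    rownames(got$geno) <- ids
    got$pheno <- cbind(sample_id = ids, dataset = sprintf("dataset%d", d),
                       got$pheno, stringsAsFactors = FALSE)
    geno_list[[d]] <- got$geno
    pheno_list[[d]] <- got$pheno
  }
  genotypes <- do.call(rbind, geno_list)
  colnames(genotypes) <- rsid
  phenotypes <- do.call(rbind, pheno_list)
  rownames(phenotypes) <- NULL

  truth <- list(
    causal_logor = config$causal_logor,
    beta = beta, alpha = alpha, eaf = eaf,
    confounder_strength = config$confounder_strength,
    covariate_logors = .covariate_logors,
    exposure_base_logit = a0_x,
    outcome_base_logit = a0_y,
    seed = config$seed
  )
  structure(list(
    genotypes = genotypes,
    variants = data.frame(rsid = rsid, chr = as.character(chrom), pos = pos,
                          a1 = pair[, 1], a2 = pair[, 2],
                          stringsAsFactors = FALSE),
    phenotypes = phenotypes,
    instruments = instruments,
    truth = truth,
    config = config
  ), class = "mr_cohort")
}

# One dataset by batched rejection sampling from the superpopulation.
.sample_dataset <- function(need_ca, need_co, eaf, beta, alpha,
                            a0_x, a0_y, center_x, center_y,
                            causal_logor, confounder_strength, max_rounds) {
  nv <- length(eaf)
  geno_ca <- geno_co <- list()
  ph_ca <- ph_co <- list()
  have_ca <- have_co <- 0L
  p_case_hat <- NA_real_
  for (round in seq_len(max_rounds)) {
    if (have_ca >= need_ca && have_co >= need_co) break
    if (is.na(p_case_hat)) {
      batch_n <- min(200000L, max(20000L, 5L * (need_ca + need_co)))
    } else {
      need <- max((need_ca - have_ca) / max(p_case_hat, 1e-6),
                  (need_co - have_co) / max(1 - p_case_hat, 1e-6))
      batch_n <- as.integer(min(200000, ceiling(1.3 * need) + 1000))
    }
    g <- matrix(stats::rbinom(batch_n * nv, 2L, rep(eaf, each = batch_n)),
                nrow = batch_n)
    u <- stats::rnorm(batch_n)
    liab <- as.vector(g %*% beta) - center_x +
      confounder_strength * u + stats::rnorm(batch_n)
    t2d <- stats::rbinom(batch_n, 1L, stats::plogis(a0_x + liab))
    age60 <- stats::rbinom(batch_n, 1L, 0.5)
    sex <- stats::rbinom(batch_n, 1L, 0.5)
    smoker <- stats::rbinom(batch_n, 1L, 0.5)
    eta_y <- a0_y + causal_logor * liab +
      as.vector(g %*% alpha) - center_y +
      confounder_strength * u +
      .covariate_logors["smoker"] * smoker +
      .covariate_logors["age60"] * age60 +
      .covariate_logors["sex"] * sex
    y <- stats::rbinom(batch_n, 1L, stats::plogis(eta_y))
    pcs <- matrix(stats::rnorm(batch_n * 10L), ncol = 10L,
                  dimnames = list(NULL, paste0("PC", 1:10)))
    p_case_hat <- mean(y)

    ph <- data.frame(case = y, t2d = t2d, liability = liab,
                     age60 = age60, sex = sex, smoker = smoker,
                     stringsAsFactors = FALSE)
    ph <- cbind(ph, as.data.frame(pcs))

    idx_ca <- which(y == 1L)
    idx_co <- which(y == 0L)
    take_ca <- idx_ca[seq_len(min(length(idx_ca), need_ca - have_ca))]
    take_co <- idx_co[seq_len(min(length(idx_co), need_co - have_co))]
    if (length(take_ca)) {
      geno_ca[[length(geno_ca) + 1L]] <- g[take_ca, , drop = FALSE]
      ph_ca[[length(ph_ca) + 1L]] <- ph[take_ca, , drop = FALSE]
      have_ca <- have_ca + length(take_ca)
    }
    if (length(take_co)) {
      geno_co[[length(geno_co) + 1L]] <- g[take_co, , drop = FALSE]
      ph_co[[length(ph_co) + 1L]] <- ph[take_co, , drop = FALSE]
      have_co <- have_co + length(take_co)
    }
  }
  if (have_ca < need_ca || have_co < need_co) {
    stop(sprintf(
      paste0("requested case/control counts unreachable after %d sampling ",
             "rounds (got %d/%d cases, %d/%d controls); the outcome model ",
             "assigns too little probability to one class"),
      max_rounds, have_ca, need_ca, have_co, need_co), call. = FALSE)
  }
  pheno <- rbind(do.call(rbind, ph_ca), do.call(rbind, ph_co))
  # Case histology: adenocarcinoma-dominant multinomial; controls have none.
  n_ca <- nrow(do.call(rbind, ph_ca))
  hist_lv <- c("adenocarcinoma", "squamous", "other")
  histology <- c(sample(hist_lv, n_ca, replace = TRUE, prob = c(0.66, 0.22, 0.12)),
                 rep(NA_character_, nrow(pheno) - n_ca))
  pheno$histology <- histology
  rownames(pheno) <- NULL
  list(geno = rbind(do.call(rbind, geno_ca), do.call(rbind, geno_co)),
       pheno = pheno)
}

#' @export
print.mr_cohort <- function(x, ...) {
  ph <- x$phenotypes
  cat(sprintf("mr_cohort: %d samples (%d cases / %d controls), %d variants, %d dataset(s)\n",
              nrow(ph), sum(ph$case == 1), sum(ph$case == 0),
              ncol(x$genotypes), length(unique(ph$dataset))))
  cat(sprintf("true causal log-OR %.3f; confounding %.3f; mean pleiotropy %.3f; seed %d\n",
              x$truth$causal_logor, x$truth$confounder_strength,
              mean(x$truth$alpha), x$truth$seed))
  invisible(x)
}
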