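#' Quality-control thresholds
#'
#' Bundle of variant- and sample-level filter thresholds. Defaults follow
#' standard array QC practice for case-control GWAS: variant call rate >= 95%,
#' control MAF >= 0.005, Hardy-Weinberg p-value floors of 1e-5 in all samples,
#' 1e-7 in controls and 1e-12 in cases, sample call rate >= 95%, relatedness
#' PI_HAT <= 0.25, and heterozygosity within 6 SD of the cohort mean. Any
#' threshold can be disabled by setting it to `NA`.
#'
#' @param variant_call_rate_min,maf_min,hwe_all_p_min,hwe_controls_p_min,hwe_cases_p_min
#'   Variant-level thresholds.
#' @param sample_call_rate_min,relatedness_pihat_max,het_sd_max Sample-level
#'   thresholds.
#' @return Object of class `mr_qc_thresholds`.
#' @export
qc_thresholds <- function(variant_call_rate_min = 0.95,
                          maf_min = 0.005,
                          hwe_all_p_min = 1e-5,
                          hwe_controls_p_min = 1e-7,
                          hwe_cases_p_min = 1e-12,
                          sample_call_rate_min = 0.95,
                          relatedness_pihat_max = 0.25,
                          het_sd_max = 6) {
  chk01 <- function(x) is.na(x) || (x > 0 && x <= 1)
  stopifnot(chk01(variant_call_rate_min), chk01(sample_call_rate_min),
            chk01(maf_min), chk01(hwe_all_p_min), chk01(hwe_controls_p_min),
            chk01(hwe_cases_p_min))
  structure(list(
    variant_call_rate_min = variant_call_rate_min,
    maf_min = maf_min,
    hwe_all_p_min = hwe_all_p_min,
    hwe_controls_p_min = hwe_controls_p_min,
    hwe_cases_p_min = hwe_cases_p_min,
    sample_call_rate_min = sample_call_rate_min,
    relatedness_pihat_max = relatedness_pihat_max,
    het_sd_max = het_sd_max
  ), class = "mr_qc_thresholds")
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against the binomial expectation at the sample allele frequency.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (total > 0).
#' @return Two-sided p-value. Monomorphic input returns 1 by convention.
#' @examples
#' hwe_test(30, 40, 30) # chi-square 4, p ~ 0.0455
#' @export
hwe_test <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  stopifnot(n > 0, n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  p <- (2 * n_hom_alt + n_het) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chi2 <- sum((c(n_hom_ref, n_het, n_hom_alt) - expected)^2 / expected)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

# Genotype counts from a dosage vector (fractional dosages are rounded to the
# nearest hard call for HWE and heterozygosity purposes).
.geno_counts <- function(g) {
  g <- round(g[!is.na(g)])
  c(sum(g == 0), sum(g == 1), sum(g == 2))
}

#' Variant-level quality-control filters
#'
#' Drops variants failing, in order: call rate, control minor-allele
#' frequency, Hardy-Weinberg equilibrium in all samples, in controls, and in
#' cases. A variant failing several rules is attributed to the first.
#'
#' @param genotypes Dosage matrix (samples x variants, `NA` = missing call).
#' @param phenotypes Phenotype table aligned with the genotype rows (only the
#'   `case` column is used).
#' @param thresholds An [qc_thresholds()] object.
#' @return List with `genotypes` (filtered matrix) and `report`: a data frame
#'   of per-rule removal counts plus a `dispositions` attribute naming each
#'   removed variant and its rule.
#' @export
apply_variant_filters <- function(genotypes, phenotypes,
                                  thresholds = qc_thresholds()) {
  stopifnot(nrow(genotypes) == nrow(phenotypes), !is.null(phenotypes$case))
  th <- thresholds
  ctrl <- phenotypes$case == 0
  case <- phenotypes$case == 1
  rules <- c("call_rate", "control_maf", "hwe_all", "hwe_controls", "hwe_cases")
  fail_rule <- rep(NA_character_, ncol(genotypes))

  for (j in seq_len(ncol(genotypes))) {
    g <- genotypes[, j]
    if (!is.na(th$variant_call_rate_min) &&
        mean(!is.na(g)) < th$variant_call_rate_min) {
      fail_rule[j] <- "call_rate"
      next
    }
    if (!is.na(th$maf_min) && any(ctrl)) {
      f <- mean(g[ctrl], na.rm = TRUE) / 2
      if (is.nan(f)) f <- 0
      if (min(f, 1 - f) < th$maf_min) {
        fail_rule[j] <- "control_maf"
        next
      }
    }
    hwe_of <- function(idx) do.call(hwe_test, as.list(.geno_counts(g[idx])))
    if (!is.na(th$hwe_all_p_min) && hwe_of(TRUE) <= th$hwe_all_p_min) {
      fail_rule[j] <- "hwe_all"
      next
    }
    if (!is.na(th$hwe_controls_p_min) && any(ctrl) &&
        hwe_of(ctrl) < th$hwe_controls_p_min) {
      fail_rule[j] <- "hwe_controls"
      next
    }
    if (!is.na(th$hwe_cases_p_min) && any(case) &&
        hwe_of(case) < th$hwe_cases_p_min) {
      fail_rule[j] <- "hwe_cases"
    }
  }

  removed <- !is.na(fail_rule)
  report <- data.frame(
    rule = c(rules, "passed"),
    n = c(vapply(rules, function(r) sum(fail_rule == r, na.rm = TRUE),
                 integer(1)),
          sum(!removed)),
    stringsAsFactors = FALSE
  )
  attr(report, "dispositions") <- data.frame(
    rsid = colnames(genotypes)[removed],
    rule = fail_rule[removed], stringsAsFactors = FALSE)
  list(genotypes = genotypes[, !removed, drop = FALSE], report = report)
}

#' Sample-level quality-control filters
#'
#' Drops samples in order: call rate below threshold; from each related pair
#' with PI_HAT above threshold, the member with the lower call rate (ties
#' broken by sample id); heterozygosity rate deviating by at least
#' `het_sd_max` standard deviations from the cohort mean.
#'
#' @param genotypes Dosage matrix with row names as sample ids.
#' @param pihat Data frame `id1`, `id2`, `pihat` of pairwise relatedness
#'   estimates (typically sparse: only pairs worth reporting).
#' @param thresholds An [qc_thresholds()] object.
#' @return List with `genotypes` and `report` (per-rule counts with a
#'   `dispositions` attribute).
#' @export
apply_sample_filters <- function(genotypes, pihat = NULL,
                                 thresholds = qc_thresholds()) {
  th <- thresholds
  ids <- rownames(genotypes)
  stopifnot(!is.null(ids))
  call_rate <- rowMeans(!is.na(genotypes))
  fail_rule <- stats::setNames(rep(NA_character_, length(ids)), ids)

  if (!is.na(th$sample_call_rate_min)) {
    fail_rule[call_rate < th$sample_call_rate_min] <- "call_rate"
  }
  if (!is.null(pihat) && nrow(pihat) && !is.na(th$relatedness_pihat_max)) {
    stopifnot(all(c("id1", "id2", "pihat") %in% names(pihat)))
    rel <- pihat[pihat$pihat > th$relatedness_pihat_max, , drop = FALSE]
    for (k in seq_len(nrow(rel))) {
      a <- rel$id1[k]; b <- rel$id2[k]
      if (!(a %in% ids) || !(b %in% ids)) next
      if (!is.na(fail_rule[a]) || !is.na(fail_rule[b])) next
      drop_id <- if (call_rate[a] < call_rate[b]) a
      else if (call_rate[b] < call_rate[a]) b
      else max(a, b)
      fail_rule[drop_id] <- "relatedness"
    }
  }
  if (!is.na(th$het_sd_max)) {
    alive <- is.na(fail_rule)
    het <- apply(genotypes, 1, function(g) {
      cnt <- .geno_counts(g)
      if (sum(cnt) == 0) return(NA_real_)
      cnt[2] / sum(cnt)
    })
    mu <- mean(het[alive], na.rm = TRUE)
    sdv <- stats::sd(het[alive], na.rm = TRUE)
    if (!is.na(sdv) && sdv > 0) {
      out <- alive & !is.na(het) & abs(het - mu) >= th$het_sd_max * sdv
      fail_rule[out] <- "heterozygosity"
    }
  }

  removed <- !is.na(fail_rule)
  rules <- c("call_rate", "relatedness", "heterozygosity")
  report <- data.frame(
    rule = c(rules, "passed"),
    n = c(vapply(rules, function(r) sum(fail_rule == r, na.rm = TRUE),
                 integer(1)),
          sum(!removed)),
    stringsAsFactors = FALSE
  )
  attr(report, "dispositions") <- data.frame(
    sample_id = ids[removed], rule = unname(fail_rule[removed]),
    stringsAsFactors = FALSE)
  list(genotypes = genotypes[!removed, , drop = FALSE], report = report)
}
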