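#' Run the full Mendelian randomization pipeline on a cohort
#'
#' Executes the analysis end to end: optional instrument selection against a
#' reference panel, genotype quality control, weighted genetic risk score
#' construction, per-dataset covariate-adjusted logistic associations (overall
#' and stratified), fixed-effect meta-analysis with between-dataset and
#' between-subgroup Cochran's Q, and the summary-statistic sensitivity suite
#' (IVW, MR-Egger, simple and weighted median). When `out_dir` is given,
#' every result table is written as TSV along with a run log recording the
#' seed and per-stage record counts.
#'
#' @param cohort An `mr_cohort` (see [simulate_cohort()] / [read_cohort()]).
#' @param candidates,reference Optional candidate locus table and
#'   [reference_panel()]; when supplied, [select_instruments()] produces the
#'   instrument set, otherwise `cohort$instruments` is used as-is.
#' @param thresholds [qc_thresholds()] for genotype QC.
#' @param pihat Optional pairwise relatedness table for sample QC.
#' @param strata Stratified analyses to run (see [run_association_suite()]).
#' @param meta_method `"fixed"` or `"random"` pooling.
#' @param per_snp Also fit each instrument SNP against the outcome.
#' @param standardize Report the risk-score odds ratio per control-SD of the
#'   score (default) rather than per weighted-allele unit.
#' @param n_boot,seed Bootstrap settings for the median estimators.
#' @param out_dir Optional output directory.
#' @return List of class `mr_pipeline_result` with elements `instruments`,
#'   `selection_report`, `variant_qc`, `sample_qc`, `scores`, `associations`,
#'   `meta` (per-stratum-level pooled estimates), `subgroup_heterogeneity`,
#'   `mr_estimates`, `sumstats`, and `log`.
#' @export
run_mr_pipeline <- function(cohort,
                            candidates = NULL, reference = NULL,
                            thresholds = qc_thresholds(),
                            pihat = NULL,
                            strata = c("overall", "age", "sex", "smoking",
                                       "histology"),
                            meta_method = c("fixed", "random"),
                            per_snp = FALSE,
                            standardize = TRUE,
                            n_boot = 1000L, seed = 1L,
                            out_dir = NULL) {
  meta_method <- match.arg(meta_method)
  log_lines <- c(
    sprintf("mrgrs %s", as.character(utils::packageVersion("mrgrs"))),
    sprintf("seed: %d; meta model: %s; strata: %s", seed, meta_method,
            paste(strata, collapse = ",")))
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  # --- instrument selection -------------------------------------------------
  if (!is.null(candidates)) {
    if (is.null(reference)) {
      stop("instrument selection requires a reference panel", call. = FALSE)
    }
    sel <- select_instruments(candidates, reference)
    instruments <- sel$instruments
    selection_report <- sel$report
    note("selection: %d candidates -> %d instruments",
         selection_report$n_input, selection_report$n_final)
  } else {
    instruments <- cohort$instruments
    selection_report <- NULL
    note("selection: skipped, %d instruments supplied", nrow(instruments))
  }

  # --- genotype QC ----------------------------------------------------------
  vq <- apply_variant_filters(cohort$genotypes, cohort$phenotypes, thresholds)
  note("variant QC: %d -> %d variants", ncol(cohort$genotypes),
       ncol(vq$genotypes))
  sq <- apply_sample_filters(vq$genotypes, pihat, thresholds)
  note("sample QC: %d -> %d samples", nrow(vq$genotypes), nrow(sq$genotypes))
  G <- sq$genotypes
  ph <- cohort$phenotypes[match(rownames(G), cohort$phenotypes$sample_id), ,
                          drop = FALSE]

  # --- weighted genetic risk score -----------------------------------------
  scores <- compute_wgrs(G, instruments, variant_info = cohort$variants,
                         phenotypes = ph, standardize = standardize)
  note("wGRS: %d of %d instruments used", scores$n_variants_used,
       nrow(instruments))

  # --- per-dataset associations, overall and stratified --------------------
  assoc <- run_association_suite(ph, scores,
                                 genotypes = if (per_snp) G else NULL,
                                 strata = strata)
  note("associations: %d fits", nrow(assoc))

  # --- meta-analysis and heterogeneity -------------------------------------
  wg <- assoc[assoc$term == "wGRS" & assoc$converged, , drop = FALSE]
  meta <- list()
  for (key in unique(paste(wg$stratum, wg$level, sep = ":"))) {
    sub <- wg[paste(wg$stratum, wg$level, sep = ":") == key, , drop = FALSE]
    meta[[key]] <- meta_fixed(sub$beta, sub$se, labels = sub$dataset,
                              method = meta_method)
  }
  subgroup_het <- list()
  for (st in setdiff(unique(wg$stratum), "overall")) {
    levs <- unique(wg$level[wg$stratum == st])
    if (length(levs) < 2L) next
    pooled <- t(vapply(levs, function(lv) {
      m <- meta[[paste(st, lv, sep = ":")]]
      c(m$beta, m$se)
    }, numeric(2)))
    subgroup_het[[st]] <- subgroup_heterogeneity(levs, pooled[, 1], pooled[, 2])
  }
  if ("overall:all" %in% names(meta)) {
    m <- meta[["overall:all"]]
    note("pooled wGRS OR %.3f (%.3f-%.3f), p = %.3g, p_het = %.3g",
         m$or, m$ci_low, m$ci_high, m$p, m$p_het)
  }

  # --- summary-statistic sensitivity suite ---------------------------------
  qc_cohort <- cohort
  qc_cohort$genotypes <- G
  qc_cohort$phenotypes <- ph
  sumstats <- cohort_to_sumstats(qc_cohort)
  mr_est <- mr_all_methods(sumstats, n_boot = n_boot, seed = seed)
  note("summary MR: IVW OR %.3f, Egger intercept p = %.3g",
       mr_est$or[mr_est$method == "ivw"],
       mr_est$p_intercept[mr_est$method == "egger"])

  result <- structure(list(
    instruments = instruments,
    selection_report = selection_report,
    variant_qc = vq$report,
    sample_qc = sq$report,
    scores = scores,
    associations = assoc,
    meta = meta,
    subgroup_heterogeneity = subgroup_het,
    mr_estimates = mr_est,
    sumstats = sumstats,
    log = log_lines
  ), class = "mr_pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_instruments(instruments, file.path(out_dir, "instruments.tsv"))
    if (!is.null(selection_report)) {
      .write_tsv(selection_report$dispositions,
                 file.path(out_dir, "selection_dispositions.tsv"))
    }
    .write_tsv(assoc, file.path(out_dir, "associations.tsv"))
    .write_tsv(data.frame(sample_id = names(scores$score),
                          wgrs = unname(scores$score),
                          stringsAsFactors = FALSE),
               file.path(out_dir, "wgrs.tsv"))
    meta_tab <- do.call(rbind, lapply(names(meta), function(k) {
      m <- meta[[k]]
      data.frame(stratum = k, beta = m$beta, se = m$se, or = m$or,
                 ci_low = m$ci_low, ci_high = m$ci_high, p = m$p, Q = m$Q,
                 df = m$df, p_het = m$p_het, k = m$k,
                 stringsAsFactors = FALSE)
    }))
    .write_tsv(meta_tab, file.path(out_dir, "meta.tsv"))
    if ("overall:all" %in% names(meta)) {
      .write_tsv(forest_table(meta[["overall:all"]]),
                 file.path(out_dir, "forest_overall.tsv"))
    }
    .write_tsv(sumstats, file.path(out_dir, "sumstats.tsv"))
    .write_tsv(mr_est, file.path(out_dir, "mr_estimates.tsv"))
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  result
}

#' @export
print.mr_pipeline_result <- function(x, ...) {
  writeLines(x$log)
  invisible(x)
}
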