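#' Per-variant exposure and outcome summary statistics from a cohort
#'
#' Produces the harmonized per-SNP input of the summary-statistic causal
#' estimators: for each instrument, a covariate-adjusted exposure association
#' and a covariate-adjusted logistic outcome association, both oriented to the
#' cohort's effect alleles.
#'
#' With the default `"published"` scale the exposure coefficients are not
#' re-estimated from the cohort at all: they are taken from the cohort's
#' instrument table, exactly as a risk-score analysis weights dosages with
#' external GWAS effect sizes. This gives a two-sample design in which
#' exposure- and outcome-side sampling errors are independent, so the ratio
#' estimators are free of the correlated-error and regression-dilution
#' artifacts that one-sample re-estimation introduces.
#'
#' On the `"liability"` scale the exposure coefficient is the
#' per-allele effect on the continuous exposure liability, estimated by
#' linear regression on the full sample: because the outcome is rare, the
#' case-enrichment tilt of the liability distribution is independent of
#' genotype, so the slope is unaffected by ascertainment and the full sample
#' gives the smallest exposure standard errors (which keeps the ratio-based
#' estimators' first-order weights nearly noise-free). With `"status"` the
#' coefficient is the per-allele log-odds of binary exposure status from a
#' logistic model fitted among controls only, since exposure status is
#' correlated with the outcome whenever the causal effect is nonzero. The
#' liability scale matches the scale on which the causal effect acts in the
#' generative model, so ratio-based estimators recover `causal_logor`
#' directly.
#'
#' @param cohort An `mr_cohort` from [simulate_cohort()], or any list with
#'   `genotypes` and a compatible `phenotypes` table (plus an `instruments`
#'   table for the `"published"` scale).
#' @param exposure_scale `"published"` (default), `"liability"` or `"status"`.
#' @return Data frame of class `mr_sumstats` with columns `rsid`, `beta_x`,
#'   `se_x`, `beta_y`, `se_y`. Monomorphic variants are dropped with a
#'   warning.
#' @export
cohort_to_sumstats <- function(cohort,
                               exposure_scale = c("published", "liability",
                                                  "status")) {
  exposure_scale <- match.arg(exposure_scale)
  ph <- cohort$phenotypes
  G <- cohort$genotypes
  stopifnot(nrow(ph) == nrow(G), !is.null(ph$case))

  pcs <- grep("^PC[0-9]+$", names(ph), value = TRUE)
  C <- as.matrix(ph[, c("age60", "sex", "smoker", pcs)])
  ds <- unique(ph$dataset)
  if (length(ds) > 1L) {
    # dataset fixed effects for the pooled fits
    dmm <- stats::model.matrix(~ factor(ph$dataset))[, -1, drop = FALSE]
    colnames(dmm) <- paste0("ds", seq_len(ncol(dmm)))
    C <- cbind(C, dmm)
  }

  mono <- apply(G, 2, stats::sd) == 0
  if (any(mono)) {
    warning(sprintf("dropping %d monomorphic variant(s): %s", sum(mono),
                    paste(colnames(G)[mono], collapse = ", ")), call. = FALSE)
    G <- G[, !mono, drop = FALSE]
  }

  is_ctrl <- ph$case == 0
  xs <- if (exposure_scale == "published") {
    inst <- cohort$instruments
    stopifnot(!is.null(inst), all(colnames(G) %in% inst$rsid))
    m <- match(colnames(G), inst$rsid)
    cbind(beta = inst$beta[m], se = inst$se[m], p = NA_real_)
  } else if (exposure_scale == "liability") {
    stopifnot(!is.null(ph$liability))
    .linear_scan(ph$liability, G, C)
  } else {
    stopifnot(!is.null(ph$t2d))
    .logistic_scan(ph$t2d[is_ctrl], G[is_ctrl, , drop = FALSE],
                   C[is_ctrl, , drop = FALSE])
  }
  ys <- .logistic_scan(ph$case, G, C)

  out <- data.frame(rsid = colnames(G),
                    beta_x = xs[, "beta"], se_x = xs[, "se"],
                    beta_y = ys[, "beta"], se_y = ys[, "se"],
                    stringsAsFactors = FALSE)
  keep <- stats::complete.cases(out)
  if (any(!keep)) {
    warning(sprintf("dropping %d variant(s) with unstable fits: %s",
                    sum(!keep), paste(out$rsid[!keep], collapse = ", ")),
            call. = FALSE)
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("mr_sumstats", "data.frame")
  out
}
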