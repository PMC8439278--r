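#' Covariate-adjusted logistic association with Wald inference
#'
#' Fits a maximum-likelihood logistic regression of a binary outcome on one
#' exposure term plus optional covariates (iteratively reweighted least
#' squares) and returns Wald inference for the exposure term. This is the
#' engine behind the per-SNP and genetic-risk-score disease models, which are
#' adjusted for age, sex, smoking status and ten principal components.
#'
#' @param outcome Binary (0/1) vector with both classes present.
#' @param exposure Numeric vector (dosage, risk score, or indicator).
#' @param covariates Optional numeric matrix or data frame of covariates.
#' @param term Label for the exposure term in the result.
#' @param epsilon,maxit IRLS convergence tolerance (relative deviance change)
#'   and iteration cap.
#' @return A one-row data frame of class `mr_assoc`: `term`, `beta` (log-OR),
#'   `se`, `or`, `ci_low`, `ci_high` (95% Wald), `p`, `n`, `converged`. Under
#'   (quasi-)separation, flagged by a divergent coefficient, estimates are
#'   `NA` and `converged` is `FALSE`.
#' @examples
#' y <- rep(c(1, 0, 1, 0), c(10, 20, 20, 10))
#' x <- rep(c(1, 1, 0, 0), c(10, 20, 20, 10))
#' fit_logistic(y, x) # OR = 0.25
#' @export
fit_logistic <- function(outcome, exposure, covariates = NULL,
                         term = "exposure", epsilon = 1e-10, maxit = 25L) {
  outcome <- as.numeric(outcome)
  exposure <- as.numeric(exposure)
  n <- length(outcome)
  stopifnot(length(exposure) == n, all(outcome %in% c(0, 1)))
  if (length(unique(outcome)) < 2L) {
    stop("outcome has a single class", call. = FALSE)
  }
  if (stats::sd(exposure) == 0) stop("exposure is constant", call. = FALSE)

  X <- cbind(`(Intercept)` = 1, exposure = exposure)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("covar", seq_len(ncol(covariates)))
    }
    X <- cbind(X, covariates)
  }
  if (anyNA(X) || anyNA(outcome)) {
    stop("missing values in model inputs; apply listwise deletion upstream",
         call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop(sprintf("rank-deficient design: collinear column(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }

  fit <- suppressWarnings(stats::glm.fit(
    x = X, y = outcome, family = stats::binomial(),
    control = stats::glm.control(epsilon = epsilon, maxit = maxit)
  ))
  separated <- any(abs(fit$coefficients) > 15, na.rm = TRUE)
  converged <- isTRUE(fit$converged) && !separated
  if (!converged) {
    out <- data.frame(term = term, beta = NA_real_, se = NA_real_,
                      or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      p = NA_real_, n = n, converged = FALSE,
                      stringsAsFactors = FALSE)
    class(out) <- c("mr_assoc", "data.frame")
    return(out)
  }
  p <- ncol(X)
  covmat <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  beta <- fit$coefficients[["exposure"]]
  pos <- which(fit$qr$pivot == 2L)
  se <- sqrt(covmat[pos, pos])
  w <- wald_row(beta, se)
  out <- data.frame(term = term, beta = w$beta, se = w$se, or = w$or,
                    ci_low = w$ci_low, ci_high = w$ci_high, p = w$p,
                    n = n, converged = TRUE, stringsAsFactors = FALSE)
  class(out) <- c("mr_assoc", "data.frame")
  out
}

# Fast per-SNP logistic scan: one glm fit per genotype column, shared
# covariate block. Returns beta/se/p for the dosage term; monomorphic columns
# come back NA.
.logistic_scan <- function(y, G, C = NULL) {
  base <- cbind(1, C)
  p <- ncol(base) + 1L
  res <- matrix(NA_real_, ncol(G), 3,
                dimnames = list(colnames(G), c("beta", "se", "p")))
  ctrl <- stats::glm.control(epsilon = 1e-8, maxit = 25L)
  fam <- stats::binomial()
  # warm start from the covariate-only fit: per-SNP effects are small, so
  # IRLS from here converges in a couple of iterations
  base_fit <- suppressWarnings(stats::glm.fit(base, y, family = fam,
                                              control = ctrl))
  start <- c(base_fit$coefficients, 0)
  for (j in seq_len(ncol(G))) {
    g <- G[, j]
    if (stats::sd(g) == 0) next
    fit <- suppressWarnings(stats::glm.fit(cbind(base, g), y, family = fam,
                                           control = ctrl, start = start))
    if (!isTRUE(fit$converged)) next
    covmat <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
    b <- fit$coefficients[p]
    pos <- which(fit$qr$pivot == p)
    s <- sqrt(covmat[pos, pos])
    res[j, ] <- c(b, s, 2 * stats::pnorm(-abs(b / s)))
  }
  res
}

# Per-SNP linear scan via Frisch-Waugh residualization: exact multiple-
# regression slope and SE for each genotype column given shared covariates.
.linear_scan <- function(y, G, C = NULL) {
  n <- length(y)
  base <- cbind(rep(1, n), C)
  qrb <- qr(base)
  ry <- stats::resid(stats::lm.fit(base, y))
  rG <- G - qr.fitted(qrb, G)
  df <- n - ncol(base) - 1L
  sxx <- colSums(rG^2)
  slope <- as.vector(crossprod(rG, ry)) / sxx
  rss <- sum(ry^2) - slope^2 * sxx
  se <- sqrt(pmax(rss, 0) / df / sxx)
  bad <- sxx < .Machine$double.eps * n
  slope[bad] <- NA_real_
  se[bad] <- NA_real_
  cbind(beta = slope, se = se,
        p = 2 * stats::pt(-abs(slope / se), df))
}

#' Per-dataset, stratified association suite
#'
#' Runs the covariate-adjusted logistic disease model for the weighted genetic
#' risk score (and optionally each instrument SNP) in every dataset and
#' stratum. Strata follow the study design: overall, age (<60 / >=60), sex,
#' smoking status and case histology (each histological subtype versus all
#' controls). The stratification variable is dropped from the covariates in
#' its own analysis. Per-SNP results are flagged significant only at the
#' Bonferroni level 0.05 / (number of SNPs).
#'
#' @param phenotypes Phenotype data frame with columns `sample_id`, `dataset`,
#'   `case`, `age60`, `sex`, `smoker`, `histology`, `PC1`..`PC10`.
#' @param scores Numeric vector of risk scores named by (or aligned with)
#'   `phenotypes$sample_id`, e.g. from [compute_wgrs()].
#' @param genotypes Optional dosage matrix for per-SNP associations.
#' @param strata Character subset of
#'   `c("overall", "age", "sex", "smoking", "histology")`.
#' @return Data frame with one row per dataset x stratum x term: columns
#'   `dataset`, `stratum`, `level`, `term`, the [fit_logistic()] fields, and
#'   `bonferroni_sig` for SNP terms. Strata with a single outcome class are
#'   skipped with a warning.
#' @export
run_association_suite <- function(phenotypes, scores, genotypes = NULL,
                                  strata = c("overall", "age", "sex",
                                             "smoking", "histology")) {
  strata <- match.arg(strata, several.ok = TRUE)
  if (inherits(scores, "mr_wgrs")) scores <- scores$score
  stopifnot(length(scores) == nrow(phenotypes))
  pcs <- grep("^PC[0-9]+$", names(phenotypes), value = TRUE)
  covar_all <- c("age60", "sex", "smoker", pcs)
  strat_var <- c(age = "age60", sex = "sex", smoking = "smoker")

  rows <- list()
  add <- function(fit, dataset, stratum, level, sig = NA) {
    fit$dataset <- dataset; fit$stratum <- stratum; fit$level <- level
    fit$bonferroni_sig <- sig
    rows[[length(rows) + 1L]] <<- fit
  }
  n_snps <- if (is.null(genotypes)) 0L else ncol(genotypes)

  run_one <- function(idx, dataset, stratum, level, covars) {
    y <- phenotypes$case[idx]
    if (length(unique(y)) < 2L || length(y) < length(covars) + 3L) {
      warning(sprintf("stratum %s=%s in %s has a single outcome class or too few samples; skipped",
                      stratum, level, dataset), call. = FALSE)
      return(invisible(NULL))
    }
    C <- as.matrix(phenotypes[idx, covars, drop = FALSE])
    add(fit_logistic(y, scores[idx], C, term = "wGRS"), dataset, stratum, level)
    if (n_snps > 0L) {
      scan <- .logistic_scan(y, genotypes[idx, , drop = FALSE], C)
      for (j in seq_len(nrow(scan))) {
        b <- scan[j, "beta"]; s <- scan[j, "se"]
        if (is.na(b)) next
        w <- wald_row(b, s)
        fit <- data.frame(term = rownames(scan)[j], beta = w$beta, se = w$se,
                          or = w$or, ci_low = w$ci_low, ci_high = w$ci_high,
                          p = w$p, n = length(y), converged = TRUE,
                          stringsAsFactors = FALSE)
        add(fit, dataset, stratum, level, sig = w$p < 0.05 / n_snps)
      }
    }
  }

  for (ds in unique(phenotypes$dataset)) {
    in_ds <- phenotypes$dataset == ds
    for (st in strata) {
      if (st == "overall") {
        run_one(which(in_ds), ds, "overall", "all", covar_all)
      } else if (st %in% names(strat_var)) {
        v <- strat_var[[st]]
        covars <- setdiff(covar_all, v)
        for (lev in sort(unique(phenotypes[[v]][in_ds]))) {
          run_one(which(in_ds & phenotypes[[v]] == lev), ds, st,
                  as.character(lev), covars)
        }
      } else if (st == "histology") {
        hls <- unique(stats::na.omit(phenotypes$histology[in_ds & phenotypes$case == 1]))
        for (h in sort(hls)) {
          idx <- which(in_ds & (phenotypes$case == 0 |
                                  (!is.na(phenotypes$histology) &
                                     phenotypes$histology == h)))
          run_one(idx, ds, "histology", h, covar_all)
        }
      }
    }
  }
  if (!length(rows)) {
    stop("no analyzable dataset/stratum combination", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[, c("dataset", "stratum", "level", "term", "beta", "se", "or",
                 "ci_low", "ci_high", "p", "n", "converged", "bonferroni_sig")]
  rownames(out) <- NULL
  out
}
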