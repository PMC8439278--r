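# Summary-statistic Mendelian randomization estimators.
#
# All three estimators consume a harmonized table of per-variant summary
# pairs: the exposure effect (beta_x, se_x) and outcome effect (beta_y, se_y)
# of the same effect allele. Weights are first-order (outcome-variance only),
# the classical choice for these estimators.

.check_pairs <- function(pairs, min_n) {
  need <- c("beta_x", "se_x", "beta_y", "se_y")
  stopifnot(all(need %in% names(pairs)))
  pairs <- as.data.frame(pairs)
  stopifnot(all(pairs$se_x > 0), all(pairs$se_y > 0),
            !anyNA(pairs[, need]))
  if (nrow(pairs) < min_n) {
    stop(sprintf("estimator requires at least %d summary pairs", min_n),
         call. = FALSE)
  }
  pairs
}

.mr_row <- function(method, beta, se, n_snps,
                    intercept = NA_real_, intercept_se = NA_real_,
                    p_intercept = NA_real_) {
  w <- wald_row(beta, se)
  out <- data.frame(method = method, beta = w$beta, se = w$se, or = w$or,
                    ci_low = w$ci_low, ci_high = w$ci_high, p = w$p,
                    n_snps = n_snps, intercept = intercept,
                    intercept_se = intercept_se, p_intercept = p_intercept,
                    stringsAsFactors = FALSE)
  class(out) <- c("mr_estimate", "data.frame")
  out
}

#' Inverse-variance weighted causal estimate
#'
#' Fixed-effect IVW: the zero-intercept weighted regression of outcome effects
#' on exposure effects with weights `1/se_y^2`, equivalently the
#' inverse-variance-weighted mean of per-variant ratio estimates
#' `beta_y/beta_x` with first-order weights `beta_x^2/se_y^2`.
#'
#' @param pairs Data frame of harmonized summary pairs (`beta_x`, `se_x`,
#'   `beta_y`, `se_y`; >= 2 rows).
#' @return One-row `mr_estimate` data frame: causal log-OR per unit exposure,
#'   `se`, `or`, 95% CI, Wald `p`, `n_snps`.
#' @export
mr_ivw <- function(pairs) {
  pairs <- .check_pairs(pairs, 2L)
  if (all(pairs$beta_x == 0)) {
    stop("all exposure effects are zero: no instrument strength", call. = FALSE)
  }
  w <- 1 / pairs$se_y^2
  denom <- sum(pairs$beta_x^2 * w)
  beta <- sum(pairs$beta_x * pairs$beta_y * w) / denom
  se <- sqrt(1 / denom)
  .mr_row("ivw", beta, se, nrow(pairs))
}

#' MR-Egger regression with pleiotropy intercept test
#'
#' Weighted least squares of outcome effects on exposure effects with a free
#' intercept and weights `1/se_y^2`, after re-orienting every pair so that
#' `beta_x >= 0` (flipping the sign of `beta_y` accordingly, so the fit is
#' invariant to input orientation). The slope estimates the causal effect
#' under the InSIDE assumption; the intercept estimates average directional
#' pleiotropy, with its own Wald test. Standard errors carry a multiplicative
#' residual over-dispersion factor bounded below by 1.
#'
#' @param pairs Data frame of harmonized summary pairs (>= 3 rows with spread
#'   in `beta_x`).
#' @return One-row `mr_estimate` data frame including `intercept`,
#'   `intercept_se`, `p_intercept`.
#' @export
mr_egger <- function(pairs) {
  pairs <- .check_pairs(pairs, 3L)
  flip <- sign(pairs$beta_x)
  flip[flip == 0] <- 1
  bx <- pairs$beta_x * flip
  by <- pairs$beta_y * flip
  if (stats::sd(bx) == 0) {
    stop("no spread in exposure effects: Egger slope unidentified",
         call. = FALSE)
  }
  w <- 1 / pairs$se_y^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X, w * X)
  coef <- solve(XtWX, crossprod(X, w * by))
  resid <- by - X %*% coef
  n <- nrow(pairs)
  sigma <- sqrt(sum(w * resid^2) / (n - 2))
  scale <- max(1, sigma)
  vc <- solve(XtWX) * scale^2
  intercept <- coef[1]
  slope <- coef[2]
  i_se <- sqrt(vc[1, 1])
  .mr_row("egger", slope, sqrt(vc[2, 2]), n,
          intercept = intercept, intercept_se = i_se,
          p_intercept = 2 * stats::pnorm(-abs(intercept / i_se)))
}

#' Simple and weighted median causal estimates
#'
#' The 50% point of the per-variant ratio estimates `beta_y/beta_x`, taken by
#' linear interpolation in cumulative weight; equal weights give the simple
#' median, inverse-variance first-order weights (`beta_x^2/se_y^2`) the
#' weighted median, which is consistent when valid instruments carry at least
#' half the weight. The standard error comes from a parametric bootstrap that
#' resamples each `beta_x` and `beta_y` from its normal sampling distribution.
#'
#' @param pairs Data frame of harmonized summary pairs; pairs with
#'   `beta_x == 0` are dropped with a warning, and at least 3 must survive.
#' @param weighted Use inverse-variance weights (`TRUE`) or equal weights.
#' @param n_boot Bootstrap replicates (>= 100).
#' @param seed Seed for the bootstrap stream (the caller's RNG state is
#'   restored afterwards).
#' @return One-row `mr_estimate` data frame.
#' @export
mr_median <- function(pairs, weighted = FALSE, n_boot = 1000L, seed = NULL) {
  pairs <- .check_pairs(pairs, 1L)
  stopifnot(n_boot >= 100L)
  zero <- pairs$beta_x == 0
  if (any(zero)) {
    warning(sprintf("dropping %d pair(s) with zero exposure effect", sum(zero)),
            call. = FALSE)
    pairs <- pairs[!zero, , drop = FALSE]
  }
  if (nrow(pairs) < 3L) {
    stop("median estimator requires at least 3 usable summary pairs",
         call. = FALSE)
  }
  est_fun <- function(bx, by, sy) {
    r <- by / bx
    w <- if (weighted) bx^2 / sy^2 else rep(1, length(r))
    weighted_percentile(r, w, 0.5)
  }
  beta <- est_fun(pairs$beta_x, pairs$beta_y, pairs$se_y)
  k <- nrow(pairs)
  boots <- with_seed(seed, {
    bxm <- matrix(stats::rnorm(n_boot * k, pairs$beta_x, pairs$se_x),
                  nrow = n_boot, byrow = TRUE)
    bym <- matrix(stats::rnorm(n_boot * k, pairs$beta_y, pairs$se_y),
                  nrow = n_boot, byrow = TRUE)
    vapply(seq_len(n_boot),
           function(b) est_fun(bxm[b, ], bym[b, ], pairs$se_y),
           numeric(1))
  })
  .mr_row(if (weighted) "weighted_median" else "simple_median",
          beta, stats::sd(boots), k)
}

#' Run the full summary-statistic sensitivity suite
#'
#' Convenience wrapper returning IVW, MR-Egger, simple median and weighted
#' median estimates as one table.
#'
#' @inheritParams mr_median
#' @return `mr_estimate` data frame with one row per method.
#' @export
mr_all_methods <- function(pairs, n_boot = 1000L, seed = 1L) {
  out <- rbind(
    mr_ivw(pairs),
    mr_egger(pairs),
    mr_median(pairs, weighted = FALSE, n_boot = n_boot, seed = seed),
    mr_median(pairs, weighted = TRUE, n_boot = n_boot, seed = seed)
  )
  rownames(out) <- NULL
  out
}
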