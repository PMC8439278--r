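#' Inverse-variance meta-analysis with Cochran's Q
#'
#' Pools per-dataset log-odds estimates with inverse-variance weights.
#' Fixed-effect pooling is the headline model; a DerSimonian-Laird
#' random-effects option is available for sensitivity. Cochran's Q is always
#' computed with the fixed-effect weights: `Q = sum w_i (b_i - b_pooled)^2`,
#' chi-square with k-1 degrees of freedom under homogeneity.
#'
#' @param beta,se Numeric vectors of estimates and standard errors (se > 0).
#' @param labels Optional estimate labels.
#' @param method `"fixed"` (default) or `"random"` (DerSimonian-Laird).
#' @return Object of class `mr_meta`: pooled `beta`, `se`, `or`, `ci_low`,
#'   `ci_high`, `p`, heterogeneity `Q`, `df`, `p_het`, count `k`, `tau2`
#'   (random-effects only), and the input table. A single estimate is passed
#'   through with `Q = 0`, `p_het = 1`.
#' @examples
#' meta_fixed(c(0, 1), c(1, 1)) # pooled 0.5, Q = 0.5, p_het ~ 0.48
#' @export
meta_fixed <- function(beta, se, labels = NULL,
                       method = c("fixed", "random")) {
  method <- match.arg(method)
  k <- length(beta)
  if (k == 0L) stop("no estimates to pool", call. = FALSE)
  stopifnot(length(se) == k, all(se > 0), !anyNA(beta), !anyNA(se))
  labels <- labels %||% paste0("estimate", seq_len(k))

  w <- 1 / se^2
  pooled_fe <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - pooled_fe)^2)
  df <- k - 1L
  p_het <- if (df == 0L) 1 else stats::pchisq(Q, df, lower.tail = FALSE)

  if (method == "random" && k > 1L) {
    tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
    wr <- 1 / (se^2 + tau2)
    pooled <- sum(wr * beta) / sum(wr)
    pooled_se <- sqrt(1 / sum(wr))
  } else {
    tau2 <- if (method == "random") 0 else NA_real_
    pooled <- pooled_fe
    pooled_se <- sqrt(1 / sum(w))
  }
  wd <- wald_row(pooled, pooled_se)
  structure(list(
    beta = wd$beta, se = wd$se, or = wd$or, ci_low = wd$ci_low,
    ci_high = wd$ci_high, p = wd$p, Q = Q, df = df, p_het = p_het, k = k,
    method = method, tau2 = tau2,
    estimates = data.frame(label = labels, beta = beta, se = se,
                           weight_pct = 100 * w / sum(w),
                           stringsAsFactors = FALSE)
  ), class = "mr_meta")
}

#' @export
print.mr_meta <- function(x, ...) {
  cat(sprintf("%s-effect meta-analysis of %d estimates\n",
              x$method, x$k))
  cat(sprintf("  OR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$or, x$ci_low, x$ci_high, x$p))
  cat(sprintf("  heterogeneity: Q = %.3f on %d df, p = %.3g\n",
              x$Q, x$df, x$p_het))
  invisible(x)
}

#' Between-subgroup heterogeneity test
#'
#' Cochran's Q across stratum-level estimates (each typically itself a pooled
#' per-dataset estimate), with (number of strata - 1) degrees of freedom.
#'
#' @param labels,beta,se Stratum labels, estimates, standard errors (>= 2
#'   strata).
#' @return List with `Q`, `df`, `p_het`, `k`.
#' @export
subgroup_heterogeneity <- function(labels, beta, se) {
  k <- length(beta)
  if (k < 2L) stop("subgroup heterogeneity needs at least 2 strata",
                   call. = FALSE)
  stopifnot(length(se) == k, all(se > 0))
  m <- meta_fixed(beta, se, labels = labels)
  list(Q = m$Q, df = m$df, p_het = m$p_het, k = k)
}

#' Forest-plot-ready table from pooled and per-dataset estimates
#'
#' @param meta An `mr_meta` object.
#' @return Data frame with `label`, `beta`, `se`, `or`, `ci_low`, `ci_high`,
#'   `weight_pct`; the pooled row is labelled `"pooled"` with weight 100.
#' @export
forest_table <- function(meta) {
  stopifnot(inherits(meta, "mr_meta"))
  est <- meta$estimates
  rows <- data.frame(
    label = c(est$label, "pooled"),
    beta = c(est$beta, meta$beta),
    se = c(est$se, meta$se),
    stringsAsFactors = FALSE
  )
  rows$or <- exp(rows$beta)
  rows$ci_low <- exp(rows$beta - Z95 * rows$se)
  rows$ci_high <- exp(rows$beta + Z95 * rows$se)
  rows$weight_pct <- c(est$weight_pct, 100)
  rows
}
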