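# Internal helpers shared across modules.

# Two-sided Wald normal quantile used for every 95% interval in the package.
# Kept as a literal so that intervals are reproducible constants.
Z95 <- 1.959964

# Wald summary from a point estimate and standard error on the log-odds scale.
wald_row <- function(beta, se) {
  z <- beta / se
  list(
    beta = beta, se = se, or = exp(beta),
    ci_low = exp(beta - Z95 * se), ci_high = exp(beta + Z95 * se),
    p = 2 * stats::pnorm(-abs(z))
  )
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so that library calls do not perturb user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

# Weighted percentile by linear interpolation in cumulative weight, the
# convention used by the weighted-median causal estimator: the j-th order
# statistic sits at cumulative probability (S_j - w_j/2) / S_n.
weighted_percentile <- function(x, w, prob = 0.5) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  cw <- (cumsum(w) - w / 2) / sum(w)
  if (prob <= cw[1]) return(x[1])
  if (prob >= cw[length(cw)]) return(x[length(x)])
  stats::approx(cw, x, xout = prob, ties = "ordered")$y
}

# DNA strand complement for allele harmonization.
flip_strand <- function(a) {
  chartr("ACGT", "TGCA", toupper(a))
}

is_palindromic <- function(a1, a2) {
  toupper(a2) == flip_strand(a1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
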