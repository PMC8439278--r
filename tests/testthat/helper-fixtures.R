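# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# A small multi-dataset null cohort used by several module tests.
small_null_cohort <- function() {
  cached("small_null", function() {
    simulate_cohort(simulation_config(
      n_variants = 12, n_datasets = 2,
      n_cases_per_dataset = 300, n_controls_per_dataset = 300,
      seed = 424242))
  })
}

# Log-likelihood maximizer independent of IRLS, used as the logistic oracle.
logistic_ml_oracle <- function(y, X) {
  nll <- function(b) {
    eta <- as.vector(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  stats::optim(rep(0, ncol(X)), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))$par
}

# Tiny phenotype/genotype pair with hand-controllable structure.
toy_phenotypes <- function(n, case, seed = 1) {
  set.seed(seed)
  ph <- data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    dataset = "dataset1",
    case = case,
    age60 = rbinom(n, 1, 0.5),
    sex = rbinom(n, 1, 0.5),
    smoker = rbinom(n, 1, 0.5),
    histology = NA_character_,
    stringsAsFactors = FALSE
  )
  ph$histology[ph$case == 1] <- sample(c("adenocarcinoma", "squamous"),
                                       sum(case == 1), replace = TRUE)
  for (k in 1:10) ph[[paste0("PC", k)]] <- rnorm(n)
  ph
}
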