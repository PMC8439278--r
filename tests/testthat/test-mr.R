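make_pairs <- function(beta_x, beta_y, se_y, se_x = 0.02) {
  data.frame(rsid = sprintf("v%02d", seq_along(beta_x)),
             beta_x = beta_x, se_x = se_x, beta_y = beta_y, se_y = se_y,
             stringsAsFactors = FALSE)
}

test_that("IVW recovers exact proportionality and the null", {
  p <- make_pairs(c(0.1, 0.2, 0.3), 0.5 * c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.15))
  expect_equal(mr_ivw(p)$beta, 0.5, tolerance = 1e-12)
  p0 <- make_pairs(c(0.1, 0.2, 0.3), c(0, 0, 0), c(0.1, 0.2, 0.15))
  fit <- mr_ivw(p0)
  expect_equal(fit$beta, 0)
  expect_equal(fit$p, 1)
  expect_error(mr_ivw(make_pairs(c(0, 0), c(0.1, 0.2), c(0.1, 0.1))),
               "instrument strength")
  expect_error(mr_ivw(make_pairs(0.1, 0.1, 0.1)), "at least 2")
})

test_that("IVW matches the zero-intercept weighted regression oracle", {
  p <- make_pairs(c(0.1, 0.2, 0.3), c(0.06, 0.05, 0.2), c(0.1, 0.15, 0.2))
  fit <- mr_ivw(p)
  lmfit <- lm(beta_y ~ 0 + beta_x, data = p, weights = 1 / p$se_y^2)
  expect_equal(fit$beta, unname(coef(lmfit)), tolerance = 1e-10)
  # unscaled weighted-least-squares SE (fixed-effect: no residual scaling)
  s <- summary(lmfit)
  expect_equal(fit$se, unname(s$coefficients[1, 2] / s$sigma),
               tolerance = 1e-10)
})

test_that("Egger regression reproduces an exact affine relationship", {
  bx <- c(0.1, 0.15, 0.2, 0.3)
  p <- make_pairs(bx, 0.1 + 0.5 * bx, se_y = c(0.1, 0.12, 0.09, 0.11))
  fit <- mr_egger(p)
  expect_equal(fit$beta, 0.5, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-10)
  # zero residuals: over-dispersion factor floored at one, so the SE is the
  # unscaled weighted normal-equations value
  w <- 1 / p$se_y^2
  X <- cbind(1, bx)
  vc <- solve(t(X) %*% (w * X))
  expect_equal(fit$intercept_se, sqrt(vc[1, 1]), tolerance = 1e-10)
  expect_equal(fit$se, sqrt(vc[2, 2]), tolerance = 1e-10)
})

test_that("Egger regression matches the weighted least-squares oracle", {
  set.seed(61)
  p <- make_pairs(c(0.12, 0.18, 0.25, 0.31),
                  c(0.08, 0.02, 0.11, 0.05),
                  c(0.05, 0.08, 0.06, 0.07))
  fit <- mr_egger(p)
  lmfit <- lm(beta_y ~ beta_x, data = p, weights = 1 / p$se_y^2)
  s <- summary(lmfit)
  expect_equal(fit$intercept, unname(coef(lmfit)[1]), tolerance = 1e-10)
  expect_equal(fit$beta, unname(coef(lmfit)[2]), tolerance = 1e-10)
  scale <- max(1, s$sigma)
  expect_equal(fit$intercept_se,
               unname(s$coefficients[1, 2] / s$sigma * scale),
               tolerance = 1e-10)
  expect_equal(fit$se, unname(s$coefficients[2, 2] / s$sigma * scale),
               tolerance = 1e-10)
})

test_that("Egger output is invariant to pair orientation", {
  set.seed(62)
  p <- make_pairs(runif(6, 0.05, 0.3), rnorm(6, 0.05, 0.05),
                  runif(6, 0.05, 0.15))
  flip <- c(1, -1, 1, -1, -1, 1)
  p2 <- p
  p2$beta_x <- p$beta_x * flip
  p2$beta_y <- p$beta_y * flip
  f1 <- mr_egger(p)
  f2 <- mr_egger(p2)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-12)
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-12)
  expect_equal(f1$se, f2$se, tolerance = 1e-12)
  expect_error(mr_egger(make_pairs(rep(0.2, 3), c(0, 0.1, 0.2), rep(0.1, 3))),
               "spread")
})

test_that("median estimators are exact on constructed ratio sets", {
  # identical ratios collapse to that ratio with vanishing bootstrap SE
  bx <- c(0.1, 0.2, 0.4)
  p <- make_pairs(bx, 0.7 * bx, se_y = rep(1e-6, 3), se_x = 1e-6)
  f <- mr_median(p, weighted = FALSE, n_boot = 200, seed = 1)
  expect_equal(f$beta, 0.7, tolerance = 1e-6)
  expect_lt(f$se, 1e-4)
  # odd equal-weight list: plain middle value, robust to the outlier
  p <- make_pairs(rep(1, 5), c(1, 2, 3, 4, 100), se_y = rep(0.1, 5))
  f <- mr_median(p, weighted = FALSE, n_boot = 200, seed = 1)
  expect_equal(f$beta, 3)
  # zero-strength pairs are dropped with a warning
  p$beta_x[1] <- 0
  expect_warning(f2 <- mr_median(p, n_boot = 200, seed = 1), "zero exposure")
  expect_equal(f2$n_snps, 4)
  expect_error(suppressWarnings(
    mr_median(make_pairs(c(0, 0, 1), c(1, 1, 1), rep(0.1, 3)),
              n_boot = 200, seed = 1)), "at least 3")
})

test_that("median bootstrap is reproducible and leaves the RNG state alone", {
  set.seed(63)
  p <- make_pairs(runif(8, 0.1, 0.3), rnorm(8, 0.1, 0.05),
                  runif(8, 0.05, 0.2))
  before <- .Random.seed
  f1 <- mr_median(p, weighted = TRUE, n_boot = 300, seed = 7)
  expect_identical(.Random.seed, before)
  f2 <- mr_median(p, weighted = TRUE, n_boot = 300, seed = 7)
  expect_identical(f1$se, f2$se)
})

test_that("estimators are equivariant under exposure rescaling", {
  set.seed(64)
  p <- make_pairs(runif(8, 0.1, 0.3), rnorm(8, 0.1, 0.05),
                  runif(8, 0.05, 0.2), se_x = 0.01)
  cc <- 2.5
  p2 <- p
  p2$beta_x <- p$beta_x * cc
  p2$se_x <- p$se_x * cc
  expect_equal(mr_ivw(p2)$beta, mr_ivw(p)$beta / cc, tolerance = 1e-12)
  expect_equal(mr_egger(p2)$beta, mr_egger(p)$beta / cc, tolerance = 1e-12)
  expect_equal(mr_egger(p2)$intercept, mr_egger(p)$intercept,
               tolerance = 1e-12)
  f1 <- mr_median(p, weighted = TRUE, n_boot = 200, seed = 5)
  f2 <- mr_median(p2, weighted = TRUE, n_boot = 200, seed = 5)
  expect_equal(f2$beta, f1$beta / cc, tolerance = 1e-12)
})

test_that("a dominating instrument drives all estimators to its ratio", {
  bx <- c(0.2, 0.1, 0.15, 0.25)
  by <- c(0.08, -0.02, 0.05, 0.01)
  se_y <- c(1e-5, 0.5, 0.5, 0.5) # first pair carries essentially all weight
  p <- make_pairs(bx, by, se_y, se_x = 1e-6)
  r1 <- by[1] / bx[1]
  expect_equal(mr_ivw(p)$beta, r1, tolerance = 1e-4)
  expect_equal(mr_median(p, weighted = TRUE, n_boot = 200, seed = 2)$beta,
               r1, tolerance = 1e-4)
})

test_that("IVW equals the fixed-effect meta-analysis of ratio estimates", {
  set.seed(65)
  p <- make_pairs(runif(10, 0.05, 0.3), rnorm(10, 0.05, 0.08),
                  runif(10, 0.05, 0.2))
  ivw <- mr_ivw(p)
  m <- meta_fixed(p$beta_y / p$beta_x, p$se_y / abs(p$beta_x))
  expect_equal(ivw$beta, m$beta, tolerance = 1e-12)
  expect_equal(ivw$se, m$se, tolerance = 1e-12)
})

test_that("the weighted median resists a pleiotropic minority that biases IVW", {
  set.seed(66)
  k <- 20
  bx <- runif(k, 0.1, 0.3)
  se_y <- rep(0.02, k)
  invalid <- seq_len(8) # 40% of instruments carry a direct effect
  alpha <- ifelse(seq_len(k) %in% invalid, 0.08, 0)
  by <- 0.2 * bx + alpha + rnorm(k, 0, se_y)
  p <- make_pairs(bx, by, se_y, se_x = 0.005)
  wm <- mr_median(p, weighted = TRUE, n_boot = 500, seed = 9)
  ivw <- mr_ivw(p)
  expect_lt(abs(wm$beta - 0.2), 2 * wm$se)
  expect_gt(ivw$beta - 0.2, 2 * ivw$se) # IVW dragged upward by the invalid set
})

test_that("mr_all_methods returns one row per estimator", {
  set.seed(67)
  p <- make_pairs(runif(10, 0.1, 0.3), rnorm(10, 0.1, 0.05),
                  runif(10, 0.05, 0.2))
  out <- mr_all_methods(p, n_boot = 200, seed = 4)
  expect_equal(out$method,
               c("ivw", "egger", "simple_median", "weighted_median"))
  expect_true(all(is.na(out$intercept[out$method != "egger"])))
  expect_false(is.na(out$intercept[out$method == "egger"]))
})
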