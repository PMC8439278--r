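test_that("ld_r2 is the squared Pearson correlation of dosages", {
  g1 <- c(0, 1, 2, 0, 1, 2)
  expect_equal(ld_r2(g1, g1), 1.0)
  expect_equal(ld_r2(g1, 2 - g1), 1.0) # perfect anticorrelation squares to 1

  # textbook Pearson r on a small constructed pair
  a <- c(0, 1, 2, 1, 0, 2, 1)
  b <- c(1, 1, 2, 0, 0, 2, 2)
  r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(ld_r2(a, b), r^2, tolerance = 1e-12)

  expect_error(ld_r2(c(1, 1, 1), c(0, 1, 2)), "monomorphic")
  expect_error(ld_r2(c(0, 1), c(0, 1, 2)))
})

# small hand-buildable panel: k variants, explicit dosages
tiny_panel <- function(dosages, chr = NULL) {
  k <- ncol(dosages)
  ids <- sprintf("v%02d", seq_len(k))
  colnames(dosages) <- ids
  reference_panel(dosages, data.frame(
    rsid = ids, chr = chr %||% rep("1", k), pos = seq_len(k) * 100,
    a1 = "A", a2 = "G", stringsAsFactors = FALSE))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_candidates <- function(ids, beta, se, chr = "1", is_indel = FALSE) {
  data.frame(rsid = ids, chr = chr, pos = seq_along(ids) * 100,
             ea = "G", oa = "A", beta = beta, se = se,
             eaf = 0.4, is_indel = is_indel, stringsAsFactors = FALSE)
}

test_that("selection is a no-op on clean independent candidates", {
  set.seed(1)
  G <- matrix(rbinom(200 * 5, 2, 0.4), 200, 5,
              dimnames = list(NULL, sprintf("v%02d", 1:5)))
  ref <- tiny_panel(G)
  cand <- tiny_candidates(colnames(G), beta = seq(0.1, 0.5, by = 0.1),
                          se = rep(0.05, 5))
  sel <- select_instruments(cand, ref)
  expect_equal(sel$report$n_final, 5)
  expect_equal(sel$instruments$rsid, cand$rsid)
  expect_equal(sel$report$n_excluded_chrX, 0)
  expect_equal(sel$report$n_excluded_maf, 0)
  expect_equal(sel$report$n_excluded_ld, 0)
})

test_that("LD pruning keeps the smaller-p member of a correlated pair", {
  set.seed(2)
  g1 <- rbinom(300, 2, 0.5)
  g2 <- ifelse(runif(300) < 0.75, g1, rbinom(300, 2, 0.5)) # r2 well above 0.1
  g3 <- rbinom(300, 2, 0.3)
  G <- cbind(v01 = g1, v02 = g2, v03 = g3)
  ref <- tiny_panel(G)
  stopifnot(ld_r2(g1, g2) > 0.3)
  # v02 has the smaller p-value (same beta, smaller se)
  cand <- tiny_candidates(c("v01", "v02", "v03"),
                          beta = c(0.2, 0.2, 0.1), se = c(0.05, 0.02, 0.04))
  sel <- select_instruments(cand, ref)
  expect_setequal(sel$instruments$rsid, c("v02", "v03"))
  expect_equal(sel$report$n_excluded_ld, 1)

  # brute-force oracle on <= 5 variants: greedy by p-order using plain cor()
  ord <- order(2 * pnorm(-abs(cand$beta / cand$se)), cand$rsid)
  kept <- character(0)
  for (id in cand$rsid[ord]) {
    ok <- all(vapply(kept, function(k2) cor(G[, id], G[, k2])^2 < 0.10,
                     logical(1)))
    if (ok) kept <- c(kept, id)
  }
  expect_setequal(sel$instruments$rsid, kept)
})

test_that("the 88-locus fixture reduces to 82 independent instruments", {
  fx <- simulate_selection_fixture(seed = 1)
  sel <- select_instruments(fx$candidates, fx$reference)
  rep <- sel$report
  expect_equal(rep$n_input, 88)
  expect_equal(rep$n_excluded_chrX, 5)
  expect_equal(rep$n_excluded_maf, 1)
  expect_equal(rep$n_proxied, 8)
  expect_equal(rep$n_final, 82)
  expect_equal(nrow(sel$instruments), 82)

  # every proxy records its origin and LD strength
  prx <- sel$instruments[!is.na(sel$instruments$proxy_of), ]
  expect_equal(nrow(prx), 8)
  expect_true(all(prx$proxy_r2 > 0.40))

  # final set is exhaustively pairwise-independent
  G <- fx$reference$genotypes[, sel$instruments$rsid]
  r2 <- cor(G)^2
  expect_lt(max(r2[upper.tri(r2)]), 0.10)

  # counts reconcile to the input and dispositions cover every candidate
  expect_equal(rep$n_input,
               rep$n_final + rep$n_excluded_chrX + rep$n_excluded_maf +
                 rep$n_excluded_ld + rep$n_excluded_no_proxy +
                 rep$n_unresolvable)
  expect_setequal(rep$dispositions$rsid, fx$candidates$rsid)
  expect_false(any(rep$dispositions$status == "pending"))
})

test_that("selection is idempotent", {
  fx <- simulate_selection_fixture(seed = 1)
  sel1 <- select_instruments(fx$candidates, fx$reference)
  sel2 <- select_instruments(sel1$instruments, fx$reference)
  expect_setequal(sel2$instruments$rsid, sel1$instruments$rsid)
  expect_equal(sel2$report$n_final, sel2$report$n_input)
  expect_equal(sel2$report$n_proxied, 0)
  expect_equal(sel2$report$n_excluded_ld, 0)
})

test_that("candidates missing from the panel are unresolvable, not fatal", {
  set.seed(3)
  G <- matrix(rbinom(200 * 3, 2, 0.4), 200, 3)
  ref <- tiny_panel(G)
  cand <- tiny_candidates(c("v01", "v02", "v03", "ghost"),
                          beta = rep(0.2, 4), se = rep(0.05, 4))
  expect_warning(sel <- select_instruments(cand, ref), "ghost")
  expect_equal(sel$report$n_unresolvable, 1)
  expect_equal(sel$report$n_final, 3)
})

test_that("an empty final set is fatal", {
  set.seed(4)
  G <- matrix(rbinom(100 * 2, 2, 0.4), 100, 2)
  ref <- tiny_panel(G)
  cand <- tiny_candidates(c("v01", "v02"), beta = c(0.1, 0.1),
                          se = c(0.05, 0.05), chr = "X")
  expect_error(select_instruments(cand, ref), "empty")
})
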