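test_that("allele harmonization resolves all four label configurations", {
  d <- c(0, 1, 2, 1)
  # effect allele equals the counted (alt) allele
  h <- harmonize_alleles("G", "A", a1 = "A", a2 = "G", d)
  expect_equal(h$action, "identity")
  expect_equal(h$dosage, d)
  # effect allele equals the reference allele: reflect the dosage
  h <- harmonize_alleles("A", "G", a1 = "A", a2 = "G", d)
  expect_equal(h$action, "swap")
  expect_equal(h$dosage, 2 - d)
  # opposite strand, same orientation: dosage unchanged
  h <- harmonize_alleles("G", "A", a1 = "T", a2 = "C", d)
  expect_equal(h$action, "strand_flip")
  expect_equal(h$dosage, d)
  # opposite strand and swapped: reflect
  h <- harmonize_alleles("G", "A", a1 = "C", a2 = "T", d)
  expect_equal(h$action, "strand_flip_swap")
  expect_equal(h$dosage, 2 - d)
  # irreconcilable labels
  expect_error(harmonize_alleles("G", "A", a1 = "A", a2 = "C", d),
               "cannot be harmonized")
})

test_that("palindromic variants resolve by frequency or fail loudly", {
  set.seed(20)
  d <- rbinom(500, 2, 0.2) # counted-allele frequency 0.2
  # instrument EAF on the same side of 0.5: keep orientation
  h <- harmonize_alleles("A", "T", a1 = "T", a2 = "A", d, eaf = 0.22)
  expect_equal(h$action, "palindromic_identity")
  # instrument EAF on the other side: reflect
  h <- harmonize_alleles("A", "T", a1 = "T", a2 = "A", d, eaf = 0.81)
  expect_equal(h$action, "palindromic_swap")
  expect_equal(h$dosage, 2 - d)
  # ambiguous frequency band
  expect_error(harmonize_alleles("A", "T", a1 = "T", a2 = "A", d, eaf = 0.50),
               "ambiguous")
  expect_warning(
    h <- harmonize_alleles("A", "T", a1 = "T", a2 = "A", d, eaf = 0.50,
                           drop_palindromic = TRUE),
    "dropped")
  expect_equal(h$action, "dropped")
})

toy_geno <- function() {
  g <- matrix(c(0, 1, 2, 1, 0,
                2, 2, 1, 0, 1,
                1, 0, 0, 2, 2), nrow = 5,
              dimnames = list(sprintf("s%d", 1:5), c("rs1", "rs2", "rs3")))
  inst <- data.frame(rsid = c("rs1", "rs2", "rs3"),
                     ea = "G", oa = "A", beta = c(0.1, 0.2, -0.3),
                     se = 0.02, eaf = 0.4, stringsAsFactors = FALSE)
  list(g = g, inst = inst)
}

test_that("the score is the dot product of betas and dosages", {
  fx <- toy_geno()
  # all-zero dosages give all-zero scores
  g0 <- fx$g * 0
  s0 <- compute_wgrs(g0, fx$inst)
  expect_equal(unname(s0$score), rep(0, 5))
  # direct dot product
  s <- compute_wgrs(fx$g, fx$inst)
  expect_equal(unname(s$score), as.vector(fx$g %*% fx$inst$beta))
  expect_equal(s$n_variants_used, 3)
  # one sample, dosages (1,2), betas (0.1,0.2) -> 0.5
  s1 <- compute_wgrs(matrix(c(1, 2), 1, dimnames = list("a", c("rs1", "rs2"))),
                     fx$inst[1:2, ])
  expect_equal(unname(s1$score), 0.5)
})

test_that("missing dosages are mean-imputed from controls before summing", {
  fx <- toy_geno()
  g <- fx$g
  g["s1", "rs2"] <- NA
  ph <- data.frame(case = c(0, 0, 0, 1, 1))
  s <- compute_wgrs(g, fx$inst, phenotypes = ph)
  # brute-force oracle: impute with 2 x (control EAF of rs2 among observed)
  imput <- 2 * mean(g[ph$case == 0, "rs2"], na.rm = TRUE) / 2
  gg <- g
  gg["s1", "rs2"] <- imput
  expect_equal(unname(s$score), as.vector(gg %*% fx$inst$beta))
})

test_that("scores are linear in the betas", {
  fx <- toy_geno()
  s1 <- compute_wgrs(fx$g, fx$inst)
  inst2 <- fx$inst
  inst2$beta <- 2 * inst2$beta
  s2 <- compute_wgrs(fx$g, inst2)
  expect_equal(s2$score, 2 * s1$score)
})

test_that("consistent allele swap shifts scores by a constant only", {
  fx <- toy_geno()
  vi <- data.frame(rsid = fx$inst$rsid, a1 = "A", a2 = "G",
                   stringsAsFactors = FALSE)
  s1 <- compute_wgrs(fx$g, fx$inst, variant_info = vi)
  # swap effect/other allele, flip beta, eaf -> 1 - eaf; harmonization
  # reflects the dosage, so associations are unchanged (scores shift by a
  # per-sample-constant 2 * sum(beta))
  inst2 <- fx$inst
  inst2$ea <- fx$inst$oa
  inst2$oa <- fx$inst$ea
  inst2$beta <- -fx$inst$beta
  inst2$eaf <- 1 - fx$inst$eaf
  s2 <- compute_wgrs(fx$g, inst2, variant_info = vi)
  shift <- s2$score - s1$score
  expect_equal(max(shift) - min(shift), 0, tolerance = 1e-12)
  expect_equal(unname(shift[1]), -2 * sum(fx$inst$beta))
})

test_that("standardized scores have unit control SD", {
  co <- small_null_cohort()
  s <- compute_wgrs(co$genotypes, co$instruments,
                    variant_info = co$variants,
                    phenotypes = co$phenotypes, standardize = TRUE)
  expect_equal(sd(s$score[co$phenotypes$case == 0]), 1.0, tolerance = 1e-12)
  expect_true(s$standardized)
})

test_that("instruments absent from the genotypes are excluded with a warning", {
  fx <- toy_geno()
  inst <- rbind(fx$inst,
                data.frame(rsid = "rs_missing", ea = "G", oa = "A",
                           beta = 0.5, se = 0.02, eaf = 0.3,
                           stringsAsFactors = FALSE))
  expect_warning(s <- compute_wgrs(fx$g, inst), "rs_missing")
  expect_equal(s$n_variants_used, 3)
})

test_that("unharmonizable instruments are fatal with the variant named", {
  fx <- toy_geno()
  vi <- data.frame(rsid = fx$inst$rsid, a1 = "A", a2 = "C",
                   stringsAsFactors = FALSE)
  expect_error(compute_wgrs(fx$g, fx$inst, variant_info = vi), "rs1")
})
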