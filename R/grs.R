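#' Harmonize an instrument's effect allele with a genotype record
#'
#' Re-orients a dosage vector so that it counts the instrument's effect
#' allele, resolving label mismatches by allele swap, strand flip, or both.
#' Palindromic variants (A/T or C/G), where strand cannot be inferred from the
#' labels, are resolved by comparing allele frequencies: if both the
#' instrument EAF and the genotype-derived frequency are outside the
#' ambiguity band (further than `eaf_tol` from 0.5), the orientation that
#' makes the frequencies agree is chosen; otherwise the variant is ambiguous.
#'
#' @param ea,oa Instrument effect and other alleles (A/C/G/T strings).
#' @param a1,a2 Genotype record alleles; `dosage` counts `a2`.
#' @param dosage Numeric dosage vector in \[0, 2\].
#' @param eaf Instrument effect-allele frequency (needed for palindromic
#'   variants).
#' @param eaf_tol Half-width of the palindromic ambiguity band around 0.5
#'   (default 0.08, i.e. frequencies in 0.42-0.58 are ambiguous).
#' @param drop_palindromic If `TRUE`, ambiguous palindromic variants return
#'   `action = "dropped"` with a warning instead of an error.
#' @return List with `dosage` (re-oriented) and `action`, one of `identity`,
#'   `swap`, `strand_flip`, `strand_flip_swap`, `palindromic_identity`,
#'   `palindromic_swap`, `dropped`.
#' @export
harmonize_alleles <- function(ea, oa, a1, a2, dosage, eaf = NA,
                              eaf_tol = 0.08, drop_palindromic = FALSE) {
  al <- toupper(c(ea, oa, a1, a2))
  if (!all(al %in% c("A", "C", "G", "T"))) {
    stop("harmonization requires single-base A/C/G/T alleles", call. = FALSE)
  }
  ea <- al[1]; oa <- al[2]; a1 <- al[3]; a2 <- al[4]
  if (ea == oa || a1 == a2) stop("degenerate allele pair", call. = FALSE)

  if (is_palindromic(ea, oa)) {
    if (!is_palindromic(a1, a2) || !(ea %in% c(a1, a2))) {
      stop(sprintf("alleles %s/%s cannot be harmonized with %s/%s",
                   ea, oa, a1, a2), call. = FALSE)
    }
    geno_eaf_a2 <- mean(dosage, na.rm = TRUE) / 2
    ambiguous <- is.na(eaf) || abs(eaf - 0.5) <= eaf_tol ||
      abs(geno_eaf_a2 - 0.5) <= eaf_tol
    if (ambiguous) {
      if (drop_palindromic) {
        warning(sprintf("palindromic variant %s/%s with ambiguous frequency dropped",
                        ea, oa), call. = FALSE)
        return(list(dosage = NULL, action = "dropped"))
      }
      stop(sprintf(paste0("palindromic variant %s/%s is frequency-ambiguous ",
                          "(EAF within %.2f of 0.5); set drop_palindromic to ",
                          "exclude it"), ea, oa, eaf_tol), call. = FALSE)
    }
    # orient so minor/major status matches the instrument EAF
    if ((eaf > 0.5) == (geno_eaf_a2 > 0.5)) {
      return(list(dosage = dosage, action = "palindromic_identity"))
    }
    return(list(dosage = 2 - dosage, action = "palindromic_swap"))
  }

  if (ea == a2 && oa == a1) {
    return(list(dosage = dosage, action = "identity"))
  }
  if (ea == a1 && oa == a2) {
    return(list(dosage = 2 - dosage, action = "swap"))
  }
  fea <- flip_strand(ea); foa <- flip_strand(oa)
  if (fea == a2 && foa == a1) {
    return(list(dosage = dosage, action = "strand_flip"))
  }
  if (fea == a1 && foa == a2) {
    return(list(dosage = 2 - dosage, action = "strand_flip_swap"))
  }
  stop(sprintf("alleles %s/%s cannot be harmonized with %s/%s (no swap or strand flip resolves them)",
               ea, oa, a1, a2), call. = FALSE)
}

#' Weighted genetic risk score
#'
#' Per-sample score `wGRS_s = sum_i beta_i * dosage_{s,i}` over the matched
#' instruments, after harmonizing each instrument's effect allele with the
#' genotype record. Missing dosages are imputed as twice the control-group
#' effect-allele frequency of that variant before summing, so every sample
#' receives a score over the same instrument set. With `standardize = TRUE`
#' the score is divided by its control-group standard deviation, giving a
#' per-control-SD unit for the reported odds ratio.
#'
#' @param genotypes Dosage matrix, columns named by variant id.
#' @param instruments Instrument table (`rsid`, `ea`, `oa`, `beta`, `eaf`,
#'   ...). Instruments absent from the genotype columns are excluded with a
#'   warning and reflected in `n_variants_used`.
#' @param variant_info Optional data frame (`rsid`, `a1`, `a2`) describing
#'   the allele that each genotype column counts (`a2`). When omitted,
#'   columns are assumed to already count the instrument effect alleles.
#' @param phenotypes Optional phenotype table; its `case == 0` rows define the
#'   control group used for missing-dosage imputation and standardization
#'   (the whole cohort is used when absent).
#' @param standardize Divide the score by its control-group SD.
#' @param drop_palindromic Passed to [harmonize_alleles()].
#' @return Object of class `mr_wgrs`: list with `score` (named numeric
#'   vector), `n_variants_used`, `standardized`, and the per-variant
#'   harmonization `actions`.
#' @export
compute_wgrs <- function(genotypes, instruments, variant_info = NULL,
                         phenotypes = NULL, standardize = FALSE,
                         drop_palindromic = FALSE) {
  stopifnot(!is.null(colnames(genotypes)), all(c("rsid", "beta") %in%
                                                 names(instruments)))
  present <- instruments$rsid %in% colnames(genotypes)
  if (!all(present)) {
    warning(sprintf("instrument(s) absent from genotypes, excluded: %s",
                    paste(instruments$rsid[!present], collapse = ", ")),
            call. = FALSE)
  }
  inst <- instruments[present, , drop = FALSE]
  if (nrow(inst) == 0L) stop("no instrument overlaps the genotype data",
                             call. = FALSE)
  is_ctrl <- if (!is.null(phenotypes) && !is.null(phenotypes$case)) {
    phenotypes$case == 0
  } else {
    rep(TRUE, nrow(genotypes))
  }

  used <- character(0)
  actions <- character(0)
  score <- numeric(nrow(genotypes))
  for (k in seq_len(nrow(inst))) {
    id <- inst$rsid[k]
    d <- genotypes[, id]
    act <- "identity"
    if (!is.null(variant_info)) {
      vi <- variant_info[match(id, variant_info$rsid), ]
      if (is.na(vi$rsid)) {
        stop(sprintf("variant %s missing from variant_info", id),
             call. = FALSE)
      }
      h <- tryCatch(
        harmonize_alleles(inst$ea[k], inst$oa[k], vi$a1, vi$a2, d,
                          eaf = inst$eaf[k],
                          drop_palindromic = drop_palindromic),
        error = function(e) {
          stop(sprintf("variant %s: %s", id, conditionMessage(e)),
               call. = FALSE)
        })
      if (h$action == "dropped") next
      d <- h$dosage
      act <- h$action
    }
    if (anyNA(d)) {
      f <- mean(d[is_ctrl], na.rm = TRUE) / 2
      if (is.nan(f)) f <- mean(d, na.rm = TRUE) / 2
      d[is.na(d)] <- 2 * f
    }
    score <- score + inst$beta[k] * d
    used <- c(used, id)
    actions <- c(actions, act)
  }
  if (!length(used)) stop("no instrument could be harmonized", call. = FALSE)
  if (standardize) {
    sdv <- stats::sd(score[is_ctrl])
    if (!is.finite(sdv) || sdv == 0) {
      stop("control-group score SD is zero; cannot standardize", call. = FALSE)
    }
    score <- score / sdv
  }
  names(score) <- rownames(genotypes)
  structure(list(score = score, n_variants_used = length(used),
                 standardized = standardize,
                 actions = stats::setNames(actions, used)),
            class = "mr_wgrs")
}

#' @export
print.mr_wgrs <- function(x, ...) {
  cat(sprintf("weighted genetic risk score: %d samples, %d variants%s\n",
              length(x$score), x$n_variants_used,
              if (x$standardized) " (per control-SD units)" else ""))
  invisible(x)
}
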