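# Readers and writers for the package's plain-text interchange formats.
# All tables are tab-separated with fixed headers; floating point values are
# written at 6 significant digits so outputs diff cleanly.

.fmt_num <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- signif(df[[nm]], 6)
  }
  df
}

.write_tsv <- function(df, path) {
  utils::write.table(.fmt_num(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = "NA")
}

#' Read / write an instrument table
#'
#' Tab-separated with header `rsid chr pos ea oa beta se eaf is_indel`
#' (optionally `proxy_of`, `proxy_r2`). `beta` is the published per-allele
#' exposure log-odds oriented to the effect allele `ea`.
#'
#' @param path File path.
#' @return `read_instruments` returns the instrument data frame.
#' @export
read_instruments <- function(path) {
  x <- .read_tsv(path)
  need <- c("rsid", "chr", "pos", "ea", "oa", "beta", "se", "eaf", "is_indel")
  if (!all(need %in% names(x))) {
    stop(sprintf("instrument table %s lacks column(s): %s", path,
                 paste(setdiff(need, names(x)), collapse = ", ")),
         call. = FALSE)
  }
  x$chr <- as.character(x$chr)
  x$is_indel <- as.logical(x$is_indel)
  stopifnot(all(x$se > 0), all(x$eaf > 0 & x$eaf < 1))
  x
}

#' @rdname read_instruments
#' @param instruments Instrument data frame.
#' @export
write_instruments <- function(instruments, path) {
  .write_tsv(instruments, path)
}

#' Read / write a dosage matrix as TSV
#'
#' First column `sample_id`, one column per variant holding effect-allele
#' dosages in \[0, 2\].
#'
#' @param path File path.
#' @return `read_dosage_tsv` returns a numeric matrix with sample row names.
#' @export
read_dosage_tsv <- function(path) {
  x <- .read_tsv(path)
  stopifnot(names(x)[1] == "sample_id")
  m <- as.matrix(x[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- x$sample_id
  m
}

#' @rdname read_dosage_tsv
#' @param genotypes Numeric dosage matrix with sample row names.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  df <- data.frame(sample_id = rownames(genotypes),
                   as.data.frame(genotypes), check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' Write a minimal VCF v4.2 with a DS (dosage) FORMAT field
#'
#' @param genotypes Dosage matrix (samples x variants).
#' @param variants Data frame `rsid`, `chr`, `pos`, `a1` (REF), `a2` (ALT);
#'   dosages count `a2`.
#' @param path Output path.
#' @export
write_vcf_dosage <- function(genotypes, variants, path) {
  stopifnot(all(colnames(genotypes) %in% variants$rsid))
  v <- variants[match(colnames(genotypes), variants$rsid), ]
  if (is.null(v$chr)) v$chr <- "1"
  if (is.null(v$pos)) v$pos <- seq_len(nrow(v))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")
  ), con)
  for (j in seq_len(ncol(genotypes))) {
    ds <- genotypes[, j]
    ds_chr <- ifelse(is.na(ds), ".", as.character(signif(ds, 6)))
    writeLines(paste(c(v$chr[j], v$pos[j], v$rsid[j], v$a1[j], v$a2[j],
                       ".", "PASS", ".", "DS", ds_chr), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read dosages from a VCF with DS (or GT) genotype fields
#'
#' Uses the `vcfR` package. DS is preferred; when absent, hard GT calls are
#' converted to alternate-allele counts.
#'
#' @param path VCF path (v4.2, biallelic records).
#' @return List with `genotypes` (samples x variants dosage matrix) and
#'   `variants` (`rsid`, `chr`, `pos`, `a1`, `a2`).
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":")))
  if ("DS" %in% fmt) {
    m <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else if ("GT" %in% fmt) {
    gt <- vcfR::extract.gt(v, element = "GT")
    m <- apply(gt, c(1, 2), function(x) {
      if (is.na(x)) return(NA_real_)
      sum(as.integer(strsplit(gsub("\\|", "/", x), "/")[[1]]) > 0)
    })
  } else {
    stop("VCF has neither DS nor GT fields", call. = FALSE)
  }
  fix <- vcfR::getFIX(v)
  rownames(m) <- fix[, "ID"]
  list(
    genotypes = t(m),
    variants = data.frame(rsid = fix[, "ID"], chr = fix[, "CHROM"],
                          pos = as.integer(fix[, "POS"]), a1 = fix[, "REF"],
                          a2 = fix[, "ALT"], stringsAsFactors = FALSE)
  )
}

#' Write / read a synthetic cohort to a directory
#'
#' Writes `genotypes.tsv` (or `genotypes.vcf`), `phenotypes.tsv`,
#' `instruments.tsv` and `truth.json`; `read_cohort` reconstructs the
#' `mr_cohort` object losslessly (dosages at 6 significant digits).
#'
#' @param cohort An `mr_cohort`.
#' @param dir Output directory (created if needed).
#' @param vcf Write genotypes as VCF with DS field instead of TSV.
#' @return The directory path (`write_cohort`) or an `mr_cohort`
#'   (`read_cohort`).
#' @export
write_cohort <- function(cohort, dir, vcf = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (vcf) {
    write_vcf_dosage(cohort$genotypes, cohort$variants,
                     file.path(dir, "genotypes.vcf"))
  } else {
    write_dosage_tsv(cohort$genotypes, file.path(dir, "genotypes.tsv"))
  }
  .write_tsv(cohort$variants, file.path(dir, "variants.tsv"))
  .write_tsv(cohort$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_instruments(cohort$instruments, file.path(dir, "instruments.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  vcf_path <- file.path(dir, "genotypes.vcf")
  if (file.exists(vcf_path)) {
    gv <- read_vcf_dosage(vcf_path)
    genotypes <- gv$genotypes
  } else {
    genotypes <- read_dosage_tsv(file.path(dir, "genotypes.tsv"))
  }
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  structure(list(
    genotypes = genotypes,
    variants = .read_tsv(file.path(dir, "variants.tsv")),
    phenotypes = .read_tsv(file.path(dir, "phenotypes.tsv")),
    instruments = read_instruments(file.path(dir, "instruments.tsv")),
    truth = truth,
    config = NULL
  ), class = "mr_cohort")
}

#' Write a pairwise relatedness (PI_HAT) table
#'
#' Three-column TSV `id1 id2 pihat`.
#' @param pihat Data frame with columns `id1`, `id2`, `pihat`.
#' @param path File path.
#' @export
write_pihat <- function(pihat, path) .write_tsv(pihat, path)

#' @rdname write_pihat
#' @export
read_pihat <- function(path) {
  x <- .read_tsv(path)
  stopifnot(all(c("id1", "id2", "pihat") %in% names(x)))
  x
}
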