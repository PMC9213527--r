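# Genotype input layer: dosage matrices, allele frequencies, pairwise LD.

new_geno <- function(sample_ids, variants, dosages) {
  stopifnot(!anyDuplicated(sample_ids),
            nrow(dosages) == length(sample_ids),
            ncol(dosages) == nrow(variants))
  rng <- range(dosages, na.rm = TRUE)
  stopifnot(rng[1] >= 0, rng[2] <= 2)
  variants$key <- variant_key(variants$chrom, variants$pos,
                              variants$ea, variants$oa)
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variants$key
  structure(list(sample_ids = as.character(sample_ids),
                 variants = variants, dosages = dosages),
            class = "htn_geno")
}

#' @export
print.htn_geno <- function(x, ...) {
  cat("htn_geno:", length(x$sample_ids), "samples x",
      nrow(x$variants), "variants\n")
  invisible(x)
}

#' Load genotypes from a VCF or a dosage matrix
#'
#' VCF input (`.vcf` / `.vcf.gz`, read via the VariantAnnotation package)
#' uses the `DS` FORMAT field when present and otherwise converts `GT`
#' calls to alternate-allele counts; missing calls stay missing.  The
#' effect allele is ALT.  The TSV alternative is a plain dosage matrix:
#' first column `sample_id`, remaining columns named `chrom:pos:ea:oa`
#' with entries in \[0, 2\] or `NA`.
#'
#' @param path path to a `.vcf`, `.vcf.gz` or dosage `.tsv` file.
#' @return an `htn_geno` object: `sample_ids`, `variants` (data frame
#'   `chrom`, `pos`, `ea`, `oa`, `key`), `dosages` (samples x variants).
#' @export
load_genotypes <- function(path) {
  if (!file.exists(path)) stop_config("genotype file not found: ", path)
  if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path)) {
    return(load_genotypes_vcf(path))
  }
  dt <- data.table::fread(path, header = TRUE)
  if (names(dt)[1] != "sample_id") {
    stop_config("dosage matrix must have 'sample_id' as first column")
  }
  ids <- as.character(dt[[1]])
  mat <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  keys <- colnames(mat)
  parts <- strsplit(keys, ":", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad)) {
    stop_config("dosage column not of form chrom:pos:ea:oa: ", keys[bad[1]])
  }
  variants <- data.frame(
    chrom = vapply(parts, `[[`, "", 1L),
    pos = as.integer(vapply(parts, `[[`, "", 2L)),
    ea = vapply(parts, `[[`, "", 3L),
    oa = vapply(parts, `[[`, "", 4L),
    stringsAsFactors = FALSE
  )
  new_geno(ids, variants, mat)
}

load_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop_config("VCF input requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- as.character(unlist(rr$ALT))
  if (length(alt) != length(rr)) {
    stop_config("multi-allelic VCF records are not supported: ", path)
  }
  variants <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ea = alt,
    oa = as.character(rr$REF),
    stringsAsFactors = FALSE
  )
  gn <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(gn)) {
    mat <- t(gn$DS)
    storage.mode(mat) <- "double"
  } else if ("GT" %in% names(gn)) {
    gt <- t(gn$GT)
    conv <- function(g) {
      a <- strsplit(g, "[/|]")
      vapply(a, function(x) {
        if (any(x == "." | x == "")) return(NA_real_)
        sum(as.numeric(x) > 0)
      }, 0)
    }
    mat <- apply(gt, 2L, conv)
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = nrow(gt))
  } else {
    stop_config("VCF has neither DS nor GT FORMAT fields: ", path)
  }
  new_geno(rownames(mat) %||% paste0("S", seq_len(nrow(mat))), variants, mat)
}

#' Per-variant effect-allele frequency
#'
#' Frequency is `mean(non-missing dosages) / 2`.  Variants with all
#' dosages missing get `NA` and are reported via a message.
#'
#' @param g an `htn_geno` object.
#' @return named numeric vector of frequencies, names are variant keys.
#' @export
allele_freq <- function(g) {
  stopifnot(inherits(g, "htn_geno"))
  f <- colMeans(g$dosages, na.rm = TRUE) / 2
  f[is.nan(f)] <- NA_real_
  if (anyNA(f)) hlog(op = "allele_freq", all_missing = sum(is.na(f)))
  f
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of dosage vectors over pairwise-complete
#' samples.  A monomorphic variant has `r2 = 0` by definition; fewer than
#' two complete pairs gives `NA`.
#'
#' @param g an `htn_geno` object.
#' @param a,b variant keys (`chrom:pos:ea:oa`) or column indices.
#' @return r-squared in \[0, 1\], or `NA` if undefined.
#' @export
ld_r2 <- function(g, a, b) {
  stopifnot(inherits(g, "htn_geno"))
  da <- g$dosages[, a]
  db <- g$dosages[, b]
  ok <- !is.na(da) & !is.na(db)
  if (sum(ok) < 2L) return(NA_real_)
  if (var(da[ok]) == 0 || var(db[ok]) == 0) return(0)
  cor(da[ok], db[ok])^2
}
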