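# GWAS summary statistics: reading, QC, and allele harmonization against a
# target variant index.  Coordinates are 1-based throughout (VCF convention).

new_sumstats <- function(df, trait) {
  stopifnot(trait %in% c("SBP", "DBP", "HTN"))
  need <- c("chrom", "pos", "ea", "oa", "beta", "se", "p")
  stopifnot(all(need %in% names(df)))
  if (!"eaf" %in% names(df)) df$eaf <- NA_real_
  if (!"n" %in% names(df)) df$n <- NA_real_
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("htn_sumstats", "data.frame"), trait = trait)
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab- or comma-separated file with a header, maps columns to the
#' canonical schema, drops rows that fail numeric parsing or violate basic
#' invariants (`se > 0`, `p` in (0, 1], `eaf` in \[0, 1\]), and resolves
#' duplicate variant keys by keeping the record with the smallest p-value.
#'
#' @param path path to the summary-statistics file.
#' @param column_map named character vector mapping canonical names
#'   (`chrom`, `pos`, `ea`, `oa`, `beta`, `se`, `p`, and optionally `eaf`,
#'   `n`) to the file's header names.  Defaults to the conventional
#'   `CHR`, `POS`, `EA`, `OA`, `BETA`, `SE`, `P`, `EAF`, `N`.
#' @param trait one of `"SBP"`, `"DBP"`, `"HTN"`.  Effect sizes are mmHg
#'   per effect allele for the BP traits and log-odds for HTN.
#' @return an object of class `htn_sumstats`: a data frame with columns
#'   `chrom`, `pos`, `ea`, `oa`, `beta`, `se`, `p`, `eaf`, `n`, sorted by
#'   `(chrom, pos)` and unique by variant key, with attributes `trait` and
#'   `n_dropped` (rows removed during parsing/QC).
#' @export
read_sumstats <- function(path,
                          column_map = c(chrom = "CHR", pos = "POS",
                                         ea = "EA", oa = "OA",
                                         beta = "BETA", se = "SE", p = "P",
                                         eaf = "EAF", n = "N"),
                          trait = c("SBP", "DBP", "HTN")) {
  trait <- match.arg(trait)
  if (!file.exists(path)) stop_config("summary-statistics file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, colClasses = "character",
                          na.strings = c("NA", ""))
  if (nrow(dt) == 0L) stop_config("empty summary-statistics file: ", path)
  mandatory <- c("chrom", "pos", "ea", "oa", "beta", "se", "p")
  for (col in mandatory) {
    src <- column_map[[col]]
    if (is.null(src) || !src %in% names(dt)) {
      stop_config("missing mandatory column '", col, "' (mapped to '",
                  column_map[[col]] %||% "<unset>", "') in ", path)
    }
  }
  pick <- function(col) {
    src <- column_map[[col]]
    if (!is.null(src) && src %in% names(dt)) dt[[src]] else NULL
  }
  df <- data.frame(
    chrom = as.character(pick("chrom")),
    pos = suppressWarnings(as.integer(pick("pos"))),
    ea = toupper(as.character(pick("ea"))),
    oa = toupper(as.character(pick("oa"))),
    beta = suppressWarnings(as.numeric(pick("beta"))),
    se = suppressWarnings(as.numeric(pick("se"))),
    p = suppressWarnings(as.numeric(pick("p"))),
    stringsAsFactors = FALSE
  )
  df$eaf <- if (is.null(pick("eaf"))) NA_real_ else
    suppressWarnings(as.numeric(pick("eaf")))
  df$n <- if (is.null(pick("n"))) NA_real_ else
    suppressWarnings(as.numeric(pick("n")))

  ok <- !is.na(df$pos) & !is.na(df$beta) & !is.na(df$se) & !is.na(df$p) &
    df$se > 0 & df$p > 0 & df$p <= 1 &
    df$ea != df$oa &
    grepl("^[ACGT]+$", df$ea) & grepl("^[ACGT]+$", df$oa) &
    (is.na(df$eaf) | (df$eaf >= 0 & df$eaf <= 1))
  n_bad <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0L) stop_config("no parseable records in ", path)

  # duplicate keys: keep smallest p (deterministic, favors signal)
  key <- variant_key(df$chrom, df$pos, df$ea, df$oa)
  ord <- order(df$p)
  dup <- duplicated(key[ord])
  n_dup <- sum(dup)
  df <- df[ord[!dup], , drop = FALSE]
  if (n_bad + n_dup > 0) {
    hlog(op = "read_sumstats", trait = trait, dropped_parse = n_bad,
         dropped_duplicate = n_dup, kept = nrow(df))
  }
  out <- new_sumstats(df, trait)
  attr(out, "n_dropped") <- n_bad + n_dup
  out
}

#' Filter variants by minor allele frequency
#'
#' Retains records whose minor allele frequency is at least `threshold` in
#' both the discovery GWAS (from `eaf`) and the target cohort (from
#' `target_freqs`).  MAF is the folded frequency `min(f, 1 - f)`.  Records
#' absent from `target_freqs` are dropped; records with missing discovery
#' `eaf` pass the discovery-side filter (only the target side applies).
#'
#' @param ss an `htn_sumstats` object.
#' @param target_freqs named numeric vector of target-cohort effect-allele
#'   frequencies, names are variant keys `chrom:pos:ea:oa` (see
#'   [allele_freq()]).
#' @param threshold MAF threshold in (0, 0.5]; default 0.01.
#' @return filtered `htn_sumstats`, a subset of `ss`.
#' @export
filter_maf <- function(ss, target_freqs, threshold = 0.01) {
  stopifnot(inherits(ss, "htn_sumstats"),
            threshold > 0, threshold <= 0.5)
  key <- variant_key(ss$chrom, ss$pos, ss$ea, ss$oa)
  f_target <- target_freqs[key]
  maf_target <- pmin(f_target, 1 - f_target)
  maf_disc <- pmin(ss$eaf, 1 - ss$eaf)
  keep <- !is.na(f_target) & maf_target >= threshold &
    (is.na(maf_disc) | maf_disc >= threshold)
  n_missing_eaf <- sum(is.na(maf_disc) & keep)
  if (n_missing_eaf > 0) {
    hlog(op = "filter_maf", note = "records without discovery eaf passed",
         n = n_missing_eaf)
  }
  out <- ss[keep, , drop = FALSE]
  new_sumstats(as.data.frame(out), attr(ss, "trait"))
}

#' Harmonize summary-statistics alleles against a target variant index
#'
#' Aligns each record's effect/other alleles to the target cohort's variant
#' definitions.  Per record the outcome is one of:
#' \describe{
#'   \item{exact}{alleles already match the target — kept unchanged;}
#'   \item{swap}{effect and other allele reversed relative to the target —
#'     alleles swapped, `beta` negated, `eaf` mirrored to `1 - eaf`;}
#'   \item{strand}{alleles match after strand complement — recoded;}
#'   \item{strand_swap}{complement plus swap — recoded, `beta` negated,
#'     `eaf` mirrored;}
#'   \item{palindromic}{A/T or C/G variant — dropped (strand cannot be
#'     resolved deterministically);}
#'   \item{unmatched}{no target variant at the locus with a compatible
#'     allele pair — dropped.}
#' }
#' Harmonization is idempotent: a second application classifies every
#' surviving record as `exact`.
#'
#' @param ss an `htn_sumstats` object.
#' @param target_index data frame with columns `chrom`, `pos`, `ea`, `oa`
#'   (e.g. the `variants` element of an `htn_geno` object), unique by locus.
#' @return harmonized `htn_sumstats` with attribute `harmonization_report`,
#'   a named integer vector of per-category counts.
#' @export
harmonize_alleles <- function(ss, target_index) {
  stopifnot(inherits(ss, "htn_sumstats"),
            all(c("chrom", "pos", "ea", "oa") %in% names(target_index)))
  tl <- locus_key(target_index$chrom, target_index$pos)
  if (anyDuplicated(tl)) stop_config("target index not unique by locus")
  idx <- match(locus_key(ss$chrom, ss$pos), tl)

  cat_ <- rep("unmatched", nrow(ss))
  pal <- is_palindromic(ss$ea, ss$oa)
  cat_[pal] <- "palindromic"

  has <- !is.na(idx) & !pal
  t_ea <- target_index$ea[idx]
  t_oa <- target_index$oa[idx]
  c_ea <- complement_allele(ss$ea)
  c_oa <- complement_allele(ss$oa)

  exact <- has & ss$ea == t_ea & ss$oa == t_oa
  swap <- has & !exact & ss$ea == t_oa & ss$oa == t_ea
  strand <- has & !exact & !swap & !is.na(c_ea) & !is.na(c_oa) &
    c_ea == t_ea & c_oa == t_oa
  strand_swap <- has & !exact & !swap & !strand &
    !is.na(c_ea) & !is.na(c_oa) & c_ea == t_oa & c_oa == t_ea
  cat_[exact] <- "exact"
  cat_[swap] <- "swap"
  cat_[strand] <- "strand"
  cat_[strand_swap] <- "strand_swap"

  out <- as.data.frame(ss)
  flip <- swap | strand_swap
  out$beta[flip] <- -out$beta[flip]
  out$eaf[flip] <- 1 - out$eaf[flip]
  recode <- exact | swap | strand | strand_swap
  out$ea[recode] <- t_ea[recode]
  out$oa[recode] <- t_oa[recode]

  report <- c(
    exact = sum(exact), swap = sum(swap), strand = sum(strand),
    strand_swap = sum(strand_swap), palindromic = sum(pal),
    unmatched = sum(cat_ == "unmatched")
  )
  out <- out[recode, , drop = FALSE]
  res <- new_sumstats(out, attr(ss, "trait"))
  attr(res, "harmonization_report") <- report
  res
}

#' Write a harmonization report as TSV
#'
#' @param ss harmonized `htn_sumstats` (from [harmonize_alleles()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_harmonization_report <- function(ss, path) {
  rep_ <- attr(ss, "harmonization_report")
  if (is.null(rep_)) stop_config("no harmonization report attached")
  df <- data.frame(category = names(rep_), count = as.integer(rep_))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
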