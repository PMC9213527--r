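# Clump-and-threshold PRS construction, scoring, standardization, PRSsum.

#' Default tuning-parameter grid
#'
#' Cartesian product of 12 p-value thresholds (5e-8 through 0.5), clumping
#' r-squared cutoffs 0.1/0.2/0.3, and clumping windows 250/500/1000 kb:
#' 108 candidate parameterizations per trait.
#'
#' @return data frame with columns `p_threshold`, `r2_max`, `window_kb`.
#' @export
default_grid <- function() {
  expand.grid(
    p_threshold = c(5e-8, 1e-7, 1e-6, 1e-5, 1e-4, 1e-3, 1e-2,
                    0.1, 0.2, 0.3, 0.4, 0.5),
    r2_max = c(0.1, 0.2, 0.3),
    window_kb = c(250, 500, 1000),
    KEEP.OUT.ATTRS = FALSE
  )
}

#' Greedy LD clumping
#'
#' Repeatedly takes the smallest-p unclaimed variant as an index variant
#' and removes all unclaimed variants on the same chromosome within
#' `window_kb` of it whose LD r-squared with the index exceeds `r2_max`.
#' Ties in p are broken by genomic `(chrom, pos)` order, so the result is
#' deterministic.  Distance is index-to-candidate in kb, inclusive;
#' cross-chromosome pairs never clump.  The r-squared boundary is strict
#' (`>` removes, `==` retains).
#'
#' @param ss harmonized `htn_sumstats`.
#' @param ref `htn_geno` LD reference panel containing every variant of
#'   `ss`.
#' @param r2_max clumping r-squared cutoff in (0, 1).
#' @param window_kb clumping window in kilobases.
#' @return character vector of retained (index) variant keys, in genomic
#'   order.
#' @export
clump <- function(ss, ref, r2_max, window_kb) {
  stopifnot(inherits(ss, "htn_sumstats"), inherits(ref, "htn_geno"),
            r2_max > 0, r2_max < 1, window_kb > 0)
  key <- variant_key(ss$chrom, ss$pos, ss$ea, ss$oa)
  miss <- setdiff(key, ref$variants$key)
  if (length(miss)) {
    stop_config("variants absent from LD reference: ",
                paste(head(miss, 3), collapse = ", "))
  }
  n <- nrow(ss)
  ord <- order(ss$p, ss$chrom, ss$pos)
  claimed <- rep(FALSE, n)
  index <- logical(n)
  win_bp <- window_kb * 1000
  D <- ref$dosages
  col_of <- match(key, colnames(D))
  for (i in ord) {
    if (claimed[i]) next
    index[i] <- TRUE
    claimed[i] <- TRUE
    nb <- which(!claimed & ss$chrom == ss$chrom[i] &
                  abs(ss$pos - ss$pos[i]) <= win_bp)
    if (!length(nb)) next
    di <- D[, col_of[i]]
    r2 <- vapply(nb, function(j) {
      dj <- D[, col_of[j]]
      ok <- !is.na(di) & !is.na(dj)
      if (sum(ok) < 2L || var(di[ok]) == 0 || var(dj[ok]) == 0) return(0)
      cor(di[ok], dj[ok])^2
    }, 0)
    claimed[nb[r2 > r2_max]] <- TRUE
  }
  key[index][order(ss$chrom[index], ss$pos[index])]
}

#' Apply a p-value threshold to a clumped variant set
#'
#' @param ss harmonized `htn_sumstats`.
#' @param retained variant keys retained by [clump()].
#' @param p_threshold inclusion cutoff: variants with `p < p_threshold`
#'   enter the score.
#' @return named numeric weight vector (variant key -> beta).  An empty
#'   result carries attribute `degenerate = TRUE` rather than erroring.
#' @export
apply_threshold <- function(ss, retained, p_threshold) {
  stopifnot(inherits(ss, "htn_sumstats"),
            p_threshold > 0, p_threshold <= 1)
  key <- variant_key(ss$chrom, ss$pos, ss$ea, ss$oa)
  stopifnot(all(retained %in% key))
  sel <- key %in% retained & ss$p < p_threshold
  w <- setNames(ss$beta[sel], key[sel])
  if (length(w) == 0L) attr(w, "degenerate") <- TRUE
  w
}

#' Build one PRS candidate (clump + threshold)
#'
#' @param ss harmonized `htn_sumstats`.
#' @param ref `htn_geno` LD reference.
#' @param params one row of [default_grid()] (list or data frame row with
#'   `p_threshold`, `r2_max`, `window_kb`).
#' @param retained optional pre-computed clump result for
#'   `(r2_max, window_kb)`; clumping is independent of `p_threshold`, so
#'   callers sweeping the grid should clump once per clumping pair.
#' @return list of class `htn_prs_candidate`: `trait`, `params`, `weights`,
#'   `degenerate` flag.
#' @export
prs_candidate <- function(ss, ref, params, retained = NULL) {
  if (is.null(retained)) {
    retained <- clump(ss, ref, params$r2_max, params$window_kb)
  }
  w <- apply_threshold(ss, retained, params$p_threshold)
  structure(list(trait = attr(ss, "trait"),
                 params = as.list(params)[c("p_threshold", "r2_max",
                                            "window_kb")],
                 weights = w,
                 degenerate = isTRUE(attr(w, "degenerate"))),
            class = "htn_prs_candidate")
}

#' Score samples with a variant weight map
#'
#' Raw score is the weighted sum of effect-allele dosages.  A missing
#' dosage is replaced by `2 * f`, the expected dosage under the variant's
#' effect-allele frequency in `g` (standard mean imputation).
#'
#' @param g `htn_geno` genotypes.
#' @param weights named numeric vector, names are variant keys.
#' @return object of class `htn_prs`: data frame `sample_id`, `raw`
#'   (`standardized` added by [standardize_prs()]).
#' @export
score_prs <- function(g, weights) {
  stopifnot(inherits(g, "htn_geno"))
  if (length(weights) == 0L) {
    return(structure(data.frame(sample_id = g$sample_ids, raw = 0),
                     class = c("htn_prs", "data.frame")))
  }
  miss <- setdiff(names(weights), g$variants$key)
  if (length(miss)) {
    stop_config("weight variants absent from genotypes: ",
                paste(head(miss, 5), collapse = ", "))
  }
  D <- g$dosages[, names(weights), drop = FALSE]
  if (anyNA(D)) {
    f <- colMeans(D, na.rm = TRUE) / 2
    for (j in seq_len(ncol(D))) {
      nas <- is.na(D[, j])
      if (any(nas)) D[nas, j] <- 2 * f[j]
    }
  }
  raw <- as.numeric(D %*% weights)
  structure(data.frame(sample_id = g$sample_ids, raw = raw),
            class = c("htn_prs", "data.frame"))
}

#' Standardize a PRS with pre-computed constants
#'
#' `standardized = (raw - mean) / sd`.  The constants are computed once on
#' the full reference cohort (or a group) and reused in every downstream
#' dataset, keeping effect sizes per 1 SD comparable across analyses.
#'
#' @param prs an `htn_prs` object.
#' @param mean,sd standardization constants; `sd` must be positive.
#' @param source label recording where the constants come from, e.g.
#'   `"full-cohort"` or `"group:AA"`.
#' @return `htn_prs` with a `standardized` column and attribute
#'   `standardization = list(mean, sd, source)`.
#' @export
standardize_prs <- function(prs, mean, sd, source = "full-cohort") {
  stopifnot(inherits(prs, "htn_prs"), is.numeric(sd), length(sd) == 1L)
  if (!is.finite(sd) || sd <= 0) stop_config("standardization sd must be > 0")
  prs$standardized <- (prs$raw - mean) / sd
  attr(prs, "standardization") <- list(mean = mean, sd = sd, source = source)
  prs
}

#' Combine standardized trait-specific PRS by unweighted summation (PRSsum)
#'
#' The components must be standardized with full-cohort constants and share
#' one sample set.  The raw PRSsum is the element-wise sum of the
#' standardized components; it is then re-standardized with its own
#' full-cohort constants (supplied, or computed from the given samples).
#'
#' @param components list of standardized `htn_prs` objects.
#' @param mean,sd optional pre-computed standardization constants for the
#'   summed score; when `NULL` they are computed from the components'
#'   samples.
#' @return standardized `htn_prs` for the combined score.
#' @export
prssum <- function(components, mean = NULL, sd = NULL) {
  stopifnot(length(components) >= 1L)
  ids <- components[[1]]$sample_id
  for (comp in components) {
    stopifnot(inherits(comp, "htn_prs"))
    if (!"standardized" %in% names(comp)) {
      stop_config("PRSsum components must be standardized")
    }
    if (!identical(comp$sample_id, ids)) {
      stop_config("PRSsum components have mismatched sample sets")
    }
  }
  raw <- Reduce(`+`, lapply(components, `[[`, "standardized"))
  out <- structure(data.frame(sample_id = ids, raw = raw),
                   class = c("htn_prs", "data.frame"))
  if (is.null(mean)) mean <- base::mean(raw)
  if (is.null(sd)) sd <- stats::sd(raw)
  standardize_prs(out, mean, sd, source = "full-cohort")
}

#' Write PRS values as TSV
#'
#' @param prs an `htn_prs` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_prs <- function(prs, path) {
  data.table::fwrite(as.data.frame(prs), path, sep = "\t")
  invisible(path)
}
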