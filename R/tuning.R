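# Tuning-parameter selection: kinship-disjoint folds, the coefficient-of-
# variation (CV) criterion, the minimum-p criterion, and the genome-wide-
# significance candidate.

#' Split samples into K kinship-disjoint folds
#'
#' Kinship components are assigned whole — largest component first, each to
#' the currently smallest fold — so no kinship edge ever crosses folds and
#' fold sizes are as equal as the component structure allows.  Ties among
#' equally-sized components are broken by a seeded shuffle.
#'
#' @param samples character vector of sample ids.
#' @param kinship an `htn_kinship` covering `samples`.
#' @param K number of folds (default 5).
#' @param seed integer seed.
#' @return integer vector of fold indices in `1..K`, named by sample.
#' @export
split_kinship_folds <- function(samples, kinship, K = 5L, seed = 1L) {
  stopifnot(K >= 2L)
  sub <- kinship_graph(
    kinship$edges[kinship$edges$id1 %in% samples &
                    kinship$edges$id2 %in% samples, , drop = FALSE],
    samples
  )
  comps <- kinship_components(sub)
  sizes <- lengths(comps)
  if (max(sizes) > length(samples) / K) {
    warning("a kinship component exceeds n/K; folds will be unbalanced",
            call. = FALSE)
  }
  ord <- with_seed(seed_stream(seed, "split_kinship_folds"), {
    order(-sizes, sample.int(length(comps)))
  })
  fold_sizes <- numeric(K)
  assign_ <- integer(0)
  out <- setNames(integer(length(samples)), samples)
  for (i in ord) {
    f <- which.min(fold_sizes)
    out[comps[[i]]] <- f
    fold_sizes[f] <- fold_sizes[f] + sizes[i]
  }
  # invariant: no kinship edge crosses folds
  stopifnot(all(out[sub$edges$id1] == out[sub$edges$id2]))
  out
}

#' Coefficient of variation of per-fold effect estimates
#'
#' `CV = sd(betas) / mean(betas)` with the sample (n-1) standard
#' deviation.  A non-positive mean disqualifies the candidate (`Inf`): a
#' PRS anti-associated with its own trait is never the intended selection.
#'
#' @param betas numeric vector of per-fold log-OR estimates (>= 2 finite).
#' @return the CV, or `Inf` when `mean(betas) <= 0`.
#' @export
effect_cv <- function(betas) {
  betas <- betas[is.finite(betas)]
  if (length(betas) < 2L) stop_config("effect_cv needs >= 2 finite estimates")
  m <- mean(betas)
  if (m <= 0) return(Inf)
  sd(betas) / m
}

# Fit the per-fold association model for one candidate's standardized PRS;
# returns the K log-ORs (NA for non-converging folds).
fold_betas <- function(std_prs, outcome, covars, folds) {
  K <- max(folds)
  vapply(seq_len(K), function(f) {
    sel <- folds == f
    tryCatch({
      if (length(unique(outcome[sel])) < 2L) return(NA_real_)
      cv <- if (is.null(covars)) NULL else covars[sel, , drop = FALSE]
      fit_logistic(outcome[sel], std_prs[sel], cv)$beta
    }, error = function(e) NA_real_)
  }, 0)
}

# deterministic tie-break chain shared by the selection criteria
candidate_order <- function(tab, crit) {
  order(crit, tab$p_threshold, tab$r2_max, -tab$window_kb, tab$n_snps)
}

# Build the per-candidate table (params, scores) shared by the selectors.
candidate_table <- function(candidates) {
  do.call(rbind, lapply(candidates, function(cand) {
    data.frame(trait = cand$trait,
               p_threshold = cand$params$p_threshold,
               r2_max = cand$params$r2_max,
               window_kb = cand$params$window_kb,
               n_snps = length(cand$weights),
               degenerate = cand$degenerate)
  }))
}

#' Select tuning parameters by the coefficient-of-variation criterion
#'
#' For each candidate PRS (one per tuning-parameter combination), fits the
#' hypertension association model separately in each kinship-disjoint fold
#' using the candidate's full-cohort-standardized score, computes the CV of
#' the K log-OR estimates, and selects the candidate minimizing the CV.
#' Ties are broken by (smaller p-threshold, smaller r2, larger window,
#' fewer SNPs).  Degenerate candidates (empty weight set) and candidates
#' with a non-converging fold or non-positive mean effect get `CV = Inf`.
#'
#' @param candidates list of `htn_prs_candidate` objects.
#' @param scores list of standardized `htn_prs`, parallel to `candidates`
#'   (scored on the training genotypes, standardized with full-cohort
#'   constants).
#' @param outcome binary hypertension indicator for the training samples.
#' @param covars covariate data frame (see [fit_logistic()]).
#' @param folds fold assignment from [split_kinship_folds()], aligned with
#'   `outcome`.
#' @return list of class `htn_selection`: `criterion = "CV"`, `chosen`
#'   (params list), `chosen_index`, `table` (per-candidate params, per-fold
#'   betas, CV, n_snps).
#' @export
select_cv_prs <- function(candidates, scores, outcome, covars, folds) {
  stopifnot(length(candidates) == length(scores))
  tab <- candidate_table(candidates)
  K <- max(folds)
  bmat <- matrix(NA_real_, nrow = length(candidates), ncol = K,
                 dimnames = list(NULL, paste0("beta_fold", seq_len(K))))
  cv <- rep(Inf, length(candidates))
  for (i in seq_along(candidates)) {
    if (tab$degenerate[i]) next
    bet <- fold_betas(scores[[i]]$standardized, outcome, covars, folds)
    bmat[i, ] <- bet
    if (anyNA(bet)) {
      hlog(op = "select_cv_prs", candidate = i, note = "fold fit failed")
      next
    }
    cv[i] <- effect_cv(bet)
  }
  if (all(!is.finite(cv))) stop_config("no valid candidate for CV selection")
  tab <- cbind(tab, bmat, cv = cv)
  best <- candidate_order(tab, cv)[1L]
  structure(list(criterion = "CV", chosen = candidates[[best]]$params,
                 chosen_index = best, table = tab),
            class = "htn_selection")
}

#' Select tuning parameters by minimum association p-value
#'
#' Fits the association model on the whole training sample for every
#' candidate and selects the candidate with the smallest Wald p-value for
#' the PRS coefficient, with the same tie-break chain as [select_cv_prs()].
#'
#' @inheritParams select_cv_prs
#' @return `htn_selection` with `criterion = "PVAL"` and a table carrying
#'   the pooled `beta` and `pvalue` per candidate.
#' @export
select_pval_prs <- function(candidates, scores, outcome, covars) {
  tab <- candidate_table(candidates)
  beta <- pval <- rep(NA_real_, length(candidates))
  for (i in seq_along(candidates)) {
    if (tab$degenerate[i]) next
    est <- tryCatch(
      fit_logistic(outcome, scores[[i]]$standardized, covars),
      error = function(e) NULL
    )
    if (is.null(est)) next
    beta[i] <- est$beta
    pval[i] <- est$pvalue
  }
  if (all(is.na(pval))) stop_config("no valid candidate for PVAL selection")
  tab <- cbind(tab, beta = beta, pvalue = pval)
  crit <- ifelse(is.na(pval), Inf, pval)
  best <- candidate_order(tab, crit)[1L]
  structure(list(criterion = "PVAL", chosen = candidates[[best]]$params,
                 chosen_index = best, table = tab),
            class = "htn_selection")
}

#' Genome-wide-significant PRS candidate
#'
#' The fixed parameterization `p < 5e-8`, clumping `r2 = 0.1`, window
#' 1000 kb — no tuning-parameter selection is performed.
#'
#' @param ss harmonized `htn_sumstats`.
#' @param ref `htn_geno` LD reference.
#' @return an `htn_prs_candidate`; `degenerate = TRUE` when no variant
#'   reaches genome-wide significance.
#' @export
gws_prs <- function(ss, ref) {
  prs_candidate(ss, ref,
                list(p_threshold = 5e-8, r2_max = 0.1, window_kb = 1000))
}

#' Write a selection report as TSV
#'
#' @param sel an `htn_selection`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(sel, path) {
  data.table::fwrite(sel$table, path, sep = "\t")
  invisible(path)
}
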