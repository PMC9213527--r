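# Small fixture builders shared across test files.  Everything is built in
# code; no stored data.

# minimal sumstats data frame -> htn_sumstats via the package constructor
make_ss <- function(chrom, pos, ea, oa, beta, se = 0.05, p, eaf = NA,
                    n = 1e5, trait = "SBP") {
  df <- data.frame(chrom = chrom, pos = pos, ea = ea, oa = oa,
                   beta = beta, se = se, p = p, eaf = eaf, n = n,
                   stringsAsFactors = FALSE)
  htnprs:::new_sumstats(df, trait)
}

# write a sumstats TSV with default headers and return the path
write_ss_file <- function(df, path = tempfile(fileext = ".tsv")) {
  names(df) <- c("CHR", "POS", "EA", "OA", "BETA", "SE", "P", "EAF",
                 "N")[seq_along(names(df))]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# htn_geno from an explicit dosage matrix (samples x variants)
make_geno <- function(dosages, chrom = "chr1",
                      pos = seq_len(ncol(dosages)) * 1000L,
                      ea = "A", oa = "G") {
  n <- nrow(dosages)
  m <- ncol(dosages)
  variants <- data.frame(chrom = rep_len(chrom, m), pos = pos,
                         ea = rep_len(ea, m), oa = rep_len(oa, m),
                         stringsAsFactors = FALSE)
  htnprs:::new_geno(sprintf("S%03d", seq_len(n)), variants, dosages)
}

# random dosage matrix at given allele frequencies
random_geno <- function(n, freqs, seed = 1, ...) {
  d <- htnprs:::with_seed(seed, {
    vapply(freqs, function(f) rbinom(n, 2, f), numeric(n))
  })
  make_geno(d, ...)
}

# small kinship graph from an edge list given as c("A","B", "B","C") pairs
make_kin <- function(samples, ...) {
  pairs <- c(...)
  if (length(pairs)) {
    e <- matrix(pairs, ncol = 2, byrow = TRUE)
    edges <- data.frame(id1 = e[, 1], id2 = e[, 2], kin = 0.25)
  } else edges <- NULL
  kinship_graph(edges, samples)
}

# independent brute-force clumping oracle: literal restatement of the
# greedy rule using ld_r2() pair by pair, no shared code with clump()
clump_oracle <- function(ss, geno, r2_max, window_kb) {
  df <- as.data.frame(ss)
  df$key <- paste(df$chrom, df$pos, df$ea, df$oa, sep = ":")
  df$claimed <- FALSE
  kept <- character(0)
  repeat {
    open <- df[!df$claimed, ]
    if (nrow(open) == 0) break
    open <- open[order(open$p, open$chrom, open$pos), ]
    idx <- open[1, ]
    kept <- c(kept, idx$key)
    df$claimed[df$key == idx$key] <- TRUE
    for (j in which(!df$claimed)) {
      if (df$chrom[j] == idx$chrom &&
          abs(df$pos[j] - idx$pos) <= window_kb * 1000) {
        r2 <- ld_r2(geno, idx$key, df$key[j])
        if (!is.na(r2) && r2 > r2_max) df$claimed[j] <- TRUE
      }
    }
  }
  sort(kept)
}

# brute-force AUC over all case-control pairs, ties counted 1/2
auc_oracle <- function(outcome, score) {
  cases <- score[outcome == 1]
  controls <- score[outcome == 0]
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(controls))
}

# independent per-visit BP classifier: literal if-chain from the clinical
# definition, used to cross-check the vectorized implementation
bp_oracle <- function(sbp, dbp, treated, self_report) {
  if (sbp >= 130 || dbp >= 80 || treated || self_report) "HYPERTENSION"
  else if (sbp >= 120 && sbp <= 129) "ELEVATED"
  else "NORMAL"
}

# covariate frame in the shape the pipeline uses
covars_for <- function(cohort, ids) {
  cv <- cohort$covars[match(ids, cohort$covars$sample_id), , drop = FALSE]
  out <- cv[, c("sex", "age", "bmi", "smoking", "site", "group",
                grep("^PC", names(cv), value = TRUE))]
  out$age2 <- out$age^2
  out$site <- factor(out$site)
  out$group <- factor(out$group)
  rownames(out) <- NULL
  out
}

# baseline hypertension indicator named by sample, from the wide table
baseline_htn <- function(wide) {
  setNames(as.integer(bp_category(wide$sbp1, wide$dbp1, wide$treated1,
                                  wide$self_report1) == "HYPERTENSION"),
           wide$sample_id)
}
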