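small_cfg <- function(seed = 1, ...) {
  sim_config(n_samples = c(EA = 120, AA = 80, HA = 60, AsA = 40),
             n_variants = 300L, n_ld_blocks = 30L, seed = seed, ...)
}

test_that("Balding-Nichols frequencies have the stated mean and variance", {
  cfg <- sim_config(n_variants = 10000L, n_ld_blocks = 10000L,
                    fst = c(EUR = 0, AFR = 0.2, EAS = 0.1), seed = 4)
  fr <- simulate_frequencies(cfg)
  # F = 0 copies the ancestral frequency exactly
  expect_equal(fr$by_pop[, "EUR"], fr$ancestral)
  # Beta(p(1-F)/F, (1-p)(1-F)/F) has mean p ...
  expect_equal(mean(fr$by_pop[, "AFR"] - fr$ancestral), 0,
               tolerance = 0.01)
  # ... and variance F p (1 - p)
  ratio <- (fr$by_pop[, "AFR"] - fr$ancestral)^2 /
    (fr$ancestral * (1 - fr$ancestral))
  expect_equal(mean(ratio), 0.2, tolerance = 0.02)
  ratio2 <- (fr$by_pop[, "EAS"] - fr$ancestral)^2 /
    (fr$ancestral * (1 - fr$ancestral))
  expect_equal(mean(ratio2), 0.1, tolerance = 0.02)
})

test_that("genotypes carry LD inside blocks and independence across", {
  cfg <- sim_config(n_samples = c(EA = 900, AA = 500, HA = 400,
                                  AsA = 200),
                    n_variants = 600L, n_ld_blocks = 60L, seed = 8)
  fr <- simulate_frequencies(cfg)
  gs <- simulate_genotypes(cfg, fr)
  D <- gs$geno$dosages
  adj <- which(diff(gs$blocks) == 0)
  r2_in <- vapply(adj, function(i) {
    suppressWarnings(cor(D[, i], D[, i + 1])^2)
  }, 0)
  cross <- which(diff(gs$blocks) != 0)
  r2_out <- vapply(cross, function(i) {
    suppressWarnings(cor(D[, i], D[, i + 1])^2)
  }, 0)
  expect_gt(mean(r2_in, na.rm = TRUE), 0.3)
  expect_lt(mean(r2_out, na.rm = TRUE), 0.02)
})

test_that("estimated frequencies track the generating admixed frequencies", {
  cfg <- small_cfg(seed = 12)
  fr <- simulate_frequencies(cfg)
  gs <- simulate_genotypes(cfg, fr)
  n <- length(gs$geno$sample_ids)
  f_hat <- allele_freq(gs$geno)
  f_gen <- colMeans(gs$admixture %*% t(fr$by_pop))
  sd_bin <- sqrt(f_gen * (1 - f_gen) / (2 * n))
  inside <- abs(f_hat - f_gen) <= 3 * sd_bin + 0.02
  expect_gt(mean(inside), 0.98)
})

test_that("family fraction controls kinship edges and sibling correlation", {
  cfg0 <- small_cfg(seed = 3, family_fraction = 0)
  gs0 <- simulate_genotypes(cfg0, simulate_frequencies(cfg0))
  expect_equal(nrow(gs0$kinship$edges), 0)

  cfg1 <- small_cfg(seed = 3, family_fraction = 0.3)
  gs1 <- simulate_genotypes(cfg1, simulate_frequencies(cfg1))
  expect_gt(nrow(gs1$kinship$edges), 10)
  # sibling correlation of frequency-centred dosages near 0.5, far above
  # unrelated pairs (centring removes shared population structure)
  e <- gs1$kinship$edges
  Dc <- scale(gs1$geno$dosages, scale = FALSE)
  rownames(Dc) <- gs1$geno$sample_ids
  sib_cor <- vapply(seq_len(nrow(e)), function(i) {
    cor(Dc[e$id1[i], ], Dc[e$id2[i], ])
  }, 0)
  expect_gt(mean(sib_cor), 0.3)
  unrel <- htnprs:::with_seed(5, {
    related <- unique(c(e$id1, e$id2))
    solo <- setdiff(gs1$geno$sample_ids, related)
    pairs <- matrix(sample(solo, 40), ncol = 2)
    vapply(seq_len(nrow(pairs)), function(i) {
      cor(Dc[pairs[i, 1], ], Dc[pairs[i, 2], ])
    }, 0)
  })
  expect_lt(abs(mean(unrel)), 0.1)
})

test_that("phenotypes respond to genetics and progression as configured", {
  cfg <- small_cfg(seed = 6)
  coh <- simulate_cohort(cfg)
  v1 <- coh$visits[coh$visits$visit == 1, ]
  v2 <- coh$visits[coh$visits$visit == 2, ]
  # follow-up prevalence exceeds baseline (progression + treatment ratchet)
  expect_gt(mean(v2$htn), mean(v1$htn))
  # oracle genetic value correlates with measured SBP
  gv <- as.numeric(coh$geno$dosages %*% coh$truth$w_sbp)
  expect_gt(cor(gv, v1$sbp), 0.2)
  # sbp > dbp everywhere and treatment is absorbing
  expect_true(all(coh$visits$sbp > coh$visits$dbp))
  expect_true(all(v2$treated[v1$treated]))
  # zero genetic and covariate effects: SBP is pure noise around the mean
  cfg0 <- small_cfg(seed = 7, effect_sd = c(SBP = 0, DBP = 0, HTN = 0),
                    sex_effect_sbp = 0, bmi_effect_sbp = 0,
                    smoke_effect_sbp = 0, age_slope_sbp = 0,
                    ancestry_shift_sbp = c(EUR = 0, AFR = 0, EAS = 0))
  coh0 <- simulate_cohort(cfg0)
  v10 <- coh0$visits[coh0$visits$visit == 1, ]
  expect_lt(abs(mean(v10$sbp) - cfg0$sbp_mean),
            3 * cfg0$resid_sd[["SBP"]] / sqrt(nrow(v10)))
})

test_that("simulated summary statistics have calibrated noise", {
  cfg <- sim_config(n_variants = 10000L, n_ld_blocks = 1000L,
                    causal_fraction = 1e-4, seed = 9)
  fr <- simulate_frequencies(cfg)
  gs <- list(variants = data.frame(chrom = "chr1",
                                   pos = seq_len(cfg$n_variants),
                                   ea = "A", oa = "G"))
  class(gs) <- "htn_geno"
  truth <- list(w_sbp = numeric(cfg$n_variants),
                w_dbp = numeric(cfg$n_variants),
                w_htn = numeric(cfg$n_variants))
  ss <- simulate_sumstats(cfg, truth, gs, fr, "SBP")
  # null variants: uniform p -> 5% below 0.05 (absolute band)
  expect_lt(abs(mean(ss$p < 0.05) - 0.05), 0.01)
  # essentially no genome-wide-significant hits among 10,000 nulls
  expect_lte(sum(ss$p < 5e-8), 1)
  # doubling n shrinks the median se by sqrt(2)
  cfg2 <- cfg; cfg2$discovery_n["SBP"] <- 2 * cfg$discovery_n[["SBP"]]
  ss2 <- simulate_sumstats(cfg2, truth, gs, fr, "SBP")
  expect_equal(median(ss$se) / median(ss2$se), sqrt(2), tolerance = 0.02)
})

test_that("identical configurations reproduce identical cohorts", {
  c1 <- simulate_cohort(small_cfg(seed = 10))
  c2 <- simulate_cohort(small_cfg(seed = 10))
  expect_identical(c1$geno$dosages, c2$geno$dosages)
  expect_identical(c1$visits, c2$visits)
  expect_identical(c1$sumstats$HTN$beta, c2$sumstats$HTN$beta)
  expect_identical(c1$truth$betas, c2$truth$betas)
  c3 <- simulate_cohort(small_cfg(seed = 11))
  expect_false(identical(c1$geno$dosages, c3$geno$dosages))
})

test_that("written cohorts reload into the same analysis inputs", {
  coh <- simulate_cohort(small_cfg(seed = 13))
  dir <- file.path(tempdir(), "cohort-rt")
  paths <- write_cohort(coh, dir)
  back <- load_cohort(paths)
  expect_equal(back$geno$dosages, coh$geno$dosages)
  expect_equal(back$geno$variants$key, coh$geno$variants$key)
  expect_equal(nrow(back$kinship$edges), nrow(coh$kinship$edges))
  expect_equal(back$sumstats$SBP$beta, coh$sumstats$SBP$beta,
               tolerance = 1e-12)
  expect_equal(back$truth$w_sbp, coh$truth$w_sbp)
  unlink(dir, recursive = TRUE)
})
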