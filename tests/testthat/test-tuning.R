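test_that("kinship-disjoint folds balance sizes and never split components", {
  # 10 singletons across 5 folds -> folds of 2
  k0 <- make_kin(sprintf("S%02d", 1:10))
  f0 <- split_kinship_folds(k0$samples, k0, K = 5, seed = 1)
  expect_equal(as.integer(sort(table(f0))), rep(2L, 5))

  # components sized 3,3,2,1,1 -> one component per fold
  samples <- sprintf("S%02d", 1:10)
  k <- make_kin(samples,
                "S01", "S02", "S02", "S03",   # 3
                "S04", "S05", "S05", "S06",   # 3
                "S07", "S08")                 # 2
  f <- split_kinship_folds(samples, k, K = 5, seed = 3)
  expect_equal(as.integer(sort(table(f))), c(1L, 1L, 2L, 3L, 3L))
  # relatives always share a fold
  expect_equal(unname(f["S01"]), unname(f["S03"]))
  expect_equal(unname(f["S04"]), unname(f["S06"]))
  expect_equal(unname(f["S07"]), unname(f["S08"]))

  # property: no edge crosses folds on random graphs
  for (seed in 1:5) {
    sm <- sprintf("R%02d", 1:40)
    ed <- htnprs:::with_seed(seed, {
      data.frame(id1 = sample(sm, 20, TRUE), id2 = sample(sm, 20, TRUE),
                 kin = 0.25)
    })
    ed <- ed[ed$id1 != ed$id2, ]
    kk <- kinship_graph(ed, sm)
    ff <- split_kinship_folds(sm, kk, K = 4, seed = seed)
    expect_true(all(ff[kk$edges$id1] == ff[kk$edges$id2]))
  }

  # an oversized component warns but is still assigned
  kin_big <- make_kin(sprintf("B%02d", 1:6),
                      "B01", "B02", "B02", "B03", "B03", "B04")
  expect_warning(split_kinship_folds(kin_big$samples, kin_big, K = 3,
                                     seed = 1),
                 "unbalanced")
})

test_that("effect_cv is sd/mean with disqualification at non-positive mean", {
  expect_equal(effect_cv(c(0.5, 0.5, 0.5, 0.5, 0.5)), 0)
  # hand: sd = sqrt(0.005), mean = 0.5
  expect_equal(effect_cv(c(0.4, 0.5, 0.6, 0.5, 0.5)), sqrt(0.005) / 0.5)
  expect_equal(effect_cv(c(0.4, 0.5, 0.6, 0.5, 0.5)), 0.1414214,
               tolerance = 1e-6)
  expect_identical(effect_cv(c(-0.1, 0.1, 0, 0, 0)), Inf)
  expect_identical(effect_cv(c(-0.2, -0.3)), Inf)
  expect_error(effect_cv(0.5), "2 finite")
  # scale invariance for positive scalars
  b <- c(0.2, 0.35, 0.3, 0.27, 0.4)
  expect_equal(effect_cv(3.7 * b), effect_cv(b))
})

make_selection_world <- function(seed = 2, n = 400) {
  # two candidates: one real signal, one noise
  htnprs:::with_seed(seed, {
    z <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.2 + 0.8 * z))
    junk <- rnorm(n)
    mk <- function(vals, p_thr) {
      sc <- structure(data.frame(sample_id = sprintf("S%04d", 1:n),
                                 raw = vals),
                      class = c("htn_prs", "data.frame"))
      sc <- standardize_prs(sc, mean(vals), sd(vals))
      cand <- structure(list(trait = "HTN",
                             params = list(p_threshold = p_thr,
                                           r2_max = 0.1, window_kb = 1000),
                             weights = setNames(1, "chr1:1:A:G"),
                             degenerate = FALSE),
                        class = "htn_prs_candidate")
      list(cand = cand, score = sc)
    }
    good <- mk(z, 1e-6)
    bad <- mk(junk, 1e-2)
    folds <- rep(1:5, length.out = n)
    list(cands = list(good$cand, bad$cand),
         scores = list(good$score, bad$score),
         y = y, folds = folds)
  })
}

test_that("CV selection picks the consistent candidate and reports folds", {
  w <- make_selection_world()
  sel <- select_cv_prs(w$cands, w$scores, w$y, covars = NULL, w$folds)
  expect_s3_class(sel, "htn_selection")
  expect_equal(sel$chosen_index, 1)
  expect_equal(sel$criterion, "CV")
  expect_equal(nrow(sel$table), 2)
  expect_true(all(is.finite(unlist(sel$table[1, paste0("beta_fold", 1:5)]))))
  expect_lt(sel$table$cv[1], sel$table$cv[2])

  # single candidate is chosen trivially
  sel1 <- select_cv_prs(w$cands[1], w$scores[1], w$y, NULL, w$folds)
  expect_equal(sel1$chosen_index, 1)
})

test_that("PVAL selection minimizes the pooled association p", {
  w <- make_selection_world()
  sel <- select_pval_prs(w$cands, w$scores, w$y, covars = NULL)
  expect_equal(sel$chosen_index, 1)
  expect_lt(sel$table$pvalue[1], sel$table$pvalue[2])

  # all-degenerate candidate set errors
  degen <- w$cands[[1]]; degen$degenerate <- TRUE
  expect_error(select_pval_prs(list(degen), w$scores[1], w$y, NULL),
               "no valid candidate")
})

test_that("selection tie-break prefers smaller p-threshold on exact ties", {
  w <- make_selection_world()
  # same score twice under different p thresholds -> identical CV
  c2 <- w$cands[[1]]; c2$params$p_threshold <- 1e-2
  sel <- select_cv_prs(list(c2, w$cands[[1]]),
                       list(w$scores[[1]], w$scores[[1]]),
                       w$y, NULL, w$folds)
  expect_equal(sel$chosen$p_threshold, 1e-6)
})

test_that("gws candidate uses the fixed genome-wide parameters", {
  g <- random_geno(50, runif(6, 0.2, 0.8), seed = 5,
                   pos = c(1e5, 2e5, 3e5, 4e5, 5e5, 6e5))
  ss <- make_ss("chr1", g$variants$pos, "A", "G", beta = 0.2,
                p = c(1e-9, 1e-10, 0.5, 0.2, 1e-3, 0.9))
  cand <- gws_prs(ss, g)
  expect_equal(cand$params,
               list(p_threshold = 5e-8, r2_max = 0.1, window_kb = 1000))
  expect_true(all(ss$p[match(names(cand$weights), g$variants$key)] < 5e-8))
  # consistency with the grid cell built the generic way
  cell <- prs_candidate(ss, g, list(p_threshold = 5e-8, r2_max = 0.1,
                                    window_kb = 1000))
  expect_equal(cand$weights, cell$weights)
  # no genome-wide-significant variant -> degenerate flag
  ss2 <- make_ss("chr1", g$variants$pos[1:2], "A", "G", beta = 0.2,
                 p = c(1e-6, 1e-5))
  expect_true(gws_prs(ss2, g)$degenerate)
})

test_that("per-fold effect dispersion shrinks as fold size grows", {
  disp <- vapply(c(250, 500, 1000), function(n_fold) {
    sds <- vapply(1:8, function(r) {
      htnprs:::with_seed(r * 1000 + n_fold, {
        n <- n_fold * 5
        z <- rnorm(n)
        y <- rbinom(n, 1, plogis(-0.1 + 0.5 * z))
        folds <- rep(1:5, length.out = n)
        sd(vapply(1:5, function(f) {
          glm(y[folds == f] ~ z[folds == f],
              family = binomial())$coefficients[2]
        }, 0))
      })
    }, 0)
    mean(sds)
  }, 0)
  expect_true(all(diff(disp) < 0))
})
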