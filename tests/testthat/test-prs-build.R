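test_that("default grid is the printed 12 x 3 x 3 product", {
  g <- default_grid()
  expect_equal(nrow(g), 108)
  expect_equal(nrow(unique(g)), 108)
  has <- function(p, r2, w) {
    any(g$p_threshold == p & g$r2_max == r2 & g$window_kb == w)
  }
  expect_true(has(5e-8, 0.1, 1000)) # the genome-wide-significant cell
  expect_true(has(0.5, 0.3, 250))   # extreme printed corner
})

test_that("clump keeps the index variant and removes linked neighbours", {
  # A (p=1e-9, 100 kb) clumps away B (p=1e-8, 150 kb, r2 ~ 0.5+);
  # C (p=1e-7, 900 kb) is outside the window and survives
  a <- c(0, 1, 2, 0, 1, 2, 0, 1)
  b <- c(0, 1, 2, 0, 1, 2, 1, 0)   # high r2 with a
  c_ <- c(2, 0, 1, 1, 0, 2, 0, 1)  # shuffled, low r2 with a
  g <- make_geno(cbind(a, b, c_), pos = c(100000L, 150000L, 900000L))
  stopifnot(ld_r2(g, g$variants$key[1], g$variants$key[2]) > 0.5,
            ld_r2(g, g$variants$key[1], g$variants$key[3]) < 0.1)
  ss <- make_ss("chr1", c(100000, 150000, 900000), "A", "G",
                beta = 0.1, p = c(1e-9, 1e-8, 1e-7))
  kept <- clump(ss, g, r2_max = 0.1, window_kb = 250)
  expect_setequal(kept, g$variants$key[c(1, 3)])

  # single variant survives; unlinked pair in one window both survive
  kept1 <- clump(ss[1, ], g, 0.1, 250)
  expect_equal(kept1, g$variants$key[1])
  ss2 <- make_ss("chr1", c(100000, 900000), "A", "G", beta = 0.1,
                 p = c(1e-9, 1e-7))
  expect_equal(length(clump(ss2, g, 0.1, 1000)), 2)
})

test_that("clump equals the brute-force greedy oracle on random instances", {
  for (seed in 1:12) {
    sim <- htnprs:::with_seed(seed, {
      m <- sample(5:30, 1)
      list(m = m,
           freqs = runif(m, 0.1, 0.9),
           pos = sort(sample.int(8e5, m)),
           p = runif(m)^3,
           r2_max = sample(c(0.1, 0.2, 0.3), 1),
           win = sample(c(100, 250, 500), 1))
    })
    g <- random_geno(40, sim$freqs, seed = seed + 100, pos = sim$pos)
    ss <- make_ss("chr1", sim$pos, "A", "G", beta = 0.1, p = sim$p)
    expect_equal(sort(clump(ss, g, sim$r2_max, sim$win)),
                 clump_oracle(ss, g, sim$r2_max, sim$win))
  }
})

test_that("apply_threshold filters the retained set and flags degeneracy", {
  ss <- make_ss("chr1", c(1000, 2000), "A", "G", beta = c(0.5, -0.2),
                p = c(1e-9, 1e-7))
  keys <- paste("chr1", c(1000, 2000), "A", "G", sep = ":")
  w <- apply_threshold(ss, keys, 1e-8)
  expect_equal(names(w), keys[1])
  expect_equal(unname(w), 0.5)
  w_all <- apply_threshold(ss, keys, 0.5)
  expect_equal(length(w_all), 2)
  w_none <- apply_threshold(ss, keys, 1e-12)
  expect_equal(length(w_none), 0)
  expect_true(attr(w_none, "degenerate"))
})

test_that("score_prs is a dot product with mean imputation for missing", {
  g <- make_geno(rbind(c(2, 1), c(NA, 1), c(0, 0), c(0, 2), c(0, 1)))
  k <- g$variants$key
  w <- setNames(c(0.2, -0.1), k)
  s <- score_prs(g, w)
  expect_equal(s$raw[1], 2 * 0.2 + 1 * -0.1)
  # missing dosage: non-missing mean of variant 1 is (2+0+0+0)/4 = 0.5,
  # so freq = 0.25 and the imputed dosage is 2 * 0.25 = 0.5
  expect_equal(s$raw[2], 0.5 * 0.2 + 1 * -0.1)
  # empty weights -> all-zero scores
  s0 <- score_prs(g, setNames(numeric(0), character(0)))
  expect_equal(s0$raw, rep(0, 5))
  # unknown variant errors with its name
  expect_error(score_prs(g, c(`chrX:1:A:G` = 1)), "chrX:1:A:G")
})

test_that("score_prs is linear in the weights", {
  g <- random_geno(30, runif(8, 0.2, 0.8), seed = 3)
  k <- g$variants$key
  w1 <- setNames(rnorm(8), k)
  w2 <- setNames(rnorm(8), k)
  expect_equal(score_prs(g, w1 + w2)$raw,
               score_prs(g, w1)$raw + score_prs(g, w2)$raw)
  expect_equal(score_prs(g, 3 * w1)$raw, 3 * score_prs(g, w1)$raw)
})

test_that("retained sets shrink with stricter clumping and grow with looser p", {
  sim_seed <- 42
  g <- random_geno(100, runif(40, 0.1, 0.9), seed = sim_seed,
                   pos = sort(sample(1:5e5, 40)))
  ss <- make_ss("chr1", g$variants$pos, "A", "G", beta = 0.1,
                p = htnprs:::with_seed(sim_seed, runif(40)^2))
  kept_loose <- clump(ss, g, 0.3, 250)
  kept_tight <- clump(ss, g, 0.1, 250)
  kept_wide <- clump(ss, g, 0.3, 500)
  expect_lte(length(kept_tight), length(kept_loose))
  expect_lte(length(kept_wide), length(kept_loose))
  n_at <- vapply(c(1e-3, 1e-2, 0.1, 0.5), function(thr) {
    length(apply_threshold(ss, kept_loose, thr))
  }, 0)
  expect_true(all(diff(n_at) >= 0))
})

test_that("standardization uses the supplied constants and records them", {
  prs <- structure(data.frame(sample_id = c("a", "b"), raw = c(1.3, 0.3)),
                   class = c("htn_prs", "data.frame"))
  out <- standardize_prs(prs, mean = 0.3, sd = 0.5)
  expect_equal(out$standardized, c(2, 0))
  expect_equal(attr(out, "standardization")$source, "full-cohort")
  expect_error(standardize_prs(prs, 0, 0), "sd")

  # standardizing by a sample's own constants gives mean 0, sd 1
  g <- random_geno(200, runif(10, 0.2, 0.8), seed = 9)
  w <- setNames(rnorm(10), g$variants$key)
  s <- score_prs(g, w)
  s <- standardize_prs(s, mean(s$raw), sd(s$raw))
  expect_equal(mean(s$standardized), 0, tolerance = 1e-10)
  expect_equal(sd(s$standardized), 1, tolerance = 1e-10)

  # a smaller group sd inflates |standardized| values
  s_grp <- standardize_prs(s, mean(s$raw), sd(s$raw) / 2, "group:AA")
  expect_true(all(abs(s_grp$standardized) >= abs(s$standardized)))
})

test_that("prssum is the order-invariant sum of standardized components", {
  mk <- function(vals) {
    standardize_prs(
      structure(data.frame(sample_id = c("a", "b", "c"), raw = vals),
                class = c("htn_prs", "data.frame")),
      mean = 0, sd = 1
    )
  }
  comps <- list(mk(c(0.5, 1, -2)), mk(c(-1.0, 0, 1)), mk(c(2.0, 1, 0)))
  out <- prssum(comps)
  expect_equal(out$raw[1], 1.5) # 0.5 - 1 + 2, before re-standardization
  expect_equal(mean(out$standardized), 0, tolerance = 1e-12)
  # permuting component order changes nothing
  out2 <- prssum(comps[c(3, 1, 2)])
  expect_equal(out2$raw, out$raw)
  # single component is an identity up to re-standardization
  one <- prssum(comps[1])
  expect_equal(one$raw, comps[[1]]$standardized)
  # mismatched sample sets error
  bad <- mk(c(1, 2, 3)); bad$sample_id <- c("x", "y", "z")
  expect_error(prssum(list(comps[[1]], bad)), "sample sets")
  # unstandardized component errors
  raw_only <- structure(data.frame(sample_id = c("a", "b", "c"),
                                   raw = 1:3),
                        class = c("htn_prs", "data.frame"))
  expect_error(prssum(list(raw_only)), "standardized")
})
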