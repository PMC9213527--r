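test_that("prs_strata produces 10/40/40/10 bands with reproducible ties", {
  x <- htnprs:::with_seed(1, rnorm(100))
  s <- prs_strata(x, seed = 1)
  expect_equal(as.integer(table(s)), c(10L, 40L, 40L, 10L))
  expect_equal(attr(s, "labels"), c("<10%", "10-50%", "50-90%", ">90%"))
  # ranks follow the score
  expect_equal(unname(s[which.max(x)]), 4L)
  expect_equal(unname(s[which.min(x)]), 1L)

  # all-tied values: seeded random partition with the same target sizes
  s_tie <- prs_strata(rep(1, 100), seed = 7)
  expect_equal(as.integer(table(s_tie)), c(10L, 40L, 40L, 10L))
  expect_equal(s_tie, prs_strata(rep(1, 100), seed = 7))
  expect_false(identical(s_tie, prs_strata(rep(1, 100), seed = 8)))

  # within-group scope re-ranks inside each group
  g <- rep(c("a", "b"), each = 100)
  x2 <- c(htnprs:::with_seed(2, rnorm(100)),
          10 + htnprs:::with_seed(3, rnorm(100)))
  sw <- prs_strata(x2, scope = "within-group", group = g, seed = 1)
  expect_equal(as.integer(table(sw[g == "a"])), c(10L, 40L, 40L, 10L))
  expect_equal(as.integer(table(sw[g == "b"])), c(10L, 40L, 40L, 10L))
})

test_that("or_by_age reproduces the delta-method arithmetic", {
  fit <- structure(list(beta_age = 0.05, beta_age2 = 0.001,
                        cov = diag(c(1e-4, 1e-8)), ref_age = 17),
                   class = "htn_trajectory")
  out <- or_by_age(fit, c(17, 37))
  # reference age: OR exactly 1 with a zero-width interval
  expect_equal(out$or[1], 1)
  expect_equal(out$ci_low[1], 1)
  expect_equal(out$ci_high[1], 1)
  # age 37: log-OR = 20*0.05 + 400*0.001 = 1.4
  expect_equal(out$log_or[2], 1.4)
  expect_equal(out$or[2], exp(1.4))
  expect_equal(out$or[2], 4.0552, tolerance = 1e-4)
  # delta-method: var = 400*1e-4 + 160000*1e-8 = 0.0416
  expect_equal(out$se[2], sqrt(0.0416))
  expect_equal(out$se[2], 0.2040, tolerance = 1e-3)
  expect_equal(out$ci_low[2], exp(1.4 - 1.96 * sqrt(0.0416)))
  expect_equal(round(out$ci_low[2], 2), 2.72)
  expect_equal(round(out$ci_high[2], 2), 6.05)
  # a non-zero covariance term enters with weight 2 D^3
  fit$cov[1, 2] <- fit$cov[2, 1] <- 2e-6
  out2 <- or_by_age(fit, 37)
  expect_equal(out2$se^2, 0.0416 + 2 * 20^3 * 2e-6)
  expect_error(or_by_age(fit, 10), "ref_age")
})

test_that("trajectory curves are invariant to a consistent age shift", {
  sim <- htnprs:::with_seed(11, {
    n <- 300; v <- 4
    id <- rep(sprintf("P%03d", 1:n), each = v)
    age <- rep(runif(n, 20, 40), each = v) + rep(0:(v - 1) * 3, n)
    u <- rep(rnorm(n, 0, 1), each = v)
    p <- plogis(-3 + u + 0.08 * (age - 17))
    data.frame(sample_id = id, age = age, htn = rbinom(n * v, 1, p))
  })
  f1 <- fit_trajectory(sim, ref_age = 17, random_intercept = FALSE)
  sim2 <- sim; sim2$age <- sim2$age + 5
  f2 <- fit_trajectory(sim2, ref_age = 22, random_intercept = FALSE)
  expect_equal(f1$beta_age, f2$beta_age, tolerance = 1e-8)
  expect_equal(or_by_age(f1, 40)$or, or_by_age(f2, 45)$or,
               tolerance = 1e-8)
})

test_that("the GLMM recovers generating age coefficients", {
  # outcome drawn directly from the random-intercept logistic model
  sim <- htnprs:::with_seed(19, {
    n <- 1000; v <- 6
    id <- rep(sprintf("P%04d", 1:n), each = v)
    age0 <- rep(runif(n, 17, 35), each = v)
    age <- age0 + rep(0:(v - 1) * 3, n)
    u <- rep(rnorm(n, 0, 1.2), each = v)
    sex <- rep(rbinom(n, 1, 0.5), each = v)
    d <- age - 17
    eta <- -3.5 + u + 0.3 * sex + 0.08 * d + (-0.0005) * d^2
    data.frame(sample_id = id, age = age, sex = sex,
               htn = rbinom(n * v, 1, plogis(eta)))
  })
  fit <- fit_trajectory(sim, covars = "sex")
  expect_equal(fit$engine, "glmer-laplace")
  dev <- c(fit$beta_age - 0.08, fit$beta_age2 + 0.0005)
  stat <- as.numeric(t(dev) %*% solve(fit$cov) %*% dev)
  expect_lt(stat, 9) # within 3 joint SEs of the truth
  # degenerate path equals pooled logistic
  f_glm <- fit_trajectory(sim, covars = "sex", random_intercept = FALSE)
  ref <- glm(htn ~ sex + I(age - 17) + I((age - 17)^2), data = sim,
             family = binomial())
  expect_equal(f_glm$beta_age, unname(coef(ref)[3]), tolerance = 1e-6)
  expect_equal(f_glm$beta_age2, unname(coef(ref)[4]), tolerance = 1e-6)
})

test_that("a zero generating age effect is not detected spuriously", {
  hits <- vapply(1:40, function(r) {
    sim <- htnprs:::with_seed(3000 + r, {
      n <- 150; v <- 4
      id <- rep(sprintf("P%03d", 1:n), each = v)
      age <- rep(runif(n, 20, 40), each = v) + rep(0:(v - 1) * 3, n)
      data.frame(sample_id = id, age = age,
                 htn = rbinom(n * v, 1, 0.3))
    })
    fit <- fit_trajectory(sim, random_intercept = FALSE)
    abs(fit$beta_age) < 3 * sqrt(fit$cov[1, 1])
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("fitted OR at the oldest age orders across PRS strata", {
  # young-adult world: six exams over 15 years, genetic effects amplified
  # with age, persistent within-person BP component
  ordered <- vapply(1:12, function(seed) {
    n <- 1600
    cfg <- sim_config(seed = seed, age_amplification = 0.035,
                      sbp_mean = 108, dbp_mean = 68, visit_spacing = 3,
                      progression_drift = 0, treat_prob = 0.3,
                      bp_track = 0.55, n_visits = 6L)
    z <- htnprs:::with_seed(seed_stream(seed, "traj_prs"), rnorm(n))
    z <- (z - mean(z)) / sd(z)
    adm <- matrix(c(rep(0.9, n), rep(0.05, n), rep(0.05, n)), n, 3,
                  dimnames = list(NULL, c("EUR", "AFR", "EAS")))
    ids <- sprintf("T%04d", 1:n)
    # per-SD genetic effect ~5.5 mmHg SBP, a per-SD log-OR near 0.7
    ph <- simulate_phenotypes(cfg, gv_sbp = 5.5 * z, gv_dbp = 3.2 * z,
                              admixture = adm, group = rep("EA", n),
                              sample_ids = ids, age_mean = 25, age_sd = 4,
                              age_range = c(17, 35))
    strata <- prs_strata(z, seed = seed)
    vis <- merge(ph$visits, ph$covars[, c("sample_id", "sex")],
                 by = "sample_id")
    or50 <- vapply(1:4, function(s) {
      d <- vis[vis$sample_id %in% ids[strata == s], ]
      fit <- fit_trajectory(d, covars = "sex", random_intercept = FALSE)
      or_by_age(fit, 50)$or
    }, 0)
    !is.unsorted(or50, strictly = TRUE)
  }, TRUE)
  expect_gte(mean(ordered), 0.9)
})
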