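# Age-dependent hypertension-risk trajectories within PRS strata.

#' Assign samples to PRS percentile strata
#'
#' Rank-based assignment to the percentile bands `<10`, `10-50`, `50-90`,
#' `>90` (configurable cut points).  Exact score ties are broken by a
#' seeded shuffle so the strata partition the sample reproducibly.  With
#' `scope = "within-group"`, ranks are recomputed inside each group label,
#' which matters when score distributions differ across groups.
#'
#' @param prs an `htn_prs` (standardized) or a numeric vector.
#' @param cuts percentile cut points as fractions, default
#'   `c(0.10, 0.50, 0.90)` giving four strata.
#' @param scope `"combined"` or `"within-group"`.
#' @param group group labels, required for `scope = "within-group"`.
#' @param seed integer seed for tie-breaking.
#' @return integer vector of stratum indices `1..(length(cuts) + 1)`,
#'   with attribute `labels` (e.g. `"<10%"`, `"10-50%"`).
#' @export
prs_strata <- function(prs, cuts = c(0.10, 0.50, 0.90),
                       scope = c("combined", "within-group"),
                       group = NULL, seed = 1L) {
  scope <- match.arg(scope)
  x <- if (inherits(prs, "htn_prs")) {
    prs$standardized %||% prs$raw
  } else as.numeric(prs)
  stopifnot(all(diff(cuts) > 0), all(cuts > 0), all(cuts < 1))
  assign_one <- function(v, seed_k) {
    n <- length(v)
    if (n < 10 * (length(cuts) + 1)) {
      warning("fewer than ~10 samples per intended stratum", call. = FALSE)
    }
    tb <- with_seed(seed_k, runif(n))
    r <- integer(n)
    r[order(v, tb)] <- seq_len(n)
    bounds <- round(cuts * n)
    findInterval(r, bounds + 0.5) + 1L
  }
  out <- if (scope == "combined") {
    assign_one(x, seed_stream(seed, "prs_strata"))
  } else {
    stopifnot(!is.null(group), length(group) == length(x))
    res <- integer(length(x))
    for (gname in unique(group)) {
      sel <- group == gname
      res[sel] <- assign_one(x[sel],
                             seed_stream(seed, paste0("prs_strata:", gname)))
    }
    res
  }
  pct <- c(0, cuts, 1) * 100
  labels <- c(paste0("<", pct[2], "%"),
              paste0(pct[2:(length(pct) - 2)], "-",
                     pct[3:(length(pct) - 1)], "%"),
              paste0(">", pct[length(pct) - 1], "%"))
  attr(out, "labels") <- labels
  out
}

#' Fit an age-trajectory GLMM for hypertension within one stratum
#'
#' Logistic generalized linear mixed model with a per-sample random
#' intercept over repeated visits.  Fixed effects are the covariates plus
#' `(age - ref_age)` and `(age - ref_age)^2`; ages are shifted by the
#' reference age (17 years, the youngest study entry age) before fitting,
#' so the age coefficients express log-odds change relative to that age.
#' Fitted by Laplace approximation (`lme4::glmer`); with
#' `random_intercept = FALSE` the model degenerates to ordinary logistic
#' regression on pooled visits.
#'
#' @param data data frame with one row per visit: columns `sample_id`,
#'   `htn` (0/1 status at the visit), `age` (years), plus any covariates.
#' @param covars character vector of covariate column names (e.g. sex and
#'   ancestry PCs).
#' @param ref_age reference age in years (default 17).
#' @param random_intercept logical; `FALSE` fits plain pooled logistic.
#' @return list of class `htn_trajectory`: `beta_age`, `beta_age2`, `cov`
#'   (2x2 covariance of the age coefficients), `ref_age`, `fit`, `engine`.
#' @export
fit_trajectory <- function(data, covars = character(), ref_age = 17,
                           random_intercept = TRUE) {
  stopifnot(all(c("sample_id", "htn", "age") %in% names(data)))
  df <- data
  df$age_c <- df$age - ref_age
  df$age_c2 <- df$age_c^2
  rhs <- paste(c(covars, "age_c", "age_c2"), collapse = " + ")
  if (random_intercept) {
    form <- as.formula(paste("htn ~", rhs, "+ (1 | sample_id)"))
    fit <- lme4::glmer(form, data = df, family = binomial(),
                       control = lme4::glmerControl(calc.derivs = FALSE))
    cf <- lme4::fixef(fit)
    V <- as.matrix(vcov(fit))
    engine <- "glmer-laplace"
  } else {
    form <- as.formula(paste("htn ~", rhs))
    fit <- glm(form, data = df, family = binomial())
    cf <- coef(fit)
    V <- vcov(fit)
    engine <- "glm-pooled"
  }
  sel <- c("age_c", "age_c2")
  structure(list(beta_age = cf[["age_c"]], beta_age2 = cf[["age_c2"]],
                 cov = V[sel, sel], ref_age = ref_age, fit = fit,
                 engine = engine),
            class = "htn_trajectory")
}

#' Odds-ratio-by-age curve with delta-method confidence band
#'
#' For age `a` with `D = a - ref_age`, the log-OR relative to the
#' reference age is `D * beta_age + D^2 * beta_age2`, with variance
#' `D^2 v11 + D^4 v22 + 2 D^3 v12` from the coefficient covariance
#' (multivariate-normal assumption).  The 95% band uses the 1.96 normal
#' quantile.  At the reference age the OR is exactly 1 with a zero-width
#' interval.
#'
#' @param fit an `htn_trajectory` from [fit_trajectory()].
#' @param ages numeric vector of ages (>= `ref_age`).
#' @return data frame `age`, `log_or`, `se`, `or`, `ci_low`, `ci_high`.
#' @export
or_by_age <- function(fit, ages) {
  stopifnot(inherits(fit, "htn_trajectory"), all(ages >= fit$ref_age))
  D <- ages - fit$ref_age
  log_or <- D * fit$beta_age + D^2 * fit$beta_age2
  v <- fit$cov
  var_ <- D^2 * v[1, 1] + D^4 * v[2, 2] + 2 * D^3 * v[1, 2]
  se <- sqrt(pmax(var_, 0))
  data.frame(age = ages, log_or = log_or, se = se, or = exp(log_or),
             ci_low = exp(log_or - 1.96 * se),
             ci_high = exp(log_or + 1.96 * se))
}
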