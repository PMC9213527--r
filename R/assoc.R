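# Association analytics: logistic (mixed) models, AUC on unrelateds,
# correlated Cochran's Q, decile analyses, ancestry strata.

# Build a model frame / design matrix from outcome, exposure and covariates,
# with listwise deletion (counts logged) and degenerate factor levels
# dropped.
build_design <- function(outcome, exposure, covars, exposure_name = "prs") {
  df <- data.frame(.y = outcome)
  if (!is.null(exposure)) df[[exposure_name]] <- exposure
  if (!is.null(covars)) {
    covars <- as.data.frame(covars)
    for (nm in names(covars)) df[[nm]] <- covars[[nm]]
  }
  cc <- complete.cases(df)
  if (any(!cc)) {
    hlog(op = "listwise_deletion", dropped = sum(!cc), kept = sum(cc))
    df <- df[cc, , drop = FALSE]
  }
  # drop constant columns and single-level factors (keeps design full rank)
  keep <- vapply(names(df), function(nm) {
    if (nm == ".y") return(TRUE)
    v <- df[[nm]]
    if (is.factor(v) || is.character(v)) length(unique(v)) >= 2L
    else var(as.numeric(v)) > 0
  }, TRUE)
  dropped <- names(df)[!keep]
  if (length(dropped)) {
    hlog(op = "drop_degenerate_covariates",
         cols = paste(dropped, collapse = ","))
  }
  list(df = df[, keep, drop = FALSE], complete = cc)
}

#' Logistic association of a standardized PRS with a binary outcome
#'
#' Without `kinship`, a maximum-likelihood logistic regression.  With
#' `kinship`, a logistic mixed model with a per-sample random effect whose
#' covariance is proportional to the sparse relationship matrix
#' (`2 * kinship`), fitted by penalized quasi-likelihood (PQL); the
#' variance component is estimated by maximizing the working-model REML, or
#' can be fixed via `tau`.  The PRS coefficient is tested by a Wald test.
#'
#' @param outcome binary 0/1 vector.
#' @param prs numeric exposure (standardized PRS, or any scalar exposure).
#' @param covars optional data frame of covariates (factors allowed);
#'   listwise deletion is applied and degenerate columns dropped, with
#'   counts logged.
#' @param kinship optional `htn_kinship`; requires `sample_ids`.
#' @param sample_ids sample identifiers aligned with `outcome` (needed for
#'   the kinship model).
#' @param tau optional fixed variance component for the kinship random
#'   effect; `tau = 0` reproduces the plain logistic fit.
#' @return list of class `htn_assoc`: `beta`, `se`, `pvalue`, `or`,
#'   `ci_low`, `ci_high`, `n`, `model` ("logistic" or "pql"), and `fit`.
#' @export
fit_logistic <- function(outcome, prs, covars = NULL, kinship = NULL,
                         sample_ids = NULL, tau = NULL) {
  stopifnot(all(outcome %in% c(0, 1)))
  if (length(unique(outcome)) < 2L) {
    stop_config("outcome must contain both classes")
  }
  d <- build_design(outcome, prs, covars)
  df <- d$df
  if (is.null(kinship) || isTRUE(tau == 0)) {
    fit <- glm(.y ~ ., data = df, family = binomial())
    if (!fit$converged) stop_config("logistic fit did not converge")
    beta <- coef(fit)[["prs"]]
    if (is.na(beta)) stop_config("exposure dropped from rank-deficient fit")
    se <- sqrt(vcov(fit)["prs", "prs"])
    # separation signature: runaway exposure coefficient, or a large
    # coefficient whose Wald SE exceeds it (likelihood is flat at the top)
    if (abs(beta) > 15 || (abs(beta) > 5 && se > abs(beta))) {
      stop_config("separation detected on the exposure; ",
                  "consider penalized regression")
    }
    model <- "logistic"
  } else {
    if (is.null(sample_ids)) {
      stop_config("kinship model needs sample_ids aligned with outcome")
    }
    ids <- sample_ids[d$complete]
    K <- kinship_matrix(kinship, ids)
    X <- stats::model.matrix(.y ~ ., data = df)
    fit <- pql_logistic(df$.y, X, K, tau = tau)
    beta <- fit$beta[["prs"]]
    se <- fit$se[["prs"]]
    model <- "pql"
  }
  z <- beta / se
  structure(list(beta = beta, se = se,
                 pvalue = 2 * pnorm(-abs(z)),
                 or = exp(beta),
                 ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se),
                 n = nrow(df), model = model, fit = fit),
            class = "htn_assoc")
}

# Penalized quasi-likelihood for a logistic model with one Gaussian random
# effect b ~ N(0, tau * K), K sparse (relationship matrix).  Stand-in for
# specialised mixed-model software: working linear mixed model iterated to
# convergence, tau by REML on the working model unless fixed.
pql_logistic <- function(y, X, K, tau = NULL, max_iter = 50, tol = 1e-6) {
  n <- length(y)
  p <- ncol(X)
  fit0 <- glm.fit(X, y, family = binomial())
  beta <- fit0$coefficients
  b <- rep(0, n)
  est_tau <- is.null(tau)
  if (est_tau) tau <- 0.1
  K <- methods::as(K, "CsparseMatrix")
  solve_beta <- function(Vchol, z) {
    Vi_X <- as.matrix(Matrix::solve(Vchol, X, system = "A"))
    Vi_z <- as.numeric(Matrix::solve(Vchol, z, system = "A"))
    XtViX <- crossprod(X, Vi_X)
    list(beta = as.numeric(solve(XtViX, crossprod(X, Vi_z))),
         XtViX = XtViX, Vi_z = Vi_z, Vi_X = Vi_X)
  }
  reml <- function(log_tau, Wi, z) {
    tt <- exp(log_tau)
    V <- Matrix::Diagonal(x = Wi) + tt * K
    ch <- Matrix::Cholesky(V, LDL = FALSE)
    sb <- solve_beta(ch, z)
    r <- z - as.numeric(X %*% sb$beta)
    Vi_r <- Matrix::solve(ch, r, system = "A")
    ld_V <- 2 * Matrix::determinant(ch, sqrt = TRUE)$modulus
    -0.5 * (as.numeric(ld_V) + determinant(sb$XtViX)$modulus +
              sum(r * as.numeric(Vi_r)))
  }
  for (iter in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta) + b
    mu <- plogis(eta)
    mu <- pmin(pmax(mu, 1e-8), 1 - 1e-8)
    W <- mu * (1 - mu)
    z <- eta + (y - mu) / W
    Wi <- 1 / W
    if (est_tau && iter <= 10) {
      opt <- optimize(reml, interval = c(log(1e-6), log(20)),
                      Wi = Wi, z = z, maximum = TRUE)
      tau <- exp(opt$maximum)
    }
    V <- Matrix::Diagonal(x = Wi) + tau * K
    ch <- Matrix::Cholesky(V, LDL = FALSE)
    sb <- solve_beta(ch, z)
    beta_new <- sb$beta
    r <- z - as.numeric(X %*% beta_new)
    b <- tau * as.numeric(K %*% Matrix::solve(ch, r, system = "A"))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) break
  }
  if (delta >= tol) {
    stop_config("PQL did not converge after ", max_iter,
                " iterations (last delta ", format(delta), ")")
  }
  cov_beta <- solve(sb$XtViX)
  list(beta = setNames(beta, colnames(X)),
       se = setNames(sqrt(diag(cov_beta)), colnames(X)),
       tau = tau, iterations = iter, cov = cov_beta)
}

#' Mann-Whitney AUC over an unrelated sample subset
#'
#' Area under the ROC curve of `score` for `outcome`, computed as the
#' Mann-Whitney statistic with ties counted 1/2, over the samples listed in
#' `unrelated` (predictive performance is assessed on unrelated individuals
#' only, so related samples do not inflate the effective sample size).
#'
#' @param outcome binary 0/1 vector.
#' @param score numeric score (PRS or linear predictor).
#' @param unrelated indices or sample ids (with `sample_ids`) defining the
#'   unrelated subset; `NULL` uses all samples.
#' @param sample_ids sample identifiers aligned with `outcome`.
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(outcome, score, unrelated = NULL,
                        sample_ids = NULL) {
  if (!is.null(unrelated)) {
    sel <- if (is.character(unrelated)) {
      stopifnot(!is.null(sample_ids))
      sample_ids %in% unrelated
    } else unrelated
    outcome <- outcome[sel]
    score <- score[sel]
  }
  n1 <- sum(outcome == 1)
  n0 <- sum(outcome == 0)
  if (n1 == 0 || n0 == 0) stop_config("AUC undefined: one class is empty")
  r <- rank(score)
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cochran's Q heterogeneity test for correlated effect estimates
#'
#' Generalized least squares pooling of stratum-specific log-ORs under a
#' full covariance matrix: pooled mean `(1' S^-1 1)^-1 1' S^-1 beta`,
#' `Q = (beta - pooled)' S^-1 (beta - pooled)`, `df = k - 1`, p-value from
#' the chi-squared distribution.  With a diagonal covariance this is the
#' textbook fixed-effects Q.
#'
#' @param betas numeric vector of stratum effect estimates.
#' @param cov covariance matrix of the estimates (symmetric positive
#'   definite); a vector is taken as a diagonal of variances.
#' @return list `Q`, `df`, `pvalue`, `pooled`.
#' @export
cochran_q <- function(betas, cov) {
  k <- length(betas)
  stopifnot(k >= 2L)
  if (is.null(dim(cov))) cov <- diag(cov, nrow = k)
  stopifnot(nrow(cov) == k, ncol(cov) == k,
            isTRUE(all.equal(cov, t(cov), tolerance = 1e-8)))
  Si <- tryCatch(solve(cov), error = function(e) {
    stop_config("singular covariance matrix in cochran_q")
  })
  one <- rep(1, k)
  pooled <- as.numeric((t(one) %*% Si %*% betas) / (t(one) %*% Si %*% one))
  d <- betas - pooled
  Q <- as.numeric(t(d) %*% Si %*% d)
  list(Q = Q, df = k - 1L, pvalue = pchisq(Q, df = k - 1L,
                                           lower.tail = FALSE),
       pooled = pooled)
}

#' Stratum-specific PRS effects with their joint covariance
#'
#' Fits a single logistic model with PRS-by-stratum interactions (no PRS
#' main effect), so each stratum gets its own PRS coefficient and the
#' off-diagonal covariance between stratum effects comes from the joint
#' information matrix.  Feed the result to [cochran_q()].
#'
#' @param outcome binary 0/1 vector.
#' @param prs standardized PRS.
#' @param strata factor of stratum labels.
#' @param covars optional covariate data frame.
#' @return list `betas` (named by stratum), `cov`, `fit`.
#' @export
strata_effects <- function(outcome, prs, strata, covars = NULL) {
  strata <- droplevels(factor(strata))
  cv <- data.frame(.stratum = strata)
  if (!is.null(covars)) cv <- cbind(cv, as.data.frame(covars))
  d <- build_design(outcome, prs, cv)
  df <- d$df
  fit <- glm(.y ~ . - prs + .stratum:prs, data = df, family = binomial())
  cf <- coef(fit)
  sel <- grep("prs:\\.stratum|\\.stratum.*:prs", names(cf))
  betas <- cf[sel]
  names(betas) <- gsub("prs|\\.stratum|:", "", names(betas))
  V <- vcov(fit)[sel, sel, drop = FALSE]
  dimnames(V) <- list(names(betas), names(betas))
  list(betas = betas, cov = V, fit = fit)
}

# Rank-based deciles with seeded tie-breaking among exactly equal scores.
prs_deciles <- function(prs, seed = 1L) {
  n <- length(prs)
  tb <- with_seed(seed_stream(seed, "deciles"), runif(n))
  r <- integer(n)
  r[order(prs, tb)] <- seq_len(n)
  as.integer(ceiling(10 * r / n))
}

#' Linear trend of longitudinal-category counts across PRS deciles
#'
#' For each longitudinal BP category, regresses the per-decile count on the
#' decile index 1..10 by ordinary least squares and reports the slope and
#' its p-value.  Reproduces the decile-plot trend analysis: a strongly
#' predictive PRS shows a positive slope for hypertension-at-both-exams and
#' a negative slope for never-hypertensive.
#'
#' @param prs numeric PRS (any monotone transform; deciles are rank-based).
#' @param categories factor of longitudinal categories per sample
#'   (levels of [longitudinal_category()]).
#' @param seed seed for decile tie-breaking.
#' @return data frame `category`, `slope`, `se`, `pvalue`.
#' @export
decile_trend <- function(prs, categories, seed = 1L) {
  stopifnot(length(prs) >= 10L, length(prs) == length(categories))
  dec <- prs_deciles(prs, seed)
  categories <- factor(categories,
                       levels = union(levels(factor(categories)),
                                      LONG_LEVELS[1:4]))
  out <- lapply(levels(categories), function(lv) {
    counts <- vapply(1:10, function(d) {
      sum(dec == d & categories == lv)
    }, 0L)
    fit <- lm(counts ~ d, data = data.frame(counts = counts, d = 1:10))
    sm <- summary(fit)$coefficients
    data.frame(category = lv, slope = sm["d", "Estimate"],
               se = sm["d", "Std. Error"], pvalue = sm["d", "Pr(>|t|)"])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Top-versus-bottom PRS decile odds ratio
#'
#' Logistic model restricted to the top and bottom deciles of the PRS with
#' a binary top-decile indicator as the exposure.
#'
#' @param prs numeric PRS.
#' @param outcome binary 0/1 vector.
#' @param covars optional covariate data frame.
#' @param seed seed for decile tie-breaking.
#' @return `htn_assoc` (see [fit_logistic()]); `beta` is the top-vs-bottom
#'   log-OR.
#' @export
top_bottom_decile_or <- function(prs, outcome, covars = NULL, seed = 1L) {
  dec <- prs_deciles(prs, seed)
  sel <- dec %in% c(1L, 10L)
  if (!any(dec == 1L) || !any(dec == 10L)) {
    stop_config("empty extreme decile")
  }
  top <- as.numeric(dec[sel] == 10L)
  cv <- if (is.null(covars)) NULL else covars[sel, , drop = FALSE]
  fit_logistic(outcome[sel], top, cv)
}

#' Label samples by predominant genetic ancestry
#'
#' A sample is labeled with ancestry `a` iff its proportion of `a` is at
#' least `threshold`; otherwise (including exact ties at the threshold
#' between two ancestries) it stays unlabeled (`NA`).
#'
#' @param admixture numeric matrix (samples x ancestries) of proportions,
#'   rows summing to 1; column names are ancestry labels.
#' @param threshold labeling threshold, default 0.8.
#' @return character vector of ancestry labels, `NA` where no single
#'   ancestry dominates.
#' @export
ancestry_strata <- function(admixture, threshold = 0.8) {
  admixture <- as.matrix(admixture)
  stopifnot(all(abs(rowSums(admixture) - 1) < 1e-6))
  labs <- colnames(admixture) %||% paste0("anc", seq_len(ncol(admixture)))
  apply(admixture, 1L, function(p) {
    hit <- which(p >= threshold)
    if (length(hit) == 1L) labs[hit] else NA_character_
  })
}
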