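# Synthetic multi-ancestry cohort generator.
#
# The generator emulates the statistical structure of the real inputs the
# pipeline was designed for: ancestry-differentiated allele frequencies
# (Balding-Nichols), LD blocks (latent Gaussian haplotypes), sparse
# relatedness (sibships), correlated SBP/DBP/HTN genetic effects,
# externally supplied discovery-GWAS summary statistics, and repeated-visit
# blood-pressure measurements with antihypertensive treatment.

#' Simulation configuration
#'
#' Returns the default configuration, optionally overridden.  Defaults
#' describe a desk-scale analog of a multi-ethnic cohort: four
#' race/ethnic background groups with distinct admixture of three
#' ancestral populations, 5,000 variants in LD blocks, ~10% of samples in
#' sibships, 1% causal variants with correlated effects on SBP, DBP and
#' the liability to hypertension, and discovery GWAS with the published
#' sample sizes (318,492 SBP; 318,891 DBP; 451,894 HTN with 27.9% cases).
#'
#' @param ... named overrides of the default fields.
#' @return list of class `htn_sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    # cohort structure
    n_samples = c(EA = 800, AA = 500, HA = 500, AsA = 200),
    n_variants = 5000L,
    n_ld_blocks = 500L,
    ld_rho = 0.8,            # latent correlation of adjacent variants
    freq_range = c(0.05, 0.95), # ancestral allele frequency range
    fst = c(EUR = 0.02, AFR = 0.12, EAS = 0.10),
    # rows: background group; cols: ancestral population mixing weights
    admixture = rbind(EA = c(EUR = 0.95, AFR = 0.03, EAS = 0.02),
                      AA = c(EUR = 0.20, AFR = 0.78, EAS = 0.02),
                      HA = c(EUR = 0.55, AFR = 0.25, EAS = 0.20),
                      AsA = c(EUR = 0.05, AFR = 0.05, EAS = 0.90)),
    family_fraction = 0.10,  # fraction of samples living in sibships
    sibship_size = 2L,
    # genetic architecture
    causal_fraction = 0.01,
    effect_sd = c(SBP = 2.0, DBP = 1.2, HTN = 0.12),
    # minimum |effect| per causal variant (same units as effect_sd); 0 keeps
    # the plain normal model, > 0 truncates effects away from zero for
    # worlds where every causal variant is detectable in discovery
    effect_floor = c(SBP = 0, DBP = 0, HTN = 0),
    effect_cor = matrix(c(1, 0.7, 0.7,
                          0.7, 1, 0.7,
                          0.7, 0.7, 1), 3, 3,
                        dimnames = list(c("SBP", "DBP", "HTN"),
                                        c("SBP", "DBP", "HTN"))),
    # phenotype model
    sbp_mean = 120, dbp_mean = 75,
    resid_sd = c(SBP = 14, DBP = 9),
    bp_cor = 0.5,            # residual SBP/DBP correlation
    # fraction of residual BP variance that is a persistent per-person
    # component (blood pressure tracks within adults); relevant for
    # repeated-visit designs, 0 makes visits conditionally independent
    bp_track = 0,
    ancestry_shift_sbp = c(EUR = 0, AFR = 5, EAS = 1),
    age_mean = 55, age_sd = 10, age_range = c(20, 80),
    age_slope_sbp = 0.45, age_slope_dbp = 0.20, # mmHg per year
    # growth of genetic BP effects per year of age past 17 (fractional);
    # > 0 makes high-PRS individuals progress faster, the pattern seen in
    # longitudinal cohorts of young adults; 0 keeps effects age-constant
    age_amplification = 0,
    sex_effect_sbp = 3, bmi_effect_sbp = 0.4, smoke_effect_sbp = 2,
    n_sites = 4L,
    treat_prob = 0.5,        # P(treated | hypertensive by BP at/ before visit)
    selfreport_prob = 0.9,   # P(self-report | treated)
    n_visits = 2L,
    visit_spacing = 5,       # years between exams
    progression_drift = 3,   # mmHg SBP added per follow-up visit
    # discovery GWAS
    discovery_n = c(SBP = 318492, DBP = 318891, HTN = 451894),
    htn_case_fraction = 126196 / 451894,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop_config("unknown sim_config fields: ", paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(cfg, over)
  stopifnot(all(cfg$fst >= 0), all(cfg$fst < 0.5),
            cfg$causal_fraction > 0, cfg$causal_fraction <= 1,
            all(abs(rowSums(cfg$admixture) - 1) < 1e-8),
            !is.null(cfg$seed))
  ev <- eigen(cfg$effect_cor, symmetric = TRUE, only.values = TRUE)$values
  stopifnot(all(ev > -1e-8))
  structure(cfg, class = c("htn_sim_config", "list"))
}

# LD-block index per variant (shared by frequency and genotype simulation)
block_assignment <- function(cfg) {
  sort(rep_len(seq_len(cfg$n_ld_blocks), cfg$n_variants))
}

#' Simulate ancestry-specific allele frequencies (Balding-Nichols)
#'
#' Ancestral frequencies are drawn per LD block (uniform on `freq_range`)
#' with a small per-variant jitter — variants sharing a block arise from a
#' shared genealogy and have similar frequencies, which is what makes
#' within-block dosage LD realistic.  Each ancestral population's
#' frequency is then Beta-distributed around the ancestral value with
#' variance `F * p * (1 - p)` (parameters `p(1-F)/F`, `(1-p)(1-F)/F`);
#' `F = 0` copies the ancestral frequency exactly.
#'
#' @param cfg an `htn_sim_config`.
#' @return list `ancestral` (length `n_variants`) and `by_pop` (matrix
#'   variants x ancestral populations).
#' @export
simulate_frequencies <- function(cfg) {
  stopifnot(inherits(cfg, "htn_sim_config"))
  with_seed(seed_stream(cfg$seed, "frequencies"), {
    m <- cfg$n_variants
    blocks <- block_assignment(cfg)
    p_block <- runif(cfg$n_ld_blocks, cfg$freq_range[1], cfg$freq_range[2])
    p <- p_block[blocks] + runif(m, -0.05, 0.05)
    p <- pmin(pmax(p, cfg$freq_range[1]), cfg$freq_range[2])
    by_pop <- vapply(names(cfg$fst), function(pop) {
      f <- cfg$fst[[pop]]
      if (f == 0) return(p)
      q <- rbeta(m, p * (1 - f) / f, (1 - p) * (1 - f) / f)
      pmin(pmax(q, 1e-4), 1 - 1e-4)
    }, numeric(m))
    list(ancestral = p, by_pop = by_pop)
  })
}

# One haplotype per call: latent AR(1) Gaussian within LD blocks thresholded
# at the per-sample allele frequency.  `rho` is the target *allele*
# correlation between adjacent variants; thresholding attenuates a latent
# correlation r to about (2/pi) asin(r), so the latent AR(1) parameter is
# the tetrachoric inverse sin(pi/2 * rho).
latent_haplotypes <- function(n, m, blocks, rho) {
  rho <- sin(pi / 2 * min(rho, 0.999))
  z <- matrix(rnorm(n * m), n, m)
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    if (length(idx) < 2L) next
    for (j in 2:length(idx)) {
      z[, idx[j]] <- rho * z[, idx[j - 1]] +
        sqrt(1 - rho^2) * z[, idx[j]]
    }
  }
  z
}

#' Simulate genotypes, relatedness and admixture
#'
#' Per-sample ancestry proportions are drawn from a Dirichlet centered on
#' the background group's mixing weights; per-sample allele frequencies
#' are the admixture-weighted ancestral-population frequencies.  Two
#' latent-Gaussian haplotypes per sample, with AR(1) correlation inside LD
#' blocks, are thresholded at those frequencies and summed to Hardy-
#' Weinberg dosages, giving controllable LD.  A configured fraction of
#' samples is arranged into sibships that draw their haplotypes from shared
#' parental haplotypes; sibling pairs appear as kinship edges with
#' coefficient 0.25.
#'
#' @param cfg an `htn_sim_config`.
#' @param freqs output of [simulate_frequencies()].
#' @return list `geno` (`htn_geno`), `kinship` (`htn_kinship`),
#'   `admixture` (matrix samples x ancestral populations), `group`
#'   (background label per sample), `blocks` (LD block index per variant).
#' @export
simulate_genotypes <- function(cfg, freqs) {
  stopifnot(inherits(cfg, "htn_sim_config"))
  with_seed(seed_stream(cfg$seed, "genotypes"), {
    n <- sum(cfg$n_samples)
    m <- cfg$n_variants
    group <- rep(names(cfg$n_samples), cfg$n_samples)
    ids <- sprintf("S%05d", seq_len(n))
    pops <- colnames(cfg$admixture)

    # Dirichlet draw around the group's mixing weights (concentration 50
    # keeps most individuals near their group's typical admixture)
    conc <- 50
    adm <- t(vapply(group, function(g) {
      a <- cfg$admixture[g, ] * conc + 1e-3
      x <- vapply(a, function(ai) stats::rgamma(1, shape = ai), 0)
      x / sum(x)
    }, numeric(length(pops))))
    dimnames(adm) <- list(ids, pops)

    pmat <- adm %*% t(freqs$by_pop) # n x m per-sample frequencies

    blocks <- block_assignment(cfg)

    # sibships: consecutive samples grouped within background groups
    n_fam_samples <- floor(cfg$family_fraction * n)
    sib <- cfg$sibship_size
    n_fams <- n_fam_samples %/% sib
    fam_of <- rep(NA_integer_, n)
    if (n_fams > 0) {
      members <- sample.int(n, n_fams * sib)
      fam_of[members] <- rep(seq_len(n_fams), each = sib)
    }

    thresh <- qnorm(pmat) # allele = 1 iff latent < qnorm(p_i)

    draw_pair <- function(rows) {
      # two independent haplotype latents for the given sample rows
      list(latent_haplotypes(length(rows), m, blocks, cfg$ld_rho),
           latent_haplotypes(length(rows), m, blocks, cfg$ld_rho))
    }

    dos <- matrix(0, n, m)
    solo <- which(is.na(fam_of))
    if (length(solo)) {
      hp <- draw_pair(solo)
      dos[solo, ] <- (hp[[1]] < thresh[solo, , drop = FALSE]) +
        (hp[[2]] < thresh[solo, , drop = FALSE])
    }
    edges <- list()
    if (n_fams > 0) {
      for (f in seq_len(n_fams)) {
        rows <- which(fam_of == f)
        # four parental haplotypes shared by the sibship; each child
        # receives one haplotype from each parent (whole-genome
        # transmission keeps within-block LD intact)
        par1 <- draw_pair(rep(rows[1], 2))
        par2 <- draw_pair(rep(rows[1], 2))
        for (i in seq_along(rows)) {
          h1 <- if (runif(1) < 0.5) par1[[1]][1, ] else par1[[2]][1, ]
          h2 <- if (runif(1) < 0.5) par2[[1]][1, ] else par2[[2]][1, ]
          dos[rows[i], ] <- (h1 < thresh[rows[i], ]) +
            (h2 < thresh[rows[i], ])
        }
        prs_ <- t(utils::combn(rows, 2))
        edges[[f]] <- data.frame(id1 = ids[prs_[, 1]], id2 = ids[prs_[, 2]],
                                 kin = 0.25)
      }
    }
    kin_pairs <- if (length(edges)) do.call(rbind, edges) else NULL

    variants <- data.frame(
      chrom = paste0("chr", ((blocks - 1) %% 22) + 1),
      pos = NA_integer_, ea = "A", oa = "G",
      stringsAsFactors = FALSE
    )
    # positions: blocks laid down consecutively, 5 kb between variants
    # within a block, 2 Mb between blocks on the same chromosome
    within <- stats::ave(seq_len(m), blocks, FUN = seq_along)
    block_on_chrom <- stats::ave(blocks, variants$chrom,
                                 FUN = function(b) match(b, unique(b)))
    variants$pos <- as.integer(block_on_chrom * 2e6 + within * 5000)

    geno <- new_geno(ids, variants, dos)
    kin <- kinship_graph(kin_pairs, ids)
    list(geno = geno, kinship = kin, admixture = adm, group = group,
         blocks = blocks)
  })
}

#' Draw causal variants and correlated per-trait effect sizes
#'
#' A `causal_fraction` of variants is causal; their per-allele effects on
#' SBP (mmHg), DBP (mmHg) and HTN liability (log-odds) are drawn from a
#' trivariate normal with the configured per-trait SDs and cross-trait
#' correlation.
#'
#' @param cfg an `htn_sim_config`.
#' @param geno `htn_geno` (defines the variant set).
#' @return list of class `htn_truth`: `causal` (variant keys), `betas`
#'   (matrix causal variants x traits), per-trait named full-length weight
#'   vectors `w_sbp`, `w_dbp`, `w_htn`.
#' @export
simulate_effects <- function(cfg, geno) {
  with_seed(seed_stream(cfg$seed, "effects"), {
    m <- nrow(geno$variants)
    n_causal <- max(1L, round(cfg$causal_fraction * m))
    causal <- sort(sample.int(m, n_causal))
    sds <- cfg$effect_sd[c("SBP", "DBP", "HTN")]
    Sigma <- diag(sds) %*% cfg$effect_cor %*% diag(sds)
    # Cholesky when positive definite; eigen square root tolerates zero
    # effect SDs (singular Sigma)
    L <- tryCatch(chol(Sigma), error = function(e) {
      ev <- eigen(Sigma, symmetric = TRUE)
      ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 3) %*% t(ev$vectors)
    })
    betas <- matrix(rnorm(n_causal * 3), n_causal, 3) %*% L
    colnames(betas) <- c("SBP", "DBP", "HTN")
    floors <- cfg$effect_floor[colnames(betas)]
    for (j in seq_len(ncol(betas))) {
      if (floors[j] > 0) {
        betas[, j] <- sign(betas[, j]) *
          pmax(abs(betas[, j]), floors[j])
      }
    }
    keys <- geno$variants$key
    w <- function(tr) {
      out <- setNames(numeric(m), keys)
      out[causal] <- betas[, tr]
      out
    }
    structure(list(causal = keys[causal], betas = betas,
                   w_sbp = w("SBP"), w_dbp = w("DBP"), w_htn = w("HTN")),
              class = "htn_truth")
  })
}

#' Simulate repeated-visit blood-pressure phenotypes and covariates
#'
#' SBP at a visit is `mean + genetic value + covariate effects + ancestry
#' shift + age effect + progression drift + noise`; DBP is analogous with
#' correlated noise.  Treatment is drawn with the configured probability
#' among individuals hypertensive (by BP or prior status) at the visit and
#' is absorbing across visits; self-reported diagnosis follows treatment.
#' Hypertension status is derived only through [bp_category()] — the
#' generator has no second definition of hypertension.
#'
#' @param cfg an `htn_sim_config`.
#' @param gv_sbp,gv_dbp per-sample genetic values (weighted dosage sums)
#'   for SBP and DBP, e.g. `as.numeric(geno$dosages %*% truth$w_sbp)`.
#' @param admixture samples x ancestral-populations proportion matrix.
#' @param group background-group label per sample.
#' @param sample_ids sample identifiers.
#' @param n_visits,age_mean,age_sd,age_range optional overrides of the
#'   config (used for the six-visit young-adult design).
#' @param stream seed-stream tag; override when simulating a second,
#'   independent phenotype realization for the same genotypes.
#' @return list `visits` (long data frame: `sample_id`, `visit`, `age`,
#'   `time`, `sbp`, `dbp`, `treated`, `self_report`, `htn`, `bp_cat`),
#'   `covars` (per-sample data frame: `sex`, `age`, `bmi`, `smoking`,
#'   `site`, `group`, PCs).
#' @export
simulate_phenotypes <- function(cfg, gv_sbp, gv_dbp, admixture, group,
                                sample_ids, n_visits = NULL,
                                age_mean = NULL, age_sd = NULL,
                                age_range = NULL, stream = "phenotypes") {
  n <- length(sample_ids)
  stopifnot(length(gv_sbp) == n, length(gv_dbp) == n)
  n_visits <- n_visits %||% cfg$n_visits
  age_mean <- age_mean %||% cfg$age_mean
  age_sd <- age_sd %||% cfg$age_sd
  age_range <- age_range %||% cfg$age_range
  with_seed(seed_stream(cfg$seed, stream), {
    sex <- rbinom(n, 1, 0.5) # 1 = male
    bmi <- rnorm(n, 28, 5)
    smoking <- rbinom(n, 1, 0.2)
    site <- sample(paste0("site", seq_len(cfg$n_sites)), n, replace = TRUE)
    age0 <- pmin(pmax(rnorm(n, age_mean, age_sd), age_range[1]),
                 age_range[2])
    shift <- as.numeric(admixture %*%
                          cfg$ancestry_shift_sbp[colnames(admixture)])
    base_sbp <- cfg$sbp_mean + shift +
      cfg$sex_effect_sbp * sex + cfg$bmi_effect_sbp * (bmi - 28) +
      cfg$smoke_effect_sbp * smoking
    base_dbp <- cfg$dbp_mean + 0.5 * shift +
      0.5 * cfg$sex_effect_sbp * sex + 0.25 * cfg$bmi_effect_sbp * (bmi - 28)
    amp <- function(age) pmax(1 + cfg$age_amplification * (age - 17), 0.2)
    track <- cfg$bp_track
    if (track > 0) {
      u1 <- rnorm(n) * sqrt(track)
      u2 <- cfg$bp_cor * u1 + sqrt(1 - cfg$bp_cor^2) * rnorm(n) * sqrt(track)
      base_sbp <- base_sbp + cfg$resid_sd[["SBP"]] * u1
      base_dbp <- base_dbp + cfg$resid_sd[["DBP"]] * u2
    }
    visit_sd_scale <- sqrt(1 - track)

    treated_prev <- rep(FALSE, n)
    htn_prev <- rep(FALSE, n)
    rows <- vector("list", n_visits)
    for (v in seq_len(n_visits)) {
      t_v <- (v - 1) * cfg$visit_spacing
      age_v <- age0 + t_v
      e1 <- rnorm(n)
      e2 <- cfg$bp_cor * e1 + sqrt(1 - cfg$bp_cor^2) * rnorm(n)
      sbp <- base_sbp + gv_sbp * amp(age_v) +
        cfg$age_slope_sbp * (age_v - age_mean) +
        cfg$progression_drift * (v - 1) +
        cfg$resid_sd[["SBP"]] * visit_sd_scale * e1
      dbp <- base_dbp + gv_dbp * amp(age_v) +
        cfg$age_slope_dbp * (age_v - age_mean) +
        0.5 * cfg$progression_drift * (v - 1) +
        cfg$resid_sd[["DBP"]] * visit_sd_scale * e2
      dbp <- pmin(dbp, sbp - 10) # keep sbp > dbp
      htn_bp <- sbp >= 130 | dbp >= 80
      eligible <- (htn_bp | htn_prev) & !treated_prev
      treated <- treated_prev | (eligible & runif(n) < cfg$treat_prob)
      self_report <- treated & (runif(n) < cfg$selfreport_prob)
      cat_v <- bp_category(sbp, dbp, treated, self_report)
      rows[[v]] <- data.frame(
        sample_id = sample_ids, visit = v, age = age_v, time = t_v,
        sbp = sbp, dbp = dbp, treated = treated,
        self_report = self_report,
        bp_cat = as.character(cat_v),
        htn = as.integer(cat_v == "HYPERTENSION"),
        stringsAsFactors = FALSE
      )
      treated_prev <- treated
      htn_prev <- htn_prev | cat_v == "HYPERTENSION"
    }
    visits <- do.call(rbind, rows)
    visits <- visits[order(visits$sample_id, visits$visit), ]
    rownames(visits) <- NULL

    # ancestry PCs: centered admixture proportions, orthogonalized; stands
    # in for computed genetic PCs (PC estimation is out of scope)
    A <- scale(admixture, scale = FALSE)
    qr_ <- qr(A)
    pcs <- qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]
    if (ncol(pcs) > 0) colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
    covars <- data.frame(sample_id = sample_ids, sex = sex, age = age0,
                         bmi = bmi, smoking = smoking, site = site,
                         group = group, stringsAsFactors = FALSE)
    covars <- cbind(covars, as.data.frame(pcs))
    list(visits = visits, covars = covars)
  })
}

#' Simulate discovery-GWAS summary statistics
#'
#' For each variant the estimated effect is `beta_hat ~ N(beta_true, se^2)`
#' with `se = sd_trait / sqrt(2 n f (1 - f))` for the continuous BP traits
#' and `se = 1 / sqrt(2 n f (1 - f) phi (1 - phi))` for hypertension with
#' case fraction `phi`; the p-value is the two-sided normal tail of
#' `beta_hat / se`.  Discovery allele frequencies are the ancestral
#' frequencies (the discovery GWAS emulates a large external multi-ethnic
#' sample).
#'
#' @param cfg an `htn_sim_config`.
#' @param truth `htn_truth` from [simulate_effects()].
#' @param geno `htn_geno` (variant index).
#' @param freqs output of [simulate_frequencies()].
#' @param trait `"SBP"`, `"DBP"` or `"HTN"`.
#' @return an `htn_sumstats`.
#' @export
simulate_sumstats <- function(cfg, truth, geno, freqs, trait) {
  stopifnot(trait %in% c("SBP", "DBP", "HTN"))
  n_disc <- cfg$discovery_n[[trait]]
  stopifnot(n_disc >= 1000)
  with_seed(seed_stream(cfg$seed, paste0("sumstats:", trait)), {
    f <- freqs$ancestral
    w <- switch(trait, SBP = truth$w_sbp, DBP = truth$w_dbp,
                HTN = truth$w_htn)
    se <- if (trait == "HTN") {
      phi <- cfg$htn_case_fraction
      1 / sqrt(2 * n_disc * f * (1 - f) * phi * (1 - phi))
    } else {
      cfg$resid_sd[[trait]] / sqrt(2 * n_disc * f * (1 - f))
    }
    beta_hat <- rnorm(length(f), mean = unname(w), sd = se)
    p <- 2 * pnorm(-abs(beta_hat / se))
    p <- pmax(p, .Machine$double.xmin)
    df <- data.frame(
      chrom = geno$variants$chrom, pos = geno$variants$pos,
      ea = geno$variants$ea, oa = geno$variants$oa,
      beta = beta_hat, se = se, p = p, eaf = f, n = n_disc,
      stringsAsFactors = FALSE
    )
    new_sumstats(df, trait)
  })
}

#' Simulate a complete cohort: genotypes, phenotypes, summary statistics
#'
#' Convenience wrapper running [simulate_frequencies()],
#' [simulate_genotypes()], [simulate_effects()], [simulate_phenotypes()]
#' and [simulate_sumstats()] for the three traits.  Identical
#' configurations (including the seed) reproduce identical cohorts.
#'
#' @param cfg an `htn_sim_config`.
#' @return list of class `htn_cohort`: `geno`, `kinship`, `admixture`,
#'   `group`, `visits`, `covars`, `sumstats` (list SBP/DBP/HTN), `truth`,
#'   `freqs`, `cfg`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  freqs <- simulate_frequencies(cfg)
  gsim <- simulate_genotypes(cfg, freqs)
  truth <- simulate_effects(cfg, gsim$geno)
  gv_sbp <- as.numeric(gsim$geno$dosages %*% truth$w_sbp)
  gv_dbp <- as.numeric(gsim$geno$dosages %*% truth$w_dbp)
  phen <- simulate_phenotypes(cfg, gv_sbp, gv_dbp, gsim$admixture,
                              gsim$group, gsim$geno$sample_ids)
  ss <- lapply(c(SBP = "SBP", DBP = "DBP", HTN = "HTN"), function(tr) {
    simulate_sumstats(cfg, truth, gsim$geno, freqs, tr)
  })
  structure(list(geno = gsim$geno, kinship = gsim$kinship,
                 admixture = gsim$admixture, group = gsim$group,
                 visits = phen$visits, covars = phen$covars,
                 sumstats = ss, truth = truth, freqs = freqs, cfg = cfg),
            class = "htn_cohort")
}

#' Reshape a long visit table to the two-visit wide format
#'
#' @param visits long visit table from [simulate_phenotypes()].
#' @param v1,v2 visit numbers to use as baseline and follow-up.
#' @return wide data frame with the columns expected by
#'   [incident_cohort()] and [longitudinal_category()].
#' @export
visits_wide <- function(visits, v1 = 1L, v2 = 2L) {
  a <- visits[visits$visit == v1, ]
  b <- visits[visits$visit == v2, ]
  common <- intersect(a$sample_id, b$sample_id)
  a <- a[match(common, a$sample_id), ]
  b <- b[match(common, b$sample_id), ]
  data.frame(sample_id = common,
             sbp1 = a$sbp, dbp1 = a$dbp, treated1 = a$treated,
             self_report1 = a$self_report, time1 = a$time, age1 = a$age,
             sbp2 = b$sbp, dbp2 = b$dbp, treated2 = b$treated,
             self_report2 = b$self_report, time2 = b$time, age2 = b$age,
             stringsAsFactors = FALSE)
}

#' Simulate a binary outcome from a standardized score
#'
#' Draws `outcome ~ Bernoulli(plogis(alpha + beta * z))` where `z` is the
#' standardized score and `alpha` is chosen so the marginal prevalence is
#' approximately `prevalence`.  Used for effect-size calibration
#' experiments where the generating per-SD log-OR must be known exactly.
#'
#' @param z standardized score vector.
#' @param beta generating log-OR per 1 SD.
#' @param prevalence target marginal prevalence.
#' @param seed integer seed.
#' @return integer 0/1 outcome vector.
#' @export
simulate_logistic_outcome <- function(z, beta, prevalence = 0.4,
                                      seed = 1L) {
  alpha <- uniroot(function(a) mean(plogis(a + beta * z)) - prevalence,
                   interval = c(-20, 20))$root
  with_seed(seed_stream(seed, "logistic_outcome"), {
    rbinom(length(z), 1, plogis(alpha + beta * z))
  })
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' Emits the dosage TSV, three summary-statistics TSVs, the phenotype CSV,
#' the kinship TSV and a ground-truth TSV under `dir`.
#'
#' @param cohort an `htn_cohort`.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genotypes = file.path(dir, "dosages.tsv"),
    phenotypes = file.path(dir, "phenotypes.csv"),
    covariates = file.path(dir, "covariates.csv"),
    kinship = file.path(dir, "kinship.tsv"),
    truth = file.path(dir, "ground_truth.tsv"),
    sumstats_sbp = file.path(dir, "sumstats_sbp.tsv"),
    sumstats_dbp = file.path(dir, "sumstats_dbp.tsv"),
    sumstats_htn = file.path(dir, "sumstats_htn.tsv")
  )
  dos <- data.frame(sample_id = cohort$geno$sample_ids,
                    as.data.frame(cohort$geno$dosages),
                    check.names = FALSE)
  data.table::fwrite(dos, paths[["genotypes"]], sep = "\t")
  data.table::fwrite(cohort$visits, paths[["phenotypes"]])
  data.table::fwrite(cohort$covars, paths[["covariates"]])
  data.table::fwrite(cohort$kinship$edges, paths[["kinship"]], sep = "\t")
  truth_df <- data.frame(key = names(cohort$truth$w_sbp),
                         beta_sbp = unname(cohort$truth$w_sbp),
                         beta_dbp = unname(cohort$truth$w_dbp),
                         beta_htn = unname(cohort$truth$w_htn))
  data.table::fwrite(truth_df, paths[["truth"]], sep = "\t")
  for (tr in c("SBP", "DBP", "HTN")) {
    ss <- cohort$sumstats[[tr]]
    out <- data.frame(CHR = ss$chrom, POS = ss$pos, EA = ss$ea, OA = ss$oa,
                      BETA = ss$beta, SE = ss$se, P = ss$p, EAF = ss$eaf,
                      N = ss$n)
    data.table::fwrite(out, paths[[paste0("sumstats_", tolower(tr))]],
                       sep = "\t")
  }
  invisible(paths)
}
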