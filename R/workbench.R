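# Orchestration: staged workflow (train -> select -> evaluate ->
# trajectories) with deterministic seeding and a report manifest.

#' Default pipeline configuration
#'
#' @param ... named overrides.  Principal fields: `seed` (top-level seed),
#'   `sim` (list of [sim_config()] overrides, or `NULL` to read inputs
#'   from files named in `inputs`), `stage_fractions` (target fractions of
#'   samples in the training / evaluation / trajectory stages), `maf`
#'   (summary-statistics MAF filter), `criterion` (`"cv"`, `"pval"` or
#'   `"gws"`), `folds` (CV folds), `grid` (`"default"` or a data frame),
#'   `use_kinship` (kinship random effect in stage-2 models),
#'   `trajectory_visits` (exam count for the stage-3 young-adult design),
#'   `out_dir` (artifact directory).
#' @return list of class `htn_pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    sim = list(),
    inputs = NULL,
    stage_fractions = c(stage1 = 0.20, stage2 = 0.60, stage3 = 0.20),
    maf = 0.01,
    criterion = "cv",
    folds = 5L,
    grid = "default",
    use_kinship = FALSE,
    trajectory_visits = 6L,
    # young-adult follow-up design: 6 exams over 15 years starting in the
    # mid-20s; genetic effects amplified with age so high-PRS strata
    # progress faster (the separation seen in longitudinal cohorts)
    trajectory_age = list(mean = 25, sd = 4, range = c(17, 35),
                          spacing = 3, amplification = 0.035,
                          sbp_mean = 108, dbp_mean = 68,
                          progression_drift = 0, treat_prob = 0.3,
                          bp_track = 0.55),
    ages_grid = 17:50,
    out_dir = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop_config("unknown pipeline_config fields: ",
                paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(cfg, over)
  stopifnot(abs(sum(cfg$stage_fractions) - 1) < 1e-8,
            cfg$criterion %in% c("cv", "pval", "gws"),
            cfg$folds >= 2L)
  structure(cfg, class = c("htn_pipeline_config", "list"))
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path config file (`.yaml`/`.yml` needs the yaml package;
#'   `.json` uses jsonlite).
#' @return an `htn_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_config("YAML config requires the yaml package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$stage_fractions)) {
    raw$stage_fractions <- unlist(raw$stage_fractions)
  }
  do.call(pipeline_config, raw)
}

#' Plan the stage split: kinship-disjoint training/evaluation/trajectory sets
#'
#' Kinship components are assigned whole to stages (largest first, to the
#' stage furthest below its target fraction), so no kinship edge connects
#' stage-1 to stage-2 samples and the three sets are pairwise disjoint.
#' Both properties are verified before any model is fitted.
#'
#' @param samples character vector of sample ids.
#' @param kinship an `htn_kinship`.
#' @param fractions named target fractions summing to 1.
#' @param seed integer seed for component tie-breaking.
#' @return list of class `htn_stage_plan` with one character vector per
#'   stage.
#' @export
stage_plan <- function(samples, kinship,
                       fractions = c(stage1 = 0.20, stage2 = 0.60,
                                     stage3 = 0.20),
                       seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  sub <- kinship_graph(
    kinship$edges[kinship$edges$id1 %in% samples &
                    kinship$edges$id2 %in% samples, , drop = FALSE],
    samples
  )
  comps <- kinship_components(sub)
  sizes <- lengths(comps)
  ord <- with_seed(seed_stream(seed, "stage_plan"),
                   order(-sizes, sample.int(length(comps))))
  n <- length(samples)
  target <- fractions * n
  got <- setNames(numeric(length(fractions)), names(fractions))
  plan <- lapply(fractions, function(...) character(0))
  for (i in ord) {
    deficit <- (target - got) / pmax(target, 1)
    s <- names(which.max(deficit))
    plan[[s]] <- c(plan[[s]], comps[[i]])
    got[s] <- got[s] + sizes[i]
  }
  validate_stage_plan(plan, sub)
  structure(plan, class = "htn_stage_plan")
}

validate_stage_plan <- function(plan, kinship) {
  ids <- unlist(plan, use.names = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop_config("stage sets overlap: ", paste(head(dup, 5), collapse = ", "))
  }
  stage_of <- rep(names(plan), lengths(plan))
  names(stage_of) <- ids
  e <- kinship$edges
  cross <- stage_of[e$id1] != stage_of[e$id2]
  if (any(cross, na.rm = TRUE)) {
    bad <- e[which(cross)[1], ]
    stop_config("kinship edge crosses stages: ", bad$id1, " - ", bad$id2)
  }
  invisible(TRUE)
}

# Build candidates + full-cohort-standardized scores for one trait over
# the grid; clumping runs once per (r2, window) pair.
build_candidates <- function(ss, geno, grid) {
  clump_pairs <- unique(grid[, c("r2_max", "window_kb")])
  clumps <- list()
  for (i in seq_len(nrow(clump_pairs))) {
    key <- paste(clump_pairs$r2_max[i], clump_pairs$window_kb[i])
    clumps[[key]] <- clump(ss, geno, clump_pairs$r2_max[i],
                           clump_pairs$window_kb[i])
  }
  lapply(seq_len(nrow(grid)), function(i) {
    key <- paste(grid$r2_max[i], grid$window_kb[i])
    prs_candidate(ss, geno, as.list(grid[i, ]), retained = clumps[[key]])
  })
}

# Score a candidate on the full cohort, standardize with full-cohort
# constants; returns list(scores = htn_prs, mean, sd).
standardized_scores <- function(cand, geno) {
  prs <- score_prs(geno, cand$weights)
  m <- mean(prs$raw)
  s <- sd(prs$raw)
  if (!is.finite(s) || s == 0) {
    # degenerate candidate: keep raw zeros, flag via sd = NA
    prs$standardized <- prs$raw * 0
    attr(prs, "standardization") <- list(mean = m, sd = NA_real_,
                                         source = "full-cohort")
    return(prs)
  }
  standardize_prs(prs, m, s, "full-cohort")
}

subset_prs <- function(prs, ids) {
  out <- prs[match(ids, prs$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(prs)
  attr(out, "standardization") <- attr(prs, "standardization")
  out
}

#' Run the staged PRS workflow end to end
#'
#' Simulates (or loads) a cohort; splits it into kinship-disjoint stages;
#' harmonizes and MAF-filters the three traits' summary statistics;
#' builds the candidate grid; selects tuning parameters per trait on the
#' stage-1 (training) samples by the configured criterion; combines the
#' selected trait PRS into the HTN-PRS via PRSsum; evaluates prevalent and
#' incident hypertension associations, AUC on unrelated individuals,
#' background-group heterogeneity and decile trends on the stage-2
#' samples; and fits PRS-stratum age trajectories on the stage-3 samples.
#' Artifacts are written under `config$out_dir` (when set) together with a
#' manifest of input hashes, seeds and the package version.
#'
#' @param config an `htn_pipeline_config`, or a path to a YAML/JSON file.
#' @return list of class `htn_report`: `selection` (per trait),
#'   `htn_prs`, `associations`, `heterogeneity`, `decile_trend`,
#'   `trajectories`, `stage_plan`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "htn_pipeline_config"))
  seed <- config$seed

  if (!is.null(config$inputs)) {
    cohort <- load_cohort(config$inputs)
  } else {
    sim_over <- config$sim %||% list()
    sim_over$seed <- sim_over$seed %||% seed_stream(seed, "simulate")
    cohort <- simulate_cohort(do.call(sim_config, sim_over))
  }
  geno <- cohort$geno
  kin <- cohort$kinship

  plan <- stage_plan(geno$sample_ids, kin, config$stage_fractions, seed)
  hlog(op = "stage_plan", stage1 = length(plan$stage1),
       stage2 = length(plan$stage2), stage3 = length(plan$stage3))

  freqs_target <- allele_freq(geno)
  grid <- if (identical(config$grid, "default")) default_grid() else
    as.data.frame(config$grid)

  wide <- visits_wide(cohort$visits)
  base_cat <- bp_category(wide$sbp1, wide$dbp1, wide$treated1,
                          wide$self_report1)
  htn_base <- setNames(as.integer(base_cat == "HYPERTENSION"),
                       wide$sample_id)

  covar_cols <- c("sex", "age", "bmi", "smoking", "site", "group",
                  grep("^PC", names(cohort$covars), value = TRUE))
  covars_of <- function(ids, incident_time = NULL) {
    cv <- cohort$covars[match(ids, cohort$covars$sample_id), covar_cols,
                        drop = FALSE]
    cv$age2 <- cv$age^2
    cv$site <- factor(cv$site)
    cv$group <- factor(cv$group)
    if (!is.null(incident_time)) cv$time_between <- incident_time
    rownames(cv) <- NULL
    cv
  }

  # --- stage 1: harmonize, build grid, select per trait ------------------
  idx1 <- match(plan$stage1, geno$sample_ids)
  folds <- split_kinship_folds(plan$stage1, kin, config$folds, seed)
  y1 <- htn_base[plan$stage1]
  cv1 <- covars_of(plan$stage1)

  selection <- list()
  selected_scores <- list()
  for (tr in c("SBP", "DBP", "HTN")) {
    ss <- cohort$sumstats[[tr]]
    ss <- filter_maf(ss, freqs_target, config$maf)
    ss <- harmonize_alleles(ss, geno$variants)
    cands <- build_candidates(ss, geno, grid)
    scores_full <- lapply(cands, standardized_scores, geno = geno)
    scores1 <- lapply(scores_full, subset_prs, ids = plan$stage1)
    sel <- switch(config$criterion,
      cv = select_cv_prs(cands, scores1, y1, cv1, folds[plan$stage1]),
      pval = select_pval_prs(cands, scores1, y1, cv1),
      gws = {
        cand <- gws_prs(ss, geno)
        structure(list(criterion = "GWS", chosen = cand$params,
                       chosen_index = 1L,
                       table = candidate_table(list(cand))),
                  class = "htn_selection")
      }
    )
    chosen_score <- if (config$criterion == "gws") {
      standardized_scores(gws_prs(ss, geno), geno)
    } else {
      scores_full[[sel$chosen_index]]
    }
    selection[[tr]] <- sel
    selected_scores[[tr]] <- chosen_score
    hlog(op = "select", trait = tr, criterion = config$criterion,
         p_threshold = sel$chosen$p_threshold, r2 = sel$chosen$r2_max,
         window_kb = sel$chosen$window_kb)
  }

  # --- PRSsum: the HTN-PRS ----------------------------------------------
  htn_prs <- prssum(selected_scores)

  # --- stage 2: association suite ---------------------------------------
  ids2 <- plan$stage2
  prs2 <- subset_prs(htn_prs, ids2)
  unrel <- unrelated_set(kin, seed)
  wide2 <- wide[match(ids2, wide$sample_id), ]

  assoc_one <- function(ids, outcome, covars, label) {
    prs_i <- subset_prs(htn_prs, ids)$standardized
    est <- fit_logistic(outcome, prs_i, covars,
                        kinship = if (config$use_kinship) kin else NULL,
                        sample_ids = ids)
    auc_ids <- intersect(ids, unrel)
    sel <- ids %in% auc_ids
    auc <- if (length(unique(outcome[sel])) == 2L) {
      compute_auc(outcome[sel], prs_i[sel])
    } else NA_real_
    data.frame(analysis = label, n = est$n, beta = est$beta, se = est$se,
               or = est$or, ci_low = est$ci_low, ci_high = est$ci_high,
               pvalue = est$pvalue, auc = auc)
  }

  associations <- assoc_one(ids2, htn_base[ids2], covars_of(ids2),
                            "prevalent")
  inc_n <- incident_cohort(wide2, "NORMAL")
  inc_e <- incident_cohort(wide2, "ELEVATED")
  for (inc in list(list(d = inc_n, lab = "incident-normal"),
                   list(d = inc_e, lab = "incident-elevated"))) {
    if (nrow(inc$d) >= 50 && length(unique(inc$d$outcome)) == 2L) {
      associations <- rbind(
        associations,
        assoc_one(inc$d$sample_id, inc$d$outcome,
                  covars_of(inc$d$sample_id, inc$d$time_between), inc$lab)
      )
    }
  }

  # background-group heterogeneity (prevalent analysis)
  grp2 <- factor(cohort$covars$group[match(ids2, cohort$covars$sample_id)])
  het <- tryCatch({
    cv2 <- covars_of(ids2)
    cv2$group <- NULL
    se_ <- strata_effects(htn_base[ids2], prs2$standardized, grp2, cv2)
    q <- cochran_q(se_$betas, se_$cov)
    list(betas = se_$betas, cov = se_$cov, Q = q$Q, df = q$df,
         pvalue = q$pvalue)
  }, error = function(e) {
    hlog(op = "heterogeneity", error = conditionMessage(e))
    NULL
  })

  long_cat <- longitudinal_category(
    bp_category(wide2$sbp1, wide2$dbp1, wide2$treated1, wide2$self_report1),
    bp_category(wide2$sbp2, wide2$dbp2, wide2$treated2, wide2$self_report2),
    wide2$treated1, wide2$treated2
  )
  dec_trend <- decile_trend(prs2$standardized, long_cat, seed)

  # --- stage 3: trajectories --------------------------------------------
  # needs simulation ground truth to draw the six-visit young-adult design
  trajectories <- NULL
  if (length(plan$stage3) >= 100 && !is.null(cohort$truth) &&
      !is.null(cohort$admixture)) {
    ids3 <- plan$stage3
    ta <- config$trajectory_age
    gv_sbp3 <- as.numeric(geno$dosages[ids3, ] %*% cohort$truth$w_sbp)
    gv_dbp3 <- as.numeric(geno$dosages[ids3, ] %*% cohort$truth$w_dbp)
    cfg3 <- cohort$cfg
    cfg3$visit_spacing <- ta$spacing %||% cfg3$visit_spacing
    cfg3$age_amplification <- ta$amplification %||% cfg3$age_amplification
    cfg3$sbp_mean <- ta$sbp_mean %||% cfg3$sbp_mean
    cfg3$dbp_mean <- ta$dbp_mean %||% cfg3$dbp_mean
    cfg3$progression_drift <- ta$progression_drift %||%
      cfg3$progression_drift
    cfg3$treat_prob <- ta$treat_prob %||% cfg3$treat_prob
    cfg3$bp_track <- ta$bp_track %||% cfg3$bp_track
    phen3 <- simulate_phenotypes(
      cfg3, gv_sbp3, gv_dbp3,
      cohort$admixture[ids3, , drop = FALSE], cohort$group[
        match(ids3, geno$sample_ids)], ids3,
      n_visits = config$trajectory_visits,
      age_mean = ta$mean, age_sd = ta$sd, age_range = ta$range,
      stream = "phenotypes:stage3"
    )
    prs3 <- subset_prs(htn_prs, ids3)
    strata3 <- prs_strata(prs3, seed = seed)
    pc_cols <- grep("^PC", names(phen3$covars), value = TRUE)
    vis3 <- merge(phen3$visits,
                  phen3$covars[, c("sample_id", "sex", pc_cols)],
                  by = "sample_id")
    trajectories <- lapply(seq_len(max(strata3)), function(s) {
      ids_s <- ids3[strata3 == s]
      d <- vis3[vis3$sample_id %in% ids_s, ]
      fit <- tryCatch(
        fit_trajectory(d, covars = c("sex", pc_cols)),
        error = function(e) NULL
      )
      if (is.null(fit)) return(NULL)
      curve <- or_by_age(fit, config$ages_grid)
      curve$stratum <- attr(strata3, "labels")[s]
      list(fit = fit, curve = curve)
    })
  }

  report <- structure(
    list(selection = selection, htn_prs = htn_prs,
         associations = associations, heterogeneity = het,
         decile_trend = dec_trend, trajectories = trajectories,
         stage_plan = plan, config = config),
    class = "htn_report"
  )
  if (!is.null(config$out_dir)) {
    report$manifest <- write_report(report, config$out_dir)
  } else {
    report$manifest <- report_manifest(report, paths = NULL)
  }
  report
}

report_tables <- function(report) {
  tabs <- list(associations = report$associations,
               decile_trend = report$decile_trend)
  for (tr in names(report$selection)) {
    tabs[[paste0("selection_", tolower(tr))]] <- report$selection[[tr]]$table
  }
  tabs$htn_prs <- as.data.frame(report$htn_prs)
  if (!is.null(report$trajectories)) {
    curves <- do.call(rbind, lapply(report$trajectories, function(x) {
      if (is.null(x)) NULL else x$curve
    }))
    if (!is.null(curves)) tabs$trajectory_curves <- curves
  }
  if (!is.null(report$heterogeneity)) {
    tabs$heterogeneity <- data.frame(
      stratum = names(report$heterogeneity$betas),
      beta = as.numeric(report$heterogeneity$betas),
      Q = report$heterogeneity$Q, df = report$heterogeneity$df,
      pvalue = report$heterogeneity$pvalue
    )
  }
  tabs
}

report_manifest <- function(report, paths) {
  manifest <- list(
    package_version = as.character(packageVersion("htnprs")),
    seed = report$config$seed,
    criterion = report$config$criterion,
    n_stage1 = length(report$stage_plan$stage1),
    n_stage2 = length(report$stage_plan$stage2),
    n_stage3 = length(report$stage_plan$stage3)
  )
  if (!is.null(paths)) {
    manifest$files <- lapply(paths, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    })
  } else {
    # hash the in-memory tables so determinism is checkable without I/O
    tabs <- report_tables(report)
    manifest$tables <- lapply(tabs, function(t) {
      tmp <- tempfile()
      on.exit(unlink(tmp))
      data.table::fwrite(as.data.frame(t), tmp, sep = "\t")
      unname(tools::md5sum(tmp))
    })
  }
  manifest
}

#' Write the report bundle and its manifest
#'
#' @param report an `htn_report`.
#' @param dir output directory.
#' @return the manifest list, invisibly written to `manifest.json`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- report_tables(report)
  paths <- character(0)
  for (nm in names(tabs)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    data.table::fwrite(as.data.frame(tabs[[nm]]), p, sep = "\t")
    paths[nm] <- p
  }
  manifest <- report_manifest(report, paths)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Load a cohort from files written by [write_cohort()]
#'
#' @param inputs named list/vector with paths `genotypes`, `phenotypes`,
#'   `kinship`, `sumstats_sbp`, `sumstats_dbp`, `sumstats_htn` (and
#'   optionally `truth`).
#' @return an `htn_cohort`-like list (without simulation ground truth
#'   unless provided).
#' @export
load_cohort <- function(inputs) {
  inputs <- as.list(inputs)
  need <- c("genotypes", "phenotypes", "kinship",
            "sumstats_sbp", "sumstats_dbp", "sumstats_htn")
  miss <- setdiff(need, names(inputs))
  if (length(miss)) {
    stop_config("missing input paths: ", paste(miss, collapse = ", "))
  }
  geno <- load_genotypes(inputs$genotypes)
  visits <- as.data.frame(data.table::fread(inputs$phenotypes))
  kin <- kinship_graph(inputs$kinship, geno$sample_ids)
  covars <- if (!is.null(inputs$covariates)) {
    as.data.frame(data.table::fread(inputs$covariates))
  } else NULL
  ss <- list(
    SBP = read_sumstats(inputs$sumstats_sbp, trait = "SBP"),
    DBP = read_sumstats(inputs$sumstats_dbp, trait = "DBP"),
    HTN = read_sumstats(inputs$sumstats_htn, trait = "HTN")
  )
  truth <- NULL
  if (!is.null(inputs$truth)) {
    td <- as.data.frame(data.table::fread(inputs$truth))
    truth <- structure(list(
      causal = td$key[td$beta_sbp != 0 | td$beta_dbp != 0 |
                        td$beta_htn != 0],
      w_sbp = setNames(td$beta_sbp, td$key),
      w_dbp = setNames(td$beta_dbp, td$key),
      w_htn = setNames(td$beta_htn, td$key)
    ), class = "htn_truth")
  }
  list(geno = geno, kinship = kin, visits = visits, covars = covars,
       sumstats = ss, truth = truth)
}
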