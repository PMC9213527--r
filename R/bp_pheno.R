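# Blood-pressure phenotyping: per-visit category, longitudinal two-visit
# category, and incident-analysis cohorts.
#
# Category precedence is HYPERTENSION > ELEVATED > NORMAL, resolving the
# overlapping printed boundaries (dbp = 80 is hypertensive; sbp = 120 with
# dbp < 80 untreated is elevated), following the ACC/AHA 2017 convention.

BP_LEVELS <- c("NORMAL", "ELEVATED", "HYPERTENSION")
LONG_LEVELS <- c("NEVER_HTN", "IMPROVED", "WORSENED", "HTN_BOTH",
                 "UNCLASSIFIED")

#' Per-visit blood-pressure category
#'
#' HYPERTENSION if `sbp >= 130` mmHg, or `dbp >= 80` mmHg, or self-reported
#' physician-diagnosed hypertension, or on antihypertensive treatment;
#' otherwise ELEVATED if `120 <= sbp <= 129`; otherwise NORMAL.
#' Vectorized over visits.
#'
#' @param sbp,dbp systolic/diastolic pressure, mmHg.
#' @param treated logical, on antihypertensive medication.
#' @param self_report_htn logical, self-reported physician diagnosis.
#' @return factor with levels `NORMAL`, `ELEVATED`, `HYPERTENSION`.
#' @export
bp_category <- function(sbp, dbp, treated = FALSE, self_report_htn = FALSE) {
  n <- length(sbp)
  treated <- rep_len(as.logical(treated), n)
  self_report_htn <- rep_len(as.logical(self_report_htn), n)
  out <- rep("NORMAL", n)
  out[sbp >= 120 & sbp <= 129] <- "ELEVATED"
  out[sbp >= 130 | dbp >= 80 | treated | self_report_htn] <- "HYPERTENSION"
  factor(out, levels = BP_LEVELS)
}

#' Longitudinal two-visit blood-pressure category
#'
#' Classifies a baseline/follow-up visit pair:
#' \describe{
#'   \item{HTN_BOTH}{hypertension (including treatment) at both visits;}
#'   \item{WORSENED}{category rank increased between visits;}
#'   \item{IMPROVED}{rank decreased and neither visit was treated;}
#'   \item{NEVER_HTN}{no hypertension at either visit and rank unchanged;}
#'   \item{UNCLASSIFIED}{rank decreased with treatment at a visit (treated
#'     baseline, untreated non-hypertensive follow-up): the published
#'     categories do not cover these records and they are excluded from
#'     tabulations rather than silently misclassified.}
#' }
#'
#' @param cat1,cat2 baseline and follow-up categories from [bp_category()].
#' @param treated1,treated2 treatment flags at each visit.
#' @return factor with levels `NEVER_HTN`, `IMPROVED`, `WORSENED`,
#'   `HTN_BOTH`, `UNCLASSIFIED`.
#' @export
longitudinal_category <- function(cat1, cat2, treated1 = FALSE,
                                  treated2 = FALSE) {
  r1 <- as.integer(factor(as.character(cat1), levels = BP_LEVELS))
  r2 <- as.integer(factor(as.character(cat2), levels = BP_LEVELS))
  n <- length(r1)
  treated1 <- rep_len(as.logical(treated1), n)
  treated2 <- rep_len(as.logical(treated2), n)
  out <- character(n)
  both_htn <- r1 == 3L & r2 == 3L
  out[both_htn] <- "HTN_BOTH"
  out[!both_htn & r2 > r1] <- "WORSENED"
  dec <- !both_htn & r2 < r1
  out[dec & !treated1 & !treated2] <- "IMPROVED"
  out[dec & (treated1 | treated2)] <- "UNCLASSIFIED"
  out[!both_htn & r1 == r2] <- "NEVER_HTN"
  factor(out, levels = LONG_LEVELS)
}

#' Build an incident-hypertension analysis cohort
#'
#' Restricts a two-visit table to samples with the requested baseline
#' category and defines the binary outcome as hypertension at follow-up.
#' Time between exams is carried along as a model covariate.
#'
#' @param visits data frame with one row per sample and columns
#'   `sample_id`, `sbp1`, `dbp1`, `treated1`, `self_report1`, `sbp2`,
#'   `dbp2`, `treated2`, `self_report2`, `time1`, `time2`.
#' @param baseline_category `"NORMAL"` or `"ELEVATED"`.
#' @return data frame `sample_id`, `outcome` (0/1), `time_between` plus the
#'   input columns, restricted to the baseline category.
#' @export
incident_cohort <- function(visits, baseline_category = c("NORMAL",
                                                          "ELEVATED")) {
  baseline_category <- match.arg(baseline_category)
  c1 <- bp_category(visits$sbp1, visits$dbp1, visits$treated1,
                    visits$self_report1)
  c2 <- bp_category(visits$sbp2, visits$dbp2, visits$treated2,
                    visits$self_report2)
  keep <- c1 == baseline_category
  out <- visits[keep, , drop = FALSE]
  out$outcome <- as.integer(c2[keep] == "HYPERTENSION")
  out$time_between <- out$time2 - out$time1
  rownames(out) <- NULL
  out
}
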