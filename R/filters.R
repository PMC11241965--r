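#' Proteins detected in every sample of a subset
#'
#' The comparative-analysis universe: proteins detected in all samples of
#' the groups being compared (detection rate exactly 1 in the subset).
#'
#' @param table an `abundance_table`.
#' @param sample_subset non-empty character vector of sample ids.
#' @return character vector of protein ids.
#' @export
complete_proteins <- function(table, sample_subset) {
  rate <- detection_rate(table, sample_subset)
  names(rate)[rate == 1]
}

#' Case-specific proteins by detection-rate contrast
#'
#' Identifies proteins detected in at least `case_min_rate` of the case
#' samples and at most `control_max_rate` of the control samples — the
#' definition of SALS-specific EV proteins (detected in >= 90% of patient
#' samples and <= 10% of control samples). Bounds are inclusive by default;
#' `strict = TRUE` switches to strict inequalities.
#'
#' @param table an `abundance_table`.
#' @param case_subset,control_subset disjoint, non-empty sample-id sets.
#'   For SALS specificity the case subset should be restricted to
#'   drug-naive patient samples.
#' @param case_min_rate,control_max_rate detection-rate thresholds
#'   (defaults 0.90 and 0.10).
#' @param strict use strict inequalities instead of inclusive bounds.
#' @return character vector of protein ids.
#' @export
sals_specific_proteins <- function(table, case_subset, control_subset,
                                   case_min_rate = 0.90,
                                   control_max_rate = 0.10,
                                   strict = FALSE) {
  if (length(case_subset) == 0L || length(control_subset) == 0L)
    stop("case and control subsets must be non-empty")
  if (length(intersect(case_subset, control_subset)))
    stop("case and control subsets must be disjoint")
  if (case_min_rate < 0 || case_min_rate > 1 ||
      control_max_rate < 0 || control_max_rate > 1)
    stop("detection-rate thresholds must lie in [0, 1]")
  case_rate <- detection_rate(table, case_subset)
  ctrl_rate <- detection_rate(table, control_subset)
  keep <- if (strict)
    case_rate > case_min_rate & ctrl_rate < control_max_rate
  else
    case_rate >= case_min_rate & ctrl_rate <= control_max_rate
  names(case_rate)[keep]
}
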