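#' Per-patient log2 fold changes from baseline
#'
#' For each patient with samples at the baseline week and the target week in
#' the given table, the log2 ratio of raw intensities per protein,
#' `log2(value_week / value_baseline)`. Patients lacking either draw are
#' excluded (mirroring the exclusion of patients without week-24 samples);
#' a cell is missing when either endpoint is undetected.
#'
#' @param table raw-scale (batch-corrected) `abundance_table`.
#' @param info validated sample metadata restricted to the table's fluid.
#' @param week target week (> baseline).
#' @param baseline_week baseline week (default 0).
#' @param subjects optional subject-id subset.
#' @param batch restrict to samples from this batch (default 1, the
#'   longitudinal patient batch); `NULL` for no restriction.
#' @return matrix proteins x subjects of log2 fold changes, with the
#'   retained subject ids as colnames.
#' @export
per_patient_log2fc <- function(table, info, week, baseline_week = 0,
                               subjects = NULL, batch = 1L) {
  stopifnot(inherits(table, "abundance_table"))
  if (abundance_scale(table) != "raw")
    stop("fold changes are computed on raw-scale intensities")
  sel <- info$cohort == "SALS" & info$sample_id %in% colnames(table)
  if (!is.null(batch)) sel <- sel & info$batch %in% batch
  if (!is.null(subjects)) sel <- sel & info$subject_id %in% subjects
  info <- info[sel, , drop = FALSE]
  at <- function(w) {
    rows <- info[info$week == w, , drop = FALSE]
    stats::setNames(rows$sample_id, rows$subject_id)
  }
  s0 <- at(baseline_week); s1 <- at(week)
  keep <- intersect(names(s0), names(s1))
  if (length(keep) == 0L)
    stop("no subject has samples at both weeks ", baseline_week, " and ", week)
  fc <- log2(unclass(table)[, s1[keep], drop = FALSE] /
             unclass(table)[, s0[keep], drop = FALSE])
  colnames(fc) <- keep
  fc
}

#' Cohen's d with pooled standard deviation
#'
#' `d = (mean(a) - mean(b)) / s_pooled` with the usual pooled variance
#' `((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2)`. Groups with zero
#' pooled spread give `d = 0` when the means agree and a signed infinity
#' otherwise.
#'
#' @param a,b numeric vectors with at least two non-missing values each.
#' @return the effect size (sign follows `a - b`).
#' @export
cohens_d <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L)
    stop("each group needs at least two non-missing values")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  diff <- mean(a) - mean(b)
  if (sp2 <= 0) {
    if (diff == 0) return(0)
    return(sign(diff) * Inf)
  }
  diff / sqrt(sp2)
}

## Row-wise Cohen's d for two matrices (NA-aware), oriented a - b.
row_cohens_d <- function(ma, mb) {
  na <- rowSums(!is.na(ma)); nb <- rowSums(!is.na(mb))
  mean_a <- rowSums(ma, na.rm = TRUE) / na
  mean_b <- rowSums(mb, na.rm = TRUE) / nb
  ssa <- rowSums(ma^2, na.rm = TRUE) - na * mean_a^2
  ssb <- rowSums(mb^2, na.rm = TRUE) - nb * mean_b^2
  sp <- sqrt((ssa + ssb) / (na + nb - 2))
  d <- (mean_a - mean_b) / sp
  zero_sp <- sp == 0
  d[zero_sp & mean_a == mean_b] <- 0
  d[zero_sp & mean_a != mean_b] <-
    sign((mean_a - mean_b)[zero_sp & mean_a != mean_b]) * Inf
  d[na < 2 | nb < 2] <- NA_real_
  data.frame(cohen_d = d, n_a = na, n_b = nb)
}

#' Magnitude band of an effect size
#'
#' The conventional interpretation bands for |d|: negligible below 0.2,
#' small in \[0.2, 0.5), medium in \[0.5, 0.8), large at 0.8 and above.
#'
#' @param d numeric vector of effect sizes.
#' @return character vector of band labels.
#' @export
d_magnitude <- function(d) {
  ad <- abs(d)
  out <- rep(NA_character_, length(d))
  out[ad < 0.2] <- "negligible"
  out[ad >= 0.2 & ad < 0.5] <- "small"
  out[ad >= 0.5 & ad < 0.8] <- "medium"
  out[ad >= 0.8] <- "large"
  out
}

#' Effect-size based drug-response scoring (es-DAP table)
#'
#' Compares per-patient baseline-to-week fold changes between treatment
#' arms by Cohen's d, protein by protein. Proteins for which the drug
#' effect is at least medium (|d| >= 0.5) are flagged effect-size based
#' differentially abundant (es-DAP); the direction is the sign of d with
#' the drug arm first, so `d > 0` means increased by the drug.
#'
#' @param fc_cube matrix from [per_patient_log2fc()] (proteins x subjects).
#' @param info sample metadata (supplies the arm of each subject).
#' @param es_threshold |d| cut-off for the es-DAP call (default 0.5).
#' @return data.frame of class `esdap_table` with columns `protein_id`,
#'   `cohen_d`, `n_ropi`, `n_placebo`, `magnitude`, `is_es_dap`,
#'   `direction`.
#' @export
es_dap_table <- function(fc_cube, info, es_threshold = 0.5) {
  arm_of <- unique(info[info$cohort == "SALS", c("subject_id", "arm")])
  arm <- stats::setNames(arm_of$arm, arm_of$subject_id)[colnames(fc_cube)]
  if (anyNA(arm)) stop("subjects with unknown arm in fold-change matrix")
  ropi <- fc_cube[, arm == "ROPI", drop = FALSE]
  plac <- fc_cube[, arm == "placebo", drop = FALSE]
  if (ncol(ropi) < 2L || ncol(plac) < 2L)
    stop("both arms need at least two subjects with fold changes")
  res <- row_cohens_d(ropi, plac)
  out <- data.frame(protein_id = rownames(fc_cube),
                    cohen_d = res$cohen_d,
                    n_ropi = res$n_a, n_placebo = res$n_b,
                    magnitude = d_magnitude(res$cohen_d),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$is_es_dap <- !is.na(out$cohen_d) & abs(out$cohen_d) >= es_threshold
  out$direction <- ifelse(out$cohen_d >= 0, "increased_by_ropi",
                          "decreased_by_ropi")
  class(out) <- c("esdap_table", "data.frame")
  out
}
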