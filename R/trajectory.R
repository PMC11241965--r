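#' Mean fold-change trajectories for one arm
#'
#' Builds the per-protein trajectory vectors used for time-series
#' clustering: at each post-baseline week, the mean over the arm's subjects
#' of the per-patient log2 fold change from baseline. Subjects are
#' restricted to those sampled through the final week, the same restriction
#' the clustering analysis applies.
#'
#' @param table raw-scale (batch-corrected) `abundance_table` of one fluid.
#' @param info sample metadata for that fluid.
#' @param weeks post-baseline weeks, in increasing order.
#' @param arm treatment arm (`"placebo"` or `"ROPI"`).
#' @param baseline_week baseline (default 0).
#' @return matrix proteins x weeks of mean log2 fold changes; the subject
#'   ids used are attached as attribute `subjects`.
#' @export
trajectory_matrix <- function(table, info, weeks, arm = "placebo",
                              baseline_week = 0) {
  info <- info[info$sample_id %in% colnames(table), , drop = FALSE]
  final <- max(weeks)
  subj <- intersect(
    info$subject_id[info$arm == arm & info$week == final & info$batch == 1L],
    info$subject_id[info$arm == arm & info$week == baseline_week & info$batch == 1L])
  if (length(subj) == 0L)
    stop("no ", arm, "-arm subject sampled at both baseline and week ", final)
  traj <- sapply(weeks, function(w) {
    fc <- per_patient_log2fc(table, info, w, baseline_week, subjects = subj)
    rowMeans(fc, na.rm = TRUE)
  })
  traj[is.nan(traj)] <- NA_real_
  dimnames(traj) <- list(rownames(table), paste0("w", weeks))
  attr(traj, "subjects") <- subj
  traj
}

#' Ward clustering of fold-change trajectories
#'
#' Agglomerative Ward (minimum-variance) clustering on Euclidean distances
#' between per-protein trajectory vectors, cut at `k` clusters, as used to
#' classify placebo-arm proteins into increased / relatively unchanged /
#' decreased groups. Cluster semantics are assigned from the centroid value
#' at the final week: the cluster with the largest final-week centroid is
#' `increased`, the smallest is `decreased`, and the remainder `unchanged`.
#' Proteins with an incomplete trajectory are excluded from clustering and
#' conservatively labelled `unchanged`.
#'
#' @param traj matrix from [trajectory_matrix()].
#' @param k number of clusters (default 3).
#' @return list of class `trajectory_clusters` with elements `labels`
#'   (named character vector over all proteins), `cluster` (numeric cluster
#'   index for clustered proteins), `centroids` (k x weeks), `hclust`,
#'   `dropped` (protein ids excluded for missingness) and `weeks`.
#' @export
fit_trajectory_clusters <- function(traj, k = 3L) {
  complete <- !apply(is.na(traj), 1L, any)
  x <- traj[complete, , drop = FALSE]
  if (nrow(x) < k)
    stop("need at least k = ", k, " proteins with complete trajectories, got ",
         nrow(x))
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  centroids <- t(sapply(seq_len(k), function(g)
    colMeans(x[cl == g, , drop = FALSE])))
  final <- centroids[, ncol(centroids)]
  sem <- rep("unchanged", k)
  sem[which.max(final)] <- "increased"
  sem[which.min(final)] <- "decreased"
  labels <- stats::setNames(rep("unchanged", nrow(traj)), rownames(traj))
  labels[rownames(x)] <- sem[cl]
  structure(list(labels = labels,
                 cluster = cl,
                 centroids = centroids,
                 semantics = sem,
                 hclust = hc,
                 dropped = rownames(traj)[!complete],
                 weeks = colnames(traj)),
            class = "trajectory_clusters")
}

#' @export
print.trajectory_clusters <- function(x, ...) {
  cat("trajectory clusters:",
      paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Transfer placebo-derived cluster labels to the drug arm and test
#'
#' For each cluster label, assembles the per-protein arm-mean log2 fold
#' change at each week for both arms (the quantity the longitudinal plots
#' display), fits a two-factor fixed-effects ANOVA (treatment, week and
#' their interaction; Type-III sums of squares on sum-to-zero contrasts),
#' and compares the arms within each week via estimated marginal means with
#' Bonferroni adjustment across the week family. Cluster membership is a
#' function of the placebo data only; the drug arm never influences the
#' partition.
#'
#' @param model a [fit_trajectory_clusters()] result fitted on placebo data.
#' @param table raw-scale `abundance_table` of the fluid.
#' @param info sample metadata for that fluid.
#' @param weeks post-baseline weeks used for the trajectories.
#' @param labels which cluster labels to test (default increased and
#'   decreased).
#' @return named list per label: `anova` (Type-III table), `contrasts`
#'   (arm contrast per week with raw and Bonferroni-adjusted p),
#'   `p_treatment` (treatment main-effect p), `n_proteins`. Labels with
#'   fewer than two member proteins are skipped with a warning.
#' @export
transfer_and_test <- function(model, table, info, weeks,
                              labels = c("increased", "decreased")) {
  traj <- list(placebo = trajectory_matrix(table, info, weeks, arm = "placebo"),
               ROPI = trajectory_matrix(table, info, weeks, arm = "ROPI"))
  out <- list()
  for (lab in labels) {
    members <- names(model$labels)[model$labels == lab]
    members <- setdiff(members, model$dropped)
    if (length(members) < 2L) {
      warning("label '", lab, "' has fewer than two proteins; skipped")
      next
    }
    long <- do.call(rbind, lapply(names(traj), function(armname) {
      m <- traj[[armname]][members, , drop = FALSE]
      data.frame(protein_id = rep(rownames(m), ncol(m)),
                 arm = armname,
                 week = rep(colnames(m), each = nrow(m)),
                 value = as.vector(m),
                 stringsAsFactors = FALSE)
    }))
    long <- long[!is.na(long$value), , drop = FALSE]
    long$arm <- factor(long$arm, levels = c("placebo", "ROPI"))
    long$week <- factor(long$week, levels = colnames(traj$placebo))
    fit <- stats::lm(value ~ arm * week, data = long,
                     contrasts = list(arm = "contr.sum", week = "contr.sum"))
    an <- car::Anova(fit, type = 3)
    em <- emmeans::emmeans(fit, ~ arm | week)
    cont <- summary(emmeans::contrast(em, method = "pairwise", by = "week"),
                    adjust = "none")
    cont <- as.data.frame(cont)
    cont$p_bonferroni <- pmin(1, cont$p.value * nrow(cont))
    out[[lab]] <- list(anova = an,
                       contrasts = cont,
                       p_treatment = an["arm", "Pr(>F)"],
                       n_proteins = length(members))
  }
  out
}
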