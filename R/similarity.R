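#' Signed membership vector over a protein universe
#'
#' Encodes a differential or trajectory protein set as a vector over the
#' universe with +1 for up/increased members, -1 for down/decreased members
#' and 0 elsewhere, so that directionally opposed sets (for example
#' "increased in patients" versus "decreased by drug") have negative
#' cosine similarity.
#'
#' @param universe ordered character vector of protein ids.
#' @param up,down character vectors of member ids (must be disjoint subsets
#'   of the universe).
#' @return named numeric vector in `\{-1, 0, +1\}`.
#' @export
signed_set_vector <- function(universe, up = character(), down = character()) {
  if (length(intersect(up, down)))
    stop("up and down sets must be disjoint")
  bad <- setdiff(c(up, down), universe)
  if (length(bad))
    stop("protein id(s) outside the universe: ", paste(bad, collapse = ", "))
  v <- stats::setNames(rep(0, length(universe)), universe)
  v[up] <- 1
  v[down] <- -1
  v
}

#' Cosine similarity of two vectors
#'
#' @param u,v numeric vectors on the same universe, each with at least one
#'   non-zero entry.
#' @return `sum(u v) / (||u|| ||v||)`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v))
    stop("vectors must share the same universe")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("cosine similarity undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Pairwise cosine similarity matrix with display ordering
#'
#' All pairwise cosines between named signed set vectors, plus an
#' average-linkage hierarchical ordering (on the distance `1 - cosine`)
#' for heatmap display.
#'
#' @param sets named list of equal-length numeric vectors.
#' @return list with `matrix` (symmetric cosine matrix), `order`
#'   (display order of the set names) and `hclust`.
#' @export
similarity_heatmap <- function(sets) {
  if (length(sets) < 2L) stop("need at least two sets")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must be uniquely named")
  n <- length(sets)
  m <- diag(1, n)
  dimnames(m) <- list(names(sets), names(sets))
  for (i in seq_len(n - 1L))
    for (j in seq((i + 1L), n))
      m[i, j] <- m[j, i] <- cosine_similarity(sets[[i]], sets[[j]])
  hc <- stats::hclust(stats::as.dist(1 - m), method = "average")
  list(matrix = m, order = names(sets)[hc$order], hclust = hc)
}

#' Per-subject serum/CSF profile correlation with Dunnett-style comparison
#'
#' For every subject-week at which both fluids were sampled, the Pearson
#' correlation between the two log10 profiles over the proteins detected in
#' both fluids for that subject-week (pairwise-complete universe). The
#' patient week-groups are then compared against the controls with a
#' many-to-one Dunnett test.
#'
#' @param serum,csf log10-scale `abundance_table`s on a shared protein
#'   universe (ids are intersected).
#' @param info sample metadata covering both fluids.
#' @param min_proteins minimum shared detected proteins for a defined
#'   correlation (default 3).
#' @return list with `correlations` (data.frame subject_id, cohort, week,
#'   n_proteins, r) and `dunnett` (data.frame of SALS week-group versus
#'   control contrasts with adjusted p-values; `NULL` when groups are too
#'   small to test).
#' @export
paired_profile_correlation <- function(serum, csf, info, min_proteins = 3L) {
  stopifnot(abundance_scale(serum) == "log10", abundance_scale(csf) == "log10")
  shared <- intersect(rownames(serum), rownames(csf))
  if (length(shared) == 0L) stop("no shared proteins between fluids")
  s_info <- info[info$fluid == "serum" & info$sample_id %in% colnames(serum), ]
  c_info <- info[info$fluid == "CSF" & info$sample_id %in% colnames(csf), ]
  key <- function(d) paste(d$subject_id, d$week, d$batch)
  joint <- merge(s_info[, c("subject_id", "cohort", "week", "batch", "sample_id")],
                 c_info[, c("subject_id", "week", "batch", "sample_id")],
                 by = c("subject_id", "week", "batch"),
                 suffixes = c("_serum", "_csf"))
  rows <- lapply(seq_len(nrow(joint)), function(i) {
    u <- unclass(serum)[shared, joint$sample_id_serum[i]]
    v <- unclass(csf)[shared, joint$sample_id_csf[i]]
    ok <- !is.na(u) & !is.na(v)
    r <- if (sum(ok) >= min_proteins) stats::cor(u[ok], v[ok]) else NA_real_
    data.frame(subject_id = joint$subject_id[i], cohort = joint$cohort[i],
               week = joint$week[i], n_proteins = sum(ok), r = r,
               stringsAsFactors = FALSE)
  })
  cors <- do.call(rbind, rows)
  cors <- cors[!is.na(cors$r), , drop = FALSE]
  dun <- tryCatch(dunnett_vs_control(cors), error = function(e) NULL)
  list(correlations = cors, dunnett = dun)
}

#' Dunnett many-to-one comparison of patient week-groups against controls
#'
#' One-way ANOVA on the per-subject correlation coefficients with groups
#' `control` and `SALS week w`, followed by Dunnett's test of every patient
#' week-group against the control group (multcomp's single-step adjustment).
#'
#' @param cors data.frame with columns `cohort`, `week`, `r` (as returned in
#'   `correlations` by [paired_profile_correlation()]).
#' @return data.frame with columns `contrast`, `estimate`, `p_adjusted`.
#' @export
dunnett_vs_control <- function(cors) {
  grp <- ifelse(cors$cohort == "control", "control",
                paste0("SALS_w", cors$week))
  lev <- c("control", sort(setdiff(unique(grp), "control")))
  if (length(lev) < 2L) stop("need controls plus at least one patient group")
  d <- data.frame(r = cors$r, group = factor(grp, levels = lev))
  fit <- stats::aov(r ~ group, data = d)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
  s <- summary(gl)
  data.frame(contrast = names(s$test$coefficients),
             estimate = as.numeric(s$test$coefficients),
             p_adjusted = as.numeric(s$test$pvalues),
             stringsAsFactors = FALSE)
}

#' Divergence trajectory of samples along planted axes
#'
#' Summarises each sample by its mean deviation from baseline along two
#' protein sets: x = mean over the `down_set` (proteins decreased in
#' disease or over time), y = mean over the `up_set` (proteins increased).
#' Patient samples are referenced to the same subject's week-0 profile;
#' control samples to the per-protein control mean, so the control cloud is
#' centred at the origin.
#'
#' @param table log10-scale `abundance_table`.
#' @param info sample metadata for the table's fluid.
#' @param up_set,down_set non-empty protein-id sets.
#' @return data.frame with columns `sample_id`, `subject_id`, `cohort`,
#'   `arm`, `week`, `x`, `y`.
#' @export
divergence_trajectory <- function(table, info, up_set, down_set) {
  stopifnot(abundance_scale(table) == "log10")
  if (length(up_set) == 0L || length(down_set) == 0L)
    stop("up and down sets must be non-empty")
  info <- info[info$sample_id %in% colnames(table), , drop = FALSE]
  m <- unclass(table)
  ctrl_ids <- info$sample_id[info$cohort == "control"]
  ctrl_mean <- rowMeans(m[, ctrl_ids, drop = FALSE], na.rm = TRUE)
  ## reference profile per sample: own week-0 draw for patients (batch 1),
  ## the control mean for controls
  ref_for <- function(i) {
    if (info$cohort[i] == "control") return(ctrl_mean)
    base <- info$sample_id[info$subject_id == info$subject_id[i] &
                           info$week == 0 & info$batch == 1L]
    if (length(base) == 0L) return(NULL)
    m[, base[1L]]
  }
  rows <- lapply(seq_len(nrow(info)), function(i) {
    ref <- ref_for(i)
    if (is.null(ref)) return(NULL)
    dvec <- m[, info$sample_id[i]] - ref
    data.frame(sample_id = info$sample_id[i], subject_id = info$subject_id[i],
               cohort = info$cohort[i], arm = info$arm[i], week = info$week[i],
               x = mean(dvec[down_set], na.rm = TRUE),
               y = mean(dvec[up_set], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
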