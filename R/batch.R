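#' Per-protein bridge-sample correction ratios
#'
#' Bridge samples are aliquots measured in both LC/MS batches. For each
#' protein the correction factor is the mean of the batch-2/batch-1
#' intensity ratios over the bridge pairs,
#' \deqn{f_p = \frac{1}{n}\sum_i X'_i / X_i,}
#' computed over pairs in which both measurements are present. With the
#' standard three bridge samples and complete data this is exactly the
#' published ratio estimator; pairs with a missing member are dropped from
#' the mean rather than imputed, and the factor is undefined (missing) when
#' no usable pair remains.
#'
#' @param batch1,batch2 raw-scale `abundance_table`s for the two batches
#'   (they may be two column subsets of one table).
#' @param bridge_pairs data.frame with columns `sample_b1`, `sample_b2`
#'   naming the paired measurements of each bridge sample.
#' @param min_pairs minimum usable pairs for a defined factor (default 1;
#'   set to `nrow(bridge_pairs)` to require complete bridges).
#' @return object of class `bridge_ratios`: data.frame with columns
#'   `protein_id`, `f`, `n_used`.
#' @export
compute_bridge_ratios <- function(batch1, batch2, bridge_pairs, min_pairs = 1L) {
  stopifnot(inherits(batch1, "abundance_table"), inherits(batch2, "abundance_table"))
  if (abundance_scale(batch1) != "raw" || abundance_scale(batch2) != "raw")
    stop("bridge ratios are computed on raw-scale tables")
  if (!all(bridge_pairs$sample_b1 %in% colnames(batch1)))
    stop("bridge sample(s) missing from batch 1 table")
  if (!all(bridge_pairs$sample_b2 %in% colnames(batch2)))
    stop("bridge sample(s) missing from batch 2 table")
  if (!identical(rownames(batch1), rownames(batch2)))
    stop("batch tables must share the same protein universe, in order")
  x1 <- unclass(batch1)[, bridge_pairs$sample_b1, drop = FALSE]
  x2 <- unclass(batch2)[, bridge_pairs$sample_b2, drop = FALSE]
  zero_den <- !is.na(x1) & x1 == 0
  if (any(zero_den)) {
    warning(sum(zero_den), " bridge pair(s) with zero batch-1 intensity skipped")
    x1[zero_den] <- NA_real_
  }
  ratio <- x2 / x1
  n_used <- rowSums(!is.na(ratio))
  f <- rowSums(ratio, na.rm = TRUE) / n_used
  f[n_used < min_pairs] <- NA_real_
  structure(data.frame(protein_id = rownames(batch1), f = f,
                       n_used = as.integer(n_used),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("bridge_ratios", "data.frame"))
}

#' Apply bridge-ratio batch correction to batch-2 measurements
#'
#' Harmonises batch-2 intensities to the batch-1 scale: corrected value
#' `Z = Y / f_p` per protein. Proteins whose factor is undefined become
#' missing in the corrected output. Correction is performed on raw
#' intensities, before the log10 transform.
#'
#' @param batch2 raw-scale `abundance_table` of batch-2 measurements.
#' @param ratios a [compute_bridge_ratios()] result on the same protein
#'   universe.
#' @return corrected raw-scale `abundance_table`.
#' @export
apply_batch_correction <- function(batch2, ratios) {
  stopifnot(inherits(batch2, "abundance_table"), inherits(ratios, "bridge_ratios"))
  if (abundance_scale(batch2) != "raw")
    stop("batch correction applies to raw-scale tables")
  if (!identical(rownames(batch2), ratios$protein_id))
    stop("ratio table does not match the protein universe of batch 2")
  z <- unclass(batch2) / ratios$f
  abundance_table(z, scale = "raw")
}

#' Correct batch 2 against batch 1 and merge into one table
#'
#' Convenience wrapper for the standard flow: compute bridge ratios, correct
#' every batch-2 sample, and return a single raw-scale table in which
#' batch-1 samples pass through unchanged. The batch-2 re-measurements of
#' the bridge samples are dropped by default since their batch-1
#' measurements are retained.
#'
#' @param batch1,batch2 raw-scale `abundance_table`s.
#' @inheritParams compute_bridge_ratios
#' @param drop_bridge_duplicates drop the batch-2 bridge columns after
#'   correction (default `TRUE`).
#' @return list with elements `table` (merged corrected raw table) and
#'   `ratios` (the `bridge_ratios` used).
#' @export
correct_and_merge <- function(batch1, batch2, bridge_pairs, min_pairs = 1L,
                              drop_bridge_duplicates = TRUE) {
  ratios <- compute_bridge_ratios(batch1, batch2, bridge_pairs, min_pairs)
  corrected <- apply_batch_correction(batch2, ratios)
  keep <- colnames(corrected)
  if (drop_bridge_duplicates)
    keep <- setdiff(keep, bridge_pairs$sample_b2)
  merged <- cbind(unclass(batch1), unclass(corrected)[, keep, drop = FALSE])
  list(table = abundance_table(merged, scale = "raw"), ratios = ratios)
}
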