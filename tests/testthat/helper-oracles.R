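# Shared fixtures and independent oracles used across the suite.

# small abundance table from a numeric matrix (adds ids when absent)
toy_table <- function(m, scale = "raw") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("P%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  abundance_table(m, scale = scale)
}

# brute-force step-up q-values: q_(i) = min_{j >= i} pi0 * m * p_(j) / j,
# computed by direct minimisation (independent of the package's cummin path)
stepup_oracle <- function(p, pi0 = 1) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(pi0 * m * p[o][i:m] / (i:m)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# greedy minimum-cost Ward merging by exhaustive pair search.
# Returns the partition (list of sorted index vectors) after each merge.
# Ward cost of merging clusters A, B: |A||B|/(|A|+|B|) * ||mean_A - mean_B||^2
ward_oracle <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  clusters <- lapply(seq_len(nrow(x)), identity)
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1L))
      for (j in (i + 1L):length(clusters)) {
        a <- clusters[[i]]; b <- clusters[[j]]
        ca <- colMeans(x[a, , drop = FALSE]); cb <- colMeans(x[b, , drop = FALSE])
        cost <- length(a) * length(b) / (length(a) + length(b)) * sum((ca - cb)^2)
        if (is.null(best) || cost < best$cost) best <- list(i = i, j = j, cost = cost)
      }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
    partitions[[length(partitions) + 1L]] <-
      lapply(clusters, sort)[order(sapply(clusters, min))]
  }
  partitions
}

# canonical partition of an hclust tree at each merge step, comparable with
# ward_oracle output
hclust_partitions <- function(hc, n) {
  lapply(seq_len(n - 1L), function(step) {
    cl <- stats::cutree(hc, k = n - step)
    groups <- split(seq_len(n), cl)
    unname(lapply(groups, sort))[order(sapply(split(seq_len(n), cl), min))]
  })
}

# minimal zero-noise simulation config for structural tests
quiet_config <- function(...) {
  args <- list(n_proteins = 40, batch_sd_log10 = 0, noise_sd_log10 = 0,
               lod_log10 = -Inf, score_noise_sd = 0)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

# small but realistic config for recovery-flavoured unit tests
small_config <- function(...) sim_config(n_proteins = 120, ...)

# linearly separable two-blob classification toy with a few noise features
blob_data <- function(n_per = 10, sd = 0.1, sep = 3, p_noise = 3, seed = 107) {
  with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * 2, 0, sd), n_per, 2),
               matrix(rnorm(n_per * 2, sep, sd), n_per, 2))
    x <- cbind(x, matrix(rnorm(2 * n_per * p_noise), 2 * n_per, p_noise))
    colnames(x) <- paste0("f", seq_len(ncol(x)))
    list(x = x, y = rep(c("control", "SALS"), each = n_per))
  })
}

# serum-side corrected/merged table plus per-fluid metadata for a cohort;
# `info` is restricted to the merged columns, `info_full` keeps the
# batch-2 bridge re-measurement rows
serum_prep <- function(cohort) {
  info <- cohort$info[cohort$info$fluid == "serum", ]
  b1 <- info$sample_id[info$batch == 1]
  b2 <- info$sample_id[info$batch == 2]
  cm <- correct_and_merge(cohort$tables$serum[, b1], cohort$tables$serum[, b2],
                          bridge_pairs(cohort, "serum"))
  list(merged = cm$table, ratios = cm$ratios,
       info = info[info$sample_id %in% colnames(cm$table), ],
       info_full = info)
}
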