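#' Pooled-variance (Student's) two-sample t test
#'
#' The classical equal-variance two-sided t test on the non-missing values
#' of the two groups. Returns the statistic oriented as `a - b`.
#'
#' @param a,b numeric vectors (missing values dropped); each group needs at
#'   least two values and the pooled variance must be positive.
#' @return list with elements `t`, `p`, `df`.
#' @export
student_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L)
    stop("each group needs at least two non-missing values")
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  if (sp2 <= 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1, df = df))
    stop("zero pooled variance with unequal means")
  }
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tt, p = 2 * stats::pt(-abs(tt), df), df = df)
}

## Row-wise pooled t on two matrices sharing rownames; NA-aware and
## vectorised so a thousand proteins cost one pass. Untestable rows
## (fewer than 2 values in a group, or zero pooled variance with unequal
## means) get NA statistics.
row_student_t <- function(ma, mb) {
  na <- rowSums(!is.na(ma)); nb <- rowSums(!is.na(mb))
  sa <- rowSums(ma, na.rm = TRUE); sb <- rowSums(mb, na.rm = TRUE)
  mean_a <- sa / na; mean_b <- sb / nb
  ssa <- rowSums(ma^2, na.rm = TRUE) - na * mean_a^2
  ssb <- rowSums(mb^2, na.rm = TRUE) - nb * mean_b^2
  df <- na + nb - 2
  sp2 <- (ssa + ssb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tt <- (mean_a - mean_b) / se
  p <- 2 * stats::pt(-abs(tt), df)
  untestable <- na < 2 | nb < 2 | !is.finite(tt)
  zero_var_equal <- !untestable & sp2 <= 0  # guarded by is.finite above
  tt[untestable] <- NA_real_; p[untestable] <- NA_real_
  data.frame(mean_a = mean_a, mean_b = mean_b, n_a = na, n_b = nb,
             t_statistic = tt, p_value = p, df = df)
}

#' Storey q-values with smoothed pi0 estimation
#'
#' False-discovery-rate adjusted significance incorporating an estimate of
#' the proportion of true nulls. `pi0` is estimated as
#' `#\{p > lambda\} / (m (1 - lambda))` across the `lambda` grid, smoothed
#' with a natural cubic smoothing spline (3 df) and read off at the largest
#' `lambda`, then clipped to `(0, 1]`; q-values are the step-up minimisation
#' `q_(i) = min_{j >= i} pi0 * m * p_(j) / j` over the sorted p-values.
#' Forcing `pi0 = 1` reduces the procedure exactly to Benjamini-Hochberg.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs are propagated and
#'   excluded from estimation).
#' @param lambda tuning grid in `[0, 1)`.
#' @param pi0 optional fixed null proportion overriding estimation.
#' @return list with elements `q` (same length/order as `p`) and `pi0`.
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05), pi0 = NULL) {
  ok <- !is.na(p)
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(list(q = p, pi0 = NA_real_))
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  if (is.null(pi0)) {
    if (m == 1L || max(pv) < min(lambda)) {
      pi0 <- 1
    } else {
      pi0_hat <- vapply(lambda, function(l) mean(pv > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lambda, pi0_hat, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
      pi0 <- min(max(pi0, .Machine$double.eps), 1)
    }
  } else {
    if (pi0 <= 0 || pi0 > 1) stop("pi0 must lie in (0, 1]")
  }
  o <- order(pv)
  q_sorted <- pi0 * m * pv[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(pmin(q_sorted, 1))))
  q <- rep(NA_real_, length(p))
  q[ok][o] <- q_sorted
  list(q = q, pi0 = pi0)
}

#' Control-versus-case differential abundance on log10 intensities
#'
#' Per-protein pooled-variance t tests between two sample groups on a
#' log10-scale table, with Storey q-value multiple-testing correction.
#' Proteins with insufficient data (fewer than two values in a group, or
#' zero pooled variance with unequal means) are flagged untestable and
#' excluded from the FDR input. A protein is called differentially abundant
#' (DAP) when `q < q_threshold`.
#'
#' @param table log10-scale `abundance_table`.
#' @param control_ids,case_ids sample-id vectors for the two groups.
#' @param q_threshold significance cut-off on q (default 0.05).
#' @param pi0 optional fixed null proportion (see [storey_qvalues()]).
#' @return data.frame of class `dap_table`: one row per protein with
#'   columns `protein_id`, `mean_log10_control`, `mean_log10_case`,
#'   `t_statistic`, `p_value`, `q_value`, `direction` (`up_in_case` /
#'   `down_in_case`), `is_dap`, `testable`. The `pi0` estimate is attached
#'   as an attribute.
#' @export
differential_abundance <- function(table, control_ids, case_ids,
                                   q_threshold = 0.05, pi0 = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  if (abundance_scale(table) != "log10")
    stop("differential abundance is computed on log10-scale tables")
  mc <- unclass(table)[, control_ids, drop = FALSE]
  ms <- unclass(table)[, case_ids, drop = FALSE]
  res <- row_student_t(ms, mc)  # oriented case - control
  out <- data.frame(protein_id = rownames(table),
                    mean_log10_control = res$mean_b,
                    mean_log10_case = res$mean_a,
                    t_statistic = res$t_statistic,
                    p_value = res$p_value,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$testable <- !is.na(out$p_value)
  st <- storey_qvalues(out$p_value, pi0 = pi0)
  out$q_value <- st$q
  out$direction <- ifelse(out$mean_log10_case >= out$mean_log10_control,
                          "up_in_case", "down_in_case")
  out$is_dap <- out$testable & out$q_value < q_threshold
  attr(out, "pi0") <- st$pi0
  attr(out, "q_threshold") <- q_threshold
  class(out) <- c("dap_table", "data.frame")
  out
}

#' Intersect differential calls between two fluids
#'
#' Overlap of the significant sets of two differential-abundance analyses,
#' keyed on protein id and direction: proteins up in both, down in both,
#' and those significant in one analysis only.
#'
#' @param dap_a,dap_b `dap_table`s (e.g. serum and CSF).
#' @return list with character-vector elements `shared_up`, `shared_down`,
#'   `a_only`, `b_only`.
#' @export
compare_daps <- function(dap_a, dap_b) {
  sig <- function(d, dir) d$protein_id[d$is_dap & d$direction == dir]
  a_up <- sig(dap_a, "up_in_case"); a_dn <- sig(dap_a, "down_in_case")
  b_up <- sig(dap_b, "up_in_case"); b_dn <- sig(dap_b, "down_in_case")
  list(shared_up = intersect(a_up, b_up),
       shared_down = intersect(a_dn, b_dn),
       a_only = setdiff(c(a_up, a_dn), c(b_up, b_dn)),
       b_only = setdiff(c(b_up, b_dn), c(a_up, a_dn)))
}
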