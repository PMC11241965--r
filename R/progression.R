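#' Fit the exponential disease-progression model to one ALSFRS-R series
#'
#' Least-squares fit of `score = -exp(a * week) + b` by multi-start
#' nonlinear optimisation: bounded Gauss-Newton (`nls` with the port
#' algorithm, Levenberg-Marquardt fallback) from starting values
#' `a in \{0.001, 0.005, 0.02, 0.05, 0.1\}`, `b = max(score) + 1`, keeping
#' the lowest-RSS solution. `a` is constrained to `[1e-6, 1]` per week; a
#' fit pinned at the lower bound (an essentially flat series) is flagged.
#'
#' @param weeks,scores the series (at least 3 observations spanning at
#'   least 2 distinct weeks).
#' @param a_starts starting values for `a`.
#' @param a_bounds lower/upper bounds for `a`.
#' @return list of class `progression_fit`: `a`, `b`, `rss`, `converged`,
#'   `at_bound`, `n_obs`.
#' @export
fit_progression <- function(weeks, scores,
                            a_starts = c(0.001, 0.005, 0.02, 0.05, 0.1),
                            a_bounds = c(1e-6, 1)) {
  ok <- !is.na(weeks) & !is.na(scores)
  weeks <- weeks[ok]; scores <- scores[ok]
  if (length(weeks) < 3L || length(unique(weeks)) < 2L)
    stop("need at least 3 observations spanning at least 2 distinct weeks")
  dat <- data.frame(week = weeks, score = scores)
  b0 <- max(scores) + 1
  best <- NULL
  for (a0 in a_starts) {
    ## some starts are expected to stall; the multi-start best-RSS rule
    ## below is what guarantees the fit, so per-start chatter is silenced
    fit <- tryCatch(
      suppressWarnings(
        stats::nls(score ~ -exp(a * week) + b, data = dat,
                   start = list(a = a0, b = b0),
                   algorithm = "port",
                   lower = c(a = a_bounds[1], b = -Inf),
                   upper = c(a = a_bounds[2], b = Inf),
                   control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
      error = function(e) NULL)
    if (is.null(fit))
      fit <- tryCatch(
        suppressWarnings(
          minpack.lm::nlsLM(score ~ -exp(a * week) + b, data = dat,
                            start = list(a = a0, b = b0),
                            lower = c(a = a_bounds[1], b = -Inf),
                            upper = c(a = a_bounds[2], b = Inf),
                            control = minpack.lm::nls.lm.control(maxiter = 200))),
        error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-10)
      best <- list(a = stats::coef(fit)[["a"]], b = stats::coef(fit)[["b"]],
                   rss = rss)
  }
  if (is.null(best))
    return(structure(list(a = NA_real_, b = NA_real_, rss = NA_real_,
                          converged = FALSE, at_bound = FALSE,
                          n_obs = length(weeks)),
                     class = "progression_fit"))
  structure(list(a = best$a, b = best$b, rss = best$rss, converged = TRUE,
                 at_bound = best$a <= a_bounds[1] * (1 + 1e-8),
                 n_obs = length(weeks)),
            class = "progression_fit")
}

#' Fit the progression model for every subject in a score table
#'
#' @param alsfrs validated data.frame with `subject_id`, `week`, `alsfrs_r`.
#' @param arms optional named vector mapping subject id to treatment arm;
#'   when given, `adj_a` (the within-arm z-score of `-log10(a)`) is added.
#' @return data.frame with one row per subject: `subject_id`, `a`, `b`,
#'   `rss`, `converged`, `at_bound` and (with `arms`) `arm`, `adj_a`.
#'   Subjects whose fit fails are kept with `converged = FALSE` and a
#'   warning.
#' @export
fit_progression_all <- function(alsfrs, arms = NULL) {
  subj <- unique(alsfrs$subject_id)
  rows <- lapply(subj, function(s) {
    d <- alsfrs[alsfrs$subject_id == s, ]
    f <- fit_progression(d$week, d$alsfrs_r)
    data.frame(subject_id = s, a = f$a, b = f$b, rss = f$rss,
               converged = f$converged, at_bound = f$at_bound,
               stringsAsFactors = FALSE)
  })
  fits <- do.call(rbind, rows)
  if (any(!fits$converged))
    warning("progression fit failed for subject(s): ",
            paste(fits$subject_id[!fits$converged], collapse = ", "))
  if (!is.null(arms)) {
    fits$arm <- unname(arms[fits$subject_id])
    fits <- adj_a(fits)
  }
  fits
}

#' Model-approximated ALSFRS-R at a sampling week
#' @param fit a `progression_fit`, or a list/row with elements `a`, `b`.
#' @param week sampling week(s).
#' @return `-exp(a * week) + b`.
#' @export
aalsfrs <- function(fit, week) alsfrs_model(fit$a, fit$b, week)

#' Fixed-point disease-progression rate
#'
#' The derivative of the fitted model at a sampling week,
#' `-a * exp(a * week)` (score points per week; negative, and strictly
#' decreasing in week for `a > 0`).
#'
#' @inheritParams aalsfrs
#' @return the instantaneous progression rate.
#' @export
fixed_point_rate <- function(fit, week) -fit$a * exp(fit$a * week)

#' Within-arm z-score of the progression rate (adj-a)
#'
#' The prognostic index: `-log10(a)` standardised (sample sd) within each
#' treatment arm. Higher values indicate slower progression. Arms with
#' fewer than two converged fits, or zero spread, get `NA` with a warning.
#'
#' @param fits data.frame from [fit_progression_all()] with an `arm` column.
#' @return `fits` with an `adj_a` column appended.
#' @export
adj_a <- function(fits) {
  if (is.null(fits$arm)) stop("fits must carry an 'arm' column")
  fits$adj_a <- NA_real_
  for (g in unique(fits$arm)) {
    i <- which(fits$arm == g & fits$converged & !is.na(fits$a))
    if (length(i) < 2L) {
      warning("arm '", g, "' has fewer than two converged fits; adj_a undefined")
      next
    }
    v <- -log10(fits$a[i])
    s <- stats::sd(v)
    if (s == 0) {
      warning("arm '", g, "' has zero spread in -log10(a); adj_a undefined")
      next
    }
    fits$adj_a[i] <- (v - mean(v)) / s
  }
  fits
}

#' Correlation-based prognostic biomarker ranking
#'
#' Pearson correlation (pairwise-complete, minimum 3 pairs) between each
#' protein's log10 level in the subjects' week-`week` samples and a
#' per-subject clinical target — the adj-a prognostic index, the
#' model-approximated ALSFRS-R at a week, or the fixed-point progression
#' rate. Proteins are ranked by r; the report flags the conventional
#' |r| >= cutoff band and the top tails.
#'
#' @param table log10-scale `abundance_table`.
#' @param info sample metadata for the table's fluid.
#' @param target named numeric vector: target value per subject id.
#' @param week which sampling week's protein levels to use (default 0).
#' @param cutoff |r| report threshold (default 0.5).
#' @param top number of proteins in each tail list (default 5).
#' @return list of class `biomarker_ranking`: `ranking` (data.frame
#'   `protein_id`, `r`, `p_value`, `n`, `rank`, `above_cutoff`),
#'   `top_positive`, `top_negative`, `n_subjects`.
#' @export
rank_biomarkers <- function(table, info, target, week = 0, cutoff = 0.5,
                            top = 5L) {
  stopifnot(abundance_scale(table) == "log10")
  sel <- info$sample_id %in% colnames(table) & info$week == week &
    info$subject_id %in% names(target) & info$batch == 1L
  smp <- info[sel, , drop = FALSE]
  smp <- smp[!duplicated(smp$subject_id), , drop = FALSE]
  if (nrow(smp) < 3L)
    stop("need at least 3 subjects with week-", week, " samples and targets")
  y <- unname(target[smp$subject_id])
  x <- unclass(table)[, smp$sample_id, drop = FALSE]
  rows <- lapply(rownames(x), function(p) {
    v <- x[p, ]
    ok <- !is.na(v) & !is.na(y)
    if (sum(ok) < 3L || stats::sd(v[ok]) == 0)
      return(data.frame(protein_id = p, r = NA_real_, p_value = NA_real_,
                        n = sum(ok), stringsAsFactors = FALSE))
    ct <- stats::cor.test(v[ok], y[ok], method = "pearson")
    data.frame(protein_id = p, r = unname(ct$estimate),
               p_value = ct$p.value, n = sum(ok), stringsAsFactors = FALSE)
  })
  rk <- do.call(rbind, rows)
  rk <- rk[order(-rk$r, rk$protein_id, na.last = TRUE), , drop = FALSE]
  rk$rank <- seq_len(nrow(rk))
  rk$above_cutoff <- !is.na(rk$r) & abs(rk$r) >= cutoff
  rownames(rk) <- NULL
  defined <- rk[!is.na(rk$r), , drop = FALSE]
  structure(list(ranking = rk,
                 top_positive = utils::head(defined$protein_id, top),
                 top_negative = rev(utils::tail(defined$protein_id, top)),
                 n_subjects = nrow(smp)),
            class = "biomarker_ranking")
}
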