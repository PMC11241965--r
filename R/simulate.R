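#' Simulation configuration for a synthetic EV proteomics cohort
#'
#' The generator emulates the sampling design of a placebo-controlled ALS
#' trial with an open-label extension: 10 controls drawn once, 20 SALS
#' patients (13 ROPI, 7 placebo) sampled longitudinally in serum (weeks 0,
#' 13, 24, 39, 48) and CSF (weeks 0, 24, 48), measured in two LC/MS batches
#' linked by bridge samples. It plants three protein classes —
#' inflammation-type proteins elevated in disease and rising with
#' progression, UPR-type proteins depressed in disease and falling with
#' progression, and null proteins — together with per-protein multiplicative
#' batch factors, detection-limit left-censoring, and exponential ALSFRS-R
#' decline per patient. All planted parameters are returned as ground truth
#' so recovery can be scored.
#'
#' @param n_controls,n_sals,n_ropi,n_placebo cohort sizes (10/20/13/7).
#' @param serum_weeks,csf_weeks sampling weeks per fluid.
#' @param n_proteins number of proteins per fluid.
#' @param frac_inflammation_up,frac_upr_down fractions of proteins planted in
#'   each affected class (fractions must sum to at most 1).
#' @param disease_shift_log10 additive log10 shift of affected proteins in
#'   SALS samples (+ for inflammation-type, - for UPR-type).
#' @param trend_slope_log10 magnitude of the progression-coupled trend, in
#'   log10 units per unit of accumulated modelled decline (see
#'   `vignette("evprot-methods")` for the calibration rationale).
#' @param trend_scale global multiplier on `trend_slope_log10`.
#' @param ropi_attenuation fraction of the trend accrual removed while a
#'   subject is on drug, in `[0, 1]`.
#' @param batch_sd_log10 sd of the per-protein batch factor (additive on
#'   log10, i.e. multiplicative on raw intensities).
#' @param noise_sd_log10 sd of per-measurement log10 noise.
#' @param lod_log10 detection limit: a measurement with true log10 abundance
#'   at or below this is reported missing.
#' @param n_bridge number of SALS week-0 samples re-measured in batch 2.
#' @param baseline_mean_log10,baseline_sd_log10 distribution of per-protein
#'   baseline log10 abundance.
#' @param a_log_mean,a_log_sd log-normal parameters of the per-patient decay
#'   rate `a` of the ALSFRS-R model `-exp(a * week) + b`.
#' @param b_mean,b_sd normal parameters of the per-patient plateau `b`.
#' @param score_noise_sd sd of the ALSFRS-R observation noise (score points).
#' @param score_weeks clinical assessment schedule.
#' @param seed integer RNG seed; the whole cohort is a deterministic
#'   function of the configuration.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_controls = 10L, n_sals = 20L, n_ropi = 13L,
                       n_placebo = 7L,
                       serum_weeks = c(0L, 13L, 24L, 39L, 48L),
                       csf_weeks = c(0L, 24L, 48L),
                       n_proteins = 1000L,
                       frac_inflammation_up = 0.10,
                       frac_upr_down = 0.10,
                       disease_shift_log10 = 0.3,
                       trend_slope_log10 = 0.3,
                       trend_scale = 1.0,
                       ropi_attenuation = 0.8,
                       batch_sd_log10 = 0.15,
                       noise_sd_log10 = 0.1,
                       lod_log10 = 5.0,
                       n_bridge = 3L,
                       baseline_mean_log10 = 6.5,
                       baseline_sd_log10 = 0.7,
                       a_log_mean = log(0.02),
                       a_log_sd = 0.5,
                       b_mean = 45,
                       b_sd = 2,
                       score_noise_sd = 1.0,
                       score_weeks = seq(0L, 60L, by = 4L),
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_ropi + cfg$n_placebo != cfg$n_sals)
    stop("n_ropi + n_placebo must equal n_sals")
  if (cfg$frac_inflammation_up + cfg$frac_upr_down > 1)
    stop("planted class fractions must sum to at most 1")
  sds <- c(cfg$batch_sd_log10, cfg$noise_sd_log10, cfg$baseline_sd_log10,
           cfg$a_log_sd, cfg$b_sd, cfg$score_noise_sd)
  if (any(sds < 0)) stop("standard deviations must be non-negative")
  if (cfg$ropi_attenuation < 0 || cfg$ropi_attenuation > 1)
    stop("ropi_attenuation must lie in [0, 1]")
  if (cfg$n_bridge > cfg$n_sals) stop("n_bridge cannot exceed n_sals")
  if (cfg$n_bridge < 0) stop("n_bridge must be non-negative")
  invisible(cfg)
}

## metadata label for a fluid table key
fluid_label <- function(key) c(serum = "serum", csf = "CSF")[[key]]

#' Evaluate the exponential ALSFRS-R model
#' @param a decay-rate parameter (> 0, per week).
#' @param b plateau parameter (score units).
#' @param week sampling week(s).
#' @return model value `-exp(a * week) + b`.
#' @export
alsfrs_model <- function(a, b, week) -exp(a * week) + b

#' Simulate one subject's ALSFRS-R series
#'
#' Scores follow `-exp(a * week) + b` plus normal noise, rounded and clipped
#' to the scale range 0..48.
#'
#' @param config a [sim_config()] (supplies schedule and noise sd).
#' @param a,b subject parameters.
#' @return data.frame with columns `week`, `alsfrs_r`.
#' @export
simulate_alsfrs <- function(config, a, b) {
  wk <- config$score_weeks
  eps <- stats::rnorm(length(wk), 0, config$score_noise_sd)
  score <- pmin(48, pmax(0, round(alsfrs_model(a, b, wk) + eps)))
  data.frame(week = wk, alsfrs_r = as.integer(score))
}

# Accumulated disease-coupled change by week t for one subject, with trend
# accrual attenuated by (1 - att) while the subject is on drug. The
# unattenuated accumulation is (b - aALSFRS)(t) = exp(a t), which starts at
# 1; exposure from week e onward scales subsequent increments, so
#   A(t) = exp(a t)                                    for t <= e
#   A(t) = exp(a e) + (1 - att) (exp(a t) - exp(a e))  for t >  e
# and the planted trend term is slope_p * (A(t) - 1), zero at baseline.
trend_accumulation <- function(a, week, exposure_start, attenuation) {
  e <- exposure_start
  ifelse(week <= e,
         exp(a * week),
         exp(a * e) + (1 - attenuation) * (exp(a * week) - exp(a * e)))
}

#' Simulate a full synthetic cohort with ground truth
#'
#' Generates raw-scale abundance tables for serum and CSF, sample metadata,
#' per-patient ALSFRS-R series, and the planted truth. The generative model
#' for the true log10 abundance of protein p in a sample from subject s at
#' week t is
#' \deqn{\mu_p + \delta_p 1[SALS] + s_p (A_s(t) - 1) + \beta_p 1[batch 2] + \epsilon}
#' where `delta_p` is the disease shift, `s_p` the progression-coupled trend
#' slope, `A_s(t)` the accumulated modelled decline with drug-exposed
#' increments attenuated by `ropi_attenuation`, `beta_p` the batch factor
#' and `epsilon` per-measurement noise. The observed raw intensity is
#' `10^true` when the true log10 value exceeds the detection limit and
#' missing otherwise. Bridge samples (week-0 draws of the first `n_bridge`
#' SALS subjects) are measured twice, once per batch, with independent
#' noise.
#'
#' @param config a [sim_config()].
#' @return list of class `ev_cohort` with elements `tables` (named list of
#'   raw `abundance_table`s per fluid), `info` (sample metadata for both
#'   fluids), `alsfrs` (clinical series), `truth` (planted parameters) and
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)

  n_p <- config$n_proteins
  protein_ids <- sprintf("PROT%04d", seq_len(n_p))

  ## exact class allocation, then random placement
  n_up <- round(config$frac_inflammation_up * n_p)
  n_dn <- round(config$frac_upr_down * n_p)
  cls <- rep("null", n_p)
  perm <- sample.int(n_p)
  cls[perm[seq_len(n_up)]] <- "inflammation_up"
  cls[perm[n_up + seq_len(n_dn)]] <- "upr_down"
  names(cls) <- protein_ids
  sign_p <- ifelse(cls == "inflammation_up", 1, ifelse(cls == "upr_down", -1, 0))

  ## subjects
  controls <- sprintf("C%02d", seq_len(config$n_controls))
  patients <- sprintf("P%02d", seq_len(config$n_sals))
  arm <- rep(c("ROPI", "placebo"), c(config$n_ropi, config$n_placebo))
  a_s <- exp(stats::rnorm(config$n_sals, config$a_log_mean, config$a_log_sd))
  b_s <- stats::rnorm(config$n_sals, config$b_mean, config$b_sd)
  subjects <- data.frame(subject_id = patients, arm = arm, a = a_s, b = b_s,
                         stringsAsFactors = FALSE)
  exposure_start <- ifelse(arm == "ROPI", 0, 24)
  bridge_subjects <- patients[seq_len(config$n_bridge)]

  alsfrs <- do.call(rbind, lapply(seq_len(config$n_sals), function(i) {
    cbind(subject_id = patients[i], simulate_alsfrs(config, a_s[i], b_s[i]))
  }))
  alsfrs <- validate_alsfrs(alsfrs)

  weeks_by_fluid <- list(serum = config$serum_weeks, csf = config$csf_weeks)
  tables <- list()
  truth_fluid <- list()
  info_all <- list()

  for (fluid in names(weeks_by_fluid)) {
    wks <- weeks_by_fluid[[fluid]]
    mu <- stats::rnorm(n_p, config$baseline_mean_log10, config$baseline_sd_log10)
    beta <- stats::rnorm(n_p, 0, config$batch_sd_log10)
    delta <- sign_p * config$disease_shift_log10
    slope <- sign_p * config$trend_slope_log10 * config$trend_scale
    pre <- substr(fluid, 1, 3)

    ## sample layout: SALS longitudinal (batch 1), controls (batch 2),
    ## bridge re-measurements (batch 2)
    sals_grid <- expand.grid(subject = patients, week = wks,
                             stringsAsFactors = FALSE)
    sals_grid <- sals_grid[order(sals_grid$subject, sals_grid$week), ]
    smp <- data.frame(
      sample_id = c(sprintf("%s_%s_w%02d", pre, sals_grid$subject, sals_grid$week),
                    sprintf("%s_%s_w00", pre, controls),
                    sprintf("%s_%s_w00_b2", pre, bridge_subjects)),
      subject_id = c(sals_grid$subject, controls, bridge_subjects),
      cohort = c(rep("SALS", nrow(sals_grid)), rep("control", length(controls)),
                 rep("SALS", length(bridge_subjects))),
      fluid = fluid_label(fluid),
      week = c(sals_grid$week, rep(0L, length(controls)),
               rep(0L, length(bridge_subjects))),
      batch = c(rep(1L, nrow(sals_grid)), rep(2L, length(controls)),
                rep(2L, length(bridge_subjects))),
      stringsAsFactors = FALSE)
    smp$arm <- ifelse(smp$cohort == "control", "none",
                      subjects$arm[match(smp$subject_id, subjects$subject_id)])
    smp$ropi_exposed <- ropi_exposure(smp$arm, smp$week)
    smp <- validate_sample_info(smp)

    ## per-sample accumulated trend (controls: no disease component at all)
    idx <- match(smp$subject_id, subjects$subject_id)
    is_sals <- smp$cohort == "SALS"
    A <- rep(1, nrow(smp))
    A[is_sals] <- trend_accumulation(a_s[idx[is_sals]], smp$week[is_sals],
                                     exposure_start[idx[is_sals]],
                                     config$ropi_attenuation)
    true_log10 <- matrix(mu, n_p, nrow(smp)) +
      delta %o% as.numeric(is_sals) +
      slope %o% (A - 1) +
      beta %o% as.numeric(smp$batch == 2L) +
      matrix(stats::rnorm(n_p * nrow(smp), 0, config$noise_sd_log10),
             n_p, nrow(smp))
    dimnames(true_log10) <- list(protein_ids, smp$sample_id)

    raw <- 10^true_log10
    raw[true_log10 <= config$lod_log10] <- NA_real_
    tables[[fluid]] <- abundance_table(raw, scale = "raw")
    truth_fluid[[fluid]] <- list(baseline_log10 = stats::setNames(mu, protein_ids),
                                 batch_log10 = stats::setNames(beta, protein_ids),
                                 disease_shift = stats::setNames(delta, protein_ids),
                                 trend_slope = stats::setNames(slope, protein_ids))
    info_all[[fluid]] <- smp
  }

  structure(list(tables = tables,
                 info = do.call(rbind, c(info_all, make.row.names = FALSE)),
                 alsfrs = alsfrs,
                 truth = list(protein_class = cls,
                              subjects = subjects,
                              bridge_subjects = bridge_subjects,
                              fluid = truth_fluid),
                 config = config),
            class = "ev_cohort")
}

#' @export
print.ev_cohort <- function(x, ...) {
  cat("synthetic EV cohort:", x$config$n_controls, "controls,",
      x$config$n_sals, "SALS patients;",
      x$config$n_proteins, "proteins per fluid\n")
  invisible(x)
}

#' Bridge sample pairs of a cohort
#'
#' @param cohort an `ev_cohort`.
#' @param fluid `"serum"` or `"csf"`.
#' @return data.frame with columns `sample_b1`, `sample_b2`: the batch-1 and
#'   batch-2 measurement ids of each bridge sample.
#' @export
bridge_pairs <- function(cohort, fluid = c("serum", "csf")) {
  fluid <- match.arg(fluid)
  pre <- substr(fluid, 1, 3)
  bs <- cohort$truth$bridge_subjects
  data.frame(sample_b1 = sprintf("%s_%s_w00", pre, bs),
             sample_b2 = sprintf("%s_%s_w00_b2", pre, bs),
             stringsAsFactors = FALSE)
}

#' Write the cohort artefacts to a directory
#'
#' Emits the abundance matrix and metadata TSVs per fluid, the clinical
#' score series, the planted truth tables, and a JSON manifest recording
#' the configuration (including the seed).
#'
#' @param cohort an `ev_cohort`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (fluid in names(cohort$tables))
    write_abundance(cohort$tables[[fluid]],
                    file.path(outdir, paste0("abundance_", fluid, ".tsv")))
  write_sample_info(cohort$info, file.path(outdir, "sample_info.tsv"))
  utils::write.table(cohort$alsfrs, file.path(outdir, "alsfrs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- data.frame(protein_id = names(cohort$truth$protein_class),
                      class = unname(cohort$truth$protein_class))
  for (fluid in names(cohort$truth$fluid)) {
    tf <- cohort$truth$fluid[[fluid]]
    truth[[paste0(fluid, "_trend_slope")]] <- unname(tf$trend_slope)
    truth[[paste0(fluid, "_disease_shift")]] <- unname(tf$disease_shift)
    truth[[paste0(fluid, "_batch_log10")]] <- unname(tf$batch_log10)
  }
  utils::write.table(truth, file.path(outdir, "truth_proteins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$subjects, file.path(outdir, "truth_subjects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
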