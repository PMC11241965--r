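#' Default pipeline configuration
#'
#' A single top-level `seed` is fanned out to the per-stage seeds by fixed
#' offsets, so one knob reproduces a whole run. Stage blocks mirror the
#' analysis stages: simulation (or input paths), differential abundance,
#' effect-size scoring, trajectory clustering, biomarker ranking, and the
#' classifier experiment.
#'
#' @param seed top-level seed.
#' @param outdir output directory.
#' @return nested configuration list.
#' @export
pipeline_config <- function(seed = 1L, outdir = "evprot_run") {
  list(seed = seed,
       outdir = outdir,
       simulation = list(),          # overrides for sim_config()
       inputs = NULL,                # or list(serum=, csf=, sample_info=, alsfrs=)
       dap = list(q_threshold = 0.05, week = 0),
       esdap = list(week = 24, threshold = 0.5),
       trajectory = list(k = 3),
       biomarkers = list(week = 0, cutoff = 0.5),
       ml = list(enabled = TRUE, fluid = "serum",
                 families = c("random_forest", "decision_tree", "perceptron")))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Chains the whole workflow — simulate (or load), bridge-ratio batch
#' correction, log10 transform, detection filters, control-versus-patient
#' differential abundance, effect-size drug scoring, placebo trajectory
#' clustering with arm transfer and ANOVA, signed-set cosine similarity,
#' divergence trajectories, progression modelling with biomarker ranking,
#' and the diagnostic-classifier experiment — writing one TSV per stage
#' plus a JSON manifest of configuration, seeds and row counts. A rerun
#' with the same configuration is bit-identical.
#'
#' @param config a [pipeline_config()]-style list, a partial override of
#'   it, or a path to a YAML file with the same structure.
#' @return the manifest, invisibly. Stage failures abort with the stage
#'   name and cause.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(pipeline_config(), config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  counts <- list()
  emit <- function(d, name) {
    path <- write_tsv(d, file.path(cfg$outdir, paste0(name, ".tsv")))
    outputs[[name]] <<- basename(path)
    counts[[name]] <<- nrow(d)
    invisible(d)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## ---- inputs --------------------------------------------------------
  cohort <- stage("inputs", {
    if (is.null(cfg$inputs)) {
      sim_args <- merge_config(list(seed = cfg$seed), cfg$simulation)
      simulate_cohort(do.call(sim_config, sim_args))
    } else {
      list(tables = list(serum = read_abundance(cfg$inputs$serum),
                         csf = read_abundance(cfg$inputs$csf)),
           info = read_sample_info(cfg$inputs$sample_info),
           alsfrs = read_alsfrs(cfg$inputs$alsfrs),
           truth = NULL, config = NULL)
    }
  })
  emit(cohort$info, "sample_info")

  fluids <- names(cohort$tables)
  corrected <- list(); log10_tab <- list()
  dap <- list(); esdap <- list(); clusters <- list(); universes <- list()

  for (fluid in fluids) {
    info_f <- cohort$info[cohort$info$fluid == fluid_label(fluid), , drop = FALSE]
    tab <- cohort$tables[[fluid]]

    ## ---- batch correction -------------------------------------------
    merged <- stage(paste0("batch_correction_", fluid), {
      b1 <- info_f$sample_id[info_f$batch == 1L]
      b2 <- info_f$sample_id[info_f$batch == 2L]
      ## bridge pairs: batch-2 re-measurements share the subject and week
      ## of a batch-1 sample
      b2_info <- info_f[info_f$batch == 2L & info_f$cohort == "SALS", ]
      b1_match <- vapply(seq_len(nrow(b2_info)), function(i) {
        hit <- info_f$sample_id[info_f$batch == 1L &
                                info_f$subject_id == b2_info$subject_id[i] &
                                info_f$week == b2_info$week[i]]
        if (length(hit)) hit[1L] else NA_character_
      }, character(1))
      pairs <- data.frame(sample_b1 = b1_match,
                          sample_b2 = b2_info$sample_id,
                          stringsAsFactors = FALSE)
      pairs <- pairs[!is.na(pairs$sample_b1), , drop = FALSE]
      if (nrow(pairs) == 0L)
        stop("no bridge pairs found between the batches")
      correct_and_merge(tab[, b1], tab[, b2], pairs)$table
    })
    corrected[[fluid]] <- merged
    log10_tab[[fluid]] <- to_log10(merged)
    emit(data.frame(protein_id = rownames(merged),
                    round(unclass(log10_tab[[fluid]]), 6),
                    check.names = FALSE),
         paste0("corrected_log10_", fluid))

    ## ---- universes and differential abundance ------------------------
    info_m <- info_f[info_f$sample_id %in% colnames(merged), , drop = FALSE]
    ctrl_ids <- info_m$sample_id[info_m$cohort == "control"]
    naive0 <- info_m$sample_id[info_m$cohort == "SALS" & info_m$week == cfg$dap$week &
                               !info_m$ropi_exposed]
    universes[[fluid]] <- stage(paste0("universe_", fluid),
                                complete_proteins(merged, c(ctrl_ids, naive0)))
    dap[[fluid]] <- stage(paste0("dap_", fluid),
      differential_abundance(log10_tab[[fluid]][universes[[fluid]], ],
                             control_ids = ctrl_ids, case_ids = naive0,
                             q_threshold = cfg$dap$q_threshold))
    emit(as.data.frame(dap[[fluid]]), paste0("dap_", fluid))

    sals_spec <- stage(paste0("sals_specific_", fluid), {
      naive_all <- info_m$sample_id[info_m$cohort == "SALS" & !info_m$ropi_exposed]
      sals_specific_proteins(merged, naive_all, ctrl_ids)
    })
    emit(data.frame(protein_id = sals_spec), paste0("sals_specific_", fluid))

    ## ---- effect-size drug scoring ------------------------------------
    esdap[[fluid]] <- stage(paste0("esdap_", fluid), {
      fc <- per_patient_log2fc(merged, info_m, week = cfg$esdap$week)
      es_dap_table(fc[universes[[fluid]], , drop = FALSE], info_m,
                   es_threshold = cfg$esdap$threshold)
    })
    emit(as.data.frame(esdap[[fluid]]), paste0("esdap_", fluid))

    ## ---- trajectory clustering ---------------------------------------
    clusters[[fluid]] <- stage(paste0("trajectory_", fluid), {
      weeks <- sort(setdiff(unique(info_m$week[info_m$cohort == "SALS"]), 0))
      traj <- trajectory_matrix(merged, info_m, weeks, arm = "placebo")
      model <- fit_trajectory_clusters(traj[universes[[fluid]], , drop = FALSE],
                                       k = cfg$trajectory$k)
      tests <- transfer_and_test(model, merged, info_m, weeks)
      list(model = model, tests = tests, weeks = weeks)
    })
    emit(data.frame(protein_id = names(clusters[[fluid]]$model$labels),
                    label = unname(clusters[[fluid]]$model$labels)),
         paste0("clusters_", fluid))
    anova_rows <- do.call(rbind, lapply(names(clusters[[fluid]]$tests), function(lab) {
      t <- clusters[[fluid]]$tests[[lab]]
      data.frame(label = lab, n_proteins = t$n_proteins,
                 p_treatment = t$p_treatment)
    }))
    emit(anova_rows, paste0("anova_", fluid))
  }

  ## ---- cross-set similarity ------------------------------------------
  sim <- stage("similarity", {
    universe <- sort(unique(unlist(lapply(corrected, rownames))))
    sets <- list()
    for (fluid in fluids) {
      d <- dap[[fluid]]
      sets[[paste0("dap_", fluid)]] <- signed_set_vector(
        universe,
        up = d$protein_id[d$is_dap & d$direction == "up_in_case"],
        down = d$protein_id[d$is_dap & d$direction == "down_in_case"])
      e <- esdap[[fluid]]
      sets[[paste0("esdap_", fluid)]] <- signed_set_vector(
        universe,
        up = e$protein_id[e$is_es_dap & e$direction == "increased_by_ropi"],
        down = e$protein_id[e$is_es_dap & e$direction == "decreased_by_ropi"])
      lab <- clusters[[fluid]]$model$labels
      sets[[paste0("time_", fluid)]] <- signed_set_vector(
        universe,
        up = names(lab)[lab == "increased"],
        down = names(lab)[lab == "decreased"])
    }
    similarity_heatmap(sets)
  })
  emit(data.frame(set = rownames(sim$matrix), round(sim$matrix, 6),
                  check.names = FALSE), "similarity")

  ## ---- divergence trajectories ---------------------------------------
  for (fluid in fluids) {
    div <- stage(paste0("divergence_", fluid), {
      d <- dap[[fluid]]; lab <- clusters[[fluid]]$model$labels
      up <- union(d$protein_id[d$is_dap & d$direction == "up_in_case"],
                  names(lab)[lab == "increased"])
      down <- union(d$protein_id[d$is_dap & d$direction == "down_in_case"],
                    names(lab)[lab == "decreased"])
      info_f <- cohort$info[cohort$info$fluid == fluid_label(fluid), , drop = FALSE]
      divergence_trajectory(log10_tab[[fluid]], info_f, up, down)
    })
    emit(div, paste0("divergence_", fluid))
  }

  ## ---- serum/CSF paired profile correlation ---------------------------
  paired <- stage("paired_correlation",
                  paired_profile_correlation(log10_tab$serum, log10_tab$csf,
                                             cohort$info))
  emit(paired$correlations, "paired_correlation")

  ## ---- progression modelling and biomarkers ---------------------------
  fits <- stage("progression", {
    arms <- with(unique(cohort$info[cohort$info$cohort == "SALS",
                                    c("subject_id", "arm")]),
                 stats::setNames(arm, subject_id))
    fit_progression_all(cohort$alsfrs, arms = arms)
  })
  emit(fits, "progression_fits")

  for (fluid in fluids) {
    bm <- stage(paste0("biomarkers_", fluid), {
      target <- stats::setNames(fits$adj_a, fits$subject_id)
      target <- target[!is.na(target)]
      info_f <- cohort$info[cohort$info$fluid == fluid_label(fluid), , drop = FALSE]
      rank_biomarkers(log10_tab[[fluid]], info_f, target,
                      week = cfg$biomarkers$week,
                      cutoff = cfg$biomarkers$cutoff)
    })
    emit(bm$ranking, paste0("biomarkers_", fluid))
  }

  ## ---- diagnostic classifiers -----------------------------------------
  if (isTRUE(cfg$ml$enabled)) {
    mlres <- stage("ml", {
      fluid <- cfg$ml$fluid
      ds <- ml_dataset_from_cohort(corrected[[fluid]],
                                   cohort$info[cohort$info$fluid == fluid_label(fluid), ])
      mc <- ml_config(seed = cfg$seed + 110L, families = cfg$ml$families)
      run_ml_experiment(ds$x, ds$y, ds$validations, mc)
    })
    emit(as.data.frame(mlres), "ml_results")
  }

  manifest <- list(config = cfg, outputs = as.list(outputs),
                   counts = counts)
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
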