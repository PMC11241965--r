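test_that("separable trajectories cluster into correctly labelled singletons", {
  traj <- rbind(up = c(1, 2), flat = c(0, 0), down = c(-1, -2))
  colnames(traj) <- c("w13", "w24")
  model <- fit_trajectory_clusters(traj, k = 3)
  expect_identical(unname(model$labels[c("up", "flat", "down")]),
                   c("increased", "unchanged", "decreased"))
  # input order never changes the labelling
  shuffled <- traj[c(3, 1, 2), ]
  model2 <- fit_trajectory_clusters(shuffled, k = 3)
  expect_identical(model2$labels[names(model$labels)], model$labels)
})

test_that("ward merges follow the exhaustive minimum-cost sequence", {
  set.seed(53)
  for (rep in 1:10) {
    n <- sample(5:8, 1)
    x <- matrix(rnorm(n), ncol = 1)
    hc <- stats::hclust(stats::dist(x), method = "ward.D2")
    got <- hclust_partitions(hc, n)
    want <- ward_oracle(x)
    for (step in seq_along(want))
      expect_identical(got[[step]], want[[step]])
  }
  # merge heights never decrease along the dendrogram
  x <- matrix(rnorm(12), ncol = 1)
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  expect_true(all(diff(hc$height) >= -1e-12))
})

test_that("incomplete trajectories are dropped and labelled unchanged", {
  traj <- rbind(a = c(1, 2), b = c(0, NA), c = c(0, 0.01), d = c(-1, -2))
  colnames(traj) <- c("w13", "w24")
  model <- fit_trajectory_clusters(traj, k = 3)
  expect_identical(model$dropped, "b")
  expect_identical(unname(model$labels["b"]), "unchanged")
  expect_error(fit_trajectory_clusters(traj[c(1, 2), ], k = 3), "at least k")
})

test_that("cluster labels depend on placebo data only and recover planted trends", {
  cfg <- quiet_config(seed = 61, n_proteins = 60)
  co <- simulate_cohort(cfg)
  prep <- serum_prep(co)
  weeks <- c(13, 24, 39, 48)
  traj <- trajectory_matrix(prep$merged, prep$info, weeks, arm = "placebo")
  expect_identical(sort(attr(traj, "subjects")),
                   sort(co$truth$subjects$subject_id[co$truth$subjects$arm == "placebo"]))
  model <- fit_trajectory_clusters(traj, k = 3)
  cls <- co$truth$protein_class
  expect_true(all(model$labels[names(cls)[cls == "inflammation_up"]] == "increased"))
  expect_true(all(model$labels[names(cls)[cls == "upr_down"]] == "decreased"))
  expect_true(all(model$labels[names(cls)[cls == "null"]] == "unchanged"))
})

test_that("two-factor ANOVA agrees with hand-computed sums of squares", {
  # measurement noise is needed here: without it the proteins of a planted
  # class share one exact trajectory and the residual variance degenerates
  cfg <- sim_config(seed = 67, n_proteins = 60)
  co <- simulate_cohort(cfg)
  prep <- serum_prep(co)
  weeks <- c(13, 24, 39, 48)
  traj <- trajectory_matrix(prep$merged, prep$info, weeks, arm = "placebo")
  model <- fit_trajectory_clusters(traj, k = 3)
  out <- transfer_and_test(model, prep$merged, prep$info, weeks)
  expect_named(out, c("increased", "decreased"))

  # independent check of the treatment sum of squares on the same data:
  # rebuild the long table for the increased label and compute Type-III
  # F for the treatment factor by explicit model comparison
  members <- names(model$labels)[model$labels == "increased"]
  tr_r <- trajectory_matrix(prep$merged, prep$info, weeks, arm = "ROPI")
  long <- rbind(
    data.frame(arm = "placebo", week = rep(colnames(traj), each = length(members)),
               value = as.vector(traj[members, ])),
    data.frame(arm = "ROPI", week = rep(colnames(tr_r), each = length(members)),
               value = as.vector(tr_r[members, ])))
  long$arm <- factor(long$arm, levels = c("placebo", "ROPI"))
  long$week <- factor(long$week)
  # explicit Type-III computation: drop the arm column from the
  # sum-contrast design matrix and compare residual sums of squares
  X <- stats::model.matrix(~ arm * week, long,
                           contrasts.arg = list(arm = "contr.sum",
                                                week = "contr.sum"))
  full_fit <- stats::lm.fit(X, long$value)
  red_fit <- stats::lm.fit(X[, colnames(X) != "arm1", drop = FALSE],
                           long$value)
  rss_full <- sum(full_fit$residuals^2)
  df_res <- length(long$value) - ncol(X)
  ss_arm <- sum(red_fit$residuals^2) - rss_full
  f_arm <- (ss_arm / 1) / (rss_full / df_res)
  p_arm <- pf(f_arm, 1, df_res, lower.tail = FALSE)
  expect_equal(out$increased$p_treatment, p_arm, tolerance = 1e-6)

  # planted drug attenuation shows as a strong treatment effect both ways
  expect_lt(out$increased$p_treatment, 1e-3)
  expect_lt(out$decreased$p_treatment, 1e-3)
  # Bonferroni contrast adjustment is min(1, m * p)
  for (lab in names(out)) {
    cc <- out[[lab]]$contrasts
    expect_equal(cc$p_bonferroni, pmin(1, cc$p.value * nrow(cc)))
  }
})

test_that("identical arm data yield a null treatment effect", {
  # two subjects per arm whose per-protein arm-mean fold changes are
  # identical across arms by construction
  base_fc <- rbind(P1 = c(1, 2), P2 = c(1.4, 2.6),   # increasing
                   P3 = c(0, 0), P4 = c(0.05, -0.05), # flat
                   P5 = c(-1, -2), P6 = c(-1.3, -2.5)) # decreasing
  weeks <- c(13, 24)
  subj <- c(R1 = "ROPI", R2 = "ROPI", Q1 = "placebo", Q2 = "placebo")
  offset <- c(R1 = 0.1, R2 = -0.1, Q1 = 0.1, Q2 = -0.1)
  cols <- list()
  for (s in names(subj)) {
    cols[[sprintf("s_%s_w00", s)]] <- rep(100, nrow(base_fc))
    for (wi in seq_along(weeks))
      cols[[sprintf("s_%s_w%02d", s, weeks[wi])]] <-
        100 * 2^(base_fc[, wi] + offset[[s]])
  }
  tab <- abundance_table(do.call(cbind, cols) |>
                           `rownames<-`(rownames(base_fc)))
  info <- validate_sample_info(data.frame(
    sample_id = colnames(tab),
    subject_id = rep(names(subj), each = 3),
    cohort = "SALS", fluid = "serum",
    week = rep(c(0, weeks), 4),
    arm = rep(unname(subj), each = 3), batch = 1L))
  traj <- trajectory_matrix(tab, info, weeks, arm = "placebo")
  model <- fit_trajectory_clusters(traj, k = 3)
  out <- transfer_and_test(model, tab, info, weeks)
  for (lab in names(out)) {
    an <- out[[lab]]$anova
    expect_lt(an["arm", "F value"], 1e-10)   # arm means coincide exactly
    expect_gt(out[[lab]]$p_treatment, 0.999)
  }
})
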