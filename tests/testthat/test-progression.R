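test_that("noiseless series recover their generating parameters exactly", {
  wk <- seq(0, 60, 4)
  f <- fit_progression(wk, alsfrs_model(0.05, 45, wk))
  expect_true(f$converged)
  expect_lt(abs(f$a - 0.05), 1e-6)
  expect_lt(abs(f$b - 45), 1e-6)
  # a different regime, sparse sampling
  wk2 <- c(0, 13, 24, 39, 48)
  f2 <- fit_progression(wk2, alsfrs_model(0.012, 43, wk2))
  expect_lt(abs(f2$a - 0.012), 1e-6)
})

test_that("degenerate flat series pin the decay rate at its lower bound", {
  f <- fit_progression(seq(0, 40, 8), rep(40, 6))
  expect_true(f$at_bound)
  expect_equal(f$b, 41, tolerance = 1e-4)  # b - exp(0) = 40
  expect_error(fit_progression(c(0, 0, 0), c(40, 41, 40)), "distinct weeks")
  expect_error(fit_progression(c(0, 4), c(44, 43)), "at least 3")
})

test_that("model evaluation and its derivative follow the closed forms", {
  fit <- list(a = 0.05, b = 45)
  expect_equal(aalsfrs(fit, 0), 44)
  expect_equal(fixed_point_rate(fit, 0), -0.05)
  expect_equal(aalsfrs(fit, 24), 45 - exp(1.2))
  expect_equal(aalsfrs(fit, 24), 41.6799, tolerance = 1e-4)
  expect_equal(fixed_point_rate(fit, 24), -0.05 * exp(1.2))
  expect_equal(fixed_point_rate(fit, 24), -0.16601, tolerance = 1e-4)
  # the rate is the analytic derivative of the curve
  h <- 1e-6
  for (w in c(0, 10, 30, 55)) {
    num <- (aalsfrs(fit, w + h) - aalsfrs(fit, w - h)) / (2 * h)
    expect_lt(abs(num - fixed_point_rate(fit, w)) / abs(fixed_point_rate(fit, w)),
              1e-4)
  }
  # strictly decreasing rate for a > 0
  rates <- fixed_point_rate(fit, seq(0, 60, 4))
  expect_true(all(diff(rates) < 0))
})

test_that("adj-a is the within-arm z-score of -log10(a)", {
  fits <- data.frame(subject_id = c("p1", "p2", "q1", "q2", "q3"),
                     a = c(0.01, 0.1, 0.02, 0.02, 0.05),
                     b = 45, rss = 0, converged = TRUE, at_bound = FALSE,
                     arm = c("ROPI", "ROPI", "placebo", "placebo", "placebo"))
  out <- adj_a(fits)
  # -log10 a = {2, 1}: two-point z-scores with sample sd are +-1/sqrt(2)
  expect_equal(out$adj_a[1:2], c(1, -1) / sqrt(2), tolerance = 1e-12)
  # within-arm mean 0, sample sd 1
  for (g in unique(out$arm)) {
    v <- out$adj_a[out$arm == g]
    expect_equal(mean(v), 0, tolerance = 1e-12)
    expect_equal(stats::sd(v), 1, tolerance = 1e-12)
  }
  # smaller a (slower progression) always maps to larger adj_a
  expect_gt(out$adj_a[1], out$adj_a[2])
  degen <- fits
  degen$a[degen$arm == "ROPI"] <- 0.02
  expect_warning(out2 <- adj_a(degen), "zero spread")
  expect_true(all(is.na(out2$adj_a[out2$arm == "ROPI"])))
})

test_that("parameter recovery improves monotonically as score noise vanishes", {
  wk <- seq(0, 60, 4)
  errs <- sapply(c(2, 0.5, 0), function(noise) {
    set.seed(89)
    median(replicate(30, {
      a <- exp(rnorm(1, log(0.02), 0.5)); b <- rnorm(1, 45, 2)
      sc <- alsfrs_model(a, b, wk) + rnorm(length(wk), 0, noise)
      abs(fit_progression(wk, sc)$a - a) / a
    }))
  })
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[3], 1e-6)
})

test_that("whole-cohort fits feed the prognostic index", {
  co <- simulate_cohort(sim_config(seed = 97, n_proteins = 50))
  arms <- with(co$truth$subjects, stats::setNames(arm, subject_id))
  fits <- fit_progression_all(co$alsfrs, arms = arms)
  expect_identical(nrow(fits), 20L)
  expect_true(all(fits$converged))
  merged <- merge(fits, co$truth$subjects, by = "subject_id")
  # slow progressors can be indistinguishable from flat under unit score
  # noise (their fits pin at the lower bound); away from that regime the
  # recovered decay rates track the planted ones closely
  expect_lte(sum(merged$at_bound), 3)
  ok <- !merged$at_bound
  expect_gt(stats::cor(log(merged$a.x[ok]), log(merged$a.y[ok])), 0.7)
  expect_lt(median(abs(merged$a.x - merged$a.y) / merged$a.y), 0.25)
  # the prognostic index exists for every converged non-degenerate fit
  expect_true(all(!is.na(merged$adj_a)))
})

test_that("biomarker ranking finds a protein affinely tied to the target", {
  set.seed(101)
  n_sub <- 12
  target <- stats::setNames(rnorm(n_sub), sprintf("S%02d", 1:n_sub))
  prot <- sprintf("P%02d", 1:20)
  m <- matrix(rnorm(20 * n_sub, 6, 0.5), 20, n_sub,
              dimnames = list(prot, sprintf("ser_S%02d_w00", 1:n_sub)))
  m["P07", ] <- 6 + 0.8 * target         # perfect affine predictor
  m["P11", ] <- 6 - 0.5 * target         # perfect negative predictor
  tab <- abundance_table(m, scale = "log10")
  info <- validate_sample_info(data.frame(
    sample_id = colnames(m), subject_id = names(target),
    cohort = "SALS", fluid = "serum", week = 0, arm = "ROPI", batch = 1L))
  bm <- rank_biomarkers(tab, info, target)
  rk <- bm$ranking
  expect_equal(rk$r[rk$protein_id == "P07"], 1, tolerance = 1e-12)
  expect_equal(rk$r[rk$protein_id == "P11"], -1, tolerance = 1e-12)
  expect_identical(rk$protein_id[1], "P07")
  expect_identical(rk$protein_id[nrow(rk)], "P11")
  expect_true("P07" %in% bm$top_positive)
  expect_true("P11" %in% bm$top_negative)
  expect_identical(sort(rk$rank), seq_len(nrow(rk)))
  # p-values match cor.test
  ct <- stats::cor.test(m["P01", ], target)
  expect_equal(rk$p_value[rk$protein_id == "P01"], ct$p.value, tolerance = 1e-12)
})

test_that("a planted bivariate correlation is recovered at realistic n", {
  set.seed(103)
  n_sub <- 20
  rho <- 0.8
  z <- rnorm(n_sub)
  target <- stats::setNames(z, sprintf("S%02d", 1:n_sub))
  m <- matrix(rnorm(10 * n_sub, 6, 1), 10, n_sub,
              dimnames = list(sprintf("P%02d", 1:10),
                              sprintf("ser_S%02d_w00", 1:n_sub)))
  m["P03", ] <- 6 + rho * z + sqrt(1 - rho^2) * rnorm(n_sub)
  tab <- abundance_table(m, scale = "log10")
  info <- validate_sample_info(data.frame(
    sample_id = colnames(m), subject_id = names(target),
    cohort = "SALS", fluid = "serum", week = 0, arm = "ROPI", batch = 1L))
  bm <- rank_biomarkers(tab, info, target)
  got <- bm$ranking$r[bm$ranking$protein_id == "P03"]
  expect_lt(abs(got - rho), 0.15)
})
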