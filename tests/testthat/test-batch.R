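make_batches <- function(x1, x2, y) {
  b1 <- toy_table(matrix(x1, 1, length(x1),
                         dimnames = list("P1", paste0("b1_", seq_along(x1)))))
  b2 <- toy_table(matrix(c(x2, y), 1, length(x2) + length(y),
                         dimnames = list("P1", c(paste0("b2_", seq_along(x2)),
                                                 paste0("y", seq_along(y))))))
  pairs <- data.frame(sample_b1 = paste0("b1_", seq_along(x1)),
                      sample_b2 = paste0("b2_", seq_along(x2)))
  list(b1 = b1, b2 = b2, pairs = pairs)
}

test_that("the published worked example reproduces f = 31/30 and Z = 290.3226", {
  w <- make_batches(c(100, 200, 400), c(110, 180, 440), y = 300)
  ratios <- compute_bridge_ratios(w$b1, w$b2, w$pairs)
  expect_equal(ratios$f, (1.1 + 0.9 + 1.1) / 3, tolerance = 1e-12)
  expect_equal(ratios$f, 31 / 30, tolerance = 1e-12)
  expect_identical(ratios$n_used, 3L)
  corrected <- apply_batch_correction(w$b2, ratios)
  expect_equal(unclass(corrected)[1, "y1"], 300 / (31 / 30), tolerance = 1e-12)
  expect_equal(unclass(corrected)[1, "y1"], 290.3226, tolerance = 1e-6)
})

test_that("identity and constant-ratio bridges give f = 1 and f = 2", {
  same <- make_batches(c(100, 200, 400), c(100, 200, 400), y = 123)
  expect_equal(compute_bridge_ratios(same$b1, same$b2, same$pairs)$f, 1)
  twice <- make_batches(c(100, 200, 400), c(200, 400, 800), y = 123)
  r2 <- compute_bridge_ratios(twice$b1, twice$b2, twice$pairs)
  expect_equal(r2$f, 2)
  expect_equal(unclass(apply_batch_correction(twice$b2, r2))[1, "y1"], 61.5)
})

test_that("missing bridge members are dropped from the mean; f undefined at zero pairs", {
  w <- make_batches(c(100, NA, 400), c(110, 180, NA), y = 300)
  r <- compute_bridge_ratios(w$b1, w$b2, w$pairs)
  expect_identical(r$n_used, 1L)
  expect_equal(r$f, 1.1)
  # requiring all pairs marks the factor undefined, and correction
  # propagates the missingness
  r_strict <- compute_bridge_ratios(w$b1, w$b2, w$pairs, min_pairs = 3)
  expect_true(is.na(r_strict$f))
  corrected <- apply_batch_correction(w$b2, r_strict)
  expect_true(all(is.na(unclass(corrected))))
  # missing measurement stays missing after correction
  y_na <- make_batches(c(100, 200, 400), c(110, 180, 440), y = c(300, NA))
  rr <- compute_bridge_ratios(y_na$b1, y_na$b2, y_na$pairs)
  out <- apply_batch_correction(y_na$b2, rr)
  expect_true(is.na(unclass(out)[1, "y2"]))
  expect_false(is.na(unclass(out)[1, "y1"]))
})

test_that("zero batch-1 bridge intensity is skipped with a warning", {
  b1 <- abundance_table(matrix(c(0, 200), 1, 2,
                               dimnames = list("P1", c("a1", "a2"))))
  b2 <- toy_table(matrix(c(110, 400), 1, 2,
                         dimnames = list("P1", c("c1", "c2"))))
  pairs <- data.frame(sample_b1 = c("a1", "a2"), sample_b2 = c("c1", "c2"))
  expect_warning(r <- compute_bridge_ratios(b1, b2, pairs), "zero batch-1")
  expect_identical(r$n_used, 1L)
  expect_equal(r$f, 2)
})

test_that("noise-free multiplicative batch effects are removed exactly", {
  cfg <- sim_config(n_proteins = 60, noise_sd_log10 = 0, lod_log10 = -Inf,
                    score_noise_sd = 0, seed = 21)   # batch_sd stays 0.15
  co <- simulate_cohort(cfg)
  prep <- serum_prep(co)
  tr <- co$truth$fluid$serum
  # every bridge ratio equals the planted factor, so f recovers it exactly
  expect_equal(unname(prep$ratios$f), unname(10^tr$batch_log10),
               tolerance = 1e-12)
  # corrected control values equal the batch-free generative values
  ctrl <- prep$info$sample_id[prep$info$cohort == "control"]
  expected <- 10^tr$baseline_log10
  for (s in ctrl) {
    rel <- abs(unclass(prep$merged)[, s] - expected) / expected
    expect_lt(max(rel), 1e-10)
  }
})

test_that("correction is idempotent and preserves within-batch rank order", {
  set.seed(14)
  n <- 25
  b1 <- toy_table(matrix(10^runif(n * 4, 4, 8), n, 4,
                         dimnames = list(NULL, paste0("x", 1:4))))
  g <- 10^rnorm(n, 0, 0.2)
  b2_vals <- unclass(b1) * g
  extra <- matrix(10^runif(n * 3, 4, 8) * g, n, 3)
  b2 <- abundance_table(cbind(b2_vals, extra)[, , drop = FALSE] |>
                          `dimnames<-`(list(rownames(b1),
                                            c(paste0("xx", 1:4), paste0("v", 1:3)))))
  pairs <- data.frame(sample_b1 = paste0("x", 1:4), sample_b2 = paste0("xx", 1:4))
  r1 <- compute_bridge_ratios(b1, b2, pairs)
  c1 <- apply_batch_correction(b2, r1)
  # after one pass the recomputed factors are 1 and a second pass is a no-op
  r2 <- compute_bridge_ratios(b1, c1, pairs)
  expect_equal(r2$f, rep(1, n), tolerance = 1e-12)
  c2 <- apply_batch_correction(c1, r2)
  expect_equal(unclass(c2), unclass(c1), tolerance = 1e-12)
  # per-protein division by a positive constant preserves sample ranks
  for (p in 1:5)
    expect_identical(order(unclass(c1)[p, ]), order(unclass(b2)[p, ]))
})

test_that("merging passes batch-1 samples through unchanged", {
  w <- make_batches(c(100, 200, 400), c(110, 180, 440), y = 300)
  cm <- correct_and_merge(w$b1, w$b2, w$pairs)
  expect_true(all(paste0("b1_", 1:3) %in% colnames(cm$table)))
  expect_equal(unclass(cm$table)[1, "b1_2"], 200)
  expect_false("b2_1" %in% colnames(cm$table))   # bridge duplicates dropped
  expect_equal(unclass(cm$table)[1, "y1"], 300 * 30 / 31, tolerance = 1e-12)
})
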