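test_that("synthetic minority points interpolate minority neighbours exactly", {
  set.seed(109)
  x <- matrix(rnorm(13 * 4), 13, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c("control", "SALS"), c(10, 3))
  out <- smote_oversample(x, y, target_count = 9, seed = 111)
  expect_identical(unname(table(out$y)["SALS"]), 9L)
  # majority rows pass through untouched
  expect_equal(out$x[1:13, ], x, ignore_attr = TRUE)
  # exact interpolation identity per synthetic point
  synth <- out$x[14:19, , drop = FALSE]
  for (i in seq_len(nrow(synth))) {
    pa <- out$parents[i, ]
    expect_equal(unname(synth[i, ]),
                 unname(x[pa$i, ] + pa$u * (x[pa$nn, ] - x[pa$i, ])),
                 tolerance = 1e-12)
    # parents are minority members and the weight lies in [0, 1]
    expect_true(all(c(pa$i, pa$nn) %in% 11:13))
    expect_true(pa$u >= 0 && pa$u <= 1)
  }
  # determinism under the published seed
  again <- smote_oversample(x, y, target_count = 9, seed = 111)
  expect_identical(out$x, again$x)
})

test_that("degenerate minorities are handled explicitly", {
  x <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("f1", "f2")))
  expect_error(smote_oversample(x, rep(c("a", "b"), c(5, 1))),
               "at least 2 members")
  # two identical minority points: every synthetic point equals them
  x[5:6, ] <- 1
  out <- smote_oversample(x, rep(c("a", "b"), c(4, 2)), target_count = 5,
                          seed = 1)
  expect_true(all(out$x[7:9, ] == 1))
})

test_that("the stratified split is exact, disjoint and seeded", {
  y <- rep(c("control", "SALS"), c(10, 9))
  sp <- split_train_test(y, seed = 111)
  expect_length(sp$train, 13)
  expect_length(sp$test, 6)
  expect_identical(sort(c(sp$train, sp$test)), 1:19)
  # both classes in both partitions
  expect_setequal(unique(y[sp$train]), c("control", "SALS"))
  expect_setequal(unique(y[sp$test]), c("control", "SALS"))
  expect_identical(split_train_test(y, seed = 111), sp)
  expect_false(identical(split_train_test(y, seed = 112)$test, sp$test))
  expect_error(split_train_test(y[1:10]), "must equal")
})

test_that("grid search returns the best row and rfe keeps a feature subset", {
  d <- blob_data()
  fam <- ml_model_zoo()$decision_tree
  gs <- grid_search_cv(d$x, d$y, fam, seed = 111)
  expect_identical(nrow(gs$results), nrow(fam$grid))
  expect_equal(gs$cv_accuracy, max(gs$results$cv_accuracy))
  rfe <- rfe_cv(d$x, d$y, fam, gs$params, seed = 111)
  expect_true(all(rfe$features %in% colnames(d$x)))
  expect_true(length(rfe$features) >= 1)
  # a family without importances keeps everything
  fam_noimp <- fam; fam_noimp$importance <- NULL
  expect_identical(rfe_cv(d$x, d$y, fam_noimp, gs$params)$features,
                   colnames(d$x))
})

test_that("a separable toy is classified perfectly by fast families", {
  d <- blob_data()
  cfg <- ml_config(seed = 111,
                   families = c("random_forest", "decision_tree", "perceptron"))
  sp <- split_train_test(d$y, train_count = 14, test_count = 6, seed = 111)
  res <- train_evaluate(train = list(x = d$x[sp$train, ], y = d$y[sp$train]),
                        test = list(x = d$x[sp$test, ], y = d$y[sp$test]),
                        config = cfg)
  expect_equal(res$accuracy_test, rep(1, 3))
  expect_true(all(res$n_features <= ncol(d$x)))
})

test_that("the full experiment is reproducible bit for bit", {
  set.seed(113)
  x <- matrix(rnorm(13 * 6), 13, 6, dimnames = list(NULL, paste0("f", 1:6)))
  x[11:13, 1] <- x[11:13, 1] + 4
  y <- rep(c("control", "SALS"), c(10, 3))
  val <- list(naive = list(x = matrix(rnorm(5 * 6, 0, 1), 5, 6,
                                      dimnames = list(NULL, paste0("f", 1:6))),
                           y = rep("control", 5)))
  cfg <- ml_config(seed = 111, families = c("random_forest", "perceptron"))
  r1 <- run_ml_experiment(x, y, val, cfg)
  r2 <- run_ml_experiment(x, y, val, cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_identical(attr(r1, "split"), attr(r2, "split"))
  # accuracies live in [0, 1] and the flagged best row maximises the mean
  expect_true(all(r1$accuracy_test >= 0 & r1$accuracy_test <= 1))
  expect_identical(which(r1$best),
                   which.max(r1$accuracy_validation_mean))
})

test_that("cohort-derived datasets separate patients from controls", {
  co <- simulate_cohort(sim_config(seed = 127, n_proteins = 120))
  prep <- serum_prep(co)
  ds <- ml_dataset_from_cohort(prep$merged, prep$info_full)
  expect_identical(as.integer(table(ds$y)[c("control", "SALS")]), c(10L, 3L))
  expect_false(anyNA(ds$x))
  expect_false(anyNA(ds$validations$naive$x))
  # drug-naive validation samples: exposed flag false in the metadata
  expect_identical(nrow(ds$validations$naive$x) +
                     nrow(ds$validations$exposed$x), 97L)
  cfg <- ml_config(seed = 111, families = "random_forest")
  res <- run_ml_experiment(ds$x, ds$y, ds$validations, cfg)
  expect_gt(res$accuracy_validation_mean, 0.8)
})
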