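#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's
#' RNG state, so seeded helpers do not perturb an enclosing simulation.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Configuration of the diagnostic-classifier experiment
#'
#' Defaults mirror the published framework: seed 111, SMOTE oversampling of
#' the minority class to 9 samples (10 controls + 9 patients = 19 total),
#' a stratified 13/6 train/test split (68.4% / 31.6%), grid search with
#' two-fold cross-validation, and recursive feature elimination with
#' cross-validation for families exposing feature importances.
#'
#' @param seed RNG seed for the whole experiment (default 111).
#' @param k_neighbors requested SMOTE neighbour count; the effective value
#'   is `min(k_neighbors, minority size - 1)` (2 at the design's minority
#'   size of 3), since the library default of 5 cannot be honoured there.
#' @param target_minority_count minority size after oversampling (default 9).
#' @param train_count,test_count split sizes (13 and 6).
#' @param cv_folds cross-validation folds (default 2).
#' @param families classifier family names to run (default: the whole zoo,
#'   see [ml_model_zoo()]).
#' @return list of class `ml_config`.
#' @export
ml_config <- function(seed = 111L, k_neighbors = 5L,
                      target_minority_count = 9L,
                      train_count = 13L, test_count = 6L,
                      cv_folds = 2L, families = NULL) {
  if (cv_folds < 2L) stop("cv_folds must be at least 2")
  structure(list(seed = seed, k_neighbors = k_neighbors,
                 target_minority_count = target_minority_count,
                 train_count = train_count, test_count = test_count,
                 cv_folds = cv_folds, families = families),
            class = "ml_config")
}

#' SMOTE minority oversampling
#'
#' Raises the minority class to `target_count` by synthesising points on
#' segments between minority samples: `x_new = x_i + u (x_nn - x_i)` with
#' `u ~ Uniform(0, 1)` and `x_nn` one of the `k` nearest minority
#' neighbours of `x_i` (Euclidean). Majority samples are never altered.
#'
#' @param x complete numeric feature matrix (samples x features).
#' @param y class labels (length `nrow(x)`; exactly two classes).
#' @param target_count minority count after oversampling; defaults to the
#'   majority count (fully balanced).
#' @param k_neighbors requested neighbour count, clamped to minority
#'   size - 1.
#' @param seed optional seed (applied via [with_seed()]).
#' @return list with `x` (original rows then synthetic rows), `y`, and
#'   `parents` (data.frame recording, per synthetic point, the minority row
#'   pair and interpolation weight used).
#' @export
smote_oversample <- function(x, y, target_count = NULL, k_neighbors = 5L,
                             seed = NULL) {
  if (!is.null(seed))
    return(with_seed(seed, smote_oversample(x, y, target_count, k_neighbors)))
  if (anyNA(x)) stop("feature matrix must be complete (impute or filter first)")
  y <- as.character(y)
  tab <- sort(table(y))
  if (length(tab) != 2L) stop("exactly two classes required")
  minority <- names(tab)[1L]
  m <- tab[[1L]]
  if (m < 2L) stop("minority class needs at least 2 members for SMOTE")
  if (is.null(target_count)) target_count <- tab[[2L]]
  n_new <- target_count - m
  if (n_new < 0L) stop("target_count below current minority size")
  if (n_new == 0L)
    return(list(x = x, y = y,
                parents = data.frame(i = integer(), nn = integer(),
                                     u = numeric())))
  k <- min(k_neighbors, m - 1L)
  min_idx <- which(y == minority)
  xm <- x[min_idx, , drop = FALSE]
  dm <- as.matrix(stats::dist(xm))
  diag(dm) <- Inf
  ord <- apply(dm, 1L, function(r) order(r)[seq_len(k)])
  nn_idx <- if (k == 1L) matrix(ord, ncol = 1L) else t(ord)
  picks <- sample.int(m, n_new, replace = TRUE)
  nns <- vapply(picks, function(i) nn_idx[i, sample.int(k, 1L)], integer(1))
  u <- stats::runif(n_new)
  synth <- xm[picks, , drop = FALSE] +
    u * (xm[nns, , drop = FALSE] - xm[picks, , drop = FALSE])
  rownames(synth) <- sprintf("synthetic_%s_%02d", minority, seq_len(n_new))
  list(x = rbind(x, synth),
       y = c(y, rep(minority, n_new)),
       parents = data.frame(i = min_idx[picks], nn = min_idx[nns], u = u))
}

#' Stratified train/test split
#'
#' Seeded random assignment into partitions of exactly `train_count` and
#' `test_count` samples, stratified so both classes appear in both
#' partitions (test allocation by largest remainder of the class
#' proportions, clamped away from empty cells).
#'
#' @param y class labels; `length(y)` must equal
#'   `train_count + test_count`.
#' @param train_count,test_count partition sizes.
#' @param seed optional seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(y, train_count = 13L, test_count = 6L,
                             seed = NULL) {
  if (!is.null(seed))
    return(with_seed(seed, split_train_test(y, train_count, test_count)))
  n <- length(y)
  if (n != train_count + test_count)
    stop("length(y) must equal train_count + test_count")
  y <- as.character(y)
  classes <- sort(unique(y))
  n_c <- vapply(classes, function(cl) sum(y == cl), integer(1))
  exact <- test_count * n_c / n
  alloc <- floor(exact)
  rem <- test_count - sum(alloc)
  if (rem > 0) {
    o <- order(exact - alloc, decreasing = TRUE)
    alloc[o[seq_len(rem)]] <- alloc[o[seq_len(rem)]] + 1L
  }
  alloc <- pmin(pmax(alloc, 1L), n_c - 1L)
  while (sum(alloc) > test_count) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
  while (sum(alloc) < test_count) {
    i <- which(alloc < n_c - 1L)[1L]
    alloc[i] <- alloc[i] + 1L
  }
  test <- integer()
  for (j in seq_along(classes)) {
    idx <- which(y == classes[j])
    test <- c(test, sample(idx, alloc[j]))
  }
  test <- sort(test)
  list(train = setdiff(seq_len(n), test), test = test)
}

## ---- classifier family registry ------------------------------------------

## A family is a list(grid, fit(x, y, params), predict(model, x),
## importance(model, features) or NULL). x is samples x features; y a
## character vector of two classes.

family_random_forest <- function() {
  list(grid = expand.grid(ntree = c(100L, 300L)),
       fit = function(x, y, params)
         randomForest::randomForest(x = x, y = factor(y), ntree = params$ntree),
       predict = function(model, x)
         as.character(stats::predict(model, x)),
       importance = function(model, features) {
         imp <- randomForest::importance(model)[, "MeanDecreaseGini"]
         imp[features]
       })
}

family_extra_trees <- function() {
  list(grid = expand.grid(num.trees = c(100L, 300L)),
       fit = function(x, y, params) {
         d <- data.frame(x, check.names = FALSE)
         d$.y <- factor(y)
         ranger::ranger(dependent.variable.name = ".y", data = d,
                        num.trees = params$num.trees,
                        splitrule = "extratrees",
                        importance = "impurity",
                        replace = FALSE, sample.fraction = 1,
                        seed = 1L)
       },
       predict = function(model, x)
         as.character(stats::predict(model,
                                     data.frame(x, check.names = FALSE))$predictions),
       importance = function(model, features)
         ranger::importance(model)[features])
}

xgb_family <- function(grid) {
  list(grid = grid,
       fit = function(x, y, params) {
         lev <- sort(unique(y))
         dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(y == lev[2L]))
         booster <- xgboost::xgb.train(
           params = list(max_depth = params$max_depth, eta = params$eta,
                         objective = "binary:logistic", nthread = 1L),
           data = dtrain, nrounds = params$nrounds, verbose = 0)
         list(booster = booster, levels = lev)
       },
       predict = function(model, x) {
         pr <- stats::predict(model$booster, xgboost::xgb.DMatrix(x))
         model$levels[(pr > 0.5) + 1L]
       },
       importance = function(model, features) {
         imp <- stats::setNames(rep(0, length(features)), features)
         tab <- xgboost::xgb.importance(model = model$booster)
         imp[tab$Feature] <- tab$Gain
         imp
       })
}

family_gradient_boosting <- function()
  xgb_family(expand.grid(nrounds = 100L, max_depth = 3L, eta = c(0.1, 0.3)))

family_xgboost <- function()
  xgb_family(expand.grid(nrounds = 50L, max_depth = c(2L, 4L), eta = 0.3))

family_decision_tree <- function() {
  list(grid = expand.grid(maxdepth = c(2L, 4L), cp = 0.0),
       fit = function(x, y, params) {
         d <- data.frame(x, check.names = FALSE)
         d$.y <- factor(y)
         rpart::rpart(.y ~ ., data = d,
                      method = "class",
                      control = rpart::rpart.control(maxdepth = params$maxdepth,
                                                     cp = params$cp,
                                                     minsplit = 2L,
                                                     minbucket = 1L,
                                                     xval = 0L))
       },
       predict = function(model, x)
         as.character(stats::predict(model, data.frame(x, check.names = FALSE),
                                     type = "class")),
       importance = function(model, features) {
         imp <- stats::setNames(rep(0, length(features)), features)
         vi <- model$variable.importance
         imp[names(vi)] <- vi
         imp
       })
}

## AdaBoost (SAMME) over depth-1 rpart stumps: classical reweighted
## boosting with vote weight log((1 - err) / err) per stump.
family_adaboost <- function() {
  list(grid = expand.grid(n_estimators = c(25L, 50L)),
       fit = function(x, y, params) {
         n <- nrow(x)
         lev <- sort(unique(y))
         d <- data.frame(x, check.names = FALSE)
         d$.y <- factor(y, levels = lev)
         w <- rep(1 / n, n)
         stumps <- list(); alphas <- numeric()
         for (t in seq_len(params$n_estimators)) {
           stump <- rpart::rpart(.y ~ ., data = d, weights = w,
                                 method = "class",
                                 control = rpart::rpart.control(
                                   maxdepth = 1L, cp = 0, minsplit = 2L,
                                   minbucket = 1L, xval = 0L))
           pred <- as.character(stats::predict(stump, d, type = "class"))
           err <- sum(w[pred != y]) / sum(w)
           if (err >= 0.5 && t > 1L) break
           err <- min(max(err, 1e-10), 1 - 1e-10)
           alpha <- log((1 - err) / err)
           stumps[[length(stumps) + 1L]] <- stump
           alphas <- c(alphas, alpha)
           w <- w * exp(alpha * (pred != y))
           w <- w / sum(w)
           if (err <= 1e-10) break
         }
         list(stumps = stumps, alphas = alphas, levels = lev)
       },
       predict = function(model, x) {
         d <- data.frame(x, check.names = FALSE)
         score <- rep(0, nrow(d))
         for (t in seq_along(model$stumps)) {
           pred <- as.character(stats::predict(model$stumps[[t]], d,
                                               type = "class"))
           score <- score + model$alphas[t] * ifelse(pred == model$levels[2L], 1, -1)
         }
         model$levels[(score > 0) + 1L]
       },
       importance = function(model, features) {
         imp <- stats::setNames(rep(0, length(features)), features)
         for (t in seq_along(model$stumps)) {
           vi <- model$stumps[[t]]$variable.importance
           if (!is.null(vi))
             imp[names(vi)] <- imp[names(vi)] + model$alphas[t] * vi
         }
         imp
       })
}

## Averaged perceptron on standardised features; |averaged weight| serves
## as the importance for feature elimination (the linear-model analogue of
## ranking by coefficient size).
family_perceptron <- function() {
  list(grid = expand.grid(epochs = 50L, learning_rate = c(0.1, 1.0)),
       fit = function(x, y, params) {
         lev <- sort(unique(y))
         mu <- colMeans(x)
         sg <- apply(x, 2L, stats::sd)
         sg[sg == 0] <- 1
         xs <- sweep(sweep(x, 2L, mu), 2L, sg, "/")
         yy <- ifelse(y == lev[2L], 1, -1)
         w <- stats::setNames(rep(0, ncol(x)), colnames(x)); b <- 0
         w_sum <- w; b_sum <- 0; n_acc <- 0L
         for (ep in seq_len(params$epochs)) {
           for (i in seq_len(nrow(xs))) {
             if (yy[i] * (sum(w * xs[i, ]) + b) <= 0) {
               w <- w + params$learning_rate * yy[i] * xs[i, ]
               b <- b + params$learning_rate * yy[i]
             }
             w_sum <- w_sum + w; b_sum <- b_sum + b; n_acc <- n_acc + 1L
           }
         }
         list(w = w_sum / n_acc, b = b_sum / n_acc, mu = mu, sg = sg,
              levels = lev)
       },
       predict = function(model, x) {
         xs <- sweep(sweep(x, 2L, model$mu[colnames(x)]), 2L,
                     model$sg[colnames(x)], "/")
         score <- as.vector(xs %*% model$w[colnames(x)]) + model$b
         model$levels[(score > 0) + 1L]
       },
       importance = function(model, features) abs(model$w)[features])
}

#' The classifier family registry
#'
#' Seven classifier families spanning the published zoo: random forest,
#' extremely randomised trees, gradient boosting, xgboost, a single
#' decision tree, AdaBoost (SAMME over decision stumps) and an averaged
#' perceptron. Each family carries a small hyperparameter grid, fit /
#' predict closures, and a feature-importance accessor used by recursive
#' feature elimination. User-defined families with the same shape can be
#' appended to the returned list.
#'
#' @param families optional character vector selecting a subset by name.
#' @return named list of family definitions.
#' @export
ml_model_zoo <- function(families = NULL) {
  zoo <- list(random_forest = family_random_forest(),
              extra_trees = family_extra_trees(),
              gradient_boosting = family_gradient_boosting(),
              xgboost = family_xgboost(),
              decision_tree = family_decision_tree(),
              adaboost = family_adaboost(),
              perceptron = family_perceptron())
  if (!is.null(families)) {
    bad <- setdiff(families, names(zoo))
    if (length(bad)) stop("unknown model famil(ies): ", paste(bad, collapse = ", "))
    zoo <- zoo[families]
  }
  zoo
}

stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep(seq_len(folds), length.out = length(idx))
  }
  fold
}

accuracy <- function(truth, pred) mean(truth == pred)

#' Grid search with stratified cross-validation
#'
#' @param x,y training data (complete matrix, two-class labels).
#' @param family one entry of [ml_model_zoo()].
#' @param folds number of CV folds (default 2).
#' @param seed optional seed for the fold assignment.
#' @return list with `params` (best grid row, as a list), `cv_accuracy`,
#'   and `results` (accuracy per grid row).
#' @export
grid_search_cv <- function(x, y, family, folds = 2L, seed = NULL) {
  if (!is.null(seed))
    return(with_seed(seed, grid_search_cv(x, y, family, folds)))
  fold <- stratified_folds(y, folds)
  grid <- family$grid
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    params <- as.list(grid[g, , drop = FALSE])
    mean(vapply(seq_len(folds), function(f) {
      tr <- fold != f; te <- fold == f
      if (length(unique(y[tr])) < 2L) return(NA_real_)
      model <- family$fit(x[tr, , drop = FALSE], y[tr], params)
      accuracy(y[te], family$predict(model, x[te, , drop = FALSE]))
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  best <- which.max(acc)
  list(params = as.list(grid[best, , drop = FALSE]),
       cv_accuracy = acc[best],
       results = cbind(grid, cv_accuracy = acc))
}

#' Recursive feature elimination with cross-validation
#'
#' Iteratively halves the feature set, dropping the least important half at
#' each step (importances re-estimated from a fit on the current subset),
#' and scores every candidate subset size by stratified CV accuracy. The
#' returned subset is the smallest one attaining the best CV accuracy.
#' Families without an importance accessor keep the full feature set.
#'
#' @param x,y training data.
#' @param family a model family.
#' @param params hyperparameters (from [grid_search_cv()]).
#' @param folds CV folds (default 2).
#' @param seed optional seed.
#' @return list with `features` (selected column names), `cv_accuracy`,
#'   and `path` (data.frame n_features / cv_accuracy per step).
#' @export
rfe_cv <- function(x, y, family, params, folds = 2L, seed = NULL) {
  if (!is.null(seed))
    return(with_seed(seed, rfe_cv(x, y, family, params, folds)))
  if (is.null(family$importance))
    return(list(features = colnames(x), cv_accuracy = NA_real_,
                path = NULL))
  fold <- stratified_folds(y, folds)
  cv_acc <- function(feats) {
    mean(vapply(seq_len(folds), function(f) {
      tr <- fold != f; te <- fold == f
      model <- family$fit(x[tr, feats, drop = FALSE], y[tr], params)
      accuracy(y[te], family$predict(model, x[te, feats, drop = FALSE]))
    }, numeric(1)))
  }
  current <- colnames(x)
  path <- list()
  subsets <- list()
  repeat {
    path[[length(path) + 1L]] <- data.frame(n_features = length(current),
                                            cv_accuracy = cv_acc(current))
    subsets[[length(subsets) + 1L]] <- current
    if (length(current) <= 1L) break
    model <- family$fit(x[, current, drop = FALSE], y, params)
    imp <- family$importance(model, current)
    imp[is.na(imp)] <- 0
    keep_n <- max(1L, floor(length(current) / 2))
    current <- current[order(imp, decreasing = TRUE)[seq_len(keep_n)]]
  }
  path <- do.call(rbind, path)
  best_acc <- max(path$cv_accuracy)
  best <- which(path$cv_accuracy == best_acc)
  pick <- best[which.min(path$n_features[best])]
  list(features = subsets[[pick]], cv_accuracy = best_acc, path = path)
}

#' Train, tune and evaluate the classifier zoo
#'
#' Per family: hyperparameter grid search with stratified two-fold CV on
#' the training set, recursive feature elimination with CV, a final refit
#' on the selected features, and accuracy on the held-out test set and on
#' each external validation set (the batch-external drug-naive and
#' drug-exposed sample sets). The family with the best mean validation
#' accuracy is flagged.
#'
#' @param train list with `x` (complete matrix) and `y`.
#' @param test list with `x` and `y`.
#' @param validations named list of `list(x, y)` validation sets on the
#'   same feature universe (default none).
#' @param config an [ml_config()].
#' @return data.frame of class `ml_results`: one row per family with
#'   `model`, `n_features`, `accuracy_test`, one `accuracy_<name>` column
#'   per validation set, `accuracy_validation_mean` and `best` flag. The
#'   fitted models and selected features are attached as attributes.
#' @export
train_evaluate <- function(train, test, validations = list(),
                           config = ml_config()) {
  zoo <- ml_model_zoo(config$families)
  rows <- list(); fitted <- list(); selected <- list()
  for (fam_name in names(zoo)) {
    fam <- zoo[[fam_name]]
    gs <- grid_search_cv(train$x, train$y, fam, folds = config$cv_folds,
                         seed = config$seed)
    rfe <- rfe_cv(train$x, train$y, fam, gs$params,
                  folds = config$cv_folds, seed = config$seed)
    feats <- rfe$features
    model <- with_seed(config$seed,
                       fam$fit(train$x[, feats, drop = FALSE], train$y,
                               gs$params))
    row <- data.frame(model = fam_name, n_features = length(feats),
                      accuracy_test = accuracy(
                        test$y,
                        fam$predict(model, test$x[, feats, drop = FALSE])),
                      stringsAsFactors = FALSE)
    vacc <- numeric()
    for (vn in names(validations)) {
      v <- validations[[vn]]
      a <- accuracy(v$y, fam$predict(model, v$x[, feats, drop = FALSE]))
      row[[paste0("accuracy_", vn)]] <- a
      vacc <- c(vacc, a)
    }
    row$accuracy_validation_mean <-
      if (length(vacc)) mean(vacc) else NA_real_
    rows[[fam_name]] <- row
    fitted[[fam_name]] <- model
    selected[[fam_name]] <- feats
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  ref <- if (all(is.na(out$accuracy_validation_mean))) out$accuracy_test
         else out$accuracy_validation_mean
  out$best <- seq_len(nrow(out)) == which.max(ref)
  attr(out, "models") <- fitted
  attr(out, "selected_features") <- selected
  class(out) <- c("ml_results", "data.frame")
  out
}

#' Run the full imbalanced-class experiment
#'
#' The published protocol end to end: SMOTE-oversample the minority class
#' of the base dataset, split the balanced data into stratified train and
#' test partitions, then tune and evaluate every classifier family
#' ([train_evaluate()]). All randomness derives from `config$seed`, so the
#' run is reproducible bit for bit.
#'
#' @param x complete feature matrix (samples x features) of the base
#'   (imbalanced) dataset.
#' @param y two-class labels.
#' @param validations named list of `list(x, y)` external validation sets.
#' @param config an [ml_config()].
#' @return an `ml_results` data.frame (see [train_evaluate()]); the
#'   oversampled dataset and split indices are attached as attributes.
#' @export
run_ml_experiment <- function(x, y, validations = list(),
                              config = ml_config()) {
  bal <- smote_oversample(x, y,
                          target_count = config$target_minority_count,
                          k_neighbors = config$k_neighbors,
                          seed = config$seed)
  sp <- split_train_test(bal$y, config$train_count, config$test_count,
                         seed = config$seed + 1L)
  res <- train_evaluate(
    train = list(x = bal$x[sp$train, , drop = FALSE], y = bal$y[sp$train]),
    test = list(x = bal$x[sp$test, , drop = FALSE], y = bal$y[sp$test]),
    validations = validations, config = config)
  attr(res, "oversampled") <- bal
  attr(res, "split") <- sp
  res
}

#' Assemble the diagnostic-classification dataset from a cohort
#'
#' Builds the base training dataset (the point-in-time measurement set: all
#' controls plus the bridge patients' week-0 draws) and the batch-external
#' validation sets (the remaining longitudinal patient samples, split into
#' drug-naive and drug-exposed) from a batch-corrected table. The feature
#' universe is the set of proteins detected in every base-dataset sample;
#' residual missing values in validation samples are imputed with the
#' training feature median.
#'
#' @param table raw-scale batch-corrected merged `abundance_table` of one
#'   fluid (see [correct_and_merge()]).
#' @param info sample metadata for that fluid.
#' @return list with `x`, `y` (base dataset) and `validations` (named list
#'   `naive` / `exposed`).
#' @export
ml_dataset_from_cohort <- function(table, info) {
  ## identify the bridge subjects before restricting to the merged table's
  ## columns: their batch-2 re-measurements are dropped during merging
  bridge_subj <- unique(info$subject_id[info$batch == 2L & info$cohort == "SALS"])
  info <- info[info$sample_id %in% colnames(table), , drop = FALSE]
  ctrl <- info$sample_id[info$cohort == "control"]
  base_sals <- info$sample_id[info$cohort == "SALS" & info$week == 0 &
                              info$batch == 1L &
                              info$subject_id %in% bridge_subj]
  base_ids <- c(ctrl, base_sals)
  universe <- complete_proteins(table, base_ids)
  if (length(universe) == 0L) stop("no protein complete in the base dataset")
  logt <- to_log10(table)
  mat <- t(unclass(logt)[universe, , drop = FALSE])
  x_base <- mat[base_ids, , drop = FALSE]
  y_base <- info$cohort[match(base_ids, info$sample_id)]
  med <- apply(x_base, 2L, stats::median)
  val_ids <- info$sample_id[info$cohort == "SALS" & info$batch == 1L &
                            !(info$sample_id %in% base_sals)]
  val_info <- info[match(val_ids, info$sample_id), , drop = FALSE]
  make_val <- function(ids) {
    m <- mat[ids, , drop = FALSE]
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- med[j]
    list(x = m, y = rep("SALS", nrow(m)))
  }
  list(x = x_base, y = y_base,
       validations = list(
         naive = make_val(val_ids[!val_info$ropi_exposed]),
         exposed = make_val(val_ids[val_info$ropi_exposed])))
}
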