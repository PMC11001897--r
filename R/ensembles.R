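# Ensemble classifiers over encoded feature tables: a stacking ensemble
# (KNN + decision tree + ANN + SVM bases, gradient-boost meta-learner on
# out-of-fold base predictions), four bagging variants and two boosting
# variants. All training is deterministic given the config seed.

ENSEMBLE_VARIANTS <- list(
  stacking = "stacking",
  bagging  = c("bagging-classifier", "random-forest", "extra-trees",
               "decision-tree"),
  boosting = c("gradient-boost", "hist-gradient-boost")
)

#' Ensemble model configuration
#'
#' @param family "stacking", "bagging" or "boosting".
#' @param variant one of: "stacking"; "bagging-classifier", "random-forest",
#'   "extra-trees", "decision-tree"; "gradient-boost" (the headline model),
#'   "hist-gradient-boost". Defaults to the family's first variant.
#' @param seed integer seed controlling all fitting randomness.
#' @param tuning if TRUE, hyperparameters are selected by internal 5-fold
#'   cross-validated grid search over small documented grids (see
#'   [tuning_grid()]); if FALSE (default), documented defaults are used.
#' @param scaling if TRUE, features are standardised (zero mean, unit
#'   variance, fit on training data only) before fitting. Defaults to TRUE
#'   for stacking (distance/margin/gradient-descent base learners) and FALSE
#'   for the tree-based bagging/boosting families.
#' @return An `ensemble_config` list.
#' @export
ensemble_config <- function(family = c("boosting", "bagging", "stacking"),
                            variant = NULL, seed = 1L, tuning = FALSE,
                            scaling = NULL) {
  family <- match.arg(family)
  if (is.null(variant)) variant <- ENSEMBLE_VARIANTS[[family]][1]
  if (!variant %in% ENSEMBLE_VARIANTS[[family]])
    stop(sprintf("variant '%s' is not legal for family '%s'", variant, family),
         call. = FALSE)
  if (is.null(scaling)) scaling <- family == "stacking"
  structure(list(family = family, variant = variant, seed = as.integer(seed),
                 tuning = isTRUE(tuning), scaling = isTRUE(scaling)),
            class = "ensemble_config")
}

#' Hyperparameter grids and defaults
#'
#' The paper-style learners are tuned, when `tuning = TRUE`, over these
#' small fixed grids by internal 5-fold cross-validation: KNN neighbours
#' \{3, 5, 7, 9\}; SVM cost \{0.1, 1, 10\} (RBF kernel); decision-tree max
#' depth \{3, 5, 10, 30\}; boosting learning rate \{0.05, 0.1, 0.2\} crossed
#' with \{100, 300\} rounds; forest mtry \{sqrt(p), 2 sqrt(p)\}.
#'
#' @param variant learner/variant name (includes the stacking base names
#'   "knn", "dt", "ann", "svm").
#' @return List of candidate parameter lists (first element = default).
#' @export
tuning_grid <- function(variant) {
  grids <- list(
    "knn" = lapply(c(5, 3, 7, 9), function(k) list(k = k)),
    "dt" = lapply(c(30, 3, 5, 10), function(d) list(maxdepth = d)),
    "ann" = lapply(c(0.01, 0.001, 0.1), function(d) list(decay = d)),
    "svm" = lapply(c(1, 0.1, 10), function(c) list(cost = c)),
    "decision-tree" = lapply(c(30, 3, 5, 10), function(d) list(maxdepth = d)),
    "bagging-classifier" = lapply(c(30, 3, 5, 10),
                                  function(d) list(maxdepth = d)),
    "random-forest" = list(list(mtry_factor = 1), list(mtry_factor = 2)),
    "extra-trees" = list(list(mtry_factor = 1), list(mtry_factor = 2)),
    "gradient-boost" = do.call(c, lapply(c(0.1, 0.05, 0.2), function(eta)
      lapply(c(100, 300), function(n) list(eta = eta, nrounds = n)))),
    "hist-gradient-boost" = do.call(c, lapply(c(0.1, 0.05, 0.2), function(eta)
      lapply(c(100, 300), function(n) list(eta = eta, nrounds = n))))
  )
  grids[[variant]]
}

# ---- individual learners ----------------------------------------------------
# Each fit_* returns list(model = <opaque>, score = function(X) prob of 1).

fit_knn <- function(X, y, params) {
  k <- params$k %||% 5L
  list(model = list(X = X, y = factor(y, levels = c(0, 1)), k = k),
       score = function(Xnew) {
         pred <- class::knn(train = X, test = Xnew,
                            cl = factor(y, levels = c(0, 1)), k = k,
                            prob = TRUE)
         p <- attr(pred, "prob")
         ifelse(pred == "1", p, 1 - p)
       })
}

fit_dt <- function(X, y, params) {
  df <- as.data.frame(X)
  df$.y <- factor(y, levels = c(0, 1))
  ctrl <- rpart::rpart.control(minsplit = 5L, cp = 1e-4, xval = 0L,
                               maxdepth = params$maxdepth %||% 30L)
  mod <- rpart::rpart(.y ~ ., data = df, method = "class", control = ctrl)
  list(model = mod,
       score = function(Xnew)
         predict(mod, as.data.frame(Xnew), type = "prob")[, "1"])
}

fit_ann <- function(X, y, params) {
  size <- params$size %||% 4L
  mod <- nnet::nnet(x = X, y = as.numeric(y), size = size,
                    decay = params$decay %||% 0.01,
                    maxit = params$maxit %||% 150L, entropy = TRUE,
                    trace = FALSE,
                    MaxNWts = (ncol(X) + 2L) * size + size + 10L)
  list(model = mod,
       score = function(Xnew) as.numeric(predict(mod, Xnew)))
}

fit_svm <- function(X, y, params) {
  mod <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "radial",
                    cost = params$cost %||% 1, probability = TRUE)
  list(model = mod,
       score = function(Xnew) {
         pr <- attr(predict(mod, Xnew, probability = TRUE), "probabilities")
         pr[, "1"]
       })
}

fit_rf <- function(X, y, params, seed) {
  p <- ncol(X)
  mtry <- min(p, floor(sqrt(p)) * (params$mtry_factor %||% 1))
  mod <- randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                    ntree = 300L, mtry = mtry)
  list(model = mod,
       score = function(Xnew) predict(mod, Xnew, type = "prob")[, "1"])
}

fit_et <- function(X, y, params, seed) {
  p <- ncol(X)
  mtry <- min(p, floor(sqrt(p)) * (params$mtry_factor %||% 1))
  df <- as.data.frame(X)
  mod <- ranger::ranger(x = df, y = factor(y, levels = c(0, 1)),
                        probability = TRUE, splitrule = "extratrees",
                        num.random.splits = 1L, num.trees = 300L,
                        mtry = mtry, replace = FALSE, sample.fraction = 1,
                        seed = seed, num.threads = 1L)
  list(model = mod,
       score = function(Xnew)
         predict(mod, data = as.data.frame(Xnew),
                 num.threads = 1L)$predictions[, "1"])
}

# Bootstrap bag of deep decision trees, combined by averaging class
# probabilities (row subsampling with replacement).
fit_bag <- function(X, y, params) {
  B <- params$n_estimators %||% 50L
  n <- nrow(X)
  df <- as.data.frame(X)
  df$.y <- factor(y, levels = c(0, 1))
  ctrl <- rpart::rpart.control(minsplit = 5L, cp = 1e-4, xval = 0L,
                               maxdepth = params$maxdepth %||% 30L)
  trees <- lapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(df$.y[idx])) < 2L)  # degenerate resample: redraw once
      idx <- sample.int(n, n, replace = TRUE)
    rpart::rpart(.y ~ ., data = df[idx, , drop = FALSE], method = "class",
                 control = ctrl)
  })
  list(model = trees,
       score = function(Xnew) {
         dfn <- as.data.frame(Xnew)
         probs <- vapply(trees, function(tr) predict(tr, dfn,
                                                     type = "prob")[, "1"],
                         numeric(nrow(dfn)))
         rowMeans(matrix(probs, nrow = nrow(dfn)))
       })
}

fit_xgb <- function(X, y, params, hist = FALSE) {
  dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(y))
  plist <- list(objective = "binary:logistic",
                eta = params$eta %||% 0.1,
                max_depth = params$max_depth %||% if (hist) 6L else 3L,
                subsample = 1, colsample_bytree = 1, nthread = 1L,
                tree_method = if (hist) "hist" else "exact")
  if (hist) plist$max_bin <- 256L
  mod <- xgboost::xgb.train(params = plist, data = dtrain,
                            nrounds = params$nrounds %||% 200L, verbose = 0L)
  list(model = mod,
       score = function(Xnew) predict(mod, xgboost::xgb.DMatrix(Xnew)))
}

fit_learner <- function(name, X, y, params, seed) {
  set.seed(seed)
  switch(name,
         "knn" = fit_knn(X, y, params),
         "dt" = ,
         "decision-tree" = fit_dt(X, y, params),
         "ann" = fit_ann(X, y, params),
         "svm" = fit_svm(X, y, params),
         "random-forest" = fit_rf(X, y, params, seed),
         "extra-trees" = fit_et(X, y, params, seed),
         "bagging-classifier" = fit_bag(X, y, params),
         "gradient-boost" = fit_xgb(X, y, params, hist = FALSE),
         "hist-gradient-boost" = fit_xgb(X, y, params, hist = TRUE),
         stop("unknown learner: ", name, call. = FALSE))
}

# Mean 5-fold CV accuracy of one learner/parameter combination.
cv_accuracy <- function(name, X, y, params, seed, k = 5L) {
  folds <- stratified_folds(y, k, seed)
  hits <- 0L
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- fit_learner(name, X[tr, , drop = FALSE], y[tr], params, seed + f)
    calls <- as.integer(fit$score(X[!tr, , drop = FALSE]) >= 0.5)
    hits <- hits + sum(calls == y[!tr])
  }
  hits / length(y)
}

tune_learner <- function(name, X, y, seed) {
  grid <- tuning_grid(name)
  accs <- vapply(grid, function(p) cv_accuracy(name, X, y, p, seed),
                 numeric(1))
  grid[[which.max(accs)]]
}

STACKING_BASES <- c("knn", "dt", "ann", "svm")

# ---- public surface ---------------------------------------------------------

#' Train an ensemble classifier
#'
#' Fits the configured ensemble on an encoded feature table. The stacking
#' family trains its four base learners (KNN, decision tree, ANN, SVM) and a
#' gradient-boost meta-learner on leakage-free out-of-fold base predictions
#' (internal stratified 5-fold). Training is deterministic given
#' (config, data).
#'
#' @param config an [ensemble_config()].
#' @param features data.frame or matrix of feature columns (any `id` /
#'   `label` columns are dropped); typically the output of
#'   [encode_dataset()].
#' @param labels binary vector (0/1), one per row.
#' @return A `trained_ensemble` with the fitted state, the feature-name
#'   contract and training metadata (sample counts, seed, tuned parameters).
#' @export
train_ensemble <- function(config, features, labels) {
  stopifnot(inherits(config, "ensemble_config"))
  X <- feature_matrix(features)
  labels <- as.integer(labels)
  if (length(labels) != nrow(X))
    stop("labels must match feature rows", call. = FALSE)
  if (any(!labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  if (min(table(factor(labels, levels = c(0, 1)))) < 2L)
    stop("need at least 2 samples in each class", call. = FALSE)
  if (anyNA(X)) stop("features contain missing values", call. = FALSE)

  scaler <- NULL
  if (config$scaling) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, sd)
    scl[scl == 0] <- 1
    scaler <- list(center = ctr, scale = scl)
    X <- scale(X, center = ctr, scale = scl)
  }

  set.seed(config$seed)
  tuned <- NULL
  if (config$family == "stacking") {
    base_params <- lapply(STACKING_BASES, function(b) {
      if (config$tuning) tune_learner(b, X, labels, config$seed)
      else tuning_grid(b)[[1]]
    })
    names(base_params) <- STACKING_BASES
    # leakage-free meta-features: out-of-fold base predictions
    folds <- stratified_folds(labels, 5L, config$seed)
    Z <- matrix(NA_real_, nrow(X), length(STACKING_BASES),
                dimnames = list(NULL, STACKING_BASES))
    for (f in 1:5) {
      tr <- folds != f
      for (b in STACKING_BASES) {
        fit <- fit_learner(b, X[tr, , drop = FALSE], labels[tr],
                           base_params[[b]], config$seed + 13L * f)
        Z[!tr, b] <- fit$score(X[!tr, , drop = FALSE])
      }
    }
    base_fits <- lapply(STACKING_BASES, function(b)
      fit_learner(b, X, labels, base_params[[b]], config$seed + 101L))
    names(base_fits) <- STACKING_BASES
    set.seed(config$seed + 202L)
    meta <- fit_xgb(Z, labels, list(eta = 0.1, nrounds = 100L, max_depth = 2L))
    fit <- list(bases = base_fits, meta = meta)
    tuned <- base_params
    metadata_extra <- list(base_learners = STACKING_BASES,
                           meta_learner = "gradient-boost")
  } else {
    params <- if (config$tuning) tune_learner(config$variant, X, labels,
                                              config$seed)
              else tuning_grid(config$variant)[[1]]
    fit <- fit_learner(config$variant, X, labels, params, config$seed)
    tuned <- params
    metadata_extra <- list()
  }

  structure(list(
    config = config,
    feature_names = colnames(X),
    scaler = scaler,
    fit = fit,
    metadata = c(list(n_pos = sum(labels == 1L), n_neg = sum(labels == 0L),
                      seed = config$seed, tuned_parameters = tuned),
                 metadata_extra)),
    class = "trained_ensemble")
}

# Numeric feature matrix from a table, dropping id/label bookkeeping columns.
feature_matrix <- function(features) {
  df <- as.data.frame(features)
  df <- df[, setdiff(colnames(df), c("id", "label")), drop = FALSE]
  X <- as.matrix(df)
  storage.mode(X) <- "double"
  X
}

#' Score samples with a trained ensemble
#'
#' @param model a `trained_ensemble`.
#' @param features feature table whose columns must match the model's
#'   feature-name contract (extra `id`/`label` columns are ignored).
#' @return Numeric vector of class-1 probabilities in [0, 1].
#' @export
predict_scores <- function(model, features) {
  stopifnot(inherits(model, "trained_ensemble"))
  X <- feature_matrix(features)
  if (!identical(sort(colnames(X)), sort(model$feature_names)))
    stop("feature columns do not match the model's feature-name contract",
         call. = FALSE)
  X <- X[, model$feature_names, drop = FALSE]
  if (!is.null(model$scaler))
    X <- scale(X, center = model$scaler$center, scale = model$scaler$scale)
  scores <- if (model$config$family == "stacking") {
    Z <- vapply(model$fit$bases, function(b) b$score(X), numeric(nrow(X)))
    Z <- matrix(Z, nrow = nrow(X), dimnames = list(NULL, STACKING_BASES))
    model$fit$meta$score(Z)
  } else {
    model$fit$score(X)
  }
  pmin(1, pmax(0, as.numeric(scores)))
}

#' Hard class calls at the 0.5 threshold
#'
#' @inheritParams predict_scores
#' @return Integer vector of 0/1 calls.
#' @export
predict_calls <- function(model, features) {
  as.integer(predict_scores(model, features) >= 0.5)
}

ENSEMBLE_FORMAT_VERSION <- 1L

#' Persist / restore a trained ensemble
#'
#' The file embeds a format version, the config, the feature-name manifest
#' and all metadata; `load_ensemble(save_ensemble(m, path))` scores any table
#' identically to `m`.
#'
#' @param model a `trained_ensemble`.
#' @param path file path.
#' @return `path` (save) or the restored `trained_ensemble` (load).
#' @export
save_ensemble <- function(model, path) {
  stopifnot(inherits(model, "trained_ensemble"))
  saveRDS(list(format_version = ENSEMBLE_FORMAT_VERSION, model = model), path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  if (!file.exists(path)) stop("no such model file: ", path, call. = FALSE)
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("corrupt model file: ", conditionMessage(e), call. = FALSE))
  if (!is.list(obj) || is.null(obj$format_version))
    stop("not a sixmA model file (missing format version)", call. = FALSE)
  if (obj$format_version != ENSEMBLE_FORMAT_VERSION)
    stop(sprintf("model format version %s not supported (expected %d)",
                 obj$format_version, ENSEMBLE_FORMAT_VERSION), call. = FALSE)
  obj$model
}

#' @export
print.trained_ensemble <- function(x, ...) {
  cat(sprintf("trained_ensemble: %s / %s (seed %d)\n", x$config$family,
              x$config$variant, x$config$seed))
  cat(sprintf("  trained on %d positive / %d negative samples, %d features\n",
              x$metadata$n_pos, x$metadata$n_neg, length(x$feature_names)))
  invisible(x)
}
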