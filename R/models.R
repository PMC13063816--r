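# ---------------------------------------------------------------------------
# Base model families
# ---------------------------------------------------------------------------

#' Model families of the stacking ensemble
#'
#' The six base classifier families combined by the ensemble: support
#' vector machine (RBF kernel, e1071), random forest (ranger), k-nearest
#' neighbours, leaf-wise gradient-boosted trees (lossguide growth),
#' depth-wise gradient-boosted trees (xgboost), and a single decision tree
#' (rpart).
#'
#' @return character vector of family names.
#' @export
modelFamilies <- function() {
  c("svm", "random_forest", "knn", "lightgbm", "xgboost", "decision_tree")
}

## Random draw from the per-family hyperparameter search space.  Spaces are
## conventional published ranges for each learner.
.sampleParams <- function(family, seed) {
  .withSeed(seed, switch(family,
    svm = list(cost = 10^stats::runif(1, -1, 2),
               gamma = 10^stats::runif(1, -3, 0)),
    random_forest = list(num.trees = sample(100:500, 1),
                         mtry = sample(4:40, 1),
                         min.node.size = sample(1:10, 1)),
    knn = list(k = sample(seq(3, 31, 2), 1)),
    lightgbm = list(nrounds = sample(50:300, 1),
                    eta = 10^stats::runif(1, -2, -0.5),
                    max_leaves = sample(8:64, 1),
                    min_child_weight = stats::runif(1, 1, 10),
                    subsample = stats::runif(1, 0.6, 1),
                    colsample_bytree = stats::runif(1, 0.6, 1)),
    xgboost = list(nrounds = sample(50:300, 1),
                   eta = 10^stats::runif(1, -2, -0.5),
                   max_depth = sample(2:8, 1),
                   min_child_weight = stats::runif(1, 1, 10),
                   subsample = stats::runif(1, 0.6, 1),
                   colsample_bytree = stats::runif(1, 0.6, 1)),
    decision_tree = list(cp = 10^stats::runif(1, -4, -1.3),
                         maxdepth = sample(2:20, 1),
                         minsplit = sample(5:40, 1)),
    stop("unknown model family: ", family, call. = FALSE)))
}

.defaultParams <- function(family) {
  switch(family,
    svm = list(cost = 10, gamma = 0.02),
    random_forest = list(num.trees = 300, mtry = 13, min.node.size = 2),
    knn = list(k = 11),
    lightgbm = list(nrounds = 150, eta = 0.1, max_leaves = 31,
                    min_child_weight = 2, subsample = 0.9,
                    colsample_bytree = 0.9),
    xgboost = list(nrounds = 150, eta = 0.1, max_depth = 5,
                   min_child_weight = 2, subsample = 0.9,
                   colsample_bytree = 0.9),
    decision_tree = list(cp = 0.003, maxdepth = 12, minsplit = 10))
}

## Fit one base model.  `calibrated = FALSE` lets the SVM skip Platt
## calibration during tuning (AUC only needs the decision value ranking).
.fitBase <- function(family, X, y, params, seed, calibrated = TRUE) {
  yf <- factor(y, levels = c(0, 1))
  fit <- .withSeed(seed, switch(family,
    svm = e1071::svm(x = X, y = yf, kernel = "radial", cost = params$cost,
                     gamma = params$gamma, probability = calibrated,
                     scale = FALSE),
    random_forest = ranger::ranger(
      x = X, y = yf, probability = TRUE, num.trees = params$num.trees,
      mtry = min(params$mtry, ncol(X)), min.node.size = params$min.node.size,
      num.threads = 1, seed = seed),
    knn = list(X = X, y = yf, k = params$k, seed = seed),
    lightgbm = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = params$eta,
                    tree_method = "hist", grow_policy = "lossguide",
                    max_depth = 0, max_leaves = params$max_leaves,
                    min_child_weight = params$min_child_weight,
                    subsample = params$subsample,
                    colsample_bytree = params$colsample_bytree,
                    nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(X, label = as.numeric(y)),
      nrounds = params$nrounds, verbose = 0),
    xgboost = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = params$eta,
                    max_depth = params$max_depth,
                    min_child_weight = params$min_child_weight,
                    subsample = params$subsample,
                    colsample_bytree = params$colsample_bytree,
                    nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(X, label = as.numeric(y)),
      nrounds = params$nrounds, verbose = 0),
    decision_tree = rpart::rpart(
      y ~ ., data = data.frame(y = yf, X, check.names = FALSE),
      method = "class",
      control = rpart::rpart.control(cp = params$cp,
                                     maxdepth = params$maxdepth,
                                     minsplit = params$minsplit))))
  list(family = family, params = params, model = fit, seed = seed,
       calibrated = calibrated)
}

.predictBase <- function(fit, X) {
  switch(fit$family,
    svm = {
      if (fit$calibrated) {
        pr <- stats::predict(fit$model, X, probability = TRUE)
        unname(attr(pr, "probabilities")[, "1"])
      } else {
        # uncalibrated decision values, squashed monotonically; the
        # decision-value column name "A/B" means positive values favour A
        dv <- attr(stats::predict(fit$model, X, decision.values = TRUE),
                   "decision.values")
        sgn <- if (startsWith(colnames(dv)[1], "1/")) 1 else -1
        stats::plogis(sgn * unname(dv[, 1]))
      }
    },
    random_forest = unname(stats::predict(
      fit$model, data = X, num.threads = 1)$predictions[, "1"]),
    knn = {
      pred <- .withSeed(fit$model$seed, class::knn(
        train = fit$model$X, test = X, cl = fit$model$y, k = fit$model$k,
        prob = TRUE, use.all = TRUE))
      pwin <- attr(pred, "prob")
      unname(ifelse(pred == "1", pwin, 1 - pwin))
    },
    lightgbm = unname(stats::predict(fit$model, X)),
    xgboost = unname(stats::predict(fit$model, X)),
    decision_tree = unname(stats::predict(
      fit$model, data.frame(X, check.names = FALSE), type = "prob")[, "1"]))
}

## Stratified fold assignment: shuffle within class, deal round-robin.
.makeFolds <- function(y, k, seed) {
  fold <- integer(length(y))
  .withSeed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Train one base classifier with out-of-fold probabilities
#'
#' Fits a base model family under k-fold cross-validation: every training
#' row receives a probability from a fold model that never saw it, and the
#' final model is refit on all rows.  Fold bookkeeping is returned so
#' leakage can be asserted.  Deterministic under `seed`.
#'
#' @param family one of [modelFamilies()].
#' @param X fingerprint matrix (rows = compounds).
#' @param y 0/1 labels.
#' @param params hyperparameters; `NULL` uses family defaults.
#' @param nFolds number of CV folds, default 5.
#' @param seed integer seed.
#' @param calibrated logical; `FALSE` lets the SVM use (monotonically
#'   squashed) decision values instead of Platt-calibrated probabilities,
#'   which is cheaper and AUC-equivalent during tuning.
#' @return list with `family`, `params`, `fit` (final refit model), `oof`
#'   (out-of-fold probabilities), `foldId`, `cvMetrics`
#'   (a `MetricsReport` on the out-of-fold column) and `trainAUC`
#'   (mean within-fold training AUC).
#' @export
trainBaseModel <- function(family, X, y, params = NULL, nFolds = 5,
                           seed = 42L, calibrated = TRUE) {
  family <- match.arg(family, modelFamilies())
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    stop("labels contain a single class", call. = FALSE)
  }
  if (nrow(X) != length(y)) stop("X rows must match labels", call. = FALSE)
  if (nrow(X) < nFolds) stop("fewer rows than folds", call. = FALSE)
  if (is.null(params)) params <- .defaultParams(family)

  fold <- .makeFolds(y, nFolds, seed)
  oof <- rep(NA_real_, length(y))
  train_auc <- numeric(nFolds)
  for (f in seq_len(nFolds)) {
    tr <- fold != f
    fit_f <- .fitBase(family, X[tr, , drop = FALSE], y[tr], params,
                      seed = seed + f, calibrated = calibrated)
    oof[!tr] <- .predictBase(fit_f, X[!tr, , drop = FALSE])
    train_auc[f] <- .rankAUC(y[tr],
                             .predictBase(fit_f, X[tr, , drop = FALSE]))
  }
  stopifnot(!anyNA(oof))
  final <- .fitBase(family, X, y, params, seed = seed,
                    calibrated = calibrated)
  list(family = family, params = params, fit = final, oof = oof,
       foldId = fold, cvMetrics = suppressWarnings(computeMetrics(y, oof)),
       trainAUC = mean(train_auc), seed = seed)
}

# ---------------------------------------------------------------------------
# Stacking meta-model
# ---------------------------------------------------------------------------

#' Fit the logistic meta-model of the stacking ensemble
#'
#' Ridge-regularized logistic regression over the six base-model
#' probability columns.  The stacked probability is
#' `plogis(intercept + w . p)`.  With degenerate inputs (single-class
#' labels or all-constant columns) the meta-model falls back to the
#' majority-class prior with a warning.
#'
#' @param oofMatrix n x m matrix of out-of-fold base probabilities in
#'   `[0, 1]`.
#' @param y 0/1 labels.
#' @param metaParams list with ridge penalty `lambda` (and optionally
#'   elastic-net `alpha`, default 0).
#' @param seed integer seed (recorded; the fit itself is deterministic).
#' @return list describing the meta-model: `type` (`"logistic"` or
#'   `"prior"`), coefficient vector `w`, `intercept`, `params`, `columns`.
#' @export
trainStacking <- function(oofMatrix, y, metaParams = list(lambda = 0.01),
                          seed = 42L) {
  oofMatrix <- as.matrix(oofMatrix)
  if (any(is.na(oofMatrix)) || any(oofMatrix < 0 | oofMatrix > 1)) {
    stop("out-of-fold probabilities must lie in [0, 1]", call. = FALSE)
  }
  y <- as.integer(y)
  cols <- colnames(oofMatrix)
  if (is.null(cols)) cols <- paste0("m", seq_len(ncol(oofMatrix)))
  degenerate <- length(unique(y)) < 2 ||
    all(apply(oofMatrix, 2, function(col) stats::var(col) == 0))
  if (degenerate) {
    warning("degenerate meta-features or labels: falling back to the ",
            "majority-class prior")
    prior <- mean(y)
    return(list(type = "prior", w = rep(0, ncol(oofMatrix)),
                intercept = stats::qlogis(min(max(prior, 1e-6), 1 - 1e-6)),
                params = metaParams, columns = cols))
  }
  alpha <- if (is.null(metaParams$alpha)) 0 else metaParams$alpha
  lambda <- if (is.null(metaParams$lambda)) 0.01 else metaParams$lambda
  fit <- glmnet::glmnet(oofMatrix, factor(y, levels = c(0, 1)),
                        family = "binomial", alpha = alpha,
                        lambda = lambda, standardize = FALSE)
  cf <- as.numeric(stats::coef(fit))
  list(type = "logistic", w = cf[-1], intercept = cf[1],
       params = list(alpha = alpha, lambda = lambda), columns = cols)
}

.predictMeta <- function(meta, P) {
  stats::plogis(drop(as.matrix(P) %*% meta$w) + meta$intercept)
}

# ---------------------------------------------------------------------------
# Biobjective tuning
# ---------------------------------------------------------------------------

#' Biobjective tuning objective
#'
#' The scalarized score maximized during hyperparameter search:
#' validation (out-of-fold) AUC, minus `lambda` times the part of the
#' train-validation AUC gap exceeding `gapTol`, minus `floorPenalty` times
#' any shortfall below the training-AUC floor (0.9) and validation-AUC
#' floor (0.8), plus `mu` times the agreement fraction on an external
#' experimentally labelled set when one is supplied.
#'
#' @param trainFloor,valFloor AUC floors in (0, 1).
#' @param lambda weight of the train-validation gap penalty.
#' @param gapTol tolerated AUC gap before the penalty starts.
#' @param floorPenalty penalty weight per unit of AUC shortfall.
#' @param mu weight of the external agreement fraction.
#' @return list of objective settings.
#' @export
tuningObjective <- function(trainFloor = 0.9, valFloor = 0.8, lambda = 1,
                            gapTol = 0.1, floorPenalty = 10, mu = 1) {
  stopifnot(trainFloor > 0, trainFloor < 1, valFloor > 0, valFloor < 1,
            lambda >= 0, gapTol >= 0, floorPenalty >= 0, mu >= 0)
  list(trainFloor = trainFloor, valFloor = valFloor, lambda = lambda,
       gapTol = gapTol, floorPenalty = floorPenalty, mu = mu)
}

.objectiveScore <- function(trainAUC, valAUC, externalAgreement, obj) {
  score <- valAUC -
    obj$lambda * max(0, (trainAUC - valAUC) - obj$gapTol) -
    obj$floorPenalty * max(0, obj$trainFloor - trainAUC) -
    obj$floorPenalty * max(0, obj$valFloor - valAUC)
  if (!is.null(externalAgreement) && !is.na(externalAgreement)) {
    score <- score + obj$mu * externalAgreement
  }
  score
}

#' Random-search hyperparameter tuning for one base family
#'
#' Draws `nTrials` hyperparameter sets from the family's search space,
#' scores each with the biobjective criterion under k-fold
#' cross-validation, and returns the best set with the full trial trace.
#' Reproducible under `seed`.
#'
#' @param family one of [modelFamilies()].
#' @param X,y training fingerprints and labels.
#' @param nTrials number of search trials (>= 1).
#' @param objective a [tuningObjective()].
#' @param externalSet optional list with `X` (fingerprints) and `y`
#'   (experimental labels); the agreement fraction at the 0.5 cutoff
#'   enters the objective with weight `mu`.
#' @param nFolds CV folds.
#' @param seed integer seed.
#' @return list with `best` (hyperparameters), `bestTrial`, `record`
#'   (one row per trial: parameters as JSON, train/validation AUC,
#'   external agreement, score).
#' @export
tuneBaseModel <- function(family, X, y, nTrials = 300,
                          objective = tuningObjective(),
                          externalSet = NULL, nFolds = 5, seed = 42L) {
  stopifnot(nTrials >= 1)
  family <- match.arg(family, modelFamilies())
  rows <- vector("list", nTrials)
  best_score <- -Inf; best <- NULL; best_trial <- NA_integer_
  for (t in seq_len(nTrials)) {
    params <- .sampleParams(family, seed = seed + 7919L * t)
    tb <- trainBaseModel(family, X, y, params, nFolds = nFolds,
                         seed = seed, calibrated = FALSE)
    ext <- if (!is.null(externalSet)) {
      p_ext <- .predictBase(tb$fit, externalSet$X)
      externalAgreement(as.integer(p_ext > 0.5),
                        as.integer(externalSet$y))$fraction
    } else NA_real_
    score <- .objectiveScore(tb$trainAUC, tb$cvMetrics$auc, ext, objective)
    rows[[t]] <- data.frame(
      family = family, trial = t,
      params = as.character(jsonlite::toJSON(params, auto_unbox = TRUE,
                                             digits = NA)),
      train_auc = tb$trainAUC, val_auc = tb$cvMetrics$auc,
      external_agreement = ext, score = score)
    if (score > best_score) {
      best_score <- score; best <- params; best_trial <- t
    }
  }
  list(best = best, bestTrial = best_trial, record = do.call(rbind, rows))
}

## Meta-level tuning: CV over the out-of-fold matrix itself.
.tuneMeta <- function(oofMatrix, y, nTrials, objective, externalSet = NULL,
                      extBase = NULL, nFolds = 5, seed = 42L) {
  rows <- vector("list", nTrials)
  best_score <- -Inf; best <- NULL; best_trial <- NA_integer_
  fold <- .makeFolds(y, nFolds, seed + 1L)
  for (t in seq_len(nTrials)) {
    lambda <- .withSeed(seed + 104729L * t, 10^stats::runif(1, -4, 0))
    params <- list(alpha = 0, lambda = lambda)
    oof_meta <- rep(NA_real_, length(y))
    tr_auc <- numeric(nFolds)
    for (f in seq_len(nFolds)) {
      tr <- fold != f
      m <- suppressWarnings(
        trainStacking(oofMatrix[tr, , drop = FALSE], y[tr], params, seed))
      oof_meta[!tr] <- .predictMeta(m, oofMatrix[!tr, , drop = FALSE])
      tr_auc[f] <- .rankAUC(y[tr],
                            .predictMeta(m, oofMatrix[tr, , drop = FALSE]))
    }
    val_auc <- .rankAUC(y, oof_meta)
    ext <- if (!is.null(extBase)) {
      m_full <- suppressWarnings(trainStacking(oofMatrix, y, params, seed))
      p_ext <- .predictMeta(m_full, extBase)
      externalAgreement(as.integer(p_ext > 0.5),
                        as.integer(externalSet$y))$fraction
    } else NA_real_
    score <- .objectiveScore(mean(tr_auc), val_auc, ext, objective)
    rows[[t]] <- data.frame(
      family = "meta_logistic", trial = t,
      params = as.character(jsonlite::toJSON(params, auto_unbox = TRUE,
                                             digits = NA)),
      train_auc = mean(tr_auc), val_auc = val_auc,
      external_agreement = ext, score = score)
    if (score > best_score) {
      best_score <- score; best <- params; best_trial <- t
    }
  }
  list(best = best, bestTrial = best_trial, record = do.call(rbind, rows))
}

# ---------------------------------------------------------------------------
# ToxModelBundle
# ---------------------------------------------------------------------------

#' @rdname trainToxModel
#' @export
setClass("ToxModelBundle",
         representation(baseModels = "list",
                        metaModel = "list",
                        families = "character",
                        dictionaryHash = "character",
                        seed = "integer",
                        tuningRecord = "data.frame",
                        metaFeatures = "character"))

setValidity("ToxModelBundle", function(object) {
  msg <- character(0)
  if (length(object@baseModels) != length(object@families))
    msg <- c(msg, "one fitted model per family required")
  if (!identical(object@metaFeatures, object@families))
    msg <- c(msg, "meta-feature order must equal the family order")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ToxModelBundle", function(object) {
  cat("ToxModelBundle: stacking ensemble of",
      length(object@families), "base models\n")
  cat("  families:", paste(object@families, collapse = ", "), "\n")
  cat("  meta-model:", object@metaModel$type,
      sprintf("(lambda = %.4g)",
              if (is.null(object@metaModel$params$lambda)) NA
              else object@metaModel$params$lambda), "\n")
  cat("  dictionary hash:", object@dictionaryHash, "\n")
  cat("  seed:", object@seed, "\n")
  if (nrow(object@tuningRecord)) {
    cat("  tuning trials:", nrow(object@tuningRecord), "\n")
  }
})

#' Train the stacking ensemble
#'
#' End-to-end training: optional biobjective hyperparameter search per base
#' family, k-fold out-of-fold probability generation for all six base
#' models (the anti-leakage meta-features), meta-model tuning and fit, and
#' assembly of a [ToxModelBundle] tied to the fingerprint dictionary that
#' produced `X`.
#'
#' @param X 0/1 fingerprint matrix of the training compounds (166
#'   columns); the `dictionary_hash` attribute set by
#'   [computeFingerprints()] is recorded in the bundle.
#' @param y 0/1 toxicity labels.
#' @param nTrials tuning trials per base family (0 skips tuning and uses
#'   family defaults).
#' @param metaTrials tuning trials for the logistic meta-model.
#' @param objective a [tuningObjective()].
#' @param externalSet optional external experimentally labelled set
#'   (list with `X`, `y`) consumed by the biobjective criterion.
#' @param nFolds CV folds, default 5.
#' @param seed integer seed governing folds, search and fits.
#' @param inFoldMeta use in-fold (refit-model) probabilities instead of
#'   out-of-fold ones as meta-features; available for comparison only,
#'   the default `FALSE` is the standard anti-leakage choice.
#' @return A [ToxModelBundle].
#' @seealso [predictToxicity()], [saveToxModel()]
#' @export
trainToxModel <- function(X, y, nTrials = 300, metaTrials = 70,
                          objective = tuningObjective(),
                          externalSet = NULL, nFolds = 5, seed = 42L,
                          inFoldMeta = FALSE) {
  X <- as.matrix(X)
  y <- as.integer(y)
  families <- modelFamilies()
  dict_hash <- attr(X, "dictionary_hash")
  if (is.null(dict_hash)) dict_hash <- NA_character_

  records <- list()
  base_fits <- vector("list", length(families))
  names(base_fits) <- families
  oof <- matrix(NA_real_, nrow(X), length(families),
                dimnames = list(NULL, families))
  for (i in seq_along(families)) {
    fam <- families[i]
    fam_seed <- seed + 1000L * i
    params <- if (nTrials > 0) {
      tuned <- tuneBaseModel(fam, X, y, nTrials = nTrials,
                             objective = objective,
                             externalSet = externalSet,
                             nFolds = nFolds, seed = fam_seed)
      records[[fam]] <- tuned$record
      tuned$best
    } else NULL
    tb <- trainBaseModel(fam, X, y, params, nFolds = nFolds,
                         seed = fam_seed, calibrated = TRUE)
    base_fits[[fam]] <- tb$fit
    oof[, fam] <- if (inFoldMeta) .predictBase(tb$fit, X) else tb$oof
  }

  ext_base <- if (!is.null(externalSet)) {
    vapply(base_fits, function(f) .predictBase(f, externalSet$X),
           numeric(nrow(externalSet$X)))
  } else NULL
  meta_params <- list(alpha = 0, lambda = 0.01)
  if (metaTrials > 0) {
    mt <- .tuneMeta(oof, y, metaTrials, objective, externalSet, ext_base,
                    nFolds = nFolds, seed = seed)
    records[["meta"]] <- mt$record
    meta_params <- mt$best
  }
  meta <- trainStacking(oof, y, meta_params, seed)

  new("ToxModelBundle", baseModels = base_fits, metaModel = meta,
      families = families, dictionaryHash = dict_hash,
      seed = as.integer(seed),
      tuningRecord = if (length(records)) do.call(rbind, c(records,
        make.row.names = FALSE)) else data.frame(),
      metaFeatures = families)
}

#' Base-model probabilities
#'
#' @param bundle a [ToxModelBundle].
#' @param X fingerprint matrix.
#' @return n x 6 matrix of positive-class probabilities, columns in the
#'   bundle's meta-feature order.
#' @export
baseProbabilities <- function(bundle, X) {
  stopifnot(is(bundle, "ToxModelBundle"))
  X <- as.matrix(X)
  P <- vapply(bundle@baseModels, function(f) .predictBase(f, X),
              numeric(nrow(X)))
  if (nrow(X) == 1) P <- matrix(P, 1, dimnames = list(NULL, names(P)))
  P[, bundle@metaFeatures, drop = FALSE]
}

.checkPredictInput <- function(bundle, X) {
  if (ncol(X) != 166) {
    stop("fingerprint matrix must have 166 columns, got ", ncol(X),
         call. = FALSE)
  }
  hash <- attr(X, "dictionary_hash")
  if (!is.null(hash) && !is.na(bundle@dictionaryHash) &&
      !identical(hash, bundle@dictionaryHash)) {
    stop("fingerprint dictionary mismatch: model was trained with ",
         bundle@dictionaryHash, " but input was computed with ", hash,
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Predict toxicity with a trained bundle
#'
#' @param object a [ToxModelBundle].
#' @param newdata 0/1 fingerprint matrix (166 columns).  If it carries a
#'   `dictionary_hash` attribute that differs from the bundle's, prediction
#'   is refused.
#' @param ... unused.
#' @return `data.frame` with `probability` (stacked positive-class
#'   probability) and `label` (1 when probability strictly exceeds 0.5, so
#'   a probability of exactly 0.5 gives label 0).
#' @export
setMethod("predict", "ToxModelBundle", function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  .checkPredictInput(object, newdata)
  p <- .predictMeta(object@metaModel, baseProbabilities(object, newdata))
  data.frame(probability = p, label = as.integer(p > 0.5))
})

#' Stacked-probability closure for model explanation
#'
#' Returns the end-to-end function mapping a 166-bit fingerprint matrix to
#' the stacked positive-class probability; this is the black-box function
#' the Shapley attribution explains.
#'
#' @param bundle a [ToxModelBundle].
#' @return `function(X) -> numeric` of probabilities.
#' @export
stackedProbability <- function(bundle) {
  stopifnot(is(bundle, "ToxModelBundle"))
  force(bundle)
  function(X) {
    X <- as.matrix(X)
    .predictMeta(bundle@metaModel, baseProbabilities(bundle, X))
  }
}

# ---------------------------------------------------------------------------
# Bundle persistence
# ---------------------------------------------------------------------------

#' Save / load a model bundle
#'
#' Serializes a [ToxModelBundle] to a directory: a JSON manifest (families,
#' seed, dictionary hash, meta-model coefficients and hyperparameters), the
#' tuning trace as delimited text, and per-model binary artifacts.  A
#' round-tripped bundle predicts identically.
#'
#' @param bundle a [ToxModelBundle].
#' @param dir target directory (created if needed).
#' @return `saveToxModel` returns `dir` invisibly; `loadToxModel` returns
#'   the restored [ToxModelBundle].
#' @export
saveToxModel <- function(bundle, dir) {
  stopifnot(is(bundle, "ToxModelBundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "StackTox",
    families = bundle@families,
    seed = bundle@seed,
    dictionary_hash = bundle@dictionaryHash,
    meta_model = bundle@metaModel,
    base_params = lapply(bundle@baseModels, `[[`, "params"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (nrow(bundle@tuningRecord)) {
    utils::write.table(bundle@tuningRecord,
                       file.path(dir, "tuning_record.tsv"),
                       sep = "\t", row.names = FALSE, quote = TRUE)
  }
  saveRDS(list(baseModels = bundle@baseModels,
               metaModel = bundle@metaModel),
          file.path(dir, "base_models.rds"))
  invisible(dir)
}

#' @rdname saveToxModel
#' @export
loadToxModel <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  tr_file <- file.path(dir, "tuning_record.tsv")
  tuning <- if (file.exists(tr_file)) {
    utils::read.delim(tr_file, stringsAsFactors = FALSE)
  } else data.frame()
  artifacts <- readRDS(file.path(dir, "base_models.rds"))
  new("ToxModelBundle",
      baseModels = artifacts$baseModels,
      metaModel = artifacts$metaModel,
      families = manifest$families,
      dictionaryHash = manifest$dictionary_hash,
      seed = as.integer(manifest$seed),
      tuningRecord = tuning,
      metaFeatures = manifest$families)
}
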