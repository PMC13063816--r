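# Shared small training set: planted-rule population, fingerprints cached
# once for the whole file.
.mod_env <- new.env()
modData <- function() {
  if (is.null(.mod_env$data)) {
    pop <- generateCompounds(syntheticConfig(n = 350, seed = 2024))
    cur <- curateCompounds(pop)
    X <- computeFingerprints(cur$records$canonical_smiles)
    .mod_env$data <- list(X = X, y = cur$records$label,
                          records = cur$records)
  }
  .mod_env$data
}

test_that("tree ensembles separate planted-rule data and fail on noise", {
  d <- modData()
  for (fam in c("random_forest", "xgboost", "lightgbm")) {
    tb <- trainBaseModel(fam, d$X, d$y, seed = 7)
    expect_gt(tb$cvMetrics$auc, 0.85)
    expect_gt(tb$trainAUC, 0.95)
  }
  # permuted labels carry no signal
  set.seed(8)
  tb0 <- trainBaseModel("xgboost", d$X, sample(d$y), seed = 7)
  expect_lt(abs(tb0$cvMetrics$auc - 0.5), 0.12)
})

test_that("out-of-fold columns are reproducible and leakage-free", {
  d <- modData()
  a <- trainBaseModel("lightgbm", d$X, d$y, seed = 99)
  b <- trainBaseModel("lightgbm", d$X, d$y, seed = 99)
  expect_identical(a$oof, b$oof)
  expect_identical(a$foldId, b$foldId)
  c2 <- trainBaseModel("lightgbm", d$X, d$y, seed = 100)
  expect_false(identical(a$oof, c2$oof))

  # leakage probe: a 1-NN memorizes any row it saw.  With unique rows and
  # random labels, in-fold predictions would be perfect; out-of-fold ones
  # must not be.
  set.seed(1)
  Xu <- matrix(rbinom(80 * 40, 1, 0.5), 80)
  Xu <- Xu[!duplicated(Xu), ]
  yu <- rbinom(nrow(Xu), 1, 0.5)
  if (length(unique(yu)) == 2) {
    knn1 <- trainBaseModel("knn", Xu, yu, params = list(k = 1), seed = 3)
    oof_acc <- mean(as.integer(knn1$oof > 0.5) == yu)
    infold <- .predictBase(knn1$fit, Xu)
    expect_equal(mean(as.integer(infold > 0.5) == yu), 1)  # memorized
    expect_lt(oof_acc, 0.9)                                # not leaked
  }
  # every row is assigned a fold and folds partition the data
  expect_setequal(unique(a$foldId), 1:5)
})

test_that("degenerate inputs to training are rejected", {
  d <- modData()
  expect_error(trainBaseModel("svm", d$X, rep(1, nrow(d$X))),
               "single class")
  expect_error(trainBaseModel("svm", d$X[1:3, ], d$y[1:3], nFolds = 5),
               "single class|fewer rows")
})

test_that("the stacking meta-model honours its contract", {
  d <- modData()
  set.seed(5)
  y <- d$y
  # six identical perfectly calibrated columns: stacked AUC equals base AUC
  p <- plogis(rnorm(length(y), ifelse(y == 1, 1.2, -1.2)))
  oof <- matrix(rep(p, 6), ncol = 6)
  meta <- trainStacking(oof, y, list(lambda = 1e-4))
  stacked <- .predictMeta(meta, oof)
  expect_equal(suppressWarnings(computeMetrics(y, stacked)$auc),
               suppressWarnings(computeMetrics(y, p)$auc))

  # one informative column among five noise columns at n = 2000
  set.seed(6)
  n <- 2000
  y2 <- rbinom(n, 1, 0.5)
  info <- plogis(rnorm(n, ifelse(y2 == 1, 1, -1)))
  oof2 <- cbind(info, matrix(runif(n * 5), n))
  meta2 <- trainStacking(oof2, y2, list(lambda = 1e-3))
  auc_info <- computeMetrics(y2, info)$auc
  auc_stack <- computeMetrics(y2, .predictMeta(meta2, oof2))$auc
  expect_gte(auc_stack, auc_info - 0.02)

  # probabilities outside [0, 1] violate the precondition
  bad <- oof; bad[1, 1] <- 1.2
  expect_error(trainStacking(bad, y), "\\[0, 1\\]")

  # degenerate all-constant features fall back to the prior
  expect_warning(prior <- trainStacking(matrix(0.5, 40, 6), rbinom(40, 1, 0.7)),
                 "majority-class prior")
  expect_identical(prior$type, "prior")
})

test_that("the biobjective score responds to every term", {
  obj <- tuningObjective()
  base <- .objectiveScore(0.95, 0.85, NULL, obj)
  expect_equal(base, 0.85)                     # inside all floors and gap
  # gap penalty beyond the tolerance
  expect_equal(.objectiveScore(0.99, 0.85, NULL, obj), 0.85 - 0.04)
  # floor shortfall dominates
  expect_lt(.objectiveScore(0.95, 0.70, NULL, obj), 0)
  # the external term can flip a selection
  t1 <- .objectiveScore(0.95, 0.86, 0.2, obj)
  t2 <- .objectiveScore(0.95, 0.84, 0.9, obj)
  expect_gt(t2, t1)  # worse validation AUC wins through external agreement
  mu0 <- tuningObjective(mu = 0)
  expect_gt(.objectiveScore(0.95, 0.86, 0.2, mu0),
            .objectiveScore(0.95, 0.84, 0.9, mu0))
})

test_that("random search is seeded, records all trials and uses the external set", {
  d <- modData()
  ext <- list(X = d$X[1:30, ], y = d$y[1:30])
  t1 <- tuneBaseModel("decision_tree", d$X, d$y, nTrials = 3, seed = 11,
                      externalSet = ext)
  t2 <- tuneBaseModel("decision_tree", d$X, d$y, nTrials = 3, seed = 11,
                      externalSet = ext)
  expect_identical(t1$bestTrial, t2$bestTrial)
  expect_identical(t1$record$score, t2$record$score)
  expect_identical(nrow(t1$record), 3L)
  expect_true(all(!is.na(t1$record$external_agreement)))
  # the recorded score actually contains the external term
  obj <- tuningObjective()
  recomputed <- .objectiveScore(t1$record$train_auc[1], t1$record$val_auc[1],
                                t1$record$external_agreement[1], obj)
  expect_equal(t1$record$score[1], recomputed)
  # a single trial returns that point
  one <- tuneBaseModel("knn", d$X, d$y, nTrials = 1, seed = 4)
  expect_identical(one$bestTrial, 1L)
  expect_error(tuneBaseModel("knn", d$X, d$y, nTrials = 0), "nTrials")
})

test_that("the assembled bundle predicts, refuses mismatches and round-trips", {
  d <- modData()
  bundle <- trainToxModel(d$X, d$y, nTrials = 0, metaTrials = 0, seed = 21)
  pr <- predict(bundle, d$X)
  expect_true(all(pr$probability >= 0 & pr$probability <= 1))
  expect_identical(pr$label, as.integer(pr$probability > 0.5))
  # tie probability 0.5 maps to label 0 (strict inequality)
  expect_identical(as.integer(0.5 > 0.5), 0L)

  # dictionary hash mismatch is refused with both hashes named
  X_alien <- d$X
  attr(X_alien, "dictionary_hash") <- "0000"
  expect_error(predict(bundle, X_alien), "dictionary mismatch.*0000")
  expect_error(predict(bundle, d$X[, 1:100]), "166")

  # save/load round-trip predicts identically
  dir <- tempfile()
  saveToxModel(bundle, dir)
  restored <- loadToxModel(dir)
  expect_identical(predict(restored, d$X)$probability, pr$probability)
  expect_true(file.exists(file.path(dir, "manifest.json")))

  # end-to-end reproducibility under the same seed
  bundle2 <- trainToxModel(d$X, d$y, nTrials = 0, metaTrials = 0, seed = 21)
  expect_identical(predict(bundle2, d$X)$probability, pr$probability)
})
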