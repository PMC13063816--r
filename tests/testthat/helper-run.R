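# Shared end-to-end study run used by several acceptance checks.
# Computed once per test session: synthetic population (n = 2000, four
# planted substructure effects, noise SD 0.4), curation, 90/10 split,
# reduced biobjective tuning (20 trials per base family, 10 meta trials),
# stacked prediction on the held-out test set, and Shapley attribution of
# the stacked model over a 100-row test subsample against a 100-row
# training background.

.study_env <- new.env()

studyRun <- function() {
  if (!is.null(.study_env$run)) return(.study_env$run)
  seed <- 101L
  pop <- generateCompounds(syntheticConfig(n = 2000, seed = seed))
  cur <- curateCompounds(pop)
  sp <- splitCompounds(cur$records, 0.10, seed = seed)
  dict <- defaultDictionary()
  Xtr <- computeFingerprints(sp$train$canonical_smiles, dict)
  Xte <- computeFingerprints(sp$test$canonical_smiles, dict)
  bundle <- trainToxModel(Xtr, sp$train$label, nTrials = 20,
                          metaTrials = 10, seed = seed)
  pred <- predict(bundle, Xte)
  stacked <- computeMetrics(sp$test$label, pred$probability)
  base_auc <- vapply(modelFamilies(), function(fam) {
    computeMetrics(sp$test$label,
                   .predictBase(bundle@baseModels[[fam]], Xte))$auc
  }, numeric(1))
  bg <- Xtr[.withSeed(seed, sample(nrow(Xtr), 100)), ]
  expl <- Xte[.withSeed(seed + 1L, sample(nrow(Xte), 100)), ]
  attr(expl, "dictionary_hash") <- dictionaryHash(dict)
  shap <- shapValues(bundle, expl, bg, mode = "sampling",
                     nPermutations = 32, seed = seed)
  .study_env$run <- list(
    curation = cur, split = sp, dict = dict, bundle = bundle,
    testMetrics = stacked, baseAUC = base_auc, shap = shap,
    topBits = rankBits(shap, dict, k = 5))
  .study_env$run
}
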