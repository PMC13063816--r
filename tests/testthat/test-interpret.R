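# Toy logistic models over 8 binary features make the Shapley axioms
# directly checkable against full coalition enumeration.

test_that("exact attributions satisfy the Shapley axioms on toy models", {
  # constant model: all attributions zero
  f_const <- function(X) rep(0.42, nrow(as.matrix(X)))
  X <- matrix(rbinom(3 * 8, 1, 0.5), 3)
  bg <- matrix(rbinom(10 * 8, 1, 0.5), 10)
  ex <- shapValues(f_const, X, bg, mode = "exact")
  expect_equal(max(abs(ex@values)), 0)
  expect_equal(ex@baseValue, 0.42)

  # symmetry: two features with identical behaviour get equal credit
  f_sym <- function(X) plogis(as.matrix(X) %*% c(1, 1, 0, 0))[, 1]
  e2 <- shapValues(f_sym, matrix(c(1, 1, 1, 0), 1), matrix(0, 1, 4),
                   mode = "exact")
  expect_equal(unname(e2@values[1, 1]), unname(e2@values[1, 2]))

  # null player: a feature the model ignores gets zero
  w <- c(2, -1.5, 1, 0.5, -0.5, 0.25, 0, 3)
  f_lin <- function(X) plogis(as.matrix(X) %*% w - 1)[, 1]
  set.seed(3)
  X8 <- matrix(rbinom(5 * 8, 1, 0.5), 5)
  bg8 <- matrix(rbinom(16 * 8, 1, 0.5), 16)
  e3 <- shapValues(f_lin, X8, bg8, mode = "exact")
  expect_equal(max(abs(e3@values[, 7])), 0)
  # local accuracy in exact mode
  expect_lt(max(shapLocalAccuracy(e3, f_lin)), 1e-6)
})

test_that("sampling estimates converge to the coalition-enumeration oracle", {
  set.seed(4)
  w <- c(2, -1.5, 1, 0.5, -0.5, 0.25, 0, 3)
  f <- function(X) plogis(as.matrix(X) %*% w - 1)[, 1]
  X <- matrix(rbinom(4 * 8, 1, 0.5), 4)
  bg <- matrix(rbinom(16 * 8, 1, 0.5), 16)
  exact <- shapValues(f, X, bg, mode = "exact")
  samp <- shapValues(f, X, bg, mode = "sampling", nPermutations = 2000,
                     seed = 5)
  # agreement within 3 Monte-Carlo standard errors wherever variance exists
  dev <- abs(samp@values - exact@values)
  has_se <- samp@se > 0
  expect_true(all(dev[has_se] <= 3 * samp@se[has_se]))
  expect_lt(max(dev[!has_se]), 1e-12)
  # sampling mode keeps local accuracy exactly
  expect_lt(max(shapLocalAccuracy(samp, f)), 1e-10)
  # reproducible under seed
  samp2 <- shapValues(f, X, bg, mode = "sampling", nPermutations = 50,
                      seed = 5)
  samp3 <- shapValues(f, X, bg, mode = "sampling", nPermutations = 50,
                      seed = 5)
  expect_identical(samp2@values, samp3@values)
})

test_that("exact mode refuses too many active features", {
  f <- function(X) rowMeans(as.matrix(X))
  X <- matrix(1, 1, 20)
  bg <- matrix(0, 1, 20)
  expect_error(shapValues(f, X, bg, mode = "exact"), "sampling")
})

test_that("bit ranking orders by mean |SHAP| with stable ties", {
  dict <- defaultDictionary()
  # synthetic explanation: one dominant bit, controlled signs
  vals <- matrix(0, 10, 166, dimnames = list(NULL, paste0("bit_", 0:165)))
  Xb <- matrix(0, 10, 166, dimnames = list(NULL, paste0("bit_", 0:165)))
  vals[, 47] <- 0.3   # bit_46 (column 47) dominant, positive
  Xb[, 47] <- 1
  vals[1:5, 10] <- -0.1  # bit_9 weaker, negative among carriers
  Xb[1:5, 10] <- 1
  sh <- new("ShapExplanation", values = vals, se = matrix(0, 0, 0),
            baseValue = 0.5, mode = "exact", X = Xb,
            backgroundIds = "1", dictionaryHash = dictionaryHash(dict))
  rk <- rankBits(sh, dict, k = 3)
  expect_identical(rk$bit[1], 46L)
  expect_identical(rk$direction[1], "toxicity_up")
  expect_identical(rk$bit[2], 9L)
  expect_identical(rk$direction[2], "toxicity_down")
  # all-zero attributions: stable ascending index order
  sh0 <- new("ShapExplanation", values = vals * 0, se = matrix(0, 0, 0),
             baseValue = 0.5, mode = "exact", X = Xb,
             backgroundIds = "1", dictionaryHash = dictionaryHash(dict))
  rk0 <- rankBits(sh0, dict, k = 5)
  expect_identical(rk0$bit, 0:4)
  # k = 0 and clamping
  expect_identical(nrow(rankBits(sh, dict, k = 0)), 0L)
  expect_warning(rk_all <- rankBits(sh, dict, k = 500), "clamped")
  expect_identical(nrow(rk_all), 166L)
})

test_that("profile clustering separates opposing attribution families", {
  set.seed(10)
  # two families driven by disjoint bits with opposite signs
  fam1 <- matrix(rnorm(25 * 166, 0, 0.01), 25); fam1[, 5] <- 0.5
  fam2 <- matrix(rnorm(25 * 166, 0, 0.01), 25); fam2[, 100] <- -0.5
  vals <- rbind(fam1, fam2)
  colnames(vals) <- paste0("bit_", 0:165)
  sh <- new("ShapExplanation", values = vals, se = matrix(0, 0, 0),
            baseValue = 0.5, mode = "exact", X = (vals != 0) * 1,
            backgroundIds = "1", dictionaryHash = NA_character_)
  cl <- clusterProfiles(sh, 2)
  truth <- rep(0:1, each = 25)
  purity <- max(mean(cl$labels == truth), mean(cl$labels == 1 - truth))
  expect_gte(purity, 0.9)
  expect_identical(dim(cl$profiles), c(2L, 166L))
  # single cluster and duplicate rows
  expect_identical(unique(clusterProfiles(sh, 1)$labels), 0L)
  dup <- new("ShapExplanation", values = vals[c(1, 1, 30, 30), ],
             se = matrix(0, 0, 0), baseValue = 0.5,
             X = (vals[c(1, 1, 30, 30), ] != 0) * 1, mode = "exact",
             backgroundIds = "1", dictionaryHash = NA_character_)
  cl2 <- clusterProfiles(dup, 2)
  expect_identical(cl2$labels[1], cl2$labels[2])
  expect_identical(cl2$labels[3], cl2$labels[4])
  expect_error(clusterProfiles(sh, 0), ">= 1")
  expect_error(clusterProfiles(dup, 10), "at least")
})

test_that("compound annotation reports matches with atom locations", {
  dict <- defaultDictionary()
  rules <- data.frame(bit = c(46L, 0L), direction = "toxicity_up",
                      mean_abs_shap = c(0.3, 0.2),
                      description = c("aromatic nitro group",
                                      "primary aromatic amine"),
                      stringsAsFactors = FALSE)
  attr(rules, "dictionary_hash") <- dictionaryHash(dict)
  hits <- annotateCompound("O=[N+]([O-])c1ccccc1", rules, dict)
  expect_identical(hits$bit, 46L)
  expect_identical(length(hits$matches[[1]]), 1L)
  expect_true(all(lengths(hits$matches[[1]]) > 0))
  # methane matches no aromatic rule
  expect_identical(nrow(annotateCompound("C", rules, dict)), 0L)
  # two distinct matches of one pattern are both located
  dinitro <- annotateCompound("O=[N+]([O-])c1ccc(cc1)[N+](=O)[O-]",
                              rules, dict)
  expect_identical(length(dinitro$matches[[1]]), 2L)
  locs <- dinitro$matches[[1]]
  expect_false(identical(sort(locs[[1]]), sort(locs[[2]])))
  # dictionary mismatch refusal
  attr(rules, "dictionary_hash") <- "stale"
  expect_error(annotateCompound("C", rules, dict), "stale")
})

test_that("screening sorts by label, probability, then entropy, stably", {
  probs <- c(a = 0.95, b = 0.40, c = 0.60, d = 0.95, e = 0.10)
  tab <- screenCompounds(names(probs), unname(probs))
  # toxic predictions first, by probability; ties keep input order
  expect_identical(tab$id[1:2], c("a", "d"))
  expect_identical(tab$id[3], "c")
  # among non-toxic, 0.40 has higher entropy than 0.10 but sorts by
  # probability first
  expect_identical(tab$id[4:5], c("b", "e"))
  expect_identical(tab$rank, 1:5)
  # rule-match counting feeds the table
  dict <- defaultDictionary()
  fps <- computeFingerprints(c("O=[N+]([O-])c1ccccc1", "CCCCCCO"), dict)
  rules <- data.frame(bit = 46L, direction = "toxicity_up",
                      mean_abs_shap = 0.3, description = "aromatic nitro")
  tab2 <- screenCompounds(c("nitro", "hexanol"), c(0.9, 0.2), fps = fps,
                          rules = rules)
  expect_identical(tab2$matched_rules[tab2$id == "nitro"], 1L)
  expect_identical(tab2$matched_rules[tab2$id == "hexanol"], 0L)
})

test_that("extracted rules keep dictionary lineage and survive file I/O", {
  dict <- defaultDictionary()
  vals <- matrix(0, 4, 166, dimnames = list(NULL, paste0("bit_", 0:165)))
  vals[, 47] <- 0.25
  Xb <- vals != 0
  sh <- new("ShapExplanation", values = vals, se = matrix(0, 0, 0),
            baseValue = 0.5, mode = "exact", X = Xb * 1,
            backgroundIds = "1", dictionaryHash = dictionaryHash(dict))
  rules <- extractRules(sh, dict, k = 5)
  expect_identical(rules$bit[1], 46L)
  expect_identical(attr(rules, "dictionary_hash"), dictionaryHash(dict))
  f <- tempfile(fileext = ".tsv")
  writeRules(rules, f)
  back <- readRules(f)
  expect_identical(back$bit, rules$bit)
  expect_identical(attr(back, "dictionary_hash"), dictionaryHash(dict))
})
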