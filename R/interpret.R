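# ---------------------------------------------------------------------------
# Shapley attribution for the stacked model
# ---------------------------------------------------------------------------

#' @rdname shapValues
#' @export
setClass("ShapExplanation",
         representation(values = "matrix",
                        se = "matrix",
                        baseValue = "numeric",
                        mode = "character",
                        X = "matrix",
                        backgroundIds = "character",
                        dictionaryHash = "character"))

setMethod("show", "ShapExplanation", function(object) {
  cat("ShapExplanation:", nrow(object@values), "compounds x",
      ncol(object@values), "features (", object@mode, "mode )\n")
  cat(sprintf("  base value: %.4f\n", object@baseValue))
  top <- utils::head(order(colMeans(abs(object@values)), decreasing = TRUE), 5)
  cat("  top features by mean |SHAP|:",
      paste(colnames(object@values)[top], collapse = ", "), "\n")
})

## Exact Shapley for one row against one background row by coalition
## enumeration over the active (differing) features.
.exactShapOne <- function(f, x, z, maxActive) {
  p <- length(x)
  active <- which(x != z)
  a <- length(active)
  phi <- numeric(p)
  if (a == 0) return(phi)
  if (a > maxActive) {
    stop("exact mode supports at most ", maxActive, " active features (",
         a, " differ from the background row); use mode = \"sampling\"",
         call. = FALSE)
  }
  n_sub <- 2^a
  # all coalition vectors in one batch
  masks <- matrix(FALSE, n_sub, a)
  for (j in seq_len(a)) {
    masks[, j] <- bitwAnd(seq_len(n_sub) - 1L, bitwShiftL(1L, j - 1L)) > 0
  }
  V <- matrix(rep(z, each = n_sub), n_sub, p)
  for (j in seq_len(a)) V[masks[, j], active[j]] <- x[active[j]]
  fv <- f(V)
  size <- rowSums(masks)
  # Shapley kernel weights by coalition size (excluding the added player)
  wt <- exp(lfactorial(0:(a - 1)) + lfactorial(a - 1 - (0:(a - 1))) -
              lfactorial(a))
  for (j in seq_len(a)) {
    without <- which(!masks[, j])
    with_j <- without + 2^(j - 1)
    phi[active[j]] <- sum(wt[size[without] + 1] * (fv[with_j] - fv[without]))
  }
  phi
}

#' Shapley-value attribution of stacked predictions
#'
#' Model-agnostic Shapley values for the end-to-end stacked probability
#' function over the 166 fingerprint bits.  `mode = "exact"` enumerates all
#' coalitions of the features on which the explained row differs from each
#' background row (at most `maxActive` of them) and is exact.  `mode =
#' "sampling"` is a permutation estimator: for each random permutation a
#' background row is morphed feature-by-feature into the explained row and
#' marginal gains are attributed.  Both modes satisfy local accuracy
#' exactly up to floating point: per-row attributions sum to the model
#' output minus the base value (the mean model output over the background
#' draws).  Sampling mode additionally reports per-feature Monte-Carlo
#' standard errors.
#'
#' @param model a [ToxModelBundle] or any `function(X) -> probability`.
#' @param X matrix of rows to explain.
#' @param background background fingerprint sample (matrix); attribution
#'   is relative to this reference population.
#' @param mode `"sampling"` (default) or `"exact"`.
#' @param nPermutations permutations per explained row (sampling mode).
#' @param maxActive exact-mode cap on differing features per background
#'   row.
#' @param seed integer seed.
#' @return A `ShapExplanation` with `values` (n x p), `se` (sampling
#'   mode), `baseValue`, the explained rows and the background ids.
#' @export
shapValues <- function(model, X, background,
                       mode = c("sampling", "exact"),
                       nPermutations = 32L, maxActive = 12L, seed = 42L) {
  mode <- match.arg(mode)
  f0 <- if (is(model, "ToxModelBundle")) stackedProbability(model) else model
  stopifnot(is.function(f0))
  X <- as.matrix(X)
  background <- as.matrix(background)
  # constructed coalition matrices must keep the feature names some
  # backends (ranger, rpart) require
  f <- if (!is.null(colnames(X))) {
    function(M) {
      colnames(M) <- colnames(X)
      f0(M)
    }
  } else f0
  if (nrow(background) < 1) stop("background must be non-empty",
                                 call. = FALSE)
  p <- ncol(X)
  n <- nrow(X)
  dict_hash <- attr(X, "dictionary_hash")
  bg_ids <- if (!is.null(rownames(background))) rownames(background) else
    as.character(seq_len(nrow(background)))

  if (mode == "exact") {
    vals <- matrix(0, n, p)
    for (r in seq_len(n)) {
      per_bg <- vapply(seq_len(nrow(background)), function(b) {
        .exactShapOne(f, X[r, ], background[b, ], maxActive)
      }, numeric(p))
      vals[r, ] <- rowMeans(per_bg)
    }
    base <- mean(f(background))
    se <- matrix(0, 0, 0)
  } else {
    m <- as.integer(nPermutations)
    nbg <- nrow(background)
    # shared background draw sequence: permutation j uses background row
    # ((j-1) mod nbg) + 1, so the base value is one scalar for all rows
    bg_idx <- ((seq_len(m) - 1L) %% nbg) + 1L
    perms <- .withSeed(seed, lapply(seq_len(m), function(j) sample.int(p)))
    contrib <- array(0, c(n, p, 2))  # running sum and sum of squares
    base_vals <- f(background[bg_idx, , drop = FALSE])
    for (j in seq_len(m)) {
      z <- background[bg_idx[j], ]
      pi_j <- perms[[j]]
      # features identical to the background contribute nothing along the
      # walk; only the differing ones need evaluations
      stage_list <- vector("list", n)
      diff_list <- vector("list", n)
      for (r in seq_len(n)) {
        x <- X[r, ]
        d <- which(x != z)
        d_ord <- pi_j[pi_j %in% d]
        k <- length(d_ord)
        diff_list[[r]] <- d_ord
        if (k) {
          staged <- matrix(rep(z, each = k), k, p)
          for (s in seq_len(k)) {
            staged[s:k, d_ord[s]] <- x[d_ord[s]]
          }
          stage_list[[r]] <- staged
        }
      }
      ks <- lengths(diff_list)
      if (sum(ks) == 0) next
      big <- do.call(rbind, stage_list[ks > 0])
      fv <- f(big)
      offset <- 0L
      for (r in seq_len(n)) {
        k <- ks[r]
        if (!k) next
        vr <- fv[(offset + 1L):(offset + k)]
        offset <- offset + k
        inc <- diff(c(base_vals[j], vr))
        d_ord <- diff_list[[r]]
        contrib[r, d_ord, 1] <- contrib[r, d_ord, 1] + inc
        contrib[r, d_ord, 2] <- contrib[r, d_ord, 2] + inc^2
      }
    }
    vals <- matrix(contrib[, , 1], n, p) / m
    ssq <- matrix(contrib[, , 2], n, p)
    se <- sqrt(pmax(ssq / m - vals^2, 0) / m)
    base <- mean(base_vals)
  }
  cn <- if (!is.null(colnames(X))) colnames(X) else paste0("f", seq_len(p))
  dimnames(vals) <- list(rownames(X), cn)
  if (length(se)) dimnames(se) <- dimnames(vals)
  new("ShapExplanation", values = vals, se = se, baseValue = base,
      mode = mode, X = X, backgroundIds = bg_ids,
      dictionaryHash = if (is.null(dict_hash)) NA_character_ else dict_hash)
}

#' @rdname shapValues
#' @param shap a `ShapExplanation`.
#' @return `shapLocalAccuracy` returns the per-row absolute deviation of
#'   `baseValue + sum(values)` from the model output, a direct check of
#'   the additivity property.
#' @param model2 the model (or function) the explanation was computed for.
#' @export
shapLocalAccuracy <- function(shap, model2) {
  f <- if (is(model2, "ToxModelBundle")) stackedProbability(model2) else
    model2
  abs(shap@baseValue + rowSums(shap@values) - f(shap@X))
}

# ---------------------------------------------------------------------------
# Bit ranking and rules
# ---------------------------------------------------------------------------

#' Rank fingerprint bits by attribution magnitude
#'
#' Orders bits by decreasing mean absolute Shapley value (ties broken by
#' lower bit index) and annotates each with its dictionary description and
#' a direction: `toxicity_up` when the mean Shapley value over the
#' compounds that actually carry the bit is positive, `toxicity_down` when
#' negative.  Bits never observed set have direction `NA`.
#'
#' @param shap a `ShapExplanation` over fingerprint bits.
#' @param dict the [FingerprintDictionary] the fingerprints came from.
#' @param k number of top bits, default 20 (clamped to 166 with a
#'   warning).
#' @return `data.frame`: `bit`, `mean_abs_shap`, `direction`,
#'   `description`, `origin`.
#' @export
rankBits <- function(shap, dict, k = 20) {
  stopifnot(is(shap, "ShapExplanation"), is(dict, "FingerprintDictionary"))
  defs <- bitDefinitions(dict)
  p <- ncol(shap@values)
  if (k > p) {
    warning("k clamped from ", k, " to ", p)
    k <- p
  }
  if (k == 0) {
    return(data.frame(bit = integer(0), mean_abs_shap = numeric(0),
                      direction = character(0), description = character(0),
                      origin = character(0)))
  }
  mean_abs <- colMeans(abs(shap@values))
  bit_idx <- defs$index  # column order is bit_0..bit_165
  ord <- order(-mean_abs, bit_idx)[seq_len(k)]
  direction <- vapply(ord, function(i) {
    present <- shap@X[, i] == 1
    if (!any(present)) return(NA_character_)
    if (mean(shap@values[present, i]) > 0) "toxicity_up" else "toxicity_down"
  }, character(1))
  data.frame(bit = bit_idx[ord], mean_abs_shap = unname(mean_abs[ord]),
             direction = direction, description = defs$description[ord],
             origin = defs$origin[ord], stringsAsFactors = FALSE)
}

#' Extract structure-toxicity rules
#'
#' Turns the top-ranked attribution bits into substructure rules: each rule
#' carries the bit, its direction, mean |SHAP| weight, SMARTS pattern and
#' description.  Bits with undefined direction (never set among the
#' explained compounds) are dropped.
#'
#' @inheritParams rankBits
#' @return `data.frame` of rules with attribute `dictionary_hash`.
#' @export
extractRules <- function(shap, dict, k = 20) {
  ranked <- rankBits(shap, dict, k)
  defs <- bitDefinitions(dict)
  ranked <- ranked[!is.na(ranked$direction), , drop = FALSE]
  ranked$smarts <- defs$smarts[match(ranked$bit, defs$index)]
  rownames(ranked) <- NULL
  attr(ranked, "dictionary_hash") <- dict@hash
  ranked
}

#' Write / read a rule file
#'
#' @param rules rule table from [extractRules()].
#' @param file path to a tab-delimited rule file.
#' @return `writeRules` returns `file` invisibly; `readRules` the rule
#'   table (with its `dictionary_hash` attribute restored from the file
#'   header).
#' @export
writeRules <- function(rules, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# dictionary_hash: ",
                    attr(rules, "dictionary_hash")), con)
  utils::write.table(rules, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' @rdname writeRules
#' @export
readRules <- function(file) {
  first <- readLines(file, n = 1)
  hash <- sub("^# dictionary_hash: ", "", first)
  rules <- utils::read.delim(file, skip = 1, stringsAsFactors = FALSE)
  attr(rules, "dictionary_hash") <- hash
  rules
}

# ---------------------------------------------------------------------------
# SHAP profile clustering
# ---------------------------------------------------------------------------

#' Cluster compounds by attribution profile
#'
#' Agglomerative clustering (Ward linkage, Euclidean distance) of the rows
#' of the Shapley value matrix, grouping compounds whose predictions are
#' driven by the same substructures.  Deterministic.
#'
#' @param shap a `ShapExplanation`.
#' @param nClusters number of clusters (>= 1, <= rows).
#' @return list with `labels` (0-based cluster labels) and `profiles`
#'   (per-cluster mean Shapley profile matrix).
#' @export
clusterProfiles <- function(shap, nClusters) {
  stopifnot(is(shap, "ShapExplanation"))
  n <- nrow(shap@values)
  if (nClusters < 1) stop("nClusters must be >= 1", call. = FALSE)
  if (n < nClusters) stop("need at least nClusters rows", call. = FALSE)
  labels <- if (nClusters == 1) rep(1L, n) else {
    hc <- stats::hclust(stats::dist(shap@values), method = "ward.D2")
    stats::cutree(hc, k = nClusters)
  }
  labels <- as.integer(labels) - 1L
  profiles <- do.call(rbind, lapply(sort(unique(labels)), function(l) {
    colMeans(shap@values[labels == l, , drop = FALSE])
  }))
  rownames(profiles) <- paste0("cluster_", sort(unique(labels)))
  list(labels = labels, profiles = profiles)
}

# ---------------------------------------------------------------------------
# Compound annotation and screening
# ---------------------------------------------------------------------------

#' Annotate a compound with matching toxicity rules
#'
#' Lists every rule whose fingerprint bit is set in the compound, together
#' with the atom indices (1-based) of each unique substructure match.
#' Refuses rule sets derived from a different dictionary.
#'
#' @param smiles a single valid SMILES string.
#' @param rules rule table from [extractRules()] (or [readRules()]).
#' @param dict the [FingerprintDictionary] in use.
#' @return `data.frame` with `bit`, `description`, `direction` and a list
#'   column `matches` of integer atom-index vectors.
#' @export
annotateCompound <- function(smiles, rules, dict = defaultDictionary()) {
  stopifnot(length(smiles) == 1, is(dict, "FingerprintDictionary"))
  rule_hash <- attr(rules, "dictionary_hash")
  if (!is.null(rule_hash) && !identical(rule_hash, dict@hash)) {
    stop("rule set was derived from dictionary ", rule_hash,
         " but the supplied dictionary is ", dict@hash, call. = FALSE)
  }
  fp <- computeFingerprints(smiles, dict)[1, ]
  set_bits <- rules$bit[fp[paste0("bit_", rules$bit)] == 1]
  hits <- rules[rules$bit %in% set_bits, c("bit", "description", "direction"),
                drop = FALSE]
  defs <- bitDefinitions(dict)
  hits$matches <- I(lapply(hits$bit, function(b) {
    sp <- obCompileSmarts(defs$smarts[defs$index == b])
    maps <- obForEachSmiles(smiles, function(mol) obMatchMaps(mol, sp))[[1]]
    lapply(maps, as.integer)
  }))
  rownames(hits) <- NULL
  hits
}

#' Prioritize screened compounds
#'
#' Builds the prioritized screening table: compounds sorted by predicted
#' label (toxic first), then descending stacked probability, then
#' ascending entropy; ties preserve input order.  Each row carries the
#' confidence tier, the in-domain flag and the number of matched
#' structure-toxicity rules.
#'
#' @param ids compound identifiers.
#' @param probability stacked positive-class probabilities.
#' @param fps optional fingerprint matrix (needed for rule matching).
#' @param rules optional rule table from [extractRules()].
#' @param inDomainFlags optional logical applicability-domain flags.
#' @param tierMode tier mode passed to [confidenceTier()].
#' @return sorted `data.frame`: `rank`, `id`, `probability`, `label`,
#'   `entropy_bits`, `tier`, `in_domain`, `matched_rules`.
#' @export
screenCompounds <- function(ids, probability, fps = NULL, rules = NULL,
                            inDomainFlags = NULL,
                            tierMode = c("entropy", "probability")) {
  tierMode <- match.arg(tierMode)
  n <- length(ids)
  stopifnot(length(probability) == n)
  entropy <- binaryEntropy(probability)
  matched <- if (!is.null(fps) && !is.null(rules) && nrow(rules)) {
    cols <- paste0("bit_", rules$bit)
    as.integer(rowSums(fps[, cols, drop = FALSE]))
  } else rep(NA_integer_, n)
  tab <- data.frame(
    id = as.character(ids),
    probability = probability,
    label = as.integer(probability > 0.5),
    entropy_bits = entropy,
    tier = confidenceTier(p = probability, mode = tierMode),
    in_domain = if (is.null(inDomainFlags)) NA else inDomainFlags,
    matched_rules = matched,
    stringsAsFactors = FALSE)
  ord <- order(-tab$label, -tab$probability, tab$entropy_bits,
               seq_len(n))  # final key keeps ties stable
  tab <- tab[ord, , drop = FALSE]
  tab <- cbind(rank = seq_len(n), tab)
  rownames(tab) <- NULL
  tab
}
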