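# ---------------------------------------------------------------------------
# FingerprintDictionary
# ---------------------------------------------------------------------------

#' @rdname FingerprintDictionary
#' @export
setClass("FingerprintDictionary",
         representation(index = "integer",
                        smarts = "character",
                        minCount = "integer",
                        description = "character",
                        origin = "character",
                        hash = "character"))

setValidity("FingerprintDictionary", function(object) {
  msg <- character(0)
  n <- length(object@index)
  if (n != 166) msg <- c(msg, "dictionary must have exactly 166 bits")
  if (!identical(sort(object@index), 0:165))
    msg <- c(msg, "bit indices must be exactly 0..165, each once")
  if (length(object@smarts) != n || length(object@minCount) != n ||
      length(object@description) != n || length(object@origin) != n)
    msg <- c(msg, "all definition slots must have one entry per bit")
  if (!all(object@origin %in% c("standard", "custom", "removed")))
    msg <- c(msg, "origin must be standard, custom or removed")
  if (any(object@minCount < 1))
    msg <- c(msg, "min_count must be >= 1")
  if (length(msg)) msg else TRUE
})

## Deterministic digest over the full set of bit definitions.
.dictionaryDigest <- function(index, smarts, minCount, description, origin) {
  txt <- paste(index, smarts, minCount, description, origin,
               sep = "\t", collapse = "\n")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' Bit definitions of a fingerprint dictionary
#'
#' @param dict a [FingerprintDictionary].
#' @return `data.frame` with columns `index`, `smarts`, `min_count`,
#'   `description`, `origin`, ordered by bit index.
#' @export
bitDefinitions <- function(dict) {
  stopifnot(is(dict, "FingerprintDictionary"))
  o <- order(dict@index)
  data.frame(index = dict@index[o], smarts = dict@smarts[o],
             min_count = dict@minCount[o],
             description = dict@description[o],
             origin = dict@origin[o], stringsAsFactors = FALSE)
}

#' Content hash of a fingerprint dictionary
#'
#' Changes whenever any bit definition changes; recorded in model bundles so
#' that fingerprints and models can never silently disagree.
#'
#' @param dict a [FingerprintDictionary].
#' @return length-1 character digest.
#' @export
dictionaryHash <- function(dict) {
  stopifnot(is(dict, "FingerprintDictionary"))
  dict@hash
}

setMethod("show", "FingerprintDictionary", function(object) {
  tab <- table(factor(object@origin,
                      levels = c("standard", "custom", "removed")))
  cat("FingerprintDictionary: 166 substructure keys\n")
  cat(sprintf("  standard: %d  custom: %d  removed: %d\n",
              tab[["standard"]], tab[["custom"]], tab[["removed"]]))
  cat("  hash:", object@hash, "\n")
})

## Parse the human-editable override config: "[bit N]" blocks with
## key = value lines (smarts, min_count, description, action).
.parseDictionaryConfig <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  # full-line comments only: "#" appears inside SMARTS atomic numbers
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  entries <- list()
  current <- NULL
  flush <- function(cur, entries) {
    if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
    entries
  }
  for (ln in lines) {
    hdr <- regmatches(ln, regexec("^\\[\\s*bit\\s+([0-9]+)\\s*\\]$", ln))[[1]]
    if (length(hdr)) {
      entries <- flush(current, entries)
      current <- list(index = as.integer(hdr[2]))
      next
    }
    kv <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3 || is.null(current)) {
      stop("malformed dictionary config line: '", ln, "'", call. = FALSE)
    }
    current[[kv[2]]] <- trimws(kv[3])
  }
  entries <- flush(current, entries)
  entries
}

#' Load a fingerprint dictionary
#'
#' Starts from the 166-key standard substructure dictionary shipped with the
#' package (a reconstruction of the classic 166-bit key design: element and
#' count keys, ring and aromaticity keys, functional-group keys, and
#' inorganic/metal keys) and applies per-bit overrides from an editable
#' config file.  An override either replaces a bit (new SMARTS, count
#' threshold and description; origin becomes `custom`) or removes it (the
#' bit always evaluates to 0; origin `removed`).
#'
#' @param config path to an override config (see the shipped
#'   `custom_keys.cfg` for the format), or `NULL` for the unmodified
#'   standard dictionary.
#' @return A [FingerprintDictionary].
#' @seealso [defaultDictionary()], [computeFingerprints()]
#' @export
loadDictionary <- function(config = NULL) {
  std <- utils::read.delim(system.file("extdata", "standard_keys.tsv",
                                       package = "StackTox"),
                           stringsAsFactors = FALSE)
  std <- std[order(std$index), ]
  if (nrow(std) != 166) {
    stop("standard key table must define 166 bits", call. = FALSE)
  }
  index <- as.integer(std$index)
  smarts <- std$smarts
  minCount <- as.integer(std$min_count)
  description <- std$description
  origin <- rep("standard", 166)

  if (!is.null(config)) {
    entries <- .parseDictionaryConfig(config)
    seen <- integer(0)
    for (e in entries) {
      i <- e$index
      if (is.na(i) || i < 0 || i > 165) {
        stop("dictionary config: bit index out of range: ", i, call. = FALSE)
      }
      if (i %in% seen) {
        stop("dictionary config: duplicate bit index ", i, call. = FALSE)
      }
      seen <- c(seen, i)
      pos <- match(i, index)
      action <- if (is.null(e$action)) "replace" else e$action
      if (!action %in% c("replace", "remove")) {
        stop("dictionary config: bit ", i, ": unknown action '", action, "'",
             call. = FALSE)
      }
      if (action == "remove") {
        origin[pos] <- "removed"
        if (!is.null(e$description)) description[pos] <- e$description
        next
      }
      if (is.null(e$smarts)) {
        stop("dictionary config: bit ", i, ": replacement needs a smarts key",
             call. = FALSE)
      }
      ok <- tryCatch({obCompileSmarts(e$smarts); TRUE},
                     error = function(err) FALSE)
      if (!ok) {
        stop("dictionary config: bit ", i, ": SMARTS does not compile: '",
             e$smarts, "'", call. = FALSE)
      }
      smarts[pos] <- e$smarts
      minCount[pos] <- if (is.null(e$min_count)) 1L else {
        mc <- suppressWarnings(as.integer(e$min_count))
        if (is.na(mc) || mc < 1) {
          stop("dictionary config: bit ", i, ": min_count must be a positive ",
               "integer", call. = FALSE)
        }
        mc
      }
      if (!is.null(e$description)) description[pos] <- e$description
      origin[pos] <- "custom"
    }
  }
  new("FingerprintDictionary", index = index, smarts = smarts,
      minCount = minCount, description = description, origin = origin,
      hash = .dictionaryDigest(index, smarts, minCount, description, origin))
}

#' Default customized fingerprint dictionary
#'
#' The standard 166-key dictionary with the shipped customization applied:
#' 43 bits (26\% of the dictionary) replaced, swapping inorganic-, metal-
#' and halogen-related keys for substructure families associated with
#' organic cytotoxicity (aromatic amines and nitro groups, aryl and
#' alpha,beta-unsaturated ketones, tertiary amines, amides, N/O/S
#' heterocycles, alkyl-chain and triple-bond descriptors).
#'
#' @return A [FingerprintDictionary] with 43 custom-origin bits.
#' @export
defaultDictionary <- function() {
  loadDictionary(system.file("extdata", "custom_keys.cfg",
                             package = "StackTox"))
}

## Session cache of compiled SMARTS keyed by dictionary hash.
.compiled_cache <- new.env(parent = emptyenv())

.compiledPatterns <- function(dict) {
  key <- dict@hash
  if (is.null(.compiled_cache[[key]])) {
    o <- order(dict@index)
    .compiled_cache[[key]] <- lapply(dict@smarts[o], obCompileSmarts)
  }
  .compiled_cache[[key]]
}

# ---------------------------------------------------------------------------
# Fingerprint computation
# ---------------------------------------------------------------------------

#' Compute 166-bit substructure fingerprints
#'
#' Bit *i* is set when the molecule contains at least `min_count` unique
#' matches of the bit's substructure pattern; removed bits are always 0.
#' Deterministic for a fixed dictionary; identical structures give
#' identical fingerprints.
#'
#' @param smiles character vector of valid (preferably standardized) SMILES.
#' @param dict a [FingerprintDictionary]; default [defaultDictionary()].
#' @return integer 0/1 matrix with one row per molecule (rownames from
#'   `names(smiles)` or the SMILES themselves) and columns `bit_0` ..
#'   `bit_165`.  The dictionary hash is attached as attribute
#'   `dictionary_hash`.
#' @examples
#' fp <- computeFingerprints("O=[N+]([O-])c1ccccc1")
#' fp[, "bit_46"]  # aromatic nitro bit
#' @export
computeFingerprints <- function(smiles, dict = defaultDictionary()) {
  stopifnot(is.character(smiles), length(smiles) >= 1,
            is(dict, "FingerprintDictionary"))
  compiled <- .compiledPatterns(dict)
  o <- order(dict@index)
  min_count <- dict@minCount[o]
  removed <- dict@origin[o] == "removed"
  counts <- obForEachSmiles(smiles, function(mol) obMatchCounts(mol, compiled))
  counts <- do.call(rbind, counts)
  bits <- (counts >= matrix(min_count, nrow(counts), 166, byrow = TRUE)) * 1L
  bits[, removed] <- 0L
  dimnames(bits) <- list(
    if (!is.null(names(smiles))) names(smiles) else smiles,
    paste0("bit_", 0:165))
  attr(bits, "dictionary_hash") <- dict@hash
  bits
}

# ---------------------------------------------------------------------------
# Tanimoto similarity and diversity
# ---------------------------------------------------------------------------

#' Tanimoto similarity between binary fingerprints
#'
#' Intersection over union of set bits.  By convention two all-zero
#' fingerprints have similarity 1 (identical absence of features), keeping
#' the metric total.
#'
#' @param a,b binary 0/1 vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stop("fingerprint length mismatch: ", length(a), " vs ", length(b),
         call. = FALSE)
  }
  a <- as.logical(a); b <- as.logical(b)
  union <- sum(a | b)
  if (union == 0) return(1)
  sum(a & b) / union
}

#' Pairwise-similarity diversity profile of a fingerprint set
#'
#' Summarizes the chemical diversity of a compound set as a histogram of
#' pairwise Tanimoto similarities.  When the number of pairs exceeds
#' `maxPairs`, a uniform random subsample of pairs (without replacement,
#' reproducible under `seed`) is used instead of full enumeration.
#'
#' @param fps 0/1 fingerprint matrix (rows = compounds).
#' @param maxPairs maximum number of pairs to evaluate.
#' @param seed integer seed for pair subsampling.
#' @param binWidth histogram bin width over `[0, 1]`.
#' @return list with `counts` (per-bin pair counts), `breaks`, `mids`,
#'   `modeBin` (midpoint of the most populated bin), `fractionAbove0.6`,
#'   `nPairs` and `similarities`.
#' @export
diversityProfile <- function(fps, maxPairs = 100000L, seed = 42L,
                             binWidth = 0.05) {
  fps <- as.matrix(fps)
  n <- nrow(fps)
  if (n < 2) stop("need at least 2 fingerprints", call. = FALSE)
  npair <- n * (n - 1) / 2
  take <- min(npair, maxPairs)
  if (take < npair) {
    rng <- .withSeed(seed, sample.int(npair, take))
  } else {
    rng <- seq_len(npair)
  }
  # map linear pair index k (1-based, column-major over i<j) to (i, j)
  k <- rng - 1
  j <- floor((1 + sqrt(1 + 8 * k)) / 2) + 1
  i <- k - (j - 1) * (j - 2) / 2 + 1
  storage.mode(fps) <- "integer"
  A <- fps[i, , drop = FALSE]
  B <- fps[j, , drop = FALSE]
  inter <- rowSums(A & B)
  union <- rowSums(A | B)
  sims <- ifelse(union == 0, 1, inter / union)
  breaks <- seq(0, 1, by = binWidth)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  h <- graphics::hist(sims, breaks = breaks, plot = FALSE)
  list(counts = h$counts, breaks = h$breaks, mids = h$mids,
       modeBin = h$mids[which.max(h$counts)],
       fractionAbove0.6 = mean(sims > 0.6),
       nPairs = length(sims), similarities = sims)
}

## Evaluate expr under a temporary RNG state.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
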