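# Internal bridge to OpenBabel via ChemmineOB's low-level SWIG bindings.
#
# ChemmineOB's exported smartsSearchOB() re-reads every molecule from SDF text
# for every pattern, which is far too slow for a 166-key dictionary applied to
# thousands of structures.  The SWIG wrappers let us precompile each SMARTS
# query once and reuse parsed OBMol objects, and expose the unique-match atom
# index maps needed for substructure annotation.

.ob_cache <- new.env(parent = emptyenv())

.ob <- function(name) {
  if (is.null(.ob_cache[[name]])) {
    .ob_cache[[name]] <- get(name, envir = asNamespace("ChemmineOB"),
                             inherits = FALSE)
  }
  .ob_cache[[name]]
}

## Compile a SMARTS query; errors name the offending pattern.
obCompileSmarts <- function(smarts) {
  sp <- .ob("OBSmartsPattern")()
  ok <- FALSE
  # OpenBabel prints its own parse diagnostics to stderr; the R-level error
  # below is the authoritative signal.
  ok <- isTRUE(.ob("OBSmartsPattern_Init")(sp, smarts))
  if (!ok) {
    stop("invalid SMARTS pattern: '", smarts, "'", call. = FALSE)
  }
  sp
}

## Apply a function to each molecule parsed from a block of SMILES (one per
## line).  All lines must be valid; validity is established upstream.
obForEachSmiles <- function(smiles, f) {
  ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"), f)
}

## Count unique substructure matches of precompiled patterns in one molecule.
obMatchCounts <- function(mol, compiled) {
  match_fn <- .ob("OBSmartsPattern_Match")
  umap_fn <- .ob("OBSmartsPattern_GetUMapList")
  vapply(compiled, function(sp) {
    match_fn(sp, mol)
    length(umap_fn(sp))
  }, integer(1))
}

## Unique-match atom index lists (1-based OpenBabel atom indices).
obMatchMaps <- function(mol, sp) {
  .ob("OBSmartsPattern_Match")(sp, mol)
  .ob("OBSmartsPattern_GetUMapList")(sp)
}

## Batch-convert SMILES, keeping per-record alignment even when some records
## fail to parse.  OpenBabel silently drops unreadable records from batch
## output, so each input is tagged with an index title and the output is
## realigned on those titles.  Returns NA for records that failed.
obConvertAligned <- function(smiles, options = NULL) {
  n <- length(smiles)
  if (is.null(options)) {
    options <- data.frame(names = character(0), args = character(0))
  }
  tagged <- paste(smiles, seq_len(n))
  out <- ChemmineOB::convertFormat("SMI", "CAN",
                                   paste(tagged, collapse = "\n"),
                                   options = options)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  res <- rep(NA_character_, n)
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    for (p in parts) {
      if (length(p) >= 2) {
        idx <- suppressWarnings(as.integer(trimws(p[[2]])))
        if (!is.na(idx) && idx >= 1 && idx <= n) res[idx] <- p[[1]]
      }
    }
  }
  res
}

## Molecular formula and average molecular weight for valid SMILES.
obFormulaWeight <- function(smiles) {
  if (!length(smiles)) {
    return(data.frame(formula = character(0), mw = numeric(0)))
  }
  fml_fn <- .ob("OBMol_GetFormula")
  mw_fn <- .ob("OBMol_GetMolWt")
  rows <- obForEachSmiles(smiles, function(mol) {
    list(formula = fml_fn(mol), mw = mw_fn(mol))
  })
  data.frame(formula = vapply(rows, `[[`, character(1), "formula"),
             mw = vapply(rows, `[[`, numeric(1), "mw"))
}
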