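#' @import methods
NULL

# ---------------------------------------------------------------------------
# SMILES standardization
# ---------------------------------------------------------------------------

#' Standardize SMILES structures
#'
#' Canonicalizes raw SMILES through OpenBabel, optionally keeps only the
#' largest covalent fragment (dropping counter-ions and solvent fragments)
#' and neutralizes charges where adding or removing protons suffices.  The
#' result is idempotent: standardizing a standardized structure returns the
#' identical canonical SMILES.
#'
#' @param smiles character vector of raw SMILES strings.
#' @param keepLargestFragment logical; keep only the fragment with the most
#'   heavy atoms (ties broken in favour of carbon-containing fragments, then
#'   input order).
#' @param neutralize logical; neutralize formal charges by proton
#'   transfer where possible (e.g. carboxylates, protonated amines).
#' @param onError `"stop"` aborts on the first unparseable record naming the
#'   offending input; `"na"` records the failure in the `error` column and
#'   continues, which is what the curation pipeline uses.
#' @return A `data.frame` with one row per input: `input`, `canonical`
#'   (canonical SMILES, `NA` on failure), `formula`, `mw` (average molecular
#'   weight, Da) and `error` (`NA` or a failure message).
#' @examples
#' standardizeSmiles("C(C(=O)O)N.Cl")$canonical  # glycine, HCl dropped
#' @export
standardizeSmiles <- function(smiles, keepLargestFragment = TRUE,
                              neutralize = TRUE,
                              onError = c("stop", "na")) {
  onError <- match.arg(onError)
  stopifnot(is.character(smiles))
  n <- length(smiles)
  out <- data.frame(input = smiles,
                    canonical = NA_character_,
                    formula = NA_character_,
                    mw = NA_real_,
                    error = NA_character_,
                    stringsAsFactors = FALSE)
  if (!n) return(out)

  blank <- !nzchar(trimws(smiles)) | is.na(smiles)
  out$error[blank] <- "empty SMILES input"
  todo <- which(!blank)
  if (length(todo)) {
    canon <- obConvertAligned(smiles[todo])
    bad <- is.na(canon)
    out$error[todo[bad]] <-
      paste0("unparseable SMILES: '", smiles[todo[bad]], "'")
    todo <- todo[!bad]
    canon <- canon[!bad]

    if (keepLargestFragment && length(todo)) {
      canon <- vapply(canon, .largestFragment, character(1), USE.NAMES = FALSE)
      empty <- !nzchar(canon)
      out$error[todo[empty]] <- "empty structure after fragment removal"
      todo <- todo[!empty]
      canon <- canon[!empty]
    }

    if (length(todo)) {
      opts <- if (neutralize) {
        data.frame(names = "neutralize", args = "")
      } else NULL
      final <- obConvertAligned(canon, options = opts)
      # canonical input cannot fail to re-parse; guard anyway
      bad <- is.na(final)
      out$error[todo[bad]] <- "canonicalization failed"
      todo <- todo[!bad]
      final <- final[!bad]
      if (length(todo)) {
        fw <- obFormulaWeight(final)
        out$canonical[todo] <- final
        out$formula[todo] <- fw$formula
        out$mw[todo] <- fw$mw
      }
    }
  }
  if (onError == "stop" && any(!is.na(out$error))) {
    stop(out$error[which(!is.na(out$error))[1]], call. = FALSE)
  }
  out
}

## Heavy (non-hydrogen) atom count of a SMILES string, by token scan.
## Exact for valid SMILES: every bracket atom is one atom (hydrogen unless
## the element symbol is H), and outside brackets only organic-subset
## element tokens contribute.
.smilesHeavyAtoms <- function(s) {
  brackets <- regmatches(s, gregexpr("\\[[^]]*\\]", s))[[1]]
  n_br <- sum(!grepl("^\\[[0-9]*H[0-9+@Hh-]*\\]$", brackets))
  rest <- gsub("\\[[^]]*\\]", "", s)
  rest <- gsub("Cl|Br", "Q", rest)  # two-letter organic-subset tokens
  n_org <- sum(strsplit(rest, "")[[1]] %in%
                 c("Q", "B", "C", "N", "O", "P", "S", "F", "I",
                   "b", "c", "n", "o", "p", "s"))
  n_br + n_org
}

.largestFragment <- function(canonical) {
  frags <- strsplit(canonical, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (!length(frags)) return("")
  heavy <- vapply(frags, .smilesHeavyAtoms, numeric(1), USE.NAMES = FALSE)
  if (!any(heavy > 0)) return("")
  has_c <- grepl("C|c", gsub("\\[[^]]*\\]", "A", frags)) |
    grepl("\\[[0-9]*[Cc]", frags)
  # prefer carbon-containing fragments, then heavy-atom count, then order
  key <- heavy + ifelse(has_c, 0.5, 0)
  frags[which.max(key)]
}

# ---------------------------------------------------------------------------
# Elemental profiles
# ---------------------------------------------------------------------------

## Parse a Hill-notation molecular formula into named element counts.
.parseFormula <- function(formula) {
  formula <- gsub("[+-]+[0-9]*$", "", formula)
  m <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (!length(m)) return(integer(0))
  el <- sub("[0-9]*$", "", m)
  ct <- as.integer(ifelse(grepl("[0-9]$", m), sub("^[A-Za-z]+", "", m), "1"))
  tapply(ct, el, sum)
}

#' Elemental profile of organic structures
#'
#' Computes element counts, average molecular weight, elemental ratios
#' (H/C, O/C, N/C, S/C), and the double bond equivalent
#' \eqn{DBE = C - H/2 + N/2 + 1} together with DBE/C, the quantities on
#' which the applicability domain is defined.  Ratios are formed from exact
#' integer counts before division.
#'
#' @param smiles character vector of valid (preferably canonical) SMILES.
#' @param strict logical; if `TRUE` (default) structures without carbon are
#'   an error because the elemental ratios are undefined, if `FALSE` they
#'   yield `NA` ratios so the caller can treat them as domain violations.
#' @return A `data.frame` with columns `smiles`, `formula`, `mw`, element
#'   counts `C`, `H`, `O`, `N`, `S`, `other` (comma-separated non-CHONS
#'   elements or `""`), ratios `h_c`, `o_c`, `n_c`, `s_c`, and `dbe`,
#'   `dbe_c`.
#' @examples
#' elementalProfile("c1ccccc1")  # benzene: dbe 4, h_c 1
#' @export
elementalProfile <- function(smiles, strict = TRUE) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  fw <- obFormulaWeight(smiles)
  counts <- lapply(fw$formula, .parseFormula)
  pick <- function(el) vapply(counts, function(x) {
    v <- x[el]
    if (is.na(v)) 0L else as.integer(v)
  }, integer(1))
  C <- pick("C"); H <- pick("H"); O <- pick("O"); N <- pick("N"); S <- pick("S")
  other <- vapply(counts, function(x) {
    extra <- setdiff(names(x), c("C", "H", "O", "N", "S"))
    paste(extra, collapse = ",")
  }, character(1))
  if (strict && any(C == 0)) {
    stop("structure without carbon: elemental ratios undefined (",
         paste(smiles[C == 0], collapse = ", "), ")", call. = FALSE)
  }
  safe <- function(num) ifelse(C > 0, num / C, NA_real_)
  dbe <- (2 * C - H + N + 2) / 2
  data.frame(smiles = smiles, formula = fw$formula, mw = fw$mw,
             C = C, H = H, O = O, N = N, S = S, other = other,
             h_c = safe(H), o_c = safe(O), n_c = safe(N), s_c = safe(S),
             dbe = dbe, dbe_c = safe(dbe),
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Applicability domain
# ---------------------------------------------------------------------------

#' @rdname ApplicabilityDomain
#' @export
setClass("ApplicabilityDomain",
         representation(allowedElements = "character",
                        mwRange = "numeric",
                        ratioBounds = "matrix"))

setValidity("ApplicabilityDomain", function(object) {
  msg <- character(0)
  if (length(object@mwRange) != 2 || object@mwRange[1] >= object@mwRange[2])
    msg <- c(msg, "mwRange must be (min, max) with min < max")
  rb <- object@ratioBounds
  need <- c("h_c", "o_c", "n_c", "s_c", "dbe_c")
  if (!all(need %in% rownames(rb)) || ncol(rb) != 2)
    msg <- c(msg, "ratioBounds must have rows h_c,o_c,n_c,s_c,dbe_c and 2 columns")
  else if (any(rb[, 1] > rb[, 2]))
    msg <- c(msg, "every ratio interval must have lower <= upper")
  if (length(msg)) msg else TRUE
})

#' Elemental applicability domain for CHONS organics
#'
#' The domain inside which model predictions are considered valid: the
#' element whitelist, a molecular-weight window, and closed intervals on the
#' elemental ratios H/C, O/C, N/C, S/C and DBE/C.  The default domain is the
#' one typical of ambient organic aerosol constituents: elements C, H, O, N,
#' S; molecular weight 50--900 Da; H/C in [0.3, 3.0]; O/C in [0, 3.0]; N/C
#' in [0, 1.3]; S/C in [0, 0.8]; DBE/C in [0, 1.0].  All bounds are closed,
#' so boundary values pass.
#'
#' @param allowedElements character vector of allowed element symbols.
#' @param mwRange numeric length-2 molecular weight window in Da.
#' @param ratioBounds numeric 5 x 2 matrix with rownames `h_c`, `o_c`,
#'   `n_c`, `s_c`, `dbe_c` giving closed lower/upper bounds.
#' @return An `ApplicabilityDomain` object.
#' @examples
#' ad <- ApplicabilityDomain()
#' inDomain(elementalProfile("c1ccccc1"), ad)
#' @aliases ApplicabilityDomain-class
#' @export
ApplicabilityDomain <- function(allowedElements = c("C", "H", "O", "N", "S"),
                                mwRange = c(50, 900),
                                ratioBounds = rbind(h_c = c(0.3, 3.0),
                                                    o_c = c(0.0, 3.0),
                                                    n_c = c(0.0, 1.3),
                                                    s_c = c(0.0, 0.8),
                                                    dbe_c = c(0.0, 1.0))) {
  new("ApplicabilityDomain", allowedElements = allowedElements,
      mwRange = as.numeric(mwRange), ratioBounds = ratioBounds)
}

setMethod("show", "ApplicabilityDomain", function(object) {
  cat("ApplicabilityDomain\n")
  cat("  elements:", paste(object@allowedElements, collapse = ", "), "\n")
  cat(sprintf("  molecular weight: [%g, %g] Da\n",
              object@mwRange[1], object@mwRange[2]))
  rb <- object@ratioBounds
  for (r in rownames(rb)) {
    cat(sprintf("  %-6s [%g, %g]\n", paste0(r, ":"), rb[r, 1], rb[r, 2]))
  }
})

#' @rdname inDomain
#' @export
setGeneric("inDomain", function(profile, ad, ...) standardGeneric("inDomain"))

#' Applicability-domain membership
#'
#' Checks every rule of an [ApplicabilityDomain] against an elemental
#' profile and reports all failed rules, not just the first.  Rule names
#' are `elements`, `mw_min`, `mw_max`, `h_c`, `o_c`, `n_c`, `s_c`,
#' `dbe_c`.
#'
#' @param profile a `data.frame` from [elementalProfile()].
#' @param ad an [ApplicabilityDomain].
#' @param ... unused.
#' @return A `data.frame` with `in_domain` (logical) and `violations`
#'   (list column of rule-name character vectors) aligned with the profile
#'   rows.
#' @rdname inDomain
#' @export
setMethod("inDomain", signature(profile = "data.frame",
                                ad = "ApplicabilityDomain"),
          function(profile, ad, ...) {
  need <- c("mw", "C", "H", "O", "N", "S", "other",
            "h_c", "o_c", "n_c", "s_c", "dbe_c")
  if (!all(need %in% names(profile))) {
    stop("profile must come from elementalProfile()", call. = FALSE)
  }
  rb <- ad@ratioBounds
  n <- nrow(profile)
  viol <- vector("list", n)
  for (i in seq_len(n)) {
    v <- character(0)
    extra <- profile$other[i]
    present <- c(c("C", "H", "O", "N", "S")[
      unlist(profile[i, c("C", "H", "O", "N", "S")]) > 0],
      if (nzchar(extra)) strsplit(extra, ",", fixed = TRUE)[[1]])
    if (!all(present %in% ad@allowedElements)) v <- c(v, "elements")
    if (profile$mw[i] < ad@mwRange[1]) v <- c(v, "mw_min")
    if (profile$mw[i] > ad@mwRange[2]) v <- c(v, "mw_max")
    for (r in rownames(rb)) {
      x <- profile[[r]][i]
      if (is.na(x) || x < rb[r, 1] || x > rb[r, 2]) v <- c(v, r)
    }
    viol[[i]] <- v
  }
  data.frame(in_domain = lengths(viol) == 0,
             violations = I(viol))
})

# ---------------------------------------------------------------------------
# Compound table I/O
# ---------------------------------------------------------------------------

#' Read a compound table
#'
#' Reads compounds from delimited text (CSV or TSV, chosen by extension or
#' `sep`) with configurable column names, or from an SDF structure file.
#' IC50 values are converted to nanomolar.
#'
#' @param file path to a `.csv`/`.tsv`/`.txt` table or an `.sdf` file.
#' @param smilesCol,idCol,ic50Col column names in delimited input.
#' @param units unit of the IC50 column: `"nM"`, `"uM"` or `"M"`.
#' @param sep field separator; defaults from the file extension.
#' @return `data.frame` with columns `id`, `smiles`, `ic50_nM`.
#' @export
readCompounds <- function(file, smilesCol = "smiles", idCol = "id",
                          ic50Col = "ic50_nM", units = c("nM", "uM", "M"),
                          sep = NULL) {
  units <- match.arg(units)
  scale <- c(nM = 1, uM = 1e3, M = 1e9)[[units]]
  if (grepl("\\.sdf$", file, ignore.case = TRUE)) {
    tmp <- tempfile(fileext = ".smi")
    on.exit(unlink(tmp))
    ChemmineOB::convertFormatFile("SDF", "CAN", file, tmp)
    lines <- readLines(tmp)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    smi <- vapply(parts, `[[`, character(1), 1)
    ids <- vapply(parts, function(p) {
      if (length(p) > 1 && nzchar(trimws(p[[2]]))) trimws(p[[2]]) else NA_character_
    }, character(1))
    ids[is.na(ids)] <- paste0("sdf_", which(is.na(ids)))
    return(data.frame(id = ids, smiles = smi, ic50_nM = NA_real_,
                      stringsAsFactors = FALSE))
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  }
  tab <- utils::read.table(file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"")
  if (!smilesCol %in% names(tab)) {
    stop("missing structure column '", smilesCol, "'", call. = FALSE)
  }
  ids <- if (idCol %in% names(tab)) as.character(tab[[idCol]]) else
    paste0("cmpd_", seq_len(nrow(tab)))
  ic50 <- if (ic50Col %in% names(tab)) {
    suppressWarnings(as.numeric(tab[[ic50Col]])) * scale
  } else NA_real_
  data.frame(id = ids, smiles = as.character(tab[[smilesCol]]),
             ic50_nM = ic50, stringsAsFactors = FALSE)
}

#' Write a compound table
#'
#' @param records `data.frame` of compounds.
#' @param file output path; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @return `file`, invisibly.
#' @export
writeCompounds <- function(records, file) {
  sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  df <- records
  df$violations <- NULL  # list columns are not writable
  utils::write.table(df, file, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(file)
}
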