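# ---------------------------------------------------------------------------
# Label assignment
# ---------------------------------------------------------------------------

#' Binary toxicity label from IC50
#'
#' Classifies a compound as highly toxic (1) when log10 of its IC50 in
#' nanomolar is below 4 (IC50 < 10 uM), and low-toxicity (0) otherwise.
#' The boundary value IC50 = 1.0e4 nM has log10 exactly 4 and is labelled 0.
#'
#' @param ic50_nM positive IC50 values in nanomolar.
#' @return integer vector of 0/1 labels.
#' @examples
#' assignLabel(c(1, 9999, 10000, 1e8))  # 1 1 0 0
#' @export
assignLabel <- function(ic50_nM) {
  if (any(is.na(ic50_nM)) || any(ic50_nM <= 0)) {
    stop("IC50 must be positive and non-missing", call. = FALSE)
  }
  as.integer(log10(ic50_nM) < 4)
}

# ---------------------------------------------------------------------------
# Curation pipeline
# ---------------------------------------------------------------------------

## Parse an IC50 column that may contain qualified values (">1000", "<5").
.parseIC50 <- function(x) {
  if (is.numeric(x)) {
    return(data.frame(value = as.numeric(x), qualified = FALSE))
  }
  x <- trimws(as.character(x))
  qualified <- grepl("^[<>]", x)
  value <- suppressWarnings(as.numeric(sub("^[<>]=?\\s*", "", x)))
  value[!nzchar(x)] <- NA_real_
  data.frame(value = value, qualified = qualified & !is.na(value))
}

#' Curate a compound table into a modelling-ready set
#'
#' Runs the multistep filtering pipeline in fixed order:
#' \enumerate{
#'   \item parse and standardize structures (largest fragment, optional
#'     charge neutralization);
#'   \item IC50 value selection (present, positive; qualified values such
#'     as ">10000" are excluded unless `retainQualified = TRUE`, in which
#'     case the bound is used as the value);
#'   \item applicability-domain filtering (elements, molecular weight,
#'     elemental ratios);
#'   \item aggregation of duplicate canonical structures (default: median
#'     of log10 IC50 per structure);
#'   \item binary label assignment at the log10(IC50 nM) = 4 threshold.
#' }
#' Every excluded record is logged once with its first failing stage; the
#' per-stage counts telescope (output of one stage is input of the next).
#' Re-curating an already curated set returns it unchanged.
#'
#' @param records `data.frame` with columns `id`, `smiles` and `ic50_nM`
#'   (numeric, or character possibly carrying `<`/`>` qualifiers).
#' @param ad an [ApplicabilityDomain]; default [ApplicabilityDomain()].
#' @param dedupPolicy how to aggregate log10 IC50 over duplicate canonical
#'   structures: `"median"` (default, robust to assay outliers), `"mean"`
#'   or `"min"` (most toxic measurement wins).
#' @param neutralize passed to [standardizeSmiles()].
#' @param retainQualified keep qualified IC50 values, treating the bound as
#'   the value.
#' @return list of class `curationResult` with elements
#'   \describe{
#'     \item{records}{curated `data.frame`: `id`, `raw_smiles`,
#'       `canonical_smiles`, `formula`, `mw`, `ic50_nM`, `log_ic50`,
#'       `label`, `n_measurements`.}
#'     \item{audit}{per-stage `data.frame` of `stage`, `n_in`, `n_out`,
#'       `n_excluded`.}
#'     \item{exclusions}{one row per excluded record: `id`, `stage`,
#'       `reason`.}
#'     \item{classBalance}{labelled counts and fractions.}
#'   }
#' @export
curateCompounds <- function(records, ad = ApplicabilityDomain(),
                            dedupPolicy = c("median", "mean", "min"),
                            neutralize = TRUE, retainQualified = FALSE) {
  dedupPolicy <- match.arg(dedupPolicy)
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("records must be a non-empty data.frame", call. = FALSE)
  }
  need <- c("id", "smiles", "ic50_nM")
  if (!all(need %in% names(records))) {
    stop("records needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  id <- as.character(records$id)
  audit <- data.frame(stage = character(0), n_in = integer(0),
                      n_out = integer(0), n_excluded = integer(0))
  excl <- data.frame(id = character(0), stage = character(0),
                     reason = character(0))
  note <- function(audit, stage, n_in, n_out) {
    rbind(audit, data.frame(stage = stage, n_in = n_in, n_out = n_out,
                            n_excluded = n_in - n_out))
  }
  drop_rows <- function(keep, stage, reasons, d) {
    if (any(!keep)) {
      excl <<- rbind(excl, data.frame(id = d$id[!keep], stage = stage,
                                      reason = reasons[!keep]))
    }
    d[keep, , drop = FALSE]
  }

  # stage 1: standardization
  std <- standardizeSmiles(as.character(records$smiles),
                           neutralize = neutralize, onError = "na")
  ic <- .parseIC50(records$ic50_nM)
  d <- data.frame(id = id, raw_smiles = as.character(records$smiles),
                  canonical_smiles = std$canonical, formula = std$formula,
                  mw = std$mw, ic50_nM = ic$value, qualified = ic$qualified,
                  std_error = std$error, stringsAsFactors = FALSE)
  n0 <- nrow(d)
  keep <- is.na(d$std_error)
  d <- drop_rows(keep, "standardization",
                 ifelse(is.na(d$std_error), "", d$std_error), d)
  audit <- note(audit, "standardization", n0, nrow(d))

  # stage 2: IC50 selection
  n1 <- nrow(d)
  reason <- rep("", n1)
  keep <- rep(TRUE, n1)
  missing_ic <- is.na(d$ic50_nM)
  keep[missing_ic] <- FALSE; reason[missing_ic] <- "missing IC50"
  nonpos <- !missing_ic & d$ic50_nM <= 0
  keep[nonpos] <- FALSE; reason[nonpos] <- "non-positive IC50"
  if (!retainQualified) {
    qual <- keep & d$qualified
    keep[qual] <- FALSE; reason[qual] <- "qualified IC50 value"
  }
  d <- drop_rows(keep, "ic50_selection", reason, d)
  audit <- note(audit, "ic50_selection", n1, nrow(d))

  # stage 3: applicability domain
  n2 <- nrow(d)
  if (n2 > 0) {
    prof <- elementalProfile(d$canonical_smiles, strict = FALSE)
    dom <- inDomain(prof, ad)
    reason <- vapply(dom$violations, function(v) {
      if (length(v)) paste("outside domain:", paste(v, collapse = ","))
      else ""
    }, character(1))
    d <- drop_rows(dom$in_domain, "applicability_domain", reason, d)
  }
  audit <- note(audit, "applicability_domain", n2, nrow(d))

  # stage 4: duplicate aggregation
  n3 <- nrow(d)
  if (n3 > 0) {
    logv <- log10(d$ic50_nM)
    agg_fun <- switch(dedupPolicy, median = stats::median,
                      mean = mean, min = min)
    first_idx <- !duplicated(d$canonical_smiles)
    groups <- split(seq_len(n3), d$canonical_smiles)
    agg_log <- vapply(groups, function(ix) agg_fun(logv[ix]), numeric(1))
    nmeas <- vapply(groups, length, integer(1))
    dup_rows <- which(!first_idx)
    if (length(dup_rows)) {
      primary <- vapply(dup_rows, function(i) {
        d$id[groups[[d$canonical_smiles[i]]][1]]
      }, character(1))
      excl <- rbind(excl, data.frame(
        id = d$id[dup_rows], stage = "duplicate_aggregation",
        reason = paste0("duplicate structure aggregated into ", primary)))
    }
    d <- d[first_idx, , drop = FALSE]
    d$log_ic50 <- unname(agg_log[d$canonical_smiles])
    d$ic50_nM <- 10^d$log_ic50
    d$n_measurements <- unname(nmeas[d$canonical_smiles])
  }
  audit <- note(audit, "duplicate_aggregation", n3, nrow(d))

  # stage 5: label assignment (no exclusions)
  n4 <- nrow(d)
  if (n4 > 0) {
    d$label <- assignLabel(d$ic50_nM)
  } else {
    d$log_ic50 <- numeric(0); d$n_measurements <- integer(0)
    d$label <- integer(0)
  }
  audit <- note(audit, "label_assignment", n4, nrow(d))

  d$qualified <- NULL; d$std_error <- NULL
  rownames(d) <- NULL
  balance <- c(n = nrow(d),
               n_high = sum(d$label == 1), n_low = sum(d$label == 0))
  out <- list(records = d, audit = audit, exclusions = excl,
              classBalance = c(balance,
                               frac_high = unname(balance["n_high"] /
                                                    max(1, balance["n"])),
                               frac_low = unname(balance["n_low"] /
                                                   max(1, balance["n"]))))
  class(out) <- "curationResult"
  out
}

#' @export
print.curationResult <- function(x, ...) {
  cat("Curation result:", nrow(x$records), "compounds retained\n")
  print(x$audit, row.names = FALSE)
  cat(sprintf("class balance: %d high (%.1f%%), %d low (%.1f%%)\n",
              x$classBalance[["n_high"]], 100 * x$classBalance[["frac_high"]],
              x$classBalance[["n_low"]], 100 * x$classBalance[["frac_low"]]))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Train/test split
# ---------------------------------------------------------------------------

#' Random train/test split
#'
#' Disjoint and exhaustive random split, reproducible under `seed`.  The
#' test-set size is `round(n * testFraction)` (round-half-even).
#'
#' @param records `data.frame` of labelled compounds.
#' @param testFraction fraction of records held out, in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `test` data.frames.
#' @export
splitCompounds <- function(records, testFraction = 0.10, seed = 42L) {
  if (!is.data.frame(records) || nrow(records) < 10) {
    stop("need at least 10 records to split", call. = FALSE)
  }
  if (!is.numeric(testFraction) || testFraction <= 0 || testFraction >= 1) {
    stop("testFraction must be in (0, 1)", call. = FALSE)
  }
  n <- nrow(records)
  n_test <- round(n * testFraction)
  test_idx <- .withSeed(seed, sample.int(n, n_test))
  list(train = records[setdiff(seq_len(n), test_idx), , drop = FALSE],
       test = records[sort(test_idx), , drop = FALSE])
}
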