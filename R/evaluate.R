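# ---------------------------------------------------------------------------
# Classification metrics
# ---------------------------------------------------------------------------

## Rank-statistic (Mann-Whitney) AUC with average ranks for ties.
.rankAUC <- function(y_true, y_prob) {
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(y_prob, ties.method = "average")
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary classification metrics
#'
#' Computes AUC (rank statistic with average-rank tie handling), precision,
#' recall, F1, Matthews correlation coefficient, accuracy and the 2x2
#' confusion matrix at a probability threshold.  Predicted label is 1 when
#' the probability strictly exceeds the threshold.
#'
#' @param y_true 0/1 vector of reference labels.
#' @param y_prob positive-class probabilities (or scores) of equal length.
#' @param threshold decision threshold, default 0.5.
#' @return list of class `MetricsReport`: `auc`, `precision`, `recall`,
#'   `f1`, `mcc`, `accuracy`, `confusion` (matrix with TP, FP, FN, TN) and
#'   `n`.  With a single-class `y_true`, AUC is `NA` with a warning; the
#'   other metrics are still computed.
#' @examples
#' computeMetrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.1))
#' @export
computeMetrics <- function(y_true, y_prob, threshold = 0.5) {
  stopifnot(length(y_true) == length(y_prob))
  y_true <- as.integer(y_true)
  if (!all(y_true %in% c(0L, 1L))) {
    stop("y_true must be binary 0/1", call. = FALSE)
  }
  y_pred <- as.integer(y_prob > threshold)
  tp <- sum(y_pred == 1 & y_true == 1)
  fp <- sum(y_pred == 1 & y_true == 0)
  fn <- sum(y_pred == 0 & y_true == 1)
  tn <- sum(y_pred == 0 & y_true == 0)
  n <- length(y_true)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  mcc_den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_
  auc <- .rankAUC(y_true, y_prob)
  if (is.na(auc)) {
    warning("AUC undefined: y_true contains a single class")
  }
  out <- list(auc = auc, precision = precision, recall = recall, f1 = f1,
              mcc = mcc, accuracy = (tp + tn) / n,
              confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                                 dimnames = list(predicted = c("1", "0"),
                                                 actual = c("1", "0"))),
              n = n)
  class(out) <- "MetricsReport"
  out
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf(paste0("AUC %.3f | precision %.3f | recall %.3f | F1 %.3f | ",
                     "MCC %.3f | accuracy %.3f (n = %d)\n"),
              x$auc, x$precision, x$recall, x$f1, x$mcc, x$accuracy, x$n))
  print(x$confusion)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Prediction uncertainty
# ---------------------------------------------------------------------------

#' Binary entropy of predicted probabilities
#'
#' \eqn{H(p) = -p \log p - (1-p) \log(1-p)} with \eqn{0 \log 0 = 0},
#' in bits by default.  Symmetric about 0.5, maximal (1 bit) at p = 0.5,
#' zero at p = 0 or 1.
#'
#' @param p probabilities in `[0, 1]`.
#' @param logBase logarithm base, default 2 (bits).
#' @return entropies, same length as `p`.
#' @export
binaryEntropy <- function(p, logBase = 2) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  term <- function(q) ifelse(q == 0, 0, -q * log(q, base = logBase))
  term(p) + term(1 - p)
}

#' Prediction confidence tiers
#'
#' Assigns each prediction to a nested confidence tier.  In `"entropy"`
#' mode the tiers are entropy (bits) < 0.2 (`highest`), < 0.3
#' (`very_high`), < 0.5 (`confident`), otherwise `uncertain`.  In
#' `"probability"` mode the tiers are the probability bands p < 0.09 or
#' p > 0.91 (`highest`), p < 0.14 or p > 0.86 (`very_high`), p < 0.21 or
#' p > 0.79 (`confident`), otherwise `uncertain`.  The two modes are
#' deliberately independent: the probability bands are conventional
#' reporting bands and are not the exact entropy preimages of the entropy
#' cutoffs.
#'
#' @param p positive-class probabilities (required in probability mode;
#'   in entropy mode used only when `entropy` is missing).
#' @param entropy binary entropies in bits; computed from `p` if missing.
#' @param mode `"entropy"` or `"probability"`.
#' @return ordered factor with levels
#'   `uncertain < confident < very_high < highest`.
#' @export
confidenceTier <- function(p = NULL, entropy = NULL,
                           mode = c("entropy", "probability")) {
  mode <- match.arg(mode)
  lv <- c("uncertain", "confident", "very_high", "highest")
  if (mode == "entropy") {
    if (is.null(entropy)) {
      if (is.null(p)) stop("need p or entropy", call. = FALSE)
      entropy <- binaryEntropy(p)
    }
    if (any(entropy < 0 | entropy > 1)) {
      stop("entropy in bits must lie in [0, 1]", call. = FALSE)
    }
    tier <- ifelse(entropy < 0.2, "highest",
                   ifelse(entropy < 0.3, "very_high",
                          ifelse(entropy < 0.5, "confident", "uncertain")))
  } else {
    if (is.null(p)) stop("probability mode needs p", call. = FALSE)
    if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
    tier <- ifelse(p < 0.09 | p > 0.91, "highest",
                   ifelse(p < 0.14 | p > 0.86, "very_high",
                          ifelse(p < 0.21 | p > 0.79, "confident",
                                 "uncertain")))
  }
  factor(tier, levels = lv, ordered = TRUE)
}

# ---------------------------------------------------------------------------
# External agreement
# ---------------------------------------------------------------------------

#' Agreement between predicted and experimental labels
#'
#' Counts exact label matches between model predictions and experimental
#' classifications for the same compounds.
#'
#' @param predicted 0/1 predicted labels, optionally named by compound id.
#' @param experimental 0/1 experimental labels, optionally named.
#' @return list with `matches` (count) and `fraction`.
#' @examples
#' externalAgreement(c(1, 0, 1), c(1, 0, 0))  # 2 of 3
#' @export
externalAgreement <- function(predicted, experimental) {
  if (length(predicted) != length(experimental)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  if (!is.null(names(predicted)) && !is.null(names(experimental))) {
    bad <- names(predicted) != names(experimental)
    if (any(bad)) {
      stop("misaligned compound ids: ",
           paste(utils::head(names(predicted)[bad], 5), collapse = ", "),
           call. = FALSE)
    }
  }
  m <- sum(as.integer(predicted) == as.integer(experimental))
  list(matches = m, fraction = m / length(predicted))
}
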