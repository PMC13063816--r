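# ---------------------------------------------------------------------------
# Synthetic compound populations with planted structure-toxicity rules
# ---------------------------------------------------------------------------

#' Planted structure-toxicity rules
#'
#' The default rule set plants four toxicity-driving substructure families
#' on aromatic scaffolds: aromatic nitro, primary aromatic amine, tertiary
#' aliphatic amine (benzylic dimethylamino) and aryl ketone.  Each rule
#' decorates a compound with probability `prevalence` and, when present,
#' lowers log10 IC50 (nM) by `effect`.  The `bit` column records which
#' default-dictionary fingerprint bit uniquely flags the decoration, which
#' is what the attribution-recovery checks use as ground truth.  Effects
#' and prevalences are generator conventions chosen so that the
#' Bayes-optimal classifier on the planted bits reaches an AUC around
#' 0.95: separations of 2-3 noise standard deviations make recovery
#' meaningful but not trivial.
#'
#' @return `data.frame` with columns `name`, `group` (SMILES fragment,
#'   parenthesized for substitution), `bit`, `effect` (log10 IC50
#'   decrement) and `prevalence`.
#' @export
plantedRules <- function() {
  data.frame(
    name = c("aromatic_nitro", "aromatic_amine", "tertiary_amine",
             "aryl_ketone"),
    group = c("([N+](=O)[O-])", "(N)", "(CN(C)C)", "(C(C)=O)"),
    bit = c(46L, 0L, 165L, 6L),
    effect = c(1.1, 0.9, 0.8, 1.2),
    prevalence = c(0.25, 0.25, 0.25, 0.20),
    stringsAsFactors = FALSE)
}

## Aromatic scaffold templates, each with four substitution slots.
.syntheticScaffolds <- function() {
  c(benzene = "c1c%sc%sc%sc%sc1",
    toluene = "Cc1c%sc%sc%sc%sc1",
    pyridine = "n1c%sc%sc%sc%sc1",
    naphthalene = "c1ccc2c%sc%sc%sc%sc2c1")
}

## Toxicity-neutral decorations that decorrelate the planted custom bits
## from their broader standard-key relatives (e.g. aliphatic nitro fires
## the generic nitro key but not the aromatic-nitro key).
.noiseGroups <- function() {
  c(methyl = "(C)", ethyl = "(CC)", methoxy = "(OC)", hydroxy = "(O)",
    aldehyde = "(C=O)", acetoxy = "(OC(C)=O)", aminomethyl = "(CN)",
    methylaminomethyl = "(CNC)", nitromethyl = "(C[N+](=O)[O-])",
    hexyl = "(CCCCCC)", ethynyl = "(C#C)")
}

#' Synthetic-population configuration
#'
#' @param n number of compounds.
#' @param rules planted rule table, default [plantedRules()].
#' @param baselineLog baseline log10 IC50 (nM) of undecorated compounds;
#'   the default 4.5 sits half a log above the toxicity threshold of 4.
#' @param noiseSd standard deviation of Gaussian noise added to log10
#'   IC50.
#' @param noiseDecorationRate probability that an unused substitution slot
#'   receives a toxicity-neutral decoration.
#' @param scaffolds named character vector of scaffold templates, each with
#'   four `%s` substitution slots.
#' @param seed integer seed.
#' @return list of configuration values.
#' @export
syntheticConfig <- function(n = 2000L, rules = plantedRules(),
                            baselineLog = 4.5, noiseSd = 0.4,
                            noiseDecorationRate = 0.4,
                            scaffolds = .syntheticScaffolds(),
                            seed = 42L) {
  stopifnot(n >= 1, noiseSd >= 0,
            all(rules$prevalence > 0 & rules$prevalence < 1))
  list(n = as.integer(n), rules = rules, baselineLog = baselineLog,
       noiseSd = noiseSd, noiseDecorationRate = noiseDecorationRate,
       scaffolds = scaffolds, seed = as.integer(seed))
}

#' Generate a synthetic compound population
#'
#' Emits `n` valid SMILES built from aromatic scaffolds with planted
#' substructure decorations:
#' `log10 IC50 = baseline - sum(effects of planted decorations present) +
#' N(0, noiseSd)`, so labels under the threshold-4 rule follow the planted
#' substructures plus noise.  Every generated structure passes the default
#' applicability domain by construction.  Reproducible under the
#' configured seed.
#'
#' @param config a [syntheticConfig()].
#' @return `data.frame` with `id`, `smiles`, `ic50_nM` and attribute
#'   `truth`: a `data.frame` of the scaffold, per-rule presence flags and
#'   the noiseless log10 IC50.
#' @examples
#' pop <- generateCompounds(syntheticConfig(n = 50, seed = 1))
#' head(pop)
#' @export
generateCompounds <- function(config = syntheticConfig()) {
  scaffolds <- config$scaffolds
  if (is.null(scaffolds)) scaffolds <- .syntheticScaffolds()
  if (!length(scaffolds)) stop("empty scaffold set", call. = FALSE)
  noise_groups <- .noiseGroups()
  rules <- config$rules
  n <- config$n
  n_slots <- 4L
  .withSeed(config$seed, {
    scaf_idx <- sample(length(scaffolds), n, replace = TRUE)
    present <- matrix(stats::rbinom(n * nrow(rules), 1,
                                    rep(rules$prevalence, each = n)) == 1,
                      n, nrow(rules))
    smiles <- character(n)
    for (i in seq_len(n)) {
      slots <- rep("", n_slots)
      order_slots <- sample(n_slots)
      groups <- rules$group[present[i, ]]
      if (length(groups)) slots[order_slots[seq_along(groups)]] <- groups
      free <- which(!nzchar(slots))
      for (s in free) {
        if (stats::runif(1) < config$noiseDecorationRate) {
          slots[s] <- sample(noise_groups, 1)
        }
      }
      smiles[i] <- do.call(sprintf,
                           c(list(scaffolds[scaf_idx[i]]), as.list(slots)))
    }
    true_log <- config$baselineLog - as.numeric(present %*% rules$effect)
    log_ic50 <- true_log + stats::rnorm(n, 0, config$noiseSd)
    out <- data.frame(id = sprintf("syn_%05d", seq_len(n)),
                      smiles = smiles, ic50_nM = 10^log_ic50,
                      stringsAsFactors = FALSE)
    truth <- data.frame(scaffold = names(scaffolds)[scaf_idx],
                        true_log_ic50 = true_log)
    for (r in seq_len(nrow(rules))) truth[[rules$name[r]]] <- present[, r]
    attr(out, "truth") <- truth
    out
  })
}

#' Deterministic worked fixtures
#'
#' Small named compound sets, fully enumerated in source with their
#' expected outcomes, covering the decision boundaries of the pipeline:
#' the IC50 labelling boundary, applicability-domain violators,
#' duplicate-structure aggregation and dictionary edge molecules.
#'
#' @return named list of data.frames:
#' \describe{
#'   \item{boundary_ic50}{IC50 values straddling 1.0e4 nM with
#'     `expected_label`.}
#'   \item{ad_violators}{structures violating named domain rules
#'     (`expected_rules`).}
#'   \item{duplicates}{one structure measured twice (100 and 10000 nM);
#'     median-of-log aggregation gives log10 IC50 = 3, label 1.}
#'   \item{dictionary_edge}{molecules with known key bits
#'     (`expected_bit`, `expected_value`).}
#' }
#' @export
workedFixtures <- function() {
  list(
    boundary_ic50 = data.frame(
      id = paste0("bnd_", 1:4),
      smiles = rep("c1ccccc1O", 4),
      ic50_nM = c(1, 9999, 10000, 1e8),
      expected_label = c(1L, 1L, 0L, 0L),
      stringsAsFactors = FALSE),
    ad_violators = data.frame(
      id = c("adv_P", "adv_CH4", "adv_F"),
      smiles = c("CP(C)C", "C", "Fc1ccccc1"),
      ic50_nM = c(100, 100, 100),
      expected_rules = c("elements", "mw_min,h_c", "elements"),
      stringsAsFactors = FALSE),
    duplicates = data.frame(
      id = c("dup_a", "dup_b"),
      smiles = rep("c1ccccc1O", 2),
      ic50_nM = c(100, 10000),
      expected_log_ic50 = 3,
      expected_label = 1L,
      stringsAsFactors = FALSE),
    dictionary_edge = data.frame(
      id = c("benzene", "nitrobenzene", "aniline", "dmbenzylamine",
             "acetophenone"),
      smiles = c("c1ccccc1", "O=[N+]([O-])c1ccccc1", "Nc1ccccc1",
                 "CN(C)Cc1ccccc1", "CC(=O)c1ccccc1"),
      expected_bit = c(62L, 46L, 0L, 165L, 6L),
      expected_value = 1L,
      stringsAsFactors = FALSE))
}
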