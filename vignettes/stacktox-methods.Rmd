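---
title: "StackTox: methods and design notes"
author: "StackTox authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{StackTox: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

StackTox is a screening toolkit for ranking organic compounds by predicted
cytotoxicity from structure alone.  It targets the situation common in
environmental health work — for example nontargeted analysis of ambient
particulate matter — where a long list of candidate structures (SMILES)
must be narrowed to the few compounds worth testing in cell assays.  This
vignette explains the model, the parameters that matter, the synthetic
benchmark, and the design choices that were genuinely open.

## The classification problem

Cytotoxicity is summarized by IC50 against an epithelial cell line, in
nanomolar.  Compounds are labelled *highly toxic* (1) when
$\log_{10}(\mathrm{IC50~nM}) < 4$ (IC50 below 10 µM, a conventional
cut-off for marked cytotoxic potential in cell-based assays) and
*low-toxicity* (0) otherwise.  The boundary value $10^4$ nM itself is
labelled 0; `assignLabel()` implements exactly this step function and is
deliberately the only place the threshold appears.

## Structure representation

Each molecule is encoded as a 166-bit substructure fingerprint.  Bit $i$
fires when the molecule contains at least `min_count` unique matches of a
SMARTS pattern.  The dictionary is a first-class, editable object:

* `loadDictionary(NULL)` gives the shipped **standard** key set, this
  package's reconstruction of the classic 166-key design (element and
  count keys, ring/aromaticity keys, functional groups, and a block of
  inorganic/metal/halogen keys).
* `defaultDictionary()` applies the shipped customization: **43 bits
  (26 %) replaced**, swapping the inorganic/metal/halogen keys — useless
  for CHONS organics — for substructure families relevant to organic
  cytotoxicity: aromatic amines (primary/secondary/tertiary-substituted),
  aromatic nitro and nitroso groups, aryl and α,β-unsaturated ketones
  (Michael acceptors), amides, N/O/S heterocycles, fused aromatic
  systems, alkyl-chain and triple-bond descriptors.  Every replacement is
  a reconstruction authored for this package, and each is documented in
  `inst/extdata/custom_keys.cfg`; users can replace or remove any bit.

A content hash over all 166 definitions travels with every fingerprint
matrix and trained model, so a model can never silently score
fingerprints from a different dictionary.

Matching runs through OpenBabel with each pattern compiled once; the test
suite verifies all 166 bits against an independent RDKit match-count
oracle on a 50-molecule panel, so the bit semantics do not depend on a
single engine's quirks.

## Applicability domain

Predictions are only meaningful inside the chemical space the training
data covers.  The domain is defined on the molecular formula: elements
⊆ {C, H, O, N, S}; average molecular weight 50–900 Da; H/C ∈ [0.3, 3.0];
O/C ∈ [0, 3.0]; N/C ∈ [0, 1.3]; S/C ∈ [0, 0.8]; DBE/C ∈ [0, 1.0] with
$DBE = C - H/2 + N/2 + 1$.  These windows describe typical ambient
organic aerosol constituents.  Three numerical choices:

* **average** (not monoisotopic) atomic masses, since the window
  describes bulk organics and no mass type is otherwise implied;
* all bounds are **closed intervals** — boundary compounds pass;
* ratios are computed from exact integer counts before division, so a
  compound exactly on a bound cannot drift across it in floating point.

`inDomain()` reports *every* violated rule, not just the first, which
makes curation audits interpretable.

## Curation pipeline

`curateCompounds()` runs a fixed five-stage cascade: standardization →
IC50 selection → domain filter → duplicate aggregation → labelling.
Standardization keeps the largest covalent fragment (dropping counter-ions
and solvents), neutralizes charges where a proton transfer suffices (both
behaviours are flags, since reasonable pipelines differ on whether mixtures
should instead be discarded), and canonicalizes; it is idempotent.
Qualified IC50 values (">", "<") are excluded by default — value selection
is meant to be stringent — with a flag to retain the bound as the value.
Duplicate canonical structures are aggregated by the **median of log10
IC50** (robust to assay outliers; `mean` and `min` are available).  The
audit telescopes: each stage's output count is the next stage's input
count, and every excluded record carries exactly one first-failure reason.

`splitCompounds()` holds out `round(n × 0.10)` records.  Rounding is
banker's rounding on the test side; published splits of this kind
occasionally disagree with their own totals by one compound, which is why
the audit never forces a target count.

## The stacking ensemble

Six base families — SVM (RBF), random forest, k-NN, leaf-wise
gradient-boosted trees, depth-wise gradient-boosted trees, and a single
decision tree — are trained under 5-fold stratified cross-validation.
The leaf-wise family is implemented with the xgboost backend's
`lossguide` grow policy (`max_leaves`-driven growth, the LightGBM-style
algorithm).  The meta-model is ridge-penalized logistic regression over
the six positive-class probabilities.

Two design points were open and decided here:

* **Out-of-fold meta-features.**  Each training row's meta-feature comes
  from a fold model that never saw that row; the meta-model therefore
  never learns from leaked in-sample fits.  In-fold features are available
  behind `inFoldMeta = TRUE` for comparison only.
* **Probability-only meta-features.**  Only the positive-class
  probability enters (6 columns); the complementary class adds no
  information.

Prediction uses a strict 0.5 cutoff: probability exactly 0.5 gives label
0.

## Biobjective tuning

Hyperparameters are tuned by seeded random search over conventional
ranges (300 trials per base family and 70 meta trials by default; both
scale down for desk-scale work).  Each trial is scored by a scalarization
of the stated goals — training AUC above 0.9, validation AUC above 0.8,
a small train–validation gap, and agreement with an external
experimentally labelled set when one is supplied:

$$score = AUC_{val} - \lambda \max(0, gap - gap_{tol})
  - 10\,\max(0, 0.9 - AUC_{train}) - 10\,\max(0, 0.8 - AUC_{val})
  + \mu \cdot \mathrm{agreement}$$

with defaults $\lambda = 1$, $gap_{tol} = 0.1$, floor penalty 10 per unit
shortfall, $\mu = 1$.  The goals come stated as objectives, not as a
formula; this scalarization is the package's own construction, every
weight is configurable, and the full trial trace is recorded in the
bundle.  During tuning the SVM is scored on monotonically squashed
decision values instead of Platt-calibrated probabilities — AUC is
invariant under monotone transforms, and this avoids paying for
calibration hundreds of times; the final refit is calibrated.

## Prediction uncertainty

Confidence is quantified by the binary entropy of the stacked
probability, $H(p) = -p\log_2 p-(1-p)\log_2(1-p)$, in bits.  Tiers are
nested: entropy < 0.2 (*highest*), < 0.3 (*very high*), < 0.5
(*confident*), else *uncertain*.  A second, independent mode assigns
tiers directly by probability bands (p < 0.09 or > 0.91; 0.14/0.86;
0.21/0.79).  The two modes are deliberately not derived from one another:
the conventional probability bands are not the entropy preimages of the
entropy cutoffs ($H_2(0.09) \approx 0.44$, not 0.2), so forcing a single
definition would silently change one set of published-style bands.  Both
are provided; the mode is always explicit.

## Shapley attribution and rules

The stacked model is explained **end-to-end as one black-box function**
of the 166 bits (not per-base-model attributions averaged), which is the
question a screener actually asks: which substructures drove *this
ensemble probability*.  Two estimators are provided:

* **exact** — coalition enumeration over the features on which the
  explained compound differs from a background row (≤ 12 of them), the
  textbook Shapley value;
* **sampling** — a permutation estimator whose telescoping construction
  makes local accuracy (base value + attributions = model output) hold
  exactly up to floating point even at small permutation counts, with
  per-feature Monte-Carlo standard errors reported.

The background is a seed-fixed subsample of training fingerprints
(default 100 rows) — attribution is always relative to a reference
population, so the background is recorded in the explanation object.
`rankBits()` orders bits by mean |SHAP| (ties to the lower index);
direction is the sign of the mean SHAP **conditional on the bit being
present**, which avoids dilution by the many rows where a bit is absent.
`extractRules()` turns the top bits into structure–toxicity rules,
`annotateCompound()` maps rules back onto atoms, and `screenCompounds()`
builds the prioritized table (label, then probability, then entropy;
stable ties).  SHAP-profile clustering uses Ward-linkage agglomerative
clustering on the rows of the attribution matrix — deterministic, no
initialization sensitivity, and the dendrogram cut is the only parameter.

## The synthetic benchmark

`generateCompounds()` emits valid CHONS structures from four aromatic
scaffolds (benzene, toluene, pyridine, naphthalene), each with four
substitution slots.  Four planted rules decorate compounds independently
(aromatic nitro, effect 1.1, prevalence 0.25; primary aromatic amine,
0.9/0.25; benzylic tertiary amine, 0.8/0.25; aryl ketone, 1.2/0.20), and

$$\log_{10} IC50 = 4.5 - \textstyle\sum_{\text{present}} effect
  + \mathcal N(0, 0.4).$$

Unused slots receive toxicity-neutral decorations (methyl, methoxy,
aliphatic nitro, aliphatic amines, hexyl, ethynyl, …) at rate 0.4.  These
confounders matter: they fire the *broad* standard keys (generic nitro,
generic primary amine, dialkyl-N) on non-toxic compounds, so the planted
*custom* bits are the uniquely informative features and attribution
recovery is a real test rather than an artifact of perfectly correlated
twins.  Effects of 2–3 noise standard deviations put the Bayes-optimal
AUC near 0.95: high enough that a correct implementation passes the 0.90
bar comfortably, low enough that a leaking or mis-stacked pipeline fails
it.  The default conditions (n = 2000, noise SD 0.4, the four effects
above) are fixed study conditions, not knobs.

What the generator does *not* emulate: real aerosol-constituent
populations have broader scaffold diversity, correlated substituents,
assay noise that is not lognormal, and activity cliffs.  Passing the
synthetic recovery test therefore demonstrates that the pipeline is
correct and leak-free — not that any particular real-data AUC will be
reached.

## Problem sizes and numerical notes

The acceptance analysis and tests run the synthetic study at n = 2000
with reduced search (20 trials per base family, 10 meta trials) and
Shapley sampling with 32 permutations over 100 explained compounds
against a 100-row background — sizes chosen so the whole study re-runs
comfortably on a laptop core while keeping all qualitative conclusions
stable.  Degenerate cases are handled explicitly: single-class labels
refuse to train (and AUC is reported `NA` with a warning in metrics); a
constant out-of-fold matrix makes the meta-model fall back to the
majority-class prior with a warning; all-zero fingerprint pairs have
Tanimoto similarity 1 by documented convention; `0·log 0 = 0` in the
entropy.

## Known limitations

* The 43 custom bit definitions are reconstructions of a customization
  family, not a copy of any published table; equivalence with any
  specific published dictionary is neither claimed nor testable from the
  open literature.
* The SMARTS engine is OpenBabel; a handful of exotic aromaticity
  perceptions differ between toolkits.  The dual-engine oracle test pins
  the shipped dictionary's behaviour on representative chemistry.
* Tuning is random search, not adaptive (no surrogate model); with the
  default trial counts this is a practical, reproducible stand-in, and
  the full trace is kept so any trial can be audited.
* Regression-grade IC50 prediction, 3D/conformer effects, tautomer
  enumeration and mixture toxicity are out of scope.
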