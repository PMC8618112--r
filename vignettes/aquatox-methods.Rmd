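---
title: "Building aquatic-toxicity QSAR models with aquatox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building aquatic-toxicity QSAR models with aquatox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Regulatory hazard assessment of chemicals in freshwater requires toxicity
values for three trophic levels — a primary producer (the green alga
*Raphidocelis subcapitata*), a primary consumer (*Daphnia magna*) and a
secondary consumer (fish) — for both acute endpoints (EC50/LC50, the
concentration affecting half the exposed population) and chronic endpoints
(NOEC, the no-observed-effect concentration). Measured values exist for
only a fraction of chemicals in commerce; quantitative structure–activity
relationship (QSAR) models fill the gaps by regressing an endpoint on
descriptors computed from a compound's structure.

`aquatox` implements a complete random-forest QSAR pipeline for these
endpoints: curation of heterogeneous replicate records into one response
per chemical, 2D descriptor computation and pruning, variable selection,
a rational training/validation split, bootstrap-tuned random-forest
regression, and — the part that makes predictions usable in a regulatory
setting — a dual applicability domain (AD) that flags compounds whose
predictions should not be trusted.

## Curation of raw records

Raw inputs are replicate toxicity records: one measured value in mg/L per
row, with a qualifier, species, endpoint, exposure duration, optional
water solubility and a pH-adjustment flag. Curation proceeds in a fixed
order; every record and every compound receives exactly one fate, logged
in the audit trail:

1. **Record filters.** Only `exact` values are kept: censored
   (`greater_than`/`less_than`), `range` and `approximate` qualifiers are
   uninformative for regression. Records outside the guideline exposure
   window for their endpoint (72 h algal tests, 48 h acute and 21 d
   chronic daphnid tests, 96 h acute fish tests, 28–90 d early-life-stage
   chronic fish tests) are dropped, as are pH-adjusted records for
   daphnid and fish data. Optional study-quality criteria (dose count,
   purity, exposure type) apply when the columns are present.
2. **Structure standardization.** SMILES are validated by a strict
   tokenizer (the chemistry toolkit silently repairs some malformed
   strings, so validation cannot be delegated to it), canonicalized,
   counter-ion fragments stripped (the parent is the component with the
   most heavy atoms; ties by carbon count, then lexicographically), and
   residual charges neutralized where valence allows. Algal datasets
   keep the ionized form: pH is critical in algal growth media, and the
   ionized species is the relevant one.
3. **Structural exclusions.** Inorganics (no carbon), metal-containing
   structures, multi-component mixtures, wildcard atoms, and elements
   outside the supported organic set are excluded with a reason;
   UVCBs, isomer mixtures, non-ionic surfactants and name/CAS mismatches
   are metadata-level categories readable only from flags.
4. **Unit conversion.** mg/L values become mmol/L by division with the
   molecular weight of the standardized parent.
5. **Replicate consolidation.** Replicates must agree within a factor of
   10 (one log unit); the boundary ratio passes, with a multiplicative
   tolerance of 1 + 1e-9 against floating-point ties. Acceptable sets
   consolidate to the geometric mean (the median and arithmetic mean are
   kept for the audit; on real collections the three agree almost
   perfectly). Compounds with a wider spread are rejected outright; the
   search for the single offending replicate is a manual-curation step,
   supported only through an override column.
6. **Solubility screen.** A consolidated value above the compound's
   water solubility cannot have been in solution and drops the compound;
   missing solubility keeps it with a warning flag.
7. **Microspecies screen (algal only).** The dominant microspecies is
   predicted at pH 7.5 and 8.1 — the two admissible growth media — with
   a pluggable pKa source (default: a SMARTS-group lookup table) and a
   Henderson–Hasselbalch majority rule: an acid group is deprotonated iff
   pH > pKa, a base protonated iff pH < pKa. Compounds whose dominant
   form differs between the two media are removed, since the assay
   medium is unknown. The default table is a deliberate heuristic; the
   commercial microspecies engines it stands in for can be plugged in.
8. **Normalization.** Responses are Box–Cox transformed,
   \((x^\lambda - 1)/\lambda\) (log at \(\lambda = 0\)), with
   \(\lambda\) maximizing the profile log-likelihood over \([-2, 2]\) by
   golden-section search (the likelihood is unimodal in practice; the
   interval covers every transform between inverse-square and square).
   Values outside mean ± 3 SD of the transformed distribution are
   excluded in a single pass — the rule is applied once, never iterated,
   and the boundary is inclusive. The sample SD (n−1) is used. The
   outlier pass runs before the training/validation split, so the split
   operates on the final dataset.

## Descriptors

Dragon, the descriptor engine used by much of the QSAR literature, is
proprietary; `aquatox` computes an open 2D descriptor block through
OpenBabel (via ChemmineR/ChemmineOB) plus its own graph code: a
Ghose–Crippen-style logP (ALOGP), molar refractivity, TPSA, H-bond
counts, constitutional counts from the molecular formula,
functional-group and SMARTS-pattern counts, and topological indices
(Zagreb, Randić connectivity, Wiener, diameter) from the heavy-atom
graph — 54 descriptors in total. The matrix records its provenance so a
model declares its descriptor space. Compounds whose logP cannot be
computed are dropped: logP is the descriptor most closely tied to
aquatic toxicity, and a compound outside its parameterization is outside
the model's chemistry. Published statistics obtained with proprietary
descriptor sets are consequently not expected to be matched numerically.

Pruning removes constant columns (variance below 1e-12 counts as
constant) and then correlated ones: while any pair has |Pearson r| >
0.95, the column with the most violating partners is removed (ties: the
higher mean |r| over its partners, then the lexicographically smaller
name). Anticorrelated descriptors are equally redundant, hence the
absolute value. One member of each correlated pair survives; removing
both would discard information the model could use.

## Variable selection

Two selectors are provided; per endpoint either can be configured, or
both can be run with the better 10-fold CV R² kept.

**Genetic algorithm.** Binary chromosomes encode subsets within size
bounds (default 5–40, matching the descriptor counts final models tend
to have). Fitness is the out-of-bag R² of a forest fitted on the subset —
a bootstrap cross-validation estimate obtained from a single fit, which
keeps the 30 × 20 fitness evaluations (population × generations)
affordable; evaluations are memoised, and a k-fold fitness is a config
switch away. Tournament selection, uniform crossover (p = 0.5), per-gene
mutation (p = 0.02) and elitism complete the loop; the best-so-far trace
is non-decreasing by construction.

**Three-phase importance selection.** (1) *Thresholding*: variables are
ranked by mean permutation importance over 25 forests; the threshold is
the minimum of a CART (piecewise-constant) fit to the importance
standard deviations — noise variables have small, flat importances whose
variability the fit isolates. (2) *Interpretation*: nested forests over
the ranked survivors; the prefix with the smallest out-of-bag error is
kept. (3) *Prediction*: survivors are re-added stepwise only when they
improve the error by more than a noise-scaled margin (the mean error
jump over the flat tail of the nested-error curve). The pipeline keeps
the interpretation set by default: the prediction set is deliberately
parsimonious and on low-noise data can discard genuinely informative,
partially redundant variables, while the interpretation set matches the
descriptor-count scale at which these models are reported. The
prediction set remains available via `vsurf_set = "prediction"`.

## Training/validation split

The 80:20 split balances both chemistry and response: PCA is run on the
autoscaled descriptor block, and splitting happens in the joint space of
the first two PCs and the autoscaled response (weight 1 each — the
relative weighting is an open choice; equal weights avoid privileging
either). Five random compounds seed the training set; the compound with
the maximal minimal distance to the current pool (maxmin) is added until
the training set holds round-half-up 80% of compounds; the rest
validate. Manhattan distance and maxsum scoring are available as
alternatives. Fitting PCA on the full dataset before splitting mirrors
the original procedure but technically lets validation compounds
influence the projection — a known, accepted leakage caveat of this
family of splits. The response coordinate concentrates response extremes
in the training set, so validation-set variance is systematically
smaller than the population's; validation R² values are accordingly
conservative.

## The activity model

The regressor is a random forest. Hyperparameters (trees, per-split
feature fraction, leaf size, per-tree row fraction) are tuned by
bootstrap cross-validation: B resamples (default 100) are drawn once and
shared across the grid; each configuration is fitted on every resample
and scored by R² on the out-of-bag rows; the best mean wins. Per-tree
spread (TREE_SD) uses the population (n) denominator. Cross-validated
absolute errors come from a seeded, shuffled k-fold (default 10).

## The dual applicability domain

Approach 1 bounds *structural* novelty: the mean Euclidean distance to
the k nearest training compounds (k ∈ {1, 5}), computed in the
autoscaled selected-descriptor space (training compounds exclude
themselves), must not exceed T_D, a percentile (100th, 97.5th, 95th or
90th) of the training distance distribution. Percentiles interpolate
linearly; the 100th is the maximum.

Approach 2 bounds *predicted unreliability*: an error model — a second
forest — regresses the activity model's cross-validated absolute errors
on six AD metrics: wRMS1 (weighted RMS difference between the target's
prediction and its five nearest neighbours' observed values), wRMS2
(same, with the neighbours' predicted values), the distance to the
nearest neighbour and the mean distance to five, TREE_SD, and the
prediction itself. The weighting of wRMS1/2 is inverse distance,
\(w_i \propto 1/(d_i + 10^{-6})\), normalized to sum one, so nearer
neighbours dominate; the weighting scheme is swappable. Predicted errors
are clamped at zero and thresholded at T_E, a percentile (100th, 90th,
75th or 65th) of the training predicted-error distribution.

A compound is inside the AD iff **both** checks pass. The 2 × 4 × 4 = 32
combinations (metric fixed to Euclidean — the only reading consistent
with a 32-sized grid; Manhattan is available but off by default) are
evaluated on the training set with 10-fold CV predictions; the selected
combination maximizes in-AD CV R² among those with coverage ≥ 0.75
(reported model coverages cluster above 0.8), ties going to higher
coverage and then milder thresholds. Leverage (hat-matrix diagonal, high
iff \(h > 3(p+1)/n\)) is computed for reporting only; it does not gate
the AD.

One behaviour worth knowing: the training-side AD metrics use
resubstitution predictions, so TREE_SD runs lower on training compounds
than on genuinely new ones. On synthetic benchmarks with sharply defined
training clouds this can push validation predicted errors above tight
T_E thresholds and depress validation coverage; on chemical descriptor
spaces the distributions overlap and coverages in the 0.8–0.95 range are
typical.

## Synthetic fixtures

The generator emulates the statistical structure the pipeline assumes,
not real toxicology: a library drawn from ~300 curated drug- and
agrochemical-like SMILES templates (guaranteeing parseability and
descriptor computability) with controlled fractions of salts, ionizable
compounds and excludable structures; replicate records (1 + Poisson
draws per compound) with multiplicative spread below one log unit;
configurable fractions of censored and pH-adjusted records,
inflated-spread compounds (which the factor-of-10 rule must reject),
solubility violators and gross outliers. The simulated response is
linear in computed descriptors (ALOGP, MW, TPSA by default) on the
transformed scale with Gaussian noise (SD 0.8), mapped to mg/L through
the inverse Box–Cox transform and the molecular weight. Bookkeeping
records every deliberate defect so curation decisions can be compared
with ground truth record by record. What passing these tests shows is
that the machinery is faithful; it says nothing about predictivity for
real species, which depends on data the generator does not imitate
(species-specific modes of action, experimental error structure,
chemistry far from the template pools).

Default generator settings are the study conditions of the test suite:
200-compound fixtures for curation replay; n = 300, p = 50 with five
informative descriptors for selection recovery; n = 400 for Box–Cox
recovery at \(\lambda^* \in \{0, 0.5, 1\}\) (simulation means/SDs chosen
once so the transform is statistically identifiable at that n); n = 500
for the end-to-end and error-model checks, with noise calibrated so the
generating linear model scores R² = 0.85 on the pipeline's own
validation subset. These sizes keep the full suite within an ordinary
desktop run while leaving each property comfortably testable.

## Numerical choices and degenerate inputs

- Percentiles: linear interpolation (R type 7), which reproduces the
  worked threshold examples exactly.
- round(0.8 n) is round-half-up.
- Golden-section tolerance on \(\lambda\): 1e-6; \(|\lambda| <\) 1e-10
  is treated as the log branch for continuity.
- Dissimilarity ties: lowest compound index wins; PCA signs are fixed by
  making each component's largest-magnitude loading positive.
- Constant responses: forests predict the constant; CV errors are zero;
  R² is undefined (NA with a warning) when observations have zero
  variance.
- Back-transformation to mg/L inverts the Box–Cox transform and
  multiplies by molecular weight; where the inverse is undefined
  (\(\lambda t + 1 \le 0\)) the value is reported missing.
- Singular descriptor cross-products fall back to the pseudo-inverse for
  leverage.

## Limitations

- Open 2D descriptors are not Dragon descriptors: models are internally
  consistent but not numerically comparable to published ones built on
  proprietary spaces.
- The default pKa table covers the common ionizable groups only; exotic
  chemistry should use a real pKa engine through the plugin interface.
- No structure lookup by name/CAS, no experimental-reliability scoring,
  no 3D or quantum descriptors, no conformal calibration of the error
  model.
- The AD grid search optimizes on training-set CV; very small datasets
  make the in-AD R² estimates noisy and the selected thresholds
  unstable.

## A worked run

```{r, eval = FALSE}
library(aquatox)

spec <- fixtureSpec(n_compounds = 150)
lib <- generateCompoundLibrary(spec, seed = 11)
gen <- generateToxicityRecords(lib, spec, seed = 11)

res <- runPipeline(list(
  endpoint = "EC50", species = "Daphnia magna", trophic_level = "daphnid",
  seed = 11, records = gen$records,
  selection_method = "vsurf",
  vsurf = list(nForests = 10, ntree = 60, nested = 25),
  rf_grid = list(list(n_trees = 200, max_features = 0.33,
                      min_samples_leaf = 3),
                 list(n_trees = 200, max_features = 0.6,
                      min_samples_leaf = 1)),
  tune_B = 15, cv_folds = 10, outdir = "run1"))

res$reports$validation$r2      # validation R2 without AD
res$reports$validation_ad$r2   # validation R2 inside the AD
res$reports$validation_ad$coverage
adConfig(res$bundle)

predictToxicity(res$bundle, c("CCOc1ccccc1", "CCCCCCCCO"))
```
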