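---
title: "Matched case-control lipidomics: networks, cluster importance, and a cross-validated multilipid score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matched case-control lipidomics pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipanet)
```

## The analysis problem

Nested case-control studies of incident disease measure a lipidomics panel
at baseline in every case and in 1-3 controls matched to it (here: on
recruitment center, sex, and age within five years). Individual lipid
species rarely survive multiple-testing correction in such designs: effects
are small, the panel is large, and lipids of the same class are strongly
correlated, so single-feature screens are both underpowered and redundant.
This package implements the complementary strategy of treating the lipidome
as a correlated system: learn a conditional-independence network over the
features, group it into clusters, ask which clusters carry predictive
signal, distill those clusters into a small set of mutually independent
predictors, and summarize them in a single cross-validated weighted score
whose association with the outcome is estimated on the odds-ratio-per-SD
scale. A parallel varimax-rotated PCA pathway provides a factor-level view
of the same data.

Because individual-level data from studies of this design are typically
held in access-controlled enclaves, the package ships a matched-cohort
simulator with known ground truth. Every stage is therefore testable:
parameter recovery, calibration under the null, and structure recovery are
all checked against the generator's truth records rather than against
irreproducible published coefficients.

## The matched design and its likelihood

A stratum is one case plus its matched controls. All association models are
conditional logistic: the contribution of stratum $s$ is

$$P(\text{observed case} \mid \text{one case in } s)
  = \frac{\exp(\beta^\top x_{\text{case},s})}{\sum_{j \in s} \exp(\beta^\top x_{j,s})},$$

which eliminates stratum-specific intercepts and with them the matching
variables (anything constant within every stratum carries no information
and is dropped, with a log entry -- recruitment center always ends up here
even though it is also listed among the adjustment covariates). The core
fitter is a Newton-Raphson maximizer with step-halving, convergence on
$|\Delta \ell| < 10^{-10}$ (at most 50 iterations), standard errors from
the inverse observed information, and explicit separation handling: a
coefficient norm above 15 on SD-scaled predictors, or a fit in which every
stratum's case is predicted with conditional probability
$1 - 10^{-6}$ or better, is returned flagged rather than silently. The
simulator assigns case status within each stratum by sampling one member
with probability proportional to $\exp(\beta^\top x)$ -- exactly the
conditional-logistic data-generating assumption -- so recovered
coefficients can be compared directly to the planted ones. True risk-set
sampling from a full cohort cannot be replicated without that cohort;
conditional-logit assignment is its likelihood-equivalent stand-in.

## Value-level preprocessing

Three transforms, applied in this order and recorded in a provenance list:

- **Half-minimum imputation.** Missing abundances of feature $j$ become
  $\min_j/2$. This presumes left-censoring (values below the detection
  limit), which is also the simulator's default missingness mechanism.
- **Blom transform.** Per feature,
  $z_i = \Phi^{-1}\!\big((r_i - 3/8)/(n + 1/4)\big)$ with tie-averaged
  ranks $r_i$. The output is approximately standard normal, so odds ratios
  are per SD, and any strictly monotone rescaling of the raw feature gives
  identical output -- which is also why the simulator's log-normal marginal
  choice is immaterial downstream. Ties must be handled explicitly because
  half-minimum imputation creates them; averaged ranks keep the map
  well-defined and symmetric. The transform is computed over the full
  analysis sample (cases and controls together).
- **Strata deviations.** Each value minus its stratum's mean for that
  feature. This carries the matched design into the stages that use
  unconditional models (the random forest and the elastic net): within a
  stratum only the case-vs-control contrast survives. The transform is
  idempotent and exactly centers every stratum.

## Network and clusters

The skeleton of the lipid network is learned with the PC algorithm:
starting from the complete graph, an edge $(i,j)$ is removed as soon as
some conditioning set $S$ drawn from either endpoint's current neighbors
makes the Fisher-z partial-correlation test non-significant,

$$z = \sqrt{n - |S| - 3}\; \tfrac{1}{2}\log\frac{1+r}{1-r},$$

for orders $|S| = 0$ up to `max_order`. Defaults are $\alpha = 0.05$ and
`max_order = 3`; both are recorded in the result. Implementation choices
that matter for reproducibility: adjacency is frozen at the start of each
order (the order-independent "stable" variant), subsets are enumerated
lexicographically in input column order, and every removal stores its
separating set, partial correlation, and p-value so the decision can be
replayed. Output is invariant to row permutation of the data; it does
depend on the column order, which is therefore fixed as the input order.

Edge robustness emulates replication across two studies on the same
platform when only one dataset is available: skeletons are learned on two
random halves of the strata (strata kept intact), and an edge is retained
only if present in both halves *and* its partial correlation on the pooled
data exceeds 0.1 in absolute value. The conditioning set for that
threshold test is the union of the two endpoints' neighbors in the
intersected skeleton, capped at `max_order` members chosen by marginal
correlation strength; the choice is recorded in `algorithm_params` rather
than claimed to be canonical, since a partial correlation is only defined
relative to its conditioning set. Walktrap community detection (step
length 4, maximum-modularity cut) partitions the robust network; isolated
nodes become singletons.

## Cluster importance by joint permutation

A 500-tree classification forest (per-tree subsample 2/3 drawn *without*
replacement -- "sampling rate" read literally; a switch enables bootstrap
instead) is grown once on the strata-deviation matrix. A cluster's
importance is the increase in out-of-bag misclassification when all of its
member columns are permuted with **one shared row permutation**, which
severs the cluster-outcome link while preserving the within-cluster
dependence structure; independent per-column shuffles would instead
present the forest with impossible feature combinations. Out-of-bag
predictions are majority votes over the trees for which a row is out of
bag, ties to the first class, and the baseline error is computed once
under the same vote rule so that the reported increase isolates the
permutation effect. Permutation is repeated 10 times per cluster and
averaged to damp Monte-Carlo noise; repeats, tree count and seed are all
recorded. The top 7 clusters (a configurable cut, chosen to match the
length of a typical "most important clusters" table) go forward.

## Predictor selection and the LOOCV score

Selection is nested: a tenfold cross-validated elastic net (binomial
deviance loss) on each top cluster's features, then a second
cross-validated elastic net over the pooled within-cluster selections.
Folds are stratified by outcome; the mixing parameter is chosen from the
small grid $\{0.1, 0.5, 0.9\}$ jointly with the penalty by minimum CV
deviance (the 1-SE rule is off by default). Selection runs on the
strata-deviation data with unconditional logistic loss -- consistent with
the deviation transform's purpose -- rather than with conditional models;
the likelihoods agree up to the within-stratum centering approximation,
and a configuration switch documents the alternative. Single-feature
clusters are handled by padding the design with an infinitely penalized
duplicate column, since the coordinate-descent fitter requires two
columns.

The multilipid score is built leave-one-stratum-out: for each stratum, a
conditional logistic model (selected features plus all adjustment
covariates) is fitted on the remaining strata, and the held-out stratum's
subjects are scored with that fold's feature coefficients only. The
left-out unit is the matched stratum, not the subject, because subjects
within a stratum are coupled through the conditional likelihood -- leaving
out one subject of a pair would leak its outcome through its partner.
Reported per-feature weights are medians across folds; per-subject scores
keep their fold-specific weights. The final association standardizes the
score to unit SD (the analysis-sample SD) and fits a conditional logistic
model of outcome on score plus covariates; effect modification by the
3-arm intervention is tested by adding two score-by-arm product terms and
a joint 2-df Wald test.

## The PCA pathway

Principal components are extracted from the *controls'* correlation
matrix; components with eigenvalue above 2 are retained and
varimax-rotated (Kaiser normalization; communalities and the orthogonality
of the loading block are preserved to numerical precision, and both are
asserted in tests). Factor scores are loading-weighted sums of features
standardized by the control means and SDs, so cases are projected into the
controls' coordinate system -- the most direct reading of applying
loadings "obtained among controls" to everyone, with regression scoring
left behind a configuration option. Features with $|loading| > 0.40$ label
a factor. Associations use quartiles with cut points from the controls
only (so no case can move a boundary), ORs for quartiles 2-4 against
quartile 1, a trend test that replaces the indicators with the per-quartile
median control score as a single continuous term (monotone by
construction), and the same 2-df intervention interaction test. Extreme
quartile contrasts are reported as Q4 vs Q1.

## What the simulator does and does not emulate

The generator reproduces the design features the methods depend on: 1-3
controls per case (mix averaging ~1.43 controls, for ~1245 subjects from
512 strata), matching on center/sex/age-within-5-years, a 216-feature
panel in 18 exchangeable-correlation blocks (within-block correlation 0.5
by default) standing in for lipid-class structure, log-normal abundances,
left-censored missingness at 5%, covariate distributions matched to a
high-cardiovascular-risk elderly trial population, and sparse true
effects acting through block members. Optional control reuse mimics
incidence-density sampling with replacement but is off by default to keep
variance-estimation assumptions simple; how often real studies reuse
controls is not generally reported, so it is a parameter rather than an
assertion.

It does **not** emulate: real lipid-class correlation topology (blocks are
exchangeable, real classes are not), assay batch or drift structure,
follow-up time, the dietary intervention's effect on the lipidome, or
isomer ambiguity in feature identities. Passing tests therefore
demonstrate that the *methods* recover planted structure under a faithful
rendering of the design -- not that any particular real-data coefficient
is reproduced. Headline numbers of enclave-held studies are out of reach
by construction; the tests instead pin down calibration (null screens
reject at the nominal rate; null score CIs cover 1; interaction p-values
are uniform) and recovery (planted clusters rank first; a planted
composite effect of 0.28 log-odds per SD is recovered as a score OR per SD
near $e^{0.28} \approx 1.32$).

## Numerical choices and degenerate inputs

- Newton-Raphson: step-halving on likelihood decrease, tolerance
  $10^{-10}$, warm starts (covariate-only solution for the screen, the
  full-data fit for LOOCV folds) cut iterations roughly in half.
- Separation and non-convergence are flags, never silent results; screen
  features whose fits fail keep their place in the output with missing
  p-values and, by default, still count toward the BY family size (the
  conservative choice; configurable).
- Constant features error in the Blom transform (degenerate ranks);
  entirely missing features error in imputation, by name.
- Singleton strata error in the deviation transform (a deviation of
  exactly zero carries no contrast).
- Empty robust networks produce singleton clusters with a warning; a PCA
  with no eigenvalue above the cutoff returns an empty model with a
  warning.
- All tie-breaks are deterministic: importance ranks break ties by cluster
  id, OOB votes break ties to the first class, cluster ids are densified
  in first-appearance order.
- One global seed fans out to fixed per-stage seeds, so toggling one stage
  never shifts another's randomness; identical configuration and seed give
  byte-identical artifacts, and numeric artifacts are written at 17
  significant digits so that replaying a stage from saved files reproduces
  single-shot results exactly.

## Problem sizes used in the checks

The test suite and the acceptance script run the generator at the design's
working scale -- 512 strata by 216 lipids for end-to-end runs, 500 strata
for screen calibration and score recovery (20 replicates each), 400
strata for cluster-importance recovery -- and at reduced sizes for unit
tests. These sizes were chosen once as the smallest at which the
respective properties are comfortably identified; recovery margins are
set by the properties themselves (e.g. the planted cluster must rank
first in at least 18 of 20 replicates), not tuned to observed runs.

## Known limitations

- **Null LOOCV scores are not calibrated on the per-SD scale.** When the
  score features carry no true effect, leave-one-stratum-out weights are
  anti-correlated with the held-out strata's chance feature-outcome
  alignment (the jackknife phenomenon familiar from pre-validation), and
  dividing by the near-zero SD of a null score amplifies this into a
  systematic *negative* bias of the estimated log-OR, with seed-to-seed
  spread well beyond the model's nominal standard error. A minimal
  independent implementation (plain logistic regression on within-pair
  differences) reproduces the effect, so it is intrinsic to the procedure,
  not an artifact of this implementation. Practically: a clearly positive
  score association (the method's intended use) cannot be manufactured by
  this bias, but an apparent *inverse* association of a weak score should
  be interpreted with caution, and null-score confidence intervals cover 1
  less often than nominally.
- The PC skeleton's output depends on the feature order (documented,
  fixed to input order); no CPDAG orientation or latent-variable variant
  is attempted, since only the skeleton feeds clustering.
- Elastic-net selection uses unconditional logistic loss on deviations;
  with very small strata counts the centering approximation degrades.
- The conditional-logistic core targets strata of size 2-4; exact
  enumeration-based inference for large strata is out of scope.
- Exchangeable blocks make cluster recovery easier than real lipid-class
  topology would; the network tests with planted DAGs partially
  compensate but do not close that gap.
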