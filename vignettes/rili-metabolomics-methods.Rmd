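---
title: "Methods: metabolomic screening and dose triage for radiation-induced lung injury"
author: "riliMetab maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolomic screening and dose triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riliMetab)
```

## The problem this package addresses

Radiation-induced lung injury (RILI) after whole-thorax irradiation (WTI)
perturbs the metabolome of both the injured tissue and circulating plasma.
A minimally invasive way to grade injury severity is to select a small
panel of plasma metabolites whose behaviour mirrors lung tissue, and to
classify an animal's dose group from that panel. `riliMetab` implements
the complete analysis chain for this design: quality control and
normalization of LC-MS peak-area tables, univariate differential
screening, cross-tissue marker-panel selection by PLS-DA variable
importance, dose-group triage with an OSC-corrected Gaussian kernel PLS
classifier, metabolite correlation networks, and carnitine
palmitoyltransferase (CPT1/CPT2) surrogate activity ratios derived from
acylcarnitine channels.

Because no public LC-MS dataset accompanies this design, the package
ships a synthetic-cohort generator that reproduces the statistical
structure the analysis assumes. All package guarantees are therefore
statements about data with that structure; see "What the simulations do
and do not show" below.

## Data model

The central container is the S4 class `SampleTable`: a samples ×
metabolites matrix of nonnegative peak areas or normalized intensities
with per-sample metadata (animal, tissue, dose in Gy, day, study/QC role,
tissue weight) and per-metabolite metadata (name, chemical class, acyl
chain, assigned internal-standard channel). Missing measurements are
`NA`, never zero — the missingness filter must distinguish "not detected"
from "measured as zero". All tables keep samples as rows; every function
in the package assumes this single orientation.

## The synthetic cohort generator

`simulateCohort()` draws log-normal peak areas

$$\log x_{amt} = \mu_m + u_a + d_m\, A_m\, \sigma\, f_{s_m}(\text{dose}/\text{dose}_{max}) \,\mathbf{1}[t \ge o_m] + \varepsilon_{amt},$$

with metabolite baseline $\mu_m$, animal random effect $u_a \sim N(0,
\tau^2)$ shared across tissues and days, residual noise $\varepsilon \sim
N(0, \sigma^2)$, signed amplitude $A_m$ in units of $\sigma$, dose-shape
$f$ (linear, square-root saturating, or high-dose-only) and onset day
$o_m$. Abundances are exponentiated, multiplied by a small per-sample
injection factor shared with the internal-standard channels (so IS
normalization is exercised non-trivially), and lung areas additionally
scale with tissue weight. QC injections are drawn around the pooled study
mean with a configurable analytical CV, and missing cells are planted
completely at random among study samples only.

Defaults (`simConfig()`) encode the study design the pipeline targets and
are held fixed rather than treated as tuning knobs:

* doses 0/10/20/35 Gy with 11/10/9/9 animals — the terminal cohort size
  of the design being emulated;
* plasma at days 1/2/3/5, lung at day 5 only;
* 67 metabolites, 7 of which carry planted effects of amplitude 3
  residual-SD — i.e. 7 markers among 60 decoys;
* residual log-SD 0.3, a typical biological+analytical spread for
  normalized LC-MS intensities; animal random effect 0.1 (a third of the
  residual scale, enough to induce realistic within-animal correlation
  without dominating);
* six QC injections at 10% CV and 5% missingness, matching ordinary
  pseudotargeted practice.

The planted-effect library (`defaultEffectLibrary()`) encodes the
qualitative injury signatures reported for WTI: long-chain acylcarnitines
(C20:1, C16:0, ...) rise from day 1 and stay up (square-root saturating
shape), free carnitine falls, short-chain AC5:0 falls only in the
high-dose group, branched-chain amino acids fall from day 3,
taurine-conjugated bile acids fall late (day 5), and urea falls from day
1. The six channels of the CPT surrogate ratios are always present in the
universe so the ratio module works on every cohort. Amplitudes are free
parameters of the simulator, not estimates from animal data: the
literature reports directions and onsets, not effect sizes.

**What the simulations do and do not show.** The generator reproduces
dose- and time-structured class separation, animal random effects,
analytical QC noise, IS-channel structure and MCAR missingness. It does
not model retention-time drift, batch effects, intensity-dependent
missingness, correlated metabolite modules (except what the animal effect
induces), or heavy-tailed contamination. A pipeline property demonstrated
here is evidence of correct implementation and of statistical behaviour
under the assumed model — not a claim about any specific animal cohort.

## Preprocessing and quality control

`normalizeTable()` divides every metabolite by its assigned
internal-standard channel (plasma) and additionally by tissue weight in
mg (lung). IS columns are removed afterwards; QC samples carry no weight
and are IS-normalized only. `qcFilter()` keeps metabolites with a
missing-value fraction strictly below 20% of study samples and a QC
relative standard deviation strictly below 30% (sample SD over QC
injections divided by their mean; the n−1 denominator is conventional for
the small QC counts involved). A metabolite failing both rules is counted
once, under missingness. The missingness denominator uses study samples
only; QC injections gauge analytical, not biological, dropout.

`qcSummary()` reports the fraction of metabolites with QC RSD below
10/20/30% and operationalizes the score-plot band check: a PCA is fitted
on unit-variance-scaled study+QC samples and each QC sample is flagged if
its first-component score lies within two standard deviations of the QC
scores' mean. A concrete rule is needed here because "QCs within 2 SD" is
usually shown, not defined; the first component carries the dominant
analytical drift that the check is meant to catch.

No imputation is performed anywhere in the univariate path; missing
values are excluded pairwise. Multivariate models (PCA/PLS/KPLS) cannot
skip cells, so they mean-impute internally and flag the fact in the
fitted model.

## Differential screening

Three tests are provided. The Wilcoxon signed-rank test
(`wilcoxonSignedRank()`) drops zero differences, midranks ties, and uses
the exact sign-enumeration null (computed by convolution over doubled
midranks) for up to 25 retained pairs, switching to a tie-corrected
normal approximation with continuity correction beyond. The Mann-Whitney
U test is exact (via the rank-sum counting distribution) for tie-free
samples of total size ≤ 20. One-way fixed-effects ANOVA covers the
four-dose lung design.

The default contrasts deserve a note: a paired signed-rank test is
sometimes quoted for control-versus-irradiated comparisons, but control
and irradiated animals are distinct individuals, so the package defaults
to the independent-sample Mann-Whitney test for between-group plasma
screens (control versus all irradiated animals pooled, per day) and
ANOVA across the four dose groups for lung. The paired test remains
available for genuine within-animal day-versus-day contrasts. Both
plasma conventions (control versus pooled, control versus each dose) are
expressible through the `design` argument.

Benjamini-Hochberg adjustment is applied within one contrast — one BH
family per call, never pooled across days, because per-day discovery
counts are the quantity of interest. A metabolite is significant iff
p < 0.05 and BH q < 0.2 (both configurable). Fold changes are arithmetic
group-mean ratios on the normalized scale, log2-transformed.

`heatmapZones()` clusters the per-dose log2 fold-change rows of the
significant metabolites (Euclidean distance, average linkage) and cuts
the tree into three zones labelled in dendrogram order — the
up-regulated / high-dose-only / down-regulated zoning used to summarize
lung responses.

## The chemometric engine

`fitPLS()` is NIPALS PLS2 with X and Y deflation. Initialization is
deterministic; for multivariate responses the inner loop starts at the
exact fixed point of the two-block relation (the dominant eigenvector of
$Y'XX'Y$), which makes convergence effectively immediate even when the
top eigenvalues are nearly tied — a situation that arises routinely when
permuted or null responses are fitted. A response numerically orthogonal
to X is accepted as a zero-variance component rather than amplified from
rounding noise. Unit-variance scaling is the default (the convention of
the SIMCA lineage of software this analysis style comes from); Pareto and
centering-only are available.

Variable importance in projection follows the standard cumulative
definition
$$\mathrm{VIP}_j = \sqrt{p \sum_a SSY_a (w_{ja}/\lVert w_a\rVert)^2 / \sum_a SSY_a},
\qquad SSY_a = \lVert q_a \rVert^2\, t_a't_a,$$
so that the mean of $\mathrm{VIP}^2$ over variables is exactly 1. This
identity is worth internalizing: VIP measures *relative* importance
within a model, and a candidate set consisting entirely of equally
informative variables will place roughly half of them below 1.

`oscFilter()` implements Wold-style orthogonal signal correction: each
component starts at the fixed point of the iteration, is orthogonalized
against the response (including an intercept column, so Pearson
correlations vanish exactly, not just inner products), re-estimated
through a PLS inner relation to a relative tolerance of 1e-6 with an
iteration cap of 500 (the fixed-point map converges linearly, so caps of
~100 are too tight when eigenvalues are close), and deflated. Two weight
vectors per component are kept: the defining weights of the iteration,
and least-squares prediction weights $w = X^{+} t_{\perp}$ used to apply
the correction to new samples. The distinction matters: the iteration
weights can overlap class-mean directions (training scores are
re-orthogonalized against Y afterwards, but a new sample's score cannot
be), and using them on held-out samples strips response-predictive
signal. The least-squares weights reproduce only the response-orthogonal
variation.

`fitKPLS()` is kernel PLS with a double-centered Gram matrix (Gaussian
$K_{ij}=\exp(-\gamma\lVert x_i-x_j\rVert^2)$ with
$\gamma = 1/\mathrm{median}$ of pairwise squared distances by default —
scale-free, no tuning table — or linear $XX'$). Components are extracted
from the exact eigen solution of the deflated two-block relation, which
is deterministic and immune to slow-convergence failures; with a linear
kernel the predictions coincide with `fitPLS()` to numerical precision,
which the test suite verifies, and new samples are predicted through the
centered cross-kernel.

`crossValidateQ2()` uses venetian-blind fold assignment (deterministic
given the seed) and defines $Q^2 = 1 - \mathrm{PRESS}/\mathrm{SSY}$ with
SSY taken about the training-fold means. Seven folds are the default.
`permutationTest()` permutes the response rows (200 times by default),
refits, and reports the empirical exceedance probability
$(1 + \#\{Q^2_{perm} \ge Q^2_{obs}\})/(n_{perm}+1)$.

## Marker-panel selection

The cascade mirrors the discovery workflow: per-day plasma screens are
unioned (`unionDifferential()`), intersected with the lung set
(`intersectTissues()`), the candidates pass a VIP > 1 screen from
2-component PLS-DA models fitted per tissue (`vipScreen()`; a candidate
survives if it passes in either tissue — configurable to `both`), their
lung/plasma levels are correlated across matched animals
(`crossTissueCorr()`), and the survivors are re-ranked by a final plasma
PLS-DA VIP, taking the top k = 7 (`selectPanel()`, ties broken
alphabetically). The correlation stage annotates rather than filters by
default (threshold |r| ≥ 0): in the workflow being reproduced no
candidate was removed at this stage, so the knob exists but does not
bind.

One behaviour discovered during validation is worth documenting. When
the differential intersection contains *only* true markers of equal
strength — exactly what a well-calibrated screen produces on the default
synthetic cohort — the VIP mean-square identity forces about half of a
homogeneous candidate set below the VIP = 1 line, and a 7-member panel
cannot be assembled from the survivors. Marker recovery is therefore
meaningful only when the candidate set is heterogeneous (true markers
diluted among weaker candidates or decoys); the package's recovery tests
run the VIP screen on the full metabolite universe — 7 planted markers
among 60 decoys — where the stage behaves as intended and the final
panel recovers at least 6 of the 7 planted markers in the large majority
of replicates.

## Dose-group triage

`triageEvaluate()` grades injury from a panel: per cross-validation fold
(leave-one-out by default, the natural choice at n ≈ 40), the training
samples are unit-variance scaled, one OSC component orthogonal to the
one-hot class indicators is removed, and a 2-component Gaussian KPLS is
fitted. The held-out sample is scaled and OSC-corrected with training
parameters only.

Class assignment defaults to the nearest class centroid by Mahalanobis
distance in the model's kernel score space, with centroids computed
through the same cross-kernel projection as the test scores (the fitted
deflation scores live in slightly skewed coordinates, so mixing the two
systems misassigns). Plain Euclidean centroids and indicator-argmax are
available. Argmax is *not* the default for a structural reason: the four
dose classes are ordered along what is essentially one latent severity
direction, and indicator regression with few components suffers the
classic masking problem — the middle classes' indicator functions are
dominated by their neighbours' — which leave-one-out kernel shrinkage
(held-out predictions pulled toward the class priors) makes dramatically
worse. In measurements on the default cohort the argmax rule drops
intermediate-class accuracy to near chance while the centroid rules do
not. This mirrors the long-standing advice around PLS-DA prediction
distances in the multiclass setting.

A parallel KPLS on the numeric dose yields a continuous dose estimate
per sample, reported alongside the class. Confusion matrices are
assembled with rows as true classes; per-class accuracy is the diagonal
over the row sum.

Expectations should be calibrated to the design: with seven markers
whose full 3-SD amplitude is only reached at the top dose, the
*adjacent* dose groups are separated by roughly 2 SD in multivariate
(Mahalanobis) distance, so even an oracle classifier misassigns an
appreciable fraction of the squeezed 10 Gy class. The acceptance script
reports exactly what the pipeline achieves under these conditions; the
qualitative pattern — later days and extreme classes classify better —
matches the triage behaviour the design anticipates.

`trajectories()` divides each irradiated group's mean by the same-day
control mean (removing time-related drift), reports the earliest
significant day per metabolite from the per-day screens, and flags
monotone ratio courses from day 2 onward (successive changes of
constant, nonzero sign; an exactly flat course is not monotone).

## Correlation networks and CPT ratios

`correlationNetwork()` computes pairwise Pearson correlations on
pairwise-complete observations within one sample stratum and connects
pairs with |r| ≥ 0.7 and two-sided p < 0.05 (t distribution, n−2 df).
The threshold applies to |r|: anti-correlated metabolite pairs are real
biology (substrate-product relations) and are kept as negative-sign
edges. Edge p-values are unadjusted by default — the convention of the
exploratory network figures this module reproduces — with BH available.
Exports target Cytoscape: SIF (`m1 pos|neg m2`, isolated nodes as bare
lines) and GraphML with r/p/sign edge attributes, via igraph.

`cptRatios()` computes, per sample, CPT1 = carnitine/(AC16:1 + AC18:0)
and CPT2 = (AC16:0 + AC18:1)/AC2. The CPT2 grouping is read with the
numerator parenthesized, paralleling CPT1 — the formula is sometimes
written without the parentheses, but the interpretation (long-chain
acylcarnitine accumulation over acetylcarnitine) requires the sum in the
numerator. Both ratios cancel any per-sample scaling, so they are
invariant to the IS normalization constant. `ratioGroupTest()` adds
medians and type-7 (linear interpolation) quartiles per dose group, a
tie-corrected Kruskal-Wallis test across groups, and pairwise
Mann-Whitney comparisons against control (star marks at 0.05/0.01/0.001)
and against the lowest irradiated dose (# at 0.05), uncorrected to match
the conventional star notation; ratios are computed on lung channels by
default since the enzyme-activity interpretation refers to the injured
tissue.

## Numerical choices collected

* NIPALS tolerance 1e-10, 500 inner iterations, exact-fixed-point
  initialization for multivariate responses; responses orthogonal to X
  short-circuit to a zero-variance component.
* OSC tolerance 1e-6, cap 500; exact orthogonality enforced by a final
  QR projection that includes an intercept; least-squares weights for
  the prediction path.
* Kernel PLS components from the exact c × c eigenproblem, sign fixed by
  the largest-magnitude loading; Gaussian γ from the median heuristic.
* Q² by venetian blinds, 7 folds, SSY about training means.
* Quartiles type 7; RSD with the n−1 SD; BH capped at 1; exact rank
  tests switch to tie/continuity-corrected normal approximations at
  n > 25 (signed-rank) and total n > 20 or ties (Mann-Whitney).
* Zero denominators (IS channels, control means, ratio denominators)
  produce errors or recorded missing values, never silent zeros.
* Panel ties broken alphabetically; all stochastic procedures consume a
  single explicit seed and are bit-reproducible.

## Problem sizes used by the test suite

Unit tests run on miniature cohorts (20 metabolites) and small random
fixtures. The pipeline-level properties use the default cohort geometry
(39 study animals, 67 metabolites): 20 replicate cohorts for marker
recovery and triage, 50 for null calibration, 20 seeds of 200-fold
permutation tests at n = 40, p = 60, and 20 replicates of the
block-correlation network recovery at n = 11. These sizes were chosen as
the smallest at which the binomial tolerances quoted in the tests are
meaningful.

## Known limitations

* The simulator's MCAR missingness understates the intensity-dependent
  dropout of real LC-MS data, so the missingness filter is exercised
  under friendlier conditions than production data would present.
* Mean imputation inside multivariate fits is simple and biased toward
  the null; with the < 20% missingness guaranteed by the upstream filter
  this is acceptable, but heavier missingness would warrant a dedicated
  imputation step, which the package deliberately does not provide.
* The triage classifier estimates its kernel width per training fold
  from the median heuristic; no kernel or component search is performed.
* Compound identification, raw spectral processing, batch correction
  and biological interpretation are out of scope; the pipeline starts
  from integrated, identified peak-area tables.
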