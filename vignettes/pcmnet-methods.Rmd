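---
title: "Models and methods in pcmnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in pcmnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pcmnet implements a complete longitudinal pharmacometabolomics workflow for
SSRI (citalopram/escitalopram) treatment studies in major depressive
disorder: a synthetic cohort generator with known ground truth, clinical
preprocessing, per-metabolite mixed-model scans, two-step time-course
regression, regularised partial-correlation networks with differential
network testing, and additive genetic association for metabolite-ratio
traits. This vignette records the models behind each stage, the defaults
and why they were chosen, and what the simulation-based tests do and do not
demonstrate about real data.

## The synthetic cohort generator

The generator is first-class, tested code: every downstream stage is
validated against cohorts whose generative truth is known exactly.

**Metabolite panel.** The packaged catalog mirrors a targeted
electrochemistry panel of 31 neurotransmitter-related plasma metabolites in
seven pathway families (tryptophan, tyrosine, phenylalanine/tyrosine
phenolic acids, purine, one-carbon/glutathione, tocopherol, other).

**Latent Gaussian graphical model.** `make_precision_matrix()` plants a
sparse positive-definite precision matrix $\Omega$ with off-diagonal
support inside community blocks. Entries get magnitude `edge_strength` with
random signs; the diagonal is rescaled to $\max(1,\ 1.1\sum_j|\omega_{ij}|)$
(diagonal dominance), which guarantees positive definiteness but also caps
the attainable partial correlations at roughly $1/(1.1\,k)$ for node degree
$k$ — a real constraint of Gaussian graphical models, not an implementation
artifact: no node can carry many strong partial correlations at once.

Two within-block topologies are provided.

* `"random"` (default): Erdős–Rényi blocks at `within_density`. Realistic
  for pathway-style connectivity, but random blocks carry chance
  substructure, and random-walk community detection legitimately resolves
  that substructure — even on the *true* graph the planted labels are then
  not the modularity optimum.
* `"crown"`: each block is a crown graph (complete bipartite between two
  halves minus a perfect matching; degree 4 in blocks of 10). Crown blocks
  are vertex-transitive with no local cliques, so the planted blocks *are*
  the modularity-optimal communities. This is the configuration used for
  community-recovery benchmarks; with `edge_strength = 0.2` the planted
  partial correlations are 0.2, comfortably identifiable at $n = 500$.

**Longitudinal structure.** Baseline latent vectors are drawn from
$N(0, \Omega^{-1})$. Follow-up visits evolve as an AR(1) on deviations from
the visit mean, $z_t = \delta_t + \rho\,(z_{t-1} - \delta_{t-1}) +
\sqrt{1-\rho^2}\,\varepsilon_t$ with $\varepsilon_t \sim N(0, \Omega^{-1})$,
so the marginal covariance is visit-invariant and the mean shift at week
$t$ equals the exposure effect $\delta_t$ exactly. The default carryover
$\rho = 0.6$ supplies the within-subject correlation that motivates
random-intercept models downstream. An optional per-subject,
per-metabolite random intercept exists but defaults to zero: a nonzero
shared intercept would add variance on top of $\Omega^{-1}$ and break the
exact correspondence between the planted precision matrix and the baseline
covariance, which the network benchmarks rely on.

**Raw abundances.** Latents map to positive raw abundances as
$2^{\mu_m + \sigma_m z}$ with defaults $\mu_m = 10$, $\sigma_m = 1$ on the
log2 scale, so the preprocessing log2 step is meaningful and "1
standardized unit" equals one log2 unit.

**Clinical trajectories.** Responder status is Bernoulli with default rate
0.693, the week-8 response rate typical of 8-week citalopram/escitalopram
cohorts of this kind. HRSD-17 scores are drawn per group and visit from
matching group means and SDs (responders
21.86 ± 5.17, 10.10 ± 5.77, 5.79 ± 3.27; nonresponders 22.03 ± 4.28,
15.03 ± 6.58, 14.90 ± 4.15), rounded to non-negative integers, with the
baseline resampled until it satisfies the $\geq 14$ inclusion rule. By
default HRSD trajectories and metabolites are conditionally independent
given group; an explicit `symptom_coupling` parameter links one
metabolite to the standardized HRSD score for testing the
symptom-association scan, because the direction of any metabolite–symptom
mechanism is an open scientific question, not something the generator
should assert.

**Differential edges.** Outcome-dependent edges are realised as two
precision matrices that differ only at the declared entries
($\omega_{ij} = -w\sqrt{\omega_{ii}\omega_{jj}}$ from the target partial
correlation $w$); responders (the low-HRSD group) receive the "low"
weights. If either matrix loses positive definiteness, the *same* ridge is
added to both diagonals, keeping every non-edge entry bit-identical
between groups.

**What the generator does not emulate:** LC–EC instrument artifacts, batch
and pooled-QC drift, non-Gaussian abundance distributions, missingness
that depends on abundance (only MCAR), linkage disequilibrium among
variants, and any causal feedback between symptoms and metabolism.
Passing tests therefore demonstrate statistical correctness of the
machinery under a clean Gaussian world, not robustness to those
real-data complications.

## Preprocessing

The pipeline order is fixed: missingness QC (drop metabolites with more
than 20% missing) → k-nearest-neighbour imputation →
log2 → unit-variance scaling.

* **kNN imputation** (default $k = 10$, a common choice at $n \approx
  300$): distances
  are Euclidean over mutually observed, per-metabolite-standardized
  columns, rescaled by the fraction of columns observed so that subjects
  sharing few observations are not spuriously close. Imputation runs per
  time point, which avoids leaking longitudinal signal into imputed
  values.
* **Scaling** uses the sample ($n-1$) standard deviation, with centering
  on by default and recorded in `transform_log`.
* **Pooled scaling across visits.** `preprocess_cohort()` log2-transforms
  and scales the three visit matrices *stacked*, not per visit. Scaling
  each visit separately would remove exactly the between-visit mean
  shifts that the exposure scan estimates. Per-visit scaling remains
  available (`pool_scaling = FALSE`).
* **Outcome labels**: response = ≥ 50% HRSD-17 reduction baseline→exit,
  remission = exit ≤ 7, complete non-response = < 30% reduction, computed
  independently.

## Longitudinal scans

Per metabolite (and per configured log2-ratio, e.g. 5HIAA/5HT — ratios are
differences of log2 abundances formed *before* unit-variance scaling, then
standardized by their pooled across-visit moments):

* **Exposure scan**: random-intercept model of the processed value on a
  time-point indicator (baseline vs week 4 or 8), adjusting for age, sex,
  and baseline HRSD-17; the indicator coefficient is the standardized
  exposure effect. Wald $z$ tests are used for fixed effects (REML fits
  via lme4); with ~290 subjects the large-sample approximation is
  adequate. Benjamini–Hochberg q-values are appended and the conventional
  cutoff is 10%.
* **Symptom scan**: value on the time-varying HRSD score + age + sex
  across all visits. The time-varying-score parameterisation is the
  default; a change-from-baseline parameterisation is available
  (`regressor = "change"`) since the wording of such analyses is often
  ambiguous between the two.
* **Two-step time course**: step 1 fits, per metabolite, ordinary least
  squares on polynomial time (degree 2, the maximum identifiable with 3
  visits), a group dummy, and group×time interactions. The *global* test
  is an F-test of the group-involving terms against the time-only model —
  the quantity of interest is profile *difference between groups*, and
  testing against the time-only null keeps the selection calibrated even
  when the drug shifts every subject's trajectory. FDR-selected
  metabolites then undergo backward elimination at $\alpha = 0.05$ with
  marginality respected (interactions leave before their main effects);
  surviving group-difference terms are reported.

## Partial-correlation networks

Edges are partial correlations
$w_{ij} = -\theta_{ij}/\sqrt{\theta_{ii}\theta_{jj}}$ of a sparse precision
estimate. The graphical lasso maximises
$\log\det\Theta - \mathrm{tr}(S\Theta) - \lambda\sum_{i\neq j}|\theta_{ij}|$
(diagonal unpenalised) by blockwise coordinate descent implemented in
RcppArmadillo, with KKT-residual stopping — per-coordinate-change stopping
can terminate early on ill-conditioned blocks — and warm starts along the
penalty path. Solutions are verified in the tests by their KKT conditions
and against direct inversion at $\lambda = 0$.

**Penalty selection.** The penalty grid is 100 log-spaced values from
$\lambda_{\max}$ (the smallest penalty giving an empty graph) down to
$0.01\,\lambda_{\max}$. EBIC is
$-2\ell(\hat\Theta) + E\log n + 4\gamma E \log p$ with $\gamma = 0.5$. By
default (`refit = TRUE`) each candidate support is scored at its
*restricted maximum likelihood* — the unpenalised Gaussian MLE constrained
to the support — as in the EBIC covariance-selection formulation. Scoring
the shrunken estimate itself (`refit = FALSE`) makes the criterion trade
$\ell_1$ shrinkage bias on true edges against the edge penalty and
systematically over-selects: in our planted-structure experiments edge
precision saturated near 0.86 under every configuration, versus ~0.94 with
restricted-MLE scoring at equal recall. With `refit = TRUE` the reported
edge weights are likewise the restricted-MLE partial correlations
("relaxed" graphical lasso); besides being less biased, this matters for
community detection — unevenly shrunken weights distort weighted random
walks even when the support is recovered perfectly. Ties in EBIC break
toward the larger penalty.

**Bootstrap.** Subjects are resampled with replacement (reference
workflow: 1000 resamples); the penalty is re-selected per resample by
default (more conservative; a flag fixes it). Edges are summarised by
median weight and inclusion frequency. Degenerate resamples (zero-variance
column) are redrawn and counted.

**Communities.** Walktrap on absolute edge weights, random-walk length 4,
partition cut at maximal modularity (igraph). An empty graph yields
singletons with modularity 0. Negative-weight community handling is out of
scope; absolute weights are the similarity.

**Differential networks.** Subjects are split at the outcome median (ties
to the low group; the week-8 HRSD-17 score is the intended outcome — a
binary outcome whose majority class sits above the median cannot be
split). Group networks are estimated independently; the structure
statistic is $M=\max_{ij}|w^{(1)}_{ij}-w^{(2)}_{ij}|$ and global strength
$S=\left|\sum|w^{(1)}| - \sum|w^{(2)}|\right|$ over the upper triangle.
The null distribution shuffles group labels and re-estimates *both*
networks per permutation; p-values use the add-one convention
$(1+\#\{\text{null}\geq\text{obs}\})/(1+n_{\text{perm}})$, so they are
never zero. Per-edge p-values come from the same permutations over the
family of edges present in either observed network and are Holm-adjusted.
Note the arithmetic floor: with $n_{\text{perm}}$ permutations and a
family of $E$ edges the smallest attainable adjusted p-value is
$E/(1+n_{\text{perm}})$ — detecting an edge at adjusted $p<0.05$ in a
15-edge family needs $n_{\text{perm}} \gtrsim 300$, so power analyses here
use 500 permutations. Paired (same-cohort, two-visit) comparison is
unsupported: only independent-group permutation is implemented.

Optionally the standardized outcome enters the matrix as an additional
node before estimation, following the practice of including the severity
score in the network model for differential analyses. Edges flagged as
differential can be validated by `validate_interaction()`, a least-squares
fit of one metabolite on the other, the outcome, and their product.

## Genetic association

Variant QC drops variants with call rate below 95% (the "call rate < 5%"
phrasing common in methods sections is read as missingness > 5%; the
literal reading would be vacuous), minor allele frequency below 5%, or
exact HWE $p < 10^{-5}$. The HWE test is the standard exact test
conditional on allele counts, summing probabilities of all heterozygote
counts no more probable than the observed one (log-factorial arithmetic,
validated exhaustively against an independent ratio-recurrence oracle for
all totals up to 200). Population structure is captured by the first five
principal components of the standardized, mean-imputed dosage matrix. Ratio
traits (e.g. HGA/GR, MET/TYR) are differences of log2 abundances,
standardized, with re-standardization after excluding subjects beyond 4
SDs. The scan is per-variant least squares of the trait on dosage plus
covariates (age, sex as 0/1, PCs, optionally the HRSD score), dropping
subjects with missing dosage per variant; calibration is monitored by the
genomic inflation factor.

## Numerical choices and degenerate inputs

* Coordinate-descent tolerances: outer $10^{-7}$ on the working
  covariance, inner KKT residual at a tenth of that; non-convergence is an
  error carrying a duality-gap proxy.
* Exact zeros: soft-thresholding produces exact structural zeros, so edge
  counts need no threshold beyond $10^{-8}$ guard digits.
* Constant columns are errors (named) in scaling and correlation; constant
  dosages yield per-variant NA rows; a constant outcome disables the
  interaction term with a warning; constant HRSD disables the symptom scan
  with NA results and a warning.
* A zero-variance outcome in the mixed model short-circuits to the exact
  degenerate answer (zero estimates and variance components) rather than
  passing lme4 an ill-posed problem.

## Problem sizes used by the packaged checks

The test suite and `scripts/acceptance.R` run entirely on generated data
at sizes chosen to finish in minutes while keeping every check
well-powered: support/community recovery at $p = 20$, $n = 500$ over 20
(tests) or 5 (script) seeds; differential-network calibration at $n = 300$
with 200 permutations over 100 (tests) or 20 (script) replicates and power
at $n = 600$ with 500 permutations; mixed-model scans on the full
31-metabolite panel at $n = 290$; genetics at $n = 500$ with up to 2000
variants. Permutation loops use a 20-point penalty grid (the EBIC optimum
is insensitive to grid density at these sizes); single-network analyses
use the full 100-point grid.

## Known limitations

* Gaussian-only network model; no mixed graphical models for categorical
  nodes.
* Independent-group permutation only; no paired two-visit network test.
* The diagonal-dominance construction bounds planted partial correlations
  by node degree, so very dense strong blocks cannot be simulated — that
  bound is intrinsic to positive-definite precision matrices.
* The two-step time-course reimplements the global-fit + stepwise logic
  generically; it is not a port of any specific package's internals.
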