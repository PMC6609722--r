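# pcmnet

Longitudinal pharmacometabolomics of antidepressant response: partial
correlation networks, mixed-model metabolite scans, and metabolite-ratio
genetics, with a fully specified synthetic cohort generator.

## The problem

In pharmacometabolomics studies of SSRI treatment (citalopram /
escitalopram) for major depressive disorder, a targeted panel of ~31
neurotransmitter-related plasma metabolites is measured at baseline and
after 4 and 8 weeks of treatment, alongside HRSD-17 symptom scores.
Three questions drive the analysis:

1. **Exposure** — which metabolites shift under drug treatment?
   Per-metabolite linear mixed models with subject random intercepts,
   `value ~ week + age + sex + baseline HRSD + (1 | subject)`,
   with Benjamini–Hochberg FDR control at 10%, plus a two-step
   time-course regression (global group-difference F-test, then backward
   stepwise) separating responder and nonresponder profiles.
2. **Interaction structure** — how do metabolites relate conditionally on
   one another? Gaussian graphical models estimated by the graphical
   lasso, with the penalty chosen by the Extended Bayesian Information
   Criterion (EBIC, γ = 0.5), edge weights being partial correlations
   `w_ij = -θ_ij / sqrt(θ_ii θ_jj)`, bootstrap-aggregated over subject
   resamples, and clustered by walktrap community detection. Whether the
   network *differs* with clinical outcome is tested by a permutation
   test on median-split (high vs low HRSD-17) group networks, using the
   maximum edge difference (structure) and total absolute edge weight
   (global strength) statistics.
3. **Genetic modulation** — are ratios of interacting metabolite pairs
   (e.g. HGA/GR, MET/TYR) genetically influenced? Variant QC (call rate,
   MAF, exact Hardy–Weinberg test), genotype principal components, and
   per-variant additive least-squares scans of standardized log-ratio
   traits adjusting for age, sex and PCs 1–5.

Because patient-level data from such studies are not public, the package
ships a first-class synthetic cohort generator
(`make_precision_matrix()`, `simulate_cohort()`, `simulate_genotypes()`)
that emulates the statistical structure of such trials — planted precision
matrices with community blocks, AR(1) within-subject carryover,
responder/nonresponder HRSD-17 mixtures, MCAR missingness,
outcome-dependent differential edges, causal variants — so every stage is
testable end to end with known ground truth.

## Worked example

```r
library(pcmnet)

gt <- make_precision_matrix(p = 31, within_density = 0.4,
                            edge_strength = 0.3, seed = 1)
gt$exposure_effects[match("5HT", metabolite_panel()$metabolite_id),
                    "week8"] <- -1          # plant a serotonin depletion
cohort <- simulate_cohort(290, gt, seed = 1)
cohort <- inject_missing(cohort, rate = 0.05, seed = 2)

pp <- preprocess_cohort(cohort)              # QC -> kNN -> log2 -> scale
scan <- exposure_scan(pp$processed, pp$clinical, week = 8)
head(scan[order(scan$q_value), ], 3)
#>    feature_id effect     se  p_value  q_value
#> 6         5HT -0.891 0.0634 7.20e-45 2.74e-43
#> 32  5HIAA/5HT  0.810 0.0619 4.04e-39 7.67e-38
#> 29      ATOCO  0.168 0.0666 1.15e-02 1.46e-01
```

The planted −1 sd serotonin drop is recovered as the top hit
(−0.89 ± 0.06 standardized units, q ≈ 3e−43), and the serotonin turnover
ratio 5HIAA/5HT rises correspondingly; the next-best metabolite does not
clear the 10% FDR cutoff.

```r
net <- ebic_select(pp$processed$t8)          # EBIC-selected network
sum(net$weights[upper.tri(net$weights)] != 0)
#> [1] 26
part <- walktrap_communities(net)
cmp <- compare_networks(pp$processed$t8, pp$clinical$hrsd_t8,
                        n_perm = 200, seed = 3, nlambda = 20)
cmp$p_structure
#> [1] 0.483
```

With no differential edge planted, the structure-invariance permutation
test is appropriately non-significant (M = 0.378, p = 0.48).

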