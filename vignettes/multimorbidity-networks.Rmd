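---
title: "Multimorbidity networks and hospitalisation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimorbidity networks and hospitalisation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mmnet` implements a complete analysis pipeline for studying how patterns of
chronic-disease co-occurrence (multimorbidity) relate to hospitalisation in
population-based ageing cohorts: survey-weighted regression of
hospitalisation outcomes under two multimorbidity definitions, and Ising
disease-network estimation with community detection, predictability,
centrality, and bootstrap stability, stratified by sex and age band. Because
the microdata such analyses run on are typically access-restricted, the
package ships a synthetic-cohort generator with a fully known ground truth,
so every stage can be validated by parameter-recovery experiments.

## The binary Ising model

All disease indicators are binary, so the joint distribution over the 19
conditions (plus hospitalisation as a 20th node during network analysis) is
modelled as an Ising model on the \{0,1\} domain:

$$P(x) \propto \exp\Big(\sum_i \tau_i x_i + \sum_{i<j} w_{ij} x_i x_j\Big),
\qquad x \in \{0,1\}^p .$$

The \{0,1\} domain (rather than ±1) is used everywhere — sampler, estimator,
predictability — because its full conditionals are exactly the logistic
regressions the estimator fits:
$P(x_i = 1 \mid x_{-i}) = \mathrm{logistic}(\tau_i + \sum_j w_{ij} x_j)$.
An edge $w_{ij} \ne 0$ encodes conditional dependence given all other
conditions; the weight is a log-odds interaction.

Two samplers realise the model. `sample_ising_exact()` enumerates all $2^p$
states (practical to $p = 16$) and draws i.i.d. samples — it is the reference
implementation. `sample_ising_gibbs()` is a single-site Gibbs sampler
(C++ core) that scales to the 19-condition graphs; its defaults
(`burn_in = 1000` sweeps, `thin = 10`) were chosen so that for $p \le 8$ the
empirical distribution of $10^5$ draws stays within total-variation distance
0.02 of the enumerated one, which the test suite verifies.

## Network estimation: eLASSO

The network estimator is nodewise $\ell_1$-penalised logistic regression with
extended-BIC model selection (eLASSO). For each node $i$, the package solves

$$\min_{\beta_0, \beta}\; -\tfrac{1}{n}\,\ell(\beta_0, \beta)
  + \lambda \lVert\beta\rVert_1$$

over a grid of 100 log-spaced $\lambda$ values from $\lambda_{\max}$ (the
smallest $\lambda$ with an all-zero solution, computed from the data) down to
$0.01\,\lambda_{\max}$, by iteratively reweighted least squares with cyclic
coordinate descent (C++, warm starts, sequential strong-rule screening with
KKT verification). Each grid point is scored with

$$\mathrm{EBIC}_\gamma(\lambda) = -2\ell + k \log n + 2\gamma\, k \log(p-1),$$

with $k$ the number of non-zero coefficients (intercept excluded) and
$\gamma = 0.25$ the default sparsity hyperparameter. The selected model
minimises EBIC on the grid. Numerical settings: convergence tolerance
`1e-6` on coefficient changes (at the fixed point this bounds the KKT
residual well below `1e-5`, which the tests assert), coefficients capped at
±15 to keep separated strata finite, IRLS weights floored at `1e-5`.

Nodewise fits are symmetrised by the AND rule (edge kept only when both
directed coefficients are non-zero) with the weight set to the mean of the
two directed coefficients; an OR rule is selectable. AND-plus-averaging is
the established eLASSO convention; the choice matters mainly for borderline
edges, and the bundled-scenario tests show the practical consequence — a
weak true edge (e.g. the respiratory pair among women) can drop out of one
stratum's network while remaining in others.

Selection on the penalised path is *not* identical to an exhaustive
maximum-likelihood EBIC search: shrinkage occasionally lets one weak extra
predictor in where the refit search would not. On four-node toys with one
strong pair ($n = 2000$) the two agree in just over 95% of nodewise
selections, which the acceptance suite checks against a brute-force
all-subsets oracle.

Stratified estimation drops constant nodes (a rare disease can have zero
cases in the oldest band) with a recorded reason, and skips strata below
`min_n = 200` — stratified binary data degenerate silently otherwise.

## Communities, predictability, centrality

Community detection uses the Walktrap algorithm with walk length $t = 4$
(the algorithm's customary default; configurable), run on **absolute** edge
weights, since random-walk transition probabilities must be nonnegative.
The sign of an edge therefore does not influence community structure — a
documented limitation. Isolated nodes become singletons; multi-component
graphs are handled per component; the final cut maximises weighted
modularity. On all small fixtures the chosen partition is verified against
exhaustive modularity maximisation over every set partition.

Community stability follows the bootstrap protocol: re-estimate the network
on `n_boot = 100` row resamples, re-run Walktrap, align each bootstrap
partition to the original by maximum-overlap label matching (solved exactly
by permutation enumeration up to 8 labels, greedily beyond), and summarise
per-node membership. "Median community" is ambiguous for nominal labels, so
the consensus is the per-node **modal** aligned label — with the median over
aligned integer labels reported alongside — and modal ties are broken by a
seeded uniform draw. A partition is flagged unstable when the original
network has no community signal (modularity < 0.05, or an all-singleton /
single-community partition) or when mean per-node agreement with the
consensus falls below 0.8. Sorted eigenvalues of each bootstrap network's
modularity matrix are retained as an additional diagnostic; no pass/fail
rule is imposed on them.

Node predictability (CC, correct classification) is the in-sample
proportion of observations of a node correctly predicted by thresholding
its conditional probability at 0.5, reported next to the trivial benchmark
$\max(\hat p, 1 - \hat p)$; held-out evaluation is available through the
`newdata` argument when in-sample optimism is a concern.
Centralities are computed on absolute weights: strength
$\sum_j |w_{ij}|$; closeness and betweenness with edge lengths $1/|w|$,
closeness using the reachable-set convention
$(n_\mathrm{reach}-1)/\sum d$ (0 for isolates) so that disconnected
stratified networks stay well-defined; and the participation coefficient
$P_i = 1 - \sum_s (\kappa_{is}/\kappa_i)^2$ over the supplied partition.

## Stability suite

Edge accuracy uses the nonparametric bootstrap (`B = 500` resamples by
default) with 2.5%/97.5% quantile intervals per edge, and edge-magnitude
difference tests that declare two edges distinguishable when the bootstrap
interval of their difference excludes zero. Centrality stability uses
case-dropping subset bootstraps over retained proportions 0.9…0.3 (step
0.1) plus 0.25, `B` subsamples per proportion (a total-budget flag divides
`B` across proportions instead, since reports differ in which convention
they mean). The CS-coefficient of a measure is the largest case-drop
proportion at which the Spearman correlation with the original centrality
stays ≥ 0.7 in ≥ 95% of subsamples, at every smaller drop as well; Spearman
is used because the standard CS definition is rank-based. The grid caps
what can be observed, so results are reported with below/above-bound flags
(CS ≥ 0.75 at the top, < the smallest tested drop at the bottom). Up to 10%
of replicate estimations may fail (degenerate resamples) before a hard
error.

## The synthetic cohort

The generator emulates the *structure* of a large ageing-survey dataset —
it does not reproduce any real population. Its frozen default scenario
(`elsi_like_truth()`):

* **Dependence graph.** Five clinically coherent planted groups
  (cardiovascular–cancer–eye, musculoskeletal–depression–renal, diabetes
  complications, respiratory, neurodegenerative) with within-group
  couplings 0.35–1.1 and a few weak bridges.
* **Prevalences.** Base thresholds were calibrated once, by damped
  stochastic approximation on the logit scale
  (`calibrate_thresholds()`, seed 20260929, 30 iterations at $n=30{,}000$),
  so mixed-population marginals match realistic targets: hypertension 52%
  overall (≈56% female / 48% male via the sex shift), back problems 41%,
  down to Parkinson's/Alzheimer's at 1.5%. Age-band shifts of −0.4/+0.55
  logits (stronger for neurodegenerative conditions) make prevalence rise
  with age.
* **Strata.** The sex × age mix matches the published complete-case margins
  (female .563; age bands .429/.412/.160).
* **Outcomes.** Hospitalisation is Bernoulli with logit linear in the
  disease indicators (largest effects, +0.5, for the cardiovascular group),
  male (+0.2) and age 75+ (+0.25), intercept set for ≈10% prevalence.
  Readmissions are 1 + Poisson (the count includes the index admission by
  default, hence ≥ 1 when hospitalised; a flag switches convention, since
  survey wording rarely settles this). Length of stay is Gamma (shape 1.5)
  with log-link mean ≈4.3 days for women and a +0.55 log effect for men —
  any positive right-skewed family would serve; Gamma composes naturally
  with the log link.
* **Weights and missingness.** Survey weights are lognormal with mean 1
  (σ = 0.5). Whole disease/outcome blocks go missing MAR with logit
  depending only on the always-observed sex and age band (+0.9 logits at
  75+), intercept solved so that a 9,412-person cohort keeps ≈8,807
  complete cases.

What the generator does **not** emulate: multistage cluster sampling and
design-based weights (weights here are i.i.d. noise), informative
missingness beyond sex/age, measurement error in self-report, and
time-ordering of diagnoses. Passing recovery tests therefore demonstrates
internal validity of the estimators under MAR and the Ising model, not
robustness to those real-data features.

## Preprocessing and regression choices

Complete-case analysis with inverse-probability weighting: completeness is
modelled by logistic regression on sex + age band — the minimal set of
always-observed covariates, hence the minimal MAR-consistent model (the
choice is configurable; nothing in the method fixes it). Combined weights
(survey / completeness probability) are normalised to unit mean over
complete cases, which leaves prevalence ratios and regression coefficients
invariant while keeping effective sample sizes honest in variance
estimates.

Hospitalisation models are log-link Poisson working models for the binary
outcome — the standard prevalence-ratio device — with the robust sandwich
variance $B^{-1} M B^{-1}$, which is mandatory because the Poisson variance
is deliberately misspecified for Bernoulli data. Readmission and length of
stay (among hospitalised persons only) use weighted least squares with HC1
standard errors by default (classical available; readmissions can also be
fit as Poisson behind a flag, but the linear model is the default to match
common reporting practice). All intervals are normal-based ±1.96 SE; no
degrees-of-freedom correction is applied since none is standard for these
survey-weighted point estimates. The model grid mirrors the usual reporting
layout: sex + age band jointly, then age band within each sex, for the MM2
(≥2 conditions) and MM3 (≥3) subsets; a person with exactly two conditions
is MM2 but not MM3, so MM3 ⊂ MM2.

## Reproducibility and problem sizes

Every stochastic function takes a `seed` argument, uses an isolated RNG
state (the caller's stream is untouched), and derives per-replicate
sub-streams, so ensembles are reproducible replicate-by-replicate. The
pipeline writes a manifest with per-artifact MD5 checksums; rerunning a
configuration reproduces the manifest byte-for-byte.

The test suite exercises every property at deliberately modest sizes chosen
by us as the smallest that still separate signal from noise: TV comparisons
at $p \le 8$ with $10^5$ Gibbs draws; eLASSO-versus-oracle agreement on
$p=4$ toys at $n=2000$ over 100 replicates; edge recovery on a planted
$p=10$ graph ($|w| \in [0.8, 1.5]$, $n = 2000$, 20 replicates); difference-
test size at $p=3$, $n=500$ with $B=200$ over 200 outer replicates; null
coverage of the sandwich CI over 1000 replicates at $n=400$; IPW bias over
200 replicates at $n=4000$; and the full scenario at $n = 9412$ with
reduced bootstrap budgets for the determinism check. Tie-breaking is fixed
throughout (lowest-index merges in igraph's Walktrap; seeded uniform draws
for modal ties) so identical inputs give identical outputs.

## Known limitations

* Community detection ignores edge signs (absolute weights).
* CC is in-sample by default and optimistic for weak nodes.
* EBIC-path selection is slightly denser than exhaustive refit selection
  (~5% of nodewise fits on the toy designs).
* The case-dropping CS grid cannot distinguish stability beyond 0.75 drop.
* Networks across strata are compared qualitatively; no formal network
  comparison test is included.
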