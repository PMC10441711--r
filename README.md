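# mmnet — multimorbidity networks and hospitalisation in ageing cohorts

`mmnet` is an R package for epidemiologists and network scientists studying
how co-occurring chronic conditions (multimorbidity) relate to
hospitalisation in population-based surveys of adults aged 50+. It provides
the full analysis chain used in such studies:

* **Survey-weighted outcome models.** Prevalence ratios for hospitalisation
  from log-link Poisson working models with robust (sandwich) variance, and
  weighted linear models (HC1 errors) for readmission count and length of
  stay among hospitalised persons — fitted per multimorbidity subset
  (MM2: ≥2 of 19 conditions; MM3: ≥3) for sex + age band jointly and for
  age band within each sex.
* **Disease networks.** The joint distribution of the 19 binary conditions
  plus hospitalisation is modelled as a \{0,1\} Ising model,
  `P(x) ∝ exp(Σ τ_i x_i + Σ w_ij x_i x_j)`, estimated per stratum (female,
  male, 50–59, 60–74, 75+) by eLASSO: nodewise L1-penalised logistic
  regression (coordinate descent in C++) with extended-BIC selection,
  `EBIC_γ = −2ℓ + k log n + 2γ k log(p−1)`, γ = 0.25, AND-rule
  symmetrisation.
* **Structure and stability.** Walktrap community detection with
  maximum-modularity cut; bootstrap community stability (100 resamples,
  aligned labels, modal consensus, agreement rates); node predictability
  (correct classification) and centralities (strength, closeness,
  betweenness, participation coefficient); nonparametric edge bootstraps
  with difference tests; case-dropping CS-coefficients (Spearman ≥ 0.7 in
  ≥ 95% of subsamples).
* **A synthetic cohort generator** with known ground truth — planted
  five-group comorbidity graph, calibrated prevalences, survey weights,
  MAR missingness handled by inverse-probability weighting — emulating the
  structure of restricted ageing-survey microdata so the whole pipeline is
  testable offline.

## Worked example

```r
library(mmnet)

truth <- elsi_like_truth()                      # frozen default scenario
full  <- apply_missingness(generate_cohort(truth, 9412, seed = 2024),
                           truth$missing_model, seed = 2025)
cc    <- classify_mm(fit_ipw_weights(full))     # IPW + MM2/MM3 flags
nrow(cc); sum(cc$mm2); sum(cc$mm3)
#> 8815   6521   4550

reg <- run_regression_suite(cc)
subset(reg, subset == "mm2" & stratum == "all" & outcome == "hospitalised")
#>   term      level  estimate ci_low ci_high
#>   sex       female     1.00     NA      NA
#>   sex       male       1.31   1.11    1.54
#>   age_group 50-59      1.00     NA      NA
#>   age_group 60-74      1.23   1.01    1.50
#>   age_group 75+        2.03   1.65    2.50
```

Of 9,412 generated persons, 8,815 are complete cases; among those with ≥2
conditions, men hospitalise 1.31× as often as women (95% CI 1.11–1.54) and
the 75+ band 2.03× the 50-somethings — the generator plants positive male
and old-age effects, and the weighted Poisson model recovers them.

```r
female <- stratify(cc, "sex")$female
net    <- estimate_ising_network(network_matrix(female))
net
#> Ising network: 20 nodes, 19 edges (AND rule, gamma = 0.25, n = 5012)

part <- walktrap_communities(net)
name_communities(part)[1:4]
#> "arthritis_rheumatism–back_problems–depression–osteoporosis–renal_failure"
#> "diabetes–diabetic_retinopathy"
#> "haemorrhagic_stroke–heart_problems–high_cholesterol–hypertension"
#> "cataract–glaucoma"

head(node_metrics(network_matrix(female), net, part)[
  order(-node_metrics(network_matrix(female), net, part)$strength), ], 3)
#>             node   cc cc_baseline strength closeness betweenness participation
#>   heart_problems 0.86        0.86      2.5      0.17          11          0.29
#>     hypertension 0.62        0.54      2.3      0.18          36          0.52
#> arthritis_rheum. 0.70        0.68      1.9      0.13           6          0.23
```

The detected communities reproduce the planted clinical groups
(musculoskeletal–depression–renal, diabetes complications, cardiovascular,
eye diseases); hypertension has high strength and the highest participation
— it bridges groups — while rare conditions sit as singletons. `cc` vs
`cc_baseline` shows how much a node's neighbours add over always guessing
its majority class.

The end-to-end runner writes all artifacts (regression tables, GraphML/JSON
networks, stability summaries, a Markdown report, and a checksummed
manifest):

```r
cfg <- run_config("out/", scenario = "elsi-like", seed = 1L)
run_pipeline(cfg)
```

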