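# rpqnet

Symptom network analysis for Rivermead Post-Concussion Symptoms
Questionnaire (RPQ) cohorts.

After mild traumatic brain injury (mTBI), patients report overlapping
somatic, cognitive, emotional and sleep symptoms on the 16-item RPQ.
`rpqnet` treats the symptoms as nodes of a Gaussian graphical model whose
edges are partial correlations — the association between two symptoms
conditional on all the others — and provides the full analysis pipeline
used in psychometric network studies of such cohorts:

* **Preprocessing** — the RPQ recode (0,1,2,3,4) → (0,0,1,2,3), the
  emotional/cognitive/visual composite nodes, the five regression
  factors, and GCS-13–15 / complete-assessment cohort filtering with a
  CONSORT-style tally.
* **Network estimation** — graphical lasso
  (max log det Θ − tr(SΘ) − λΣ|θᵢⱼ|, off-diagonals penalized) over a
  100-point log-spaced λ path with extended-BIC model selection at
  γ = 0.5 (EBIC = −2ℓ(Θ̂) + E log n + 4Eγ log p); candidate supports are
  scored by the EBIC of their constrained unpenalized refit. Compiled
  core, cross-checked in the tests against an independent ADMM solver of
  the same objective.
* **Centrality** — expected influence EIᵢ = Σⱼ wᵢⱼ (signed) and strength
  Σⱼ |wᵢⱼ|, raw and z-standardized, with the conventional z > 1
  "notable" flag.
* **Network comparison** — permutation test of structure invariance
  (M = max |Δwᵢⱼ|) and global strength, paired (within-subject swap) or
  independent schemes, add-one p-values, Holm-adjusted edge-wise
  post-hoc tests.
* **Stability** — case-dropping bootstrap and the correlation-stability
  (CS) coefficient: the largest drop proportion at which ≥ 95% of
  replicates keep r ≥ 0.7 with the full-sample centrality.
* **Outcome models** — adjusted logistic (incomplete recovery,
  GOSE < 8) and linear (QOLIBRI-OS, SF-12 PCS/MCS) regressions of
  two-week symptom factors, with age, sex, education, prior TBI,
  psychiatric history and CT status as covariates.
* **Synthetic cohorts** — a Gaussian-copula generator with a known
  sparse item-level partial-correlation structure (three tight clusters
  with weights in [0.29, 0.46]), ordinal thresholds, correlated
  timepoints and known outcome coefficients, so that every stage of the
  pipeline can be validated against ground truth.

## Worked example

```r
library(rpqnet)

truth  <- make_true_network(seed = 2026)      # known ground truth
cohort <- recode_cohort(simulate_cohort(truth, 800, seed = 11))

nodes <- build_network_nodes(cohort, "W2")
net   <- select_network(nodes)
net
#> Partial-correlation network (10 nodes, 5 edges)
#>   n = 800, lambda = 0.1296 (EBIC 7853.59, gamma = 0.5), pearson input
#>   |edge weights| in [0.005, 0.142]

ct <- expected_influence(net)
head(ct[order(-ct$z_ei), c("node", "ei", "z_ei", "notable")], 3)
#>        node    ei  z_ei notable
#> 2 cognitive 0.278 1.995    TRUE
#> 9   fatigue 0.209 1.284    TRUE
#> 1 emotional 0.136 0.527   FALSE
```

The generator designs the cognitive composite as the most connected
node, and the pipeline recovers it: cognitive has the highest
z-standardized expected influence (1.99, flagged notable), i.e. raising
cognitive symptoms is expected to activate more of the remaining network
than any other node.

```r
lg <- fit_outcome_model(regression_spec("gose_incomplete", "M6"), cohort)
lg[lg$term == "somatic", ]
#>      term estimate conf_low conf_high      p_value
#> 5 somatic    1.814    1.382     2.381 1.794648e-05
```

An odds ratio of 1.81 per unit of the 0–3 somatic factor (headache,
dizziness, nausea at two weeks) for incomplete recovery at six months,
close to the generating value of 1.84.

`run_pipeline(run_config(seed = ...))` runs everything — per-timepoint
networks and centrality, all pairwise network comparisons, stability
bootstraps and the eight outcome regressions — and writes CSV/JSON
tables plus a manifest that reproduces the run bit-for-bit.

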