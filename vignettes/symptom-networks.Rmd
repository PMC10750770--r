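---
title: "Estimating and probing post-concussion symptom networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and probing post-concussion symptom networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpqnet)
```

## The problem

After a mild traumatic brain injury (mTBI; Glasgow Coma Scale 13–15 at
emergency-department arrival), patients report constellations of somatic,
cognitive, emotional and sleep-related symptoms on the 16-item Rivermead
Post-Concussion Symptoms Questionnaire (RPQ). Network analysis treats each
symptom as a node in an undirected graph whose edges are *partial
correlations*: the association between two symptoms after conditioning on
all others. Under a Gaussian model a zero partial correlation is
conditional independence, so the estimated graph separates direct symptom
interactions from associations that merely pass through third symptoms.
Central nodes — those that can activate or deactivate much of the rest of
the network — are candidate treatment targets.

`rpqnet` implements this workflow end to end: ordinal recoding and
composite construction, regularized network estimation with model
selection, expected-influence centrality, permutation comparison of
networks across recovery timepoints, case-dropping bootstrap stability,
and adjusted regressions linking two-week symptom factors to six- and
twelve-month outcomes. A synthetic-cohort generator with fully known
ground truth backs every stage with checkable simulations.

## Preprocessing

Raw RPQ items are scored 0–4, but categories 0 ("not experienced at
all") and 1 ("no more of a problem than before injury") both describe an
unchanged symptom burden. `recode_rpq()` therefore maps
(0, 1, 2, 3, 4) → (0, 0, 1, 2, 3), giving analysis scores from 0 (no
problem) to 3 (severe problem).

Three item triplets are so tightly interrelated that they measure single
constructs; each is averaged into a composite node: *emotional*
(irritable, depressed, frustrated), *cognitive* (poor memory, poor
concentration, slow thinking) and *visual* (blurred vision, light
sensitivity, double vision). The remaining seven items enter as their own
nodes, for 10 network nodes in all. For the outcome regressions two
further averages are formed: *somatic* (headache, dizziness, nausea) and
*other* (noise sensitivity, sleep disturbance, fatigue, restlessness).
All five factors are averages rather than sums so that a one-unit change
is always on the 0–3 item scale; this extends the averaging rule the
composites already use and keeps "per unit increase" interpretable.

Missingness is handled complete-case *per analysis*: the network cohort
requires complete items at every analyzed timepoint, while each
regression requires complete W2 items, covariates and the modeled
outcome. Dropped counts are reported (`filter_cohort()` attaches a
CONSORT-style tally). Partially missing RPQ assessments are excluded
rather than imputed; this is the strictest reading of "complete
assessment" and is flagged in the filter report rather than silently
applied.

## Network estimation

Let $S$ be the correlation matrix of the 10 node scores at one timepoint.
The graphical lasso estimates a sparse precision matrix by maximizing

$$\log\det\Theta \;-\; \operatorname{tr}(S\Theta)\;-\;
\lambda \sum_{i\neq j} |\theta_{ij}|,$$

with only off-diagonal entries penalized, so $\lambda = 0$ recovers
$S^{-1}$ and $\lambda \ge \max_{i\ne j}|s_{ij}|$ the empty graph. Edge
weights are the partial correlations
$w_{ij} = -\hat\theta_{ij}/\sqrt{\hat\theta_{ii}\hat\theta_{jj}}$. The
solver is block coordinate descent (a lasso regression per column of the
covariance estimate) in compiled code; convergence is declared when the
largest covariance update in a sweep falls below `tol` (default `1e-6`)
relative to the mean absolute off-diagonal of $S$, with at most `maxit =
1000` sweeps. The test suite cross-checks the solution against an
independent ADMM solver of the same objective to $10^{-5}$.

The penalty is chosen on a log-spaced path of `n_lambda = 100` values
from $\lambda_{\max}$ (smallest penalty emptying the graph) down to
$\lambda_{\max}/100$, by minimizing the extended Bayesian information
criterion with $\gamma = 0.5$:

$$\mathrm{EBIC} = -2\,\ell(\hat\Theta) + E\log n + 4E\gamma\log p,$$

where $E$ is the number of edges. Ties go to the larger penalty (the
sparser model). Two details are deliberate design choices:

* **Refit scoring.** By default each candidate support is scored by the
  EBIC of its support-constrained *unpenalized* maximum-likelihood refit,
  not of the penalized estimate itself. Scoring the penalized estimate
  lets shrinkage bias on strong edges trade against small spurious edges
  and systematically over-selects; scoring refits compares supports on
  likelihood alone. In our chain-graph simulations (10 nodes, partial
  $r = 0.3$, $n = 2000$) refit scoring recovers the exact support in 99
  of 100 replicates versus roughly 1 in 10 without it. The reported
  weight matrix is still the penalized estimate at the selected
  $\lambda$, the reporting convention of regularized psychometric
  networks; `refit = FALSE` restores pure penalized-likelihood scoring.
  The two scores serve different goals, and the resampling procedures
  deliberately use the penalized score (`refit = FALSE` is their
  default): the comparison test and the case-dropping bootstrap depend
  on edge-*weight* stability across re-estimated networks, and the
  sparser refit selection makes borderline edges flip in and out of
  resampled fits, inflating the null of the maximum-difference statistic
  and destroying power (from essentially certain detection to a few
  percent in our single-edge simulations). Penalized scoring is also how
  the canonical implementations of both procedures estimate their
  networks. Single-network estimation keeps `refit = TRUE`, where exact
  support recovery is the aim.
* **Input correlations.** Pearson correlations of the node scores are
  the default: composites of 0–3 items are quasi-continuous, and the
  estimator is surfaced in the output rather than hidden. Spearman is
  available for heavy skew. A polychoric option is deliberately out of
  scope; treating the thresholded scores through a rank or product-moment
  estimator attenuates edge weights somewhat (visible in the generator
  recovery tests) but preserves structure and ranking, which is what the
  downstream analyses use.

Degenerate inputs are handled explicitly: zero-variance nodes raise an
error naming the node, near-collinear pairs warn, and an indefinite
correlation estimate is repaired to the nearest positive-semidefinite
matrix by eigenvalue clipping with a logged flag.

## Centrality

Expected influence of node $i$ is the signed sum $\sum_j w_{ij}$;
strength is $\sum_j |w_{ij}|$. In a network with negative edges expected
influence, not strength, captures whether activating a node should
activate the rest of the network. Both are reported raw and
z-standardized across the 10 nodes; the conventional "notable" flag marks
nodes with $z > 1$ (strict inequality). The one-step quantity is the
primary index; a two-step variant
($EI^{(2)}_i = EI_i + \sum_j w_{ij}\,EI_j$) is available. If the selected
graph is empty the z-scores are undefined; the table then carries `NA`
z-columns, flags nothing and warns rather than dividing by zero.

## Comparing networks across timepoints

`nct_compare()` is a permutation network comparison test with two global
statistics: structure invariance $M = \max_{i<j} |w^{A}_{ij} -
w^{B}_{ij}|$ and global strength difference $S = |\sum_{i<j}|w^A_{ij}| -
\sum_{i<j}|w^B_{ij}||$. Both networks are re-estimated from scratch
(correlation, penalty path, EBIC selection) in every permutation, so the
null distribution reflects the entire estimation pipeline.

Because the cohort is repeated-measures, the default scheme for
timepoint comparisons is *paired*: each subject's two records are swapped
with probability one half, preserving within-subject dependence. An
independent-groups scheme (pool rows, redraw membership) is available by
flag; it canonicalizes the pooled row order so that results are invariant
to which dataset is passed first. p-values use the add-one estimator
$(1 + \#\{T_{perm} \ge T_{obs}\})/(1 + B)$, never exactly zero. Edge-wise
post-hoc tests apply the Holm step-down adjustment over all 45 node
pairs — all pairs, not just edges present in either estimate, since a
difference can appear as an edge present in one network only. Plain
Bonferroni is a trivial special case the user can apply to the raw
column; Holm is the default because it dominates Bonferroni uniformly.

## Stability of centrality

`case_drop_bootstrap()` drops a proportion $q$ of subjects uniformly
without replacement, re-estimates the network and centrality, and
correlates subset with full-sample centrality across nodes; `B`
replicates per $q$ on the grid $0.1, \dots, 0.7$. The correlation
stability coefficient is the largest $q$ at which at least 95% of
replicates retain $r \ge 0.7$. A step-0.1 grid is the default; stability
limits between grid points (a CS of 0.517, say) require the finer grid
(`seq(0.025, 0.75, 0.025)`) that the same function accepts at
proportional cost. Replicates whose estimation fails or whose subset
centrality is constant (correlation undefined) are flagged and excluded,
with the failure count reported; if no replicate at any proportion
succeeds the CS is indeterminate (`NA`) rather than fabricated.

## Outcome models

Eight adjusted models associate the five W2 symptom factors with M6 and
M12 outcomes: logistic regression for incomplete recovery (GOSE < 8
versus GOSE = 8) and ordinary least squares for QOLIBRI-OS and the SF-12
physical and mental component scores. Every model adjusts for age, sex,
years of education, prior TBI, psychiatric history and head-CT status —
11 terms. Logistic estimates are odds ratios with Wald 95% intervals
(the standard reporting convention for adjusted ORs); linear estimates
are $\beta$ with t-based intervals. Factors enter on the raw 0–3 scale
(`standardize = TRUE` rescales them). No multiplicity adjustment is
applied across the eight models, matching per-model reporting practice;
this is recorded in the result attributes. Perfect separation, rank
deficiency and constant outcomes raise errors naming the offending
terms.

## The synthetic generator

`make_true_network()` builds a 16-item latent Gaussian copula truth:

* **Clusters.** Within-cluster partial correlations for the emotional,
  cognitive and visual triplets are drawn uniformly from $[0.29, 0.46]$,
  the range where tight symptom clusters in this population live.
* **Cross-cluster edges.** A fixed default set connects headache,
  dizziness and nausea; sleep disturbance, fatigue and restlessness; and
  links the cognitive cluster to fatigue and the emotional cluster. The
  implied *node-level* network (the composites are linear maps of the
  latent items, so their partial correlations follow analytically) makes
  the cognitive composite the top node by expected influence, with
  fatigue and the emotional composite next and nausea weakly tied — the
  qualitative profile the pipeline should recover.
* **Ordinal thresholds.** Latent margins are cut at
  $\Phi^{-1}(0.45, 0.70, 0.85, 0.95)$, i.e. 45% symptom-free and a
  tapering severity distribution; the implied category frequencies are
  checkable in closed form and are verified in the tests.
* **Longitudinal structure.** A within-subject latent correlation
  $\rho_t = 0.5$ couples the four timepoints; per-timepoint edge scaling
  defaults to 1 everywhere, i.e. a structurally stable network over
  recovery, which is also the regime the comparison test's null
  calibration assumes.
* **Outcomes.** Incomplete recovery is Bernoulli on a logistic mean with
  odds ratios of 1.84 (somatic), 1.55 (other), 1.39 (emotional and
  cognitive) per factor unit and modest covariate effects; QOLIBRI-OS
  and SF-12 scores are linear with Gaussian noise (SD 14, 9 and 10) and
  factor coefficients of a few points per unit. These magnitudes sit in
  the range reported for ED-recruited mTBI cohorts, and the intercepts
  put incomplete recovery near 50%.
* **Covariates.** Age is log-normal (median 38, about 40.6 ± 17 years),
  34% female, education 14 ± 2.5 years, 20% prior TBI, 25% psychiatric
  history, 34.7% CT-positive, GCS 13/14/15 at 4.1/18.5/77.4%.

The generator does *not* emulate enrollment dynamics, attrition,
informative missingness, site effects, or response styles
(acquiescence, all-zero responders beyond what the thresholds imply).
Passing tests therefore demonstrate that the estimators recover the
structure of an idealized cohort of this shape — not that any particular
clinical dataset satisfies the model.

## Validation design and problem sizes

The package validates itself at sizes chosen to balance statistical
resolution against desk-scale runtimes: support recovery on a 10-node
chain ($|r| = 0.3$, $n = 2000$, 100 replicates), comparison-test
calibration on null pairs ($n = 300$ per group, 200 permutations, 200
replicates) and power against a single-edge difference of 0.3
($n = 500$ per group), odds-ratio recovery at $n = 5000$ (200
replicates) with null calibration at $n = 1000$ (500 replicates), and
the end-to-end centrality ranking at $n = 1000$ (100 replicates).
Production analyses would typically use 1,000 permutations and 1,000
bootstrap replicates, as the defaults do.

## Known limitations

* Partial-correlation networks are cross-sectional; they cannot orient
  edges or establish symptom-to-symptom causation. Temporal (lag-1)
  network models are out of scope.
* Edge weights from the penalized estimate are biased toward zero by
  construction; comparisons and rankings are the reliable quantities,
  not individual weight magnitudes.
* Pearson input correlations on ordinal composites attenuate absolute
  edge weights relative to the latent scale.
* The paired permutation scheme assumes the two timepoints are
  exchangeable under the null within subject; strong marginal severity
  drift between timepoints (without structural change) weakens that
  assumption, and the global-strength test is the more sensitive check
  in that regime.
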