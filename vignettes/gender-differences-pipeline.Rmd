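---
title: "Measuring gender differences in a multiplex behavioural cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring gender differences in a multiplex behavioural cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gendernet)
```

# The problem

Densely instrumented student cohorts — smartphone proximity scans, call and
text logs, online friendship and feed activity, location traces, and
personality questionnaires — make it possible to ask how men and women
differ across *many* behavioural channels at once, in a single population.
`gendernet` implements that analysis as a reusable, tested pipeline:

1. a weekly-aggregated data model with an activity filter,
2. subsampled pooled-SD effect sizes for individual-level indicators,
3. entropy-based mobility and interaction metrics,
4. gender-label permutation tests for dyad and triad homophily on each
   interaction network,
5. overlap-distance k-nearest-neighbour imputation of missing features, and
6. an imbalance-aware, cross-validated gender classification stage with
   feature-importance ranking.

Because the cohort data this kind of study uses is private, the package
ships a synthetic cohort generator whose outputs have the statistical
structure the analysis assumes; every stage is exercised end to end on
generated cohorts, and every planted parameter is recorded in a truth file.

# Data model and weekly protocol

All indicators are computed per week and then averaged over each
participant's weeks, which prevents participants with patchy coverage from
dragging indicator values toward zero: a week in which an indicator is
undefined is skipped, not imputed (`weekly_average()`). Participants with
three or fewer active weeks are excluded (`filter_active()`, default
threshold 4).

The observation protocol does not define "active week", so the package
uses the most permissive reading: a week counts as active if the
participant has at least one interaction record in any channel or at least
one location observation. Weeks are indexed `0..N-1` from the study start;
calendar alignment is metadata only, which avoids ISO-week year-boundary
ambiguity.

All five channels are stored as undirected weekly graphs (structural
metrics are defined on undirected graphs); calls and texts additionally
keep a directed event list with durations, because call-duration
statistics depend on who initiated. After the activity filter, graphs are
restricted to retained participants; alters without a gender label count
toward degree but never toward homophily metrics.

# Effect sizes

Two groups are compared with the standardized mean difference

$$r = \frac{\mu(x_{male}) - \mu(x_{female})}{\sigma_p}, \qquad
\sigma_p^2 = \frac{(n_1-1)\sigma^2(x_1) + (n_2-1)\sigma^2(x_2)}
{n_1+n_2-2},$$

so negative values always mean women score higher. With 166 women and 601
men the class sizes are very unequal, which would distort the standard
deviations; the pipeline therefore draws 1000 random half-size subsamples
*without replacement* from each class, computes $r$ on each pair, and
reports the mean and the 5th/95th percentiles of the resulting
distribution (`subsample_comparison()`). Half of an odd class size is
rounded down (601 → 300). A difference is called significant when the
central 90% percentile interval excludes zero.

Two properties of this construction are worth knowing:

* The subsample mean is an unbiased, fast-converging estimate of the
  full-sample $r$; the package tests verify convergence directly.
* Drawing half the class without replacement gives the subsample mean
  *exactly* the full-sample variance
  ($\tfrac{\sigma^2}{n/2}(1-\tfrac{1}{2}) = \sigma^2/n$), so "the 5–95%
  band excludes zero" behaves as a two-sided test at a nominal 10% level:
  under a true null it fires about 10% of the time, never 5%. At the
  166/601 class sizes the implied significance cutoff is
  $1.645\sqrt{1/166 + 1/601} \approx 0.144$ pooled SDs. This is a property
  of the percentile construction itself; users wanting a stricter level
  can widen the percentile pair on the exposed `r_samples`.

# Mobility and interaction entropy

Weekly location behaviour is summarized by the number of unique locations
and by the Shannon entropy (natural log) of the relative-time distribution
over locations,
$H_u = -\sum_{l \in L(u)} P_u(l)\, \log P_u(l)$:
people who spread their time evenly across many places have high entropy.
Location clustering is upstream of this package — inputs are
already-clustered weekly distributions. Interaction entropy uses base-2
logs, $S_u = -\sum_{i \in N(u)} P_u(i) \log_2 P_u(i)$, over the share of a
participant's interactions going to each contact; the two bases follow the
respective conventions for each quantity and both cancel in effect-size
comparisons. The log base for location entropy is exposed as an argument.

# The permutation reference model

Subsampling cannot be used on networks without destroying their structure,
so network indicators are referenced against a permutation null: gender
labels are shuffled uniformly across nodes (conserving the 166/601 counts
exactly) with the topology held fixed, the indicator is recomputed per
realization — `2E` of them by default, where `E` is the edge count — and
the deviation is summarized as
$z = (x - \mu(\tilde{x}))/\sigma(\tilde{x})$ plus one-sided permutation
p-values counting realizations *strictly* beyond the observed value, so
p = 0 is representable; an optional `(k+1)/(n+1)` correction is available.
Tested indicators are the mean same-gender neighbour fraction per gender,
the dyad motif counts (FF/MM/FM) and the closed-triangle motif counts
(FFF/MMM/mixed). Triads are closed triangles only. Whether to test a
weekly or a month-aggregated graph is a user choice
(`aggregate_graph()`); triad tests need triangles, which in practice only
the dense proximity network supplies in volume.

# Imputation

Participants missing more than two of the five feature categories
(personality, location, call, Facebook, person-to-person) are removed; a
category counts as missing only when every feature in it is missing.
Remaining holes are filled by k-nearest-neighbour imputation (k = 7) under
the overlap distance
$d_{uv} = \tfrac{1}{|L_{uv}|}\sum_{i \in L_{uv}} |x_i(u) - x_i(v)|$
over the features observed in both participants. Three details are the
package's own choices, stated here because the distance as written is
scale-sensitive: features are z-standardized before the distance is
computed (entropies and questionnaire scores live on very different
scales); distance ties at the k-th neighbour break by ascending
participant id, making the result independent of row order; and a feature
observed by no neighbour falls back to the cohort mean with a warning.
A single observing neighbour donates its value directly. Observed cells
are never altered.

# Gender classification

The feature table (trait scores; mobility; per-channel degree, same-gender
fraction, betweenness, interaction entropy; text volume) feeds five model
families: ridge-penalized logistic regression, random forest, gradient
boosting, AdaBoost and SVC. The bespoke content of this stage is the
protocol, not the learners, which come from the surrounding ecosystem
(glmnet, randomForest, xgboost, e1071); AdaBoost alone is implemented
in-package as discrete SAMME over depth-1 rpart stumps. The logistic C
grid maps onto the ridge penalty as $\lambda = 1/(C\,n)$, matching the
"inverse regularization strength" convention.

Evaluation is 10-fold stratified cross-validation; each family's grid
point is scored by the unweighted mean over folds of ROC-AUC and F1 (the
fold-aggregation rule is a package choice), and the configuration with the
highest harmonic mean of the two is selected and reported. Women are the
positive class for F1. With a fixed seed the whole evaluation is
bit-reproducible. The imbalance-aware baselines are analytic: a random
ranking has AUC 0.5, and a classifier predicting "female" with probability
equal to the prevalence p has expected F1 = p (0.22 at 166/767), which a
Monte-Carlo helper confirms. Feature importance is the normalized mean
Gini decrease of a random forest refitted on the full table.

The shipped grid reproduces the published tuning grid, including a printed
C grid that lists 1 twice — kept as printed, with 0.1 added as the likely
intended value. Ensemble sizes default to 1000 estimators in
`default_model_grid()`; tests and the analysis drivers use
`small_model_grid()` (200 estimators, one or two values per knob), which
changes runtimes, not conclusions.

# The synthetic cohort generator

`generator_config()` defaults encode the study conditions end to end:

* **Composition**: 166 women, 601 men (78% male), 12 weeks.
* **Traits**: unit-variance normals per gender whose mean gap *is* the
  planted pooled-SD effect, using the full set of published trait effect
  sizes (neuroticism −0.635 through loneliness +0.095) as defaults, so
  effect-size recovery is exact in expectation.
* **Mobility**: weekly symmetric-Dirichlet time distributions; women get a
  slightly higher concentration and unique-location rate, yielding
  modest negative effect sizes for both mobility indicators.
* **Channels**: weekly edge probabilities 0.12 / 0.006 / 0.0025 / 0.002 /
  0.002 (proximity / friendship / feed / call / text) chosen so four-week
  unions reproduce the familiar monthly densities (≈40% proximity, 2–3%
  online, <1% telecom), since the printed densities refer to monthly
  aggregation.
* **Homophily**: same-gender dyads accepted proportional to (1+h), mixed
  to (1−h), normalized to preserve the target density; under random mixing
  (h = 0) the same-gender edge fraction equals the closed-form dyad share,
  and the fraction is strictly increasing in h
  (`expected_same_gender_fraction()`). Homophily is planted at the dyad
  level only; triad homophily *emerges* and is measured, not planted.
* **Calls**: log-normal durations with the printed means per ordered
  gender pair (M→F 117 s, F–F 114.56 s, M–M 71.52 s); the F→M mean is not
  printed anywhere and defaults to 105 s, between the printed extremes,
  consistent with women talking longer regardless of initiator.
  Poisson(+1) weights and log-normal durations are conveniences — no
  distributional forms are published.
* **Missingness**: per-(participant, category) MCAR masking at rate
  0.047, calibrated so that about 21.5% of participants miss at least one
  category, matching the reported fraction.
* **Person heterogeneity**: each participant draws a personal
  unique-location rate, Dirichlet concentration and interaction-activity
  multiplier around their gender's mean. Without this, within-gender
  variance collapses and any planted gap becomes an implausibly large
  effect size.
* **Determinism**: one seed; the same seed yields byte-identical fixture
  files.

## What the generator does *not* emulate

Trait scores are drawn independently (real instruments correlate);
activity is Bernoulli per week with no burstiness or churn; degree
distributions are binomial-like rather than heavy-tailed; there are no
non-participant alters; and the symmetric homophily tilt combined with the
4:1 gender imbalance makes the same-gender neighbour fraction an almost
deterministic separator between genders (the minority's baseline fraction
is far lower). Synthetic classification AUC therefore saturates near 1.0
— comfortably above the acceptance floor of 0.75, but *not* a reproduction
of the 0.86–0.87 reported on real data, where homophily features are
informative but noisy. Passing tests show the pipeline machinery is
correct, not that real cohorts are this easy. For the same reason the
generator makes no attempt to reproduce any real cohort's printed values
beyond the structural conditions listed above.

A related artifact worth knowing: with a symmetric tilt and unequal
groups, minority members end up with slightly fewer partners, so synthetic
degree/entropy gaps favour men — opposite in sign to findings on real
cohorts, where women had more contacts in online and mobile channels.
Gender-specific sociality is deliberately not planted; only homophily is.

# Numerical choices and problem sizes

Distributions must sum to 1 within 1e-9; entropy terms at P = 0 contribute
zero. Degenerate permutation nulls (constant indicator) yield a signed-
infinity z rather than an error. Betweenness ignores edge weights
(hop-count shortest paths, unnormalized, summed over unordered pairs).
Imputation and evaluation are deterministic given a seed.

The test-suite and acceptance-script problem sizes are the package's
choices: full 166/601 cohorts with 1–8 weeks where class sizes matter
(effect-size recovery, baselines, classification), 500–5000 permutations
for homophily tests (2E on the sparse channels), oracle comparisons on
graphs of up to 25–30 nodes where brute force is exact, and 200-estimator
grids for cross-validated stages. The exhaustive-enumeration oracle for
the permutation test runs on 6-node graphs where all label placements can
be enumerated.

# Known limitations

Binary gender labels are an assumption inherited from the questionnaire
design of such studies. The percentile significance criterion is a
nominal-10% test (see above). The permutation model permutes labels only —
no degree-preserving null is provided. No multiple-testing correction is
applied across indicators, matching the original analysis protocol.
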