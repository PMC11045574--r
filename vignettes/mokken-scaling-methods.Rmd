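---
title: "Nonparametric scaling of ordinal questionnaires: models, diagnostics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonparametric scaling of ordinal questionnaires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scalemok)
```

## The model

`scalemok` evaluates whether a short polytomous questionnaire — the running
case is a 9-item, five-level health-and-wellbeing instrument — supports
unweighted level-sum scoring. The underlying model is the polytomous
monotone homogeneity model (MHM) of Mokken scaling, which assumes

1. *unidimensionality*: the scale's items reflect one latent trait θ;
2. *local independence*: responses are conditionally independent given θ;
3. *monotonicity*: every item step response function (ISRF)
   P(X_j ≥ x | θ) is non-decreasing in θ.

Under the MHM the sum score stochastically orders respondents on θ, which
is precisely the property a level sum score needs. The model is not fitted;
its observable consequences are checked. Responses are coded 1..5
externally (1 = least severe) and stored 0..4 internally; every
covariance-based statistic is invariant to that offset, and level-sum
scoring reports externally.

## Scalability coefficients

For items i, j with observed margins, `H_ij` norms their covariance by the
largest covariance any joint table with those margins allows. That maximum
is attained by the comonotone coupling — pair the two samples' order
statistics rank for rank — equivalently, the coupling whose joint survival
function is `min(P(X_i >= x), P(X_j >= y))`. `H_i` is the ratio of an
item's summed covariances with the other items to the summed maxima, and
`H_S` the same ratio over all pairs, so `H_S` always lies between the
smallest and largest `H_i` (a mediant). `H = 1` holds exactly when every
pair is comonotone ("Guttman-perfect"); `H = 0` at independence; negative
values indicate model violation.

Two numerical conventions matter:

* *Covariances divide by n* (not n − 1) in both numerator and denominator,
  so the convention cancels and small-sample H values match direct
  enumeration exactly. The test suite verifies equality to 1e-12 against a
  brute-force oracle built from pairwise cross-tables, and against the
  equivalent weighted-Guttman-error form
  `H_ij = 1 − F/E` (observed vs independence-expected error mass over all
  cross-item step pairs).
* *Standard errors are a nonparametric bootstrap over respondents*
  (default 1000 resamples, seeded). The classical delta-method estimator is
  deliberately not implemented; the bootstrap is assumption-free and its
  method is recorded in the result metadata. Bootstrap SEs are not claimed
  to match any particular published standard errors.

An item with zero variance makes H undefined for its pairs; such items are
excluded with a warning (an error only if fewer than two items survive).

## Automated item selection

`run_aisp()` implements the greedy bottom-up variant: seed a scale with the
admissible pair of largest `H_pair` (significantly positive and at least
the lower bound c), then repeatedly admit the item that maximises the
candidate scale's `H_S`, subject to the entrant's within-scale `H_i >= c`
and significantly positive pairwise H with every member. Significance is a
one-sided z-test using a seeded bootstrap SE for each pair (default 200
resamples, alpha 0.05); ties prefer the lower item index, for determinism.

Greedy growth can leave an early member's within-scale `H_i` below c after
later admissions, so a closing scale is pruned worst-first until every
member satisfies the bound; pruned items return to the pool, and a seed
pair whose scale collapses entirely is not reused as a seed at that bound.
Every returned scale therefore satisfies the membership criterion — this is
rechecked property-style in the tests. Assignments need not nest across
bounds (the procedure is greedy), and no nesting is asserted.

`sweep_lower_bounds()` tabulates assignments over a user grid (the
conventional grid 0.1–0.6 in steps of 0.05 has 11 points);
`find_split_threshold()` scans a step-0.001 grid from below and reports the
first bound at which the partition is no longer a single all-items scale,
with an explicit no-split sentinel. Because the pairwise statistics do not
depend on the bound, they are precomputed once and the scan costs only the
greedy search per grid point.

## Manifest monotonicity

Latent monotonicity implies manifest monotonicity: P(X_j ≥ x | R) must be
non-decreasing in the rest score R (the scale sum excluding item j).
`check_monotonicity()` groups respondents by R — merging adjacent rest-score
values from the low end until each group reaches `minsize`, a trailing
undersized group merging backwards — and compares every step's estimated
probability across ordered group pairs. Defaults:

* `minsize` follows the sample-size ladder N/10 (N ≥ 500), N/5
  (250 ≤ N < 500), max(N/3, 50) otherwise;
* all ordered group pairs g < h are compared (the stricter reading of
  "as the rest score increases"); `pairs = "adjacent"` restricts to
  neighbours;
* a decrease greater than `minvi = 0.03` counts as a violation; each
  violation is additionally tested by a one-sided pooled two-proportion
  z-test at alpha 0.05 (`zsig`).

The `crit` diagnostic aggregates an item's violation evidence. No standard
closed form exists for it, so this package defines and documents its own:

    crit = 0                                   if vi = 0, otherwise
    crit = 50 max(0, 0.3 − H_i) + sqrt(vi) + 100 vi / ac
           + 100 maxvi + 50 sum_vi + 10 sqrt(zsig)

It is zero exactly when the item has no violations, increases in every
ingredient, and every ingredient is also exported separately. Numerical
crit values are not comparable with other software's crit values.

### Sampling flutter at moderate discrimination

A property worth knowing when reading violation counts: with rest-score
groups of N/10 respondents, the estimated ISRF in a region where the true
curve is nearly flat (probabilities around 0.9 or 0.1) has a standard error
near 0.02, so adjacent-group decreases slightly above 0.03 occur by chance.
Measured on monotone graded-response data with nine five-level items at
N = 2000 (the suite's type-I replications): with item slopes around 1.8
roughly one replicate in six reports at least one such violation, while
with slopes around 2.8 — the discrimination level this package's default
generator is calibrated to — the rate is a few percent at most, and the
flagged drops are almost never significant. At moderate discrimination, small `vi` with
`zsig = 0` and near-zero `crit` should be read as noise; conclusions should
rest on significant violations and on `crit`.

## Invariant item ordering

For interpreting item hierarchies, `check_miio()` tests manifest invariant
item ordering: items are ordered by overall mean, and for each pair the
conditional means within rest-score groups (the pair excluded from the rest
score) must respect that order. A reversal larger than the number of item
steps times 0.03 — 0.12 for five-level items — is a violation. Backward
selection removes the item with the most violations (ties: larger crit,
then lower item index — the tie-break is this package's documented choice)
until none remain or only two items survive.

`compute_HT()` measures ordering accuracy as Loevinger's scale coefficient
on the transposed matrix (respondents as items). Respondents with constant
response vectors carry no ordering information and are excluded, with the
count reported. The transposed computation uses a closed-form identity over
respondent pairs (sums of products of rows and of sorted rows), verified in
the tests against the explicit pairwise oracle on the transpose. Rules of
thumb: below 0.3 items cannot be ordered, 0.3–0.4 low accuracy, 0.4–0.5
accurate, 0.5 and above highly accurate.

## Scoring

The LSS assigns 1..5 per response (higher = more problems) and sums; the
transform `(raw − J) / (4J) × 100` maps the attainable range exactly onto
0–100, so for nine items every score is a multiple of 100/36 (0, 2.78,
…, 100). Composite items merge two source items through a symmetric 5×5
table with identity diagonal; the default is the worst-of-pair rule
max(a, b), the conservative severity-respecting merge — any explicit table
overrides it, and the rule in force is recorded in the composite's
metadata. Reliability is reported as Cronbach's alpha and Guttman's
lambda-2 (λ2 ≥ α always; both equal 1 for parallel items and 0 at exact
independence).

Missing data policy throughout: listwise deletion *per analysed item set*,
so a subscale analysis keeps every respondent complete on that subscale.
No imputation is offered.

## The synthetic-data generator

`generate_grm()` draws data the analysis assumptions describe: factor
scores from a correlated bivariate normal (one factor per item cluster,
correlation 0.5), additive trait shifts for known groups, and graded
response sampling P(X_j ≥ x | θ) = logistic(a_j (θ − b_jx)). The defaults
are fixed study-like conditions, chosen once:

* 9 items in clusters of 6 (psychosocial) + 3 (physical), five levels;
* discriminations a = 2.8 and per-item difficulty locations solved by
  root-finding against the analytic marginals so the item means span
  roughly 1.8–2.9 externally — the spread of a mixed physical/psychosocial
  wellbeing instrument in a combined general/patient sample. Under these
  defaults the subscales reach H ≈ 0.70, the full scale ≈ 0.55, alpha and
  lambda-2 ≈ 0.9, and the AISP splits the full scale into the two clusters
  in the low-0.4 region — the scalability regime such instruments report;
* long-term-condition prevalence 0.735 with trait shift +0.5, carer
  prevalence 0.30 with shift +0.3, 55% women, country mix 27/15/58%, ages
  normal(50, 18) truncated to 18–90 and banded ≤35 / 36–50 / 51–65 / >65;
* N = 3000.

The truth record (trait draws, labels, cluster map, config echo) enables
recovery tests; identical seeds give bit-identical output, and
`grm_expected_marginals()` provides the analytic level frequencies the
samples converge to (checked at total-variation distance < 0.02,
N = 50000).

What the generator does **not** emulate: real response styles, item-specific
discrimination spread, differential item functioning across countries or
modes, and missingness. Passing tests on generated data therefore certify
the statistics and the procedure — not that any particular real instrument
fits the model.

### Controlled violations

`inject_violation()` perturbs one item for trait values inside an interval.
The `nonmonotone_isrf` type lowers one step's cumulative probability by
`depth`, clamping later steps so the cumulative system stays valid, and
errors if the depth would drive a probability negative. Placement matters:
a constant-depth dip placed where the ISRF is still rising is partly masked
by the curve's own slope between rest-score groups, so detectability tests
dip a step in its saturated region (the test fixtures dip the easiest
item's first step from the trait center upwards; depth 0.15 there is
detected in essentially every replicate at N = 2000). The `crossing_irf`
type shifts the item's difficulty by ±4 × depth below/above the interval
midpoint, flattening its response functions so its conditional means cross
those of neighbouring items — the signature MIIO is built to catch.

## Pipeline

`run_full_analysis()` executes scalability (with bootstrap SEs), the AISP
sweep and split search, monotonicity, MIIO with H^T, reliability, LSS
summaries and rank-sum known-group tests on the pooled data, then
recomputes scale coefficients within every stratum of the configured
stratification variables whose size reaches the floor (default 500;
smaller strata are skipped with a logged reason). Age bands default to
≤35, 36–50, 51–65, >65. No multiple-testing correction is applied (the
report footer says so). Rank-sum tests use mid-ranks and the tie-corrected
normal approximation (the all-tied case returns p = 1); Spearman
correlations use mid-ranks. The JSON manifest echoes the full
configuration including the seed, and re-running from it reproduces every
table bit for bit — asserted in the tests.

## Problem sizes used in validation

The test suite runs oracle equivalence on 200 random 200 × 4 matrices;
type-I and detection properties on 100 replicates at N = 2000; structure
recovery at N = 3000; known-group direction and significance over 40
replicates at N = 2000 with prevalence 0.5 (about 1000 per arm); and
marginal convergence at N = 50000 — sizes chosen to make binomial noise on
the tested rates small relative to their margins.

## Known limitations

* The double monotonicity model is not tested (generally not meaningful
  for polytomous scales); manifest invariant item ordering is its
  practical stand-in here.
* Local independence is assumed, not tested.
* No latent-trait estimation, no parametric IRT fits, no exploratory
  factor analysis, no preference-weighted scoring, no regression
  adjustment of group contrasts.
* The AISP is the greedy variant only; a genetic-search variant may find
  different partitions near the split threshold.
* `crit` is a package-defined diagnostic; compare only within analyses run
  by this package.
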