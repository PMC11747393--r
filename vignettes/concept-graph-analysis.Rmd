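---
title: "Concept-graph analysis of pairwise similarity ratings: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concept-graph analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conceptgraph)
```

# The measurement model

The pairwise rating task elicits one integer judgment s(i,j) in −7..+7 for
every unordered pair of concepts: +7 maximal relatedness, −7 maximal
opposition, 0 no relation. For the canonical 16-concept set this gives 120
pairs, enumerated lexicographically by concept index (`canonical_pair_index()`);
that ordering is the column order of every matrix in the package and is
stable across runs.

Ratings are treated as **discrete**: the 15-level marginal is what the
entropy stage measures, and non-integer inputs are rejected at validation.
Whether the original instrument permitted intermediate responses is not
knowable from the published scale description; modelling the levels as
integers is the reading consistent with computing "the probability that
rating i is selected".

Ratings map to edge weights by the affine rescaling
e = 1 − (s − r_min)/(r_max − r_min), so e ∈ [0, 1] acts as a distance
(0 = maximally associated). All inference operates on weights; effects on
the rating scale divide by the scale range (14) to land on the weight scale.

## News-bias scores

Each participant lists up to three news sources; a user-supplied lookup
table assigns each source a partisan score on the 5-point Left(1)–Right(5)
scale, and the participant's bias is the arithmetic mean over scorable
sources. Matching is case-insensitive with whitespace normalization and
deliberately *not* fuzzy — silent misattribution of a source is worse than a
missing score. Participants with no scorable source (typically
algorithm-driven platforms with no fixed editorial stance) get a missing
score, are excluded from news-based analyses, and are logged with a reason.
For participants with one or two scorable sources the default is to average
what can be scored; `require_three_sources = TRUE` switches to strict
exclusion. The published exclusion rule ("insufficiently detailed
information") does not pin down the partial-list case, so both policies are
exposed and the lenient one — which discards less data — is the default.

# Edge-wise inference

Each pair's weight is modelled by ordinary least squares on a focal
predictor plus nuisance covariates (gender dummy, ordinal income bracket,
age). Inference on the focal coefficient is by permutation:

* **simple** scheme (default): the focal column is permuted across
  participants, covariates and response fixed — exchangeability of the
  predictor under the marginal null;
* **freedman_lane**: residuals of the nuisance-only model of y are
  permuted and added back to the nuisance fit.

Both use the Frisch–Waugh–Lovell identity, so each permutation costs one
projection rather than a refit; the observed coefficient is identical to the
full-model OLS coefficient to machine precision (tested against a
normal-equation oracle at 1e−8). The two-sided p-value is
(1 + #{|β*| ≥ |β̂|})/(n_perm + 1): the +1 smoothing keeps p > 0, ties count
against the observed statistic, and the comparison uses a relative
tolerance so p is invariant under affine rescaling of the response.
Benjamini–Hochberg correction is applied per predictor across the 120 pairs
(families of 120, not 120 × predictors, matching per-effect reporting).
Per-edge permutation streams are derived by hashing (root seed, predictor,
edge index), so results do not depend on evaluation order; the batched
Fisher–Yates shuffle is compiled (splitmix64 generator with Lemire bounded
draws) because index generation dominates the screen's cost.

**Which covariates enter which model.** A single model containing both race
and news bias cannot serve as the race screen for a mediation analysis: an
edge whose group effect flows entirely through news bias has a zero race
coefficient once news bias is controlled, so a "fully mediated" edge could
never be flagged race-differing in the first place. The package therefore
fits one model per focal predictor: the race screen estimates the **total**
group effect (the c that mediation later decomposes), while the news model
controls race in addition to the nuisance covariates
(`control_race_in_news = TRUE`), preventing direct group effects from being
misattributed to news bias through the group–bias correlation.

Defaults: `n_perm = 10000` (the full-resolution setting; `pipeline_config()`
defaults to 1000, which keeps a desk-scale end-to-end run in minutes),
`alpha = 0.05`.

# Subgraphs and centrality

Edges surviving FDR form the group-difference subgraph; each edge carries
the sign of the difference (a negative weight coefficient = stronger
association for the group coded 1). Degree centrality divides a node's
degree by (number of nodes participating in the subgraph − 1). The
alternative reading — dividing by the number of pairs featuring the concept
in the full set — is available via `denominator = "all_nodes"`; the
subgraph-node denominator is the default because it is the normalization
consistent with hub values like 9/14 ≈ 0.64 on a 15-node subgraph, whereas
the full-set denominator cannot produce them. Force-directed layouts are
deliberately not computed: node coordinates are non-deterministic plotting
artifacts, so exports stop at the weighted edge list (CSV/GraphML).

# Split-half reliability

Participants are split into random halves; each half's 120-vector of mean
ratings is correlated (Pearson) and the correlation averaged over 500
splits. Participant ids are sorted before splitting so the result depends
only on the seed, not input order. Both the raw mean correlation and the
Spearman–Brown correction 2r/(1+r) are reported, because a published scalar
reliability does not say which convention it used.

# Entropy and the offset sigmoid

Per-pair entropy uses empirical frequencies over the 15 nominal levels with
0·log 0 = 0; no smoothing by default (a Miller–Madow correction is
available, off by default, since the default sample sizes make the bias
term negligible). Bounds 0 ≤ H ≤ log2(15) ≈ 3.907 bits.

The relationship between entropy and the **absolute** news-bias coefficient
is fitted by y = 1/(1+exp(−a(x−b))) + c with Levenberg–Marquardt least
squares. Absolute values are the fitted response; signed coefficients are
reported for plotting only. Initialization: a = 4/range(x) (the logistic
slope whose linear region spans the data), b at the steepest increase of a
moving average of y, c = min(y); ten jittered restarts under a fixed seed,
lowest residual sum of squares wins. Degenerate inputs (constant y, or no
start converging) return a flagged fit with R² = 0 and no parameters rather
than an error, so a pipeline run survives a flat scenario.

# Mediation

For each screened edge, three nested OLS fits with a common covariate set
give a (group → bias), c (total), and c′, b (direct and bias → weight); the
identity c = c′ + a·b then holds exactly (tested at 1e−10). Primary
inference on the indirect effect is a permutation test; the Sobel normal
approximation z = a·b/√(b²se_a² + a²se_b²) is reported as converging
evidence and never gates classification.

**What gets permuted.** Permuting the raw mediator breaks the group→bias
and bias→weight links simultaneously, so it tests the joint null a = b = 0.
On an edge with a real group→bias path but no bias→weight path (the
configuration every unmediated race-differing edge is in), that test is
sharply anti-conservative: the observed a·b̂ inherits the full magnitude of
a while the null products shrink to noise × noise. The package therefore
permutes the **residuals of the mediator given x and the covariates**,
preserving the a path and breaking only the b path — calibrated under the
b = 0 null the screen actually faces (verified by simulation in the test
suite, where the raw-mediator scheme is also shown to inflate). The raw
scheme remains available as `scheme = "simple"`.

The direct effect is tested by permuting x in the full model y ~ x + m + C.
FDR correction runs separately over the indirect and direct families within
the screened set. Labels: *full* = indirect survives, direct does not;
*partial* = both survive; *unmediated* = indirect does not survive.
"Complete mediation" as loss of direct-effect significance after FDR is the
only operationalization compatible with reporting a fixed count of
completely mediated edges.

# The synthetic cohort generator

`simulate_cohort()` draws, per participant: a balanced group indicator g; a
latent partisan position μ = 2.52 − 0.48·g with between-participant sd 1.1;
three integer source scores (within-participant sd 0.7, rounded and clipped
to 1..5) whose mean is the news-bias score — so the mediator written to CSV
round-trips exactly; covariates (gender Bernoulli(0.5), income bracket 1–8,
age ~ N(45, 13) clipped to 18–90, all with zero effect by default, matching
the near-null covariate findings the analysis treats as nuisance); and per
pair a latent rating
baseline + direct·g + b·(m − mean m) + covariate terms + N(0, noise_sd),
rounded and clipped to −7..+7.

Defaults are the study conditions: 223 per group (446 analyzed
participants); group-to-bias path −0.48 bias points (the reported
Black-vs-white difference 2.04 vs 2.52); mediator dispersion chosen so that
the simulated group contrast reproduces the reported scale of evidence
(t ≈ −4, r ≈ −0.2, d ≈ −0.4). That dispersion (≈1.2 total) necessarily puts
mass outside [1, 5] before clipping; the generator accepts the floor
clipping at 1, which bounded bias scores genuinely exhibit, rather than
shrinking the dispersion to avoid it — a deliberately different trade-off
from keeping ±3σ inside the scale, which would triple the group–bias
correlation. Rating noise sd defaults to 3; planted direct effects are
±1.5 rating units (d = 0.5); partial-mediation b paths ±1.2 and full ±3.0
rating units per bias unit (a fully mediated edge must carry its whole
group difference through a·b); news-only b paths ±0.6. Baselines spread
evenly over [−3, +5], the between-pair dispersion that gives real-data
reliability levels (> 0.9). The `paper_like` preset plants 31 race-differing
edges (18 partial, 3 full — conservatives–healthcare, religion–anger,
religion–love — and 10 unmediated) over a 15-node subgraph with hub degrees
religion 9, conservatives 8, science 7, police 6, plus 23 news-only edges
(44 news-affected in total). The `entropy_gradient` preset raises noise sd
from 0.5 to 2.2 across pairs with stepwise-increasing news slopes (0 to
1.5); the range is kept below the regime where clipping at ±7 makes
discretized entropy non-monotone in total sd.

**What the generator does not emulate:** within-participant correlation
across edges beyond the shared mediator (no participant random intercept by
default), item-order or stimulus-position effects, response styles
(end-point pileups, midpoint overuse), non-normal rating noise, and
demographic covariates that actually predict ratings. Passing recovery
tests therefore shows the estimators are correct under the stated
generative model, not that real rating data satisfy that model. Simulated
reliabilities (~0.99) exceed published ones (~0.94) because real raters add
shared-variance distortions the generator omits; the clipped mediator's
group contrast lands near, not on, the published t and r.

# Numerical choices and degenerate inputs

* OLS via QR; rank deficiency is an error naming the collinear columns.
* Permutation ties count as exceedances, with relative tolerance 1e−12.
* Sobel with a = b = 0 returns z = 0, p = 1 (limit convention).
* Empty race-differing sets yield an empty, correctly typed mediation table;
  empty subgraphs are legal and have no centralities.
* A configuration with no planted effects at all is legal and flagged with a
  message (it is the null scenario).
* All randomness flows from one root seed through named substreams
  (`substream_seed()`), so stage results are independent of evaluation
  order and end-to-end runs are byte-reproducible.

# Problem sizes used in the test suite

Unit and property tests run at reduced sizes (tens to hundreds of
participants, 150–1000 permutations, 20–200 Monte-Carlo replicates); the
calibration study uses 200 null cohorts of 300 participants at 1000
permutations, and label-recovery uses 50 cohorts at the full 446. These
sizes were chosen so the whole suite completes in a few minutes on one core
while leaving Monte-Carlo error well inside the asserted bands.

# Known limitations

* The mediation screen is associational; nothing here identifies causal
  direction, and the package takes no stance on it.
* Permutation schemes assume exchangeability of participants; clustered
  recruitment would violate it.
* The sigmoid fit can be weakly identified when entropies span a narrow
  range (b drifts outside the data); the fit object reports standard errors
  and a convergence flag rather than hiding this.
* BH controls FDR under independence or positive dependence; edge weights
  sharing a concept are correlated, which BH tolerates in practice but
  without a formal guarantee here.
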