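---
title: "Methods: ideal-observer analysis of active information sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ideal-observer analysis of active information sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circlequest)
```

## The task and its economics

In the Circle Quest paradigm a circle of radius $r = 130$ px hides
somewhere in a circular search field. Touching the field yields a purple
dot if the touch lies inside the hidden circle (boundary included) and a
white dot otherwise. Each paid touch costs $\eta_s$ credits (1 or 5,
depending on the block), and the final localisation error $e$ costs
$\eta_e = 1.2$ credits/px, all deducted from an initial reserve $R_0$ (95
or 130 credits):

$$\mathrm{Score} = R_0 - s\,\eta_s - e\,\eta_e.$$

The four $(R_0, \eta_s)$ combinations define four blocks of 15 trials,
counterbalanced in order across participants. Sampling is free-form within
an 18 s window; a free purple dot is shown at trial onset. The default
field radius of 540 px makes the hidden circle cover 5.80% of the field
($130/\sqrt{0.058} \approx 539.8$).

## The ideal observer

Candidate hidden-circle centres $\lambda$ live on a square lattice of
stride `grid_stride` (default 4 px). The prior is uniform over centres
whose circle lies fully inside the field, i.e. $|\lambda| \le 540 - 130 =
410$ px. We chose full containment because every hidden circle in the task
is findable within the field; this is a modelling decision the task
description leaves open.

Each dot updates the posterior by Bayes' rule with the deterministic
likelihood: a purple dot at $\sigma$ is consistent with $\lambda$ iff
$|\lambda - \sigma| \le r$, a white dot iff $|\lambda - \sigma| > r$. With
0/1 likelihoods the posterior is always uniform over the *feasible set* of
centres consistent with every dot, which yields an independent oracle:
`batch_posterior()` builds that set directly and must agree with
sequential updating — the support agrees exactly and the masses to
renormalisation round-off (about one ulp; the tests compare the support
bit-for-bit and the masses at $10^{-12}$). Observations that empty the
feasible set signal corrupt data and raise an error rather than returning
a degenerate posterior.

The uncertainty metric is the expected error map

$$EE_s(\lambda) = \sum_i p_s(\lambda_i)\,|\lambda - \lambda_i|,$$

the posterior-weighted mean distance from a candidate placement to the
possible centres. Its minimiser $\lambda^\star$ is a Weber point of the
posterior; since the map is a convex, nonnegative-weighted sum of
distances, $\lambda^\star$ lies in the convex hull of the support, so
candidate placements are the lattice points in the support's bounding box.
Exact ties go to the lexicographically smallest candidate, making results
deterministic. For a uniform disk the analytic optimum is at the centre
with $EE = 2r/3 = 86.67$ px; the grid observer reaches this within 1% at
strides of 2 px and below, which is the documented convergence check for
the stride discretisation (a tractability choice — per-pixel evaluation is
the stride-1 limit).

## Sampling efficiency: the decay model

Across a participant's trials, the minimal expected error decays roughly
exponentially with the number of dots $s$ on screen (the free dot is $s =
1$):

$$\widehat{EE}(s) = (EE_1 - EE_\infty)(1 - \alpha)^{s-1} + EE_\infty,$$

with the baseline $EE_1$ fixed to the mean first-dot expected error over
the participant's trials. The extraction rate $\alpha \in (0,1)$ is the
per-sample proportional reduction of uncertainty — the efficiency index —
and $EE_\infty > 0$ is the floor imposed by task geometry. One fit pools
all of a participant's trials and conditions, because the baseline is
defined as the average over the whole session; participants with missing
trials are averaged over the trials they have.

Least squares is used, but not as a 2-D search: for fixed $\alpha$ the
objective is quadratic in $EE_\infty$, so the asymptote has a closed-form
profile solution (clipped to $(10^{-6}, EE_1)$) and $\alpha$ is found by a
coarse grid (step 0.01) followed by `optimize()` refinement at tolerance
$10^{-10}$, within $(10^{-6}, 1 - 10^{-6})$. This is better conditioned
than a bivariate multistart and cannot be trapped between grid cells of a
2-D lattice. A flat objective (e.g. constant trajectories) returns
$\alpha$ at its lower bound. Noiseless model data is recovered to optimiser
precision; with 5 px Gaussian noise on 60 trials the rate is recovered
within $\pm 0.05$.

## Optimal stopping

Replacing the error term of the score rule with the predicted expected
error gives the expected value of stopping after $s$ paid samples:

$$\widehat{EV}(s) = R_0 - s\,\eta_s - \eta_e\,\widehat{EE}(s + 1).$$

Indexing deserves a note: the score charges $s$ *paid* touches, while the
decay model counts *dots on screen* starting at the free dot. We take
$EV$ as a function of paid samples, so the screen shows $s + 1$ dots and
the decay term uses exponent $s$. This preserves both the free initial
dot and the per-touch charge. The curve is evaluated for $s = 0..s_{max}$,
where $s_{max}$ is the smallest count at which the decay term is within
0.1% of the asymptote (capped at 60); beyond that point $EV$ falls
linearly and the softmax tail mass is negligible.

The stopping distribution is a unit-temperature softmax over the $EV$
values in raw credits, computed with max-subtraction for overflow safety.
The optimal count $s^\star$ is the smallest argmax of the curve (equal to
the softmax mode). $s^\star$ is invariant to $R_0$ (an additive shift) and
weakly decreasing in $\eta_s$. Against intuition, $s^\star$ is *not*
increasing in $\alpha$ beyond small rates: the marginal gain of sample $s$
is $\eta_e\,\alpha(1-\alpha)^s (EE_1 - EE_\infty)$, so faster extraction
exhausts the information sooner and brings the optimum earlier; the test
suite pins the empirically verified direction (weakly decreasing over
$\alpha \in [0.1, 0.95]$ at both cost levels). Over- or under-sampling is
the participant-by-condition difference between the mean number of paid
samples and $s^\star$.

## Behavioural markers and statistics

The inter-sampling interval (ISI) is the mean time between consecutive
paid touches; trials with fewer than two paid touches contribute nothing.
Subjective uncertainty in the passive task is the sign-flipped z-score of
a participant's confidence ratings, computed within participant with the
sample SD — the conservative reading when the alternative (cohort-wide
z-scoring) is not specified.

Affective burden is the first principal component of the standardised
depression (BDI-II) and anxiety (HADS-A) scores, oriented positively with
both. For two standardised variables PC1 carries $(1 + |r|)/2$ of the
variance, which the tests use as an analytic oracle; at $r = 0.68$ this is
84%.

Group contrasts use permutation tests on per-participant summaries
(difference of means, two-sided p from label permutations with the
add-one correction), a desk-scale substitute for cohort-level
mixed-effects models whose coefficients depend on the real cohort and are
not reproduction targets. Brain-behaviour style correlations use partial
Spearman correlations: all variables rank-transformed, the two variables
of interest residualised on the covariates by least squares, Pearson
correlation of the residuals, and a permutation p-value; with one
covariate this equals the textbook recursive partial-correlation formula
on ranks, which the tests check to $10^{-12}$. Families of correlations
reported together are held to the Bonferroni threshold $0.05/k$.
Complete-case handling is used throughout.

## The synthetic cohort generator

The generator exists so that every pipeline stage is testable without the
study's raw data; its defaults are the study conditions: 27 controls and
27 SCI participants, 4 blocks x 15 active trials, 100 passive
presentations, questionnaire means/SDs from the published demographics
table, and a depression-anxiety correlation of 0.68 (the value implied by
the 84% shared-variance result).

An agent touches at lognormal intervals (lognormal for positivity and the
right skew of human inter-response times; the participant-level mean ISI
is drawn around 1.7 s for controls, SD 0.2 s). With probability $q$ a
touch is *informative*: from a coarse proposal set (feasible centres
displaced by up to $\approx r$, so the circle boundary can cut through
small feasible sets), the agent picks the touch minimising the expected
one-step-ahead uncertainty under an area-scaling approximation,

$$E[EE' \mid \sigma] \approx EE \left(p_{in}^{3/2} + p_{out}^{3/2}\right),$$

where $p_{in}$ is the posterior probability that the touch lands inside
the circle. The approximation is exact for sets that shrink
self-similarly ($EE \propto \sqrt{A}$ for a fixed shape) and makes the
greedy policy and the stop rule cheap enough for cohort-scale simulation;
the policy's one-step reduction is verified against random touching in
the tests. Otherwise the touch is uniform over the field.

Stopping is a myopic expected-value rule, not the softmax benchmark: the
agent stops when $\eta_e(EE - E[EE']) - \eta_s$ falls below its
`stop_threshold` (except with a small lapse probability, default 0.05).
This separates over/under-sampling from efficiency by construction: the
SCI shift is applied to the ISI mean (-0.4 s) and the stop threshold (-5
credits), both 2 between-subject SDs, with identical policy quality $q =
0.75$, reproducing the faster-but-equally-efficient group structure. The
hidden centre is drawn uniformly over the prior support, snapped to the
observer lattice so the feasible set can never empty out; placement is the
final $\lambda^\star$ plus optional Gaussian motor jitter (default 0).

Inside the simulator, expected errors are evaluated with point caps
(support thinned to 400 points, candidate lattice coarsened to 400): on
the 8 px grid this costs under 2 px against the exact observer on average
(verified in the tests) at a small fraction of the runtime. Analysis-side
functions (`ee_trajectory()`, `expected_error_map()`) always use the full
grid.

### Passive offers

Passive offers cross five experimentally defined uncertainty bands
(16.3–24.4, 27.1–38.9, 57.5–58.9, 73.33–74.18, 91.9–93.3 px) with four
rewards (40, 65, 90, 115 credits); each of the 20 types is presented five
times. A configuration is four purple and four white dots consistent with
one hidden-circle realisation. Because two of the bands are under 1.5 px
wide, plain rejection sampling is hopeless; instead each attempt fixes a
random geometry and bisects a single deterministic scale knob:

* lower four bands: the purple dots' radial spread — more spread means a
  smaller disk intersection and lower uncertainty, spanning roughly 15 px
  up to the single-dot ceiling of $2r/3 \approx 86.7$ px;
* top band: the spread mechanism cannot exceed that ceiling (the feasible
  set of any purple dot is contained in a disk of radius $r$, and white
  dots cannot carve a hole around the true centre). Instead, two white
  dots placed just outside the circle on opposite sides pinch the
  feasible disk into two lobes; uncertainty then *exceeds* the ceiling
  and decreases as the pinch distance grows, so it can be bisected onto
  91.9–93.3 px. The remaining two white dots sit near the field edge,
  outside the feasible region.

Every accepted configuration's uncertainty is the ideal observer's
`EE_opt` at the configured stride, and the tests re-verify each band
membership independently. Confidence ratings and accept/reject choices
are then simulated per participant (linear-in-EE confidence with unit
noise on a 1–10 scale; logistic acceptance increasing in reward and
decreasing in uncertainty).

## Pipeline and reproducibility

`run_pipeline()` executes simulate, observe, fit, optimality, metrics and
report stages with a single seed, writing `trials.csv`, `samples.csv`,
`questionnaires.csv`, `passive.csv`, `ee_trajectories.csv`,
`efficiency.csv`, `optimality.csv`, `metrics.csv` and
`stats_report.json`. Numeric output is serialised at six significant
digits so repeated runs are byte-identical; the report records the seed
and a hash of the configuration. Stage switches isolate stages (e.g.
disabling the passive stage removes only passive outputs); a stage
failure aborts with the stage's name. By default the observe stage reuses
the observer replay computed during simulation; `trajectories = "exact"`
recomputes every trajectory on the full grid.

## Problem sizes and limitations

The test suite runs the observer checks on the 8 px grid (about 8,300
prior points), the convergence check at 2 and 1 px, and the cohort-level
recovery study as 100 replicates of 27 + 27 agents with 3 trials per
block on the 8 px grid — enough for participant-level contrasts at 2-SD
effects, which depend on between-agent variability far more than on
trials per agent. The acceptance script's PCA target uses 100,000
simulated score pairs.

The generator emulates the statistical structure the analysis assumes,
not the participants: there is no motor noise in touching, no learning or
fatigue across blocks, inter-touch intervals are i.i.d. within trial, the
confidence and acceptance models are simple link functions, and
questionnaire scores are rounded truncated Gaussians rather than item
sums. Passing recovery tests therefore shows that the pipeline inverts
its own generative assumptions at the study's size — it does not validate
those assumptions against real behaviour. Real-data caveats documented
above (the top passive band lying above the single-dot ceiling; softmax
stopping in raw credit units implying near-deterministic stopping for
large EV gaps) are inherent to the published task description and left
as-is.
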