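---
title: "Decomposing spatial cueing effects with the diffusion decision model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing spatial cueing effects with the diffusion decision model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gazecue)
```

## The scientific question

In a non-predictive localisation cueing task, a centrally presented face
gazes left or right, and shortly afterwards a target appears on the left
or right of the screen; the participant reports the target's side. People
respond faster when the target appears at the gazed-at (cued) location
than at the gazed-away-from (miscued) location. The mean RT difference —
the *cueing magnitude* — is robust, but it does not say *why* responses
are faster. At least three mechanisms could produce it:

* **attentional orienting** — attention must move to the target before
  processing begins, so miscued targets pay a reorienting time cost that
  is outside the decision process;
* **a transient processing burst** — a brief initial allocation of
  processing resources toward the cued side that heads-starts the
  decision and then dissipates;
* **sustained preferential processing** — persistently more efficient
  evidence extraction at the cued location for the duration of the
  decision.

The diffusion decision model (DDM) separates these. A two-choice decision
is modelled as noisy evidence accumulating from a starting point `z`
(a fraction of the boundary separation `a`) at mean rate `v` (the drift)
until it is absorbed at one of two boundaries; the measured RT adds a
non-decision component `t0` for encoding and motor time. The three
mechanisms map onto condition differences in `t0` (orienting cost: larger
`t0` when miscued), `z` (transient burst: start point shifted toward the
boundary for the cued side), and `v` (sustained boost: larger drift when
cued). `a` indexes response caution and is held equal across conditions
throughout: cue validity is unpredictable trial-to-trial, so there is no
opportunity to adjust caution by condition.

The package implements a three-stage analysis: (1) descriptive cueing
magnitudes after standard exclusions, (2) individual-level comparison of
eight constrained DDM variants by BIC/AIC, and (3) hierarchical Bayesian
estimation of the group-level cued-minus-miscued difference in each
parameter.

## The likelihood

The model is the *simple* DDM: no between-trial variability in any
parameter. The defective first-passage-time density of each boundary is
evaluated with the standard pair of series expansions (a small-time and a
large-time form), choosing per evaluation whichever needs fewer terms for
a truncation error below 1e-9. The two defective densities integrate to
the closed-form absorption probabilities
`P(upper) = (1 - exp(-2 v a z / s^2)) / (1 - exp(-2 v a / s^2))`,
which the test suite verifies by quadrature and against an independent
Euler–Maruyama simulation.

Units and scaling: RTs are modelled in **seconds** and the diffusion
coefficient is fixed at `s = 1`. The scale is a pure convention (the
legacy `s = 0.1` parameterisation is available through the `s` argument
everywhere), but it must be stated because raw likelihoods, and hence raw
BIC/AIC values, depend on it: with densities in 1/seconds, per-trial log
densities are typically positive and raw information criteria come out
negative for well-fit RT data, matching the sign and order of magnitude
this analysis tradition reports.

Boundary coding ties the likelihood to the design: the upper boundary is
the *correct* response on every trial. On cued trials the start point
toward the correct boundary is `z_c`; on miscued trials the same spatial
bias points away from the correct response, so the effective start point
is `1 - z_c`. Correctness and condition therefore fully determine which
defective density a trial contributes.

Each trial's log density is floored at −700 so that a response faster
than a proposed `t0` contributes a large negative constant rather than
−Inf; this keeps likelihood sums finite everywhere while leaving model
ranking intact.

## The eight model variants

Every variant shares `a` across conditions and constrains any condition
difference to the direction of a *positive* cueing effect:

| variant | t0 | z | v |
|---|---|---|---|
| simple | equal | 0.5 | equal |
| t0 | t0c < t0m | 0.5 | equal |
| z | equal | zc > 0.5, zm = 1 − zc | equal |
| v | equal | 0.5 | vc > vm |
| z-v | equal | free | vc > vm |
| t0-v | t0c < t0m | 0.5 | vc > vm |
| t0-z | t0c < t0m | free | equal |
| complex | t0c < t0m | free | vc > vm |

The inequalities are enforced *by construction* through the free-parameter
vector: nonnegative gaps `delta_t0` (with the base `t0` the cued value,
`t0m = t0 + delta_t0`) and `delta_v` (base `v` the miscued value,
`vc = v + delta_v`), and `z_c` bounded in `[0.5, 1)`. Strict inequalities
in the constraint table are implemented as closed gaps (`delta >= 0`):
the prior puts negligible mass exactly at zero, so the distinction is a
measure-zero boundary rather than a behavioural difference, and the
closed form avoids an awkward open-set parameter space. A consequence
worth noting is nesting: every variant can reproduce the simple model at
the gap = 0 / `z_c = 0.5` boundary, so the complex variant's maximum
likelihood must dominate all others up to sampler resolution — the test
suite asserts this with a 0.5 log-unit tolerance.

## Stage 2: individual-level estimation and model comparison

Each variant is fitted to each participant by differential-evolution
MCMC: `3k` chains (k = number of free parameters), proposals
`theta_i + gamma (theta_m - theta_n) + U(-jitter, jitter)` with
`gamma = 2.38 / sqrt(2k)` and jitter half-width 1e-4, Metropolis-accepted
on the log posterior. The full-scale configuration is 4,000 iterations
with 2,000 discarded as burn-in (`mcmc_config()`); a reduced preset
(`reduced_mcmc_config()`, 1,000 iterations / 500 burn-in, chains capped
at 12) exists for continuous-integration-scale runs, and the acceptance
checks use 1,500 / 500 without the chain cap so the maximum-likelihood
extraction of the six-parameter variant is adequately sampled.

Priors are truncated normals chosen to be wide relative to typical
localisation-task estimates — v ~ TN(2, 3) on [0, 10], a ~ TN(1.5, 1.5)
on [0.1, 5], t0 ~ TN(0.3, 0.3) on [0.03, 1] s, delta_t0 ~ TN(0, 0.2) on
[0, 1] s, z_c ~ TN(0.5, 0.2) on [0.5, 0.99], delta_v ~ TN(0, 2) on
[0, 10] — so the likelihood dominates the posterior and its maximum is
comfortably contained in it ("reasonably uninformed"). All are
overridable (`default_priors()`); none of these exact values is taken
from any external source.

Chains start at independent prior draws, re-drawn until *every* trial has
positive density. The re-draw matters: a chain initialised with `t0`
above the participant's fastest RT sits on the floored-likelihood
plateau, and differential-evolution proposals — scaled differences of
*other* chains — cannot rescue it once the remaining chains have
contracted, which shows up as split-Rhat far above 1. Initialisation is
the only place the data inform the starting values; the sampler itself
explores the full prior support.

The per-sample log likelihood is cached during sampling, and the
*maximum-likelihood* estimate is the retained sample with the highest
data likelihood (not the highest posterior), ties broken by first
occurrence in (chain, iteration) order. From it:
`BIC = k ln(n) − 2 max_log_lik` and `AIC = 2k − 2 max_log_lik`, with `n`
the participant's own post-exclusion trial count (the only coherent
choice for per-participant criteria; no external convention fixes it).
Scores become Akaike weights `w_i ∝ exp(−Δ_i/2)` after subtracting the
minimum score for numerical stability. Parameter-inclusion probabilities
sum the weights of the four variants in which a parameter varies (for
drift: v, t0-v, z-v, complex) against the four in which it does not.

Two small conventions: best-model ties break toward fewer free
parameters, then lexicographically; and the Bayes factor attached to the
simple-model-probability vs cueing-magnitude correlation uses the
Fisher-z likelihood of the observed correlation integrated over a
stretched-beta prior on rho (uniform for `kappa = 1`) against the point
null — a default-prior formulation chosen because no estimator is fixed
by the analysis tradition, exposed via the `kappa` argument and named in
the output.

## Stage 3: hierarchical estimation of group differences

Stage 3 asks a different question: not which constrained variant wins,
but whether the *group-level* cued-minus-miscued difference in one target
parameter is credibly non-zero. Constraining that target at the
individual level would beg the question — every individual difference
would be forced positive (or negative), dragging the group estimate away
from zero even under a null. So, per target θ in {t0, z, v}, one model is
fitted in which:

* the target's cued and miscued values are free per participant, each
  drawn from its own condition-specific truncated-normal group
  distribution whose means are *unconstrained in order*;
* the non-target directional parameters keep their base + nonnegative-gap
  construction, with group distributions truncated at the constraint
  boundary;
* `a` is shared across conditions under a single group distribution.

Group means get wide truncated-normal hyperpriors over each parameter's
domain and group SDs get half-normal scale priors (documented in
`hierarchical_spec()`, all visible in the returned table); these are the
package's own weakly-informative choices. The sampler is blocked
DE-MCMC: per iteration, each participant's block is updated conditional
on the group level, then each (mu_j, sigma_j) pair conditional on the
individuals. Early versions updated the whole group level as one
12-to-14-dimensional DE block; acceptance collapsed to a few percent and
chains never coalesced, so the per-pair blocking is a deliberate
numerical choice, not an optimisation.

The reported quantity is the posterior of `Δ = mu_θ,cued − mu_θ,miscued`
with an equal-tailed 95% credible interval (the highest-density interval
is available behind the `hdi` flag; "95% credible interval" alone does
not pin the variant, and equal-tailed is the more reproducible choice).
The theoretically plausible direction is negative for t0 and positive
for z and v, and the summary reports the posterior mass on that side.

## The synthetic-data generator

`generate_cohort()` produces cohorts whose cued/miscued behaviour comes
from a *known* mechanism, which is what makes every pipeline stage
testable without external data. Defaults state a world consistent with
the localisation gaze-cueing literature: base parameters v = 3, a = 1.2,
t0 = 0.30 s (s = 1) give accuracies of 94–99% and mean RTs of a few
hundred milliseconds; cueing effects of tens of milliseconds; a
mechanism mixture of 0.55 t0 / 0.25 z / 0.05 v / 0.10 simple / 0.05 t0-z
echoing the qualitative prevalence of orienting over transient over
sustained processing accounts; cohort presets matching the shapes of the
three analysed data sets (41×240, 50×~256, 71×~1,500 trials per
participant); and optional contaminant RTs outside [100, 5000] ms to
exercise the exclusion filters. Trials come from an Euler–Maruyama
simulation (default step 1e-4 s) with a Brownian-bridge boundary-crossing
correction each step; without the correction, discrete boundary checking
inflates RTs and biases absorption probabilities by several binomial
standard errors at n = 1e5, which is visible against the analytic
densities.

What a green test on this generator does *not* establish: real data
contain contaminant processes beyond uniform fast/slow outliers, RT
autocorrelation, fatigue and practice drifts, and moderator structure
(SOA, emotional expression), none of which are emulated. Recovery results
here certify the pipeline's internal consistency, not the truth of any
mechanism in real cohorts.

## Stage 1 conventions and edge cases

Exclusions follow the stated rules literally: RTs *below* 100 ms or
*above* 5,000 ms are removed (exactly 100 and 5000 are kept), then
participants under 80% accuracy — computed over their RT-filtered trials,
the base set not being otherwise specified — are removed entirely.
Cueing magnitudes default to correct trials only (conventional RT
practice; with accuracies above 94% the choice moves means by under
1 ms, and it is a flag). The standardised mean change is the
change-score-standardised variant — mean change divided by the SD of the
per-participant change scores, times the small-sample correction
`1 − 3/(4(n−1)−1)` — with a raw-score-standardised alternative behind
`method = "raw"`; the variant used is recorded in the output because
published SMC values in this literature are frequently not reproducible
from printed summaries, and ours should be.

## Numerical choices, in one place

* series truncation error 1e-9; branch chosen per evaluation by
  predicted term count, and the two branches agree to 1e-8 at the switch;
* log-density floor −700 (configurable), applied per trial;
* simulator step 1e-4 s with bridge correction; unabsorbed walks are
  cut off at 100 s of decision time (unreachable for sane parameters);
* DE gamma `2.38/sqrt(2k)` per block, jitter 1e-4; donor chains distinct
  from each other and the target;
* group-SD support starts at 1e-4 to keep truncated-normal terms finite;
* `rtnorm` draws are clamped to their truncation interval, guarding the
  vanishing-mass case where inverse-CDF sampling can otherwise step
  outside;
* split-Rhat is computed on half-split retained chains; fits with any
  value above 1.1 are flagged by the pipeline, not silently included.

## Known limitations

Raw BIC/AIC magnitudes depend on the likelihood scale convention and are
not comparable across conventions — only differences within a
participant matter. The reduced MCMC presets trade tail-exploration for
speed; maximum-likelihood extraction from posterior samples is biased
slightly low for the richer variants at those settings (the 0.5 log-unit
dominance tolerance absorbs this). The hierarchical sampler reports
group-level split-Rhat but, at reduced settings, values up to ~1.3 occur;
inferences at full settings should check diagnostics. Moderator analyses
(SOA, emotion), arrow cues, inter-trial variability parameters and
collapsing-bound or conflict-accumulation variants are out of scope.
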