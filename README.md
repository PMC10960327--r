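# gazecue

Why do people respond faster to targets at locations another person's
eyes point toward? The *gaze cueing effect* — faster localisation of
targets at gazed-at (cued) than gazed-away-from (miscued) locations — is
one of the most robust findings in social attention, but a mean RT
difference alone cannot say which cognitive mechanism produces it.
`gazecue` decomposes the effect with the diffusion decision model (DDM):
evidence accumulates from a starting point `z` (fraction of the boundary
separation `a`) at drift rate `v` until a boundary is hit, plus a
non-decision time `t0`. The candidate mechanisms map onto condition
differences in

- `t0` — attentional orienting: miscued targets pay a reorienting time
  cost outside the decision;
- `z` — a transient processing burst toward the cued side that
  head-starts accumulation;
- `v` — sustained preferential processing of the cued location.

The package implements a three-stage pipeline for long-format trial
tables (participant, cue validity, response side, correctness, RT):

1. **Stage 1** — exclusions (RT < 100 ms or > 5,000 ms; participants
   under 80% accuracy) and per-participant cueing magnitudes
   (mean miscued − mean cued RT), with a bias-corrected standardised
   mean change.
2. **Stage 2** — eight DDM variants per participant, differing in which
   of `t0`, `z`, `v` may vary across conditions (always in the
   positive-effect direction; `a` always shared), fitted by
   differential-evolution MCMC over a Wiener first-passage-time
   likelihood; compared via BIC/AIC Akaike weights
   `w_i ∝ exp(−Δ_i/2)` and per-parameter inclusion probabilities
   (summed weight of the four variants where that parameter varies).
3. **Stage 3** — per target parameter, a constrained hierarchical
   Bayesian model with truncated-normal group distributions whose
   condition means are unconstrained in order, yielding the posterior of
   the group-level cued − miscued difference with a 95% credible
   interval.

A synthetic-data generator (`generate_cohort()`) produces cohorts from
known mechanisms — including presets matching the shapes of the three
published data sets the pipeline was built around — so every stage is
testable without any download. The likelihood core (adaptive small-/
large-time series for the first-passage density) is implemented in C++.

## Worked example

```r
library(gazecue)

prof <- generative_profile(n_participants = 6, trials_per_condition = 150,
                           mixture = c(t0 = 0.5, z = 0.3, simple = 0.2),
                           seed = 7, contaminant_fast = 0.01,
                           contaminant_slow = 0.005)
coh <- generate_cohort(prof)

ex <- apply_exclusions(coh$trials)
ex$report
#> <exclusion_report> 1800 trials in; 27 removed by RT window; 0 removed
#> with 0 accuracy-excluded participant(s); 1773 trials analysed

cueing_magnitudes(ex$trials)
#> <cueing_summary> 6 participants; mean magnitude 51.5 ms (SD 27.3);
#> 6/6 positive; SMC (change) = 1.588
```

Every planted contaminant RT fell outside the [100, 5000] ms window and
was removed; all six synthetic participants show the positive cueing
effect their generating mechanisms imply. Fitting the eight variants to
one participant (this one was generated from the no-difference
mechanism):

```r
one <- ex$trials[ex$trials$participant == "p01", ]
fits <- lapply(model_catalogue(), function(sp)
  fit_participant(one, sp, config = reduced_mcmc_config(seed = 42)))
round(model_weights(sapply(fits, `[[`, "bic")), 3)
#>  simple      t0       z       v     z-v    t0-v    t0-z complex
#>   0.836   0.047   0.046   0.061   0.003   0.003   0.003   0.000

round(inclusion_probabilities(model_weights(sapply(fits, `[[`, "bic"))), 3)
#>    t0     z     v
#> 0.053 0.052 0.067

fits$simple
#> <ddm_fit> model 'simple': 297 trials, k = 3; max log-lik 158.57;
#> BIC -300.06, AIC -311.15; max split-Rhat 1.019
```

BIC puts 84% of the weight on the no-difference model and every
parameter's inclusion probability is near zero — the fit recovers the
generating truth. For a cohort, `run_stage2()` writes the
per-participant selection table, the inclusion table and the collapsed
cohort summary; `run_stage3()` (or `fit_hierarchical()` +
`group_difference()`) reports whether `t0`, `z` or `v` differs credibly
across conditions at the group level.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the installed package end to end: it generates a cohort with the
shape of the smallest published data set, applies the Stage 1
exclusions and descriptives, fits the eight-variant catalogue to a
participant subset at reduced MCMC settings, runs the Stage 3
hierarchical model for the non-decision-time target, logs the
intermediate summaries, and writes the JSON report to `--out`.

## Documentation

The methods vignette (`vignettes/gazecue-methods.Rmd`) describes the
likelihood and its numerical choices, the constraint construction for
the eight variants, sampler settings and priors, the hierarchical model,
what the synthetic generator does and does not emulate, and known
limitations.
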