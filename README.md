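# microdrift

Quantifying the contribution of **selection** versus **ecological drift**
to community assembly in dispersal-limited, replicated microbial time
series.

## The problem

In closed microcosms inoculated from one source community, dispersal and
diversification are excluded, so only two assembly processes remain.
Selection — deterministic fitness differences — drives replicate
microcosms towards the same composition: their pairwise similarity rises
over time and its spread shrinks. Drift — fitness-independent stochastic
birth and death — drives replicates apart: similarity falls and its spread
grows. `microdrift` turns this contrast into an estimator. It is written
for microbial ecologists running replicated time-series experiments
(dilution-disturbance microcosms, serial-transfer lines, chemostats) who
want a process-level verdict per experimental group.

## The method

For replicate pairs $p$ observed on day $t$, the community similarity
$y$ (Bray–Curtis or Sørensen) is modelled with a hierarchical Bayesian
*distributional* regression — fixed effects on both distribution
parameters:

$$y \sim \mathcal{N}\big(\mu,\ \sigma\big),\qquad
\mu = x^\top\beta + b_p,\qquad
\log\sigma = z^\top\gamma,\qquad b_p \sim \mathcal{N}(0,\tau)$$

where $x$ holds centred day × disturbance × carrying-capacity interactions,
$z$ holds centred day × disturbance, and $b_p$ is a random intercept per
replicate comparison. Posterior daily slopes per group,
$\Delta\mu/\text{day}$ and $\Delta\sigma/\text{day}$, feed the quadrant
rule:

| $\Delta\mu \ge 0$, $\Delta\sigma < 0$ | $\Delta\mu < 0$, $\Delta\sigma > 0$ | otherwise |
|---|---|---|
| **selection** | **drift** | **mixed** |

The package also ships a stochastic microcosm simulator (per-taxon logistic
growth with washout, Poisson demographic drift, optional environmental
noise, pulsed 1:50 or continuous dilution, crossover designs, multinomial
read sampling), multi-rarefaction normalisation (averaging 1,000
subsamples of 10,000 reads), Hill diversity, PCoA and PERMANOVA support,
and PSIS-LOO/WAIC predictive model comparison.

## Worked example

Simulate a strong-selection benchmark (pulsed 1:50 dilutions, dispersed
growth rates), normalise, build the replicate-similarity series, fit the
model and classify:

```r
library(microdrift)

sim  <- simulate_scenario("selection_disturbed", seed = 5)
rare <- rarefy_mean(sim$counts, depth = 10000, n_rep = 100, seed = 5)
rec  <- replicate_similarity_series(rare, sim$metadata, index = "bray_curtis")

dat  <- prepare_model_data(rec, period = 1,
                           spec = model_spec(~ centered_day, ~ centered_day))
fit  <- fit_distributional_model(
  dat, mcmc_config(chains = 2, iterations_per_chain = 2500,
                   warmup = 500, seed = 5))
calls <- assembly_calls(derive_group_slopes(fit))
assembly_report(calls)
```

```
Community assembly calls (quadrant rule on posterior mean slopes)
------------------------------------------------------------------
group             d_mu/day   d_sigma/day  label         P(label)
all               0.001114       -0.3149  selection         1.00
```

Replicate similarity rises by ~0.0011 per day (posterior SD 0.00045) while
its log-scale standard deviation falls by 0.31 per day: the replicates are
converging and tightening, so assembly is labelled selection, with the
whole posterior mass in the selection quadrant (`p_selection = 1.00`).
`plot_similarity_series(rec)` and `plot_assembly_quadrants(calls)` draw the
trajectories and the slope-quadrant plane; `tidy(fit)` and `glance(fit)`
give broom-style summaries. A full multi-regime analysis is one call:
`run_pipeline(pipeline_config(seed = 1))` (stages: simulate → normalize →
similarity → fit → classify → report), also available from a shell via
`inst/scripts/microdrift-pipeline.R`.

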