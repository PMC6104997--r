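# traitds — trait-based multi-species distance sampling

`traitds` estimates how plant traits shape the detectability of understorey
species in line-transect surveys. It was built for the situation faced by
invasive-plant surveyors in dense tropical forest: many exotic species, most
of them detected only a handful of times, and a need to know how far from
the transect line an individual of a given species can still be found. By
pooling all species in one hierarchical model and letting detectability
depend on species-level traits (plant height, leaf size, leaf shape), the
model borrows strength across species and yields detectability estimates
even for sparsely detected ones — the information needed to plan search
effort.

## The model

Each detection is an individual of species *i* seen at site *j* at
perpendicular distance *d* (m) from the transect. Detection follows a
half-normal function, perfect on the line and truncated at *w* = 10 m:

    g_ij(d) = exp( -d² / (2 σ_ij²) ),   0 ≤ d ≤ w

The scale parameter σ (m) — how slowly detectability decays with distance —
is modelled on the log scale as a regression on centered species traits,
with per-site intercepts and a species random effect:

    log σ_ij = b0_j + bS·S_i + bS2·S_i² + bA·L_i + bA2·L_i² + bH·H_i + ε_i
    ε_i ~ Normal(0, sd_eps)

where S is leaf shape (the McLellan–Endler dissection index,
perimeter / √area), L is leaf size (√ leaf area, cm), and H is plant height
(m). The likelihood is the conditional distance-sampling likelihood: each
observed distance contributes g(d) / ∫₀ʷ g(u) du, with the closed-form
half-normal integral σ·√(π/2)·erf(w/(σ√2)). Inference is Bayesian —
Normal(0, 1000) priors on all fixed effects, Uniform(0, 10) on sd_eps —
via an adaptive Metropolis-within-Gibbs sampler run as 3 chains × 10,000
iterations (5,000 burn-in), with convergence judged by the Gelman-Rubin
R-hat < 1.1 rule. Species detected fewer than 5 times are excluded before
fitting.

Supporting modules compute the leaf traits from outlines (exact polygons or
raster masks), contrast traits between species groups with Welch's t-test,
simulate complete surveys from known truth for parameter-recovery
experiments, and read/write the detection and trait CSV formats.

## Worked example

```r
library(traitds)

truth   <- default_truth(seed = 7)          # 4 sites, 25 species
records <- simulate_survey(truth)           # ~1650 detections
fit     <- fit_detectability(records, truth$traits,
                             mcmc = mcmc_config(seed = 7))
print(fit)
```

```
Trait-based hierarchical distance-sampling fit
  1657 detections, 25 species, 4 sites; truncation 10 m
  3 chains x 10000 iterations (burn-in 5000)
  max R-hat (fixed effects + sd): 1.012

Posterior means (fixed effects):
      b0[Bali] b0[Baturraden]    b0[Cibodas]   b0[Kuningan]             bS
         1.324          1.151          1.509          0.960          0.019
           bS2             bH             bA            bA2         sd_eps
         0.003          0.101          0.061          0.004          0.134
```

The site intercepts say that a species with average traits has
σ ≈ e^1.5 ≈ 4.5 m at Cibodas but only e^0.96 ≈ 2.6 m at Kuningan — the same
plant is visible from roughly twice as far at the first site. The positive
height coefficient `bH` (posterior mean 0.101, generating value 0.136)
means taller species keep high detectability further from the line.
`summary(fit)` adds posterior sds, 95% credible intervals and per-parameter
R-hat; all R-hat values here are below 1.02, comfortably inside the < 1.1
convergence rule. Predictions for particular species, sites and distances:

```r
predict(fit, data.frame(species_id = "sp01", site_id = "Cibodas",
                        distance_m = c(2, 5, 10)))
#   species_id site_id distance_m    sigma detection_prob
# 1       sp01 Cibodas          2 12.02931      0.9862738
# 2       sp01 Cibodas          5 12.02931      0.9172428
# 3       sp01 Cibodas         10 12.02931      0.7078435
```

`plot(fit)` draws the per-species detectability curves,
`simulate(fit)` generates posterior-predictive distance sets, and
`run_pipeline()` performs the whole CSV-in → CSV/JSON-out analysis in one
call.

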