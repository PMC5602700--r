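# islandcall

Acoustic point-count surveys are the workhorse for monitoring island bird
communities: automated recorders capture short morning recordings across
land-use strata, analysts count species-specific vocalizations in
spectrograms, and occupancy models separate *where a species lives* from
*how often it is detected*.  `islandcall` implements that whole workflow for
a nine-species island passerine community (two natives, seven non-natives)
surveyed at 15 sites stratified over agriculture, mixed and forest land
use — three 5-minute recordings per morning around sunrise on three
consecutive mornings (45 site-mornings, 675 recorded minutes) — and ships a
ground-truth synthetic data generator so every stage is testable without
field data.

The stages, each an exported module and an `analysis/` driver:

1. **Synthetic survey generation** — latent occupancy `z[i,s] ~ Bern(ψ_s)`,
   detection `logit p = α_s + β^C_s·canopy_i + β^P_s[period_j] ± c·u_ij`
   with a shared survey-activity variable `u` that couples the guilds
   (non-natives up, natives down), and per-survey vocal element streams
   with species-specific call structure.
2. **Call segmentation** — unique-call counting under per-species rules:
   a 2-s inter-call gap for the kingfisher, 1-s for the myna,
   opening-large-coo markers for the doves, per-element counting for the
   rest.
3. **Habitat analysis** — per-species ANOVA of calls per 5-minute survey
   across strata (one-way by default, site-nested optional) with Tukey HSD
   pairwise comparisons.
4. **Co-detection structure** — hierarchical clustering of species by the
   correlation of their per-survey detection profiles, and logistic
   regression (native IRLS implementation) of native detection on
   concurrent non-native richness.
5. **Multi-species occupancy model** — species fixed effects on ψ,
   community hyperparameters on all detection parameters, canopy + survey
   period as detection covariates; fitted by a Metropolis-within-Gibbs
   sampler written in C++ (exact Gibbs for the latent state and ψ), three
   chains of 10,000 iterations, burn-in 5,000, thinning 3, convergence by
   Gelman–Rubin R̂ < 1.1.

## Worked example

The numbered drivers run the full study on the default synthetic survey
(seed 2017) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_segment.R
Rscript analysis/03_habitat.R
Rscript analysis/04_cooccurrence.R
Rscript analysis/05_occupancy.R
```

Stage 2 verifies the segmentation round trip — every one of the 1,215
survey × species cells reproduces the generator's intended call count
exactly — and tallies 13,330 silvereye and 6,969 bulbul calls against 55
kingfisher and 59 fruit-dove calls, the natives being the rarest callers.
Stage 3 finds the generated habitat structure: myna (F = 13.2,
p = 5.8e-06), waxbill (F = 15.0) and zebra dove (F = 9.6) significantly
most active in agriculture, kingfisher and firetail with no habitat
association.  Stage 4 restricts to the six sites where all nine species
were detected and recovers the two-guild structure exactly:

```
Co-detection clustering (correlation distance, average linkage)
  group 1: kingfisher, fruit_dove
  group 2: myna, silvereye, waxbill, firetail, jungle_fowl, zebra_dove, bulbul
Logistic regression: detection of 'kingfisher' ~ non-native richness (n = 54)
  slope = -0.865 (SE 0.2261), z = -3.83, p = 0.0001299
```

— native detection odds fall by a factor of ~2.4 for each additional
non-native species calling in the same 5-minute survey.  Stage 5 fits the
occupancy model at the standard protocol and prints, per species, posterior
occupancy with 95% credible interval, naive occupancy and mean detection
probability:

```
convergence: max R-hat = 1.0085 over 53 model parameters (converged, < 1.1)
  kingfisher   psi = 0.72 [0.49, 0.91]  naive = 0.73  p(det) = 0.36
  zebra_dove   psi = 0.94 [0.80, 1.00]  naive = 1.00  p(det) = 0.69  [canopy]
  myna         psi = 0.88 [0.70, 0.99]  naive = 0.93  p(det) = 0.61  [canopy]
  ...
```

The `[canopy]` flag marks species whose canopy slope's 95% credible
interval excludes zero — here the species generated with strongly negative
canopy effects, i.e. the agriculture-associated non-natives.  Natives show
the lowest detection probabilities, the pattern that motivates separating
detection from occupancy in the first place.

`vignettes/island-occupancy-methods.Rmd` documents the model, the
generator's assumptions, all tunable parameters and the validation
strategy.

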