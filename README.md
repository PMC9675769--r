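# camtrapdiel

Diel activity analysis for tropical camera-trap mammal communities.

Camera-trap networks photograph ground-dwelling mammals around the clock,
and the timestamps carry a community-level signal: *when* each species is
active, and whether that schedule is shaped by thermoregulation (larger
animals shifting into the cooler night), by predators tracking prey
(bottom-up), or by prey avoiding predators (top-down). `camtrapdiel` is for
ecologists who have multi-site detection tables (site, camera, species,
timestamp) plus species traits (body mass, fractional diet, forest
stratum) and want the full analysis chain:

1. **Solar geometry** — sunrise/sunset (altitude −0.833°) and nautical
   dawn/dusk (−12°) per site and date; classification of every event as
   day / twilight / night; *double anchoring* of event times onto a circle
   where sunrise is always π/2 and sunset 3π/2, making activity comparable
   across sites and seasons.
2. **Independent events** — species filters (> 75 g, terrestrial or
   scansorial), burst collapsing (> 1 h rule per species × camera), guild
   assignment at the ≥ 80% diet thresholds, 20 kg size classes.
3. **Diel multinomial model** — with day as reference and protected-area
   random intercepts,

   log(p_night/p_day) = xᵀβₙ + bₙ,ₐ, log(p_twilight/p_day) = xᵀβₜ + bₜ,ₐ,
   bₐ ~ N(0, σ²),

   fitted by Laplace-approximated maximum likelihood with an exact analytic
   gradient; candidate formulas {1, mass, guild, mass + guild,
   mass × guild} ranked by AIC (ΔAIC < 2 = equal support); probability
   predictions over each guild's mass range with simulation-based 95% CIs.
4. **Coupling GLMM** — Poisson mixed model of one group's sun-anchored
   hourly counts on another's (`lme4`), over areas where large carnivores
   occur; a 95% CI above / below zero reads as bottom-up / top-down.
5. **Activity overlap** — von Mises kernel densities (Taylor plug-in
   bandwidth), overlap coefficients Dhat1 (< 75 events per group) or Dhat4
   (≥ 75), 500-iteration smoothed-bootstrap CIs, and a randomisation
   probability that the observed overlap arose by chance.
6. **Synthetic generator** — multi-site detection streams with known
   ground truth (guild-specific mass–nocturnality slopes,
   latitude-dependent photoperiod, photo bursts, tunable predator–prey
   coupling), so every stage is testable without field data.

## Worked example

The repository is organised as a numbered workflow under `analysis/`
(synthetic data stand in for a survey; swap in your own CSVs to analyse
real data):

```sh
Rscript analysis/01_simulate.R    # community + detection stream -> results/synthetic/
Rscript analysis/02_events.R     # filters + 1 h rule + solar annotation -> results/events.csv
Rscript analysis/03_diel_model.R # candidate multinomial fits + predictions
Rscript analysis/04_coupling.R   # pairwise Poisson GLMM suite
Rscript analysis/05_overlap.R    # per-area overlap with bootstrap + null test
```

Output from a run (seed 42; 4 areas × 40 cameras × 30 days, 18 species):

```
detections: 4002 -> after species filter: 4002 -> independent events: 1977
AIC ranking (best first): mass_by_guild dAIC=0; mass_plus_guild dAIC=106; ...
night-equation mass slopes (per ln g): carnivore -0.357 +/- 0.121;
  herbivore 0.282 +/- 0.121; insectivore 0.28 +/- 0.117; omnivore -0.214 +/- 0.081
largest herbivore (27.0 kg, p_night = 0.51) is 2.3 times more likely
  nocturnal than the smallest (0.28 kg, p_night = 0.22)
  large herbivore ~ large carnivore: beta = 0.074 [0.031, 0.116] -> bottom_up
overlap suite: 30 area x pair estimates (26 skipped below the 25-event minimum)
vs large carnivores: Dhat 0.61-0.94 (median 0.84), p_null < 0.05 in 13/23
```

Read: the interaction model wins decisively (ΔAIC ≥ 106 to the runner-up);
the fitted night-equation slopes recover the generator's ground truth
(herbivores and insectivores more nocturnal with mass, carnivores and
omnivores less — the generating slopes are ±0.8/ln 10 ≈ ±0.35 per ln g);
the heaviest herbivore on the simulated mass range is 2.3× more likely to
be nocturnal than the lightest; and large-carnivore activity is positively
coupled to herbivore activity (bottom-up), with high per-area overlap.

In code, the same chain is:

```r
library(camtrapdiel)
ev   <- join_traits(independent_events(filter_species(detections, traits)), traits)
fits <- fit_candidate_set(ev)           # 5 candidate formulas
select_model(fits)                      # AIC ranking
best <- fits$mass_by_guild
predict_probabilities(best, "herbivore", mass_g = c(240, 210000))
run_pairwise_suite(ev)                  # coupling GLMMs
run_overlap_suite(ev, seed = 1)         # Dhat + bootstrap CI + p_null
```

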