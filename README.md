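# dolphinCR

Estimation of density, abundance and survival for coastal common
bottlenose dolphin (*Tursiops truncatus*) populations from
photo-identification capture-recapture surveys, together with
satellite-telemetry home-range and hot spot analysis. The package targets
the kind of bay/sound/estuary study in which boat-based photo-ID surveys
follow a robust design (closed primary periods of repeated secondary
occasions, open between primaries) and a subset of animals carries
Argos-linked tags.

## What it computes

**Spatially-explicit robust-design capture-recapture.** Marked-animal
detections are modelled on a discretized habitat mask (1-km water cells
with Inshore / Island / Offshore stratum labels). Each individual — real
or data-augmented — has a latent activity center `s_it` on water with
prior intensity `exp(β₀ + β_Island·1[Island] + β_Offshore·1[Offshore])`,
Gaussian intensity-weighted dispersal between primaries, and per-secondary
detection probability

```
p_itk = p0 · exp( −d(s_it, effort)² / 2σ² )
```

where `d` is the distance to the nearest surveyed transect line. Sighting
locations are Gaussian around the center (scale σ, truncated to water).
Alive states follow entry (recruitment, absorbed by augmentation) and
per-interval survival φ_t; the posterior is sampled by a Metropolis-within-
Gibbs MCMC written in C++ (alive intervals are enumerated exactly). Density
is the realized number of marked activity centers per stratum area; it is
inflated to the total population by the marked proportion `1/p̂` and
extrapolated to abundance by configured stratum areas (`N_s = D_s·A_s` per
draw). Inter-primary survival draws are annualized as
`φ_ann = φ^(365.25/Δt)` and averaged by year.

**Photo-ID descriptives.** Capture histories, per-primary marked proportion
with binomial SE `√(p(1−p)/n)`, discovery curve, site-fidelity bins
(LSF 1–2, MSF 3–4, HSF ≥5 of 8 primaries), and group-size summaries.

**Telemetry ranges.** Argos fixes filtered to LC3/LC2 and one random fix
per animal-day; kernel utilization distributions on the habitat mask with
land masked and renormalized; ad hoc bandwidth selection (shrink from the
bivariate-normal reference while the 95% contour stays a single connected
region holding ≥95% of fixes); 95%/50% UD areas and maximum pairwise
distance.

**Hot spots.** Monthly 1-km² count grids; incremental spatial
autocorrelation (first local peak of the Global Moran's I z-score across
distance bands) selects the weight threshold; Getis-Ord Gi* with self
inclusion and a minimum of 8 neighbors per cell; hot cells at p < 0.05 and
p < 0.01 (no multiple-testing correction by default) and consecutive-month
overlap as intersection / union.

**Synthetic worlds.** `make_world()` / `simulate_population()` /
`simulate_captures()` / `simulate_telemetry()` generate data with the exact
structure the model assumes, with known truth, so parameter recovery is
testable end to end.

## Worked example

A reduced-scale synthetic sound (16 × 10 km, one barrier island), true
marked densities 1.0 (Inshore) and 4.0 (Island) dolphins km⁻², p0 = 0.4,
σ = 1.5 km, φ = 0.8 per interval:

```r
library(dolphinCR)
mainland <- list(cbind(c(0, 16, 16, 0), c(9, 9, 10, 10)))
island   <- list(cbind(c(5, 11, 11, 5), c(1.4, 1.4, 2.6, 2.6)))
mask <- build_mask(mainland, island,
                   list(origin = c(0, 0), nx = 16, ny = 10, cell_size = 1))
truth <- make_world(list(mask = mask,
                         density_by_stratum = c(Inshore = 1, Island = 4,
                                                Offshore = 0),
                         p0 = 0.4, sigma_det = 1.5,
                         phi_by_interval = rep(0.8, 7), marked_prop = 1),
                    seed = 42)
pop       <- simulate_population(truth)
sightings <- simulate_captures(truth, pop)
histories <- build_capture_histories(sightings, 8, 3)
fit  <- fit_model(histories, mask,
                  model_config(M = 600, n_iter = 2700, burn = 700,
                               chains = 3, seed = 42))
dens <- summarize_density(fit, marked_prop = 1.0)
head(dens$table, 4)
```

which prints (seed 42):

```
secr_draws: 6000 draws (3 chains), 8 primaries, M=600, n_obs=373
posterior means: p0=0.397 sigma=1.531 beta_island=1.29 mean phi=0.781

  primary stratum  est    lo   hi
1       1 Inshore 1.20 1.083 1.32
2       1  Island 4.20 3.562 4.81
3       2 Inshore 1.05 0.958 1.14
4       2  Island 3.71 3.188 4.19
```

The period-1 Island CI (3.56, 4.81) covers the realized simulated island
density (4.24 on average across primaries); p0, σ and mean φ sit on their
true values 0.4 / 1.5 / 0.8. `extrapolate_abundance(dens, stratum_areas())`
turns stratum densities into abundances per draw, and
`annualize_survival(fit$phi, delta_days, year_map)` gives equivalent-annual
survival (note: φ = 0.8 over a ~3-month interval is ~0.4 per year).

The full pipelines are one call each — `run_cr_pipeline(config)` and
`run_telemetry_pipeline(config)` with a YAML or list config — or via the
CLI launcher `inst/cli/dolphincr <simulate|cr-fit|telemetry|report>`.

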