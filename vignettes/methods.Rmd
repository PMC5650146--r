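---
title: "Models and methods in dolphinCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in dolphinCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

dolphinCR estimates density, abundance and survival of coastal bottlenose
dolphin populations from photo-ID capture-recapture under a spatially
explicit robust design, and summarizes satellite-telemetry ranging with
kernel utilization distributions and Getis-Ord hot spots. This vignette is
the package's own account of the models, the defaults, and the choices made
where the design was genuinely open.

## The habitat mask

All spatial computation happens on a discretized mask of square cells
(default 1 km, the resolution at which activity centers are defined).
Coordinates are planar kilometres in a local projection supplied by the
caller; the package does no geodetic math, because at 1-km resolution the
projection belongs upstream. Cell membership is decided by the cell-center
point (boundary ties count as inside — deterministic and cheap). Stratum
rules follow barrier-island sound geometry: water
within 1 km of an island (or inside an explicitly supplied pass-corridor
polygon) is *Island*; water 1–2 km out is *Offshore*; all remaining water
is *Inshore*. Pass corridors are explicit polygon inputs rather than
inferred, because no text description pins down their geometry; both band
widths are parameters.

## The capture-recapture model

The robust design has $T$ primary periods (default 8) of $K$ secondary
occasions (default 3), closed within primaries and open between them. The
likelihood the package samples from is assembled from standard spatial
capture-recapture components, each declared explicitly here:

* **Data augmentation.** $M$ individuals (observed plus never-detected
  pseudo-individuals) carry an *alive interval* $[e_i, d_i]$ — entry at
  primary $e_i$ via per-primary entry probabilities $\gamma_t$, survival
  between consecutive primaries with per-interval $\phi_t$, no re-entry
  after death. Recruitment is absorbed by augmentation rather than modelled
  demographically. Because detected individuals' intervals necessarily
  start at or before first detection, survival information is conditioned
  on first capture.
* **Activity centers.** Every individual has a center $s_{it}$ on a water
  cell for every primary. At $t = 1$ the prior is the stratum intensity
  $\propto \exp(\beta_I x_I(s) + \beta_O x_O(s))$; between primaries the
  center moves by an intensity-weighted Gaussian kernel
  $k(s'|s) \propto \exp(\beta x(s'))\,e^{-d^2/2\sigma_m^2}$ normalized over
  water. The weighting matters: an unweighted kernel has a near-uniform
  stationary distribution, so stratified density would erode across
  primaries in both the generator and the model. The dispersal scale
  $\sigma_m$ is a fixed convention (default 1.5 km), not estimated — the
  data at this design barely inform it.
* **Detection.** On each secondary occasion an alive individual is
  detected with probability $p = p_0 \exp(-d^2/2\sigma^2)$, $d$ being the
  distance from its center to the nearest surveyed transect line. Detected
  locations are Gaussian around the center with the same $\sigma$ and
  truncated to water. The likelihood uses the per-primary sufficient
  statistics (detection count, mean location, within-primary sum of
  squares); the truncation normalizer is the water-cell sum of the Gaussian
  kernel, recomputed when $\sigma$ moves. Dropping the within-primary
  scatter or the truncation normalizer biases $\sigma$ (low) and pushes
  island-ring centers seaward — both were visible in development and are
  covered by the recovery tests.
* **Priors.** $p_0, \phi_t, \gamma_t \sim \mathrm{U}(0,1)$ (the latter two
  via conjugate Beta updates), $\sigma \sim$ half-normal(10 km),
  $\beta \sim N(0, 3^2)$. These are weakly informative on the scales involved.

Sampling is Metropolis-within-Gibbs in C++: alive intervals are sampled
*exactly* by enumerating all $T(T+1)/2 + 1$ monotone trajectories;
$\phi_t, \gamma_t$ are conjugate; centers use neighborhood Metropolis
proposals; $p_0, \sigma, \beta$ use random walks. Chains are seeded
deterministically (`seed + chain − 1`); split-$\hat R$ is reported and a
warning fires above 1.1. The stratum coefficient $\beta_I$ decorrelates
slowly against the center configuration (its $\hat R$ can sit near 1.2 at
the default chain lengths); the reported quantities — densities, $\phi$,
$p_0$, $\sigma$ — mix an order of magnitude faster, which is why the
recovery tests validate coverage on those.

**Estimands.** Density draws are *realized*: alive marked centers per
stratum divided by in-mask stratum area. Realized density is what the data
identify; accordingly, simulation tests compare credible intervals against
the realized simulated truth, not the intensity parameter (which differs by
Poisson noise). Total-population density divides by the per-primary marked
proportion; its binomial uncertainty (~0.015 at $p = 0.8$, $n = 800$) is
small relative to the other variance sources and deliberately *not*
propagated. Abundance is
$N_s = D_s A_s$ per draw with configured full-region areas (defaults
Island 242, Inshore 2196 km²); credible intervals discard the lowest and
highest 2.5% of draws (order statistics, so draws $1..1000$ give
$(26, 975)$). Equivalent annual survival is
$\phi^{365.25/\Delta t}$ per draw, averaged over the intervals mapped to
each year; intervals can be dropped from the yearly average (`NA` in
`year_map`) as is appropriate for a final interval confounded with capture
probability. The Offshore stratum is estimable but excluded from reported
tables by default; the survey effort layout does not support reporting it.

## The synthetic generator

The generator is the model's exact mirror plus the telemetry process, so a
green recovery test establishes internal consistency of estimator and
stated world — not robustness to real-data pathologies (photo
misidentification, per-individual detection heterogeneity, trap response,
tides, salinity-driven movement are all absent). Defaults state the
emulated study: 8 primaries × 3 secondaries; marked proportion 0.8;
densities 1.09 (Inshore) and 4.43 (Island) km⁻²; per-interval survival
0.723, 0.812, 0.561, 0.745, 0.520, 0.686, 0.314 (a published annualized
sequence for this system, reused as interval survivals in the absence of
raw interval values); detection $p_0 = 0.4$ per secondary (a realistic
photo-ID value); one shared 1.5-km scale for detection decay, location
noise and dispersal, separately overridable (no field estimate pins these
scales down; sharing keeps the parameter count honest). Effort is
east-west transect lines 1 km apart spanning the water, emulating full
coverage per secondary. Telemetry is a water-restricted
Ornstein-Uhlenbeck walk around a home cell (step SD 0.7 km, attraction
0.05 at 6 fixes/day — chosen once to give ~100 km² home ranges), with
Argos classes from a configurable multinomial and class-specific error SDs
(0.125 / 0.25 / 0.75 km for LC3/LC2/LC1) and tag life uniform on 73–253
days.

The parameter-recovery world (16 × 10 km, one island, ~150–190 marked
animals, marked proportion 1) populates only the two reported strata;
with a populated Offshore band the 1–2-km Offshore/Island rings are
confounded at $\sigma = 1.5$ km observation noise and island coverage
degrades — a real identifiability limit at this reduced scale, and the
reason Offshore densities are excluded from reports by default.

## Telemetry ranges

Filtering keeps LC3/LC2 only, then one uniformly random fix per animal-day
(seeded; day boundary from a configurable timezone). Animals below 150
retained locations are flagged, not dropped. The UD is a plain Gaussian
kernel density evaluated at water-cell centers with land set to zero and
the mass renormalized — barrier handling by mask-and-renormalize rather
than geodesic kernels, a documented simplification isolated behind
`kernel_ud()` for replacement. Contour areas are the minimal
highest-density cell set reaching the level, so ranges may be spatially
broken. The ad hoc bandwidth rule concretizes the rule-based methods of
GIS home-range tools, whose stopping conditions vary: starting from the
bivariate normal reference $h_{ref} = \sqrt{(s_x^2+s_y^2)/2}\,n^{-1/6}$, multipliers
$1.0, 0.9, \dots, 0.1$ are scanned and the smallest one whose 95% contour
is a single (queen-)connected region containing ≥95% of fixes is kept;
failing all, $h_{ref}$ is returned. Multipliers are configurable.

## Hot spots

Monthly fixes are binned into 1-km² cells with the half-open convention
$[x, x+1) \times [y, y+1)$. The distance threshold comes from incremental
spatial autocorrelation: Global Moran's I z-scores (binary band weights,
self excluded, normality variance, $E[I] = -1/(n-1)$) over bands starting
at the average nearest-neighbor distance of occupied cells, taking the
*first local maximum* ("initially peaked"); a monotone-rising scan returns
the last distance with a warning. Gi* uses binary weights with self
included; cells with fewer than 8 neighbors in the band (perimeter cells)
have their band expanded to the nearest 8. P-values are two-sided normal by default (configurable); hot cells
require $Z > 0$ and $p < \alpha$ at $\alpha \in \{0.05, 0.01\}$, without
multiple-testing correction (a Bonferroni correction is far too
conservative for an exploratory scan of this size; available behind a
flag). Consecutive-month overlap is $100\,|A \cap B| / |A \cup B|$ —
the union reading makes the percentage symmetric and bounded by 100,
which fixed the interpretation.

## Numerical and degenerate-input choices

Zero-variance count grids error (Moran's I, ISA and Gi* are undefined;
the all-equal-counts case is unreachable rather than $Z=0$). Zero
photographed dolphins, empty transects, empty histories, unknown stratum
labels, non-positive interval lengths and too-few draws (< 40 for a 95%
interval) all error with named messages. Exhausted augmentation (every
slot included in any retained draw) errors with an instruction to enlarge
$M$. Off-mask detection locations are snapped to the nearest water cell
with a warning. Ties on polygon boundaries count as inside; fixes on cell
edges belong to the upper cell. All randomness is seeded; pipelines write
byte-identical tables on rerun with the same config and seed, with the
seed recorded in every output header.

## Known limitations

The likelihood is a documented composition of standard components;
field photo-ID datasets for systems like this are not released, so
absolute agreement with any one published posterior is not claimable —
validation rests on arithmetic anchors plus simulation-based coverage.
Group-size structure in the generator is a spatial binning convenience,
not a social model. The marked proportion's
denominator counts unmarked animals per sighting record (they cannot be
de-duplicated), giving a small downward bias relative to the generator's
marked fraction. $\beta_I$ mixes slowly at default chain lengths. The UD
ignores within-day autocorrelation beyond the one-fix-per-day rule, and
the mask-and-renormalize barrier treatment lets density bleed across
narrow peninsulas that a geodesic kernel would respect.
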