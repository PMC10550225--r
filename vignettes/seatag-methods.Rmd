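---
title: "Methods: dive bioenergetics and scattering-layer overlap from archival tags"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dive bioenergetics and scattering-layer overlap from archival tags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seatag)
```

## The problem

Archival (data-storage) tags on diving pelagic fishes record depth, ambient
temperature and relative light at 30- or 60-second resolution for months to
years. From those four channels alone, `seatag` reconstructs three things:

1. **Behavior** — individual daytime dives below the mixed layer, segmented
   into descent / bottom / ascent phases and classified as U-shaped
   (sustained foraging at a target depth) or V-shaped (brief prey-searching
   excursions);
2. **Environment** — the midday diffuse light attenuation profile \(k(z)\)
   the animal swam through, and, below the depth where chlorophyll can no
   longer contribute, increases in attenuation consistent with dense
   mesopelagic scattering layers;
3. **Energetics** — a per-dive metabolic cost from a speed-and-temperature
   metabolic model, a cost rate (mg O~2~ kg^-1^ min^-1^), and a foraging
   profitability proxy (bottom time per unit cost), summarized across ocean
   biomes.

Because recovered tag datasets are proprietary and rare, the package ships a
first-class synthetic-data module: an `ocean_scenario` (temperature
profile, attenuation field with deep chlorophyll maximum and scattering
layers, diel solar cycle) plus a `behavior_config` generate tag records with
a known ground-truth dive schedule, so every downstream stage is testable
against what was actually simulated.

## Time and solar geometry

All timestamps are UTC; sunrise, solar noon and sunset come from the NOAA
low-precision solar equations at each day's track position (`solar_events()`,
accurate to a few minutes). Two conventions matter:

* **Local solar dates.** The study-region longitudes (200–246°E) put local
  noon near 20:00–22:00 UTC, so a local day straddles UTC midnight. Every
  per-day operation (daily MLD, dive dates, midday windows, daily positions)
  therefore groups records by the *local solar date*
  (`solar_date()` = UTC + lon/15 h), and `solar_events()` deliberately
  returns unwrapped instants so sunrise < noon < sunset always holds.
* **Diel hour.** Layer migration schedules and acoustic composites use the
  longitude-only local solar hour (UTC + lon/15, composites rounded to the
  integer hour); full solar-equation precision is unnecessary at
  hour resolution.

## The synthetic world

`build_scenario()` states the environment explicitly:

* temperature \(T(z) = T_d + (T_s - T_d)\,[1 - \tanh((z - m)/w)]/2\):
  a two-layer column with mixed-layer temperature \(T_s\), deep temperature
  \(T_d\), thermocline center \(m\) (the "true" MLD) and width \(w\);
* attenuation \(K(z,t) = k_0 + \sum_i a_i \exp[-(z-c_i(t))^2/2\sigma_i^2]\):
  constant background plus Gaussian components; migrant scattering layers
  interpolate their center sinusoidally between a midnight (shallow) and
  noon (deep) depth;
* surface ln-irradiance: a half-sine between sunrise and sunset with peak
  `surface_light_max` (default 18 ln-units above the sensor floor), darkness
  (the floor) at night. Light at depth is Beer–Lambert:
  \(\ln I(z,t) = \ln I_0(t) - \int_0^z K(z',t)\,dz'\) (closed form via
  normal CDFs), clamped at the floor.

`simulate_tag_series()` alternates mixed-layer occupation with scheduled
daytime dives. Dive counts per day are deterministic integers (a "mean
count" drawn stochastically would make the generator's own ground truth
fuzzy); U dives form a midday bout — deep daytime foraging peaks around
noon, which is also why midday attenuation profiles exist at all — while V
dives fill the remaining daylight slots, each dive centered in its slot. A
dive that cannot finish by sunset is truncated there and flagged in the
schedule, never silently dropped.

Default behavior values and why:

| parameter | default | rationale |
|---|---|---|
| sampling interval | 30 s | the finer of the two archival-tag rates |
| U dives/day, V dives/day | 6, 24 | ~30 round trips to 200–250 m ≈ 12 km of daily vertical travel, the magnitude reported for gyre-resident albacore |
| U bottom duration | 12 ± 3 min | between the coastal (10 min) and gyre (13 min) mean bottom times |
| V apex depth | 200 ± 20 m | typical searching-dive depths below the euphotic zone |
| descent/ascent rate | 0.85 ± 0.08 m s^-1^ | between the published biome means (0.7 and 1.0 m s^-1^) |
| noise (depth, temp, light) | 0.5 m, 0.1 °C, 0.02 ln-units | sensor resolution-scale jitter; light noise at the quantization scale of log-compressed tag light channels |

What the generator does **not** emulate: horizontal movement within a day
(positions are fixed or linearly drifting), internal (visceral) temperature,
tag attachment artifacts, cloud cover and sea-state light variability,
sensor drift, and non-dive vertical behavior such as thermoregulatory
basking. A green test therefore establishes that the estimators recover a
*stated* world of this structure — not that they are robust to every failure
mode of real tag data.

## Mixed layer depth and dive extraction

The MLD method is a temperature threshold on the tag's own vertical
excursions: daily records are binned in 5-m depth bins, each bin takes its
median temperature, and the MLD is the shallowest bin center more than
0.5 °C colder than the 0–10-m reference. Isothermal days return the deepest
binned depth, flagged `no-crossing`. This is the standard fallback when no
CTD-style profile exists; its resolution is set by the bin width and by how
often the fish actually crosses the thermocline.

Dives start and end 10 m below the day's MLD (a fixed offset makes dives
comparable across oceanographic regimes); candidates shorter than 5 min
(the lower bound of published retained-dive durations) are dropped. Phases
follow the 75%-of-maximum-depth rule: the bottom phase spans the first to
last sample at ≥ 0.75 × max depth. Phase durations are sample counts times
the sampling interval, so a one-sample spike bottom carries one full
interval and the three phase durations always sum exactly to the dive
duration. Retained dives must start after sunrise, end before sunset, and
exceed the euphotic-zone cutoff — the mean deep-chlorophyll-maximum depth
plus 3 SDs for the dive's 10° latitude band. The packaged cutoff table
(`default_dcm_table()`) is a *synthetic placeholder* with mid-latitude
cutoffs of 145–165 m; replace it with a real climatology for real data.

Classification default is an unsupervised 2-means partition of
(bottom-time proportion, log duration), standardized, with deterministic
initialization at the dives with the lowest and highest bottom proportion;
the cluster with more bottom time is U. A fixed-threshold rule mode
(U: proportion ≥ 0.5 and ≥ 10 min; V: proportion < 0.5 and 5–23 min)
calibrated to the published U/V descriptors serves as fallback and
cross-check.

## Light attenuation profiling and layer detection

Within local solar noon ± 1 h, attenuation is estimated from **along-path
gradients**: every consecutive-sample pair with ≥ 5 m of depth change gives
\(k = -\Delta\ln I / \Delta z\) at the pair's midpoint, and pair estimates
are pooled into 10-m bins by span-weighted mean. Two design points deserve
explanation:

* *Why gradients rather than binned means?* Surface irradiance changes by
  ~0.4 ln-units across the two-hour window. Differencing the means of depth
  bins that were occupied at different times aliases that diel drift into
  spurious attenuation. Consecutive samples are 30–60 s apart, over which
  the surface drift is ≤ 10^-2^ ln-units; descent and ascent pairs carry
  opposite-signed residuals and cancel in the bin mean.
* *Why 10-m bins?* At ~1 m s^-1^ vertical speeds and 30-s sampling, one
  pass yields one observation per 20–60 m of depth; 5-m bins are simply not
  populatable at realistic pass counts, 10-m bins reach useful occupancy
  while still resolving layers tens of meters wide.

Negative-attenuation bins are retained and flagged, never clipped, so QC
statistics stay honest. QC (`qc_rules()`) requires ≥ 8 defined bins below
the 20-m surface-anomaly exclusion depth, ≤ 20% negative bins, and bounds
the attenuation change per meter between adjacent bins (0.003 m^-1^ m^-1^, a
cloud/occlusion spike heuristic). QC failure is a state, not an error.

Scattering-layer overlap detection is presence-only and deliberately
conservative: only where the profile passes QC *and* extends below the
latitude band's DCM cutoff is it evaluated at all (otherwise the result is
"not evaluated", distinct from "no detection"). The reference is the
minimum binned attenuation at or below one bin above the cutoff; overlap is
declared when ≥ 2 consecutive defined bins *deeper than both the cutoff and
the depth of that minimum* exceed the reference by 25%. Requiring the
qualifying bins to lie below the within-profile minimum is what makes a
monotonically decreasing profile undetectable by construction; the 25%
margin operationalizes a "marked" increase and is exposed in configuration
and swept in the tests (sensitivity is non-decreasing in layer strength).

Within-biome profiles with detections are clustered (seeded k-means on
standardized, per-depth mean-imputed \(k(z)\) vectors) and composited as
per-depth means with normal-approximation 95% CIs, ordered by mean
attenuation above 100 m.

## Energetics

The published experimentally calibrated metabolic-rate surface for tunas is
not reproducible from its description, so the model here is a **surrogate**
with the same qualitative structure, swapped out via configuration if a
tabulated surface becomes available:

\[ \mathrm{MR}(u, T) = \left(R_0 + c\,\max(u, u_{\min})^p\right)
   \exp\!\big(\beta \max(0,\, T_{\mathrm{ref}} - T)\big) \]

in mg O~2~ kg^-1^ h^-1^, with speed \(u\) in body lengths s^-1^. Defaults
\(R_0 = 175\), \(c = 70\), \(p = 2\), \(\beta = 0.035\,°C^{-1}\),
\(T_{\mathrm{ref}} = 18\) °C, \(u_{\min} = 0.8\) BL s^-1^ place typical
simulated foraging dives in the 4–6 mg O~2~ kg^-1^ min^-1^ cost-rate range
with colder dives costlier — the two features the biome comparisons rest
on. The speed proxy is the vertical rate only (central differences on the
depth series), floored at \(u_{\min}\); horizontal swimming is absorbed
into \(R_0\). The surrogate makes no absolute field-metabolic-rate claim
for real fish.

Per-dive cost integrates MR sample-wise (each sample owns one sampling
interval) rather than by the trapezoid rule: with sample-count phase
durations this makes phase costs exactly additive and constant-rate dives
exact unit conversions. Cost rate is cost ÷ total duration; profitability
is bottom time ÷ cost; both identities hold to 10^-12^ by construction and
are asserted as such.

Hypothetical deeper dives keep the observed dive's start depth, vertical
rates and bottom duration, extend travel to the target depth, and take
temperatures from a water-column profile. Both the observed and
hypothetical dives are evaluated with the same idealized-geometry
integrator (adaptive quadrature of MR over depth), so the
target-equals-observed case yields ratios of exactly 1. The cost-equivalent
bottom duration solves `travel + bottom_rate × b = observed cost` in closed
form; when even `b = 0` overspends — the hypothetical travel alone costs
more than the whole observed dive — the dive is flagged infeasible, the
regime in which no shortening of the foraging phase can compensate for
reaching a deeper layer.

## Biome statistics and acoustics

Provinces are first-match rectangular boxes (defaults: the three
study-region boxes; how real provinces were modified from biogeochemical
ones is not reproducible here). Summaries are per-province mean/SD/n;
percent change between provinces is `100 × (m₂ − m₁)/m₁` reported to 0
decimals. The cost-rate–temperature relation is fit as a power law by OLS
on the log-log scale (deterministic and closed-form; nonlinear least
squares offered nothing the tests could distinguish); the linearized
sensitivity `10 b` (% per 10% temperature increase) is reported alongside
the exact `(1.1^b − 1) × 100`. Spatial fields use inverse-distance-weighted
interpolation with great-circle distances and exact reproduction at
coincident nodes. The planned mixed-effects models are intentionally out of
scope.

Acoustic composites pool backscatter profiles in a region box into local
hour × 10-m depth cells by plain averaging (cells without data are missing,
never zero-filled; an alternative per-cruise-day pre-averaging is a
config-level variation that plain pooling approximates for balanced
sampling). Layer traces per hour give the argmax depth and a
backscatter-weighted centroid restricted to cells within 6 dB of the hourly
stratum maximum — without that standard layer-core threshold, the noise
floor drags centroids toward the stratum midpoint. Dive-depth overlays use
type-7 quantiles, stated so tests can be exact.

## Numerical choices, degenerate inputs, tie-breaks

* Dive boundaries use strict `depth > MLD + 10`; bottom phase uses
  `≥ 0.75 × max`, so ties at exactly 75% belong to the bottom.
* A dive whose maximum falls on its first or last sample gets an empty
  (zero-duration) descent or ascent and a `degenerate` flag.
* k-means label order is made deterministic by relabeling clusters (U =
  more bottom time; attenuation clusters sorted by shallow mean k).
* `stats::integrate` with `rel.tol = 1e-10` handles even discontinuous
  temperature profiles in the travel-cost integral; the closed-form
  cost-equivalent solution is verified against bisection to < 1 s.
* All randomness flows from explicit integer seeds; identical
  configuration + seed is bit-identical.

## Known limitations

* The MLD estimator sees only depths the fish visited; days without
  thermocline crossings yield flagged, weak estimates.
* Attenuation profiles need vertical movement through the midday window;
  a fish that surfaces at noon yields no profile (an error state, by
  design).
* Layer detection is presence-only: `FALSE` means "no detection", and
  absolute layer biomass or composition is out of reach of a light sensor.
* The metabolic surrogate is structurally, not experimentally, calibrated;
  only orderings and ratios across conditions should be interpreted, not
  absolute costs.
* Province boxes are rectangles, not real biogeochemical polygons.
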