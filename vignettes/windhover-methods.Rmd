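---
title: "Methods: synthetic flows, hover detection and glide envelopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic flows, hover detection and glide envelopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(windhover)
```

## The problem

Windhovering birds (kestrels, ospreys, pied kingfishers) keep their heads
essentially fixed relative to the ground while flying into the wind; when
an orographic updraft supplies the sink rate, they can do so without
flapping ("hanging"). Studying this behaviour indoors requires a wind
tunnel that reproduces the relevant flow: windspeeds of roughly 5–17 m/s,
time-averaged updraft angles of 4.5–10° through the flight volume, and
turbulence intensities up to about 15 % — the envelope spanned by outdoor
measurements at windhovering sites and by published glide polars of
soaring birds.

`windhover` implements the computational side of such a facility as a
reusable, fully tested pipeline: synthesis of replicated turbulence and
updraft fields, flow characterisation and mapping, hover detection from
motion-capture trajectories, association of hovers with local flow, and
glide-envelope arithmetic. Because no flight or probe recordings are
publicly deposited, a synthetic-data module generates all inputs with
known ground truth; every downstream stage is validated against that
truth or against independent numerical oracles.

## Turbulence synthesis

`generate_turbulence()` performs frequency-domain synthesis: complex
Gaussian coefficients are shaped by the one-dimensional von Kármán
longitudinal spectrum

$$ S(f) \propto \left(1 + \left(1.339\,\frac{2\pi f L}{\bar U}\right)^2\right)^{-5/6}, $$

inverse-transformed, and rescaled *exactly* to the target mean $\bar U$
and standard deviation $\sigma_u = \mathrm{TI}\cdot\bar U$. Two
properties follow by construction:

* the sample turbulence intensity $\mathrm{sd}(u)/\mathrm{mean}(u)$
  equals the target to floating-point precision, for any seed;
* at high frequency $S \sim f^{-5/3}$, the Kolmogorov inertial-range
  decay, so a log–log least-squares fit over 6–60 Hz recovers a slope of
  $-5/3 \pm 0.15$ on 60 s records.

The constant 1.339 ties the spectral knee to the integral scale: the
normalised spectrum has zero-frequency limit $4L/\bar U$, hence the
shaped process has integral time scale $L/\bar U$ and, by Taylor's
frozen-turbulence hypothesis, integral length scale $L$.

Lateral and vertical components are generated independently with the
same $\sigma$ and $L$ and zero mean. This isotropy assumption is a
modelling choice — grid turbulence is only approximately isotropic, and
the facility quantifies longitudinal properties only.

**Known bias.** The synthesis grid has frequency resolution
$1/\mathrm{duration}$, so spectral content below that is absent and the
record is duration-periodic. Because the lowest frequencies carry the
autocorrelation tail, the integral-length-scale estimator recovers the
target with a mild low bias (about −10 % at 60 s, target 0.31 m). Across
ten seeds the mean recovery is comfortably within the ±20 % acceptance
band, but an individual seed can graze the band edge (we observed
−20.3 % once). We considered synthesising a longer record and cropping,
which removes the bias but inflates seed-to-seed variance (single-seed
excursions to +40 %); the simple duration-resolution synthesis is kept
and the bias documented here. Defaults: 1250 Hz (probe-class
instruments are flat to 2 kHz), 60 s records — the one-minute
convention used for point statistics.

## The updraft field model

The facility measures its ramp-generated updraft; it does not model it.
Downstream code only needs a *smooth deterministic* field consistent
with the measured envelope, so `generate_updraft_field()` samples a
parametric model: a uniform stream plus a deflection kernel decaying
exponentially with distance $d$ from the ramp surface segment,

$$ \theta(x,z) = \min(0.8\,\alpha, 45°)\,e^{-d/\lambda},\qquad
   U(x,z) = U_\infty\,(1 + 0.25\,e^{-d/\lambda}),\qquad \lambda = 0.4\ \mathrm m, $$

with ramp incline $\alpha$ (default 52°, surface length 1.215 m, leading
edge at $x = 7.14$ m, raised 0.145 m). Consequences, all tested:

* pitch angle depends on geometry only — *exactly* invariant to tunnel
  speed — and the speed field scales *exactly* linearly with tunnel
  speed, so cross-speed map comparisons are zero after normalisation
  (the physical facility repeats within 2 % and 0.5°);
* with defaults at 6 m/s: ~6.7° at the flight-volume centroid (inside
  the observed 4.5–10° band), a 41.6° ceiling (observed maximum 42°),
  speeds within [6, 7.5] m/s in the flight volume (observed 5–8 m/s);
* zero incline gives zero deflection everywhere.

The gains (0.8, 0.25) and decay length were fixed once from the
geometry of the measured envelope, not fitted to data. Turbulence
intensity is boosted by the same kernel towards the ramp surface,
mimicking the developing boundary layer there. The model is defined on
the central $y=0$ plane only, matching the mapped plane; applying it to
hovers at $y \neq 0$ repeats the facility's own implicit approximation.

## Trajectories and hover detection

`generate_flight_trajectory()` renders a plan of hover and transit
segments at 200 Hz (capture-class default). Hovers hold the head at an
anchor plus isotropic Gaussian noise (default 0.3 mm per axis,
comfortably inside the sub-millimetre spread of real hanging flight);
transits follow a cubic smoothstep, chosen so velocity is continuous
and zero at the joins — no spurious stationary points are created at
segment boundaries, but the *starts* of transits are genuinely slow.
The mantle marker is the head plus a fixed offset plus independent
noise. Ground-truth intervals come from the plan itself.

`detect_hovers()` operationalises "stationary for ≥ 0.5 s": every
sliding window of width `min_duration` (step one sample) whose per-axis
head-position standard deviation is strictly below `std_threshold`
(default 1 mm) qualifies; maximal runs of consecutive qualifying
windows form candidate epochs. Per-axis (rather than 3-D resultant)
spread is the stricter, axis-symmetric reading. Two refinements:

* *No gap bridging.* Epochs separated by any non-qualifying window stay
  distinct — birds typically hover briefly in several places per flight.
* *Event-level trim.* A merged epoch can drag in slow drift at its
  edges (each window qualifies; their union need not). Since a hover
  event is defined to have per-axis spread below threshold, the
  detector sheds edge samples — always the sample farther from the
  event centroid on the worst axis — until the event satisfies the
  bound; it stops, at worst, at a single window, which qualifies by
  definition, so the duration floor is preserved. Without this trim the
  cohort-wide maximum spread hovers at ≈ 1.0–1.07 mm; with it the
  detector guarantees the documented sub-millimetre property while
  leaving recall and precision at 1.0 on planted hovers ≥ 0.6 s.

What a green closed-loop test establishes: on *this* generator — clean
isotropic noise, no marker dropout, no wingbeat oscillation, transits at
≥ 1 m/s — detection is exact. Real trajectories add occlusions, slow
drifts and flapping harmonics the generator deliberately omits;
marker-loss handling is out of scope.

## Association and cohort statistics

`associate_hovers()` projects each event centroid (mantle by default —
the marker plotted on flow maps; head selectable) onto the mapped
plane, converts mm to m, and bilinearly interpolates speed, angle and
turbulence intensity. Bilinear interpolation is exact at nodes and on
affine fields, and is verified against a brute-force oracle to 1e-12.
Hovers outside the mapped hull are flagged and excluded from statistics
— never extrapolated — with explicit accounting
(`n + n_excluded = total`). `cohort_statistics()` reports per-group
arithmetic mean, sample sd ($n-1$), and counts; `format_cohort()`
renders the conventional `"10.4 ± 2.0 deg s.d., n = 63"` strings.

The published flight-cohort numbers themselves depend on unreleased
recordings and are *not* reproduced; instead the pipeline is validated
by parameter recovery: a synthetic cohort of 63 hovers placed where the
field angle is $10° + N(0, 2°)$ recovers its mean within two standard
errors.

## Glide envelopes

In equilibrium glide the shallowest glide path satisfies
$\theta_{\min} = \cot^{-1}(L/D)$. `load_polar_table()` ships a reference
table of wind-tunnel glide tests (six bird species, two bird-sized
UAVs); $\theta_{\min}$ is always recomputed from $(L/D)_{\max}$, never
read, and matches the printed one-decimal values for all eight rows.
`envelope_check()` uses closed-interval containment (boundary values
count as covered; the prose the defaults come from does not
distinguish). Note the source table's pigeon row (8–22 m/s) exceeds the
text's stated 6–16.8 m/s velocity range; the fixture keeps the table
values, and the pigeon is correctly reported as not covered by the
default 5–17 m/s facility envelope.

## Numerical choices

* PSD: averaged modified periodogram, Hann window, 50 % overlap, 4 s
  segments (config-exposed); Parseval consistency with sample variance
  is within 5 % on 60 s records.
* Integral scale: autocorrelation (FFT-based) integrated by trapezoid to
  its first zero crossing, with the crossing located by linear
  interpolation; full-range integration would be noise-dominated.
* Cone filter: samples whose instantaneous vector deviates from the
  probe axis by more than ±45° are rejected; the boundary is retained.
  Synthetic records essentially never trigger it — matching the
  facility's "zero samples rejected" experience.
* Pitch angle from *mean* components, `atan2(mean w, mean u)`, robust to
  zero-mean noise; angles interpolated directly in degrees (all far
  from ±180°).
* Coordinates: x downstream of the test-section inlet, z above the
  floor, metres; trajectories in mm; seeds are single integers and every
  stochastic output is reproducible from (spec, seed).

## Limitations

The updraft model is a geometric kernel, not CFD: it satisfies the
measured envelope but carries no wake physics, no grid-decay evolution
and no lateral structure. The turbulence synthesis is Gaussian and
stationary — real atmospheric boundary layers are neither. The detector
is tuned for rigid station-keeping heads; it has no notion of wingbeat
frequency. None of these affect the contracts the tests assert, but all
of them matter before extrapolating a green suite to field data.
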