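---
title: "Methods: idealized strait connectivity and stranding simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: idealized strait connectivity and stranding simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(medusadrift)
```

## The scientific problem

Jellyfish such as *Pelagia noctiluca* spawn in sheltered island basins and
turn up, months later and in large numbers, inside energetic tidal straits
where they grow, bloom and strand on beaches. Because early life stages
drift passively in the surface layer, the connection between basin and
strait is fundamentally a transport problem: surface currents, a small
direct wind contribution, and sub-grid turbulent dispersion. `medusadrift`
provides that transport model in a fully synthetic, reproducible setting —
an idealized strait-and-basin domain with prescribed forcing — together
with the metrics used to quantify connectivity, retention and stranding,
and the analytics applied to beach-survey observations.

The synthetic scenario is an abstraction, not a hindcast. Headline numbers
from any real region (which depend on real bathymetry, coastline shape and
a data-assimilating circulation model) are *not* reproduced here; what the
package reproduces are the metric definitions and the qualitative dynamical
structure, each verified against independent oracles.

## The idealized domain and forcing

The domain is a 60 km x 80 km plane in local Cartesian metres (the region
is small enough that no geographic projection is needed; external fields
should be projected before ingestion). A 6-km-wide channel (the strait)
runs north–south between two mainland blocks — "sicily_side" to the west,
"calabria_side" to the east — and opens at y = 35 km into a northern basin
holding a five-island archipelago. The spawning region is a 20 km x 26 km
box around the islands. Two cross-channel gates (y = 4 km and y = 33 km)
bound the strait region; the outer rectangle is an open boundary. Both
mainland coastlines are pre-segmented into 5-km stretches (`Sic1..`,
`Cal1..`), Sicily numbered clockwise from the southern channel end and
Calabria counter-clockwise, mirroring the usual field convention.

The flow field is the sum of four components (`make_strait_field()`):

* **Tidal jet** — an along-channel oscillation `v_amp(x, y) * cos(2*pi*t/T)`
  with period T = 44712 s (the M2 semi-diurnal constituent; the default
  because strait tides are dominantly semi-diurnal, configurable) and a
  Gaussian amplitude profile peaked at the sill (y = 15 km, decay scale
  8 km, peak 2.2 m/s). Peaking the jet at the sill is the physically
  expected structure for a sill-controlled strait, and it bounds the tidal
  excursion well inside the 35-km channel; a uniform 2.2 m/s oscillation
  would translate particles by ~31 km each half-cycle and empty the strait
  unrealistically fast.
* **Residual through-flow** — a steady southward 0.25 m/s current in the
  channel (the 0.2–0.3 m/s residual range typical of such straits), fed by
  a convergent Gaussian inflow patch at the mouth.
* **Recirculation cell** — a clockwise (anticyclonic) vortex just north of
  the sill, with a smooth Rankine-style tangential profile
  `v_t(r) = V * (r/R) * exp((1 - (r/R)^2)/2)` peaking at V = 0.25 m/s at
  R = 2 km. The through-flow is suppressed inside the cell so the
  time-mean speed at the rim equals the configured tangential speed.
* **Basin drift** — a uniform 0.08 m/s drift toward the southeast
  (heading 135 degrees), the order-5–10 cm/s background flow that carries
  basin water past the islands toward the strait mouth. The drift, rather
  than a radially convergent "sink" flow, is what makes source cells
  genuinely unequal: only release locations whose drift line passes the
  mouth's capture zone connect efficiently, which is exactly the structure
  the Normalized Source Index is designed to map.

Land cells carry zero velocity; all four components are zeroed on land.
The field is stored as a residual pattern plus a tidal-amplitude pattern
(an exact "harmonic" representation, compact enough for year-long runs at
any temporal resolution); `as_snapshot_field()` samples it to explicit
(time, y, x) arrays, and externally supplied snapshot fields use linear
time interpolation.

**Wind.** Wind is spatially uniform. Each interval (default hourly) draws
a compass sector from a monthly prevalence table dominated by
north-westerlies — about 50% of the year, peaking at 95% in May and 80% in
June with an October minimum of 8%; the remaining probability is spread
evenly over the other seven sectors. Field observations constrain only the
direction climatology, not speeds, so speed is a free modelling choice: we
use a Weibull(shape 2, scale 6 m/s) distribution, a standard coastal wind
speed model with mean ~5.3 m/s. A NW wind drives drift toward the
southeast, i.e. toward the eastern (Calabrian) shore of the channel.

## The particle tracker

Particles obey

    dX = [u_current(X, t) + alpha * u_wind(t)] dt + sqrt(2 K dt) dW

* **Windage** `alpha = 0.004` (4 per mille of wind speed), the standard
  leeway fraction for surface drifters of this kind.
* **Diffusivity** `K = 5 m^2/s` by default — a typical sub-grid horizontal
  eddy diffusivity at ~500 m grid resolution. The source studies of this
  problem class do not state K, so it is fully configurable and `K = 0` is
  supported for deterministic oracle tests.
* **Integration**: classical RK4 for the deterministic part (midpoint RK2
  and Euler available), explicit Euler–Maruyama for the noise, `dt = 300 s`
  by default. On a solid-rotation field RK4 at dt = 300 s closes a 12-h
  orbit to better than 1e-3 of the radius; halving dt moves double-gyre
  endpoints by well under 1% of the path length.
* **Interpolation**: bilinear in space with land cells removed from the
  stencil and the remaining weights renormalized, so velocities near the
  coast are not artificially dragged toward zero; linear in time for
  snapshot fields.
* **Stranding** is geometric, not cell-based: each sub-step's displacement
  segment is intersected with every coastline edge (gated by a
  near-coast band wider than the largest possible sub-step) and the
  earliest crossing in path order strands the particle at the contact
  point, which is then mapped by coastal arc length to its 5-km segment.
  This keeps stranding results independent of grid resolution. `reflect`
  is available as an alternative land interaction (specular reflection,
  holding position when the reflection is itself blocked).
* **Statuses**: every particle ends in exactly one of `active`,
  `stranded`, `exited_tyrrhenian`, `exited_ionian`, `left_domain`. Gate
  crossing after the first strait entry is terminal: the metrics count
  first entries and first exits, and a single terminal status keeps the
  conservation identity (released = active + stranded + exited + left)
  exact at every output time. A particle that had entered the strait and
  left the domain through the southern boundary within one output interval
  is classified as an Ionian exit.
* **Seeding**: release pulses are semi-diurnal by default, quantized to
  the hourly output grid; positions are drawn uniformly over the water
  portion of the release region by rejection sampling.
* **Reproducibility**: one master seed governs seeding, wind generation
  and diffusion. The implementation is single-threaded and draws noise in
  a fixed particle order, so runs are exactly reproducible; the run
  manifest (seed, configuration hash, package version) identifies a run
  completely.

The compiled (Rcpp) core advances all particles between hourly outputs;
strait entries and gate exits are classified on the hourly positions, the
same cadence at which such analyses are conventionally done.

## Experiments

All experiments use an abstract 365-day year starting 1 January.

* **exp1 — connectivity** (`run_exp1()`): semi-diurnal releases in the
  spawning region from day 25 to day 155 (the mid-winter-to-late-spring
  reproductive window), 40 particles per pulse at desk scale (~10,040
  total), tracked to year end. Outputs: NSI source grid (2-km bins), mean
  travel-time map over cells with NSI > 0.6, daily cumulative entry ratio.
* **exp2 — retention** (`run_exp2()`): semi-diurnal releases inside the
  strait all year (15 per pulse, ~10,575 total). Outputs: daily strait
  occupancy (mean over each day's hourly snapshots), cumulative
  exit-to-entry retention ratio, mean residence time.
* **exp3 — stranding** (`run_exp3()`): semi-diurnal releases inside the
  strait through June–August (56 per pulse, ~10,000 total), run to day 365.
  Outputs: per-segment stranding shares and the Calabria:Sicily coast
  ratio.

Desk-scale counts (~1e4 particles per experiment) were chosen as the
package's default study conditions; `scale` multiplies them for smoother
fields. Share-type metrics are scale-invariant within binomial noise.

## Metric definitions and their ambiguities

* **NSI**: the definition fixes the ratio (entrants/released per source
  element) and the max-normalization, but not what "averaging" runs over.
  We average cohort-wise (per release pulse) before normalizing, which
  weights release times equally and makes the index insensitive to uneven
  cohort sizes; this is flagged as an open interpretation. Source
  "elements" are regular 2-km bins over release positions — no
  finite-element mesh exists in the synthetic setting and the index is
  mesh-agnostic as defined. Cells with no releases are undefined (`NA`),
  never zero; if no particle enters anywhere the whole index is undefined
  and flagged, since the normalization does not exist.
* **Entry ratio**: cumulative distinct entrants over cumulative releases
  minus particles lost through the open boundary ("still within the model
  domain"); days with a zero denominator are undefined. Multi-year runs
  are averaged by day of year.
* **Occupancy**: whether the daily value is a fixed-time count or a daily
  mean is ambiguous in the source material; we use the mean over the
  day's 24 hourly snapshots, which is insensitive to the tidal phase at
  an arbitrary sampling hour.
* **Retention**: cumulative Tyrrhenian exits over cumulative entrants;
  values near zero mean the strait retains what it captures.
* **Stranding shares** are percentages over mainland segments (islands
  tallied separately); the coast ratio is the Calabrian total over the
  Sicilian total, undefined when the Sicilian total is zero.

## Survey and habitat analytics

* Biomass `W = 0.0002 * D^2.8786` (g, mm) is taken as given from the
  regional allometric study; the implementation is verified against a
  50-digit evaluation to 10 significant digits.
* Abundance classes 0 / 1–10 / 10–100 / >100: the published ranges overlap
  at 10 and 100, resolved here by assigning boundary counts to the lower
  class. `large_aggregation` is set only by explicit flag.
* Size-class tables use half-open bins [20,30), [30,50), [50,70), [70,90)
  mm (shared edges resolved downward-exclusive); out-of-range diameters go
  to an explicit `other` column, and seasons without measurements are
  undefined rather than zero. Seasons are meteorological quarters
  (DJF/MAM/JJA/SON), since the survey convention leaves season boundaries
  implicit.
* Damaged-specimen imputation is an explicit per-record
  `reference_diameter` column (the diameter of a reference specimen
  collected nearby); unmeasured individuals without a reference are
  excluded from biomass rather than silently defaulted.
* Upwelling depth is the shallowest depth at which sigma-t reaches the
  threshold (default 28.5), linearly interpolated between samples; if the
  surface sample already qualifies the dense water fills the whole column
  and the routine flags `surface_reached`.

## What the synthetic scenario does and does not show

The generator emulates the *regimes* — a sill-peaked semi-diurnal jet
exceeding 2 m/s, a 0.25 m/s southward residual with an anticyclonic cell,
a weak southeastward basin drift around islands, NW-dominated winds — on a
deliberately simple geometry: straight channel walls, rectangular regions,
circular islands, barotropic forcing, no internal waves, no vertical
motion (the motivating transport problem is surface-layer and horizontal).
Consequences to keep in mind:

* Passing tests demonstrate correctness of the transport and metric
  machinery and qualitative recovery of the expected structure (near-mouth
  sources outrank far-basin sources; removing the residual lengthens
  residence; a symmetric strait strands symmetrically; onshore wind biases
  the coast ratio). They do not validate any real region's numbers.
* The default forcing flushes the strait southward, so Tyrrhenian exits
  are rare and the retention series sits near zero — a regime statement,
  not a bug; setting `residual_speed = 0` produces the
  high-retention contrast.
* Real coastlines trap drifters in bays and harbours; straight walls do
  not, so absolute stranding probabilities are not comparable to surveys,
  only their spatial contrasts.

## Numerical choices and degenerate inputs

Zero-width channels, negative speeds, non-summing prevalence rows,
non-increasing depths, empty polylines and land-only release regions are
rejected with configuration errors. Points exactly on a region boundary
count as inside (regions are closed sets). The NSI threshold comparison
uses a 1e-12 tolerance so cohort-mean round-off cannot flip a cell across
the 0.6 travel-time cutoff. Cohort release times are quantized to the
hourly output grid. Problem sizes used by the test suite and the
acceptance script — ~1e4 particles per experiment, 5000-particle diffusion
checks, 1000-step geometric property sweeps — are the package's chosen
desk-scale defaults.
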