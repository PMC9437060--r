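# medusadrift

Biophysical transport toolkit for studying how a spawning basin feeds a
tidal strait: Lagrangian particle tracking of passive surface drifters
(jellyfish ephyrae and young medusae are the motivating organisms) through
idealized strait-and-basin forcing, connectivity and retention metrics, and
companion analytics for beach-survey observations of stranded jellyfish.

It is written for marine ecologists and coastal modellers who want a
self-contained, reproducible sandbox for source–sink questions of the form
*"where do the animals arriving in the strait come from, how long does the
journey take, how long do they stay, and where do they beach?"* — without
needing a full hydrodynamic hindcast.

## What it computes

Particles drift through a gridded velocity field with windage and
random-walk diffusion:

    dx/dt = u_current(x, y, t) + alpha * u_wind(t) + noise,
    noise per axis ~ N(0, sqrt(2 K dt)),  alpha = 0.004 (4 per mille)

integrated with classical RK4 (Euler–Maruyama for the noise), bilinear
space interpolation with land-masked stencils, and geometric
path–coastline stranding detection.

The headline metric is the **Normalized Source Index (NSI)**. For source
cell *i* with release cohorts *c*:

    NSI_i = mean_c( entered_{i,c} / released_{i,c} ) / max_j mean_c( ... )

i.e. the cohort-averaged probability of reaching the strait, normalized so
the best-connected cell scores 1. Around it the package computes per-cell
mean travel times (particle age at first strait entry), the daily
cumulative entry ratio, daily strait occupancy, the cumulative
exit-to-entry retention ratio, and per-5-km-segment stranding shares with
the Calabria:Sicily coast ratio.

Survey-side routines implement the allometric biomass law
`W = 0.0002 * D^2.8786` (W in g, D = bell diameter in mm), abundance-class
coding (0, 1–10, 10–100, >100), seasonal size-class and biomass tables,
current-speed/slack statistics and upwelling depth from a sigma-t
threshold.

## Worked example

Simulate the summer stranding experiment at reduced particle count and
look at where particles beach:

```r
library(medusadrift)
cfg <- run_config("exp3", seed = 1, scale = 0.2, duration_days = 260)
res <- run_exp3(cfg)
res$stranding
#> <stranding_shares> 487 mainland strandings; Calabria/Sicily ratio: 3.348
head(subset(res$stranding$shares, count > 0), 8)
#>    segment_id    coast count share_pct
#> 1        Sic1   sicily     1 0.2053388
#> 2        Sic2   sicily    23 4.7227926
#> 3        Sic3   sicily     7 1.4373717
#> 4        Sic4   sicily    24 4.9281314
#> 5        Sic5   sicily    17 3.4907598
#> 6        Sic6   sicily    36 7.3921971
#> 7        Sic7   sicily     4 0.8213552
#> 14       Cal1 calabria    21 4.3121150
```

487 of the ~2000 released particles beach on the mainland coasts; the
north-westerly summer wind drives surface drift toward the eastern
(Calabrian) shore, so the coast ratio is well above 1. With the wind and
the recirculation cell switched off the strait is symmetric and the ratio
returns to ~1.

The survey analytics work standalone:

```r
round(biomass(c(50, 102, 124)), 2)
#> [1]  15.55 121.06 212.40      # grammes wet weight
abundance_class(c(0, 7, 45, 250))
#> [1] "0" "1" "2" "3"
```

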