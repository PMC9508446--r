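# marsalt

How far can viable bacterial endospores travel on Mars by wind-driven
saltation before abrasion sterilises them?

Tumbling experiments (spores of *Bacillus subtilis* coated on crushed
basalt, rotated under simulated martian atmosphere) show that abrasion
kills spores fastest at the outset — about 50% in the first minute — but
that inactivation then slows by orders of magnitude: 3% remain after an
hour, 0.5% after a day. `marsalt` couples that survival curve to a
saltation hop-length model to bound the travel distance of the spores that
survive. It is written for planetary-protection and astrobiology analysts
who want the bounding argument as tested, reusable code.

## The model

One laboratory rotation collision is taken to correspond to one saltation
hop. The hop length on a planetary surface is

    L_salt = 1091.5 * (v^2/g)^(1/3) * (u* - u*t) / sqrt(g d)

with `v = eta/rho` the kinematic viscosity of the atmosphere, `g` gravity,
`d` grain diameter, `u*` the shear velocity and `u*t` the impact threshold.
With Mars values (`eta = 1.3e-5` kg/m/s, `rho = 0.02` kg/m^3, `g = 3.71`
m/s^2, `u* = 1.45`, `u*t = 1.12` m/s) this gives ~29 m hops for 1 mm grains
and ~81 m for 0.125 mm grains. After `n` hops the travel distance is
bracketed by two end-members: a maximum `n * L_salt` under a prevailing
wind (hops add linearly) and a minimum `sqrt(n) * L_salt` with no
prevailing direction (isotropic random walk, RMS net displacement). The
survival fraction at `n` hops comes from a log-log interpolant through the
three measured anchors; a Weibull fit `S(t) = exp(-(t/lambda)^k)` (shape
`k ≈ 0.29 < 1`, i.e. sub-exponential inactivation) is provided for
extrapolation and synthetic-data generation.

## Worked example

```r
library(marsalt)

hop_length(planetary_environment(), wind_regime(), particle_class(1e-3))
#> [1] 28.66388

print(run_report(default_table1_config()))
#> Saltation travel-distance and survival report
#>   eta=1.3e-05 kg/m/s  rho=0.02 kg/m^3  g=3.71 m/s^2  u*=1.45  u*t=1.12 m/s
#>   hop lengths: 1 mm -> 28.7 m, 0.125 mm -> 81.1 m
#>
#> Rounded table (km):
#>  tumbling_time n_hops min_km_1mm max_km_1mm min_km_0p125mm max_km_0p125mm surviving_percent
#>       1 minute     60        0.2          2            0.6              5              50.0
#>         1 hour   3600        2.0        100            5.0            300               3.0
#>          1 day  86400        8.0       2000           24.0           7000               0.5
#>
#> Rounding-sensitive cells:
#>  tumbling_time diameter column    value_km
#>          1 day     1 mm    min    8.425426
#>          1 day     1 mm    max 2476.559323
```

Reading the last row: after a day of saltation (86,400 hops) 0.5% of the
original spores are still viable, and those survivors have travelled
between 24 km (0.125 mm grains, random walk) and 7,000 km (0.125 mm grains,
linear) — abrasion alone does not confine viable spores to the vicinity of
a lander. Distances are rounded half away from zero to one significant
figure (two in [10, 100) km); cells whose rounded value depends on whether
the hop length is itself pre-rounded to the nearest metre are flagged
rather than forced.

The numbered drivers under `analysis/` (hop-length sensitivity over the
`u*` range, survival-curve fit, table reproduction, Monte Carlo walk
validation, synthetic-assay parameter recovery) each narrate what they find
and write tables under `results/`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the headline quantities from scratch with the installed package
— the two Mars hop lengths, the three surviving percentages, and six
travel-distance cells at the table's printed precision — and writes them
as JSON.
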