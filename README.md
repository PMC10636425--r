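# scrcamtrap

Bayesian spatial capture–recapture (SCR) for camera-trap surveys of
individually identifiable animals, written for wildlife ecologists who
need defensible density estimates from sparse photographic data — a
handful of lynx, leopards or wildcats detected a few times each over a
winter season.

The package covers the whole path from raw records to mapped density:

* **Capture histories** under field-standard identification rules:
  unidentified events counted and removed, juveniles merged into their
  mothers, single-flank individuals excluded (configurable), one-day
  occasions, at most one detection per individual–site–day, and a
  per-site usage mask that absorbs stolen or broken cameras.
* **The M0 SCR model with data augmentation.** Each of `M` augmented
  individuals has a latent activity centre `s_i` uniform on a buffered
  state space `S` and membership `z_i ~ Bernoulli(psi)`; detection at a
  trap distance `d` away follows the half-normal
  `p = g0 * exp(-d^2 / (2 sigma^2))`, Bernoulli per day and masked by
  effort. Realized abundance is `N = sum(z)` and density
  `D = N / |S| * 100` per 100 km² at every posterior draw.
* **A purpose-built Metropolis-within-Gibbs sampler** (vectorised
  random-walk updates for all centres with boundary reflection,
  logit/log-scale Metropolis for `g0` and `sigma`, Gibbs for `z` and
  `psi`, burn-in-only adaptation), 3 × 10,000 iterations by default,
  exactly reproducible from a seed.
* **Diagnostics and precision**: Gelman–Rubin statistic with
  Brooks–Gelman 95% upper bound (converged when < 1.1), shortest-interval
  HPDs, and the CV of realized density (≤ 0.20 = high precision).
* **Spatial products**: trap-array minimum convex polygon (MCP) and its
  density, and a 1-km raster of realized activity-centre density,
  written as GeoJSON and ESRI ASCII grid.
* **A synthetic survey generator** (checkerboard 2.5-km camera grid,
  Poisson population, half-normal daily detections, camera-loss
  scenarios, known truth) so every stage is testable end to end.

Everything is tibble-first and pipe-friendly; fitted models support
`tidy()`, `glance()`, `autoplot()`.

## Worked example

Simulate a 30-site winter survey with known truth (density 1.5/100 km²,
`g0` = 0.05/day, `sigma` = 2.5 km), then analyse it as field data would
be:

```r
library(scrcamtrap)

sim <- simulate_survey(
  sim_config(D = 1.5, g0 = 0.05, sigma = 2.5,
             n_cells_x = 6, n_cells_y = 10, K = 60, buffer_km = 7.5),
  seed = 42)

cfg <- scr_config("2020-11-01", "2020-12-30", buffer_km = 7.5, M = 100,
                  mcmc = mcmc_config(n_iter = 4000, burn_in = 1000),
                  seed = 9)

result <- scr_analyze(sim$detections, sim$traps, cfg)
result
#> Survey summary
#>   individuals: 12 | recaptures: 52 ( 28 spatial )
#>   sites: 30 | occasions: 60 | effective trap-nights: 1800
#>   per-individual recaptures: 3 (8); 1 (7); 2 (6); 1 (3); 2 (2); 2 (1); 1 (0)
#> State-space buffer: 7.50 km | area 1031.2 km^2 | M = 100
#> Converged (Gelman-Rubin 95% upper bounds < 1.1)
#> Density: 1.83 / 100 km^2 (95% HPD 1.26-2.42), CV = 0.18 (high precision)
#> MCP: 275.0 km^2, density 1.73 / 100 km^2
```

Reading the output: 12 of the simulated animals were detected, with 52
recaptures of which 28 were at additional sites — those spatial
recaptures are what identify the movement scale. The posterior mean
realized density is 1.83 individuals/100 km² with a 95% HPD of
1.26–2.42, which covers the simulated truth of 1.5; the CV of 0.18
rates as high precision. The MCP density (1.73/100 km² over the 275 km²
trap polygon) counts only animals centred inside the array.

Posterior detail in broom form:

```r
tidy(result$fit)
#> # A tibble: 5 × 7
#>   term  estimate std.error conf.low conf.high  rhat rhat_upper95
#>   <chr>    <dbl>     <dbl>    <dbl>     <dbl> <dbl>        <dbl>
#> 1 g0      0.0469   0.00911   0.0310    0.0661 1.00          1.00
#> 2 sigma   2.62     0.216     2.23      3.07   1.00          1.01
#> 3 psi     0.195    0.0519    0.0960    0.295  1.000         1.00
#> 4 N      18.9      3.44     13        25      1.00          1.00
#> 5 D       1.83     0.333     1.26      2.42   1.00          1.00
```

`g0` and `sigma` (truth 0.05 and 2.5) sit well inside their intervals.
`autoplot(result$fit)` draws chain traces,
`autoplot(result$raster, traps = sim$traps)` maps activity-centre
density, and `write_scr_results(result, "out/")` serialises every
artifact (summary, chains, diagnostics, estimates, MCP GeoJSON, ASCII
raster) as plain text. Real data enter the same way through
`read_traps()` / `read_detections()` or, file-to-files, through
`run_analysis_files()` with a YAML configuration.

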