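---
title: "Bayesian spatial capture-recapture for camera-trap surveys: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian spatial capture-recapture for camera-trap surveys: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scrcamtrap)
```

## The problem

Camera-trap surveys of individually identifiable animals — lynx and other
patterned felids are the canonical case — yield sparse binary detection
records: a handful of identified individuals, each photographed a few
times at a few sites over a season. Naive (non-spatial) capture-recapture
turns these into abundance but needs an ad hoc effective survey area to
become density, and is known to inflate density estimates. Spatial
capture-recapture (SCR) instead models *where* each individual was
detected, linking detections to a latent activity centre per animal, so
density falls out of the model rather than out of a buffer guess.
`scrcamtrap` implements the complete pipeline: identification-rule
filtering, capture-history construction, a Bayesian M0 SCR model fitted
by a purpose-built Metropolis-within-Gibbs sampler, convergence and
precision diagnostics, and spatial posterior summaries. A synthetic
survey generator with known truth makes every stage testable.

## From photographs to a capture history

The package starts after photo identification: records carry an
individual id, a site, a date, the photographed flank and an age class.
Three field-standard rules are applied by `apply_exclusions()`, each
logged so the report can state what was discarded:

* **Unidentified events** (overexposed frames, pattern not visible) are
  removed and counted.
* **Juveniles** are dependent young and not separate demographic units;
  their detections are re-assigned to the mother when she is known,
  which adds recaptures. Juveniles with unknown mothers are removed and
  counted.
* **Single-flank individuals**: when an animal is known only from one
  flank, its left- and right-flank catalogues cannot be matched and one
  animal risks being counted as two. The default policy drops such
  individuals (and counts them); `keep-left`/`keep-right` retain one
  flank's catalogue for sensitivity analyses.

`build_capture_history()` then bins detections into one-day occasions
numbered from the configured window start. Seasonal exclusions (for
lynx, the March mating peak, when roaming males violate closure) are
expressed through the window, never hard-coded. Repeat photographs of an
individual at a site on one day collapse to a single detection: the
observation model is Bernoulli per individual-site-occasion, which both
bounds temporal autocorrelation and makes effort bookkeeping exact. The
per-site, per-day usage mask carries partial effort — a stolen camera is
simply usage 0 from its loss date; detections at inactive site-days are
dropped and logged. Full exclusion of a lost site is expressible by
zeroing its whole row, but the usage mask is the default treatment
because it keeps the effort the site did contribute.

`summarize_survey()` reports the margins that predict how well SCR will
do: the number of individuals, total recaptures (detections beyond each
individual's first), spatial recaptures (distinct sites beyond each
individual's first — the movement information that identifies the
detection scale), the per-individual recapture breakdown (skewed
breakdowns mean the information is concentrated in few animals), and
effective trap-nights.

## The model

The M0 SCR observation model has two detection parameters. An individual
with activity centre $s_i$ is detected at a trap at $x_j$ on one
occasion with probability

$$p_{ij} = g_0 \exp\!\left(-\frac{\lVert s_i - x_j\rVert^2}{2\sigma^2}\right),$$

the half-normal detection function: $g_0$ is the per-day detection
probability at the centre itself and $\sigma$ (km) the spatial decay
scale. M0 means both are shared across individuals — with unsexed,
sparsely detected animals, individual or sex effects are not estimable
and would overfit.

Abundance is handled by data augmentation. The $n$ detected individuals
are embedded among $M$ rows ($M$ well above any plausible population
size); row $i$ carries a membership indicator $z_i \sim
\mathrm{Bernoulli}(\psi)$ and an activity centre $s_i \sim
\mathrm{Uniform}(S)$, where the state space $S$ is the trap bounding box
buffered on all sides. Detections follow

$$y_{ijk} \mid z_i, s_i \sim \mathrm{Bernoulli}\!\left(z_i\,u_{jk}\,p_{ij}\right),$$

with $u_{jk}$ the usage mask. Realized abundance is $N = \sum_i z_i$ and
realized density $D = N / |S| \times 100$ (individuals per 100 km²) at
every posterior draw. Because occasions are exchangeable under M0, the
likelihood is evaluated site-wise as a binomial with the site's summed
usage as the trial count — algebraically identical to the per-occasion
Bernoulli product (the package's test suite verifies this against a
brute-force enumeration to 1e-10) and an order of magnitude faster.

Priors are the vague defaults of the Bayesian SCR literature:
$g_0 \sim \mathrm{U}(0,1)$, $\sigma \sim \mathrm{U}(0, L/2)$ with $L$
the longer state-space side, $\psi \sim \mathrm{U}(0,1)$. They let the
data dominate whenever there are spatial recaptures; with almost none,
posteriors for $\sigma$ widen honestly toward the prior.

### Choosing the buffer

The buffer must be wide enough that animals centred beyond it are
essentially undetectable — two to three $\sigma$ in practice. Without
telemetry, `suggest_buffer()` estimates the movement scale from the data
as the root pooled spatial variance (RPSV) of capture locations about
individual centroids and suggests $4 \times \mathrm{RPSV}$. RPSV is a
heuristic, not the bias-calibrated algorithm some ML-SCR packages ship;
simulation tests show it recovers $\sigma$ within 20% under heavy
sampling, and `buffer_km` can always be set explicitly (e.g. to
reproduce a published state space). With no spatial recaptures the
heuristic refuses and asks for a manual buffer.

## The sampler

`fit_scr()` runs a Metropolis-within-Gibbs sweep:

1. **Activity centres**: per-row Gaussian random-walk proposals,
   reflected at the state-space boundary (reflection keeps the proposal
   symmetric, so plain Metropolis acceptance applies). Rows are
   conditionally independent given the scalars, so all $M$ proposals are
   evaluated in one vectorised pass. Rows with $z_i = 0$ contribute unit
   likelihood and therefore follow their uniform prior.
2. **$g_0$** on the logit scale and **$\sigma$** on the log scale, each
   by Metropolis with the appropriate Jacobian; $\sigma$ proposals above
   the prior bound are rejected.
3. **$z$** for undetected rows from its Bernoulli full conditional,
   $\Pr(z_i = 1 \mid \cdot) = \psi p^{(0)}_i / (\psi p^{(0)}_i + 1 -
   \psi)$ with $p^{(0)}_i$ the probability of an all-zero history.
   Detected rows keep $z_i = 1$ throughout.
4. **$\psi$** from its conjugate $\mathrm{Beta}(1 + \sum z_i,\; 1 + M -
   \sum z_i)$.

Proposal scales adapt in batches of 50 sweeps during burn-in only
(stochastic-approximation steps toward 0.44 acceptance for scalars and
0.25 for the bivariate centres, the standard optima); scales freeze at
the end of burn-in so retained draws form a valid Markov chain. Default
settings are 3 chains × 10,000 iterations with 2,000 burn-in — the
standard protocol for sparse carnivore surveys — retaining 8,000 draws
per chain; activity-centre draws are thinned by 10 for mapping memory.
Each chain runs on an independently seeded RNG stream derived from the
analysis seed, so identical configuration and seed reproduce every draw
(and every written artifact) exactly.

Starting values are data-informed but jittered across chains: $\sigma$
from RPSV when available, detected individuals' centres at their mean
capture location, $\psi$ near $n/M$. With diffuse starts and short
chains the Gelman-Rubin flag fires more often; that is the diagnostic
doing its job.

## Diagnostics and precision

* `gelman_rubin()` implements the classic multi-chain potential scale
  reduction factor, point estimate
  $\sqrt{((n-1)/n \cdot W + B/n)/W}$, with a Brooks-Gelman 95% upper
  bound from the F sampling distribution of the between/within variance
  ratio. Convergence is declared when every monitored parameter's upper
  bound is below 1.1; `scr_analyze()` flags (never suppresses)
  non-convergence. A split-chain variant is available behind a flag for
  users who prefer the modern form; the classic form is the default
  because it is what the camera-trap SCR literature reports.
  Degenerate inputs are handled by convention: all chains constant and
  equal return 1 with a warning; disjoint constant chains return a
  large finite value rather than infinity.
* `hpd_interval()` returns the shortest contiguous interval containing
  `ceiling(mass * n)` order statistics, ties broken by the lowest start
  — so `1:100` at 95% gives [1, 95], and the interval is never wider
  than the equal-tailed one.
* `coefficient_of_variation()` is posterior SD over posterior mean of
  the realized-density chain, pooled across chains post burn-in; 0.20
  or below is labelled high precision, the conventional threshold.

## Spatial posterior products

`mcp_polygon()` builds the minimum convex polygon of the trap array
(convex hull, shoelace area) — the conventional reporting region.
`mcp_density()` counts realized activity centres falling inside the MCP
(boundary inclusive) across all stored draws, divides by the number of
draws and the MCP area: the expected number of animals *centred* in the
reporting region per 100 km². It is usually below the state-space
density when activity-centre clusters sit near the array edge.
`activity_center_raster()` bins realized centres onto a 1-km grid
aligned to the integer-km lattice; pixels are half-open cells, so they
partition the plane, the raster mass equals the posterior mean realized
N over its extent, and an axis-aligned MCP tiled by pixels gives exactly
the same density through either pathway (both identities are tested).
Draw bookkeeping is post burn-in by default;
`mcmc_config(ac_from = "all")` makes the stored draws (and all
denominators) span every iteration for analyses that follow the literal
all-iterations convention. The raster extent is the MCP by default,
matching how such maps are usually published, and is configurable to the
full state space.

## The synthetic generator

`simulate_survey()` generates surveys from the same generative model the
estimator assumes, with known truth:

* a 2.5 × 2.5 km grid with a paired-camera site in every other cell
  (checkerboard) — the standard lynx design, guaranteeing at least one
  site per home range while halving camera count; cell size,
  checkerboard and array dimensions are configurable;
* activity centres uniform over the buffered rectangle, with $N \sim
  \mathrm{Poisson}(D\,|S|/100)$ or fixed;
* daily Bernoulli detections from the half-normal model, masked by
  usage; camera thefts are emulated by zeroing usage from a loss day;
* sparsity arises through low $g_0$ (around 0.01/day, as real lynx
  surveys report), never by post-hoc subsampling, so the generative
  model stays honest.

`preset_scenarios()` ships three scenarios spanning the realistic design
range — a small mountain-park array (35 sites, 90 occasions, density
0.46/100 km²), a large exclusion-zone array (65 sites, 112 occasions,
density 1.54/100 km², augmented size 300 because many individuals are
expected) and a large lowland array (50 sites, 120 occasions, density
0.45/100 km², the largest movement scale). True $\sigma$ values of
4.5-6.5 km correspond to analysis buffers of 13-20 km.

What the generator does *not* emulate — and hence what passing tests do
not certify about field data: territorial spacing (real centres are not
uniform-independent), sex-specific detection, behavioural responses to
traps, misidentification, and habitat heterogeneity in both density and
detectability. Recovery results on synthetic data certify the estimator,
not the field design.

## Validation problem sizes

The test suite checks the likelihood against brute-force enumeration on
all fixtures up to 3 individuals × 3 traps × 3 occasions (tolerance
1e-10), the ψ full conditional against its Beta law by Kolmogorov-
Smirnov at α = 0.01, and the diagnostics against closed forms and
against the `coda` reference implementations. Parameter recovery runs
the exclusion-zone scenario scaled to 30 sites, 60 occasions, M = 100
and 3 chains × 2,000 iterations (burn-in 500) over 20 seeded
replicates, requiring the true density, $g_0$ and $\sigma$ each inside
their 95% HPD in at least 17 of 20 — the size at which a full recovery
study stays a few minutes on one core while each replicate still
detects 20-35 individuals. `scripts/acceptance.R` re-runs the same
quantities from scratch under a caller-supplied seed.

## Known limitations

* Rectangular state spaces only: no habitat mask, so density refers to
  the buffered rectangle including any unsuitable habitat in it.
* M0 only: no sex, individual, behavioural or temporal detection
  effects; densities can be biased low when detection is strongly
  sex-structured.
* Single closed season: no open-population dynamics.
* RPSV buffers are heuristic; for bias-calibrated buffers use an
  explicit `buffer_km`.
* The Gelman-Rubin flag is necessary, not sufficient: inspect
  `autoplot(fit)` traces, as every careful analysis should.
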