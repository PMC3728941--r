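---
title: "Delineating foraging areas from satellite telemetry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating foraging areas from satellite telemetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ridleyfaf)
```

## The problem

Adult female Kemp's ridley turtles (*Lepidochelys kempii*) leave their Gulf
of Mexico nesting beaches after the nesting season and take up residence at
discrete nearshore foraging sites, sometimes pausing to forage along the
migratory route. Argos satellite tags record their positions — irregularly
in time, gated by a transmitter duty cycle, and with location-class (LC)
dependent errors ranging from a few hundred metres (LC 3) to many kilometres
(LC A/B). Turning such records into defensible statements about *where*
animals foraged, *how faithful* they were to those sites, and *which
environmental conditions* characterise them requires a chain of inferential
steps. This package implements that chain end to end:

1. a **switching state-space model** that regularises each track to an 8-h
   grid while classifying every interval as migration or foraging;
2. **segmentation** of the behavioural sequence into foraging periods,
   labelled `F` (final destination) and `F1`–`F3` (sites used just prior,
   walking backwards in time);
3. **fixed-kernel density core areas** (50% contours) of the mean daily
   locations at each site, with least-squares cross-validated bandwidths;
4. a **Monte-Carlo site-fidelity test** comparing the observed path's
   dispersion against bathymetry-constrained random walks;
5. a **habitat regression** of gridded foraging-day counts on bathymetry,
   SST, net primary production, and distances to shore and release site.

Because the original tracking data were never deposited, the package ships a
**synthetic-data generator** that reproduces the statistical structure of
the study system, so every stage is testable without a download.

## The movement model

The core model is a two-state switching first-difference correlated random
walk (DCRW). Let $x_t$ be the (unobserved) position at node $t$ of a regular
8-hour grid, in an equal-area km plane, and $d_t = x_t - x_{t-1}$ the
displacement. Then

$$ d_t \mid d_{t-1}, b_t \;\sim\; \mathcal{N}\!\big(\gamma_{b_t}\,
   R(\theta_{b_t})\, d_{t-1},\; \Sigma\big), $$

where $b_t \in \{1,2\}$ is the behavioural state (1 = migration,
2 = foraging/nesting), $\gamma_k \in [0,1]$ the move persistence,
$R(\theta_k)$ a rotation by the mean turn angle, and $\Sigma$ a single
process covariance shared by both states (parameterised by per-axis standard
deviations and a correlation). The state sequence is Markov, with
$\alpha_k = \Pr(b_t = 1 \mid b_{t-1} = k)$. Migration is *identified* as the
higher-persistence state by the prior constraint $\gamma_1 > \gamma_2$.

Each Argos fix $y_j$, observed at an arbitrary time inside grid interval
$i_j$ with fractional offset $w_j$, is linked to the linear interpolation of
the bracketing states, with a heavy-tailed error whose scale depends on the
fix's location class:

$$ y_j = (1 - w_j)\, x_{i_j} + w_j\, x_{i_j+1} + \varepsilon_j, \qquad
   \varepsilon_j \sim t_{\nu_c}(0, \psi_c) \text{ per axis.} $$

Class-Z fixes are invalid and removed before fitting.

### Sampler

The posterior is explored by an adaptive Metropolis-within-Gibbs sampler
written in C++:

* latent positions: per-node random-walk proposals, scales adapted during
  burn-in toward a 0.25–0.45 acceptance band;
* behavioural states: a **joint forward-filter backward-sampling** update of
  the whole sequence (single-site updates can lock a chain into a merged
  one-state mode; the joint update removes that failure);
* switch probabilities: conjugate Beta draws from the transition counts;
* $\gamma_k$, $\theta_k$: random-walk Metropolis, the turn angle with an
  occasional half-turn mode jump so chains can cross between the
  forward-persistence and reversal (area-restricted search) modes;
* $\Sigma$: log-scale and Fisher-z random-walk Metropolis.

Priors are uniform on $[0,1]$ for $\gamma$'s and $\alpha$'s, uniform on the
circle for turn angles, half-normal (scale 10 km) on the process SDs, and
uniform on $(-1, 1)$ for the correlation. LC observation scales are fixed at
configured constants (defaults 0.25, 0.5, 1.5, 5, 8, 15 km for classes
3, 2, 1, 0, A, B, all with $\nu = 4$) — the published accuracy ordering with
literature-order magnitudes, configurable because the study does not print
its own values.

Production settings follow the study: two independent chains, 10,000
retained samples after a 7000-iteration burn-in, thinned by five, on an
8-hour grid (`ssm_config()`). A reduced preset (2000 retained, burn-in 1000,
thin 2; `preset = "desk"`) is used throughout the experiments; at these
problem sizes (150-day tracks, about 450 nodes) a fit takes a few seconds
and recovery experiments stay within minutes. Convergence is gated
quantitatively — per-parameter potential scale reduction factor across
chains, flagged above 1.1 — replacing the visual trace-plot inspection of
the original workflow, because a numeric gate is testable.

A node is classified as foraging when the posterior mean behavioural index
is at least 1.5, the symmetric binary choice; the cutoff is a parameter.

## Segmentation and site labels

Maximal runs of constant mode form behavioural segments. If the track ends
in a foraging segment, that segment is the final site `F` (the assumed final
destination); earlier foraging segments of at least 20 days are labelled
`F1`, `F2`, `F3` walking backwards in time. Tracks ending in migration have
no `F`, and labelling starts at `F1`. Foraging segments shorter than 20 days
are skipped for labelling and kernel estimation but still contribute their
days to the habitat grid, which excludes only periods shorter than 2 days —
the two thresholds serve different analyses and are both configurable.
Sub-2-day mode flickers are not smoothed away; robustness to flicker is
delegated to the posterior mean of the behavioural index.

## Core areas

Within each labelled site, fixes are re-filtered for the foraging context
(water no deeper than 100 m, never on land, a 10 km/h speed gate for
spatially distant outliers) and collapsed to mean daily locations to limit
temporal autocorrelation. For sites with at least 10 daily locations the
utilization distribution is estimated with a fixed Gaussian kernel on a
planar grid of resolution $h/4$; the 50% core area is the set of cells of
highest density holding half the total mass (threshold chosen on the
discrete grid by sorting cell masses — deterministic and testable), clipped
to water, with areas in km² read off the equal-area plane.

The bandwidth minimises the least-squares cross-validation score of the
Gaussian product kernel. When the coordinate standard deviations differ by
more than a factor of 1.5 the data are standardised per axis first and the
bandwidth back-scaled (the "unequal variance" rescaling, with the trigger
made explicit since the source workflow states none). Two numerical
safeguards matter in practice:

* duplicate coordinates (common in telemetry) drive the LSCV score to
  $-\infty$ as $h \to 0$; the minimiser is therefore taken as the best
  *interior* local minimum on a log-spaced grid, refined by golden-section
  search, with a warning-and-reference-bandwidth fallback when no interior
  minimum exists;
* the plug-in 50% region of a kernel estimate is inflated by smoothing —
  for Gaussian data its area concentrates near
  $2\pi \ln 2\, (\sigma^2 + h^2)$ rather than $2\pi \ln 2\, \sigma^2$.
  No shrinkage correction is applied, matching the behaviour of the
  standard home-range tools this stage mirrors; validation therefore
  checks the *median* relative error over replicate Gaussian fixtures
  (about 12% at $n = 500$) against a 15% band rather than a single draw of
  the notoriously variable LSCV bandwidth.

When a core area comprises several disjoint activity centers, the reported
centroid is the mass-weighted centroid of the largest center by area.

## Site fidelity

The fidelity statistic is the mean squared distance (MSD) of the site's
daily locations about their mean center. Each of 100 replicate paths keeps
the observed step lengths in order, starts at the observed start point, and
draws headings uniformly; any step landing outside the −100 to 0 m
bathymetry band is redrawn (up to 100 attempts, then reflected back along
the incoming direction). `proportion_higher` is the percentage of replicates
whose MSD exceeds the observed value; fidelity is declared at 95
(a one-sided 0.05 level). Under the null — an observed path that is itself
a constrained random walk — the observed MSD is exchangeable with the
replicates and the rejection rate sits near $6/101 \approx 5.9\%$, which the
calibration experiment reproduces (4–7% over 200 repeats).

One deliberate design choice: the historical test offers coordinate
standardisation when latitude and longitude have unequal standard
deviations. That device corrects the unequal *metric* scales of geographic
degrees. This pipeline tests in an equal-area km plane where the axes are
already commensurate, and weighting by the observed path's own realised
shape breaks null exchangeability (random walks are characteristically
elongated), inflating the null rejection rate to about 10%. Standardisation
is therefore off by default and available via `rescale_trigger` for paths
supplied in geographic coordinates.

## Habitat regression

A 25 × 25 km lattice is laid over the projected domain; a cell is retained
when any of a 3 × 3 subsample of points inside it falls in water no deeper
than 100 m (the isobath bound). Covariates are sampled at cell centers:
bathymetry, annual SST, NPP, distance to the mainland shore, and distance
to the mean release location. Every mean daily foraging location from
periods of at least 2 days adds one turtle-day to its cell, pooled over
animals (an exact conservation law used as a test). To limit spatial
correlation, a random 20% of cells is drawn without replacement before
fitting.

The source workflow states only "a generalized linear model with log
transformation". Day counts are non-negative integers with many zeros, so
the default here is a log-link Poisson fit with Pearson overdispersion
scaling (quasipoisson); a log-normal alternative — Gaussian on
$\log(y + 1)$, keeping zero cells — is available via `family`. Wald
statistics (estimate, SE, 95% CI, chi-square, p) are reported per
coefficient. Parameter recovery is validated by simulating counts from the
published coefficient vector on 155 synthetic cells with realistic covariate
distributions and refitting: each coefficient falls within 2 SE of truth in
roughly 90–98% of replicates.

## The synthetic generator: what it does and does not emulate

`sim_config()` + `simulate_cohort()` generate a 31-animal postnesting
cohort, 98–342 days per animal, released from two tagging areas in a 22:9
ratio, over a seeded synthetic shelf (`generate_environment()`): a smooth
east–west coastline, depth increasing monotonically offshore (the 100-m
isobath near 150 km), southwards-warming SST in a 24–28 °C band,
nearshore-enriched NPP near 3600 mg C/m²/day at typical site distances,
and a barrier island so "nearest land" and "mainland" are genuinely
different quantities.

The true movement process is the switching DCRW above, with three
realism extensions: wrapped-Cauchy turn noise, *per-state* process SDs
(4 km migration, 1.5 km foraging), a foraging mean turn of $\pi$ (the
area-restricted-search reversal signature), and confinement to the shelf
band (steps into water deeper than 90 m are redrawn like steps onto land,
matching the species' strictly nearshore habit — every observed final site
lay in water shallower than 68 m). Observation: fix times as a Poisson
process thinned by a 6 h on/6 h off duty cycle (plus a deployment fix at
release — without it the estimation grid is phase-shifted from the
simulator's discrete truth and the interpolation artificially smooths the
process), multinomial LC classes, isotropic per-axis $t_4$ errors with the
per-class scales above, and a 2% share of class-Z junk.

Two emulation gaps matter for interpreting test results. First, the
cohort generator's per-state process SDs and stochastic turns deliberately
violate the fitted model's shared-covariance assumption — mode
classification survives this mismatch (90–98% node accuracy against the
simulator's truth) but the foraging-state persistence absorbs part of the
unmodelled variance, so cohort-level parameter estimates are not unbiased.
The *parameter-recovery* experiment therefore generates from the model's own
assumptions (shared $\sigma$ = 3 km, deterministic turns). Under the
experiment's conditions ($\gamma$ = 0.8/0.2, stay-probabilities 0.95) the
Bayes-optimal classification ceiling — forward–backward smoothing given the
*true* positions and parameters — is itself only 88–96% depending on the
realisation, so node-accuracy results just below 90% at some seeds reflect
the information content of the fixture, not estimator error. Second,
synthetic animals select habitat by movement dynamics alone, not by
SST/NPP preference, so cohort-level regression coefficients need not match
the published signs; the regression stage is validated by the dedicated
coefficient-recovery experiment instead.

## Numerical and interface choices

* All areas, distances and MSDs are computed in a spherical Albers
  equal-area projection centred on the Gulf (−90°E, 25°N; standard
  parallels 20°/30°N): the source workflow's "meter-based projection" is
  unnamed, and equal-area is what km² core areas require. Round-trip error
  is sub-metre and a 0.5° test square's area is preserved to <0.1% across
  the domain.
* Great-circle distances use the haversine formula with radius 6371 km.
* Duplicate timestamps within an animal keep the better location class
  (quality ordering 3 > 2 > 1 > 0 > A > B > Z); the day boundary for mean
  daily locations is the UTC calendar date.
* The "spatially very distant" filter is a forward pass dropping fixes that
  imply more than 10 km/h from the last retained fix — above sustained
  hard-shelled-turtle speeds, configurable, and idempotent by construction.
* Every stochastic function takes a seed; a pipeline master seed fans out
  to stage-level child seeds by fixed offsets, and same-seed reruns are
  byte-identical.

## Known limitations

* Position credible intervals summarise running means and variances of the
  retained samples (a normal approximation), not full posterior quantiles.
* No hierarchical pooling across animals: each track is fitted
  independently, as in the source workflow.
* The fidelity replicate preserves step lengths but not their serial order
  relative to headings; long-memory speed structure is only partly retained.
* Spherical (not ellipsoidal) geometry throughout; results are insensitive
  at the sub-percent level at Gulf scales.
* The habitat grid samples covariates at cell centers; within-cell
  heterogeneity is ignored, as in the 25-km source analysis.
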