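---
title: "Chilling and forcing assessment under climate scenarios: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chilling and forcing assessment under climate scenarios: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chillforce)
```

Temperate fruit trees (apple, pear, plum, and at the warm margin citrus)
need a dose of winter cold to break dormancy and a dose of warmth to flower
and ripen. When winters warm, the cold dose can fail; when summers warm past
the physiological optimum, extra heat stops helping. chillforce quantifies
both sides of this balance — chill accumulation with the Dynamic model
(Chill Portions, CP) and heat accumulation with the Growing Degree Hours
model (GDH) — and carries them through a full climate-scenario workflow:
bias correction of simulated temperatures, percentile-based risk indices,
multi-model ensembles, and regional trends. A synthetic weather generator
with known imposed structure makes every stage testable end to end without
external gridded datasets.

This vignette documents the models, the conventions the package commits to
where the literature leaves a choice open, and the limits of what the
synthetic tests demonstrate.

## Thermal models

### Growing Degree Hours

Each hour at temperature $T$ (degC) contributes

$$
\mathrm{GDH}(T) =
\begin{cases}
0 & T \le T_b \text{ or } T \ge T_c\\[2pt]
F\,\dfrac{T_u - T_b}{2}\left(1 + \cos\left(\pi + \pi\dfrac{T - T_b}{T_u - T_b}\right)\right) & T_b < T \le T_u\\[6pt]
F\,(T_u - T_b)\left(1 + \cos\left(\dfrac{\pi}{2} + \dfrac{\pi}{2}\dfrac{T - T_u}{T_c - T_u}\right)\right) & T_u < T < T_c
\end{cases}
$$

with base $T_b = 4$ degC, optimum $T_u = 25$ degC, critical $T_c = 36$ degC
and stress factor $F = 1$ (no stress adjustment). Both branches equal
$F\,(T_u - T_b) = 21$ degree-hours at $T_u$, so the response is continuous
and maximal at the optimum. Totals are accumulated over the forcing season
(1 February – 31 October) and conventionally reported in units of $10^3$
degree-hours.

```{r gdh}
gdh_hour(c(4, 14.5, 25, 36))
```

### Dynamic model (Chill Portions)

Chill is modelled as a two-step chemical kinetic: each hour an intermediate
relaxes first-order toward a temperature-dependent equilibrium
$x_s = (a_0/a_1)\,e^{(e_1 - e_0)/T_K}$ at rate $k_1 = a_1 e^{-e_1/T_K}$
($T_K$ in Kelvin); whenever the intermediate reaches 1, a sigmoidal
fraction $\xi(T)$ of it converts irreversibly into chill portions and the
remainder carries over. The canonical published constants are used
(`slp = 1.6`, `tetmlt = 277` K, `a0 = 1.395e5`, `a1 = 2.567e18`,
`e0 = 4153.5` K, `e1 = 12888.8` K), and the intermediate is reset to zero
at the start of every chill season (1 October – end of February, including
29 February in leap years).

Because warm hours relax the intermediate back down, high temperatures
cancel partially accumulated chill — the behaviour that makes the Dynamic
model preferable to simple chilling-hour counts in warm production regions.
Two consequences verified by the test suite: the cumulative CP series is
monotone, and chill efficiency at constant temperature peaks a few degrees
above freezing (about 6 degC under the canonical constants; the often-cited
"about 4 degC" optimum is an approximation), falling to exactly zero below
about $-16$ and above about $24$ degC.

```{r cp}
sapply(c(-20, 0, 4, 6, 10, 30), function(T) chill_portions(rep(T, 720))$total)
```

The hourly recursion cannot be vectorized (the conversion event resets the
state), so it is implemented in C++; an independent scalar R implementation
serves as the test oracle, and the two agree to within $10^{-6}$ relative
on multi-season series.

### Season windows and labels

A chill season labelled $Y$ spans 1 October of $Y-1$ through the end of
February of $Y$ — the label follows the January–February year, matching how
safe-chill years are counted against harvest years. A forcing season
labelled $Y$ spans 1 February – 31 October of $Y$. Seasons whose window is
not fully covered by the data (typically the first chill season) are
omitted with a warning, never silently filled. Windows are
northern-hemisphere only; southern-hemisphere grids are rejected with an
explicit error rather than given wrong seasons.

## Daily-to-hourly reconstruction

Both thermal models need hourly temperatures, but gridded products provide
daily extremes. The package uses an idealized diurnal curve: daytime
follows a sine from `tmin` at sunrise up to `tmax` at the daily peak —
placed at sunset minus 3 hours — and back down until sunset; from sunset
the temperature decays logarithmically toward the next day's `tmin`,
reached exactly at the next sunrise. Sunrise and sunset come from the
standard day-angle formulation of solar declination
($\delta = 23.45^\circ \sin(2\pi(284 + d)/365)$,
$\cos H_0 = -\tan\phi\tan\delta$), with solar noon fixed at 12:00 local
solar time: thermal sums are insensitive to a constant phase shift, so no
longitude or timezone correction is applied.

Two numerical choices worth knowing:

* Sunrise, sunset and the peak are rounded to whole hours, so the 24
  sampled values of a day attain `tmin` (at the sunrise hour) and `tmax`
  (at the peak hour) exactly rather than approximately.
* Late-night hours of a day can fall slightly below that day's own `tmin`
  when the following day is colder — the decay targets the *next* sunrise.
  Hourly values always stay within the envelope of the three neighbouring
  days' extremes, which is the invariant downstream accumulation relies on.

At the series edges the first/last day stands in for its missing
neighbour. Daylength at polar latitudes is clamped to $[0, 24]$ h with a
warning; the intended domain is $|\phi| \le 66.5^\circ$.

## Bias correction and regridding

Observations are first bilinearly regridded to the (coarser) scenario grid
— the interpolation is exact for fields linear in latitude and longitude,
and target cells outside the source span get nearest-edge extrapolation
with a warning. Empirical Quantile Mapping is then fitted per cell,
calendar month and variable (`tmin` and `tmax` independently), pooling all
years of the overlap between the observed period and the simulated
historical segment:

* 99 probability levels $k/100$, $k = 1\dots99$;
* piecewise-linear interpolation between matched quantile pairs inside the
  fitted range;
* constant shift (the offset at the outermost quantile) beyond the fitted
  range — values are shifted, never clamped, so future warming beyond the
  historical range survives correction;
* a fitted pool of fewer than 30 days is an error naming the pool, and a
  corrected `tmin`/`tmax` pair that inverts is swap-repaired and counted.

Monthly pooling and the 99-percentile ladder are standard practice; they
are recorded here as this package's convention since the underlying
literature frequently leaves them unstated. The transform is monotone by
construction. Applied back to its own fitting data it reproduces the
observed quantiles almost exactly; the acceptance suite also verifies the
pipeline-level property that a $+3$ degC additive bias leaves the corrected
chill climatology within 5% of the observation-derived one.

## Indices, ensembles, trends

**Safe Winter Chill / Safe Heat Forcing** are the 10th percentiles of the
annual CP and GDH totals over a period — the dose exceeded in 90% of
years, which is what an orchard investment actually needs. Percentiles use
linear interpolation between order statistics with plotting position
$h = (n-1)p + 1$ (R's type 7): with annual values $10, 11, \dots, 26$ the
10th percentile is $11.6$, a worked value frozen into the tests. At least 5
seasons are required per cell; short cells are returned missing with a
warning.

**Ensembles** are summarized by the arithmetic mean and the *population*
standard deviation (divide by $n$): the model pairs enumerate the ensemble
rather than sample a larger population.

**Future subperiods** are 2021–2040 (short term), 2041–2060 (medium term)
and 2061–2080 (long term) — three disjoint 20-year blocks compared against
the 1989–2005 baseline.

**Trends** are ordinary-least-squares slopes of the regional annual
ensemble-mean index against calendar year over 2021–2080, in index units
per year, with standard errors and 95% confidence intervals carried along.

**Regional statistics**: a cell belongs to a region if its centre lies
inside the region polygon (even-odd rule) or is listed explicitly; the two
representations are interchangeable and tested as such. Boxplot statistics
(min, q25, mean, median, q75, max) use the same percentile convention as
the indices.

## The synthetic weather generator

The generator is first-class, tested code — it defines the study
conditions under which every pipeline property is demonstrated. Daily mean
temperature at cell $c$, day $d$ is

$$
T(c,d) = T_0 + g\,(\phi_c - \phi_{\mathrm{ref}})
 + A\cos\!\left(\frac{2\pi\,(\mathrm{doy}_d - 196)}{365.25}\right)
 + w\,t_d + \varepsilon(c,d),
$$

i.e. a seasonal cycle peaking at day-of-year 196 (northern mid-July), a
latitudinal gradient, a linear warming trend and stationary AR(1) noise;
extremes are $T \pm \mathrm{diurnal\ range}/2$ plus independent
half-amplitude noise, with a swap repair preserving
$t_{\min} \le t_{\max}$. Defaults describe a Portugal-like temperate
domain (36.5–42.5 degN, 9.5–6 degW): annual mean 15 degC at 40 degN,
gradient $-0.7$ degC per degree latitude, amplitude 6.5 degC, diurnal
range 10 degC, AR(1) coefficient 0.7, noise sd 2 degC. These were chosen
once as field-realistic values for a western-Iberian fruit-growing
climate and are not tuned thereafter.

Scenario series share one synthetic truth per scenario; each mock model
pair receives a known bias $\mathrm{scale}\cdot T + \mathrm{offset}$, with
per-model offsets drawn deterministically from the seed around the
configured central bias, and the true bias is recorded in the series
metadata so tests can assert against it. Scenario warming starts the year
*after* the historical segment, so the historical overlap reproduces the
baseline climate — with zero bias and the same seed it reproduces the
baseline series bit for bit, which is itself a tested property. RNG
substreams are per cell and per noise component, so extending the future
horizon never changes the historical values.

The demo scenarios impose 0.02 degC/yr (moderate) and 0.045 degC/yr
(strong) of warming — roughly the mid-range and high-end trajectories of
the scenario literature over 2006–2080. For the trend-recovery
experiment, a rate of 0.035 degC/yr on a small warm two-by-two domain
(37–37.9 degN) was calibrated once, in a standalone experiment, to
produce a chill decline of about $-0.45$ CP/yr; the recovered OLS slopes
across seeds are required to land in $[-0.60, -0.30]$, and a zero-trend
null must yield a slope confidence interval covering zero.

### What the synthetic tests do and do not show

The generator reproduces the *statistical shape* real products have —
seasonal cycle, spatial gradient, day-to-day persistence, known biases and
trends — which is exactly what the pipeline's correctness depends on. It
deliberately does not emulate: spatially correlated weather (cells are
independent realizations around a smooth surface), non-Gaussian tails,
humidity or precipitation, elevation effects, or the observational error
structure of any real gridded product. Passing tests therefore demonstrate
that the machinery is correct — that biases are removed, trends recovered,
indices computed as defined — not that any particular real-world number is
reproduced. Quantities that depend on real observational and scenario
archives are out of reach of a desk-scale synthetic rerun by construction.

## Problem sizes and determinism

The demo configuration (10x10 observational grid regridded to 8x8, two
model pairs, two scenarios, 1989–2080, eight regions) was sized so a full
run completes in about a minute on a single CPU while still exercising
every stage on a genuinely gridded, multi-member problem. All randomness
flows from one integer seed through deterministic substreams; rerunning
the pipeline with the same configuration and seed reproduces every CSV
output byte for byte, and the JSON manifest records the configuration
hash, seed and package version needed to reproduce a run.

## Known limitations

* Ensemble spread is understated: members share one weather realization
  and differ only in bias (and bias is largely removed by correction), so
  the ensemble standard deviation exercises the machinery rather than
  emulating real inter-model divergence.
* The hourly curve is an idealized clear-sky shape; advection days,
  inversions and coastal fog do not follow it. Thermal totals inherit
  whatever error that causes in real applications.
* Quantile mapping is stationary: the historical simulated-observed
  correspondence is assumed to hold in the future (the usual EQM
  assumption); trend-preserving variants are intentionally out of scope.
* Region masks are user-supplied polygons or cell lists; no land-use
  filtering is performed.
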