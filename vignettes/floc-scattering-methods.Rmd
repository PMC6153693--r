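---
title: "Methods: optical fractal dimension and size structure of activated-sludge flocs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optical fractal dimension and size structure of activated-sludge flocs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flocscatter)
```

## The measurement model

Activated-sludge flocs are aggregates of bacterial cells, extracellular
polymeric substance and inorganic fines. Over an intermediate range of
length scales their mass scales as a power of their size, and in a static
light-scattering experiment this fractal organisation appears as a linear
stretch on the log-log plot of scattered intensity $I$ against the
scattering-vector magnitude

$$q = \frac{4\pi n \sin(\theta/2)}{\lambda},$$

with $\theta$ the scattering angle, $n$ the refractive index of the medium
(1.33 for water) and $\lambda$ the illumination wavelength (0.6328 µm for
the He-Ne laser of a typical granulometer; both are fields of
`optical_config()`). The scattering vector probes structure at length
scale $\sim 1/q$, which gives the three-regime forward model implemented
in `composite_intensity()`:

* **Guinier regime**, $q \le 1/a$: $I(q) = I_0 e^{-q^2 R_g^2/3}$, governed
  by the radius of gyration $R_g$ of the whole floc;
* **fractal regime**, $1/a \le q \le 1/R_\mathrm{p}$:
  $I(q) \propto q^{-D_f}$, with $D_f \in (1, 3]$ the mass fractal
  dimension;
* **Porod regime**, $q \ge 1/R_\mathrm{p}$: $I(q) \propto q^{-4}$, surface
  scattering from the smooth primary particles of size $R_\mathrm{p}$.

Here $a$ is the largest structure whose scattering is not yet of Porod
type; the reciprocals $1/a$ and $1/R_\mathrm{p}$ bound the fractal window.
The branch prefactors are rescaled so the composite curve is continuous at
both crossovers, making it strictly positive and non-increasing for every
admissible parameter set.

Two functional-form choices deserve a note. First, the textbook quadratic
Guinier expansion $I_0(1 - q^2R_g^2/3)$ (available as
`guinier_intensity()`) turns negative once $qR_g \ge \sqrt3$. Flocs
typically have $R_g$ much larger than $a$ — with the defaults used here,
$R_g/a$ runs from about 1 to 15 — so the quadratic form would go negative
*before* the first crossover. The composite model therefore uses the full
exponential Guinier law, which agrees with the quadratic form where that
form is valid (to 0.5% for $qR_g \le 0.3$) and stays positive everywhere.
Second, the model is deliberately piecewise rather than a smooth unified
(Beaucage-type) blend: the regime bounds are themselves quantities of
interest, and sharp crossovers keep them exactly recoverable in tests.

The exact Rayleigh-Gans-Debye (RGD) sphere form factor

$$P(x) = \left[\frac{3(\sin x - x\cos x)}{x^3}\right]^2, \qquad x = qR,$$

is included (`rgd_sphere_form_factor()`) purely as an independent oracle:
its small-$x$ expansion $1 - x^2/5 + O(x^4)$ combined with
$R_g^2 = \tfrac{3}{5}R^2$ for a sphere reproduces the $1/3$ Guinier
coefficient, and the log-log slope of its local-maxima envelope at large
$x$ reproduces the Porod exponent $-4$. Both identities are asserted in
the test suite, so the forward model's two limiting exponents are derived
rather than assumed. Numerically, $P$ is evaluated from its series
$1 - x^2/10 + x^4/280 - x^6/15120$ below $x = 0.1$, where the direct
formula loses up to half its significant digits to cancellation.

## Estimating the fractal dimension

`fd_pipeline()` composes four steps, each available separately.

**Regime detection** (`detect_power_law_regime()`). The instrument
literature marks the fractal window by eye; an explicit algorithm is a
design choice of this package. We search for the *longest contiguous*
window of grid points satisfying three gates:

1. the OLS fit of $\log_{10} I$ on $\log_{10} q$ over the window has
   $r^2 \ge$ `r2_min` (default 0.995);
2. every per-point local slope deviates from the window's OLS slope by
   less than `slope_tol` (default 0.15). Local slopes are centred finite
   differences for interior points and one-sided secants at the window
   ends, so the test never looks outside the candidate window — this makes
   detection exactly idempotent (re-running on the curve restricted to its
   own bounds returns the same bounds) and recovers ground-truth
   crossovers to within one grid step on synthetic curves;
3. the window's slope magnitude is below `max_slope` (default 3.5). This
   gate is essential: the Porod branch is itself an exact power law and on
   a wide grid is often the *longest* one, but its exponent 4 exceeds the
   physical ceiling of 3 for a mass fractal. The default 3.5 sits midway
   between that ceiling and the Porod exponent.

Windows shorter than `min_points` (default 8) are ignored; ties between
equally long windows go to the smaller $q$. A curve with no qualifying
window — pure Guinier curvature, or noise that defeats the $r^2$ gate —
raises a typed `flocscatter_no_regime` error rather than returning a
meaningless fit. With the default grid spacing (200 points over five
decades) and noise model, per-point local-slope noise has a standard
deviation of about 0.06, so `slope_tol = 0.15` trims occasional outlying
points without shortening the window materially; `r2_min = 0.995` rejects
curved (Guinier) stretches while accepting fractal windows whose residual
scatter comes only from measurement noise.

**Fitting** (`fit_power_law()`). Ordinary least squares of
$\log_{10} I$ on $\log_{10} q$ inside the window; the slope is
base-invariant. The slope's standard error uses the residual variance
with $n - 2$ degrees of freedom. A zero-variance response (an exactly
flat curve) is treated as perfectly fit ($r^2 = 1$) rather than
undefined. The fractal dimension is the negated slope; estimates outside
$(1, 3]$ warn but are never clamped — values just below 2 occur in real
sludge and must be reportable.

**Confidence interval** (`student_t_ci()`). The halfwidth is
$t_{(1+\ell)/2,\,n-2} \cdot \mathrm{se}(\hat\beta)$ at confidence level
$\ell$ (default 0.95). Under the default synthetic noise model every
interval in a 69-sample ensemble has halfwidth below 0.01, comfortably
inside the ±0.05 ceiling the package's acceptance checks enforce.

**Diameter conversion** (`q_to_diameter()`). The regime bounds are
reciprocals of sizes, so the default convention is $d = 1/q$: the window
$[q_\mathrm{low}, q_\mathrm{high}]$ maps to diameters
$[1/q_\mathrm{high}, 1/q_\mathrm{low}]$. The Bragg-like alternative
$d = 2\pi/q$ is available (`convention = "two_pi"`) but never the
default; fitted dimensions are unaffected by the choice, only the
reported diameter range scales. The RGD approximation nominally requires
$d < \lambda$; `fd_pipeline()` flags (`exceeds_rgd`) when the fitted
range extends beyond the wavelength, which for flocs it essentially
always does — the flag documents the extrapolation instead of forbidding
it.

## Size distributions: volume versus number

Laser granulometers natively report *volume-weighted* PSDs; particle
counts tell a different story. `reweight()` bridges the two bases with
the cubic rule $n_i \propto v_i/d_i^3$ per bin (and its exact inverse),
where $d_i$ is the bin's representative diameter — the geometric mean of
its edges, the natural centroid on grids whose bins are uniform in
$\log d$ (arithmetic means would be badly biased in bins spanning
decades). The conversion pair is an exact involution on a shared grid,
and converting volume to number always shifts cumulative mass toward
small diameters (first-order stochastic dominance) — the mechanism by
which microflocs vanish from volume plots while dominating counts.

Range fractions (`fraction_between()`) prorate bins that straddle a cut
by the overlapped share of their log-width, so cuts such as 10 µm need
not coincide with instrument bin edges. Percentile diameters
(`percentile_diameter()`) interpolate the cumulative weight log-linearly
within bins; d50 of a single occupied bin is its representative diameter,
and other percentiles remain inside the bin. Band counting
(`band_counts()`) uses half-open bands $[e_k, e_{k+1})$ with open ends,
so the conventional "<10 / 10–100 / ≥100 µm" report is
`band_edges = c(10, 100)`; counts always sum to the list length.

## The synthetic generator and its calibration

`generate_psd()` builds a deterministic volume-basis PSD as an analytic
mixture of lognormal modes integrated over the default grid (100
log-uniform bins, 0.02–2000 µm, the working range of a granulometer).
The default calibration has two modes:

| mode | median (µm) | sd of $\log_{10} d$ | volume weight |
|------|------------|--------------------:|--------------:|
| macrofloc | 100 | 0.30 | 0.999 |
| microfloc | 4  | 0.25 | 0.001 |

The macrofloc mode reproduces the one-modal volume PSD peaking near
100 µm that granulometry reports for activated sludge; the microfloc mode
is the "concealed" 2–10 µm population. The microfloc volume weight is
*the* calibration constant, and it is necessarily small: under the exact
cubic bridge a mode at 4 µm is amplified about $25^3 \approx 16{,}000$-fold
relative to one at 100 µm when converting to numbers, so about 0.1% of the
volume suffices to place roughly 90% of the particle *number* below 10 µm
while leaving 99.9% of the *volume* above 10 µm. Weights of a few percent
— a plausible first guess — overshoot badly, putting >99% of the number
below 10 µm. A corollary worth stating: a volume share of 2–4% below
10 µm and a number share of ~90% below 10 µm cannot both hold under an
exact cubic bridge for any two-lognormal mixture; instrument number
distributions are evidently not produced by a literal per-bin cube rule.
The calibration here targets the number-fraction band (85.5–92.4%) and
the volume bound (≥96% above 10 µm), which the defaults meet with margin.

`sample_particles()` draws per-particle diameters from a number-basis
PSD (bins by weight, log-uniform within a bin, matching the log-prorate
convention of `fraction_between()`), emulating automated image-analysis
records. Absolute particle concentrations are arbitrary — no counts per
unit volume are modelled, only proportions.

`generate_scattering_sample()` and `generate_study_ensemble()` produce
noisy curves with known truth. The measurement-noise model multiplies
each intensity by an independent lognormal factor (median 1, log-sd
`rel_noise_sd`, default 0.02) per replicate and averages `n_reps`
(default 15, the usual repetition count of a granulometer sweep)
arithmetically per grid point. The ensemble draws, per sample, $D_f$
uniform on [1.98, 2.34] (the span observed across sludge samples, the
low edge covering the occasional sub-2 estimate), $R_g$ on 50–150 µm,
$R_\mathrm{p}$ on 0.4–1.0 µm and $a$ on 10–45 µm — ranges chosen so the
fractal window always spans at least a decade of the default grid and the
implied maximum regime diameters reach the 30–45 µm extremes seen in
practice. All generators are pure functions of their parameters and a
single integer seed; the caller's RNG state is saved and restored.

What the generator does **not** emulate: multiple scattering (real
measurements control it via obscuration), polydispersity of $R_g$ within
one curve, multi-fractal structure (one $D_f$ per curve), correlated
noise across $q$, instrument smearing, and any covariate structure across
samples (plant, season). Passing tests therefore demonstrate correctness
of the estimation chain on curves that *obey* the three-regime model with
independent multiplicative noise — not robustness to every artefact of
real instruments.

## Numerical choices and problem sizes

* Detection is $O(n^2)$ in grid length via prefix sums; at the default
  $n = 200$ a full pipeline call runs in ~20 ms.
* Test and acceptance runs use 200-point curves, ensembles of 69 samples,
  recovery sweeps of 50 seeds per dimension value, and particle samples
  of $10^5$ for binomial checks — sizes at which every stochastic
  tolerance retains a wide margin while the whole suite runs in seconds.
* Grid endpoints of `q_log_grid()` are pinned exactly to the requested
  limits so inclusive window selections are not lost to floating-point
  drift.
* Intensities must be strictly positive (they are powers); zeros are
  rejected at construction rather than silently dropped at log time.

## Limitations

* The fitted $D_f$ is a single, optically averaged exponent; flocs with
  genuinely multi-fractal architecture are summarised, not resolved.
* $R_g$ is a forward-model input only; the package does not fit Guinier
  radii from data.
* Mie inversion (what the instrument firmware does to produce PSDs from
  raw detector counts) is out of scope: PSDs are consumed or simulated,
  never inverted from curves.
* The q-to-diameter proportionality constant is a convention; reported
  diameter ranges shift by $2\pi$ under the alternative convention while
  dimensions are unchanged.
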