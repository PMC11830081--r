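---
title: "Mechanistic modeling of tumor-spheroid growth and invasion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic modeling of tumor-spheroid growth and invasion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spherowave)
```

## The models

Multicellular tumor spheroids of patient-derived glioblastoma cells grow
and invade simultaneously, and radial density profiles extracted from
time-lapse brightfield imaging confound the two processes. spherowave
implements a family of radially symmetric PDE models of the aggregated
cell density and the machinery to fit, compare, and interpret them.

The richest variant (RD-ARD) tracks two subpopulations $u_1, u_2$ on
$r \in [0, L]$:

$$\frac{\partial u_1}{\partial t}
  = \frac{1}{r^2}\frac{\partial}{\partial r}
    \Big(r^2 D_1 \frac{\partial u_1}{\partial r}\Big)
  + \rho_1 u_1 \Big(1 - \frac{u_1 + u_2}{K_1}\Big),$$

$$\frac{\partial u_2}{\partial t}
  = \frac{1}{r^2}\frac{\partial}{\partial r}
    \Big(r^2 D_2 \frac{\partial u_2}{\partial r}\Big)
  + \rho_2 u_2 \Big(1 - \frac{u_1 + u_2}{K_2}\Big)
  - \frac{\partial}{\partial r}(A_2 u_2),$$

with no-flux boundaries at $r = 0$ and $r = L$, and the observable being
the total density $u = u_1 + u_2$. The simpler variants are restrictions:
RD (one population, no advection), ARD (one population with advection),
RD-RD (two populations, no advection). Coefficients are constant and
nonnegative; density-dependent or otherwise nonlinear coefficients are out
of scope. The initial subpopulation split is proportional to the observed
total initial profile, $u_{10} = \alpha u_0$, $u_{20} = (1-\alpha) u_0$,
because the subpopulations are not separately observable at $t = 0$.

Note the advection term is the one-dimensional form
$\partial_r (A_2 u_2)$, not the spherical divergence
$(1/r^2)\,\partial_r(r^2 A_2 u_2)$ — the model is implemented exactly as
written above. The two differ by a dilution-like term $2 A_2 u_2 / r$;
with the full divergence, outward transport would additionally thin the
migrating population at larger radii.

## Numerics

The solver uses the method of lines on a uniform node-centered grid
(default 400 nodes over $L = 5$ mm):

* **Diffusion** is discretized in conservative finite-volume form (face
  fluxes $r^2 D\, \partial_r u$ divided by the cell volume
  $\int r^2 \mathrm{d}r$), which is the central-difference scheme for the
  spherical Laplacian and conserves spherical mass exactly for pure
  diffusion. At $r = 0$ the scheme reproduces the symmetry limit
  $3 D\, \partial_r^2 u$, so the $1/r^2$ singularity never appears; this
  keeps a node at the origin, matching the radial bins of the data.
* **Advection** uses centered face averages, i.e. classical central
  differencing in the interior, with the advective face flux set to zero
  at both boundaries. Central differencing of advection can oscillate on
  coarse grids; at the default resolution (12.5 µm spacing) oscillations
  are negligible for advection rates up to the fitting bound of
  3 mm/week.
* **Time integration** is `lsoda` (stiff-capable, variable order) with
  `rtol = 1e-6`, `atol = 1e-8` and a banded Jacobian (the two
  compartments are interleaved, bandwidth 2). Output densities are
  clipped at zero; overshoot beyond $-10^{-6}$ aborts with an error.
* A carrying capacity of exactly zero is admissible only for a
  compartment that carries no mass and no growth (the logistic term is
  then evaluated as 0); fitting rejects candidate vectors that violate
  this with a penalty objective value rather than an abort.

Grid-refinement checks in the test suite show the final-time profile for
the validation scenarios changes by less than 1% in max-norm when the
node count doubles.

## Fitting and model comparison

Parameters are estimated by least squares: the sum of squared residuals
between the observed total density and the simulated total density at
every observed (time, radius) point, the initial slice included (it
contributes essentially nothing because the simulation starts from the
observed initial profile; this is documented rather than special-cased).
The simulation runs on the solver grid and is linearly interpolated to
the observed radii, decoupling solver resolution from data binning.

The admissible box is $D \in [0, 0.2]$ mm²/week, $\rho \in [0, 15]$
week⁻¹, $K \in [0, 1]$ density units, $A \in [0, 3]$ mm/week,
$\alpha \in [0, 1]$. Optimization is two-stage: a DIRECT global search
over the box (default budget 2000 objective evaluations for the
single-population models, 10000 for the two-population models; the
objective surface is multimodal and derivative-free global search avoids
committing to a basin), then bounded local refinement with L-BFGS-B
started from the DIRECT optimum. The local stage works in unit-box
coordinates so that finite-difference steps are a fixed fraction of each
parameter's range — with raw parameters the default step is 2% of a
diffusion coefficient but 0.007% of a growth rate, which stalls the
refinement. The returned SSE never exceeds the global-stage SSE.

Models are ranked by the least-squares AIC
$$AIC = n\left[\ln(2\pi) + 1\right] + n \ln(SSE/n) + 2(\kappa + 1),$$
with $n = N_t N_r$ observations and $\kappa$ estimated parameters
(3, 4, 7, 8 for RD, ARD, RD-RD, RD-ARD). Ties are broken toward fewer
parameters. Replicates are fitted independently and cell-line-level
parameters are arithmetic means over replicate fits; a joint fit across
replicates would be a reasonable alternative, but the mean keeps
replicate-level diagnostics and failure isolation simple.

## Wave parameters

Two-population models generally lack a single traveling-wave speed: the
dense core and the dilute invasive halo expand at different rates. The
package therefore estimates, for a density level $u^{(i)}$, the outermost
radius where the simulated profile crosses the level from above (linear
interpolation between the bracketing grid nodes, i.e. the leading
invasive edge; inner crossings of non-monotone "hump" profiles are
deliberately ignored), and regresses that radius on time over the last
quarter of the horizon. The slope is the front speed $c_i$; levels
attained fewer than three times have undefined speed and are dropped.

`wave_parameters()` sweeps 100 levels from 0.02 (absolute, as the
convention is stated) to $0.8\, u_{\max}$ and summarizes
$c_{\max}$, $c_{\min}$, $c_\text{diff} = c_{\max} - c_{\min}$, and
$c_\text{shape}$, the magnitude of the slope of the line through the
final-time front positions of the two extreme levels (the $(r, u)$ slope
of a decaying front is negative; a magnitude is reported since the scale
is what distinguishes diffuse from sharp spheroids). Speeds are meant to
be computed on simulations at fitted parameters — simulation denoises the
data before differencing — though nothing prevents applying them to raw
series.

Two cautions, both visible in the validation analysis
(`analysis/01_wave_validation.R`): near the lowest levels the sweep can
pick up boundary-inflated speeds once the halo reaches the no-flux wall
within the horizon, and a level that coincides exactly with an
inter-front plateau (for the validation scenarios, total density 0.4
equals $K_2$) measures the slow invasion of population 1 into
$u_2$-occupied territory, $2\sqrt{D_1 \rho_1 (1 - K_2/K_1)} \approx
0.164$ mm/week, rather than a free Fisher front. For the two-level
validation comparison the representative densities 0.4 and 0.1 are used
directly.

For a single-population RD run the low-level speed approaches the
Fisher-KPP minimum wave speed $2\sqrt{D\rho}$; the finite horizon and
spherical geometry leave the numerical estimate a few percent below the
planar asymptote, which is why the validation tolerance is 15%.

## Go-or-Grow classification

Fitted coefficients are made dimensionless by population aggregates:
$\bar{D}$ is the mean over cell lines of $(D_1 + D_2)/2$, $\bar\rho$ the
mean of $(\rho_1 + \rho_2)/2$, and $\bar{A}$ the mean of $A_2$. (The
aggregates could equally be bare sums over the panel; every barred value
then scales by the same constant and the classification below is
provably unaffected — the package uses means so the barred values read
as fold-of-average. The normalization of $\bar\rho_2$ is $\rho_2 /
\bar\rho$, matching the symmetry of the other coefficients.) A line is
Go-or-Grow at factor $k$ (default 5, strict inequalities) when one
subpopulation out-migrates and the other out-proliferates:

$$\bar{D}_1 > k(\bar{D}_2 + \bar{A}_2) \ \text{and}\ \bar\rho_2 > k \bar\rho_1,
\qquad\text{or}\qquad
(\bar{D}_2 + \bar{A}_2) > k \bar{D}_1 \ \text{and}\ \bar\rho_1 > k \bar\rho_2.$$

Advection counts toward the second population's motility since there is
no canonical exchange rate between advective and diffusive transport;
normalizing each by its population aggregate is the package's (and the
source field's) resolution of that incommensurability.

Cell lines are grouped by agglomerative average-linkage clustering on
standardized Euclidean distances (each feature divided by its
across-line sample standard deviation, ddof = 1); the default feature
set is the eight raw fitted RD-ARD parameters. First-order partial
correlation, $\rho_{AB\cdot C} = (\rho_{AB} - \rho_{AC}\rho_{BC}) /
\sqrt{(1-\rho_{AC}^2)(1-\rho_{BC}^2)}$, supports confounder-adjusted
association analyses (e.g. survival against a parameter, adjusting for
age); applying it to real clinical cohorts is outside the package's
scope.

## Synthetic data: what it emulates and what it does not

`generate_density_series()` simulates a model from a smooth compact
initial profile — a logistic step with a ~0.5 mm core at density ~0.5,
the geometry of a freshly seeded spheroid at first imaging — and adds
i.i.d. Gaussian observation noise (default sd 0.01, roughly 2–5% of peak
density), clipped at zero. `generate_spheroid_image()` renders a dark
radially symmetric core-plus-halo object on a light background (so
$1 - \text{image}$ is high on the object, the brightfield convention the
profiling algorithm inverts), with optional elongated dark distractors
and pixel noise, deterministically per seed.

Real processed profiles differ in ways that matter for interpretation.
Their background is *identically zero* — the profiling pipeline holds the
profile constant beyond the detected boundary and subtracts that level —
whereas clipped additive noise leaves a small positive-mean background
everywhere. Because fitting simulates from the observed initial slice,
that bias grows at rate $\rho$ and the two-population model can absorb
the artifact better than the single-population model, an effect real
data does not exhibit. The model-recovery analyses therefore place noise
only where signal exists when emulating processed data. Passing tests on
synthetic data demonstrate correctness of the machinery, not that the
RD-ARD model describes any particular real cell line; synthetic images
likewise contain no optics (PSF, vignetting) and a single spheroid per
frame.

## Image processing choices

Center estimation follows median subtraction → Gaussian smoothing
(σ = 4 px) → thresholding at 0.08 → connected components → removal of
objects under 4000 px² → selection of the minimum-eccentricity object.
The threshold is applied to the *absolute* deviation from the median so
that a dark-on-light spheroid is detected as well as a bright one; a
constant image still yields the "no spheroid found" error. Eccentricity
is the ellipse-fit (second-moment) region property, the standard
estimator; ties are broken toward larger area (the spheroid is the
largest round object in frame). Radial profiling uses 600 annuli of 2 px
(1536 px ↔ 4.33 mm, so 2.819 µm/px and a 3.38 mm span), a moving average
truncated at the array edges (100 bins each side), and a boundary at the
first bin past bin 100 where the raw first difference of the moving
average turns from negative to positive — the raw difference, not a
smoothed derivative, with distances measured from pixel centers. When no
sign change exists (clean synthetic images with monotone halos), the
boundary falls back to the last populated bin with a warning.

## Problem sizes and defaults used in the shipped analyses

The shipped analyses and tests run the validation simulations at 400
grid nodes over 5 mm and 51 output times over 5 weeks, and the fitting
studies on 31–61 radial bins × 6–9 times with DIRECT budgets of 300–1500
evaluations — sizes chosen so a full study runs on a laptop in minutes
while the refinement and recovery checks stay comfortably inside their
tolerances. Full-scale fits (the 10000-evaluation default for
two-population models) behave identically, only slower.

## Known limitations

* The planar advection form (as the model is written) slightly
  understates geometric dilution compared to the spherical divergence.
* Level speeds are undefined where a level is attained fewer than three
  times in the window; which levels are defined can differ between runs
  and is logged, and $c_{\max}/c_{\min}$ are taken over defined levels
  only.
* No uncertainty quantification: single point estimates per fit, no
  profile likelihood or bootstrap.
* Parameters of the two-population models can be weakly identified on
  0–1 week windows; trajectory recovery is the honest target there, and
  the tests check exactly that.
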