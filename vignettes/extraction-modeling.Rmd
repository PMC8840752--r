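---
title: "Response-surface optimization and mass-transfer modeling of supercritical extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response-surface optimization and mass-transfer modeling of supercritical extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfekin)
```

## What the package models

Supercritical-CO2 extraction (SFE) of a solute from milled plant material is
tuned along two axes that this package covers end to end:

1. **Which operating point to run at.** Yield and selectivity respond to
   pressure, temperature, particle size and cosolvent. The package represents
   two-level factorial and three-factor Box-Behnken designs, fits first- and
   second-order response surfaces by ordinary least squares, decomposes the
   fit into the conventional sequential/adjusted ANOVA with lack-of-fit and
   pure error, and maximizes the fitted quadratic exactly over the
   experimental box.

2. **How fast the extraction proceeds there.** Cumulative yield-versus-time
   curves are described by three classical mass-transfer models of
   increasing structure, with least-squares parameter estimation and
   conversions from the fitted parameters to physical mass-transfer
   coefficients.

The package ships one worked dataset: a 2^2 factorial (pressure x cosolvent,
7 runs) and a 15-run Box-Behnken design (pressure 200-300 bar, temperature
40-60 degC, particle size 42/60/150 Tyler mesh) from a study of *p*-anisic
acid extraction from *Acacia mearnsii* flowers, exposed through
`sfe_fixture()`. Selectivity means grams of target compound per 100 g of
crude extract; global yield means grams of extract per 100 g of feed.

## Response-surface model and ANOVA conventions

`fit_surface()` fits the full 10-term quadratic

$$y = b_0 + \sum_i b_i x_i + \sum_i b_{ii} x_i^2 + \sum_{i<j} b_{ij} x_i x_j$$

by OLS. Two conventions matter for reproducing published tables and are
therefore explicit, settable choices:

* **Natural (uncoded) units by default.** In coded units the linear columns
  of a Box-Behnken design are orthogonal to every other column, so
  sequential and adjusted sums of squares coincide for them. Published
  Minitab tables for these data were evidently computed in natural units,
  where (for example) temperature absorbs a large sequential SS when
  entered first but has a negligible adjusted SS. `coding = "coded"` is
  available when orthogonality is wanted.
* **Fraction scale for the ANOVA.** Responses recorded in percent w/w are
  analysed as w/w fractions (`surface_anova(scale = "fraction")`, the
  default), the scale on which replicate scatter in selectivity has
  interpretable magnitude (pure-error SS of a few 1e-6). Every F ratio,
  p-value and R^2 is provably invariant under the percent/fraction
  rescaling — the test suite asserts this to 1e-10 — so the choice only
  affects the printed SS magnitudes.

Sequential (Type I) SS follow a stated term order (`order =` a permutation
of the factors; squares inherit it, interactions follow in pair order);
adjusted (Type III) SS come from drop-term refits and are order-invariant.
Lack-of-fit and pure error split the residual using replicated runs; with no
replicates the rows are omitted with a recorded warning. Rows whose adjusted
mean square is exactly zero report no F statistic rather than infinity.

```{r anova}
fit <- fit_surface(sfe_fixture("table3"), "selectivity", scale = "fraction")
surface_anova(fit, order = c("T", "P", "G"))
```

## Exact box-constrained optimization

A quadratic restricted to any face of a box is a lower-dimensional quadratic
whose stationary point is a linear solve. `optimize_surface()` therefore
enumerates all faces (interior, edges, vertices), collects in-box stationary
points and vertices, and compares their values — an exact, non-iterative
global optimizer for this model class. A brute-force sampling oracle in the
test suite confirms it is never beaten. Ties within 1e-9 are all reported,
lowest pressure first, reflecting the usual preference for energy-efficient
operation among equivalent optima. Singular face restrictions are skipped
safely: along a flat direction the optimum is also attained on a sub-face,
which is enumerated anyway.

```{r optimum}
optimize_surface(rescale_surface(fit, "percent"))
```

For these data the maximum sits at the low-temperature, coarse-particle edge
near 279 bar, predicting about 2.8% w/w selectivity — the same operating
point reported from Minitab's response optimizer in the source study.

## The three kinetic models

All three forward models produce curves that start at zero, are
nondecreasing, and approach their asymptote; the suite asserts this over
randomized parameter draws.

**Crank sphere diffusion** (`crank_yield()`): Fick's second law for a sphere
initially at uniform concentration with zero surface concentration,

$$M_t/M_\infty = 1 - \frac{6}{\pi^2}\sum_{n\ge1} \frac{1}{n^2}
  e^{-D n^2 \pi^2 t / r^2}.$$

The series is truncated adaptively when the next term falls below 1e-12
(hard cap 1e5 terms). Below Fourier number 1e-4 convergence is slow and a
warning is raised; no short-time approximation is silently substituted. A
radial finite-difference solution serves as the independent oracle in the
tests (agreement to better than 1e-4 over Fo in [0.01, 2]).

**Sovova broken-and-intact-cells** (`sovova_yield()`): the initial load
`x0` (per insoluble solid) splits into accessible (`x0 - xk`) and
intact-cell (`xk`) solute. Extraction proceeds in three periods of the
specific solvent consumption `q` — solubility-limited at rate
`yr (1 - e^{-Z})`, a transition while the depletion boundary `zw` crosses
the bed, and diffusion-limited depletion governed by `W`. The boundaries
`qm = (x0 - xk)/(yr Z)` and
`qn = qm + W^{-1}\ln[(xk + (x0 - xk) e^{W x0/yr})/x0]` are evaluated first
and the curve is continuous at both (asserted to 1e-9 x0 over 1e3 random
parameter sets). Periods are left-closed; where the transition-period
logarithm would see a non-positive argument (outside the model's validity)
evaluation raises an error rather than clamping. `sovova_mass_transfer()`
converts `Z`, `W` to film coefficients `kf`, `ks` through the bed
properties, exactly invertibly.

**Reverchon internal-diffusion model** (`reverchon_yield()`): plug flow
through the bed with a linear solid-fluid equilibrium `q* = K c` and
first-order solid depletion with internal diffusion time `ti`:

$$\frac{\partial c}{\partial t} + \frac{1}{\tau}\frac{\partial c}{\partial h}
 + \frac{(1-\varepsilon)\rho_s}{\varepsilon}\frac{\partial q}{\partial t} = 0,
 \qquad
 \frac{\partial q}{\partial t} = -\frac{q - K c}{t_i},$$

on the nondimensional axial coordinate `h in [0, 1]`. Grouping the
advection through the residence time `tau` removes all other dimensional
bookkeeping: only `(tau, ti, K, q0, porosity, solid density)` enter the
solver. Axial dispersion and density/flow variation along the bed are
deliberately out of scope. `ti` converts to the internal diffusivity
(`Di = mu l^2 / ti`, `mu = 3/5` and `l = r/3` for spheres) and to the
lumped coefficient `kTM` via the bed holdup.

### Numerical choices in the PDE solver

The method of lines uses a **third-order upwind-biased (QUICK) finite-volume
reconstruction** on 50 cells by default, integrated with `deSolve`'s
stiff-capable `lsoda` at rtol 1e-8 / atol 1e-12. Two facts drove the choice
of the spatial scheme:

* The flux (telescoping) form conserves solute exactly at the ODE level;
  the reported mass-balance audit closes to machine precision, and any
  residual error in the yield is the integrator's, not the grid's.
* First-order upwind converges only as O(1/N): its yield curve still moves
  by ~4e-3 (relative) when the grid is doubled from 50 to 100 cells, and
  reaching 1e-4 would need thousands of cells. The QUICK reconstruction
  brings the 50-to-100-cell change below 5e-5 at every sampled time,
  including through breakthrough, while remaining monotone and
  non-negative for this problem class.

The cumulative extract is carried as an extra ODE state (the time integral
of the outlet flux), so no post-hoc quadrature error enters the yield.

## Parameter estimation

`fit_kinetics()` minimizes the unweighted sum of squared residuals by
Nelder-Mead (via `stats::optim`, whose reflection/expansion/contraction
coefficients 1, 2, 0.5 are the classical ones; function-value reltol 1e-12,
at most 1e4 iterations). Positive parameters are searched on the log scale;
the Sovova constraint `xk <= x0` is enforced by a logit transform of
`xk/x0`, so no penalty terms are needed. Non-finite model evaluations during
the search receive an effectively infinite objective and the search
continues.

Free parameters are `D` (Crank), `Z, W, xk, yr` (Sovova, with `x0` fixed at
the observed asymptote unless supplied — the identifiability of `x0` from a
finite curve is poor, and pinning it to the exhaustion plateau is the
conventional choice), and `ti, K` (Reverchon; the normalized yield is
independent of `q0`). Initial guesses come from moment heuristics (the 63.2%
crossing time for `D` and `ti`; the initial slope for the Sovova pair), and
`n_starts` seeded Gaussian jitters of the transformed start make the search
multi-start; the best start wins and the per-start table is kept. The same
seed and data reproduce a fit bit-identically. A curve still rising by more
than 5% of its maximum at the last point flags the asymptote as uncertain.
Weighting is off by default (`relative = TRUE` weighting is not implemented;
the report schema reserves space for bootstrap intervals but they are a
non-goal here).

## The synthetic-data generator

`simulate_curve()` evaluates a forward model on a sampling grid and applies
multiplicative (default 2%) or additive Gaussian noise from a seeded
`noise_spec()`; `simulate_design_response()` does the same for design
responses, with independent noise per run including centre replicates. The
defaults emulate the regime of the embedded study: a 6-hour horizon with
15-20 weighings biased toward early times, parameter magnitudes as published
(`ti` ~ 1.7e3 s, `K` ~ 5e-3, `D` ~ 1e-10 to 1e-12 m^2/s), and 2%
replicate-level scatter, a typical figure for gravimetric triplicates (the
study does not publish its replicate scatter). Values are clipped at zero
after noising; noisy curves are deliberately not monotonized, so fitters
must tolerate non-monotone data. The generator reproduces bit-identically
from its seed and restores the caller's RNG state.

What passing the recovery tests shows — and what it does not: synthetic
curves share the forward model's structure, so recovery demonstrates the
estimator and the identifiability of the parameterization, not that any one
of the three models is the right description of a particular plant matrix.
Real curves carry basis ambiguity (per-feed vs per-solid vs normalized),
flow fluctuations and weighing error structure that the generator does not
emulate.

## Default bed configuration

`default_bed()` documents one consistent reference bed: 0.5 L extractor,
800 g/h CO2 over 78 g of solute-free milled feed, CO2 density 910 kg/m^3
(approximately the 279 bar / 40 degC operating point), solid density
1200 kg/m^3, porosity 0.55, and an effective interfacial area of 8.2e4 m^-1.
The area is an *effective* value: for a milled-flower bed the true
solid-fluid contact area is unknown and published solvent/feed bookkeeping
for such rigs is often internally inconsistent, so the default absorbs that
uncertainty while keeping the derived film coefficients at the orders of
magnitude reported for flower SFE (kf ~ 1e-10, ks ~ 1e-9 m/s). Derived
quantities (specific flow, residence time, total particle area) are computed
from the primary ones, and a user-supplied residence time inconsistent with
the flows is rejected.

## Problem sizes used by the test suite

The suite runs entirely on synthetic or embedded data: the 15-run and 7-run
fixtures for all DoE checks; 50-60-point curves for estimator checks; 1e3
random parameter sets for the Sovova continuity property; 100 seeded
replicates per noise level for the estimator-consistency sweep; and 50- vs
100-cell grids for the PDE convergence check. These sizes keep every
statistical assertion comfortably powered while the whole suite stays in the
one-to-two-minute range on a single CPU.

## Known limitations

* Design support is limited to 2-level factorials with centre points and the
  3-factor Box-Behnken layout; no design generation, desirability functions
  or mixture designs.
* The Sovova `e`-basis (extract per insoluble solid) and per-feed yields are
  interconvertible only when the insoluble-to-feed ratio is known; absent
  that, curves are handled on a declared basis without conversion.
* No confidence intervals on kinetic parameters (no profile likelihood or
  bootstrap); no model-selection criteria; no multi-curve simultaneous fits.
* The printed regression equations of the source study are shipped verbatim
  (`printed_surface_coefficients()`) for display only: they are not exactly
  recoverable from the rounded published responses, and one printed
  constant is internally inconsistent with its own reported optimum, so all
  computation uses refits of the embedded tables.
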