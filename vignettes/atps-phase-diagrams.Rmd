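---
title: "Phase-diagram inference for PEG-dextran aqueous two-phase systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-diagram inference for PEG-dextran aqueous two-phase systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(atpsdiagram)
```

## The system and the model

Mixing solutions of poly(ethylene glycol) (PEG) and dextran in buffer
above critical concentrations produces an aqueous two-phase system
(ATPS): the mixture demixes into a PEG-rich and a dextran-rich aqueous
phase. The phase diagram in composition space — dextran wt% on the
x-axis, PEG wt% on the y-axis — is organized by two objects:

* the **binodal**, the curve separating single-phase from two-phase
  compositions; and
* the **tie-lines**, segments joining the equilibrium compositions of
  the two coexisting phases. Every average composition on a tie-line
  separates into the same two endpoint compositions; only the relative
  phase amounts change (the lever rule).

These objects matter practically because PEG microgels are commonly
synthesized by photopolymerizing functionalized PEG inside the ATPS
emulsion: the formulation's position in the phase diagram controls the
phase compositions, the dextran:PEG volume ratio, and downstream
material properties of the microgels (stiffness, polymer content, size).

### Binodal

The binodal is fitted to cloud-point titration data — compositions at
which an incrementally titrated mixture first turns turbid — by
nonlinear least squares on the model

$$ y = A\,e^{B\sqrt{x} - C x^{3}} + D/x , $$

the widely used three-parameter exponential for polymer-polymer
binodals augmented with an additive inverse term. The inverse term makes
the curve asymptotic with the ordinate, so the model never predicts a
negative polymer concentration at small dextran: physically, a trace of
dextran cannot phase-separate at any finite PEG concentration. With
`D = 0` the classic three-parameter form is recovered (`form = "exp"`),
and arbitrary alternative curves can be wrapped with `binodal_custom()`
without touching anything downstream.

Fitting choices: unweighted ordinary least squares in y; the
Levenberg-Marquardt optimizer with bounds `A > 0`, `C >= 0`, `D >= 0`;
a deterministic multistart (the default initial guess `A = max(peg)`,
`B = -0.3`, `C = 1e-4`, `D = 0.1` plus four jittered restarts under a
fixed seed) guards against local minima, and the restart with the
lowest residual sum of squares wins. Convergence is reported honestly
in the `convergence` flag, and the parameter covariance of the best fit
is kept for uncertainty propagation. Boundary compositions (exactly on
the curve) classify as single phase: clouding is the positive signal in
titration, so the two-phase call uses a strict inequality.

### Tie-lines from gravimetric data

A sample of known total mass $M$ and average composition
$(\bar{x}, \bar{y})$ is allowed to separate; the decanted PEG-rich top
phase is weighed, giving the top-phase mass fraction
$f = M_{top}/M$. The endpoint compositions then satisfy a closed
system: PEG and dextran mass balances

$$ \bar{y} = f\,y_t + (1-f)\,y_b , \qquad
   \bar{x} = f\,x_t + (1-f)\,x_b , $$

with both endpoints on the binodal, $y_t = f(x_t)$, $y_b = f(x_b)$,
and mass closure $M_b = M - M_t$. Substituting the binodal and the
dextran balance reduces the system to one equation in $x_t$, solved on
the admissible branch $x_t < \bar{x} < x_b$ by a grid-bracketed Brent
search (bisection-refined with interpolation polish, tolerance 1e-12).
At the boundary of the bracket the residual diverges to $+\infty$ (the
binodal's asymptote) and is negative at $\bar{x}$ for any two-phase
average, so a bracket always exists; if several admissible roots ever
appear, the solver warns and takes the smallest top-phase dextran. All
wt% values are per total system mass (polymers plus buffer).

The lever rule gives $f$ back from any tie-line:
$f = (\bar{y}-y_b)/(y_t-y_b)$, identically on the dextran axis for a
mass-balance-consistent tie-line. The **dextran:PEG volume ratio** —
the ratio of continuous to disperse phase volume, the main handle on
microgel size — converts the mass split to volumes with nominal phase
densities:

$$ VR = \frac{1-f}{f}\cdot\frac{\rho_{top}}{\rho_{bottom}} , $$

with defaults 1.0 g/mL (PEG-rich) and 1.1 g/mL (dextran-rich),
configurable through `phase_densities()`. This equals the classical
segment-length construction on the phase diagram, density-corrected.

```{r}
t1 <- reference_tielines()
tl <- tie_line(top = c(dex = t1$top_dex[1], peg = t1$top_peg[1]),
               bottom = c(dex = t1$bottom_dex[1], peg = t1$bottom_peg[1]),
               avg = c(dex = t1$avg_dex[1], peg = t1$avg_peg[1]))
lever_fraction(tl)
volume_ratio(tl)
```

### Interpolated tie-lines

Tie-lines are measured at a handful of compositions; formulations of
interest rarely sit exactly on one. Interpolation uses a **conjugate
curve**: a quadratic $y = q_0 + q_1 x + q_2 x^2$ fitted by ordinary
least squares through the midpoints of the measured tie-lines. The
midpoint anchor is one standard construction among several; the anchor
function is pluggable in `fit_conjugate()`. An interpolated tie-line
through a target composition must then (i) have both endpoints on the
binodal, (ii) be collinear with the target, and (iii) have its midpoint
on the conjugate curve. The solver marches along the conjugate curve —
candidate tie-lines indexed by midpoint abscissa, monotonically related
to arc length — brackets the sign change of the collinearity residual,
and polishes by Brent refinement in two nested one-dimensional solves.
Targets whose solution midpoint falls outside the anchored range are
allowed but flagged with an extrapolation warning, since a quadratic
extrapolates with no guarantees.

On the bundled empirical tables this machinery places the three
"intermediate" microgel formulations on one common tie-line with a
PEG-rich phase near 30 wt% PEG, which is exactly why their microgels
share polymer concentration and stiffness while differing in volume
ratio and hence size.

### Monte Carlo uncertainty

`mc_tielines()` and `mc_interpolated()` propagate three independently
switchable noise sources — balance noise on the top-phase mass
(default sd 2 mg), pipetting noise on the average composition (default
sd 0.05 wt% per axis), and parameter draws from the binodal /
conjugate fit covariances (multivariate normal) — by re-running the
deterministic solvers per iteration (default 10,000) and summarizing
mean, sd and central 95% intervals. Iterations whose solve fails are
dropped and counted; more than 20% failures raises an error, since
that indicates a noise model inconsistent with the diagram, not bad
luck. Fixed seeds give bit-identical summaries.

One numerical caveat, documented because it is easy to misread as a
bug: the solve is nonlinear, so MC means carry a second-order bias
proportional to input variance that does not shrink with the number of
iterations, while the CLT band around the mean does. At the default
noise level all summarized quantities sit within three standard errors
of the deterministic solution; at several-fold larger noise the
flattest quantity (bottom-phase PEG, where the binodal is nearly flat)
drifts outside that band first.

### Property models

Three phenomenological fits connect formulation variables to microgel
properties:

* `fit_property_surface()`:
  $\text{value} = a\,\overline{PEG} + b/VR + c$, linear in the average
  PEG concentration and inverse in the volume ratio — the form chosen
  because pellet polymer content tracks average PEG linearly while
  stiffness falls as the volume ratio grows; a `linear_vr` variant
  ($b\,VR$) is available and the form is recorded in the output.
* `fit_linear_peg()`: simple OLS of a property on average PEG, which
  suffices for pellet polymer content.
* `pdi()`: polydispersity of diameters, population variance over
  squared mean (the n-denominator convention, stated explicitly since
  labs differ).

All fits report $R^2$, adjusted $R^2$, and the PRESS-based predicted
$R^2$ computed through the hat-matrix shortcut
$\mathrm{PRESS} = \sum_i (e_i/(1-h_{ii}))^2$, which the tests verify
equals the brute-force leave-one-out value to 1e-10. Replicates enter
individually and unweighted. Group comparisons are routed through a
Bartlett gate at p = 0.05: homoscedastic groups go to one-way ANOVA
with Tukey HSD, heteroscedastic ones to Kruskal-Wallis (nonparametric
pairwise post hoc is left to the caller's preferred procedure); a
zero-variance group makes Bartlett's statistic undefined and routes
nonparametric with a warning.

## The synthetic laboratory

`atps_ground_truth()` defines a complete known system so every stage is
testable by parameter recovery, without any laboratory data:

* a truth binodal (`A = 10.7, B = -0.45, C = 2.6e-4, D = 0.5`), chosen
  so the curve crosses 9.3 wt% PEG near 0.4 wt% dextran and 0.9 wt%
  PEG near 14.5 wt% dextran — representative of a 4-arm PEG 20 kDa /
  dextran 40 kDa system in PBS, not a transcription of any measured
  one;
* a tie-line field. The default construction defines tie-lines as
  binodal chords whose midpoints lie on an exact quadratic conjugate
  (`q = 4.446 - 0.605 x + 0.0693 x^2`), so the interpolation machinery
  can in principle recover the field exactly and zero-noise round
  trips close at solver precision; those coefficients were themselves
  frozen from the alternative `"slope"` construction (tie-line slope
  quadratic in bottom-endpoint dextran, steepening from about -0.46 to
  -0.93 across the diagram, as gravimetric data show), which remains
  available and whose midpoint curve is quadratic only to ~0.05 wt%;
* truth property surfaces (stiffness `2*PEG + 30/VR + 5` kPa, modulus
  `150*PEG + 2000/VR + 300` Pa), a pellet-polymer line
  (`0.24*PEG + 0.47` wt%), and a lognormal size model whose median
  diameter decreases with volume ratio.

`simulate_cloud_titration()` walks the titration arithmetic: quantized
titrant additions, composition update by mass balance, clouding checks
against the truth binodal, buffer dilution until clouding subsides,
repeat. Because the composition is recorded at the first clouded
addition, recorded points overshoot the binodal one-sidedly by up to
one increment — a real feature of cloud-point titration, and the
reason a fit on protocol-scale increments (5–30 µL titrant, 10–150 µL
buffer) tracks the truth curve only to within about 1 wt% mid-range
and worse near the y-axis asymptote, where increments are coarse
relative to the curvature. The infinitesimal-increment limit of the
walk puts points on the curve; for "zero-noise" round-trip checks the
package samples the curve exactly, which is that limit.

`simulate_gravimetric()` computes true top-phase masses through the
truth tie-line field and adds Gaussian weighing noise;
`simulate_property_measurements()` draws stiffness and modulus values
with noise proportional to the true value (default CV 30% and 15%,
emulating force-map and rheometer scatter), pellet polymer content
with additive noise, and diameters from the lognormal size model
(≥ 300 per formulation, mirroring image-analysis sizing).

What the generator does **not** emulate: decantation losses and
interphase volume, temperature or salt dependence of the binodal,
droplet coalescence/coarsening kinetics and their effect on size
distributions, or spatial heterogeneity within a formulation. Passing
recovery tests therefore demonstrate that the estimators are correct
and calibrated under the stated statistical structure — not that real
titrations or force maps satisfy that structure.

## Validation results the tests compute

* Zero-noise round trip: binodal parameters recovered to ~1e-8
  relative (asserted at 1e-4); solved tie-line endpoints to ~1e-13 wt%
  (asserted at 1e-6); interpolated tie-lines at held-out compositions
  to ~1e-12 wt% (asserted at 1e-4).
* At measurement-scale noise (0.05 wt% composition, 2 mg weighing,
  triplicates at six compositions), recovery is summarized by the
  **median** across compositions of the replicate-averaged endpoint
  errors, asserted below 0.2 wt%. The median is used deliberately: the
  steepest tie-line amplifies top-mass noise by
  $\partial y_t/\partial f \approx 100$, so its endpoint scatter is
  several-fold larger — consistent with the replicate scatter real
  gravimetric experiments show at such compositions — and a max-based
  summary would measure that amplification, not solver quality.
* The PEG coefficient of the stiffness surface, refit across 100
  simulated campaigns at the design size (5 formulations, 9
  measurements each, CV 30%), has median standardized error ~0.7
  (calibrated standard errors) and median relative error ~0.45 — an
  honest statement of how much information that design carries about
  the PEG slope; single-fit recovery is asserted within 3 standard
  errors.

## Problem sizes and numerical choices

Simulated campaigns in the tests use the study-scale design throughout
(six gravimetric compositions in triplicate at 500 mg; five
formulations with 9–10 stiffness, 3 modulus and 3 pellet measurements;
300 diameters per formulation; 10,000 Monte Carlo iterations for the
tie-line contract and a few hundred for the costlier interpolated
solver). Root solves use Brent's method at tolerance 1e-12 with
grid-based bracketing (200 points for the tie-line solve, 120
candidate midpoints for interpolation). Printed "~0" phase
concentrations in the bundled tables are stored as exactly 0, being
below reporting precision. Ties and degenerate inputs fail loudly:
single-phase averages, vanished phases (lever fraction 0 or 1),
rank-deficient property designs and zero-variance groups are errors or
routed warnings, never silent.

## Known limitations

* The binodal and property-surface algebraic forms are conventions of
  this package (pluggable); other parametrizations of the same data
  will interpolate slightly differently, especially under
  extrapolation.
* The conjugate-curve quadratic is an empirical smoother. Its
  residuals against the bundled empirical midpoints reach ~1.4 wt%
  (one tie-line sits off-trend), so interpolated endpoints inherit
  smoothing error of that order near the anchors' edges; tie-lines
  far outside the anchored range (flagged extrapolations) are
  indicative only.
* Monte Carlo summaries assume independent Gaussian input noise;
  correlated pipetting errors between the two composition axes are not
  modeled.
* Real AFM/rheology regression diagnostics cannot be reproduced
  without the raw force maps and moduli; the property-model machinery
  is validated on synthetic data with known truth instead.
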