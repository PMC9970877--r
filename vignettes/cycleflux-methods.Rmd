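---
title: "Methods: cell-cycle-resolved biosynthesis and flux inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-cycle-resolved biosynthesis and flux inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycleflux)
```

This vignette is the package's own account of the models and procedures
it implements, their assumptions, the tunable parameters that matter,
and the numerical choices made where the design was genuinely open.

## The scientific problem

Budding yeast shows hour-scale oscillations of metabolic readouts —
most visibly NAD(P)H autofluorescence — locked to the cell division
cycle. `cycleflux` implements the analysis chain for testing the
hypothesis that these oscillations are driven by *temporally
segregated biosynthesis*: protein synthesis running in two waves per
cycle (around START and mid S/G2/M), lipid and cell-wall-polysaccharide
synthesis in a single S/G2/M wave, DNA replication confined between
budding and karyokinesis. The chain has four stages: trace processing,
phase alignment, activity inference, and conversion to absolute rates
and metabolic fluxes.

## Trace processing

**Geometry.** Bright-field segmentation yields major/minor ellipse
radii $R, r$ (µm) per compartment. Under the prolate-spheroid
assumption, volume is $V = \tfrac{4}{3}\pi R r^2$ (fl) and surface
$S = 2\pi r^2\!\left(1 + \tfrac{R}{re}\arcsin e\right)$ with
$e = \sqrt{1 - r^2/R^2}$. At $e \to 0$ the analytic limit
$\arcsin(e)/e \to 1$ is substituted, so spheres are exact. Ellipse
fitters do not guarantee axis order; $r > R$ inputs are swapped with a
warning rather than rejected.

**Cycle assembly.** A cycle is the half-open interval
$(ME_i, ME_{i+1}]$ between consecutive mitotic exits. Cytokinesis makes
total volume and surface discontinuous at the boundaries, so up to
50 min of each adjacent cycle is appended after a geometric
translation: the preceding context is shifted down by the previous
daughter's size at $ME_i$, the following context up by the current
daughter's size at $ME_{i+1}$. The daughter size "at ME" is read from
the last frame at or before the boundary — the frame that still
contains the bud. Buds are unmeasurable for the first 2–4 frames after
budding; those values are interpolated linearly from zero at the
budding event to the first measured size, in every bud window of the
trace (the context of a cycle contains its neighbors' early buds too).

**Smoothing and differentiation.** Volume, surface and fluorescence are
smoothed with LOWESS, parameterized by a window in *points* (converted
internally to the span fraction). Defaults follow the per-quantity
medians of the source protocol: volume 6, surface 8, fluorescence 7.
One design decision deserves a note: robustness reweighting makes
LOWESS a nonlinear operator, while the pipeline's correctness
arguments (and the linearity property tested in the suite) rely on the
smoother being linear; `lowess_smooth()` therefore uses a single
fitting pass (`iter = 0`). NAD(P)H traces use a Savitzky–Golay (7,3)
filter instead, which follows crests and troughs that a running mean
would flatten; edges are padded with three copies of the edge value
(nearest mode). Derivatives are taken either from the natural cubic
interpolating spline (volume, surface, reporter abundance — always on
the context-extended window, so the natural boundary condition acts
outside the cycle of interest) or as midpoint differences
$(x_{i+1}-x_i)/\delta t$ at $t_i + \delta t/2$ (the stop-and-respond
convention). Detrending of long NAD(P)H traces divides the raw values
by a large-window LOWESS curve; the detrended series fluctuates
around 1.

**Flat-field correction.** For low-signal readouts, the illumination
shape is learned from the per-pixel median over many stage positions:
subtract the fixed camera baseline (500 counts), fit a 2-D Gaussian,
rescale each baseline-subtracted frame by $\max(G)/G$. If the Gaussian
fit diverges (for example on a perfectly flat field) the correction
falls back to normalizing by the median image, with a warning.

## Cell-cycle phase

**Event detection.** Whi5 concentrates in the nucleus at mitotic exit
and disperses at START, which raises and lowers the sd/mean ratio of
the reporter pixels. Candidate events are the time points before the
local extrema of the ratio's midpoint derivative, found with a
symmetric comparison window of $x$ points per side ($x = 12$ at
$\delta t = 6$ min, $x = 24$ at 3 min — 72 min of context either way).
Ties break to the earliest point; series edges are never extrema; a
flat ratio yields no candidates (not an error). Because the source
protocol curates these calls visually, the package adds a reproducible
proxy: an ordering filter (ME before START before BUD, inter-ME gap
within median ± 2 sd) plus a manual-override channel in the events
table.

**Karyokinesis.** Nuclear division is read from the mother-nucleus
histone abundance: pixels are selected by the local threshold
$F_i > \bar F_i(15{\times}15) + p30$ (15×15 local mean, nearest
border; offset = 30th percentile of the mother-mask intensities),
objects under 25 pixels at orthogonal connectivity are removed, the
object containing the brightest pixel is kept, enclosed unselected
pixels are added back, and abundance is the member-pixel intensity
sum. Karyokinesis is the time of the most negative smoothed derivative
of that abundance. The threshold rule is *intensity-scale dependent*:
both the local mean and the absolute percentile shift when a constant
is added to the image, so the threshold moves twice as fast as the
signal. That is a property of the published rule, not an
implementation artifact; adding a large constant can only shrink the
selection, and the test suite asserts exactly that.

**Phase map.** Each cycle's time axis is mapped to $[0,1]$ by
piecewise-linear interpolation between the four reference events,
anchored at the population-mean relative phases
$\bar\varphi^e = \tfrac1N \sum_{cc} (t^e_{cc} - t^{ME}_{cc}) /
(t^{nextME}_{cc} - t^{ME}_{cc})$. The map is continuous, monotone and
exact at the anchors; the tests verify a 1e-9 round trip through its
inverse.

## Biosynthetic activity

**Reporter production rate.** Fluorescent proteins mature with
first-order kinetics, so the visible abundance $A$ (smoothed
fluorescence × smoothed volume) lags production. Assuming no active
degradation,
$$r(t) = \frac{t_{1/2}}{\ln 2}\,\frac{d^2A}{dt^2} + \frac{dA}{dt},$$
with $t_{1/2} = 6$ min for superfolder GFP. Two successive derivatives
amplify measurement noise; single-cycle rate traces legitimately dip
negative, and shape recovery is assessed at the population level
through the Gaussian-process summary, not per cycle.

**Stop-and-respond.** After an acute perturbation of one biosynthetic
process, the NAD(P)H derivative of each cell deviates from its normal
cell-cycle trajectory in proportion to how active the process was at
that moment. The pipeline: (i) keep cells with at least two pre-switch
buddings whose latest inter-budding duration lies within
median ± 1 sd (set S1); (ii) compute the mean event timings
$\Delta\bar t_{START}, \Delta\bar t_{BUD}, \Delta\bar t_{CC}$ from the
two latest pre-switch cycles; (iii) smooth each trace with the (7,3)
filter and differentiate at midpoints; (iv) read
$P^c = \dot F^c(t_p - \delta t/2)$ at the first frame $t_p$ of severe
perturbation; (v) anchor each cell's phase to its most recent event,
rejecting cells whose nearest event is abnormally delayed; (vi) build
the unperturbed profile $N(\phi)$ as the across-cell median of the
derivative at the comparable time in the *preceding* cycle (derivative
values live on frame midpoints and are linearly interpolated in
between — the printed definition leaves the grid convention open);
(vii) normalize, $R^c = \alpha(P^c - N(\varphi^c))/(\max N - \min N)$,
with $\alpha = -1$ when the population-average NAD(P)H drops at $t_p$.

Two procedural details were resolved deliberately. First, trace
smoothing is split at the medium switch *only* when the population
shows a sharp step there (the case for translation-inhibitor or degron
perturbations); unconditional splitting attenuates the derivative at
the piece edge and injects phase-locked structure into a null
experiment. Second, $t_p$ may be auto-detected as the first post-switch
frame where the absolute population-mean derivative exceeds three
pre-switch standard deviations; the per-experiment values of the
source protocol are config inputs when known.

**GP summary and model selection.** Phase-scattered values are
summarized with a zero-mean Gaussian process, covariance
$\sigma_f^2\,\mathrm{RBF}(\ell) + \sigma_n^2 I$, hyperparameters by
maximizing the log marginal likelihood with ten deterministically
seeded restarts of L-BFGS-B (analytic gradients). For stop-and-respond
data the length scale is bounded in $[2\delta t, 5\delta t]$ (the
protocol's "5 (or 6)" upper multiplier defaults to 5,
config-overridable); the posterior is reported on a uniform grid of
101 points. No correlation beyond the kernel is assumed: all
variability at a phase is attributed to measurement noise. The
oscillatory-versus-linear adjudication fits the alternative
constant + dot-product (+ white) kernel and reports two criteria that
are never merged: the difference in maximized log marginal likelihood
(Bayesian) and 5-fold cross-validated predictive log density and MSE
(frequentist); disagreement yields the verdict "inconclusive".
Interior-maxima counting ignores boundary extrema, since regression
edges are unconstrained.

## The cell-mass model

The model converts dimensionless activities $a_j(t)$ into absolute
rates (pg/min) over one cycle ($ME = 0$, next $ME = T$):

* protein, lipid, polysaccharide: $r_j = k_j (a_j(t) + b_j)$, with
  conversion factors $k_j \ge 0$ fitted and vertical translations
  $b_j$ bounded by the activity uncertainty; negative values are
  clipped at zero and clipping at the optimum is flagged;
* DNA: constant between budding and karyokinesis, integrating to
  $\Delta M_{DNA}$, zero elsewhere;
* RNA: non-rRNA constant; rRNA proportional to the protein rate from
  15 min before mitotic exit (config `rrna_lead_min`) through budding,
  then held at its budding value until karyokinesis (continuity fixes
  the plateau, avoiding a redundant parameter), zero otherwise;
* masses: $M_j(t) = M_j(0) + \int_0^t r_j$, with initial masses closed
  by division periodicity $M_j(0) = f_j M_j(T)$ — $f$ is the mother
  volume fraction at division for protein and RNA, the mother surface
  fraction for lipid and polysaccharide, and DNA keeps one genome copy
  (config, default 0.013 pg);
* estimate: $\sum_j M_j(t)(1 + h_j) + w\,V(t)$, hydration-shell
  fractions $h_j$ as config values standing in for literature windows,
  and a free-water-plus-metabolites coefficient $w$ (pg/fl) scaling
  with *total* volume (the total-vs-mother choice is config-exposed
  and cannot be resolved from the printed text).

Fitting minimizes the unweighted squared distance between this
estimate and the empirical mass (volume × density), under box bounds
and optional cycle-average composition windows enforced by a quadratic
penalty whose binding is reported. The optimizer is multi-start
L-BFGS-B; because the estimate is linear in
$(k_j, \Delta M_{DNA}, r_{nonrRNA}, \gamma k_{protein}, w)$ at
$b_j = 0$, a least-squares solve on the component basis trajectories
provides an informed start that random restarts then guard. On
self-consistent synthetic data (exact solutions; each seed draws the
true parameters at 20% CV) the fitted $k_j$ recover truth with median
relative error well under 5%. With 1–2% observation noise, the lipid
and polysaccharide factors degrade quickly — their waveforms are
nearly collinear — which is precisely why identifiability is checked
by profile likelihood rather than asserted.

**Profile likelihood.** Each profile fixes one parameter on a grid and
re-optimizes the rest, warm-starting each refit from its neighbor so
the search tracks compensating valleys. A parameter is identifiable
when the profile exceeds the minimum plus a threshold on both sides:
the 95% $\chi^2_1$ quantile scaled by the estimated residual variance,
floored at $10^{-5}$ of the centered data sum of squares (objective
differences below that floor are within refit resolution and cannot
support a claim either way). Freeing the protein hydration fraction
creates an exact $(1+h)k$ scale degeneracy — the package's built-in
non-identifiable control.

## Phase-resolved FBA under a dissipation cap

The relative contributions $c^j(t) = r_j(t)/r_{biomass}(t)$ rescale
the reference biomass stoichiometry: component $j$'s coefficient at
phase $t$ is $c^j(t)/c^j_{model}$ times its reference molar
coefficient, the storage coefficient is zero throughout (no storage
turnover under high glucose), and one LP is solved independently per
phase (quasi-steady state; default the 17 moments $t = 3, 9, \dots,
99$ min):
$$\max v_{biomass} \quad \text{s.t.} \quad S v = 0,\; lb \le v \le ub,
\; g(v) \le g_{lim},$$
with $g_{lim} = 12.3\ \mathrm{J\,gDW^{-1}h^{-1}}$. Dissipation is kept
*linear*: with fixed external conditions it is the formation-energy
content crossing the boundary,
$g(v) = \sum_{i \in boundary} v_i \gamma_i / M_{biomass}$, where
$\gamma_i$ is the formation energy of what reaction $i$ exports. The
biomass species' formation energy follows the zero-Gibbs-error
convention for the assembly reaction,
$\Delta_f G_{biomass}(t) = \sum_j x_j(t) \Delta_f G_j$. The source
model's nonconvex concentration-coupled formulation (and its
regression of formation energies against metabolomics data) is out of
scope here.

The shipped network (`inst/extdata/network_synthetic.json`) is a
synthetic ~18-reaction reduced network — glucose transport, lumped
glycolysis, fermentation, TCA + respiratory chain, ATP maintenance,
six component-synthesis lumps with distinct ATP/NADH/precursor costs,
and the biomass assembly — with carbon-balanced stoichiometry
(audited at load) and species formation energies chosen so that every
internal reaction is exergonic as written. The latter makes boundary
dissipation provably non-negative for any feasible flux and makes the
12.3 J/gDW/h cap the binding constraint under normal operation; with
the cap slack, solutions coincide with plain FBA. The fixture's
numbers are illustrative, not a published reconstruction, and the
growth rates it yields under the cap are small — what the module is
for is the *transformations*: phase-dependent stoichiometry, the cap,
the unit conversion
$v^{cell} = 10^{-3}(v^{FBA}/v^{FBA}_{biomass})(1/M_{biomass})
r_{biomass}$ (anchored at $M_{biomass} = 0.966$ g/mmol; note
$r_{biomass}$ enters in pg cell⁻¹ h⁻¹), newborn-weighted yields
(weights $79.75/11$ at $t \in \{3, 9\}$ min, the early-G1 dwell of
newborn versus mature cells), metabolite turnover and precursor-sink
aggregation. The LP solver is the two-phase simplex of the `boot`
package behind a bounded-variable wrapper; conserved cofactor pairs
make $S$ rank-deficient, so an independent equality-row subset is
selected by QR before solving (dropped rows are linear combinations
and remain satisfied).

## The synthetic-data generator

The generator defines the study conditions everything is tested
against: a 100-min mean cycle at 5% CV (the within-population timing
variance is not constrained by the source and is a free knob), START
at 11 min, budding at 33% and karyokinesis at 85% of the cycle,
imaging every 6 min, maturation half-time 6 min, additive Gaussian
channel noise at 2% of the channel mean, 1% lognormal noise on radii,
three unmeasurable bud frames after budding. Activity waveforms are
wrapped-Gaussian bumps on a floor (two-peak protein at phases
0.15/0.60; one-peak lipid and polysaccharide near 0.6), exactly
periodic by construction. Volume growth integrates the component mass
rates divided by a density of 1.1 pg/fl, directed to the mother before
budding and the bud after; reporter pools obey the maturation ODE and
partition with the departing daughter at division so that
concentration is continuous across cytokinesis — the assumption the
reporter pipeline relies on. The NAD(P)H baseline is a phase-locked
periodic spline through user-supplied control points (the source shows
but does not parameterize it). In perturbation experiments the
derivative offset, `gain × activity(φ at t_p)`, is applied from one
frame *before* $t_p$, which is what makes $t_p$ the first frame at
which the midpoint derivative reads the perturbation; the (7,3) filter
then attenuates the read-out by the factor 0.667 that follows from its
coefficients, and the recovery tests use exactly that factor as their
oracle.

What the generator does **not** emulate: photophysics and bleaching,
segmentation failure modes, cell-to-cell interactions, death, phase
drift between the metabolic and division cycles, and realistic
background structure in images. Passing tests therefore demonstrate
correctness of the *computational chain* under its stated assumptions,
not robustness to every failure mode of real microscopy.

## Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale: 50-cell
populations for rate recovery, 200-cell perturbation experiments,
20 + 20 model-selection datasets of 60 points, 10 cell-mass fits on an
18-point cycle grid, 17 phase LPs. All stochastic steps are seeded;
identical seed and configuration reproduce results bit for bit
(GP hyperparameters to 1e-8 across repeated fits).

## Known limitations

* The cell-mass model's supplementary equations are not public; the
  reconstruction from the stated assumptions fixes the rRNA plateau by
  continuity and closes initial masses by division periodicity, both
  of which are choices a different reconstruction could make
  differently.
* Lipid and polysaccharide conversion factors are poorly separated
  whenever their activity waveforms are similar; treat their absolute
  values with the profile-likelihood verdicts in hand.
* The nucleus-segmentation threshold depends on the absolute intensity
  scale (see above); images must be compared at a common calibration.
* The dissipation constraint is a linearized boundary balance; it
  cannot reproduce concentration-dependent reaction-direction changes.
* The flux fixture's stoichiometry and energies are synthetic; yields
  and turnovers computed on it illustrate the machinery, not yeast
  physiology.
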