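---
title: "Tuning Windkessel outlet boundary conditions and propagating their uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tuning Windkessel outlet boundary conditions and propagating their uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcrtune)
```

## The modelling problem

Patient-specific simulations of aortic blood flow need outflow boundary
conditions that represent the vasculature downstream of each outlet.  The
standard choice is the three-element Windkessel model (RCR): a proximal
resistance $R_p$ in series with a parallel pair of compliance $C$ and
distal resistance $R_d$.  For an aortic-coarctation model with four
outlets — brachiocephalic (BCA), left common carotid (LCCA), left
subclavian (LSA) arteries and the descending aorta (DA) — the narrowing
adds resistance on the DA pathway, and the RCR triplets must be tuned so
that the simulated flow split and pressures match the patient's catheter
and PC-MRI measurements.

`rcrtune` implements that tuning chain and quantifies how uncertainty in
the tuning propagates to the hemodynamic outputs:

1. **Total calibration** — a constrained genetic algorithm fits the total
   triplet $(\bar R_p, \bar R_d, \bar C)$ so that the Windkessel pressure
   response to the measured inlet flow reproduces the patient's maximum,
   minimum and mean ascending-aorta pressures.
2. **Area distribution** — the totals are distributed to the outlets in
   proportion to cross-sectional area, with the *minimum coarctation area*
   substituted for the DA area before stenting, which encodes the extra
   resistance of the narrowing geometrically.
3. **Split-value redistribution** — a dimensionless parameter $\alpha$
   rescales the supra-aortic resistances by $(1+\alpha)$ while the DA
   resistance absorbs the difference so that the parallel total resistance
   is conserved.
4. **Forward model** — a 0D single-junction network splits the prescribed
   inlet flow among the RCR-terminated outlets (a desk-scale surrogate
   behind the same contract a 3D CFD solver would satisfy).
5. **Uncertainty propagation** — $\alpha$ is treated as a uniform random
   variable and propagated with generalized polynomial chaos (gPC),
   yielding stochastic means, standard deviations and probability density
   maps of every quantity of interest.

All internal arithmetic is in CGS units (resistances in
g cm$^{-4}$ s$^{-1}$, compliances in g$^{-1}$ cm$^4$ s$^2$, pressures in
barye); mmHg appears only at I/O boundaries, with
1 mmHg = 1333.22 barye.

## The Windkessel pressure solution

For a prescribed periodic inflow $Q(t)$ the RCR pressure satisfies the
closed form

$$P(t) = \left[P(0) - \bar R_p Q(0)\right] e^{-t/\tau} + \bar R_p Q(t)
  + \int_0^{t} \frac{e^{-(t-s)/\tau}}{\bar C}\, Q(s)\, \mathrm{d}s,
  \qquad \tau = \bar R_d \bar C .$$

Two numerical choices matter here.

* **Convolution quadrature.** Within each sampling interval the flow is
  taken piecewise linear (the waveform's interpolation rule) and the
  exponential kernel is integrated in closed form, giving an $O(n)$
  recursion.  The rule is second order in the step and — unlike a plain
  trapezoid of the kernel — remains exact in the stiff limit
  $\tau \to 0$, where the integral must collapse to $\bar R_d Q$.  The
  near-cancellation $1 - (1-e^{-x})/x$ is evaluated by series for small
  $x$.
* **Periodic initialisation.** The solution is affine in $P(0)$, so the
  unique initial pressure that makes it $T$-periodic is available in
  closed form (`wk_periodic_p0()`).  Running several start-up cycles and
  keeping the last converges to the same limit cycle; the closed form
  reaches it exactly, which also makes the question of "how many cycles
  before extracting statistics" moot.

The test suite checks this solution against an independent stiff-ODE
integration (`deSolve::lsoda` of $C\,\dot P_c = Q - P_c/R_d$,
$P = P_c + R_p Q$) to $10^{-6}$ relative on smooth pulses, and verifies
second-order convergence against a nested fine-grid reference.

## Calibration: the constrained genetic algorithm

The calibration problem is

$$\min_{x = (\bar R_p, \bar R_d, \bar C)}
  \Bigl(\tfrac1T \int_0^T P\,\mathrm{d}t - P_{\text{mean}}\Bigr)^2
  \quad\text{s.t.}\quad
  |\max P - P_{\text{max}}| \le \varepsilon_{\max},\;
  |\min P - P_{\text{min}}| \le \varepsilon_{\min},\;
  l_b \le x \le u_b .$$

The optimiser is a single-objective genetic algorithm of the MOGA-II
operator family: each parameter axis is discretised into a uniform grid
(default 4096 values — about 1.2 g cm$^{-4}$ s$^{-1}$ in $R_d$, i.e.
roughly 0.1 mmHg of mean-pressure resolution, an order below the
practical tolerance); the initial population is an unscrambled Sobol
sequence snapped to the grid; reproduction applies directional crossover,
mutation and selection with probabilities 0.5, 0.1 and 0.05.  Defaults
are a population of 40 and 250 generations.

Choices the operator list leaves open, and how they were resolved:

* **Constraint handling.** A static penalty plus feasibility-first
  ranking: feasible individuals always outrank infeasible ones, and
  infeasible ones compete on objective $+ W\sum$violations
  (default $W = 10^3$).
* **Tolerances.** The nominal $\varepsilon = 0.001$ is interpreted in
  mmHg (the unit of the pressure targets) and kept configurable; it is
  numerically unattainable on practical grids, so a practical
  `eps_run = 0.5` mmHg governs feasibility during the search.
* **Directional crossover.** Offspring = parent
  $+\,u\,\mathrm{sign}(\Delta\text{fitness})\,(\text{partner} -
  \text{parent})$ with $u \sim U(0,1)$ per coordinate; the partner is the
  best of a small tournament so the move usually points toward an
  improving region.
* **Survivor rule and elitism.** Each child competes with its parent and
  the best individual is always retained, which makes the best penalized
  fitness non-increasing by construction.
* **Mutation.** Half of mutations set one coordinate to a fresh uniform
  grid value (global exploration).  The other half apply a small joint
  perturbation of *all* coordinates (1% or 0.1% of each range).  The
  joint step is essential: with both pressure constraints active the
  feasible set is a thin tube in $(R_p, R_d, C)$ on which every
  single-coordinate move is blocked, and without it the search reliably
  stalls a few mmHg from the optimum.
* **Restarts.** `calibrate_total_wk()` runs two independent starts by
  default (seeds derived from the user seed) and returns the better final
  individual; the landscape has rare deceptive corners where one start
  can park on the constraint boundary.

Because three scalar targets cannot uniquely pin three parameters plus a
waveform shape, the recovery guarantee is on the *achieved pressure
summary*, not the triplet: for synthetic targets generated from a known
triplet inside the bounds, the calibrated summary matches the targets to
within 0.5 mmHg.  With a constant inflow only $R_p + R_d$ is
identifiable (the pressure is flat), and the suite checks exactly that.
The bounds default to $R_p \in [5, 300]$, $R_d \in [100, 5000]$,
$C \in [10^{-4}, 10^{-2}]$ (CGS), bracketing published aortic totals for
both clinical stages with wide margin.

## Area distribution and the $\alpha$ split value

With $A_{\text{tot}} = A_{\text{BCA}} + A_{\text{LCCA}} + A_{\text{LSA}}
+ A_{\text{CoA}}$ (pre-stenting; the restored DA area replaces
$A_{\text{CoA}}$ after stenting), each outlet receives
$R_{p,i} = \bar R_p A_{\text{tot}}/A_i$,
$R_{d,i} = \bar R_d A_{\text{tot}}/A_i$,
$C_i = \bar C A_i / A_{\text{tot}}$.  The split value rescales the
supra-aortic totals, $R_i = (1+\alpha) R_{\text{tot}}
A_{\text{tot}}/A_i$, and the DA receives
$R_{\text{DA}} = k\, R_{\text{tot}} A_{\text{tot}}/A_{\text{CoA}}$ with

$$k = \frac{A_{\text{CoA}}}{A_{\text{tot}} - \sum_i A_i/(1+\alpha)} ,$$

which conserves the parallel total resistance exactly for every
admissible $\alpha$ (the package guards admissibility by positivity of
the $k$ denominator rather than a hard-coded interval, since the DA
resistance diverges as the supra-aortic conductance share approaches the
total).  Design choices:

* The published per-outlet tables never state how an $\alpha$-modified
  outlet total splits into proximal and distal parts; the constant ratio
  $\bar R_p : \bar R_d$ is adopted because every published row satisfies
  it to better than 0.5%.
* Compliances are $\alpha$-independent, matching the identical compliance
  columns across all published $\alpha$ rows.
* The published pre-stenting compliance columns are about 1.51× the
  values implied by the area rule (their sum is
  $\approx 1.6 \times 10^{-3}$, not the calibrated
  $1.06 \times 10^{-3}$); the package follows the area rule and documents
  the discrepancy, so compliance columns are not used as a validation
  surface.
* Reproducing the published pre-stenting resistance rows works best with
  the coarctation area computed from the printed minimum diameter
  (0.98 cm $\Rightarrow \pi(0.98/2)^2 = 0.7543$ cm$^2$) rather than its
  2-decimal rounding 0.75 cm$^2$: near the $k$ denominator's zero the
  rounding shifts the DA entries by more than 1%, and the diameter-derived
  area brings every entry within $\sim$0.5%.  `patient_fixture()`
  nevertheless reports the printed 0.75 cm$^2$, as the published value.
* The published post-stenting table is internally consistent with area
  fractions that match neither the printed post-operative cross-sections
  under either DA-pathway choice; which areas produced it is not
  recoverable, so it is not used for validation.  The post-stenting
  fixture defaults to the restored DA area (`da_area_mode = "da"`), the
  physically sensible choice once the narrowing is removed.

## The 0D forward model

The surrogate couples the prescribed inlet flow to the outlet RCRs
through a single junction with zero proximal branch impedance: every
outlet sees one junction pressure, so the flow split is governed entirely
by the outlet parameters and the surrogate adds no flow-split bias of its
own.  Per outlet, $C_i \dot P_{c,i} = Q_i - P_{c,i}/R_{d,i}$ with
$Q_i = (P_j - P_{c,i})/R_{p,i}$, and mass conservation gives $P_j$ in
closed form.  Time integration is explicit RK4 (default
$\Delta t = 0.002$ s, far below stability limits for physiological
$\tau$), with the junction pressure recomputed at every stage; cycles run
until the junction-pressure trace changes by less than a relative
tolerance ($10^{-6}$) or the cycle budget (default 6) is exhausted, and
the last cycle is returned with a convergence flag.  The compliance
states start from the steady resistive split, which removes most of the
start-up transient.

An optional quadratic coarctation element
$\Delta P = K (\rho/2) (Q_{\text{DA}}/A_{\text{CoA}})^2$,
$\rho = 1.060$ g/cm$^3$, can be placed in series on the DA pathway (the
junction pressure is then found by Newton iteration).  It is **off** by
default: the $\alpha$ mechanism already represents the coarctation
resistance, and the element exists to emulate a stenosis-dominated
pressure-drop waveform shape.

The reported pressure drop is junction-to-DA-compliance-node.  The
clinical measurement spans catheter positions on either side of the
supra-aortic ostia, so the surrogate's $\Delta P$ is an analogue of the
clinical index, not a replica; its absolute value at desk scale is not
comparable to catheter numbers.

## Polynomial chaos over $\alpha$

$\alpha$ is modelled as uniform on $[-0.15, -0.08]$ (no prior information
favours any value; the interval spans the range over which the
coarctation flow varies substantially while staying admissible for the
pre-stenting geometry).  The basis is Legendre — the optimal family for a
uniform measure — mapped to the interval and *orthonormalised*, so every
basis norm is 1, the mean is the zeroth coefficient and the standard
deviation is the plain Euclidean norm of the higher coefficients; this
eliminates a whole class of normalisation bugs.  With one parameter the
tensor truncation $\Lambda = \prod_i (P_i + 1) - 1$ reduces to
$\Lambda = P$ (default order 3).

Galerkin coefficients are computed by Gauss–Legendre quadrature at exact
collocation nodes (the published deterministic $\alpha$ values −0.15,
−0.13, −0.10, −0.08 are those nodes rounded to two decimals); a
least-squares projection accepts arbitrary user-supplied nodes, including
the rounded ones, whenever the node count exceeds the order — both paths
are provided because which one produced the published results is not
stated.  Probability densities are obtained by resampling the surrogate
with a fixed seed and histogramming (no kernel bandwidth to choose, fully
reproducible).  Truncation adequacy is monitored by the relative weight
of the highest-order coefficient (`gpc_convergence()`, threshold 0.05 by
convention); for the pipeline quantities it sits near $2.6\times10^{-2}$
at order 3, and for smooth scalar responses on this narrow interval it is
below $10^{-4}$.

## Synthetic inputs and what they do (not) show

The patient flow waveforms exist only as published figures, so the
package generates single-peaked pulses: a half-sine systolic lobe over a
constant diastolic baseline.  (The figure legend's "parabolic" refers to
the spatial velocity profile across the inlet plane, not the temporal
shape.)  The closed-form cycle mean
$Q_d + (2/\pi)\,f_{\text{sys}}\,(Q_{\text{peak}} - Q_d)$ lets
`default_inflow()` solve the peak so that the mean flow equals
$P_{\text{mean}}/(\bar R_p + \bar R_d)$ of the clinical fixture
(118 cm$^3$/s pre-stenting), making fixture pressures and totals mutually
consistent for round-trip tests.  Defaults: cycle lengths 0.7 s (pre) and
1.0 s (post), diastolic baseline 30 cm$^3$/s, systolic duration
$\approx$ 0.245 s scaled to the cycle; optional Gaussian noise emulates
intra-operator variability, whose published error bars are figure-only,
so the noise amplitude is arbitrary and documented as such.

These pulses reproduce the morphology, not the patient: absolute flows,
absolute pressure drops and the published flow-error percentages depend
on the real waveforms and the 3D geometry and are *not* reproducible at
desk scale.  What the passing tests do show is structural: the tuning
algebra reproduces the published resistance tables; total resistance is
conserved to $10^{-10}$; the calibration recovers synthetic pressure
targets; and the stochastic DA-flow variability concentrates at the
systolic peak (systolic standard deviation more than twice the diastolic
level, factor $\approx 5$ here) with the mean DA flow monotone in
$\alpha$ — the qualitative signature of the published stochastic
analysis.

## Problem sizes and budgets

The test suite and the acceptance script use desk-scale sizes chosen for
convergence headroom rather than fidelity: waveforms of 128–350 samples
per cycle (4096 for oracle comparisons against `deSolve`), RK4 at
$\Delta t = 2\times10^{-3}$ s (5 × 10$^{-4}$ s for the single-outlet
degeneracy check), GA budgets of 40 × 250 by default and 40 × 600 × 2
starts for the recovery checks, $10^6$ Monte-Carlo draws for the moment
oracle, and 4–6 collocation nodes at order 3.

## Known limitations

* The 0D surrogate has a single junction: it cannot represent wave
  propagation, branch inertance (the model is strictly RCR, no L
  element) or spatial WSS patterns; TAWSS is implemented as the temporal
  averaging operator on user-supplied WSS magnitude fields.
* Calibration is stochastic; with pathological seeds the practical
  tolerance can be met at the constraint boundary rather than the
  interior.  Restarts make this rare but not impossible.
* $\alpha$ is explored as an uncertain input, never estimated from data;
  estimating it would be a different method.
* Only one uncertain parameter is propagated ($M = 1$); the general
  tensor-truncation formula is honoured so a multi-parameter extension is
  mechanical, but compliance uncertainty, geometry uncertainty and
  multi-parameter interactions are out of scope.
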