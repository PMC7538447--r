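---
title: "Force laws, solvers and calibration in centre-based cell mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force laws, solvers and calibration in centre-based cell mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbmech)
```

## The model

`cbmech` implements the overlapping-spheres flavour of the centre-based
model (CBM) of multicellular mechanics: each cell is reduced to its midpoint
$\mathbf{x}_i$ and a fixed radius $R$, spheres may overlap, and cells
interact through pairwise central forces
$\mathbf{F}_{ij} = F(\lVert \mathbf{r}_{ij}\rVert)\,
\mathbf{r}_{ij}/\lVert\mathbf{r}_{ij}\rVert$ with
$\mathbf{r}_{ij} = \mathbf{x}_j - \mathbf{x}_i$. At the low Reynolds numbers
of a tissue micro-environment inertia is negligible, so Newton's second law
with a linear drag $-\eta \dot{\mathbf{x}}_i$ collapses to the first-order
system

$$\dot{\mathbf{x}}_i \;=\; \frac{1}{\eta} \sum_{j \ne i} \mathbf{F}_{ij},$$

summed over all cells within a maximum interaction distance $r_A$. The drag
coefficient only rescales time, so it is fixed at $\eta = 1$; lengths are
measured in cell diameters and time in hours.

Every scalar force law $F(r)$ obeys the same five structural assumptions:
central and distance-dependent; a rest length $s$ with $F(s) = 0$; repulsion
($F < 0$) for overlapping cells; zero-or-adhesive ($F \ge 0$) beyond the
rest length; and no interaction beyond $r_A$. The package ships the three
laws used as defaults by the major CBM simulators — the **cubic** law
(MecaGen), the **piecewise quadratic** law (PhysiCell) and the
**generalized linear spring** (GLS, Chaste) — plus linear and Hertz laws for
completeness. Their closed forms are given in `?force_params`. Two
structural facts matter numerically:

* for the piecewise quadratic law, demanding $F(s) = 0$ ties the repulsive
  cutoff to the stiffness ratio $m = \mu_A/\mu_R$ through
  $r_R = s / (1 - \sqrt{m}\,(1 - s/r_A))$ (`r_R_from_ratio()`), leaving
  $(\mu_R, m)$ free;
* the GLS adhesive branch is *truncated* at $r_A$ rather than decaying to
  zero there, so it carries a jump discontinuity of size
  $\mu (r_A - s) e^{-\alpha (r_A - s)}$ (`gls_jump()`).

## Default geometry

All defaults describe equal cells of radius $R = 0.5$ diameters: rest
length $s = 2R = 1$, cutoff $r_A = s + R = 1.5$ (between $2\sqrt{2}R$ and
$2\sqrt{3}R$, so a square lattice relaxes into a honeycomb but
next-to-nearest honeycomb neighbours do not interact at rest), and
post-division daughter separation $r_0 = 0.3$. Division is instantaneous:
the mother is replaced by two daughters of her radius placed symmetrically
at separation $r_0$ along a uniformly random direction, with no growth
phase. These are deliberate simplifications; their cost is a transiently
unphysical compression spike right after division, which is exactly the
regime the robustness analysis below targets.

## Calibration by relaxation time

Parameterisations of different laws are made comparable by requiring the
same *pairwise relaxation time*: two daughters starting at separation
$r_0 = 0.3$ must reach $99\%$ of the rest length after $t_0 = 1$ h. For a
pair, the separation obeys the scalar ODE $\dot r = -2F(r)$
(`pairwise_ode()`), and `fit_relaxation_time()` adjusts the stiffness so
that $r(t_0) = 0.99\,s$, integrating with the high-accuracy reference
solver inside the objective:

* cubic and GLS: a bracketed 1-D root solve (the residual is monotone in
  $\mu$) — more robust than a general minimiser on the non-smooth absolute
  residual;
* piecewise quadratic: Nelder–Mead jointly over $(\mu_R, m)$ from the
  initial guess $(10, 0.2)$. The zero set of the residual is a curve in the
  $(\mu_R, m)$ plane, so the returned point is guess-dependent; any point on
  the curve yields the same pairwise dynamics, and checks should be stated
  on the relaxation time, not the raw pair.

Fitted stiffnesses are rounded to two decimals (the ratio $m$ to three)
before downstream use; derived parameters ($\mu_A = m\mu_R$, $r_R$,
$\alpha$) are computed from the rounded inputs but carried at full
precision.

Because the pair ODE is separable, the fit has a closed-form cross-check,
e.g. for the cubic law
$\mu = \tfrac12 \int_{r_0}^{0.99s} \frac{dr}{(r - r_A)^2 (s - r)}
= 5.658$. The test suite pins the fit against this independent quadrature.
Note that the accurately computed optima ($\mu_{\text{cubic}} = 5.66$,
$\mu_{\text{GLS}} = 1.94$) sit about $0.7\%$ below the conventionally
quoted $5.7 / 1.95$: the separation curve is exponentially flat near
equilibrium, so an $O(10^{-4})$ integration error inside a fitting pipeline
shifts the optimum by $O(0.05)$ in $\mu$. The forward check makes this
concrete: with $\mu = 5.7$ the pair sits at $r(1\,\mathrm{h}) = 0.9902$
rather than $0.9900$ — a physically negligible difference, but one worth
understanding when comparing fitted constants across implementations.
`cbmech` reports what accurate integration gives.

The relaxation fit leaves the GLS breadth $\alpha$ free (it only affects
adhesion). Two selection strategies are provided:

1. **shape fit** — match the GLS adhesive magnitude to the cubic law over
   $[s, r_A]$ (`fit_force_shape()`), giving $\alpha \approx 7.51$ and a
   cutoff jump of $\approx 0.02$;
2. **small jump** (default) — choose $\alpha$ in closed form so the force at
   the cutoff equals $\varepsilon = 10^{-3}$ (`alpha_small_jump()`), giving
   $\alpha \approx 13.76$.

Strategy 1 makes the pair dynamics more cubic-like but, as shown below, the
jump destroys second-order convergence; strategy 2 preserves smoothness at
the price of weaker long-range adhesion.

`fit_force_shape()` minimises the root-mean-square difference of force
magnitudes over 200 uniformly spaced points on the requested interval. The
discretisation (grid size, norm) is a package choice — different but
reasonable choices move the optima by a few percent, which is why
shape-fitted constants are only quoted loosely.

## Solvers and step-size bounds

Production CBM codes integrate with cheap explicit schemes; the package
implements forward Euler, the explicit midpoint rule, and the two-step
Adams–Bashforth method (`solve_fixed()`), next to an adaptive
Dormand–Prince 5(4) reference solver (`solve_reference()`, via
\pkg{deSolve}) at tolerances `rtol = 1e-9`, `atol = 1e-12`. Numerical
choices worth recording:

* **Grid fitting.** If the time span is not an integer multiple of `dt`,
  interior steps use `dt` exactly and only the final step is shortened to
  land on the end time. Interior steps also use `dt` itself rather than
  differences of the time grid, so a fixed-step run is bit-for-bit a
  sequence of single steps.
* **AB2 bootstrap.** The first step of Adams–Bashforth is one forward Euler
  step — the simplest consistent starter; its local error is second order,
  which leaves the global order-2 behaviour intact (verified empirically by
  the convergence tests). After every division event the state dimension
  changes, so AB2 re-bootstraps.
* **Divergence.** A non-finite state aborts with a diagnostic pointing at
  the stability bound; in convergence studies such runs are recorded as
  missing points.
* **State layout.** Positions are flattened cell-id-major,
  coordinate-minor ($x_1, y_1, x_2, y_2, \dots$); the error norm below
  depends on this contract.

For the post-division pair, forward Euler admits closed-form step-size
thresholds. The Euler iteration on the separation is
$r_{n+1} = r_n - 2\Delta t\,F(r_n)$; requiring no overshoot of the rest
length, and contraction of $|s - r_n|$, gives

$$\Delta t^*_{\text{mono}} = \frac{r_0 - s}{2F(r_0)}, \qquad
  \Delta t^*_{\text{stab}} = \frac{r_0 - s}{F(r_0)} = 2\Delta t^*_{\text{mono}},$$

computed by `step_bounds()`. Because the repulsive force is strongest at
the initial overlap, the first step is the binding one. Below
$\Delta t^*_{\text{mono}}$ the pair relaxes monotonically; between the
bounds it overshoots into the adhesive regime but still converges
(unphysical division trajectories); above $\Delta t^*_{\text{stab}}$ the
first step already moves the pair further from equilibrium — typically
beyond the cutoff, where it freezes, permanently separated. For the
calibrated laws at $r_0 = 0.3$ the bounds are $(0.0609, 0.1218)$ cubic,
$(0.0912, 0.1823)$ piecewise quadratic and $(0.1491, 0.2982)$ GLS: matching
relaxation times makes the cubic law the stiffest and GLS the most
forgiving.

## Experiments and the error metric

`convergence_study()` measures the relative space-time error

$$\epsilon_{\text{rel}} =
  \frac{\lVert \mathbf{y}_{\Delta t} - \mathbf{y}_{\text{ref}} \rVert_2}
       {\lVert \mathbf{y}_{\text{ref}} \rVert_2}$$

against a fine-step run of the same scheme, linearly interpolating the
coarse solution onto the fine grid per coordinate over the common span
(linear interpolation is the package's choice of reconstruction). The
empirical order is the log–log least-squares slope over the four smallest
step sizes with finite error; larger steps may be pre-asymptotic. Standard
problems and horizons: pairwise relaxation to 1 h (reference step
$10^{-5}$ h), an adhering pair from 1.15 diameters to 3 h ($10^{-4}$ h),
and monolayers of initially 19 or 37 cells to 4 h ($5\times10^{-4}$ h) —
the same problem sizes the test suite uses. For monolayer studies one seed
is shared by every step size and the reference, so division geometry is
identical and the measured differences are purely numerical.

`monolayer_experiment()` is the population-level driver: a honeycomb of 19
(or 37) cells at unit spacing, every cell dividing at $t = 0$, relaxing to
10 h, tracked through the population radius
$r = R + \max_i \lVert \mathbf{x}_i - \bar{\mathbf{x}} \rVert_2$ —
a deliberately coarse, relabelling-invariant summary. Ensembles over seeds
(10 by default in the tests) are reported as mean ± sd.

## What the generated data does and does not emulate

All inputs are generated programmatically — honeycomb lattices, two-cell
fixtures, and division schedules — because the study object is the
*numerics* of the model, not a data set. The generator reproduces the
standard study conditions: equal radii, unit rest length, simultaneous
division at $t = 0$, uniformly random division directions. It does not
emulate cell growth between divisions, dumbbell-shaped division, cell-cycle
time distributions, apoptosis, contact inhibition, cell–substrate friction,
or 3D spheroid geometry (the code paths are dimension-generic, but all
shipped experiments are 2D). Passing tests therefore certify the mechanics
and its numerical analysis under these idealised conditions; they say
nothing about biological realism of any particular parameter choice.

## Findings the test suite reproduces

* Forward Euler is globally first order; midpoint and Adams–Bashforth are
  second order on all smooth problems (slopes within $\pm 0.15$).
* The three Euler step-size regimes around
  $(\Delta t^*_{\text{mono}}, \Delta t^*_{\text{stab}})$ behave exactly as
  the closed-form analysis predicts.
* With the shape-fitted GLS breadth ($\alpha = 7.51$, jump $\approx 0.02$)
  the midpoint rule loses second order on the 19-cell monolayer (fitted
  slope $< 1.5$, in practice $\approx 0.85$); with the small-jump breadth it
  stays at order 2. Smoothness of the force law, not just stability, decides
  whether higher-order solvers pay off.
* Calibrated to a common relaxation time, the three laws give monolayer
  radius curves that agree within $5\%$ (in practice $\lesssim 3\%$) under
  accurate integration and a shared division seed, and the radius never
  falls below the initial configuration's.
* Adhesive-regime errors sit below repulsive-regime errors at matched
  steps: the post-division transient is the worst case, so choosing
  $\Delta t$ to resolve pairwise relaxation is a sound a-priori rule for
  tissue-scale runs.

## Limitations

The all-pairs $O(K^2)$ force assembly is intentional — the study object is
step counts, not per-step cost — so populations beyond a few thousand cells
are out of intended scope, as are neighbour-list accelerations, Voronoi
connectivity, implicit or adaptive production solvers, and the
contact-mechanics (JKR) family of force laws with history-dependent
adhesion. The equal-weight centroid is conserved by the dynamics within an
epoch but not across a division (the cell count changes); only the two
daughters' mean position equals the mother's.
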