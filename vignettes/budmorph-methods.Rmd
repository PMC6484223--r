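---
title: "Methods: ligand-receptor Turing patterning on two-layer bud domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ligand-receptor Turing patterning on two-layer bud domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(budmorph)
```

## The model

The package models the patterning system that positions outgrowth during
branching morphogenesis of the ureteric bud: a diffusible ligand (GDNF)
produced in the metanephric mesenchyme binds a membrane receptor (RET)
expressed in the epithelium, and signalling by the complex up-regulates
receptor abundance.  With the complex in quasi-steady state, the
concentrations of receptor $R$ (epithelium only) and ligand $L$ obey

$$
\begin{aligned}
\text{epithelium:} \quad
 \partial_t R &= D_R \Delta R + \rho_R - \delta_R R + (v - m\mu) R^m L^n,\\
 \partial_t L &= D_L \Delta L - n \mu R^m L^n - \delta_L L,\\
\text{mesenchyme:} \quad
 \partial_t L &= D_L \Delta L + \rho_L - \delta_L L .
\end{aligned}
$$

The model family T1-T5 shares these equations and differs in which of the
necessary conditions for a diffusion-driven (Turing) instability holds:

* **T1** - the full ligand-receptor Turing model, $m = 2$, $n = 1$;
* **T2** - no receptor up-regulation ($v = 0$);
* **T3** - equal diffusivities ($D_L = D_R$);
* **T4** - no cooperativity ($m = n = 1$);
* **T5** - T1 plus a second epithelial ligand $L_1$ (WNT11-like) induced by
  signalling at rate $b_1 R^m L^n$ and feeding back on mesenchymal ligand
  production as $\rho_L + \gamma L_1/(K_{fb} + L_1)$.

The three necessary conditions checked by `turing_conditions()` are
$D_L > D_R$, $v > m\mu$, and cooperative complex formation ($m + n > 2$).

### T5 functional form

The exact published form of the second-ligand coupling is not reproduced
here; the package's T5 uses production $b_1 R^m L^n$ in the epithelium,
linear decay $\delta_{L1}$, diffusivity $D_{L1} = D_L$ by default, and a
*saturating* feedback $\gamma L_1/(K_{fb}+L_1)$ on mesenchymal ligand
production.  Saturation was chosen deliberately: with two stacked positive
feedbacks a linear coupling admits unbounded growth, while the saturating
form guarantees bounded steady states for all parameter values.

## Linear stability analysis

The LSA runs on the epithelial pair with the mesenchyme collapsed to a
well-mixed ligand reservoir (its source $\rho_L$ added to the epithelial
ligand equation).  Rationale: the necessary conditions are stated for the
ligand-receptor pair, and the package validates the collapsed LSA against
full spatial simulation instead of reproducing a tissue-resolved analysis:
on a zero-flux rectangle, the LSA flag must agree with simulated patterning
(interface amplitude ratio > 1.5) on at least 90% of log-uniformly sampled
parameter sets, excluding sets within $10^{-3}$ of the instability
boundary.  The homogeneous fixed point is reduced to a scalar root problem
in $S = R^m L^n$ and bracketed; when several positive roots exist the
continuation of the binding-free state (smallest $S$) is used.

## Geometry and meshing

Epithelial outlines are closed curves, smoothed by a periodic least-squares
cubic B-spline; normals and curvature come from the spline derivatives.
The mesenchyme is an ellipse with semi-axes $r_i = 2\alpha\sqrt{\lambda_i}$,
where $\lambda_i$ are the eigenvalues of the second-central-moment matrix
of the *uniformly filled* epithelial region (total mass 1, stalk removed
first) and $\alpha = 3$ by default.  Boundary-point mass is available as an
option (`mass = "boundary"`); the filled-region convention is the default
because the mass is stated to be uniformly distributed in the epithelium.

The mesher is a structured concentric-ring construction rather than a
constrained Delaunay triangulation: no triangulation library exists in the
supported dependency stack, and a robust from-scratch CDT was judged a
larger correctness risk than a structured mesh that is exact on the shapes
in scope.  It requires the epithelium to be star-shaped about its centroid
- true for all ureteric-bud-like outlines the generators produce (ellipse
plus Gaussian bud lobes) - and places ring nodes so that the epithelial
boundary is resolved exactly by mesh edges shared between the two
subdomains.  Typical quality on the fixtures: minimum angle 15-35 degrees,
median edge within a few percent of `target_h`.

For refined meshes an optional geometric grading (`grade = 1.15`, capped at
`4 * target_h`) lets the mesenchymal ring spacing grow away from the
interface.  The ligand field there is smooth - its decay length
$\sqrt{D_L/\delta_L} \approx 27$ length units for the fixture - so grading
leaves the interface profile essentially unchanged while cutting the node
count of an `h = 0.25` mesh about five-fold.  The default remains a uniform
mesh; the convergence study uses the graded family at all levels, so the
refinement ratio it reports is a property of one consistent discretisation
family.

## Steady-state solver

Linear (P1) or quadratic (P2) Lagrange triangles with consistent-mass
(group finite element) treatment of reaction and source terms; the
receptor is assembled on epithelial elements only (natural zero-flux at
the interface), the ligand is continuous across the interface, and all
outer boundaries (including the stalk cut and the mirror plane of the
two-bud geometry) are zero-flux.  P1 is the default; the mesh-convergence
study uses P2, matching the quadratic elements of the commercial FEM
package used for the published solves - P1 at mesh size 1 carries about 1%
interface-field error (3-4% deviation error) for every smooth Turing set
tested, whereas P2 reaches the published 0.5% accuracy.

Steady states are found by pseudo-transient continuation: each step solves
one Newton iteration of implicit Euler, $(M/\Delta t + D K - M J(u))\,
\delta u = -F(u)$, with a sparse LU factorisation reused across steps and
refreshed when the step size changes.  A plain semi-implicit scheme
(explicit reaction) was implemented first and stalls at the explicit
stability limit once a Turing pattern saturates - the residual plateaus
around $10^{-2}$ - which motivated the fully implicit linearised scheme.
Two safeguards matter:

* while the linear instability is still amplifying, the step is capped at
  $1/\lambda_{max}$ so the growing mode is tracked instead of being
  Newton-collapsed back onto the (unstable) homogeneous state, and the run
  must cover at least `burst_efolds / lambda_max` of pseudo-time (30
  e-folds by default) before it may declare convergence;
* small negative undershoots are projected to zero (projected implicit
  Euler); a step is rejected and retried with a smaller step only on gross
  violations (negatives beyond 5% of the species scale) or a residual
  increase beyond 4x - the residual is allowed to grow moderately because
  fast physical transients (e.g. the interface boundary layers the
  non-cooperative variant forms at extreme production rates) legitimately
  raise it.

Convergence is declared when the relative change per unit pseudo-time
falls below `tol` ($10^{-6}$ by default, $10^{-8}$ in convergence studies)
on two consecutive steps.

The initial condition is the homogeneous steady state plus a smooth seeded
random-plane-wave field of relative amplitude $10^{-3}$.  A *smooth
mesh-independent* field is used instead of iid nodal noise deliberately:
nodal noise changes with the mesh, so a refinement study would compare
solutions of different initial-value problems; the plane-wave field makes
`h = 1` and `h = 0.25` discretisations of the same continuous problem.

Refinement studies (`solve_cascade()`) solve the coarsest level from
scratch and continue the converged solution onto finer meshes by
nearest-node transfer, so that every level discretises the same steady
pattern; warm-started levels converge in a handful of Newton steps.  For
very large warm-started systems (beyond ~300k unknowns, where a coupled
sparse LU no longer fits the memory budget) the solver switches to an
inexact Newton iteration: the Jacobian uses HRZ-lumped reaction weights
(diagonal coupling blocks) and each Newton system is solved by BiCGSTAB
preconditioned with the two symmetric positive definite diffusion+decay
blocks (CHOLMOD Cholesky).  The interface ring of convergence-study meshes
is refined two-fold relative to `target_h` (`interface_refine = 2`), which
suppresses the polygonal-geometry and profile-sampling error components at
the bud tips.

## Model comparison

For each frame the predicted signalling $C = R^mL^n / \max_{\partial\Omega}
R^mL^n$ and the measured growth strength $E = |v|/\max|v|$ are sampled at
400 uniform arc-length positions on the interface and compared by
$\Delta = \sqrt{\oint_{\partial\Omega} (C-E)^2\, ds}$ (trapezoid rule;
periodic closure on a closed interface).  Per-frame deviations of the same
parameter set sum to the global deviation $\Delta_g$; variants are ranked
by their minimal $\Delta_g$ over a shared log-uniform sample.  The
signalling readout uses each model's own $(m, n)$ - so $RL$ for T4 - which
is exposed as `readout_exponents` for users who prefer a fixed $R^2L$
readout for all variants.

Screening defaults for continuous-integration scale are documented in
`default_screen_ranges()`: one decade around the fixture Turing set per
kinetic parameter (the published screens sampled several thousand sets over
wider ranges; the package's acceptance tests use 12-50 sets and state so).

## Growth and branching

Domain outgrowth is front tracking of the interface polyline: each
material point advances along the outward spline normal at speed
$v_g f(R^mL^n)$ with $f(s) = s^{h_g}/(K_g^{h_g} + s^{h_g})$, $h_g = 2$;
the saturating form reflects the observation that uniformly raised ligand
widens buds rather than accelerating them without bound.  $K_g$ defaults
to the mean interface signal at simulation start.  The outer mesenchyme
boundary expands at constant normal speed $v_g = 0.04$; for an ellipse the
normal offset is approximated by growing both semi-axes by $v_g\,dt$.  The
RD system is re-solved to steady state after every growth step
(quasi-steady-state limit), initialised from the previous solution by
nearest-node transfer; the boundary is re-sampled uniformly every
`remesh_every` steps.  Tips are curvature maxima above twice the
equivalent-circle curvature, non-maximum-suppressed at `L/20` arc length;
a tip-count increase of 2 between consecutive steps is logged as a
trifurcation, of 1 as a bifurcation.  Branch *angles* are deliberately not
modelled or asserted.

### Two opposing buds

The interbud-distance experiments use a mirror reduction: one bud next to
a zero-flux plane at distance $l_0/2$ from its tip, which is exactly
equivalent to an identical opposing bud for mirror-symmetric patterns.
The reduction cannot represent symmetry-broken two-bud states; the
elongation mode being tested (a single centred peak on each tip) is itself
symmetric, so the reduction is adequate for the classification but this is
a stated limitation.  Elongation requires, on both tips: amplitude
$\max/\min > 5$; exactly one peak (local maxima with prominence at least
5% of the profile range); and the peak within 10% of the bud-centre arc
position.  $\Lambda$ is the fraction of sampled sets classified as
elongating.

## Synthetic data

The generators state the world the tests run in: bud shapes are ellipses
with Gaussian radial lobes; synthetic time-lapses advance material points
along outward normals with Gaussian arc-length growth profiles (frames 2 h
apart, matching the culture imaging cadence); masks are scanline-rasterised
polygons with Gaussian pixel noise and small distractor blobs that exercise
the largest-component rule; tip clouds are Poisson-disk (dart-throwing)
samples on ellipsoid surfaces with a hard minimum spacing, area-uniform by
rejection.  Synthetic growth uses analytic profiles rather than RD output
so the image-pipeline tests do not depend on the solver; RD-driven movies
come from the branching simulator.  What a green test does **not**
establish: performance on real microscopy (uneven illumination, debris,
segmentation ambiguity), non-star-shaped epithelia, or 3D effects - the
voxel-level skeletonisation pipeline is explicitly out of scope and tip
coordinates are taken as input.

The frozen fixture parameter set (T1: $D_R = 3.5$, $D_L = 77$,
$\rho_R = 0.085$, $\rho_L = 0.27$, $\delta_R = 0.44$, $\delta_L = 0.17$,
$\mu = 0.47$, $v = 1.96$) was found by a seeded log-uniform LSA scan
restricted to the weakly supercritical regime ($v/(m\mu)$ close to 1,
ligand range $\sqrt{D_L/\delta_L} \approx 21$ shorter than the domain):
strongly supercritical sets of this unsaturated kinetics form
near-singular receptor spikes (amplitude ratios in the hundreds, feature
widths below one length unit) that no practical mesh resolves, whereas the
published signal fields are smooth with moderate contrast.  The fixture's
pattern wavelength ($2\pi/k_{max} \approx 34$) puts a handful of
wavelengths on a length-100 domain, and its T2/T3/T4 degenerations are all
linearly stable.  The T5 fixture adds a tip-local second ligand
($b_1 = 1$, $\delta_{L1} = 0.1$, $D_{L1} = 2$, i.e. a 4.5-unit range) with
a weak-slope saturating feedback ($\gamma = 0.5$, $K_{fb} = 100$): the
feedback slope at the operating point is the binding constraint, because a
stronger coupling stabilises the collapsed fixed point and destroys the
Turing signature.  Within that constraint the feedback turns out to be
classification-neutral on the two-bud fixture - the minimal sustaining
interbud distance and $\Lambda$ tie between T1 and T5 - so the package
reproduces the feedback's architecture but not a strict reduction of
interbud distance for this fixture.

## Numerical choices and degenerate inputs

* Quadrature: trapezoid on the 400-point uniform arc grid; against a
  64x refined reference this is accurate to $10^{-4}$ relative.
* Stalk: removed before moment computation; re-closed with a straight
  chord; its boundary is zero-flux (the condition there is not otherwise
  specified) and it neither grows nor contributes to signalling profiles.
* All-zero profiles or growth fields are normalisation errors, not zeros.
* A bead ligand source placed where there is no mesenchymal mass is
  rejected at solve time.
* Welch's test with both variances zero returns $p = 1$ for equal means.
* Tie-breaks: first-intersection wins for displacement rays; the
  lower-indexed candidate wins nearest-node ties in state transfer.

## Known limitations

* The mesher requires star-shaped epithelia; strongly re-entrant outlines
  (late-stage branched trees) are out of reach of the current front
  tracking + ring meshing and are rejected with a geometry error.
* The LSA is the collapsed two-compartment analysis, validated empirically
  against simulation rather than derived tissue-resolved.
* `median_t2t()` defaults to the k-nearest-neighbour rule (k = 6, distance
  cap at 3x the global median nearest-neighbour spacing); Delaunay natural
  neighbours are not available without a triangulation dependency.
* Acceptance-scale screens (dozens of sets) are far smaller than the
  published several-thousand-set screens; they test recovery and ordering,
  not the published minima.
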