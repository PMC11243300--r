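---
title: "Methods: desk-scale fluid-structure interaction for sidewall aneurysms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale fluid-structure interaction for sidewall aneurysms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sacflow` implements, at desk scale, a complete rigid-versus-compliant
haemodynamics study of sidewall intracranial aneurysms: synthetic labelled
bulge geometry, an idealized toroidal parent artery, a strongly coupled
two-dimensional fluid-structure solver, the standard haemodynamic risk
indicators, cohort statistics, and a braided flow-diverter analog. This
vignette records the models, the numerical choices, and the limits of what
the desk-scale reduction can and cannot show.

## The physical configuration

The parent vessel is a 4 mm-calibre torus section (centerline radius 6 mm,
arc from 40 to 140 degrees) with the aneurysm mounted over a neck opening at
the outer-wall apex. The torus lies in the x-y plane with y vertical; with
these radii the outer-wall apex sits at y = 8 mm, so the sac cut plane
y > 8 mm used for regional material assignment and for the indicator masks
coincides with the apex. The centerline radius is not uniquely determined by
the configuration the package emulates; 6 mm is the package's declared
default and is configurable.

Blood is Newtonian (density 1000 kg/m^3, viscosity 0.004 Pa s). The wall is
a Neo-Hookean solid with a Simo-Taylor volumetric part,

  Psi(C) = (1/4) kappa (J^2 - 1) - (1/2) kappa ln J
           + (1/2) mu_s (tr Cbar - 3),

with E = 0.75 MPa and nu = 0.45 in the bulge (mu_s = 258.6 kPa,
kappa = 2.5 MPa), reference density 1200 kg/m^3, and a tenfold stiffer
artery segment (elements with centroid below the y = 8 mm plane). The
volumetric stress is p_s = U'(J) = (1/2) kappa (J - 1/J): this is the
derivative of the stored energy and the only form with U'(1) = 0; a
published variant with a "+" sign in place of the "-" is not
derivative-consistent and is treated here as a typographical artefact.

The pulsatile inflow has period 0.8 s and mean 4 mL/s; its shape is the mean
plus three harmonics with geometrically decaying amplitudes
a_k = a_1 rho^(k-1) and a fixed systolic peak at 15% of the cycle. The two
free parameters (a_1, rho) are solved so that the peak and trough match tube
Reynolds numbers 520 and 220 in the 4 mm vessel (6.534 and 2.765 mL/s). Two
harmonics were tried first and proven infeasible: with the peak pinned at
15% of the cycle, no symmetric two-harmonic waveform reaches a trough as
shallow as 2.765 mL/s while peaking at 6.534 mL/s, so a third harmonic
carries the required asymmetry between systole and diastole. The resistive
outlet P = P0 + Rd Q with P0 = -3.7 kPa and Rd = 1.31 kPa s/mL then yields a
pulse pressure of Rd * dQ = 4.94 kPa = 37.0 mmHg; the commonly quoted round
value of 40 mmHg is not simultaneously consistent with these Reynolds
bounds, and the Reynolds calibration wins here. Likewise, the standard
Womersley number for D = 4 mm, T = 0.8 s, nu = 4e-6 m^2/s is 2.80; the
package reports that value and does not force any other convention.

## The two-dimensional reduction

All transient simulations run on the mid-plane cut of the configuration: a
curved channel (annulus sector) carrying a circular-arc sac over the neck
chord. Two consequences of cutting a vessel in its plane deserve emphasis:

* **Lost hoop stiffness.** A 2D wall strip is a bending arc; the
  out-of-plane hoop ring that carries most of the pressure load in a real
  vessel is gone, and at arterial pressures the strip would simply collapse.
  The solid model therefore carries a Winkler foundation with coefficient
  k = E_eff / R^2 per unit volume (R the out-of-plane curvature radius: the
  2 mm tube radius in the artery, the dome radius in the sac), which is
  exactly the membrane stiffness of the missing ring. With it, a 4.9 kPa
  pulse produces sac wall excursions of tens of micrometres and sac-area
  pulsations of a few percent - the same order as the systolic volume
  changes of about 12% seen in comparable three-dimensional compliant
  simulations, without being numerically equal to them.
* **Flow-rate mapping.** The 2D slice conserves the 3D mean velocity
  (0.3183 m/s at 4 mL/s), not the volumetric rate; the resistive outlet
  converts the 2D outlet mean velocity back to an equivalent 3D flow rate
  before applying the resistance.

## Fluid solver

Equal-order P1-P1 triangles with residual-based SUPG/PSPG and grad-div
stabilization; implicit Euler in time; Picard iterations on the advection
field; ALE kinematics with the convective velocity v - v_mesh. Three
numerical choices matter:

* The element residual of a P1 discretization has no viscous term, which
  makes the classical stabilized method inconsistent at first order in
  developed flows. The solver restores the viscous residual with a
  patch-recovered Laplacian (area-weighted nodal gradient averaging followed
  by an element-wise divergence). With it, steady channel flow converges at
  second order in the L2 norm; without it the observed order drops below
  one.
* The viscous term uses the Laplacian form nu grad v : grad w. Its natural
  outlet condition nu dv/dn - p n is exact for developed channel flow, and
  on no-slip walls the associated boundary flux coincides with the true
  Cauchy traction, which is what the wall-shear post-processing needs.
* The linear resistive outlet is assembled implicitly as a rank-one boundary
  operator (Rd k / rho) w w^T. The explicit (lagged) update has a feedback
  gain above one at physiological Rd and diverges.

Wall tractions are evaluated variationally (the reaction of the momentum
residual at wall rows), which is superconvergent: the steady channel-flow
wall shear is reproduced to a fraction of a percent on coarse meshes. The
stabilization parameter is
tau = ((2/dt)^2 + (2|a|/h)^2 + (4 nu/h^2)^2)^(-1/2) with tau_c = h^2/tau,
evaluated with a global advection scale so tau varies smoothly across
uniform meshes.

## Solid solver

Mixed displacement-pressure P1-P1 plane-strain triangles, assembled
total-Lagrangian (the updated-Lagrangian narrative of the configuration is
algebraically equivalent for this material). The volumetric constraint is
div(u) - p/kappa = 0 by default, i.e. the linearized compressibility
relation as printed in the source formulation; the finite-strain variant
p = U'(J) is available behind `finite_vol = TRUE` and is the
energy-consistent choice for conservation checks. A small
pressure-Laplacian stabilization (alpha h^2/mu with alpha = 0.05) suppresses
the equal-order pressure checkerboard. The Newton iteration uses a
finite-difference consistent tangent with backtracking; the linear systems
are block-scaled (pressure rows by kappa, pressure columns by mu) because
the raw mixed system spans fourteen orders of magnitude and defeats sparse
LU otherwise. Time integration is Newmark-beta (trapezoidal by default);
energy drift in free vibration is below 1% per cycle at the tested step.

## Partitioned coupling

Dirichlet-Neumann: the fluid sees the interface velocity, the solid receives
the consistent nodal wall forces, and the interface displacement is the
fixed-point unknown, relaxed by Aitken's delta-squared with factors clipped
to [0.05, 1]. Convergence uses the plain L2 norm of the displacement change
divided by the number of solid nodes, against 1e-5 mm; "scaled by the number
of nodes" is taken literally (divide by N, not sqrt(N)). Three further
choices were forced by experiment:

* **Backward-Euler solid kinematics in coupled runs.** With trapezoidal
  Newmark the interface velocity (about 2 du/dt) disagrees with the ALE mesh
  velocity (du/dt) at first order, pumping a spurious volume flux through
  the moving wall each step; on the closed, resistively-terminated vessel
  this feedback grows and tangles the mesh within a few dozen steps - and it
  grows *faster* the tighter the sub-iteration tolerance, which identifies
  it as a property of the converged partitioned solution, not of loose
  coupling. With backward-Euler kinematics (u_dot = du/dt) the wall, mesh
  and solid velocities coincide exactly and the runs are stable. The pure
  solid module keeps trapezoidal Newmark as its default.
* **A minimum of two sub-iterations per step.** The displacement predictor
  alone can meet the tolerance, which silently degenerates the scheme to
  loose coupling; the added-mass effect then amplifies step-to-step errors.
* **A final consistency sweep.** On convergence the fluid is re-solved once
  with the converged solid interface velocity, so the returned states
  satisfy discrete kinematic continuity exactly (the interface velocity
  mismatch of the accepted step is zero to solver precision).

Mesh motion is a harmonic extension of the interface displacement with
inverse-area stiffening, prefactored once on the reference mesh. The outlet
pressure model is ramped with the same 0.2 s envelope as the inflow: the
reference pressure P0 = -3.7 kPa applied instantaneously to a wall at rest
is a shock that serves no physical purpose during initialization.

## Indicators and statistics

WSS is the tangential wall traction; the projection uses the deformed wall
geometry of each stored sample, because a fixed reference normal leaks a
slice of the kPa-scale pressure into the Pa-scale shear on a compliant wall.
TAWSS and OSI integrate by trapezoid over the second cardiac cycle
(t in [1.0, 1.8] s). The sac battery follows the standard definitions: KER
and VDR are sac-to-parent ratios of kinetic-energy and viscous-dissipation
densities; HSA/LSA are sac-wall fractions above/below the parent-wall TAWSS
mean +/- 1 SD (the parent reference excludes a 2 mm buffer at the in/outflow
planes); ICI relates the ostium inflow concentration to the inflow-length
fraction; SCI concentrates the sac shear force on the high-WSS region.
Relative changes are 100 (compliant - rigid)/rigid; indicators whose rigid
magnitude sits at solver-noise level (below 1e-10) are flagged undefined
rather than divided by - in the smooth 2D demo the sac flow never reverses,
so OSI is numerically zero in both modes and its relative change is
meaningless there, unlike in the three-dimensional setting this emulates.

The signed-rank test ranks zeros before dropping them (Pratt; the
conventional drop-first variant is available), uses the exact tie-aware null
up to 50 nonzero pairs via the generating polynomial of doubled midranks,
and a continuity-corrected normal approximation beyond. Spearman
correlations verify the Pearson-on-ranks identity on every call.

## Flow-diverter analog

Deployment maps 24 + 24 counter-wound helices of 40 um wire onto the luminal
torus surface; the cited curvature-compaction deployment is out of scope and
replaced by pitch calibration: the braid pitch is solved so the analytic
patch-mean porosity (1 - f)^2, with the local per-family coverage
f = (d/dc) sqrt(1 + m^2) accounting for the outer-wall metric stretch
(R_c + a cos phi)/R_c, equals the 0.69 target; the resulting patch porosity
range stays inside 67-71%. A dense sampled porosity in the flattened strip
cross-checks the analytic route to better than 1%. In 2D the device appears
as equally spaced wire cross-sections along the neck chord at the target
linear porosity 1 - n d / L; immersion removes the mesh nodes inside each
strut (plus a strut-fitting margin of 0.65 local grid cells, so the hole
boundary resolves the circular strut) and tags the hole boundaries no-slip.
The stented-versus-unstented comparison uses steady solves at the mean
inflow - the time-averaged analog - and shows sac-mean velocity reductions
far beyond the 50% audit threshold at 70% porosity.

## Problem sizes and what the tests show

The default demo case uses a fluid mesh of about 700 nodes (three
wall-normal boundary layers of ratio 1.2 starting at 60 um, 0.45 mm core), a
four-layer 0.25 mm solid shell, and dt = 2 ms (400 steps per cycle); the
test suite exercises the same protocol at dt = 4 ms and coarser meshes so
the whole suite stays within a desk-scale run time. Mesh operations default
to the reference resolutions (20 um first boundary layer, 1.2 ratio, 4x0.0625
mm shell). These sizes are the package's own desk-scale choices: the
verification problems (channel flows, Lame cylinder, free vibration) have
analytic or independently computed references and carry tolerances, whereas
the cohort-level physics of the emulated three-dimensional study
(sac-averaged OSI shifts, stented velocity increases, volume pulsation
percentages) is *not* reproduced numerically at this scale - the
corresponding checks in this package are directional audits only (signs,
orderings, containment in wide physical ranges).

Known limitations: the 2D reduction has no secondary (out-of-plane) flow,
so the helical inflow jet of the 3D configuration is absent and the sac sees
a milder, recirculation-dominated exposure with near-zero OSI; the Winkler
foundation restores the membrane response but not bending coupling across
the hoop; the isotropic remesher targets uniform edge lengths only; 3D
volume meshing is limited to exact prismatic boundary-layer stacks plus a
centroid-fan core for star-shaped cavities; the stent wires are rigid and
the braid is a pure helix family. Within those limits every module of the
pipeline is exercised end to end by code, with no external data.
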