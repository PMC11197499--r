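---
title: "Simulating wall shear stress in cerebral arteries: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating wall shear stress in cerebral arteries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical model

`hemowss` simulates laminar blood flow through a single artery segment and
extracts the wall shear stress (WSS), the tangential traction the flowing
blood exerts on the vessel wall. Blood is treated as an incompressible
Newtonian fluid with constant density $\rho = 1.06\times10^{3}\,$kg/m$^3$
and constant dynamic viscosity $\mu = 3.5\times10^{-3}\,$kg/(m·s), governed
by the unsteady incompressible Navier–Stokes equations

$$\frac{\partial v}{\partial t} + (v\cdot\nabla)v
  = -\frac{1}{\rho}\nabla p + \frac{\mu}{\rho}\nabla^2 v + f,
  \qquad \nabla\cdot v = 0,$$

with zero body force $f$ (stored explicitly so a nonzero choice remains
possible), a no-slip vessel wall, zero initial conditions, and a laminar
regime: at a characteristic carotid diameter $D = 6\times10^{-3}$ m and
velocity $v = 0.4$ m/s the Reynolds number $Re = \rho v D / \mu \approx
727$, far below the pipe-flow transition near 2300. `reynolds_number()`
always evaluates the formula; the package makes no attempt to force any
other printed value.

Boundary data mimic a patient-specific protocol. Each inflow artery
carries a Doppler-derived mean velocity
$V_{in} = w_{sys} V_{systole} + w_{dia} V_{diastole}$ and a cross-section
$A_{in}$ from the measured lumen radius, giving $Q_{in} = V_{in} A_{in}$.
The total peripheral resistance is $R_{total} = P / Q_{in}$ with $P$ the
brachial cuff pressure, split across outlets so the parallel combination
reproduces $R_{total}$; each outlet then imposes the resistance condition
$P_{out} = R_{out} Q_{out}$.

Three conventions in this chain are genuinely ambiguous in the clinical
literature this pipeline emulates, and the package fixes each one
explicitly, with the alternative available as an argument:

* **Mean-velocity weights.** The default is $(1/3, 2/3)$ — the classical
  cycle-mean estimate whose weights sum to one. A literal $(1/2, 2/3)$
  variant can be requested in `mean_inlet_velocity()`; it inflates the
  mean by 8–17% but only rescales the flow.
* **Inlet area.** The default is the geometric cross-section $\pi r^2$; a
  doubled `paper_2pi_r2` convention (e.g. paired arteries counted as one
  inflow) is available in `inlet_flow_rate()`. WSS ratios are invariant
  under both choices.
* **The resistance relation.** $P_{out} = R_{out} Q_{out}$ is implemented
  as an instantaneous algebraic relation, evaluated with $Q_{out}$ lagged
  one nonlinear iterate. A literal time integral would grow without bound
  under steady flow, so the integral notation is read as the resistance
  boundary operator.
* **The outlet split.** How $R_{total}$ distributes over several outlets
  is rarely stated; the default is Murray-law-like, flow fractions
  proportional to $r_k^{3}$ (exponent configurable), constrained so
  $\sum 1/R_{out,k} = 1/R_{total}$.

At the wall, the Cauchy stress of an incompressible Newtonian fluid is
$\sigma = -pI + \mu(\nabla v + \nabla v^\top)$ (the constitutive form is
fixed here; Newtonian rheology implies it), and the WSS vector is the
tangential part of the traction:

$$\mathrm{WSS} = \sigma n - (\sigma n \cdot n)\, n.$$

Regional WSS is the area-weighted mean of $|\mathrm{WSS}|$ over a region
(each face weighted by its area; a per-face unweighted mean is available,
as the phrase "mean of the calculated magnitude" is ambiguous between the
two). Two summary ratios describe the spatial pattern:
`rwss_vi_ds()` (ventral+inferior over dorsal+superior walls) and
`rwss_inner_outer()` (inner over outer wall of the vessel curve). In a
curved tube, secondary (Dean) flow displaces the peak axial velocity
toward the outer wall, so the inner/outer ratio is expected below one —
the directional fact the curved-tube validation checks.

## What the synthetic generator does and does not emulate

Real studies segment patient MR angiography; this package instead
generates parametric vessels so every downstream stage is testable without
patient data. `make_centerline()` produces straight, constant-curvature
and S-shaped centerlines (arcs lie in the axial anatomical plane, where
the M1 segment of the middle cerebral artery predominantly curves);
`make_vessel_surface()` sweeps a circular cross-section along the
centerline using a rotation-minimizing frame. An optional eccentric plaque
narrows the lumen on a named wall with smooth cosine falloff, so the
thinnest thickening is always under 50% of the thickest — the
identification rule for eccentric plaques. Plaque is modeled as inward
narrowing because the flow domain is the lumen: only lumen shape affects
WSS.

`make_image_phantom()` voxelizes the lumen at the vessel-wall-imaging
geometry (0.4 × 0.4 mm in-plane, 0.8 mm slices by default) as a binary
mask — it is a geometry phantom, not an MR signal simulation.
`make_ultrasound_panel()` draws measurement panels from plausible adult
ranges: systolic velocity 0.4–1.2 m/s, diastolic fraction 0.3–0.6,
radius 1.5–3.5 mm, brachial pressure 80–120 mmHg. No public cohort
distributions exist for these quantities in the imaging population the
pipeline emulates, so the ranges are asserted as physiologically
plausible rather than cohort-matched, and they are fixed defaults, not
fitted quantities. Seeds are mandatory arguments everywhere and never
touch the global RNG state.

Consequently, passing tests demonstrate correctness of the machinery —
conservation, convergence to analytic oracles, label geometry, agreement
statistics — on idealized tube geometries. They do not reproduce any
patient-level result: real M1 segments have branches, non-circular lumens
and measured (not parametric) curvature, and published group-level WSS
tables derive from such cohorts.

## Discretization and solver

The mesh (`tetrahedralize()`) is a structured sweep: a polar cross-section
grid (center node plus rings) swept along the centerline, each triangular
prism split into three tetrahedra by a minimum-global-index diagonal rule
that guarantees conformity. Radial ring spacing is graded toward the wall
by `near_wall_factor` (default 0.5), boundary-layer style: refinement is
wall-normal only, since that is the direction that controls wall-gradient
accuracy; circumferential and axial sizing follow `target_edge`. Outward
normals are fixed by the adjacent-tet-centroid sign test, and the closed
surface satisfies the divergence identity
$\oint x\cdot n\, dA = 3V$ to near machine precision — the validity check
`mesh_divergence_check()` applies. Cell counts at the default desk-scale
resolutions run $10^4$–$10^5$; production studies use million-cell meshes
on parallel hardware, and that scale is intentionally out of scope here,
with the minimum-cell-volume audit (1.0 × 10⁻⁸ cm³) retained in
`mesh_quality()`.

The flow discretization is equal-order P1/P1 velocity–pressure with PSPG
pressure stabilization (an inf-sup-stable mixed pair being the
alternative; equal-order was chosen for its much smaller system at equal
node count, and it must—and does—pass the Poiseuille oracle). The PSPG
parameter per element is
$\tau = \left[(2|w|/h)^2 + (4\nu/h^2)^2\right]^{-1/2}$; the time-step
term conventionally added to $\tau$ is omitted so the discrete steady
state is independent of `dt`, and in Stokes mode the diffusive limit
($|w| = 0$) applies, which also keeps Stokes solutions exactly linear in
the flow rate — a property the test suite checks bit-for-bit.

Each nonlinear step solves an Oseen system: convection is implicit at the
previous Picard iterate (a lagged explicit treatment is structurally
attractive but its fixed-point map is non-contractive at arterial
Reynolds numbers), stabilized by a streamline-upwind (SU) artificial
diffusion term $\sum_K \tau_K \rho\, (w\cdot\nabla\phi_a)(w\cdot\nabla
\phi_b)$. SU adds diffusion only along streamlines; for developed tube
flow the streamwise velocity gradient vanishes, so the Poiseuille
solution is not polluted. The nonsymmetric saddle system is solved by
right-preconditioned GMRES with a block upper-triangular preconditioner:
the velocity block uses one sparse Cholesky factorization of the
(component-decoupled) symmetric viscous operator, reused across all
iterations, and the pressure Schur complement is approximated
SIMPLE-style by $C_p + W^\top \mathrm{diag}(A)^{-1} W$, which stays
effective on the anisotropic near-wall grading where the classical
pressure-mass scaling degrades. Momentum and continuity rows are scaled
to comparable weight in the residual norm ($\alpha = \mu/\bar h$), and
outlet tractions are applied relative to their area-weighted mean, with
the datum re-added to the reported pressure: both choices keep the
relative GMRES tolerance meaningful for the velocity-scale physics.

The nonlinear loop is Picard iteration with Aitken adaptive relaxation
(plain damping admits limit cycles on curved geometries) and an
inexact-Newton forcing term: the linear tolerance tightens proportionally
with the nonlinear residual (down from `tol_linear`, default $10^{-4}$),
otherwise linear-solver noise places a floor under the nonlinear
residual. Convergence is declared below `tol_nonlinear` (default
$10^{-6}$ relative change).

Steady solves (the default — the boundary data are cycle means) compute
the fixed point directly; this is algebraically the $\Delta t \to \infty$
limit of the implicit backward Euler map, and by uniqueness of the steady
laminar solution it agrees with time marching, which the test suite
verifies to $10^{-3}$. The transient path advances from zero initial
conditions by backward Euler at `dt` (default 0.01 s), with an optional
sinusoidal pulsatile inflow; the steady waveform is the validated
acceptance path.

Velocity gradients for the wall stress are recovered per wall-adjacent
element from the P1 basis (where they are constant) and pressures as face
means; nodal averaging was rejected because it smears across the
inlet/outlet cap creases. Faces within `cap_exclusion` (default 2) axial
spacings of the caps are excluded from regional means — the prescribed
inlet profile and outlet traction make the stress there a boundary
artifact.

## Anatomical labeling

Wall quadrants are defined by image planes, so an explicit axes
convention is required: the default `anatomical_axes()` is RAS-style (+y
ventral/anterior, +z superior) and is stored with every labeled dataset.
Faces are assigned by the angular position of their centroid around the
local centerline, against the anatomical directions projected into the
cross-sectional plane, in 45° sectors — two orthogonal half-plane splits
are exactly that for a vessel perpendicular to the image planes, and the
sector form keeps them consistent on oblique vessels. Trisection divides
the span from an origin to a branch arclength into three equal parts.
Curve sides use the sign of the face offset against the local curvature
direction, with sides undefined below a curvature threshold of 5 m⁻¹
(straight vessels are never labeled inner/outer; the threshold is half
the curvature of the gentlest arc the generator defaults produce).
A plaque annotation of 2–5 points is assigned by its arithmetic centroid
("central" read as centroid), snapped to the nearest wall face; a
centroid farther than one local lumen diameter from the wall is rejected
as a mislocated annotation.

## Registration

The model-to-image projection uses 0-based indices, the voxel-center
convention and nearest-neighbor rounding:
$\mathrm{index} = \lfloor (x - \mathrm{origin})/\mathrm{spacing} + 0.5
\rfloor$, with orientation signs carried in the transform. The in-house
conventions behind published projections are unpublished, so these are
fixed here and serialized with every output; round-trip error is bounded
by half a voxel by construction, and the test suite checks the bound on
random points. WSS deposition takes the area-weighted mean over faces
landing in one voxel and emits a validity mask for untouched voxels.

## Statistics

The agreement and comparison battery mirrors the analysis such studies
run: paired t, Welch or Student two-sample t (from summaries or raw
data; Welch is the default since the variant behind published age
comparisons is unstated, and both land in the same neighborhood there),
one-way ANOVA with Bonferroni-capped pairwise p-values (the correction
inferred from p-values printed as exactly 1.000), Fisher's exact test,
Cohen's κ and ICC. The ICC variant is fixed to ICC(2,1) — two-way random
effects, absolute agreement, single measurement — because the variant
behind published rater tables is unstated; the choice is recorded in the
function's output. κ and ICC above 0.75 are flagged excellent. Fisher's
exact test is delegated to the standard library implementation and is
cross-checked in the tests against an independent brute-force
hypergeometric enumeration over all tables with the observed margins;
ANOVA is cross-checked against a hand sum-of-squares decomposition, and
κ/ICC against simulations with designed ground truth (e.g. variance
components set for ICC = 0.8, recovered within ±0.05 at 500 subjects).

## Problem sizes and validation scope

The validation suite runs at desk scale on one CPU: the straight-tube
Poiseuille oracle uses a ~5 × 10⁴-cell mesh (r = 2 mm, L = 30 mm,
Re ≈ 100), where wall $|\mathrm{WSS}|$ must match $4\mu Q/\pi r^3$ and
the centerline velocity $2Q/\pi r^2$ within 5%; the curved-tube check
uses curve radius 12 mm, arc length 36 mm and Re ≈ 121, inside the
100–700 band of interest, with an arc long enough that the middle third
lies beyond the curved-entry crossover where the classical inviscid
inner-wall speedup gives way to the developed Dean pattern
(inner < outer). Mass conservation is checked as
$|\sum Q_{out} - Q_{in}|/Q_{in}$ from exact boundary-face integration;
because summing the discrete continuity equations telescopes to the
boundary flux, the residual is set by the linear tolerance, not by the
mesh. `scripts/acceptance.R` recomputes all of these quantities from
scratch against the installed package.

## Known limitations

Rigid walls (no fluid–structure interaction); Newtonian rheology;
single-inlet, single-outlet tube topologies (no circle-of-Willis
networks); steady validation path (the pulsatile mode exists but is not
oracle-validated); geometric phantoms rather than MR signal simulation;
and univariable statistics only. The quadrant convention for strongly
oblique vessels, and any bit-compatibility with unpublished in-house
projection routines, are fixed by this package's own declared
conventions.
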