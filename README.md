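# hemowss

Wall shear stress (WSS) — the tangential traction flowing blood exerts on
the vessel wall — shapes where atherosclerotic plaques form in the
middle cerebral artery (MCA) and other intracranial vessels. Studies that
relate plaque location on high-resolution vessel-wall MRI to hemodynamics
need a chain of machinery: a flow simulation with patient-style boundary
conditions, WSS extraction at the wall, anatomical labeling of the wall
into segments and quadrants, projection of the results back onto the
image grid, and a battery of regional-ratio and agreement statistics.
`hemowss` implements that chain as a tested, reusable R package, with a
synthetic vessel/phantom/measurement generator in place of patient data,
for researchers in vascular biomechanics and quantitative neuroimaging
who want the machinery reproducible and verifiable end to end.

## The model

Blood is an incompressible Newtonian fluid (ρ = 1.06×10³ kg/m³,
μ = 3.5×10⁻³ kg·m⁻¹·s⁻¹) obeying the Navier–Stokes equations

    ∂v/∂t + (v·∇)v = −(1/ρ)∇p + (μ/ρ)∇²v + f,   ∇·v = 0

on a tetrahedral mesh of the lumen, with a no-slip wall, a parabolic
inflow carrying Q_in = V_in·A_in (V_in from Doppler systolic/diastolic
velocities, A_in from the measured radius), and resistance outlets
P_out = R_out·Q_out with R_total = P_brachial/Q_in split Murray-style
across outlets. The discretization is equal-order P1/P1 finite elements
with PSPG/streamline-upwind stabilization; steady states are computed by
Aitken-relaxed Picard (Oseen) iteration with a preconditioned-GMRES inner
solver, and an implicit backward-Euler path (dt = 0.01 s) covers
transient and pulsatile inflow.

At the wall, the Cauchy stress σ = −pI + μ(∇v + ∇vᵀ) gives the WSS
vector as the tangential traction

    WSS = σn − (σn·n)n,

and regional means (area-weighted) feed two summary ratios:
`rWSS_VI-DS`, ventral+inferior over dorsal+superior wall WSS, and
`rWSS_inner-outer`, inner over outer wall of the vessel curve — in curved
tubes secondary (Dean) flow shifts high shear to the outer wall, so the
latter sits below one. Cohen's κ, ICC(2,1), Fisher's exact test, paired
and two-sample t, and Bonferroni-corrected one-way ANOVA cover the
agreement and group-comparison analyses, with κ/ICC > 0.75 flagged
excellent.

## Worked example

A curved MCA-like segment (lumen radius 2 mm, arc length 20 mm, curve
radius 12 mm) at Re = 60, with boundary conditions derived from a
synthetic ultrasound panel:

```r
library(hemowss)
cfg <- run_config(seed = 3, shape = "curved", length = 0.02,
                  target_edge = 9e-4, reynolds = 60)
s <- run_pipeline(cfg, out_dir = "run1")
```

prints (via the summary fields):

```
cells: 6468
Q_in: 6.224e-07 m^3/s  Q_out: 6.224e-07 m^3/s  (residual 2.4e-09)
R_total: 2.171e+10 Pa.s/m^3  P_out: 13513.7 Pa
mean WSS: 0.345 Pa
rWSS_VI-DS (middle): 0.936
rWSS_inner-outer (middle): 0.868
```

Reading these: the solve conserves mass to 2.4×10⁻⁹ (inflow equals
outflow); the outlet pressure equals R_total × Q_out exactly, i.e. the
resistance boundary condition holds at convergence; the mean wall shear
of 0.345 Pa is the area-weighted |WSS| over the wall away from the end
caps; and both ratios are below one — the inner wall of the curve and the
ventral+inferior walls carry less shear than their counterparts, the
spatial pattern these ratios are designed to quantify. `run1/` receives
the vessel surface (STL/PLY), the labeled mesh and solution (VTU,
ParaView-readable), the WSS and label surfaces, the voxel phantom and
projected WSS (NIfTI), the regional table (CSV) and a summary/manifest
(JSON) that is bit-identical across reruns of the same config.

Individual stages are exported on their own (`make_centerline`,
`make_vessel_surface`, `tetrahedralize`, `solve_flow`, `compute_wss`,
`wall_labels`, `project_wss_to_image`, `rwss_inner_outer`, ...), and a
thin CLI wrapper lives at `inst/scripts/hemowss`.

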