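---
title: "The biomorphoelastic post-burn scar model: methods and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The biomorphoelastic post-burn scar model: methods and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(scarfem)
```

## The model

`scarfem` simulates the first year of healing of a deep (burn) wound in a
two-dimensional cross-section of skin: x runs along the skin from the wound
center (a symmetry axis) into intact tissue, y through the dermal thickness.
Two coupled processes shape the outcome: *contraction* — myofibroblasts pull
the wound edge inward — and *hypertrophy* — the tissue over the wound
thickens into a raised scar.

Four biochemical species are transported and react on the moving tissue:
fibroblasts $N$, myofibroblasts $M$, a generic signaling molecule $c$
(PDGF/TGF-beta-like chemoattractant), and collagen $\rho$. Each obeys a
conservation law in material form,
$$\frac{DZ}{Dt} + z\,(\nabla\cdot v) = -\nabla\cdot J_z + R_z,$$
with cell fluxes $J_{N/M} = -D_n(N+M)\nabla z + \chi z \nabla c$
(density-dependent random motility plus chemotaxis), Fickian transport
$J_c = -D_c \nabla c$ for the signaling molecule, and no collagen transport.
The reactions encode logistic-type proliferation with a chemokine
enhancement and a crowding factor $\kappa$, chemokine-driven differentiation
of fibroblasts into myofibroblasts ($k_1 c N$), linear apoptosis, secretion
of signaling molecules and collagen by both cell types (myofibroblast
fractions $\eta^I$ in secretion, $\eta^{II}$ in MMP-mediated cleavage), and
MMP cleavage of $c$ and $\rho$ with the MMP pool at a local equilibrium so
that it never appears as a separate variable.

The mechanics couple in through a visco-elastic momentum balance
$$\rho_t\left(\frac{Dv}{Dt} + v\,(\nabla\cdot v)\right) = \nabla\cdot\sigma
  + \nabla\cdot\left(\frac{\xi M \rho}{R^2+\rho^2}\,I\right),$$
where the Cauchy stress combines shear/bulk viscosities $\mu_1,\mu_2$ acting
on $\mathrm{sym}(\nabla v)$ with a linear-elastic part whose stiffness
$E\sqrt{\rho}$ grows with the local collagen density. The body-force
potential $\psi = \xi M\rho/(R^2+\rho^2)$ is the traction myofibroblasts
exert on the matrix; it vanishes without myofibroblasts and is maximal at
$\rho = R$. Permanent deformation enters through morphoelasticity: the
effective Eulerian strain $\varepsilon$ (the part of the deformation that
still generates stress) evolves by
$$\frac{D\varepsilon}{Dt} + \varepsilon\,\mathrm{skw}(\nabla v)
 - \mathrm{skw}(\nabla v)\,\varepsilon
 + (\mathrm{tr}\,\varepsilon - 1)\,\mathrm{sym}(\nabla v)
 = -\zeta\,\frac{[N+\eta^{II}M]c}{1+a_c^{III}c}\,\varepsilon,$$
so strain is generated by flow and converted into permanent deformation at
the morphoelastic rate $\zeta$ wherever cells and signaling coexist.

## Parameters

All parameters live in a flat, validated set (`scar_params()`); the shipped
defaults (`inst/extdata/table1_defaults.json`, units cm/g/cells/day) are the
mean values of the validated hypertrophy and contraction models this model
descends from. Two parameters are *dependent* and always recomputed from
the intact-skin equilibrium $(N,M,c,\rho) = (\bar N, 0, 0, \bar\rho)$:

* the proliferation exponent
  $q = \ln\!\big(\delta_n/(r_n(1-\kappa \bar N))\big)/\ln \bar N \approx -0.42$, and
* the collagen secretion rate $k_\rho = \delta_\rho\,\bar\rho^2$.

`check_stability()` reports the constraint
$k_c \le \delta_c\,a_c^{II}\,\bar\rho$ under which the homeostatic
equilibrium cannot destabilize through signaling autocatalysis; the default
set satisfies it with ratio 0.71. Inside a fresh wound (low $\rho$) the same
balance is transiently *unstable*, which is what ignites healing: $c$ grows,
fibroblasts differentiate, and the myofibroblast ring contracts the wound
until collagen recovery shuts the loop down again. With the low apoptosis
rate $\delta_m = 0.02$/day myofibroblasts persist long enough to produce
pronounced hypertrophy; $\delta_m = 0.06$/day is the high-apoptosis
contrast.

The defaults were transcribed from the source models' parameter tables.
Two entries could not be pinned down unambiguously and were fixed, once, by
consistency with the model's own validity regime and printed behavior
rather than by fitting: the cell force constant $\xi = 0.0044$ (the
alternative reading makes the active stress tens of times the tissue
stiffness, driving $\mathrm{tr}\,\varepsilon < -1$ where the infinitesimal
morphoelastic law loses meaning within days), and the role assignment
$\eta^I = 0.5$, $\eta^{II} = 2$ (the swapped assignment makes wound
signaling a positive feedback that never shuts off, so the documented
late-time retraction of the wound edge could not occur at all).

## Geometry, initial state, observables

The domain is the half slab $[0, 10] \times [0, 0.15]$ cm (symmetry at
x = 0). The wound occupies $x < W$ with default half-width $W = 4$ cm —
chosen so that the documented 61.3% peak contraction corresponds to the
documented 1.55 cm minimum of the wound boundary — with a
$\sin^2$ ramp of width $s = 0.5$ cm at the edge ($C^1$ at both ends).
Initial densities are 20% of the equilibria for fibroblasts and collagen
inside the wound, $c = 10^{-8}$ g/cm³ there, and everything mechanical at
rest. A collagen-graft scenario raises the initial wound collagen fraction
(e.g. to 100% of $\bar\rho$).

Two observables summarize a run: the *central thickness* (the y-coordinate
of the free surface at the symmetry axis) and the *wound boundary* (the
material point initially at $(W, 0)$, advected along the bottom boundary
with the computed velocity). From their time series `extract_metrics()`
derives TH\_max, TH\_day, TH\_end, WB\_min, WB\_day, WB\_end and the peak
contraction percentage.

## Discretization

Linear Lagrangian triangles with Newton-Cotes (vertex) quadrature; all nine
nodal unknowns ($N, M, c, \rho, v_1, v_2, \varepsilon_{xx},
\varepsilon_{yy}, \varepsilon_{xy}$) are advanced monolithically by backward
Euler with inner Picard iterations (nonlinear coefficients frozen at the
iterate, at most 6 iterations, relative $L^2$ update tolerance $10^{-6}$
per field). Each Picard iteration solves one sparse direct system,
equilibrated by column scales (the characteristic field magnitudes) and row
2-norms because the nine fields span twelve orders of magnitude. At
convergence the iterate satisfies the fully nonlinear backward-Euler
equations; the linearization choices (implicit decay, source terms at the
iterate, differentiation and collagen-secretion coupled implicitly across
fields) only affect the iteration path.

The mesh is fully Lagrangian: nodes move with the converged velocity
(`advance_mesh()`), so convective terms vanish at the nodes while the
dilution term $z(\nabla\cdot v)$ remains. The essential conditions pin
$v_1 = 0$ on the lateral boundaries and $v_2 = 0$ on the bottom; the top
surface is free. The species hold their equilibrium values on the far
lateral boundary and are flux-free elsewhere.

The myofibroblast body force is integrated by parts, and the potential's
flux is retained on the free top surface. This surface load is what lifts
the tissue over the wound: without it the model produces monotone thinning
and no hypertrophy at all. Its price is that the unregularized free surface
can sharpen into single-column ridges; the remesher counters this (below).

Strain unknowns are collocated at the nodes; the velocity gradients they
need are recovered by lumped $L^2$ projection, which keeps the
strain-velocity coupling linear inside the monolithic matrix and preserves
the symmetry of $\varepsilon$ exactly.

## Meshing, remeshing, time stepping

The mesh is a structured graded triangulation of
$\{0 \le x \le 10,\ 0 \le y \le h(x)\}$: an x-grid with a refinement band
(default spacing 0.15 cm) that follows the wound edge, spacing elsewhere
0.30 cm, modulated by $1/h(x)$ so element areas stay near-uniform as the
profile thickens, three element layers through the thickness, each quad
split into two triangles. Mesh quality is the ratio of smallest to largest
element area; remeshing triggers when it falls below
$\min(0.5,\ 0.7\times\text{birth quality})$ — the second term acknowledges
that a sharply ridged free surface can cap the best achievable structured
quality below the nominal 0.5. Remeshing rebuilds the grid on the deformed
domain (the resampled top curve gets one clip-only 1-2-1 smoothing pass,
which shaves single-column ridges and never raises the surface) and
transfers all fields by barycentric interpolation; nodes that fall in
pockets of a locally sheared source mesh take the nearest node's value.

Time stepping follows a convergence-based controller: initial step 0.05
day, capped at 0.05 day for the first half day and 0.5 day after; growth by
1.1 per converged step; shrink to 80% on Picard non-convergence; after a
remesh, a failed step rewinds one accepted step at half the step size, and
a second consecutive failure rewinds five accepted steps and halves again.
Past the thickness peak, convergence within two iterations boosts the
maximal step by 10% (compounding, capped at twice the phase-2 maximum).
The final step is clipped to land exactly on day 365, as is the phase
boundary at half a day.

Negative densities are monitored, never clamped: the solver aborts with
diagnostics if any density undershoots beyond 5% of its characteristic
scale. Mild undershoot near the steep wound edge is ordinary for linear
elements without limiters and diffuses away.

## Sensitivity pipeline

`variation_plan()` enumerates the one-at-a-time sweep: 30 of the 35
parameters (the dependent $q$ and $k_\rho$, the Poisson ratio, and the two
initial fractions tied to the equilibria stay fixed), each scaled by
$\pm\{5, 10, 15\}\%$, with $q$ and $k_\rho$ re-solved per set and the
stability constraint re-checked — 6 x 30 variations plus one control per
apoptosis level, 362 runs in all. `run_sweep()` executes and caches runs
(resumable; failures logged and excluded), `compute_z_scores()`
standardizes each outcome within each signed-variation group across the
varied parameters, and `sensitivity_scores()` sums absolute z-scores over
variations and the three thickness outcomes into the per-parameter score
and ranking. `contraction_hypertrophy_report()` emits the per-run point
pairs that relate peak contraction to peak thickness. The `runner` argument
of `run_sweep()` is injectable, so the pipeline's statistics are testable
with inexpensive surrogate dynamics; a full 181-run PDE sweep per apoptosis
level is a batch job of several hours on one CPU.

## Verification and problem sizes

The test suite exercises, at the default resolution (41 x 4 node initial
grid, 276 nodes after the wound-edge band refinement): an intact-skin year
that must hold the homeostatic equilibrium to $10^{-4}$; the closed-form
exponential decay of the effective strain under frozen chemistry, with
first-order-in-step error that halves when the step halves; the equilibrium
identities of the dependent parameters across all 180 varied sets; the
full low-apoptosis control year against the documented trajectory (peak
contraction 61.3% at a 1.55 cm wound boundary, 0.396 cm central thickness
at that time, 0.176 cm and 3.48 cm on day 365) within 5% — the resolution
and tolerance settings of the reference computation are not documented, so
agreement is asserted at that level rather than to print precision; the
published between-run differences for the high-apoptosis and collagen-graft
variants (propagating the same 5% through the differences); the z-score
bookkeeping of a reduced sweep; the near-coincidence (within 3 days) of
maximal contraction and maximal thickness; and a quasi-1D strip on which
the chemical subsystem must match an independent vertex-centered
finite-volume method-of-lines discretization (integrated by `deSolve`)
within 1% of each field scale.

## Known limitations

* The morphoelastic law is infinitesimal-strain; the simulated deformations
  (60% contraction, 2.5-fold thickening) sit at the edge of its validity,
  and the post-peak thickness decline is accordingly fast.
* In this reconstruction the thickness/contraction peak falls near day 45
  rather than day 63; the peak *values* and the day-365 state agree with
  the documented trajectory, but the mechanical timescale (set by the
  viscosities and the morphoelastic rate, whose sources are second-hand)
  carries that uncertainty.
* The free surface has no bending or tension regularization; very sharp
  hypertrophic ridges are handled by remeshing plus clip-only boundary
  smoothing, which bounds but does not eliminate the associated
  interpolation error.
* Element areas, not shapes, drive the remeshing criterion; strongly
  sheared but equal-area meshes are only caught indirectly.
* No angiogenesis, no anisotropic fiber mechanics, no 3D.
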