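# scarfem

Moving-mesh finite-element simulation of post-burn scar **contraction** and
**hypertrophy** in a two-dimensional cross-section of skin, with a z-score
parameter-sensitivity pipeline over the hypertrophy outcomes. It is aimed at
mechanobiology and wound-healing modelers who want a self-contained,
scriptable implementation of the biomorphoelastic continuum model of dermal
scarring.

## The model

Four biochemical fields — fibroblasts `N`, myofibroblasts `M`, a generic
signaling molecule `c`, and collagen `rho` — obey conservation laws on the
deforming tissue,

    Dz/Dt + z (div v) = -div J_z + R_z,

with density-dependent diffusion plus chemotaxis for the cells,
`J = -D_n (N+M) grad z + chi z grad c`, Fickian transport for `c`, and no
collagen transport. The kinetics include chemokine-enhanced logistic
proliferation, differentiation `k_1 c N` of fibroblasts into
myofibroblasts, apoptosis, secretion, and MMP-mediated cleavage with the
MMP pool at local equilibrium. The mechanics solve the visco-elastic
momentum balance

    rho_t (Dv/Dt + v div v) = div sigma + div( xi M rho / (R^2 + rho^2) I ),

where `sigma` carries shear/bulk viscosities and a linear-elastic stress
with collagen-dependent stiffness `E sqrt(rho)`, and the myofibroblast
traction potential drives both the inward pull on the wound edge and the
lifting of the free surface. Permanent deformation is morphoelastic: the
effective Eulerian strain evolves by

    De/Dt + e skw(grad v) - skw(grad v) e + (tr e - 1) sym(grad v)
      = -zeta [N + eta_II M] c / (1 + a_cIII c) e,

so elastic strain converts into permanent contracture at rate `zeta`.

Numerics: linear triangles with vertex (Newton-Cotes) quadrature, one
monolithic backward-Euler system per step over all nine nodal unknowns,
Picard iteration, a fully Lagrangian moving mesh with area-ratio
quality-driven remeshing and barycentric field transfer, and a
convergence-based adaptive timestep controller. See the methods vignette
(`vignettes/biomorphoelastic-model.Rmd`) for the discretization and all
numerical choices.

## Worked example

The control run — mean parameters, low myofibroblast apoptosis
(`delta_m = 0.02`/day), a 4 cm half-width wound in a 10 x 0.15 cm slab —
takes about two minutes:

```r
library(scarfem)
params <- scar_params(delta_m = 0.02)
spec <- domain_spec()
sim <- run_simulation(params, spec, solver_config())
print(sim)
#> <scar_sim> 1106 accepted steps to day 365.0
#>   thickness: start 0.1500, max 0.3821 (day 46.3), end 0.1695 cm
#>   wound boundary: start 4.0000, min 1.5438 (day 44.7), end 3.5199 cm
extract_metrics(sim, spec)
```

Reading: the wound edge, initially at 4 cm, is pulled in to 1.54 cm —
a peak contraction of 61.4% — while the tissue at the wound center
thickens from 0.15 cm to a hypertrophic maximum of 0.38 cm at nearly the
same time (the gap between the two peaks is under two days). Afterwards
the myofibroblasts die off, the signaling decays, and the scar partially
resolves: by day 365 the thickness is back to 0.17 cm and the wound edge
has retracted to 3.52 cm. Raising apoptosis to `delta_m = 0.06`/day
roughly halves the peak hypertrophy; starting the wound at 100% instead of
20% of the equilibrium collagen density (a graft scenario,
`collagen_fraction = 1.0`) lowers the peak by ~0.13 cm.

The one-at-a-time sensitivity sweep is driven by `variation_plan()` /
`run_sweep()`, which cache completed runs and assemble the per-parameter
z-score tables and rankings (`compute_z_scores()`,
`sensitivity_scores()`). A thin command-line wrapper for runs, sweeps and
metric extraction is installed at `inst/cli/scarfem.R`.

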