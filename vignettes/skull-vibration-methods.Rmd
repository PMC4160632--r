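---
title: "Simulating bone-conduction skull vibration: model, surrogate and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating bone-conduction skull vibration: model, surrogate and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical problem

In bone-conduction (BC) hearing, a force applied to the skull — by a
bone-anchored hearing aid, a vibrating transducer pressed behind the ear, or
one's own voice — sets the whole cranium into vibration, and it is the
motion of the temporal bone around the cochlea, not ear-canal sound, that
stimulates the inner ear. Classic bench experiments use a *dry skull*: a
defleshed cranium, suspended freely, with a few hundred grams of
polyurethane poured inside to restore a realistic amount of damping. Two
quantities summarise the mechanics:

* the **mechanical point impedance** `Zm = F / v`, the complex ratio of the
  applied force to the velocity of the driving point, which tells a
  transducer designer what load the skull presents; and
* the **acceleration of the cochlear bone**, ipsilateral and contralateral
  to the stimulation site, per newton of drive, which tells a hearing
  scientist how much vibration actually arrives at each inner ear.

`vibroskull` is a self-contained harmonic finite-element engine for this
class of problem: viscoelastic solids meshed with 4-node tetrahedra, driven
by a point force over a frequency grid, with no supports (free-free).

## Governing equations

The steady-state equation of motion at angular frequency `w = 2 pi f` is

    K(f) x - w^2 M x = F

with `M` the consistent mass matrix, `x` the complex nodal displacement
vector and `F` the nodal force vector. Damping is hysteretic and enters
exclusively through the stiffness: each material has a complex Young's
modulus

    E(f) = E1 (1 + i eta(f)),

whose real (storage) part sets the stiffness and whose imaginary (loss)
part `E2 = E1 eta` dissipates energy. Because the isotropic constitutive
matrix is proportional to E, the global stiffness splits as
`K(f) = K1 + i K2(f)` with `K2(f) = sum_r eta_r(f) K_r`, a sum of the
per-region elastic stiffnesses weighted by their loss factors. There is no
viscous damping matrix and no `C x'` term.

Two loss-factor laws are provided:

* **constant** — used for cranial bone, `eta = 0.01`;
* **linear in frequency** — used for the polyurethane lining,
  `eta(f) = alpha_f f`, calibrated so that `eta(1 kHz) = 0.1` and hence
  0.01 at 100 Hz and 1 at 10 kHz. The law is parameterised on ordinary
  frequency: the calibration points are given at ordinary frequencies, so a
  radian-frequency slope would only rescale `alpha_f` without changing any
  prediction.

The storage modulus is taken frequency-independent: one value per material
is all the experimental record provides.

Default materials (`material_preset("stenfelt2002_dry_skull")`):

| region       | E1 (Pa) | nu   | rho (kg/m^3) | loss          |
|--------------|---------|------|--------------|---------------|
| bone         | 7.3e9   | 0.30 | 870.23       | 0.01 constant |
| polyurethane | 1e6     | 0.33 | 997.40       | 0.1 at 1 kHz, linear |

## Elements and assembly

The 4-node tetrahedron has constant strain, so the element stiffness
`Ke = V B' D B` is exact with one-point integration; the element mass is
the standard consistent matrix (`rho V / 10` diagonal, `rho V / 20`
off-diagonal blocks per axis; a row-sum lumped option exists for rigid-body
checks). `D` is the isotropic elasticity matrix in Voigt order
(exx, eyy, ezz, gyz, gxz, gxy) with engineering shear strains; its Lamé
form means a complex E simply scales it. Elements are reoriented to
positive signed volume on construction, and assembly is a standard
symmetric scatter-add into sparse matrices, kept per region so `K2(f)` can
be formed at any frequency without re-assembly.

No essential boundary conditions are applied: the experimental skulls hang
freely, so the stiffness matrix has exactly six rigid-body modes (verified
in the tests by dense eigendecomposition on small meshes).

## The synthetic skull surrogate

The original geometry behind this class of model comes from segmented
cryosection images; no such data ships with a desk-scale package. The
surrogate instead emulates what the preparation *is mechanically*: a closed
bone shell of total mass 470 g lined on the inside with a polyurethane
layer of mass 340 g and nominal thickness about 5 mm, with a
retro-auricular stimulation site and mirror-symmetric cochlear probe
patches.

Geometry: two concentric spherical shells (bone outside, lining inside,
hollow core), built by subdividing an icosahedron `L` times, projecting to
the sphere, radially extruding the surface into prism layers and splitting
every prism into three tetrahedra with index-ordered diagonals, which makes
neighbouring prisms conform and the mesh watertight. The default outer
radius is 80 mm — in the middle of the adult range of half-breadths — and
with the Table-of-materials densities the calibrated shell comes out about
6.8 mm (bone) and 5.2 mm (lining) thick, both anatomically sensible.

Mass calibration is analytic. A radially extruded layer of the faceted
sphere between radii `r` and `R` has volume `c(L) * (4/3) pi (R^3 - r^3)`
*exactly*, where `c(L)` is the faceted-to-true volume ratio of the unit
icosphere (the prisms are frusta of the cone decomposition). Solving for
the two inner radii therefore hits the target masses to round-off; the
tests assert the 1 % contract with margin. The same factor explains the
monotone volume convergence across refinement levels (the deficit shrinks
about fourfold per level).

Probe geometry: the stimulation node sits on the outer surface at azimuth
0 in the x–y plane (x is the medial-lateral axis; the drive is applied in
+x, the medial direction). The ipsilateral probe patch is centred 25
degrees away along the same plane — a great-circle distance of about 35 mm,
matching the classic "35 mm behind the ear-canal opening" stimulation
layout — and the contralateral patch is its exact mirror image through the
mid-sagittal plane (the icosphere vertex set is symmetric under negation of
any axis, so the mirroring is exact). Probe accelerations average the
complex displacement over the patch, reflecting the assumption that nodes
within a few millimetres of each other move alike; a patch-versus-centre
test quantifies this below the first elastic mode. The force is applied at
a single node by default (the experimental footprint was ~3 mm; a
node-patch load option splits the force equally over a node set).

## Solver numerics

Each frequency requires one solve of the complex symmetric system
`(K1 + i K2(f) - w^2 M) x = F`. The package factorises it directly with a
complex sparse LU (Eigen's SparseLU with COLAMD ordering, wrapped in a
small compiled routine), after a symmetric diagonal equilibration
`D Z D, D = diag(1/sqrt(|Z_ii|))`. The equilibration matters: bone and
lining moduli differ by nearly four orders of magnitude, and without it
numerical pivoting abandons the fill-reducing ordering and factorisation
cost explodes. Scale factors are clamped at `1e-8` of the largest diagonal
so that a diagonal entry passing through zero near a resonance cannot blow
up the scaling. Each solve finishes with up to three steps of iterative
refinement.

Every solve is verified against the residual contract
`||(K - w^2 M) x - F|| / ||F|| < 1e-9`; a breach is an error naming the
frequency, not a warning. On the default 0.1–10 kHz band measured
residuals are around 1e-11. One finite-precision caveat: far below the
first elastic mode the free-free matrix is dominated by its six near-null
rigid modes and the attainable residual is floored at about
`eps * ||K|| / (w^2 m)` — at 2 Hz this floor is ~4e-8 and *no* double
precision solver can do better, which is why the package's low-frequency
property checks (mass-line impedance, rigid translation) run at 30–70 Hz,
still a decade below the first elastic resonance.

Singular systems are only possible at exactly zero damping on a resonance;
they surface as a factorisation error naming the frequency.

## Derived spectra

* **Impedance**: `v = i w x` at the drive node projected on the drive
  direction; `Zm = F / v`. Levels are `20 log10 |Zm|` dB re 1 N·s/m (the
  natural reading of "dB N·s/m"; 82 dB corresponds to 12 589 N·s/m).
  Below the first elastic mode `|Zm|` follows the rigid mass line
  `2 pi f m_total`; a structural resonance is a local *minimum*.
* **Acceleration**: `a = -w^2 x_bar` per newton, with `x_bar` the patch
  average, reported per axis in dB re 1 (m/s²)/N. The acceleration figure
  normalisation of the original experiments is not stated, so absolute
  comparisons to those plots are out of scope; shapes, resonance positions
  and phase slopes are in scope.
* **Phase and group delay**: phases are kept in cycles; unwrapping maps the
  first point into (-0.5, 0.5] and wraps successive steps into the same
  interval, valid while true inter-point jumps stay below half a cycle (60
  log-spaced points over two decades satisfy this for the shipped
  scenarios). Group delay is `-(1/2pi) d phi/d f` with phi in radians —
  with phase in cycles simply `-d phase/d f` — evaluated by central
  differences (one-sided at the ends), which are exact for the linear and
  quadratic phase laws used as test oracles.
* **Extrema**: local extrema of the dB level versus log10 frequency,
  refined by a parabola through the extremum and its neighbours (the
  natural coordinates for resonance peaks); plateau ties break toward the
  lower frequency. For impedance, minima are resonances; for transfer
  accelerations the labels invert.

## The scenario campaign and its variants

`scenario_preset("stenfelt2002_dry_skull")` reproduces the classic
parametric study on the surrogate: a calibrated baseline plus seven
variants — lining storage modulus ×100 and /100, lining loss modulus ×100
and /100, lining density 99.740 kg/m³ (a 34 g lining), ×10, and
8800 kg/m³ (the *heavy-head* case, bringing bone plus lining to 3.47 kg,
the mass of an intact cadaver head). Outputs per run: `impedance.csv`,
`accel_ipsi.csv`, `accel_contra.csv`, an extrema report, optional legacy
VTK displacement fields (default 100 Hz and 600 Hz at phases 0° and 180°,
baseline run only unless requested for all), and a YAML manifest with every
resolved parameter. Runs are deterministic: identical configs give
byte-identical CSVs.

Two design points deserve explanation:

* **Modulus variants are constant complex moduli.** The published study
  describes its modulus sweep as complex constants ({1e8+1e4i},
  {1e4+1e4i}, {1e6+1e6i}, {1e6+1e2i} around a "normal" {1e6+1e4i}), while
  the baseline lining uses the frequency-linear loss law. Scaling the
  *law* by 100 instead would give `eta(1 kHz) = 10` — far beyond critical
  damping for every lining-coupled mode, a regime the published sweep never
  entered. The preset therefore implements the variants exactly as complex
  constants (`E1` plus a constant loss factor).
* **Damping moves levels, not structural resonance frequencies — tested at
  the persistent resonance.** On a sphere the *first* impedance dip is the
  compressional thickness resonance of the soft lining itself (roughly
  `c/4t` with `c = sqrt(E1/rho)` ≈ 32 m/s, i.e. near 1 kHz); heavy lining
  damping legitimately wipes that dip out, because the dip *is* the damped
  component. The damping-invariance property holds for resonances of the
  bone structure, so the acceptance test matches resonances between the
  two damping extremes by nearest frequency and asserts that a common
  structural resonance stays within 2 % while its level shifts. A real
  skull's published impedance shows no lining thickness mode — its
  geometry is far from spherically symmetric — which is the main caveat
  when reading surrogate spectra as skull spectra.

## Problem sizes

The shipped preset uses refinement level 3 with 3 + 2 radial layers
(19 200 tets, 3 852 nodes, 11 556 dofs) and 60 frequencies. The test suite
runs its sweep-based physics checks on the level-2 surrogate (3 840 tets,
2 430 dofs), where a 60-point sweep takes tens of seconds on a single
core, and its mesh/mass checks on the level-3 surrogate; eigendecomposition
checks use level 1, where dense `eigen()` is exact and fast. These sizes
are the package's choices for routine verification; all contracts
(volumes, masses, residuals, reciprocity) are formulated
size-independently. A full level-3 campaign (8 runs × 60 frequencies at
~6 s per factorisation) is a batch job of the order of an hour on one core;
the level-2 campaign covers the same physics in a few minutes.

## Known limitations

* The surrogate is a sphere: correct total masses, layer thicknesses,
  probe layout and material laws, but none of the real skull's flexural
  compliance (orbits, foramina, vault curvature variation). Its in-band
  mode inventory is lining-dominated; absolute resonance frequencies and
  levels are not comparable to skull measurements, only the parametric
  trends are.
* Linear tetrahedra are stiff in bending; resonance frequencies converge
  from above with refinement.
* Middle-ear and cochlear mechanics, and the five classical BC
  contributors, are outside the model: it ends at the vibration of the
  bone surrounding the cochlea.
* Only isotropic, temperature-independent materials with constant storage
  modulus; no poroelasticity, no measured master curves.
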