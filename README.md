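# vibroskull

Harmonic finite-element simulation of skull vibration for bone-conduction
(BC) hearing research.

When the skull is driven by a point force — a bone-anchored hearing aid, a
transducer pressed behind the ear — the quantities that characterise the
mechanics are the **mechanical point impedance** at the stimulation site,

    Zm = F / v        (force over driving-point velocity, N·s/m),

and the **acceleration of the cochlear bone** per unit force, on the
ipsilateral and contralateral sides. `vibroskull` computes both from first
principles: it assembles consistent mass and complex viscoelastic stiffness
matrices over a 4-node tetrahedral mesh and solves the free-free forced
response

    K(f)·x − (2πf)²·M·x = F,      K(f) = K1 + i·K2(f)

at each frequency of a grid by direct complex sparse factorisation. Damping
is hysteretic: every material carries a complex Young's modulus
`E(f) = E1·(1 + i·η(f))` with either a constant loss factor η (cranial
bone, η = 0.01) or one linear in frequency (polyurethane lining, η = 0.1
at 1 kHz). Post-processing yields impedance and acceleration spectra in dB,
unwrapped phase in cycles, group delay `τgd = −(1/2π)·dφ/df`, and
resonance/antiresonance detection with parabolic refinement.

Because the image-based geometry of a real cranium is not reproducible at
desk scale, the package ships a **synthetic two-layer skull surrogate**: a
closed spherical bone shell (470 g) lined internally with ~5 mm of
polyurethane (340 g), mass-calibrated analytically against the component
densities, with a retro-auricular stimulation node and mirror-symmetric
cochlear probe patches ~35 mm away. Any external Gmsh MSH (ASCII v2.2)
tetrahedral mesh with region labels can be used instead; displacement
fields export as legacy VTK.

## Worked example

```r
library(vibroskull)

spec <- calibrate_masses(
  shell_spec(refinement_level = 2, layers_bone = 2, layers_lining = 2),
  c(bone = 870.23, polyurethane = 997.40))
mesh <- generate_shell(spec)
mesh
#> <tet4_mesh> 810 nodes, 3840 tet4 elements
#>   regions: bone (1920), polyurethane (1920)
#>   node sets: stim_site (1), ipsi_cochlea (1), contra_cochlea (1)

sys <- assemble_system(mesh, material_preset("stenfelt2002_dry_skull"))
c(bone_g = 1000 * total_mass(sys, "bone"),
  lining_g = 1000 * total_mass(sys, "polyurethane"))
#>   bone_g lining_g
#>      470      340

load <- point_load(mesh, node_set = "stim_site", direction = c(1, 0, 0))
sol  <- solve_sweep(sys, load, frequency_grid(60))   # 0.1-10 kHz, log-spaced
imp  <- point_impedance(sol)
glance(imp)
#> # A tibble: 1 × 6
#>   n_freq f_min  f_max f_resonance level_at_resonance_db n_extrema
#>    <int> <dbl>  <dbl>       <dbl>                 <dbl>     <int>
#> 1     60   100 10000.       1052.                  67.7         9
```

The mass calibration is exact (bone 470 g, lining 340 g), and the first
impedance minimum — the first resonance of this spherical surrogate — sits
near 1.05 kHz at 67.7 dB re 1 N·s/m. `find_extrema(imp)` lists all nine
resonances/antiresonances in the band; `autoplot(imp)` draws the spectrum.
Probe spectra chain the same way:

```r
acc <- probe_acceleration(sol, "ipsi_cochlea")
tr  <- group_delay(unwrap_phase(acc$f_hz[acc$axis == "x"],
                                acc$phase_cycles[acc$axis == "x"]))
```

The full parametric campaign of the classic dry-skull study — baseline plus
lining-modulus ×100//100 (real and imaginary part), lining density 34 g /
×10 / heavy-head (8800 kg/m³, total 3.47 kg) — runs from one call or from
the shell:

```r
run_scenario(scenario_preset("stenfelt2002_dry_skull"), "out/")
```

```sh
exec/vibroskull run inst/extdata/stenfelt2002_dry_skull.yaml --outdir out/
```

Each run writes `impedance.csv`, `accel_ipsi.csv`, `accel_contra.csv`, an
extrema report, VTK displacement fields (100/600 Hz at phases 0°/180°) and
a YAML manifest; identical configs give byte-identical numbers. The
methods vignette (`vignettes/skull-vibration-methods.Rmd`) documents the
model, the surrogate's construction and calibration, the solver numerics
and the known limitations.

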