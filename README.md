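# helixvessel

Desk-scale biomechanics of decellularized vascular scaffolds externally
reinforced with extruded polymer helices.

## The problem

Decellularized xenogenic arteries are promising substrates for
small-diameter (< 6 mm) vascular grafts, but decellularization weakens the
wall: locally thin regions can dilate into aneurysms under ordinary blood
pressure, and this is the main failure mode of such grafts in practice.
One countermeasure is to wind a double helix of extruded thermoplastic —
non-degradable PVDF or biodegradable PCL — onto the scaffold's outer
surface. A coil is axially soft but circumferentially stiff, so it should
multiply radial (hoop) stiffness and suppress bulging while leaving
longitudinal behaviour essentially unchanged.

`helixvessel` simulates that mechanism end to end for three comparison
arms sharing one biological geometry: unreinforced **control**, **PVDF**
(E = 458 MPa, pitch 2.25 mm, thread 0.33 mm) and **PCL** (E = 321 MPa,
pitch 2.15 mm, thread 0.30 mm), each a 5 mm-ID tube with a 0.5 mm wall
containing one thin patch (0.06 mm) that activates the damage mechanism.

## The model in brief

* **Wall law** (damage-coupled elastoplasticity): linear elastic with
  E₀ = 1 MPa up to the yield strain ε_y = 0.6 mm/mm; beyond it plastic
  strain accumulates monotonically, PE ← max(PE, ε − ε_y), and the modulus
  degrades as f = max(0.1, 1 − (1 − 0.1)·PE/PE_ref), i.e. from 100% down
  to a 10% floor; stress is σ = f·E₀·(ε − PE). Below yield everything is
  reversible.
* **Pressure solver**: reduced thin-shell equilibrium in the radial
  displacement w(z, φ) — hoop membrane (t·σ(ε), ε = w/r) plus homogenized
  helix hoop stiffness E_p·A·cos²α·n_layers/pitch (≈ 34 N/mm for PVDF vs
  E₀·t = 0.5 N/mm for the wall), bending, and the von Kármán axial
  membrane-stretch term that saturates a growing bulge. A uniform tube
  reproduces the Laplace closed form ε = p·r/(t·E) to better than 1%.
* **Cyclic growth**: 150 load/unload cycles of 80–120 mmHg
  (0.011–0.016 MPa); per cycle, a pressure solve at systole, a
  plasticity/damage update from the peak hoop strain, and an unload whose
  residual radial displacement is PE·r per element.
* **Virtual bench**: compliance across the hypo-/normo-/hypertensive
  ranges (50–90 / 80–120 / 110–150 mmHg), longitudinal tension
  (annular bar + coil spring), transverse ring tension (planar beam FE,
  checked against δ = F·R³/(EI)·(π/4 − 2/π)), a 30% force-drop stop
  criterion, and odd-polynomial (σ = a₁ε + a₃ε³) fits of J-shaped curves.

See the vignette (`vignettes/reinforced-scaffold-model.Rmd`) for the full
account of assumptions, calibrations and limitations.

## Worked example

```r
library(helixvessel)

mc <- build_scaffold("control")
mp <- build_scaffold("pvdf")
mp
#> scaffold_model: ID 5 mm, L 60 mm, wall 0.06-0.5 mm, PVDF 2-layer helix (pitch 2.25 mm, thread 0.33 mm, E 458 MPa)

run_cycles(mc, pressure_protocol(n_cycles = 150))
#> growth_trace: 150 cycle(s), 0.011-0.016 MPa
#>   final: residual U1 6.091 mm, min f 0.1, max PE 2.215
#>   flag: model validity exceeded

run_cycles(mp, pressure_protocol(n_cycles = 150))
#> growth_trace: 150 cycle(s), 0.011-0.016 MPa
#>   final: residual U1 0 mm, min f 1, max PE 0
```

The unreinforced wall yields at its thin patch on the first cycle and its
modulus degrades to the 10% floor (`min f 0.1`), growing a permanent bulge
(the saturated magnitude is an artifact of the deliberately extreme
synthetic patch, hence the validity flag — see the vignette). The PVDF
helix holds peak hoop strain near 0.1%, so the same wall never yields:
no modulus loss, no residual bulge. PCL behaves the same with a slightly
larger loaded diameter (lower polymer modulus).

The virtual bench shows the anisotropy the reinforcement is designed for:

```r
compliance_test(build_scaffold("control", with_patch = FALSE), "normo")
#> compliance_result [normo]: 6.3025 -> 6.4400 mm, compliance 2.18%

rc <- tension_test(build_scaffold("control", length = 15, with_patch = FALSE),
                   "transverse", max_strain = 0.3, n_steps = 150)
rp <- tension_test(build_scaffold("pvdf", length = 15, with_patch = FALSE),
                   "transverse", max_strain = 0.3, n_steps = 150)
stiffness_ratio(rp, rc)
#> [1] 24.27168
```

Compliance stays on the few-percent physiological scale while transverse
(radial) stiffness is multiplied — PVDF more than PCL (ratio 24.3 vs 12.7
on the homogenized model).

A command-line front end wraps the same pipeline:

```sh
Rscript inst/exec/helixvessel growth --scenario pvdf --cycles 150 --out out/
Rscript inst/exec/helixvessel compliance --scenario pvdf --range normo --out out/
```

Every run writes its resolved configuration (seed included) next to its
outputs.

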