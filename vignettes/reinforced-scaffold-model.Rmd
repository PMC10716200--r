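---
title: "Modelling aneurysm protection by external helix reinforcement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling aneurysm protection by external helix reinforcement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixvessel)
```

## The problem

Decellularized xenogenic arteries are attractive substrates for
small-diameter (< 6 mm) vascular grafts, but decellularization weakens the
wall, and localized thin regions can dilate into aneurysms under ordinary
arterial pressure. One proposed remedy is to wind an external double helix
of extruded thermoplastic (non-degradable PVDF, or biodegradable PCL) onto
the scaffold: the helix should multiply radial (hoop) stiffness — resisting
bulging — while leaving longitudinal behaviour and physiological compliance
nearly unchanged, because a coil is axially soft and only "embraces" the
wall.

`helixvessel` is a desk-scale simulator of that mechanism. It deliberately
replaces the original workflow's micro-CT tetrahedral meshes and commercial
FE contact models with an idealized cylindrical shell, a homogenized
reinforcement description, and closed-form-validated reduced solvers, so
that the full three-arm comparison (control / PVDF / PCL) runs in seconds
on one CPU and every mechanical ingredient is testable against an
independent oracle.

## Geometry

A specimen is a tube of inner diameter 5 mm, length 60 mm (15 mm for
transverse ring tests), and base wall thickness 0.5 mm, discretized as a
structured `n_axial x n_circ` grid on the wall mid-surface (default 60 x 32;
elements ~1 mm x 0.54 mm). The wall thickness of the physical scaffolds was
never reported; 0.5 mm is this package's assumption and is config-exposed.

Real scaffolds have uneven walls. Two generators emulate that:

* **thin patches** — smooth local thinning to `min_thickness` with a
  flat-bottomed cosine taper (the `transition` exponent sharpens the taper
  towards the edge), representing the "regions of minor thickness" where
  aneurysmal change localizes;
* **correlated thickness noise** — a seeded Gaussian random field
  (separable Gaussian-kernel smoothing of white noise, periodic around the
  circumference), off by default in the presets.

The helix is a polyline on the winding radius (outer surface + half thread
diameter). Layer 1 advances +z at the measured pitch; layer 2 returns with
opposite angular slope and a half-turn phase offset, so the layers cross in
the lattice seen on the physical scaffolds. Fusion at crossings is
represented purely as shared coverage — no joint mechanics. Coverage
assigns each polyline segment's length, by midpoint, to the element whose
(z, phi) footprint contains it; summed coverage equals path length to
numerical precision, the invariant the homogenized stiffness rests on.

Preset parameters are the measured medians: pitch 2.25 mm / thread 0.33 mm
(PVDF), 2.15 mm / 0.30 mm (PCL), two layers, moduli 458 and 321 MPa as
extruded. Pitch jitter emulating winding irregularity is available but off
by default.

## Wall constitutive law

The biological wall is linear elastic with initial modulus `E0 = 1` MPa up
to a strain-based yield limit `eps_y = 0.6` mm/mm. Beyond yield, two
coupled irreversible processes start, the standard reduced picture of
aneurysmal degeneration (elastin loss plus permanent set):

* plastic strain accumulates monotonically,
  `PE <- max(PE, eps - eps_y)` — no reverse plasticity, appropriate for
  repeated same-sign pressure cycling;
* the elastic modulus degrades with accumulated plastic strain through the
  damage factor `f = max(floor, 1 - (1 - floor) * PE / PE_ref)`, a linear
  ramp from 100% down to the `floor = 0.1` fraction.

Stress is `sigma = f * E0 * (eps - PE)`. Below yield the response is
exactly linear and the state untouched, so a sound wall cycles elastically
forever. The ramp shape is this package's calibration decision (only the
endpoints, trigger, and floor of the degradation are prescribed by the
source data); `PE_ref = 0.0055` mm/mm places the floor at the plastic
strain level observed in the most damaged wall regions (0.55%). All four
numbers are config-exposed.

Two deliberate simplifications are worth flagging. First, there is no
post-yield hardening: the modulus collapse past yield makes the virtual
longitudinal tension curve drop sharply just beyond `eps_y`, which the
30%-force-drop stop criterion registers as the rupture analogue. Real
collagenous tissue stiffens (J-shape) before rupturing, so absolute
post-yield magnitudes are not meaningful here — only comparisons are.
Second, the yield measure is the scalar hoop strain, consistent with the
pressure-dominated loading; reported "plastic strain" is that scalar, not
a principal-strain tensor measure.

The polymers are purely linear elastic (no plasticity, no degradation).

For compliance studies below yield, the wall can instead carry an odd
polynomial law `sigma = a1*eps + a3*eps^3` fitted through the origin to
(pseudo-)bench curves; this reproduces the J-shaped stiffening and with it
the observed decrease of compliance from the hypotensive towards the
hypertensive range.

## The reduced pressure solver

Kinematics are reduced to the radial displacement field `w(z, phi)`:

* **hoop membrane**: per element, hoop strain `eps = w/r_mid` and force
  resultant `N = t * sigma_bio(eps; f, PE) / (1 - nu^2) + C_hx * eps`;
* **helix homogenization**: the thread's axial stiffness `E_p * A`,
  projected on the hoop direction (`cos^2` of the helix angle, about 6.8
  degrees), distributed over the wall area its coverage occupies and
  smeared around each axial row ("tied coverage" — the helix embraces the
  whole circumference and engages immediately in hoop). For the ideal
  double helix this equals `E_p * A * cos^2(alpha) * n_layers / pitch`,
  about 34 N/mm for PVDF against the wall's `E0 * t = 0.5` N/mm;
* **bending**: axial and circumferential second-difference stencils with
  flexural rigidity `f * E * t^3 / 12 / (1 - nu^2)` from the local
  thickness and damage state — the plate action that bridges thin patches;
* **membrane stretch (von Karman term)**: axial strain `(dw/dz)^2 / 2`
  with stiffness `f * E * t`. This geometric term is what saturates a
  growing bulge: a localized protrusion must stretch its meridian, and
  that elastic cost grows with the fourth power of the bulge amplitude.
  Without it, a floored-modulus patch ratchets without bound;
* **load**: pressure on the lumen, `p * r_in / r_mid` per unit mid-surface
  area, making the uniform tube reproduce the thin-wall closed form
  `eps = p * r_in / (t * E)` exactly away from the clamps.

Equilibrium is found by Newton iteration with a backtracking line search;
linear wall laws converge in one step, and cyclic runs warm-start each
cycle from the previous solution. Ends are fully fixed over 5 mm bands
("encastre"), matching the bench mounting. A solve whose peak strain
exceeds 50% is flagged `"model validity exceeded"` — it still returns, but
its magnitudes are outside the small-strain regime the shell reduction
assumes.

The Poisson ratio default is `nu = 0`: the yield calibration of the thin
patch (hoop stress `p*r/t` marginally above the 0.6 MPa yield stress at
120 mmHg) and the Laplace benchmarks are all stated in terms of the
unfactored hoop stiffness `E*t`, and tissue-realistic values near 0.45
would silently deactivate the damage mechanism that the control arm is
constructed to exhibit. The parameter is exposed for sensitivity runs.

## Cyclic growth simulation

Each of the (default 150) cycles does: equilibrium at systolic pressure
with the current damage field; per-element plasticity/damage update from
the peak hoop strain; unload. With the default unload-to-zero, the
residual radial displacement is reconstructed as `PE * r_mid` per element
rather than by a second equilibrium solve — consistent with the
scalar-hoop plasticity and cheap; an unload-to-diastolic solve is
available instead. The default protocol is the normotensive 80–120 mmHg
range (0.011–0.016 MPa presets).

On the control preset the thin patch yields on cycle 1 (peak strain 0.68),
the modulus ramps to its floor immediately (`PE_ref` is far below the
first-cycle plastic increment), the bulge deepens over the next few cycles,
and the von Karman term saturates it: residual increments drop to zero and
the trace plateaus. Because the patch is 8x thinner than the wall and its
modulus floors at 10%, the saturated bulge (about 6 mm) is far beyond the
small-strain regime, and the run carries the validity flag. This is an
accepted artifact of the synthetic stand-in geometry: absolute bulge
magnitudes depend entirely on the unknown real thin-region thickness
distribution, and only the comparative picture — control degrades to the
floor, reinforced arms do not degrade at all — is the result. On the
reinforced arms the homogenized helix holds peak hoop strain near 0.1%,
two orders below yield, so `f` stays 1 and the residual is zero.

## Virtual bench

* **Compliance**: two static solves at the endpoint pressures of a named
  range; compliance is the outer mid-span diameter change as a percentage
  of the diastolic diameter (video-camera convention). With the linear
  wall the three ranges agree within a few percent; with a fitted J-shaped
  polynomial compliance falls monotonically from the hypo- to the
  hypertensive range. Note one honest divergence from the physical bench:
  tied coverage engages the helix in hoop at any pressure, so reinforced
  compliance is much lower than control in relative terms (the absolute
  change is still small, under 3 percentage points). The bench saw no
  significant compliance difference — capturing that would need
  contact-gap engagement, which tied homogenized coverage cannot express.
* **Longitudinal tension**: composite bar (annular wall section times the
  wall law) in parallel with the helix as a coil spring,
  `G d^4 / (8 D^3 n_turns)` per layer — about four orders softer than the
  wall, hence the null longitudinal effect of reinforcement.
* **Transverse ring tension**: initial diametral stiffness from a linear
  planar frame FE of the ring (within 2% of the classical curved-beam
  closed form `delta = F R^3/(EI) (pi/4 - 2/pi)`); the large-pull response
  continues through a lumped series model — inextensional ovalization
  saturating at `(pi - 2) R`, then stretching of the two wall strands with
  the pin-wrap arc frozen (no sliding). The composite section adds the
  threads crossing the cut at their own-axis bending stiffness only,
  because the helix is not fused to the wall. Nominal stress is
  `F / (2 t L)` (two cut wall sections); this normalization is a
  convention, flagged as such. Pin diameter (default 2 mm) only shortens
  the stretching strand; it is validated against the lumen.
* **Stop criterion**: curves are truncated at the first sample below 70%
  of the running force maximum.

## Synthetic bench statistics

`gen_bench_curves()` emulates the qualitative structure of tissue tensile
data — J-shaped cubics with replicate-level coefficient scatter
(`sd 0.15` on `a1 = 1` MPa, `sd 0.4` on `a3 = 2.5` MPa, chosen to echo the
high interquartile spread of biological subgroups while keeping `a1`
positive) plus small pointwise noise (0.02 MPa). It makes no attempt to
match bench interquartile ranges numerically. The recovery test fits the
pooled ensemble and requires the generating coefficients back within three
replicate-level standard deviations.

## Problem sizes and determinism

The default grid (60 x 32 elements, ~2000 unknowns) runs a 150-cycle
three-arm comparison in well under a minute; the test suite uses the same
or smaller grids throughout. All stochastic pieces (thickness noise, pitch
jitter, curve ensembles) are seeded and bit-reproducible; the preset
geometry itself is deterministic, so growth traces are identical across
runs regardless of seed.

## Known limitations

* Absolute post-yield and rupture magnitudes are not modelled (no
  hardening, no rupture law); comparisons between arms are the output.
* Tied homogenized coverage overstates low-pressure hoop engagement of the
  helix (see compliance note above) and ignores frictional sliding.
* The reduced shell has no axial membrane degrees of freedom, no
  anisotropy from fibre orientation, and no bending stiffness assessment
  of the whole graft.
* Residual geometry is reconstructed from plastic hoop strain, not
  re-equilibrated; cyclic runs keep the reference geometry fixed.
* The imported-STL path supports geometry statistics only; the structured
  solvers require native meshes.

## A minimal run

```{r example, eval = FALSE}
model <- build_scaffold("pvdf")
trace <- run_cycles(model, pressure_protocol(n_cycles = 150))
growth_metrics(trace)

compliance_test(build_scaffold("pvdf", with_patch = FALSE), "normo")
```
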