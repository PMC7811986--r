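---
title: "Contact-current dosimetry on a synthetic voxel phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-current dosimetry on a synthetic voxel phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(contactdose)
```

## The problem

When a person touches an energized conductor, a contact current flows from
the contact area through the body to whatever surface completes the circuit.
The quantity that decides the risk of ventricular fibrillation is not the
total body current but the electric field it induces in the ventricular
myocardium, and that field depends strongly on the current path: a
hand-to-feet current drives a much larger share of the current through the
heart than a foot-to-foot current. Safety standards encode this path
dependence as heart current factors (HCFs), historically derived from
cadaver measurements at 50 Hz. `contactdose` implements a numerical version
of that dosimetry chain for frequencies from DC to 1 MHz: a voxel body
model, a frequency-dependent tissue dielectric table, a contact-impedance
model of the skin, an electro-quasi-static field solver, and the dose
statistics built on the solved fields.

## The model

Below about 1 MHz, capacitive displacement through air and magnetic
induction are negligible for conduction-dominated contact scenarios, and the
complex potential obeys

$$\nabla \cdot \left[\left(\sigma(\mathbf x, f) + j\,2\pi f\,
\varepsilon_0\,\varepsilon_r(\mathbf x, f)\right)\nabla\varphi\right] = 0$$

inside the body, with the touched electrode held at the touch voltage
$U_t$, the return electrode(s) at 0 V, and a homogeneous Neumann condition
at the body--air surface. The solver discretizes this with a finite-volume
7-point stencil on the uniform voxel grid. Face admittances between
neighbouring voxels use the harmonic mean of the two complex
conductivities: this is the discretization that preserves flux continuity
across material interfaces, and it matters here because the skin and the
contact slice are thin, highly resistive layers whose impedance an
arithmetic mean would underestimate badly.

Dirichlet rows are eliminated, leaving a complex-symmetric system. At DC
the system is real and symmetric positive definite and is factorized
directly (sparse supernodal Cholesky). At nonzero frequency the system is
solved by conjugate-orthogonal CG (COCG, the complex-symmetric variant of
CG), preconditioned with the Cholesky factor of the real part. The factor
is reused across frequencies of the same electrode layout, where it remains
an excellent preconditioner (typically 5--50 iterations to a relative
residual of $10^{-9}$, the default tolerance). Systems below 3000 unknowns
are solved directly through the equivalent real block form; this is also the
route the test suite cross-checks against dense complex LU on small grids.

### Tissue dielectric table

Each tissue carries either constant properties or a Cole--Cole dispersion
$\hat\varepsilon(\omega) = \varepsilon_\infty + \sum_k \Delta\varepsilon_k /
(1 + (j\omega\tau_k)^{1-\alpha_k}) + \sigma_{dc}/(j\omega\varepsilon_0)$,
from which $\sigma(f)$ (non-decreasing) and $\varepsilon_r(f)$
(non-increasing) follow. The bundled table covers the ten phantom materials
with literature-style single-term parameters; it is a deliberately small,
fully overridable stand-in for the large reference databases, which are
external resources. Two values are pinned to the contact-dosimetry setup
and asserted in the tests: skin conductivity at ELF is 0.2 mS/m and the
electrode bulk material is a constant 1.0 S/m (high enough to be
insignificant next to tissue impedances, low enough not to destabilize the
solver). Skeletal muscle is isotropic at its longitudinal conductivity
value; published comparisons find no major differences against an
anisotropic setup for these scenarios, so tensor conductivities are out of
scope. $\varepsilon_0$ is fixed at $8.854\times10^{-12}$ F/m and DC is
encoded as `frequency = 0`, never a sentinel value.

### The two body models

The total body impedance splits into the skin impedance of the contact area
in series with the internal body impedance. Which part matters depends on
the exposure: below roughly 1 kHz with intact skin (touch voltages up to
220 V) the skin dominates and must be modeled (`TOTAL` mode); above 10 kHz,
or above 220 V where the skin breaks down, it is negligible (`INTERN`
mode); between 1 and 10 kHz the choice is an explicit per-case decision
(`CASE_BY_CASE`), which the pipeline refuses to make silently. At the
printed boundaries the package classifies 1 kHz as `TOTAL`, 10 kHz as
`CASE_BY_CASE`, and 220 V as intact skin; the published table's interval
labels overlap at these points, so closed-below/open-above intervals are a
documented package convention.

In `TOTAL` mode the skin under the 100 × 100 mm contact patch is removed
and replaced by a 2-mm slice of the electrode carrying voltage-dependent
properties (a parallel-RC slab with one conductivity and one permittivity
-- exactly what gets voxelized, rather than the multi-element RC networks
of the standards). The tabulated slice properties run from 0.14 mS/m and
$2.4\times10^4$ at 25 V to 0.85 mS/m and $1.32\times10^5$ at 220 V -- the
conductivity rises by a factor of six, reflecting progressive partial skin
breakdown. Between the four tabulated voltages both properties are
interpolated linearly in log-voltage (four points admit no more elaborate
rule); outside 25--220 V there is no data and the package refuses to
extrapolate. `fit_skin_properties()` recovers slice properties from
reference $|Z|(f)$ curves by least squares on the relative magnitude error
(phase is not fitted because reference sources report magnitudes);
the per-frequency residual profile is returned rather than assuming a
particular anchoring frequency for the permittivity.

### Dose quantities

* `body_current()` evaluates the conduction current through several full
  cross-section planes between the electrodes (the numerical analogue of
  measuring the body current with a set of surface integrals) and reports
  the mean plus the cross-plane spread as a conservation diagnostic. On a
  converged solve the spread is at the solver-tolerance level, orders of
  magnitude below the 1% acceptance bound.
* `total_impedance()` is Ohm's law $Z = U_t / I$, with the touch voltage
  real by convention and the phase carried by the current.
* `e99_heart()` is the 99th percentile of the phasor magnitude $|E|$ over
  ventricular-myocardium voxels only (lumen blood, vessels, and all other
  tissues excluded). The percentile uses linear interpolation between the
  closest order statistics (`stats::quantile` type 7); compliance
  guidelines do not fix an interpolation convention, so the package states
  one and pins it with a brute-force sorted-order-statistic oracle in the
  tests (100 voxels with $|E| = 1..100$ give 99.01).
* `sam_field()` imitates the classical trans-cardiac voltage measurements:
  three orthogonal line integrals of $E \cdot dl$ across the heart at
  $\le 1$ mm sampling with trilinear field interpolation, each voltage
  divided by its axis length, and the three orthogonal component estimates
  combined as a Euclidean norm. The historical method reports "the field
  vector" without stating a combination rule; the norm is the unique
  rotation-consistent choice for orthogonal components.
* `hcf_table()` forms $F(p, f) = [E(p,f)/|I(p,f)|] \cdot
  [|I(\mathrm{ref},f)|/E(\mathrm{ref},f)]$ with LH-BF as the reference
  path, for both the percentile statistic (F99) and the line-integral
  statistic (FSam). The denominators use $|I|$; the current's phase is
  reported separately in the dose table. The reference row is exactly 1 by
  construction, and solver linearity makes the whole table invariant to the
  drive voltage (asserted to $10^{-9}$ relative).

## The synthetic phantom

The licensed high-resolution anatomical model used in reference studies
cannot be redistributed, so the package generates a parametric voxel body:
a reduced-stature (~1.1 m) figure with an elliptic-cylinder trunk wrapped
in skin and subcutaneous fat shells, cylindrical limbs with long bones, two
lung ellipsoids sized to fill most of the thorax, a spine, an ellipsoidal
ventricular-myocardium shell (20 mm wall) enclosing a blood lumen, and a
blood-vessel tree (18 mm diameter trunks). Everything is configurable via
`phantom_config()`; the build is deterministic, and seven electrode patches
(nominal 100 × 100 mm, grown geodesically over the surface until the
exposed-face area reaches the nominal area) are registered at the hands,
feet, anterior/posterior thorax and seat. Electrode positions on the
thorax are configuration parameters rather than hard-coded anatomy, and
`shift_electrode_site()` supports the ±2 cm position-sensitivity sweeps.

The vessel topology is the part of the anatomy that carries the
current-channeling mechanism, and its design is deliberate. The subclavian
analogues run from each arm to a great-vessel junction just above the heart
base; the descending aorta / vena-cava analogues continue past the heart to
the lower trunk. The vessel trunks terminate 2 mm above the base and below
the apex without puncturing the ventricular wall: they import the remote
junction potential to the base's doorstep and collect the apex exit current
into the caval trunk, which concentrates the through-wall current at the
poles. The lumen joins the tree through a narrow lateral root (a
pulmonary-vein analogue) at the equator, where the wall current is small.
Early design variants in which wide vessels pierced the poles *reduced* the
99th-percentile wall field -- a bare conductive tube equilibrates with the
surrounding tissue and a polar hole simply relieves the hottest wall
crossings -- so the pole-adjacent, laterally-rooted topology is what makes
the phantom reproduce the channeling signature: at 50 Hz on the LH-BF path,
the myocardial E99 with vessels present exceeds the vessels-off variant,
and down-scaling the blood conductivity (the post-mortem direction) lowers
the per-unit-current heart field. With this geometry the longitudinal paths
(xH-xF, PS-xH) produce F99 within a few per cent of 1.0 and the transversal
paths fall well below 1, the qualitative pattern reported for anatomical
models.

What the phantom does *not* emulate: realistic organ shapes, atria and
valves (the reference model also has no valves), myocardial fiber
anisotropy, posture, or the fine vascular network. Consequences observed
and accepted: the heart sits below the shoulder-level hand-to-hand current
corridor, so the LH-RH path produces a weak fringe field at the heart whose
*relative* dispersion is large for a reason unrelated to electrode
proximity. The proximity-inhomogeneity effect is therefore demonstrated
against the longitudinal reference (anterior-thorax versus LH-BF) rather
than against LH-RH. Passing tests demonstrate the mechanisms on this
geometry; they do not certify absolute HCF values for real anatomy.

## Numerical choices

* Grid: uniform spacing (default 4 mm, accepted range 1--5 mm), no local
  refinement; convergence is assessed by spacing-halving (tissue volumes
  change < 10%, analytic impedances converge monotonically, < 1% error at
  2 mm for the cylinder oracle) rather than by adaptive meshing.
* Solver tolerance: relative residual $10^{-9}$ by default; $10^{-12}$ to
  $10^{-13}$ where tests assert reciprocity ($10^{-8}$) and voltage
  invariance ($10^{-9}$). Non-convergence is an error carrying the
  residual history, never a silent result.
* Determinism: there is no randomness anywhere in the phantom, solver or
  pipeline; campaign outputs are a pure function of the configuration, and
  reruns against a populated output directory reuse completed solves
  byte-for-byte.
* Degenerate inputs: empty electrode sets, unmapped labels, missing
  dielectric entries, out-of-range touch voltages and cross-section planes
  that miss the body are all hard errors with named subjects.
* Problem sizes: the default phantom solves ~180k unknowns; the bundled
  analyses (HCF campaign over two paths and five frequencies, channeling
  comparison, reciprocity and linearity checks) were sized to run
  comfortably on a single desktop core.

## Known limitations

The absolute impedances and HCFs of the synthetic phantom are not those of
a real human: the anatomy is schematic and the tissue table is a ten-entry
stand-in. Reference impedance curves from the standards literature are not
bundled (they are licensed content); `fit_skin_properties()` accepts them
as user-supplied delimited text. HDF5 serialization is not provided; label
volumes and field exports use NIfTI with a JSON sidecar. Users who hold a
license for an anatomical voxel model can load it through
`load_label_volume()` with their own tissue map and heart axes.
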