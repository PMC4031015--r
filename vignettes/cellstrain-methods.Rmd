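---
title: "Methods: a finite-element model of an adherent cell under cyclic equibiaxial strain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a finite-element model of an adherent cell under cyclic equibiaxial strain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cellstrain)
```

# The model

`cellstrain` simulates a single adherent osteoblastic cell bonded to a
stretched elastomeric (PDMS) membrane. The membrane imposes a radially
isotropic (equibiaxial) sinusoidal strain field with peak amplitude
1,000 µstrain at stimulation frequencies between 1 and 45 Hz; the
questions the scenario suite addresses are how peak intracellular Von
Mises stress and principal strain depend on stimulation frequency,
cytoplasmic viscoelasticity, the stiffness mismatch between nucleus and
cytoplasm, and a minimal actin stress-fiber cytoskeleton.

**Geometry.** The cell is a rotationally symmetric flattened shell
("fried-egg" morphology): 20 µm plan diameter, 5 µm apex height, a 1 µm
foot, and 490 µm³ total volume. Only the first three of these are
independent shape parameters; the profile family is a cosine-power dome

$$h(r) = f + (H - f)\cos\!\left(\frac{\pi r}{2R}\right)^{p},$$

with the single exponent $p$ calibrated by quadrature and root bracketing
so the revolved volume meets the 490 µm³ target to 0.1 µm³ (the default
geometry gives $p \approx 5.10$). This family was chosen because it is
smooth, monotone, matches all four stated dimensions with one free
parameter, and is deterministic to calibrate. The nucleus is an oblate
spheroid (5 µm equatorial, 2 µm polar diameter) centred on the symmetry
axis. Its height above the substrate is not fixed by the published
description; the default (2.25 µm) centres it vertically in the local
cytoplasm column while keeping ≥ 0.25 µm clearance everywhere. Note that
the oblate 5 × 5 × 2 µm spheroid has an analytic volume of 26.18 µm³; a
nuclear volume of 46 µm³ sometimes quoted alongside these diameters is
inconsistent with an ellipsoid, and the diameters are treated as
authoritative here.

**Materials.** The cytoplasm is a single-branch Generalized Maxwell
(standard linear solid) material with $E_0 = 6.5$ kPa, $E_\infty = 4.3$
kPa, $\tau = 15.4$ s and nominal $\nu = 0.5$; the nucleus is isotropic
linear elastic at $4 E_0 = 26$ kPa. Viscoelasticity acts on the
deviatoric response only (the volumetric branch is elastic), the common
FEM treatment and immaterial near incompressibility. Exact
incompressibility is realized as an effective $\nu = 0.499$ in a purely
displacement-based formulation; quadratic tetrahedra plus a
mean-dilatation (B-bar) volumetric treatment keep locking negligible (the
bonded-slab oracle reproduces the plane-stress closed form to ~1% away
from free edges).

**Stress-fiber network.** The optional cytoskeleton is 8 radial groups of
3 fibers at 45° intervals (24 total), each a straight tension-only elastic
cable ($E = 1.45$ MPa, 0.3 µm diameter) from a basal anchor (radii 6, 7.5,
9 µm) to the nuclear surface (latitudes −45°, 0°, +45°). Pre-tension is
force-prescribed: the static pre-tension step applies the nominal
$E\,\varepsilon_{pre}\,A \approx 102.5$ pN pair loads and the solved
state becomes the reference configuration, so every fiber starts exactly
at nominal tension. The exact anchor coordinates of the original model
are not published; the defaults are explicit, configurable, and symmetric.

**Loading and coupling.** The membrane (0.25 mm PDMS, 1.8 MPa, ν = 0.49)
is ~277× stiffer in modulus than the cytoplasm, so the cell cannot
perturb the imposed strain field; the default coupling therefore
prescribes the basal displacement $u_r = \varepsilon_a \sin(2\pi f t)\,r$,
$u_z = 0$ directly (no-slip adhesion over the whole contact area). An
`explicit_shell` coupling mode is reserved in the configuration schema but
not implemented; given the stiffness ratio it would only re-derive the
prescribed field.

# Discretization

**Meshing.** The axisymmetric cross-section is triangulated by rays from
the nucleus centre, constructed in sheared coordinates $(r, z/h(r))$ in
which the cross-section is exactly a rectangle (hence star-shaped for any
dome profile), with ray endpoints spaced uniformly by real arclength along
the outer boundary. The triangulation is revolved into wedges over
azimuthal sectors and split into tetrahedra by a rotation-invariant
diagonal rule, so the mesh possesses the exact discrete rotational
symmetry of its sector count (always a multiple of 8, matching the 45°
fiber layout). Mid-edge nodes on the nuclear interface, dome and lateral
surfaces are snapped to the true curved surfaces; the basal plane stays
exactly flat. At the reference resolution (target edge 0.8 µm, ~5,400
ten-node tetrahedra) total and nuclear volumes are within ~1% and ~0.1%
of the analytic values. The published implementation used ~58,656
elements; mesh density here is configurable and the reduced default is a
deliberate desk-scale choice — peak values at material interfaces are
mesh-sensitive, which is one reason comparisons against published peaks
use a ±30% band.

**Elements.** Ten-node tetrahedra with the standard 4-point rule carry
both regions; the strain-displacement operator built by the compiled
kernel is the single source of truth (stiffness is assembled as
$B^{\mathsf T} W D B$, internal forces as $B^{\mathsf T} W \sigma$), which
makes the constant-strain patch test exact to solver precision. Fibers
are 3-node quadratic trusses whose mid node is slaved to the ends (static
condensation of a straight quadratic truss is exact and avoids
transverse-singular degrees of freedom); fiber ends tie to the nearest
mesh surface node at the fiber's azimuth — a pin joint, since node ties
transmit translations only.

**Time integration.** The hereditary integral of the standard linear
solid is advanced by the recursive exponential integrator

$$h_{n+1} = a\,h_n + g_1 (1-a)\,e_n +
g_1\!\left[1 - \tfrac{\tau}{\Delta t}(1-a)\right](e_{n+1}-e_n),
\qquad a = e^{-\Delta t/\tau},$$

with $\sigma^{dev} = 2G_0(e - h)$; the update is exact for strain varying
linearly within a step, and is verified against direct evaluation of the
convolution integral to 10⁻⁶ and against the closed-form complex modulus
in steady state to 0.5%. Because the update is linear for a fixed step,
one sparse Cholesky factorization of the effective stiffness serves an
entire run. Two solver modes are exposed: implicit Newmark (average
acceleration, consistent mass, default density 1050 kg/m³ — neither the
density nor the integrator of the original study is published) and a
quasi-static mode. Prescribed-boundary kinematics follow the Newmark
recurrences, which makes the discrete work–energy identity exact
(verified to machine precision). No damping beyond viscoelasticity is
applied. Loading starts at full amplitude ("10 complete input strain
cycles"), with an optional cosine start-up ramp off by default; peaks are
taken over all recorded frames.

**Numerical defaults.** 96 implicit steps per cycle (8 per recorded
frame) is the package default; the analysis scripts and acceptance runs
use 24 steps per cycle at the reduced mesh, a problem-size choice that
changes peaks by well under 1% because the viscoelastic update is exact
for piecewise-linear strain and the quasi-static elastic response at
frame times is independent of step size. Runs record 12 frames per cycle
for 10 cycles (121 stored states including the initial/pre-tension
state). The taut/slack state of each fiber is resolved by fixed-point
iteration inside each step; with every fiber taut the fiber load is
constant and the iteration converges in one solve.

# Post-processing

Field scalars are element-level quantities: volume-weighted averages over
each element's quadrature points of the Von Mises stress
$\sqrt{3/2\,s\!:\!s}$ and of the largest-magnitude principal value of the
small-strain tensor. The published maps never name their scalar strain
measure; the largest-magnitude principal strain is used here (documented
and swappable) because it reproduces the expected ~2,000 µstrain
out-of-plane value for an incompressible slab under 1,000 µstrain
equibiaxial stretch. Element averages rather than nodal extrapolations
are used deliberately: the fiber attachment points are singular, and
element averaging is the less mesh-sensitive choice. Peaks "distal to the
attachments" are implemented as a one-ring exclusion (every tetrahedron
sharing a node with an anchor); the original criterion is unstated.

# What the synthetic scenarios do and do not show

All inputs are generated: there is no measured image or experimental
trace anywhere in the pipeline. The geometry module is the synthetic-data
generator and its defaults are the study conditions (1,000 µstrain, 1-45
Hz, 10 cycles, 12 frames/cycle, the material values above). Passing tests
therefore demonstrate that the implementation solves the stated
continuum-mechanical model correctly — they cannot show that the model
describes any particular real cell, whose geometry, adhesion pattern and
cytoskeletal architecture are far richer than a revolved dome with 24
straight fibers.

**Known limitation, stated plainly.** With the published parameters the
model's response is nearly frequency-flat between 1 and 45 Hz in *both*
solver modes: the storage modulus changes by less than 0.01% over that
band for τ = 15.4 s (ωτ ≫ 1 throughout), and inertia is negligible at
cell scale (elastic wavelength at 45 Hz ≈ 5 cm against a 20 µm cell;
adding Newmark dynamics at 1050 kg/m³ changes fields by ~10⁻⁴
relatively). The frequency-dependent amplification reported for the
original implementation (about 4–5× higher cytoplasmic stress and strain
at 45 Hz than at 1 Hz) therefore does not emerge from the stated
equations, whatever the integrator; this package reports the discrepancy
in both modes rather than tuning toward it. Quantities that do not hinge
on that amplification — the 1 Hz strain peaks, the τ-insensitivity above
1 Hz, the τ = 0.1 s stress reduction at 1 Hz, the ~50% nuclear stress
drop for an iso-elastic nucleus, and the cytoskeletal peri-nuclear stress
concentration — are reproduced within the stated bands.

Other limitations: small-strain kinematics throughout (driving strain
10⁻³; fiber pre-strain 10⁻³); no focal adhesions, contact or de-adhesion;
no multi-branch Prony series; no mixed pressure formulation (effective
ν = 0.499 instead); the `explicit_shell` membrane mode is not
implemented; peak values at the bimaterial interface and near fiber
anchors remain mesh-sensitive, which is intrinsic to the model's corner
and point singularities.

# Reproducing the analyses

The numbered scripts under `analysis/` run the full scenario suite at the
reduced mesh and write their tables under `results/`:
`01_geometry_and_materials.R` (calibration, mesh metrics, SLS moduli),
`02_frequency_sweep.R` (both solver modes), `03_tau_sweep.R`,
`04_nucleus_stiffness.R`, `05_cytoskeleton.R` (including VTU export) and
`06_report.R` (aggregate comparison with the published values).
`scripts/acceptance.R` recomputes the headline quantities from scratch
and writes them as JSON; the test suite under `tests/testthat/` checks
the constitutive, geometric, symmetry and energy guarantees quoted above.
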