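---
title: "Virtual femoral tunnel drilling: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual femoral tunnel drilling: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In single-bundle ACL reconstruction with the transportal (medial portal)
technique, the femoral tunnel is drilled through a far anteromedial portal
toward the femoral ACL footprint. Two operative choices — the knee flexion
angle during drilling and how transversely the drill is oriented — jointly
determine three quantities a surgeon cares about:

* **tunnel length** (a tunnel under 25 mm is considered too short for
  secure graft fixation),
* **tunnel wall breakage** (posterior wall blowout at the aperture, or a
  breach of the wall within the first 25 mm of the tunnel), and
* **graft bending angle** at the femoral aperture (a sharper bend
  concentrates stress on the graft).

`kneedrill` implements this experiment as a deterministic geometric
simulation on triangulated bone surfaces: given a distal femur and a
proximal tibia in millimetres, it localizes both ACL footprint centers,
poses the knee at 100–130° of flexion, finds the maximum transverse drill
angle (MTA) and its −10° and −20° offsets, drills a virtual 8-mm cylinder,
and measures the three outcome variables over the 4 × 3 condition grid,
followed by the matching within-subject statistics.

## Geometric model and assumptions

**Canonical frame.** All analysis runs in a right-knee canonical frame:
+X lateral, +Y anterior, +Z proximal, millimetre units, full-extension
pose. Left knees are mirrored across the sagittal plane on entry and the
flag recorded.

**Bones are rigid, bone-only surfaces.** Menisci, cartilage thickness and
all other soft tissue are not modelled. Where the method refers to the
cartilage of the medial femoral condyle (the structure the drill must
clear), the simulation substitutes the labelled articular bone surface of
the medial condyle. This is a deliberate simplification: on bone-only
models, articular bone is the best available proxy for cartilage.

**Flexion is a pure hinge.** The tibia rotates rigidly about the fixed
transepicondylar axis (TEA); femoral roll-back and the screw-home
mechanism are ignored. A consequence worth stating: the femur, the
femoral footprint and any drilled tunnel are *identical* across poses,
and only the tibia (and with it the portal) moves.

**Quadrant-method footprints.** The femoral footprint center is placed on
the medial wall of the lateral condyle using the quadrant (Bernard)
convention in the true-lateral projection (viewing along the TEA, where
the condyles superimpose). Because no radiograph exists, the Blumensaat
line is proxied by the intercondylar notch roof: the roof is traced by
casting distal-to-proximal rays along the intercondylar corridor,
accepting stations where the corridor ray enters bone at least 2 mm above
the condylar surfaces either side, and fitting a least-squares line
through the traced points. The grid spans the full projected silhouette of
the medial-wall region: its first axis runs along the Blumensaat proxy
(origin at the posterior border), the second perpendicular to it from the
proxy line toward the distal articular margin. Defaults are 28.4% along
the proxy and 35.7% perpendicular to it. The perpendicular fraction is
measured *toward distal*; the source convention does not state which
border carries the 100% end, and the Bernard convention (full condyle
height) is adopted. The projection is along the TEA, so computing the grid
in the extension pose is equivalent to the 90°-flexion "true medial view"
it is usually drawn in.

The tibial footprint sits at 35.7% of the plateau's AP depth from the
anterior border and 51.5% of its ML width from the medial border, on the
bounding box of the plateau outline in the proximal-to-distal view, lifted
onto the surface by a vertical ray.

**Portal and drill angles.** The far anteromedial portal center is
constrained to a line 10 mm above the posed tibial plateau plane, parallel
to the plateau ML axis, 15 mm anterior to the plateau's anterior-most
point. The AP offset is not specified by the method being modelled; 15 mm
is a configurable default, and results are mildly sensitive to it (it
shifts all transverse angles together, and differences between conditions
are what matter). The transverse drill angle is measured between the
portal→footprint direction projected into the posed plateau plane and the
plateau AP axis (0° = sagittal drill, 90° = fully transverse). The datum
is a convention — only the −10°/−20° differences propagate into the
results.

**MTA search.** Feasibility of a portal is clearance ≥ 0 between the full
drill cylinder (radius 4 mm around the portal→exit segment) and the
medial condyle's articular region. The search runs over the branch of the
portal line *medial* of the footprint's ML station. (The naive bracket —
the whole plateau width plus margins — is not usable: a portal lateral of
the footprint aims the extended drill axis across the notch into the
medial condyle, so feasibility is no longer monotone. Medial of the
footprint the transverse angle is zero at the branch point, strictly
increasing medially, and feasibility is monotone; this also matches the
anatomy of a far anteromedial portal.) Feasibility is pre-scanned at 24
stations, required to be monotone, and the boundary bisected to 0.05 mm.
The MTA is re-determined at every flexion angle, since the portal line
moves with the tibia; whether the original protocol fixed it per subject
is not stated.

**Drilling and breakage.** The tunnel axis starts at the femoral footprint
F and continues along the portal→footprint direction; the exit point is
the *last* inside→outside crossing with the femur, so re-entries through
the notch do not truncate the tunnel. Length is |exit − F|; `short ⟺
length < 25 mm`, exactly. The wall-breakage definition is verbal in the
source ("breakage at the entrance"; "breakage within 25 mm of the
entrance without entrance breakage"), so the package operationalizes it
with wall generators: 72 lines on the cylinder surface are sampled every
0.25 mm over the first `min(length, 25)` mm. A generator that finds no
bone within the first 8 mm (the oblique-aperture allowance `a_cap`)
signals **entrance breakage**; otherwise a generator that leaves bone
between its first in-bone station (+0.5 mm) and the 25-mm cap (−0.5 mm)
signals **mid-tunnel breakage**. All five constants are configurable, the
two classes are mutually exclusive by construction, and the test suite
requires the classification of constructed defect fixtures to be stable
when both sampling steps are halved. An alternative operationalization via
the topology of the cylinder/surface intersection curves would avoid
sampling but is substantially harder to make robust on faceted meshes.

**Graft bending angle.** At full extension, the angle at the femoral
footprint B between the continuation of the tibial→femoral footprint line
beyond B and the direction from B to the tunnel exit D. 0° means the
tunnel prolongs the graft line; larger is a sharper bend.

## The synthetic knee generator

No imaging data accompanies the package, so cohorts are generated
parametrically. A femur is the implicit-surface union of two condylar
ellipsoids, a metaphyseal block whose inclined lower face forms the notch
roof (sagittal slope 0.35, ≈19°, a plausible Blumensaat inclination), and
a shaft cylinder; the tibia is a superelliptic plateau slab plus a shaft.
Surfaces are extracted by marching tetrahedra (six tetrahedra per grid
cube sharing the main diagonal) at a default pitch of 1 mm. The
tetrahedral variant of the marching-cubes family was chosen because each
tetrahedron case is unambiguous, which guarantees watertight output —
every downstream query assumes a closed surface.

The only population-referenced dimension is the transepicondylar distance,
drawn from 82.1 ± 5.7 mm. Every other dimension is an invented but
plausible fixed proportion of it (condyle radii 0.27×, notch width 0.22×,
notch height 0.30×, shaft radius 0.17×, plateau ML width 0.95×, AP depth
0.62×), jittered per subject with a 4% log-normal coefficient of
variation so that cohorts vary in shape and not only in scale — with pure
scaling, all angle-valued outcomes would be identical across subjects and
the within-subject statistics degenerate. Eight seeded Gaussian surface
bumps (SD 0.5 mm, clamped at ±1.2 mm, width 8 mm) on the condyles add
local asymmetry. In the extension pose the condyles rest 2 mm above the
plateau plane with the TEA parallel to the plateau ML axis.

**What the generator does and does not emulate.** It reproduces the
gross features the simulation relies on: two condyles separated by an
open notch with an inclined roof, a medially-facing wall of the lateral
condyle, a flat-ish plateau, realistic overall dimensions, and seeded
inter-subject variation. It does **not** reproduce real cortical/trochlear
morphology, per-patient footprint variation, menisci or cartilage.
Passing trend tests on synthetic cohorts therefore demonstrates that the
*pipeline* responds to flexion and drill angle in the directions reported
for patient anatomy — longer tunnels and larger bending angles at higher
flexion, less breakage risk at higher flexion — not that its absolute
values transfer to any patient. Notably, the synthetic anatomy is more
forgiving than real knees: with the default proportions no tunnel is
short and no wall breaks anywhere on the grid, whereas patient data show
frequent short tunnels and breakage at 100–110° of flexion. The
drill-angle direction of the bending-angle effect at fixed flexion ≥ 110°
likewise comes out opposite to the patient-data trend on synthetic
cohorts; trend assertions are therefore limited to the flexion direction,
which is geometrically forced.

## Numerical choices

* **Surfacing pitch** 1 mm (configurable). Epicondyle detection, chord
  oracles and footprint placement are accurate to roughly the pitch;
  tolerance choices in the tests (±2 mm on the epicondylar span, ±0.5 mm
  on chords) follow from it. Crossing vertices are kept at least 2×10⁻⁴
  of an edge away from grid nodes so that the 10⁻⁶-mm duplicate-vertex
  weld cannot collapse distinct crossings (which would open the surface);
  implicit values within 10⁻⁶ of zero are treated as outside for the same
  reason.
* **Watertightness** is enforced at construction: every undirected edge
  shared by exactly two faces, every directed edge unique, signed volume
  positive (orientation flipped if negative). Meshes loaded from STL/PLY
  get a duplicate-vertex merge at 10⁻⁶ mm first and are rejected if still
  open, with the open-edge count in the error.
* **Containment** is crossing-parity of an upward ray through a uniform
  2D grid over face bounding boxes; query points are nudged by ~3×10⁻⁸ mm
  so rays avoid edges and vertices. Points within ~10⁻⁶ mm of the surface
  may classify either way; containment at that scale is not meaningful on
  a faceted surface.
* **MTA bisection** to 0.05 mm in portal position; offset portals
  root-found to 0.01° in angle. The clearance at a returned constrained
  MTA lies in [0, 0.1] mm and half a degree more transverse produces
  contact — both asserted in the tests.
* **Degenerate statistics inputs** are reported, not errored: identical
  columns give F = 0, p = 1; zero error variance gives F = ∞, p = 0 with
  a degeneracy flag; an all-constant-rows Cochran table gives Q = 0,
  p = 1, flagged. Greenhouse–Geisser correction exists but is off by
  default, matching the convention of reporting uncorrected
  within-subject F tests.

## Problem sizes

The test suite and the acceptance script use a cohort of n = 10 knees
(seed 42 and the script's `--seed`, respectively) for the full 4 × 3
grid, n = 30 parameter draws for the population checks, 2 000 replicates
for the ANOVA type-I-error simulation, and coarser 1.5–4 mm pitches where
only parameters or gross shape matter. These sizes were chosen to make
the whole suite run in a few minutes on a single core while keeping every
scientific check meaningful; the pipeline itself scales linearly in
subjects and conditions.

## Known limitations

* Bone-only geometry; cartilage ≈ articular bone at the MTA constraint.
* Pure-hinge kinematics without roll-back changes where the posed portal
  sits relative to a physiological knee, especially at high flexion.
* The breakage rule is one operationalization of a verbal definition;
  the `a_cap` aperture allowance (8 mm) trades oblique-aperture false
  positives against missed true blowouts.
* Aperture morphology (shape/area of the tunnel opening) is out of scope.
* Synthetic cohorts support property- and trend-level validation only.
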