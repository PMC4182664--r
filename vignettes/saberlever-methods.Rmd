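---
title: "Jaw kinematics and lever mechanics of the sabertooth bite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Jaw kinematics and lever mechanics of the sabertooth bite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saberlever)
```

## The scientific question

How did *Smilodon fatalis* close its jaws around prey at the enormous
gapes its maxillary canines demand?  The long-favoured "canine
shear-bite" holds that the ventral neck flexors depress the cranium at
the atlantooccipital joint (AOJ) while the mandible, braced against the
prey, stays stationary, so that neck musculature augments jaw closure.
`saberlever` implements the planar rigid-body test of that claim and the
alternative it motivates: a Class 1 lever mechanism in which a dorsally
directed force from forelimb extension rotates the cranium anteriorly at
the temporomandibular joint (TMJ) against an immobilized mandible, with
the cranium simultaneously pivoting about the virtual center of the
maxillary canine curvature so the canines enter tissue along their own
long axis.

Everything is modelled in the sagittal plane: the skull faces +x
(anterior), +y is dorsal, lengths are millimetres and interface angles
degrees.  A "ventral" rotation of the anterior-facing skull is clockwise
internally; user-facing functions take positive ventral/anterior degrees
and handle the sign.

## The landmark model

A `skull_config` is a set of twelve named 2D landmarks partitioned into
neck, cranium, mandible and derived segments, joined in an articulated
chain: caudal neck, mid-neck, AOJ, TMJ, with the cranium rostral of the
AOJ and the mandible suspended at the TMJ.  No digitized coordinates of
the original replica exist in print, so the generator
(`generate_skull()`) constructs the configuration exactly from
parameters:

* the mandible axis (TMJ to lower incisor tip) is built vertical, the
  posture described for the bulldogging restraint;
* the cranial axis is opened from the mandible axis by the **gape**
  angle, measured at the TMJ between the two incisor tips (90° is the
  accepted maximum);
* the straight neck chain leaves the AOJ at the **extension** angle;
  the published experiment increases extension by 36° from an unstated
  neutral pose, so extension is exposed as an absolute angle with the
  neutral pose defined as 0° — the +36° increment is then an exactly
  testable difference;
* the upper canine base and tip are placed exactly on a circle of the
  given radius centred on the **virtual point**, which is constrained
  anteroventral to the TMJ (offset given in the cranium frame so the
  relation is posture-independent; on the default 90°-gape posture the
  cranium frame coincides with the world frame).

Absolute dimensions (neck segments 120 mm each, AOJ–TMJ 90 mm, TMJ to
upper/lower incisor 180/160 mm, canine radius 110 mm, virtual point
(+15, −20) mm from the TMJ) are documented, configurable plumbing chosen
at a plausible large-felid scale: no measurements are published, and
every property the package tests holds for any valid parameter set, not
only the defaults.  Digitization noise is isotropic Gaussian per
landmark, applied after exact construction under a private seeded RNG
stream; the derived virtual point is never noised.

```{r}
bulldog <- generate_skull(skull_preset("bulldogging"))
bulldog
```

## The rotation experiment

`apply_trial()` rotates the neck-and-skull unit ventrally about one of
four pivots (caudal neck, mid-neck, AOJ, TMJ) by an arc (15° in the
published experiment, an arbitrary choice) under one of three mandible
policies:

* `FIXED_TO_CRANIUM` — the mandible keeps a constant position relative
  to the cranium;
* `FREE_RETURN_TO_VERTICAL` — the mandible additionally rotates freely
  at the displaced TMJ back to vertical;
* `STATIONARY_MANDIBLE` — the mandible is not moved at all, and the
  trial is feasible only if the TMJ itself stayed put.

The original experiment rotated a whole image; this package rotates only
the landmarks rostral to the pivot, the physically meaningful
articulated-chain reading.  The superposition conclusions are identical
either way because they depend only on the relative motion of the TMJ
and mandible.

```{r}
feasibility_table(bulldog, arc_deg = 15)
```

The table is the falsification: at every pivot except the TMJ the TMJ is
carried along a chord of length `2 r sin(arc/2)` (`chord_displacement()`),
where `r` is the pivot–TMJ distance, so a stationary mandible —
articulated to the TMJ — is geometrically impossible there.  The verdict
is arc-independent for arcs in (0°, 360°); a full 360° turn is the
degenerate feasible identity and is documented as such.  "Stationary" in
the published account was a visual judgement on superimposed images; the
package uses a numeric threshold, 1e-6 of the configuration's
characteristic length (largest pairwise landmark distance), configurable
via `stationarity_tol`.

Under the free-return policy the mandible's dorsal return rotation
always equals the trial arc — neck rotation translates the mandible but
never re-orients it — and the gape after the return is the initial gape
minus the arc.  That closure is deceptive: it is achieved by moving the
mandible ventrally with the TMJ, not by closing the jaws on a stationary
prey, which is exactly the kinematic point at issue.  (Geometrically the
gape *must* change by the arc under free return; an unchanged gape would
contradict the rigid rotation of the cranial ray.  The package reports
the measured angle.)

Jaw closure with a stationary mandible requires an anterior rotation of
the cranium at the TMJ (`rotate_cranium()`): gape then decreases by
exactly the arc.

## Lever mechanics

A `lever_system` is a fulcrum plus effort and resistance lines of action
(point + direction); magnitudes are out of scope, since the comparison
is geometric.  The in-lever (out-lever) is the perpendicular distance
from the effort (resistance) line to the fulcrum, and the mechanical
advantage is `MA = in-lever / out-lever`.  `classify_lever()` projects
the fulcrum and the two application points onto the line through the
application points and names the middle element: fulcrum → Class 1,
resistance → Class 2, effort → Class 3.

`build_named_lever()` assembles the three bite mechanisms:

* **shear_bite** — fulcrum at the AOJ, ventral effort from the neck
  flexors applied between the AOJ and the canine tips (default: the
  AOJ–TMJ midpoint), resistance at the upper canine tip: a Class 3
  lever;
* **c1lm** — fulcrum at the TMJ, dorsal effort at the caudal neck force
  point (where forelimb extension lifts the neck), same resistance: a
  Class 1 lever;
* **mandibular_bite** — fulcrum at the TMJ, effort at the coronoid
  process along a modelled temporalis line of action (only the
  temporalis is considered).

The resistance line is modelled normal to the fulcrum–bite-point radius,
so the out-lever equals the fulcrum-to-bite-point distance; the bite
point defaults to the upper canine tip but may be placed more
posteriorly in the mouth.  Because the forelimb-powered lever and the
mandibular bite then share fulcrum and out-lever exactly, their MA ratio
is algebraically the ratio of their in-levers — the package asserts this
identity to 1e-12 over random configurations.  The temporalis
attachment default (30 mm caudal, 50 mm dorsal of the TMJ in the cranium
frame) is plumbing, not measured anatomy; it yields the short adductor
in-lever expected at a 90° gape, and the resulting MA ordering
(forelimb-powered > adductor bite) is then a testable consequence of the
geometry, not an input.  Absolute MA values are not reproducible — no
lever lengths are published — so only the ratio identity and the
ordering are asserted.

```{r}
lever_report(bulldog)
```

`mmHg_to_N_per_mm2()` converts the carotid collapse pressure quoted in
the prey-death discussion (120 mm Hg ≈ 0.016 N/mm²) at
1 mm Hg = 133.322 Pa.

## The strike model

The strike-phase narrative — "the cranium rotates anteriorly at the TMJ
while the TMJ rotates anteriorly at the virtual point, the mandible
moving relative to the prey" — admits exactly one rigid planar reading,
which the package adopts and documents as an interpretive decision: a
single rotation of the neck-and-skull unit about the fixed virtual
point, with the mandible translating (orientation locked) so its TMJ
attachment tracks the cranium's TMJ.  Both descriptions advance by the
same angle φ: the cranium's orientation change is φ and the
cranium–mandible relative angle (the gape) also changes by φ, a 1:1
coupling asserted as an invariant.  Consequences, all tested:

* the canine tip traces its curvature circle (constant radius about the
  virtual point to 1e-9 relative), i.e. the canines traverse tissue
  along their own long axis;
* gape decreases linearly, `gape(φ) = gape(0) − φ`; progress is
  angle-parameterized (the published account states simultaneity but no
  drive ratio, and gives no forelimb-extension distance to
  parameterize by);
* negative φ is the withdrawal phase, and strike followed by equal
  withdrawal restores the start bit-for-bit to 1e-9;
* the finite-difference tangency error of the tip trace is half the
  per-step arc and vanishes under refinement.

The prey hide is modelled as a straight line in the sagittal projection
(`penetration_depth()` measures signed perpendicular depth past it);
surface curvature, tissue resistance and force magnitudes are out of
scope.

## Numerical choices and degenerate inputs

* Angles are normalized to (−180°, 180°]; unsigned angles (gape) are
  reported in [0°, 180°] via `atan2` of cross and dot products, stable
  near 0° and 180°.
* Degeneracy tolerance: 1e-9 × characteristic length, overridable;
  coincident points, zero direction vectors, collinear circle-fit input
  and ambiguous lever projections raise classed errors rather than
  returning garbage.
* Circle fitting uses the exact circumcircle for 3 points and algebraic
  (Kåsa) least squares for more; residuals are reported.  The Kåsa fit
  is biased for large noise/arc ratios, which is immaterial at the
  digitization noise levels modelled here (≤ 1 mm on ~100 mm arcs).
* The gape parameter admits 0° (closed jaws) so the strike-end posture
  is representable; 180° is excluded as degenerate.
* Problem sizes in the test suite — 200 randomized parameter sets for
  the feasibility sweep, 1000 random cases for the kinematic property
  checks, 90-step strike trajectories — were chosen so the full suite
  documents the claims at interactive speed.

## What the synthetic generator does and does not show

The generator emulates the *geometry* of the digitized experimental
image: an articulated chain in one sagittal plane with exact rigid
segments.  It does not emulate out-of-plane motion, joint translation
(e.g. TMJ articular cartilage thickness), soft-tissue deformation, or
real digitization error structure beyond isotropic Gaussian noise.
Passing tests therefore establish the *kinematic* claims — which pivots
permit a stationary mandible, what each lever's class and MA ratio is,
what path the canine tip follows — for any rigid planar skull of this
topology.  They cannot establish anatomical magnitudes (absolute MA,
bite force, penetration depth in real tissue), and the package asserts
none.

## Known limitations

* 2D only; no dynamics (forces as functions of time) and no muscle
  force magnitudes.
* The neutral (pre-extension) posture of the original replica is
  unknown; extension is absolute with neutral defined as 0°, so only
  extension *increments* are comparable to the published +36°.
* The qualitative suggestion that hide traction on the mandibular
  canines explains rotation about the virtual point is not modelled; no
  force balance is implemented.
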