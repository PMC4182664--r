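# saberlever

Planar jaw kinematics and lever mechanics for sabertooth bite models.

`saberlever` is for functional morphologists and biomechanists who want
to test craniomandibular bite hypotheses on 2D landmark models.  Its
motivating case is the *Smilodon fatalis* jaw: the long-favoured
"canine shear-bite" claims that the ventral neck flexors, rotating the
cranium ventrally at the atlantooccipital joint (AOJ), help close the
jaws against a mandible held stationary on the prey.  The package
implements the rigid-body test of that claim and the forelimb-powered
Class 1 lever alternative.

The kinematic core: if the neck-and-skull unit rotates by an arc θ
about a pivot at distance *r* from the temporomandibular joint (TMJ),
the TMJ is translated along a chord of length

    d = 2 r sin(θ / 2),

so a mandible articulated to the TMJ cannot remain stationary unless
*r* = 0 — i.e. unless the pivot *is* the TMJ.  The lever core: for a
fulcrum with effort and resistance lines of action, the mechanical
advantage is

    MA = in-lever / out-lever,

the in-lever (out-lever) being the perpendicular distance from the
effort (resistance) line of action to the fulcrum; the lever class is
decided by which of fulcrum, effort and resistance lies between the
other two along the lever axis.  The strike model rotates the cranium
about the virtual point — the center of the maxillary canine curvature,
slightly anteroventral to the TMJ — so the canines enter tissue along
their own long axis while the immobilized mandible translates.

All geometry is sagittal-plane: +x anterior, +y dorsal, millimetres and
degrees.  No digitized coordinates of the original skull replica are
published, so configurations come from a parameterized, seeded
generator; every tested property holds for any valid parameter set, not
just the defaults.

## Worked example

```r
library(saberlever)

## the experimental posture: cranium extended +36 deg at the AOJ,
## mandible vertical at the maximum gape of 90 deg
bulldog <- generate_skull(skull_preset("bulldogging"))

feasibility_table(bulldog, arc_deg = 15)
#>         pivot              policy arc_deg tmj_dx_mm tmj_dy_mm tmj_disp_mm mandible_return_deg gape_after_deg feasible
#> 1 CAUDAL_NECK STATIONARY_MANDIBLE      15 -74.37520 -36.43390    82.81968                  NA       43.95600    FALSE
#> 2    MID_NECK STATIONARY_MANDIBLE      15 -44.33894 -27.53676    52.19401                  NA       56.49325    FALSE
#> 3         AOJ STATIONARY_MANDIBLE      15 -14.30268 -18.63961    23.49471                  NA       69.22254    FALSE
#> 4         TMJ STATIONARY_MANDIBLE      15   0.00000   0.00000     0.00000                  NA       75.00000     TRUE
```

A 15° ventral rotation at the caudal neck, mid-neck or AOJ drags the
TMJ 83, 52 or 23 mm ventrally (each exactly `2 r sin(7.5°)` for its
pivot distance), so the stationary-mandible premise of the neck-powered
bite fails at every pivot except the TMJ itself.  Letting the mandible
swing freely instead quantifies the same failure:

```r
apply_trial(bulldog, rotation_trial("CAUDAL_NECK", 15, "FREE_RETURN_TO_VERTICAL"))
#> Rotation trial: pivot CAUDAL_NECK, arc 15.00 deg ventral, policy FREE_RETURN_TO_VERTICAL
#>   TMJ displacement: 82.820 mm (dx -74.375, dy -36.434)
#>   mandible return rotation: 15.000 deg dorsal
#>   mandible 0.000 deg from vertical; feasible: TRUE
```

The mandible needs a dorsal rotation exactly equal to the arc to return
to vertical — it was translated, never re-oriented, by the neck
rotation.  The lever comparison:

```r
lever_report(bulldog)
#>             label class in_lever_mm out_lever_mm         MA
#> 1      shear_bite     3   38.971143     222.5608 0.17510333
#> 2            c1lm     1  175.559081     134.7951 1.30241429
#> 3 mandibular_bite     3    2.773501     134.7951 0.02057568
```

The neck-powered shear bite is a Class 3 lever (effort between fulcrum
and resistance); the forelimb-powered mechanism is a Class 1 lever
sharing fulcrum (TMJ) and out-lever with the ordinary adductor bite, so
their MA ratio equals their in-lever ratio (here 175.6 / 2.8 ≈ 63; the
absolute values are plumbing — the identity and the ordering are the
claims).  Finally the strike:

```r
traj <- strike_trajectory(bulldog, 90, steps = 90)
traj
#> Strike trajectory: 91 states over 90.00 deg; gape 90.00 -> 0.00 deg
#>   canine tip radius about the virtual point: 110.000 mm
mmHg_to_N_per_mm2(120)
#> [1] 0.01599864
```

The canine tip stays on its 110 mm curvature circle while the gape
closes linearly to 0°, and the carotid collapse pressure of 120 mm Hg
converts to ≈ 0.016 N/mm².

A command-line wrapper is installed at `inst/cli/saberlever`
(subcommands `generate`, `gape`, `rotate`, `feasibility`, `lever`,
`strike`, `convert-pressure`), and `export_svg()` writes superposition
scenes of configurations, four-pivot experiments and strike frames.

## Documentation

See the methods vignette (`vignettes/saberlever-methods.Rmd`) for the
model, its assumptions, parameter conventions, numerical choices and
limitations.
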