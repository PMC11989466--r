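---
title: "Joint-volume quadrants and impingement-limited motion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint-volume quadrants and impingement-limited motion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`glenovol` quantifies how reverse-shoulder-arthroplasty (RSA) glenosphere
design — diameter, lateralization, inferior eccentricity — changes the free
periprosthetic joint volume and the bony-impingement-limited range of
motion. This vignette documents the models, the parameters that matter, the
numerical choices, and what the synthetic generators do and do not emulate.

## The glenoid frame and the seven designs

All constructions are anchored in a glenoid frame: the **entry point** (the
center of the baseplate stud hole), a **lateral** axis (the
total-least-squares normal of the annotated reamed-face points, oriented
away from the bone centroid), a **superior** axis (the in-plane projection
of an annotated superior hint) and an **anterior** axis completing the
frame. For left shoulders the anterior axis is mirrored so that
anteroinferior/posteroinferior labels remain anatomically consistent; the
spatial placement of a specimen never affects any result (a property the
tests check explicitly).

The seven designs combine diameter D ∈ {36, 42} mm, lateralization
λ ∈ {0, 5, 7, 10} mm and inferior eccentricity ε ∈ {0, 2} mm, named
`36+0 … 42+10`. The sphere center is

    center = entry + λ·lateral − ε·superior.

## Joint volume: region convention and estimator

The joint region for a design is the set of points

* inside the ball of radius D/2 about the sphere center,
* on the medial side of the cut plane with normal `lateral`,
* outside the scapula mesh.

Two cut-plane conventions are provided. The default, `center_cut`, passes
the plane through the **sphere center**: lateralization then slides the
half-ball off the bone and eccentricity slides it past the inferior rim, so
free volume grows with both — the directionality cadaveric gain tables
report. The alternate `baseplate_cut` mode passes the plane through the
entry point (the literal "cut the sphere at the reamed face" reading); the
two coincide for centered spheres but the literal mode keeps only the deep
medial cap of a lateralized sphere and cannot produce volume gains under
lateralization. Which mode produced a result is recorded in its metadata.
Whether the original cadaveric protocol subtracted bone and where its cut
plane passed is not decidable from the protocol text alone; the discrepancy
is documented rather than resolved, and both modes are first-class.

Volumes are estimated by Monte Carlo sampling of the ball's bounding box:
`volume = box_volume × hit_fraction`, standard error
`box_volume·√(p(1−p)/n)`. The region is an intersection of a ball,
half-spaces and the complement of a mesh; predicates compose robustly where
exact mesh booleans are fragile, which is why sampling was chosen as the
volumetric backend. All four quadrants (assigned by the signs of the
superior and anterior coordinates relative to the entry point, ties to the
inferior/anterior side — a zero-measure convention fixed for determinism)
are counted from **one shared sample**, so AI + PI + AS + PS equals the
total exactly and inferior = AI + PI by construction, not re-estimation.

Default `n_samples = 2×10⁶` gives a relative standard error below ~0.5% at
the 2,500–7,500 mm³ scales of interest; the cohort-level tests and examples
use 1–4×10⁵ samples (SE ~1–2%), which is ample for ordering properties and
keeps the full 7-configuration × 10-specimen pipeline near a minute.
Membership queries within ~10⁻⁶ mm of a surface are an explicitly
undefined-behaviour band (the ray-parity kernel retries grazing rays along
alternate directions and reports such points as outside).

## The humeral component and the sweeps

The humeral side is a simplified parametric solid of revolution: a
spherical socket whose inner surface is concentric with the glenosphere
(inner radius = sphere radius), a conical metaphysis and a cylindrical stem
stub, posed at a 155° neck-shaft angle. Two modelling decisions deserve
justification:

* **Socket coverage.** The liner is shallow: its polyethylene depth is held
  fixed (default 4 mm), so angular coverage is `acos(1 − depth/R)` —
  smaller on the 42 mm sphere than on the 36 mm one, as a fixed-depth
  insert dictates. The +6 mm insert rise is modelled as additional coverage
  along the sphere surface (`rise/R` radians), because a cylindrical rim
  extension would lie inside the glenosphere envelope, which is not
  physical. With a deep (≥60° half-angle) shell at 155° inclination the rim
  would sit medial of the reamed face plane at every elbow-at-side pose and
  every centered design would measure 0° mobility — inconsistent with the
  cadaveric pattern the simulator emulates (mean ER1 ≈ 32° for the centered
  36 mm sphere, adduction deficits of 5–17°). The effective coverage is
  ~54° for 36 mm and ~52° for 42 mm spheres; all dimensions are parameters
  of `humeral_config()`.
* **Pose model.** Both sweeps are rigid rotations about axes through the
  sphere center (the joint constrains the cup center there): abduction in
  the scapular plane about the anterior axis, axial rotation about the
  humeral shaft axis. Rotation is neutral when the socket tilt lies in the
  scapular plane, matching a forearm perpendicular to that plane. The sweep
  plane for adduction is the scapular plane.

`max_rotation` and `max_adduction` scan in 5° steps from a collision-free
start (rotations at 20° abduction — a deliberately low elevation at which
rotational conflicts with the pillar appear; adduction from 20° downward)
and bisect the first colliding bracket to 0.25°, finer than protractor
resolution at modest cost. The rotation ceiling is 150°, the adduction
floor 40° past vertical. Adduction is reported with the cadaveric sign
convention: negative when contact occurs while still abducted (a deficit),
positive past vertical. Collision is bony contact only — an edge of one
watertight mesh crossing a face of the other, or full containment — with no
soft-tissue model (the emulated protocol is a passive cadaveric one, and
soft tissue is its acknowledged limitation too).

## Synthetic scapulae

`generate_scapula()` builds a watertight parametric bone: a flat circular
reamed face (default radius 13.5 mm) on a glenoid vault whose
anteroposterior half-width follows an elliptical, pear-shaped outline
toward the inferior rim; behind the face the vault narrows over a few
millimetres to a thin blade; below the rim the bone steps medially by the
**scapular-neck recess** (default 7.5 mm over a 5 mm band) and then recedes
at the **pillar angle** (the dihedral between face plane and pillar
surface, default 120°, admissible range 80–130°) while narrowing to the
pillar half-width (6 mm). Larger pillar angles and deeper recesses are the
"favorable" morphologies that open inferior joint space — the tests assert
that a 120° pillar strictly beats a 90° one for the centered 36 mm sphere.

These defaults were calibrated once so that the geometric pipeline
reproduces the structure the package is designed to study: per-specimen
inferior volumes strictly ordered
`36+0 < 36+2 < 36+5 < 36+7 < 42+0 < 42+7 < 42+10`, and ER1/adduction
non-decreasing in measured joint volume on a fixed specimen. Two
couplings drove the calibration and are worth recording. First, the
2 mm-eccentric design gains volume from the openness immediately below the
rim while lateralized designs gain from sliding off the vault; a bone model
that is too open below the rim ranks `36+2` above `36+5`. Second, the
centered 42 mm sphere must beat the 7 mm-lateralized 36 mm sphere both in
volume (its larger ball wraps around the thin pillar) and in mobility (its
fixed-depth liner covers a smaller angle); the neck recess is the lever
that differentiates its deeper contact point from the 36 mm rim's shallow
one. With the defaults, per-config inferior volumes come out at roughly
2,650–7,600 mm³ — the same scale as published cadaveric means, though no
absolute value is fitted or asserted anywhere.

The geometric cohort draws face radius U(13, 16) mm, pillar angle
U(95, 120)°, pillar offset U(2, 5) mm and neck recess U(5, 8) mm, with
sides alternating right/left; it emulates inter-specimen variability of the
*favorability* of anatomy, not statistical shape variation of real
scapulae — no real-bone validation is implied by its tests passing.

## The parametric cohort and its calibration

For statistics at thousands of replicates, `generate_statistical_cohort()`
bypasses geometry. Per configuration, inferior volume is drawn from a
normal truncated at the published per-configuration min–max envelope with
σ = range/4; because those envelopes are asymmetric about the published
means, the location parameter is solved (by `uniroot`) so the **truncated**
mean equals the published mean exactly. The anteroinferior share of the
inferior volume is the published share plus N(0, 0.03) noise (clamped to
[0.2, 0.8]), and PI = inferior − AI, so additivity is exact. Mobility
follows a monotone linear link on inferior volume,
`rom = a + b·volume + N(0, 15°)`, with slope and intercept the
least-squares fit through the seven published (volume mean, mobility mean)
pairs — for ER1, b ≈ 0.0107 °/mm³ — clamped to instrument bounds
(rotations [0, 150]°, adduction [−40, 40]°). A `link_slope = 0` override
gives the null model used for calibration tests. The linear-link choice is
the weakest assumption consistent with the published monotone scatter; no
functional form stronger than monotonicity is claimed.

## Nonparametric machinery

* `mann_whitney_mc` / `kruskal_wallis_mc`: midrank U and tie-corrected H,
  with two-sided Monte Carlo permutation p-values
  `(b + 1)/(n_iter + 1)` (default 10,000 iterations). On enumerable
  instances the tests verify agreement with exhaustive permutation within
  3 binomial standard errors, and type-I error 0.05 ± 0.02 over 1,000 null
  replicates.
* `pairwise_matrix`: the 21 pairwise comparisons across the 7 designs as an
  upper-triangular matrix with unit diagonal. Published pairwise tables cap
  values at 1.000, suggesting an adjustment whose method is unnamed; the
  default is Holm's step-down over the 21 pairs with an unadjusted mode,
  and the choice is recorded in the result's attributes.
* `gains_table` / `volume_gain`: integer percentage gains
  `100·(mean − ref)/ref`, rounded half away from zero (the rule under
  which the published integer tables reproduce from the published means —
  with one caveat: the inferior gain of the 7 mm-lateralized 36 mm sphere
  computes to 64.4985 → 64 from the printed means, while the source table
  prints 65; no consistent nearest-integer rule yields both that cell and
  the others, so the printed means and printed gains are mutually
  inconsistent by one unit there, and this package reports 64).
* `find_threshold`: scans candidate thresholds on a 100 mm³ grid, keeps
  candidates leaving ≥2 points on each side, and selects the split with the
  largest tie-corrected standardized U (ties toward the smallest
  threshold); the reported threshold is rounded to 500 mm³ for clinical
  readability. Selecting by raw Monte Carlo p is unusable here — with
  strong volume–mobility links the MC p floors at 1/(n_iter+1) across
  dozens of candidates and a smallest-tie rule would return an arbitrary
  low candidate — hence the deterministic selection statistic.
  Significance is a **scan-corrected** max-statistic permutation p: each
  permutation of the volume/mobility pairing recomputes the maximal |Z|
  over the entire grid, so the reported p accounts for the threshold having
  been chosen by the scan. On null data this p is calibrated (a naive
  per-split p after scanning ~60 candidates is optimistically small); on
  the calibrated cohort the detected thresholds are 5,000 mm³ (inferior)
  and 2,500 mm³ (anteroinferior) with p < 10⁻⁴.
* `summarize_values`: min, quartiles, mean, max with inclusive
  linear-interpolation quartiles (`quantile` type 7); the convention is
  stated because the emulated protocol does not name one.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed and restores the caller's
RNG state; identical inputs and seeds give bit-identical outputs (volumes,
p-values, CSV files). The shipped tests run the geometric cohort at 10
specimens × 2×10⁵ samples, analytic oracles at 2×10⁶ samples, permutation
tests at 10³–10⁴ iterations, and calibration at 1,000 replicates × 999
iterations — sizes chosen so the full suite completes in minutes while
keeping Monte Carlo error far below every asserted margin.

## Known limitations

* The humeral component is a revolved simplification: no greater-tuberosity
  geometry, no retroversion adjustment, and an axisymmetric stem stub along
  the neck axis; only rim/metaphysis contact is meaningful.
* ER1 and IR1 coincide on the default synthetic scapula because the bone
  model is anterior–posterior symmetric; real glenoids are not, and the
  published ER1/IR1 asymmetry is not emulated.
* The synthetic generators reproduce orderings and threshold structure, not
  absolute cadaveric values; the published per-configuration means and the
  published pairwise p-values depend on specimen geometries that are not
  available and are used here only as calibration constants and direction
  checks.
* No soft tissue, scapulothoracic motion, or abduction/elevation envelopes.
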