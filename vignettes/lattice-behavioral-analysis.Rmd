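---
title: "Lattice-computing analysis of behavioral states from face-landmark session logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lattice-computing analysis of behavioral states from face-landmark session logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcbehave)
```

## The problem

In robot-assisted interventions for children on the autism spectrum, a
humanoid robot logs its own actions (animations, sounds, eye LEDs, speech)
alongside 68 facial landmarks of the child at 3 Hz. `lcbehave` turns those
logs into a quantitative account of the child's behavior: it represents
each detected face as a hierarchical tree of polar features, classifies it
into one of nine head poses, induces data-driven *behavioral states* by
clustering, and relates robot-action *events* to the resulting state
dynamics. No manual behavior annotation is required anywhere in the
pipeline.

## The face tree

A face observed as 68 landmarks is reduced to a 59-node tree. The root is
the nose, defined by its bridge-top and tip landmarks; the top-to-tip nose
vector is the unit of measurement. Eight *primary* features radiate from
it: the two eye centers (centroids of the 6-point eye contours, measured
from the nose top), the mouth center (centroid of the 12-point outer mouth
contour, from the nose tip), and the five lower-nose points (from the nose
tip). Fifty-one *secondary* features hang off the first three primaries:
eye contour + brow (11 nodes per eye) and outer mouth + jaw (29 nodes),
each the vector from its parent's endpoint to the raw landmark. Every
vector is stored as a nondimensional length `r` (divided by the nose
length) and an orientation `phi` (relative to the nose direction, wrapped
to [-pi, pi]), which makes the representation invariant to uniform
scaling, rotation and translation — and anonymous, since the original
geometry cannot be recovered.

Two constructions deserve a note, because the published description of the
representation leaves them open:

* the secondary mouth group uses the outer mouth (12 points) and the jaw
  (17 points), excluding the 8 inner-mouth points; the verbal description
  mentions the inner mouth, but only 29 mouth-group nodes are consistent
  with the stated total of 51 secondary features and with the per-branch
  index spans of the distance expansion. We follow the arithmetic.
* "left" means image-left. The convention is immaterial as long as the
  generator, the prototypes and the classifier share it.

## The lattice distance

Each node of a tree carries an interval pair: `[a, b]` for `r` and
`[c, d]` for `phi`. A *trivial* tree (one face) has all intervals
degenerate; a genuine *interval tree* is an information granule — a
neighborhood of faces, such as a head-pose prototype. The per-node
distance uses the positive valuation `v(x) = lambda * x` with the dual
isomorphism `theta(x) = 1 - x`, which reduces to the weighted L1 form
`lambda * (|a - c| + |b - e|)`. Branch distances accumulate from the
leaves to the root: a primary node's own term plus `k1`/`k2`/`k3` times
the sum of its children's terms. The tree distance sums the eight branch
distances separately for `r` and `phi` and combines the two parts as
`k_r * D_r + k_phi * D_phi`; the normalized nose root contributes zero.
That gives 126 tunable nonnegative weights in total (2 x 59 lambdas, 2 x 3
hierarchy weights, 2 combiners), all defaulting to 1 (the plain linear
case).

Numerical notes:

* the whole hierarchical distance collapses to a flat weighted L1 over the
  118 interval endpoints; the package's vectorized classification and
  clustering paths use that closed form, and the test suite pins it
  against the explicit leaf-to-root recursion to 1e-9 relative error.
* `phi` is treated as a linear, non-circular quantity inside the distance,
  exactly as the valuation formulas state. Faces whose features straddle
  the ±pi cut would be judged farther apart than the circular geometry
  suggests; with the nose-relative convention used here, real faces keep
  their `phi` away from the cut, so the linearization is harmless in
  practice but is a known limitation.
* distances are not invariant under a joint rescaling of *all* weights:
  the hierarchy weights multiply child lambdas, so a joint rescale by `c`
  scales primary terms by `c^2` and child terms by `c^3`. Rescaling only
  the lambdas, or only `k_r`/`k_phi`, scales every distance uniformly and
  leaves every nearest-prototype decision unchanged.

## Head-pose prototypes and metric learning

Nine head poses are used, numbered 0-8 (Front, UpperLeft, Up, UpperRight,
Right, LowerRight, Down, LowerLeft, Left); Front is split into three
subclasses (FrontLeft, FrontProper, FrontRight), giving 11 prototypes.
A prototype is the per-node min-max envelope of its class's training
trees, so every training tree lies inside its own prototype by
construction. Classification assigns a tree to the closest prototype
(ties to the lowest prototype index — a deterministic choice the source
material does not prescribe), and the three Front subclasses merge to a
single reported Front label.

The 126 metric weights are tuned by a real-coded genetic algorithm whose
fitness is the stratified k-fold cross-validated accuracy; folds are
re-stratified per seed, prototypes are re-induced on each training split
only (avoiding leakage — another choice left open by the source), and a
chromosome is the flat vector of the 126 weights bounded in [0, 10].
Operator settings are not prescribed either; we use tournament selection
(size 3), uniform crossover (rate 0.9), per-gene Gaussian mutation
(sigma 0.5, rate 1/126) with clipping, and a single elite carried over, so
the best-so-far fitness is non-decreasing. Fitness values are cached per
chromosome (the fold split is fixed by the seed, making fitness a pure
function of the genes). The full-scale setting is a population of 500 for
50 generations; the package default (50 x 10) is a desk-scale choice that
the test suite exercises end to end.

## Behavioral states

States are induced by k-means over the trivial trees of all complete
frames, under the lattice distance, initialized at the 11 prototype
midpoint trees. The centroid update is the per-coordinate arithmetic mean
— the classical k-means update, kept for fidelity even though the
weighted-L1 geometry would make the median the exact minimizer (a
`update = "median"` switch is provided; the empirical objective decreases
under both on all tested corpora, and the suite asserts it). Assignment
ties go to the lowest cluster index and an emptied cluster keeps its
previous centroid; iteration stops when assignments stabilize or after
300 rounds. The 11 clusters merge onto 9 states exactly as the pose
subclasses do, so cluster counts are conserved under the merge.

## The four analysis tools

1. **Modality histograms** — the normalized distribution of states over
   the complete frames during which a modality is active (Animation: any
   value other than `None`; Sound/LEDs/Speaking: `yes`). Read as an
   empirical probability mass function of the child's state conditional
   on the stimulus.
2. **Event-triggered transitions** — an *event* is the outset of a robot
   action (inactive-to-active transition scanned over the complete-frame
   series). A transition occurs at event time `k` iff
   `s[k-1] != s[k+lag]`, `lag` in {1, 2, 3} to allow for response delay;
   it is labeled by the two-digit string `ab`. Events too close to the
   series boundary are skipped, not clamped.
3. **State time series** — the per-frame state sequence of an attempt with
   explicit gap markers at frames where no face was detected, exportable
   to CSV and plotted.
4. **Pattern mining** — the state series is read as a string over 0-8;
   substrings that collapse to the same symbol sequence after removing
   successive repetitions of up to 3 (a run of up to three repeats at
   3 Hz is the same behavior at a different speed) form an *equivalence
   class*. An occurrence is a window of exactly 3 maximal runs with 3
   distinct states and all run lengths at most 3; windows are maximal, so
   an occurrence of `8066` is not additionally counted as `806`, and
   per-class totals are the sums of their variants' counts. The window
   length and distinctness threshold are configurable for generality.

## What the synthetic generator emulates — and what it does not

The generator stands in for data that cannot be redistributed: labeled
head-pose stills and clinical session logs.

* **Poses.** A fixed 68-point 3D face template (anatomically plausible
  constants shipped with the package) is rigidly rotated by per-pose
  yaw/pitch presets (±35° yaw, ±25° pitch; Front subclasses at -8/0/+8°
  yaw), orthographically projected, and jittered per landmark with
  Gaussian noise scaled by the inter-ocular distance. The four noise
  presets (0.5%, 1%, 2%, 3%) emulate the *ordering* of difficulty of the
  near/far x normal/dim recording conditions, not their absolute
  accuracies.
* **Sessions.** Robot-action schedules are two-state (off/on) processes
  per modality; the child's state follows either a sticky Markov chain
  over 0-8 whose rows are pulled toward Front for a fixed number of
  frames after every event (the `boost`), or an iid draw with a known
  conditional distribution while a modality is active — the latter makes
  the modality-histogram recovery test exact up to binomial sampling
  error. A configurable fraction of frames has the landmarks blanked to
  emulate failed face detection.

Passing tests on these data demonstrate the *mechanics* — envelope
soundness, classification, clustering, counting — under controlled
geometry. They do not demonstrate robustness to real-world landmark
failure modes: occlusion, expression-driven non-rigid deformation,
perspective distortion at 40 cm, or detector-specific bias. The pipeline
consumes landmarks; it does not detect them.

## Problem sizes and defaults

Defaults mirror the study conditions where stated: 3 Hz sampling, 9 poses
with Front split in 3 (11 prototypes), 100 stills per pose for prototype
induction at full scale, 10-fold cross-validation, GA bounds [0, 10] with
population 500 x 50 generations at full scale. Package test runs use the
same machinery at desk scale — around a dozen stills per subclass,
sessions of a few hundred frames, GA populations of 10-50 for 5-10
generations — sizes chosen as this package's own trade-off between
coverage and turnaround, and stated here rather than hidden in the tests.

## Known limitations

* The linearized `phi` near ±pi, discussed above.
* The mean-update k-means is a heuristic under the L1 geometry; the
  objective decrease is asserted empirically, not guaranteed.
* Interval envelopes are axis-aligned min-max boxes: outliers in a
  training class inflate the prototype irreversibly (no trimming is
  applied, matching the source procedure).
* The event/transition machinery indexes the complete-frame series, so a
  face-detection gap immediately before or after an event changes which
  frames `k-1` and `k+lag` refer to; this matches the stated counting
  contract but means transition counts are sensitive to detection
  dropouts.
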