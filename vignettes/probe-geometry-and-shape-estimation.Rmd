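---
title: "Probe geometry, multiplexing schedules, and IMU-based shape estimation"
author: "fnirsprobe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe geometry, multiplexing schedules, and IMU-based shape estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsprobe)
```

## The problem

Modular fNIRS probes are assembled from repeating circuit modules, each
carrying light sources, detectors, and an orientation sensor (IMU), wired to
its neighbors by short flexible cables. Three planning questions recur for
every probe built this way:

1. **Which source-detector pairs form usable channels?** Light launched more
   than ~35-50 mm from a detector is too attenuated to use, so the channel
   list depends on the geometry of the assembled probe, not just on the
   modules.
2. **How fast can the probe acquire a full frame?** Turning on every source
   in sequence is safe but slow; sources far enough apart can be lit
   simultaneously (spatial multiplexing), and the achievable speed-up
   depends on the conflict structure of the layout.
3. **Where are the optodes in 3D?** Tomographic reconstruction needs 3D
   optode positions. Each module's IMU reports its orientation as a unit
   quaternion; combined with the known connection topology and cable
   lengths, these orientations determine the 3D shape of the worn probe
   without an external digitizer.

`fnirsprobe` implements all three, plus a synthetic-data generator that
places probes on analytic surfaces with exact ground truth so that every
algorithm can be validated end to end without hardware.

## The module

The canonical module is a diamond (two equilateral triangles of side
50 mm joined on their short diagonal) carrying three dual-wavelength
(735/850 nm) LED sources and two photodiode detectors. Module-local
coordinates put the origin at the module center, x along the short axis, y
along the long axis, z along the outward normal.

The published design quotes the six intra-module source-detector
separations — one 8 mm, four 24.5 mm, one 30 mm — but not the optode
coordinates. The coordinates used here are *derived*: requiring (i) the
distance multiset above, (ii) mirror symmetry about the long axis, and
(iii) D1, D2, S3 collinear on the long axis (consistent with the published
module photographs) fixes the layout uniquely:

```{r}
spec <- default_module_layout()
intra_module_channels(spec)
```

Alternative layouts can be supplied through `module_spec()`; everything
downstream consumes the spec, not the constants.

Two conventions for **channel density** coexist in the field: counting each
dual-wavelength pair once (6 channels / 21.65 cm² = 0.28 cm⁻²) or once per
wavelength (12 / 21.65 = 0.55 cm⁻²). Neither reproduces every printed
figure exactly, so `channel_density()` reports both, flagged.

Connector **ports** sit at the four diamond-edge midpoints with the edge's
outward normal as their direction. Exact port positions are not published;
only the port *directions* (for the 2D fold-out) and the port *pairing*
(for topology and the planar constraint) affect any computed quantity,
because inter-module spacing is supplied per cable as a center-to-center
distance (55 mm for the standard cables).

## Topology and the 2D fold-out

The hardware discovers connectivity electrically; this package starts from
the equivalent declarative description, a `wiring_list()` of
(module, port, module, port, distance) records. `discover_topology()`
validates it (each port used once, at most four neighbors, one connected
probe) and selects a reference module — by default a graph center, the
natural choice since estimation error grows with hop distance from the
reference.

`fold_out_2d()` places modules in the plane breadth-first from the
reference: each neighbor at its cable's center distance along the
connecting port's direction, rotated so its own connecting port points
back. Traversal order is ascending module id, so layouts are reproducible.
The fold-out is the coordinate space for multiplexing analysis; it is also
exactly what the 3D estimator produces in the flat limit, which is used as
a consistency test.

## Channels, conflicts, and frame rates

`enumerate_channels()` lists all source-detector pairs within the SDS
threshold (default 35 mm, the operating threshold for short-cable probes;
50 mm is typical when planning full-head coverage with longer usable
channels).

The **conflict rule** for simultaneous illumination is not published as a
formula; the rule adopted here is *shared detector*: two sources conflict
iff some detector holds a valid channel to both, because that detector
could not attribute simultaneously arriving light. This is the default; a
pure source-source distance rule is available
(`build_conflict_graph(rule = "source_distance")`) for comparison.

`assign_smgs()` colors the conflict graph greedily, largest degree first,
ties broken by source id — a deterministic, practical scheduler rather than
an exact minimum coloring. An exact branch-and-bound chromatic-number
oracle ships for small graphs and is used in the tests; on open-chain
(interval-like) probes the greedy result matches it.

The **timing model**: one illumination slot must cover both wavelengths and
an interleaved dark measurement,

t_slot = 7.5 ms x 2 wavelengths x 2 (signal + dark) = 30 ms,

and the full-frame rate is `1000 / (count x t_slot)` with count = number of
sources (sequential) or number of groups (multiplexed). The 30 ms slot is
not printed anywhere; it is validated by reproducing two independently
printed rates (11 Hz for a single 3-source module and 2.2 Hz for 15
sequential sources), and it further reproduces 2.4 Hz at 14 groups and
4.8 Hz at 7 groups. IMU sampling is treated as absorbed into the slot.
Report displays round to 2 significant figures (the convention used for
such rates); raw values are always retained. Note one published table
entry (6.6 Hz for 15 sources in 5 groups) is the *rounded* sequential rate
times the speed-up (2.2 x 3.0); the unrounded value is 6.67 Hz and rounds
to 6.7.

## Shape estimation

### The piece-wise spherical model

Each module's IMU gives a unit quaternion q (module frame to world); the
module normal is n = q (0,0,1) q*. For two adjacent modules R and P, the
surface between them is approximated by a sphere. The bending angle theta
between their normals and the cable's center-to-center length L give its
radius

r = L / theta,

and the neighbor's center follows by

p_P = p_R − r (n_R − n_P).     (center propagation)

On a common sphere of radius R this is *exact*: every center satisfies
p = c + R n, so differences of normals translate centers without error.
`estimate_probe_shape()` applies this breadth-first from the reference
module.

**Bending angle, not full rotation angle.** The geodesic angle of the
relative quaternion q_R⁻¹ q_P equals the bending angle only when the two
modules are not twisted relative to one another about their normals. A
connection through non-opposite ports (any bent probe, including the
V-shaped evaluation probe) *is* such a twist, and feeding the full relative
angle into r = L/theta would collapse the radius estimate. The
implementation therefore uses the angle between the normals,
acos(n_R · n_P) — the swing component of the relative rotation, identical
to the full angle for straight connections, and the quantity the
propagation formula's geometry actually involves. `rotation_angle()`
(the full geodesic angle) is still exported for orientation analysis.

### Degenerate cases

The propagation is singular as theta → 0. Below eps = 1e-4 rad
(~0.006°, far below any IMU's noise floor) the pair is flagged flat and
the neighbor placed at the cable length along the connecting port's world
tangent direction, which is the exact limit of the spherical formula. The
quaternion sign ambiguity (q and −q encode the same rotation) is resolved
by hemisphere-aligning all quaternions to the reference's.

### Planar constraint

Modules wired in a straight line — each interior module entered and left
through opposite ports — physically lie in a common plane, and noisy
normals are regularized accordingly: for each maximal straight chain, the
pairwise planes spanned by an anchor module's normal and each member's
normal are averaged (via their unit plane normals, sign-aligned), each
member normal is projected onto the average plane and renormalized, and
centers are recomputed from the reference with the adjusted normals. The
anchor is the chain member nearest the reference (the reference itself
when it lies on the chain). Plane-*normal* averaging was chosen over
fitting a plane through estimated centers because it needs no provisional
centers; the alternative is noted as a possible refinement. Chains shorter
than three modules carry no constraint and are skipped. On noiseless
spherical data the chain normals are already coplanar and the constraint
is a no-op, preserving exactness.

### Optode placement

Each optode's 2D offset (x, y) from the module center is an *arc length*
d = sqrt(x² + y²) over the local sphere, whose radius is the mean of the
module's incident pairwise radii:

p_opt = center + r [(cos(d/r) − 1) n + sin(d/r) t],

with t the in-plane direction (x, y)/d rotated by the module quaternion
(and re-orthogonalized against the possibly constraint-adjusted normal).
The quaternion — not the normal alone — is needed here: a normal leaves the
in-plane spin of the module undetermined. Isolated modules (no incident
cable, hence no radius) fall back to flat placement with a warning.

### Evaluation

`compare_positions()` registers an estimate to digitized positions either
by the reference module (translation only — orientations are already
world-referenced; this mirrors the hardware evaluation protocol) or by a
full least-squares rigid fit (Kabsch), and reports per-optode, per-module,
and probe-mean Euclidean errors. `fit_sphere_center()` recovers a phantom
sphere's center from landmarks digitized along its equator (plane fit, then
least-squares circle), and `conformity_stats()` summarizes optode radial
distances against the expected value — surface radius plus module
thickness, e.g. 100 + 5 = 105 mm for a 100 mm hemisphere: module optodes
ride on top of the 5 mm-thick module body, so a perfectly conforming probe
digitizes at the outer surface.

## The synthetic generator

`place_on_surface()` walks the probe over an analytic sphere or plane along
geodesics: the reference module sits at the anchor (sphere top by default)
with local z mapped to the surface normal, and each neighbor is placed at
its cable's arc length along the connecting port's direction, with a
quaternion constructed so its own port points back along the geodesic and
its z axis matches the arrival normal. Optodes are placed by the same
arc-length construction the estimator uses.

What this emulates — and what it does not:

* Geodesic walking makes the piece-wise spherical model *exact* on the
  sphere, so noiseless recovery isolates implementation error from model
  error. Passing the 1e-6 mm recovery test therefore validates the
  propagation algebra, not the model's adequacy on real heads, which are
  not spheres.
* `add_orientation_noise()` models IMU error as a random small rotation
  (uniform axis, Normal(0, sigma) angle) composed onto each quaternion.
  Real IMU errors are not isotropic (heading drifts more than inclination)
  and are temporally correlated; neither is modeled.
* `emit_digitizer_file()` adds isotropic Gaussian jitter per digitization
  pass. The 1.8 mm default used in examples matches the repeat spread
  reported for a handheld digitizer on a phantom, as a plausibility anchor.
* A physical probe bends only approximately along great circles, cables
  flex, and silicone couples modules — none of which is simulated. The
  published phantom-test figure (~4 mm mean optode error) therefore cannot
  be reproduced synthetically and is not asserted anywhere; the synthetic
  noise sweep shows the *shape* of the degradation (monotone in sigma,
  ~2 mm at sigma = 2°) rather than a hardware error budget.

The V-shaped five-module probe used in the published evaluations ships as
`v_probe_topology()`. The exact port wiring of the physical V is not
published; the fixture's assumption (arms through ports 4-2 and 1-3,
meeting at module 3 with a 120° opening) is documented in its help page.
Notably, this fixture at the 35 mm threshold yields 38 channels and 5
multiplexing groups — the same counts as the published first example
layout.

## Numerical choices

* Flat-surface threshold eps = 1e-4 rad; below it, radii are `Inf` and the
  tangent-limit path is used.
* Greedy coloring tie-breaks by source id; group labels are renumbered by
  first appearance in id order, so plans are stable across runs.
* BFS traversal visits neighbors in ascending module id everywhere
  (fold-out, placement, estimation), making all outputs deterministic.
* `fit_sphere_center()` uses the Kasa algebraic circle fit after an SVD
  plane fit; collinear landmarks (second singular value ~ 0) are an error.
* Frame rates are exact rationals 1000/(n x 30) before display rounding;
  the identity rate x n x t_slot = 1000 holds to machine precision.

## Problem sizes used in the tests

The suite exercises probes of 1-20 modules, property tests over 200
randomly grown tree topologies (3-8 modules), noise sweeps of 50 seeds x 4
noise levels on the five-module V probe, and sphere radii from 80 mm to
1e5 mm (flat-limit checks). These sizes keep the full suite under a minute
while covering every code path; all scale linearly in module count except
the exact chromatic oracle, which is only invoked on probes of at most ~15
sources.

## Known limitations

* The estimator propagates error cumulatively with hop distance from the
  reference; no global optimization or loop closure is performed (cycles in
  the probe graph contribute radii but not constraints).
* The conflict rule is binary; it does not model partial cross-talk or
  detector gain interactions.
* SNIRF export writes probe geometry and a measurement list with a zero
  placeholder data block — no optical time series is simulated.
* Heads are not spheres: the piece-wise spherical model is a local
  approximation, and its adequacy on real anatomy must be judged from
  hardware studies, not from this package's synthetic tests.
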