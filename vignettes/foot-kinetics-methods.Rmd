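---
title: "Multisegment foot kinetics from plantar pressure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multisegment foot kinetics from plantar pressure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footkinetics)
```

## The problem

Multisegment kinetic foot models resolve the external loading of the foot
into moments at individual foot joints — here the ankle, the midtarsal (MT)
joint between hindfoot and forefoot, and the metatarsophalangeal (MP) joint
between forefoot and hallux. A force plate only reports the total ground
reaction at one center of pressure (CoP), so it cannot attribute load to
segments. Pressure grids can: every sensing cell has a known position, so the
cells distal to a joint can be pooled into that joint's external load at
every time point. `footkinetics` implements this pipeline for two
complementary sensors recorded simultaneously during shod walking:

* a **pressure platform** fixed in the laboratory frame (10 mm cells,
  4–1000 kPa), measuring shoe-sole/ground contact pressure, and
* an **instrumented insole** traveling with the foot (≈ 5 mm cells,
  4–862 kPa), measuring foot/shoe contact pressure.

Both devices only sense the *normal* component of contact. Friction is not
measured and is deliberately not modeled; segment weight and inertial terms
are likewise neglected. The external moment about a joint is therefore the
moment of the vertical resultant of the cells distal to it:

$$
\mathbf{M} = (\mathbf{r}_{\mathrm{CoP}} - \mathbf{r}_{\mathrm{JC}}) \times
\begin{pmatrix}0\\0\\F_n\end{pmatrix},
$$

expressed in the proximal segment's coordinate system and normalized by body
mass (N·m/kg). Because all cell forces are parallel, the moment of the
resultant applied at the CoP is *algebraically identical* to the sum of
per-cell moments; the package carries both routes and the test suite checks
the identity to 10⁻¹⁰ relative on random frames.

## Coordinate systems and kinematics

The global frame follows the acquisition convention: origin at the platform
center, +Y anterior, +X lateral, +Z up. Segment frames (shank, hindfoot,
forefoot, hallux) are built from shoe-mounted markers by Gram–Schmidt
orthogonalization of a recipe: an origin marker (or pair midpoint), a long
axis, and a three-marker plane supplying the superior normal. Recipes are
plain data (`default_recipes()`) and deliberately swappable, because marker
models differ between laboratories; the defaults place the flexion axis
laterally (local x), the long axis anteriorly (y) and the normal up (z).

Joint centers default to medial/lateral marker-pair midpoints
(`default_joint_pairs()`): ankle = MC/LC, MT = NV/CU (navicular/cuboid),
MP = H1/H3 (first/third metatarsal heads). Joint angles use a Cardan
sequence — flexion about x, then abduction about z, then inversion about y —
referenced to an upright static posture by premultiplying with the inverse
of the static relative rotation, so the reference posture reads exactly
(0, 0, 0)°. Near gimbal lock (second angle within 10⁻⁶ degrees of ±90°) the
third angle is conventionally zeroed and the result flagged; walking-foot
joints never approach this region in practice.

## Pressure processing

**Force and CoP.** Each frame's resultant is $F_n = \sum_i p_i A_i$ (kPa →
Pa conversion applied; $A_i$ = cell area) and the CoP is the
pressure-weighted mean of cell centers. An all-zero frame yields zero force
with a flagged CoP.

**Stance detection** takes the longest run of frames with total force above
a threshold, defaulting to max(10 N, 1.5% body weight) for at least 3
consecutive frames — standard practice for 100 Hz gait data; the sources do
not fix a value. Trials with stance under 0.2 s are rejected with a warning.

**Insole registration.** Insole cells live in the foot frame and must be
placed in the laboratory frame. One rigid 2D transform is estimated at a
single matching instant 0.1 s after initial contact: the rotation is the
foot progression angle (ground-plane direction of the C1→H2 marker line
versus +Y, positive toe-out to +X), and the translation superimposes the
insole CoP on the platform CoP at that instant. The transform is held
constant over the stance — the loaded foot is quasi-static on the ground,
and re-estimating it after heel-off (when the foot is no longer flat) would
use exactly the frames where the assumption is weakest. The rotation is
exact when markers are clean; the translation inherits the CoP
discretization of both grids, about 1 mm in simulation, and criterion-level
checks bound it by one insole cell pitch.

**Segmentation.** Cells are assigned by comparing their coordinate along the
anteroposterior axis with the joint centers' coordinates: behind the MT
center → hindfoot; in [MT, MP) → forefoot; at or beyond MP → hallux.
Boundaries are half-open with the boundary cell going to the *distal*
segment, a deterministic tie-break consistent with pooling "cells distal to
the joint". Two design choices matter here:

* **Axis.** "Anteroposterior" is ambiguous for a toed-out foot. The default
  axis is the foot's own long axis (C1→H2 projected to the ground plane),
  which is invariant to foot rotation; `segmentation_axis = "global"` falls
  back to the laboratory +Y.
* **Per-frame updates.** Joint-center positions are re-projected every
  frame from the (low-pass filtered) markers, so the boundaries track the
  foot throughout stance.

Per joint, the distal pools are: MP → hallux cells; MT → hallux + forefoot;
ankle → all cells. Nesting $F(\mathrm{MP}) \le F(\mathrm{MT}) \le
F(\mathrm{ankle}) = F_{\mathrm{total}}$ and exact partition of the total
force hold by construction and are asserted on every simulated trial.

## Filtering, normalization, descriptors

Markers are low-passed at 10 Hz and kinetic series at 50 Hz, both with
fourth-order zero-phase (forward–backward) Butterworth filters. Zero phase
matters because the curve descriptors include peak *times*; a causal filter
would bias them. The implementation takes coefficients from
`signal::butter` and applies the two passes itself with odd-reflection
padding (3 × order samples) and steady-state initial conditions, so
constants pass through to 10⁻⁹ and the net gain at the cutoff is exactly
0.5. A 50 Hz cutoff equals the Nyquist frequency at 100 Hz sampling and is
ill-posed in design; the package clips such cutoffs to 0.95 × Nyquist and
warns, keeping the filter as close to the stated setting as mathematics
allows (at 47.5 Hz the pass is nearly an identity on gait signals, whose
energy sits far below 20 Hz).

Moments are divided by body mass (N·m/kg; the figure-axis convention of
this literature, where "body-weight normalization" yields curves of order
1 N·m/kg) and linearly resampled to 101 stations over 0–100% of the
detected stance, endpoints exact. Each curve is summarized by MaxVal/TMax
and MinVal/TMin (first occurrence on ties; smoothed curves make ties
measure-zero). Flexion moments are read at MaxVal/TMax and
inversion/eversion at MinVal/TMin; abduction/adduction curves are computed
but excluded from the default device-comparison report because they are
near zero throughout stance.

Across-subject summaries average trials within subject first (subjects are
the unit of analysis), then report the pointwise mean with a t-based 95%
interval, $\bar x \pm t_{n-1,0.975}\, s/\sqrt n$ — the t rather than the
normal quantile because typical samples are small (n = 10).

## Device agreement

The long-format parameter table (one row per subject × shoe × device ×
trial × joint × motion × parameter; 200 values per parameter in the
standard 10 × 2 × 2 × 5 design) feeds two reliability layouts, both two-way
mixed-effects mean-rating ICCs computed from ANOVA mean squares:

* consistency ICC(3,k) = (MS_R − MS_E)/MS_R, insensitive to a systematic
  device offset;
* absolute agreement ICC(2,k) = (MS_R − MS_E)/(MS_R + (MS_C − MS_E)/n),
  which penalizes it.

The default device-agreement report treats the two devices as k = 2 raters
on per-subject means; `test_retest_icc()` exposes the k = 5 repeated-trials
layout per device. Both are provided because "rating" is genuinely
ambiguous when 2 devices × 5 repetitions are available; the report labels
which layout produced each number. The p-value is the between-subject F
test, MS_R/MS_E on (n−1, (n−1)(k−1)) degrees of freedom.

## The synthetic gait generator

`gait_model()` + `simulate_trial()` generate the full measurement setting
from one continuous pressure field, so every stage of the pipeline can be
validated against exact ground truth without laboratory data. The field is
a mixture of three bivariate-Gaussian loading centers (heel, metatarsal
heads, hallux) whose weights shift smoothly from heel-dominant at contact
to metatarsal/hallux-dominant before toe-off, scaled by a double-hump
vertical force profile built from half-cosine segments: peaks of 1.1 and
1.05 body weight at 25% and 75% stance and a 0.8 body-weight valley —
standard adult walking values; the half-cosine construction attains the
configured extremes exactly (no interpolation overshoot). Default stance is
0.7 s at 100 Hz, body mass 71 kg, foot length 0.25 m with joint axes at
25/45/75% of it, and a 4.6° toe-out.

Both grids sample *the same field*: the platform on its fixed global grid
after transforming cell centers into the foot frame, the insole directly in
the foot frame. Blob widths were chosen as realistic concentrated pressure
areas whose support lies (to > 99%) inside both sensing areas — a
construction requirement, since load escaping the insole's edge would
confound the device comparison with a trivial coverage artifact.
Sensor imperfections are emulated explicitly: range clipping with a
saturation mask, the 4 kPa sensing floor, and additive Gaussian cell noise
(default 2 kPa) applied to loaded cells only — resistive/capacitive cells
read zero when unloaded, and an unconditional noise floor would make an
empty 1600-cell platform register tens of newtons.

Because the blobs are Gaussian, segment integrals, CoPs and moments of the
continuous field have closed forms (truncated-normal moments), so the
ground truth is exact rather than finely sampled; an independent 1 mm
quadrature helper cross-checks it to 0.1% in the tests. A multiplicative
`insole_bias` scales the field seen by the insole, emulating the insole's
incomplete capture of contact forces and enabling in-silico device
comparison experiments with a known injected effect.

`design_models()` draws a whole study: subject-level anthropometrics
(mass ~ N(71, 12) kg, foot length ~ N(0.25, 0.012) m, truncated), gait
style (peak heights, toe-out), a systematic shoe effect (a stiffer shoe B
spreads forefoot load and shifts it laterally), and trial-level jitter in
pose, timing and loading. All draws flow from one seed; repeated runs are
bitwise identical.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: soft-tissue and shoe-sole deformation, marker
motion relative to the foot, heel rise (the synthetic foot stays flat, so
markers are constant over stance and joint angles stay at the reference),
friction, within-stance insole slip, and vendor-specific sensor
nonlinearities. The generator validates the *computational* pipeline, not
the measurement physics.

## Numerical choices and degenerate inputs

* Orthonormality of every frame rotation is enforced to 10⁻⁹; collinear
  plane markers raise a degenerate-geometry error rather than producing a
  near-singular frame.
* Zero-force frames yield zero moment and a flagged CoP; empty distal sets
  yield zero segment force.
* The moment identity (resultant + CoP vs per-cell sum) is exact for
  parallel forces; it is asserted numerically rather than assumed.
* Resampling is linear; with 70 stance frames mapped to 101 stations the
  interpolation error is O(Δt²) and negligible against grid discretization.
* Missing marker samples are flagged, never silently interpolated; gap
  filling is opt-in (`gap_fill`), linear, and limited to 10 frames.
* Test problem sizes: module tests run hundreds of random frames and a
  0.6 s stance; the end-to-end checks run 10³ random frames, 10⁴ Cardan
  triples and one full 10 × 2 × 2 × 5 design (≈ 30 s) — sizes chosen to
  exercise every code path at full design scale while keeping the suite
  fast to iterate.

## Known limitations

Moment arms are measured to the CoP lifted to the ground plane z = 0 for
both devices; sole thickness is not added, which is a comparability caveat
rather than an error (both devices get the same geometric treatment).
Friction and inertial terms are out of scope by design. The C3D container
is not read natively (convert to TRC or the package's CSV). The default
segment recipes stand in for laboratory-specific definitions and should be
reviewed before use with real marker sets.
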