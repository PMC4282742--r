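---
title: "Multi-segment foot kinematics: model, calibration and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-segment foot kinematics: model, calibration and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footkin)
```

## The model

`footkin` implements a four-segment kinematic model of the foot --
calcaneus, midfoot, metatarsus and the proximal phalanx of the hallux --
referenced to the shank, for barefoot walking recorded by
stereophotogrammetry. Its clinical focus is the flexible flat foot
(pes planus), whose two key functional measures are the frontal-plane
alignment of the calcaneus and the behaviour of the medial longitudinal
arch (MLA) across the gait cycle.

All computations take place in a laboratory frame with X along the walking
direction, Y vertical (up) and Z to the subject's right; the ground is the
plane Y = 0. Positions are in millimetres, angles in degrees, rates in Hz.
Left feet are mirrored (Z to -Z) when a trial is read, so that a single set
of sign conventions -- dorsiflexion +, inversion +, adduction +, hindfoot
eversion/valgus offset + -- serves both sides; reports un-mirror the labels
for display.

### Anatomical frames

Each segment frame is built from three skin markers by a common kernel: the
antero-posterior X axis joins an origin landmark to a forward target, the
vertical Y axis is the unit normal of the three-marker plane, and
Z = X x Y completes a right-handed orthonormal triad:

* **Calcaneus**: origin CA (upper posterior calcaneus), X toward the
  midpoint of PT and ST.
* **Midfoot**: origin at the TN--C midpoint, X toward SMB.
* **Metatarsus**: origin SMB, X toward the FMH--VMH midpoint.
* **Phalanx** (hallux): origin FMH, X along FMH to PM, Y normal to the
  PM--FMH--VMH plane. Modelling the hallux as a three-marker 3D segment
  removes the numerical singularities that plague two-marker descriptions
  of the first metatarso-phalangeal joint at push-off; the price is that
  axial rotation of the hallux is not meaningful, so only its sagittal and
  transverse components (F2Ps, F2Pt) are reported.
* **Whole foot**: origin CA, X toward the FMH--VMH midpoint. The *sagittal
  plane of the foot* is the vertical plane through CA spanned by this X
  axis and the lab vertical, and is recomputed at every frame.
* **Shank**: origin at the malleolar midpoint, Y toward the HF--TT
  midpoint, Z the malleolar axis re-orthogonalized, X = Y x Z.

Plane normals are disambiguated "upward" (positive lab-Y) at construction,
which is unambiguous in the near-upright poses where frames are first
built; during walking the sign is instead matched frame-to-frame so a
steep push-off cannot flip a frame. Marker triads with a triangle area
below 1e-6 mm^2 raise a degeneracy error -- orders of magnitude below any
physiological inter-marker spacing, so the bound only catches genuinely
corrupt data.

### Joint rotations

Six joints are decomposed -- Sha-Foo, Sha-Cal, Cal-Mid, Mid-Met, Cal-Met
and Met-Hal -- with a Grood--Suntay joint coordinate system adapted to
segments whose long axis is X: the body-fixed flexion axis e1 is the
proximal Z, the body-fixed axis e3 is the distal X, and the floating axis
e2 = e3 x e1 carries ab-/adduction. Algebraically this is the intrinsic
Z--Y'--X'' Euler factorization of the relative rotation

$$ R_{rel} = R_{prox}^\top R_{dist} = R_z(\alpha)\,R_y(\beta)\,R_x(\gamma), $$

with dorsi-/plantar-flexion $\alpha$, ab-/adduction $\beta$ and
eversion/inversion $\gamma$. The closed-form extraction uses
$\beta = \arcsin(-R_{31})$, $\alpha = \mathrm{atan2}(R_{21}, R_{11})$,
$\gamma = \mathrm{atan2}(R_{32}, R_{33})$; within 1e-6 deg of the
$|\beta| = 90$ gimbal the angles are still returned with a warning. The
forward constructor `jcs_compose()` exists so that tests can verify
decompose-compose round trips and drive the simulator; it is not part of
the analysis path.

### Planar angles

Eight planar angles complement the 3D joints. F2G, S2G and V2G are the
pitches of the 1st, 2nd and 5th metatarsal (base-to-head vector projected
into the foot sagittal plane, head-up positive). S2F and S2V are the
transverse-plane deviations of the 1st and 5th ray from the 2nd, both
projected onto the ground plane, positive toward medial. F2Ps and F2Pt are
the sagittal and transverse Met-Hal components. The choice of the
foot-heading sagittal plane (rather than a fixed laboratory plane) keeps
the metatarsal pitches meaningful when the walking path is not aligned
with the lab X axis, and makes every ground-referenced angle exactly
invariant under vertical-axis rotations and horizontal translations of the
whole scene.

### The arch angle and the virtual heel point

The MLA is measured at the sustentaculum tali: the angle at ST between the
rays to FMH and to CAp, all projected into the foot sagittal plane, where
CAp is the *vertical projection of CA onto the ground* captured during the
static trial. CAp is expressed once in a technical frame built from the
calcaneus triad (CA, PT, ST) and then rigidly tracked through every
walking frame. Because the reference ray ends at ground level, a lowered
arch apex can fall below the CAp-FMH chord; the convention is: interior
angle when ST is dorsal to the chord, 360 minus the interior angle when it
has dropped below. Flat or collapsed arches therefore read at or above
180 deg, matching how the clinical radiographic angle behaves, and the
angle decreases strictly as the arch rises.

Technical frames deliberately use the raw cross-product orientation of
their triad rather than the lab-up disambiguation: only an orientation
intrinsic to the markers tracks a virtual point exactly through arbitrary
rigid motion such as heel rise.

### Static calibration and the hindfoot offset

The static trial (a few seconds of double-leg upright stance) yields three
products. First, the **hindfoot frontal-plane offset**: the angle between
the projection of CA-HL into the shank frontal plane and the shank
vertical axis, time-averaged, eversion/valgus positive. HL sits at the
most distal attachment of the Achilles tendon and is used *only* in the
static trial. This marker-pair measure replaces the frame-derived static
frontal angle as the reported alignment value because the conventional
calcaneus frame is biased toward inversion by the usual landmark heights
(ST sits higher than PT); the frame-based dynamic Eve/Inv curves are still
reported relative to the JCS. Second, CAp and its technical-frame
coordinates. Third, the static reference value of all 15 joint components
and 8 planar angles, computed through the same pipeline as walking data
and time-averaged over all static frames without trimming. Calibration is
persisted as JSON at full double precision so that reload is bit-exact.

Clinical classification uses the offset with inclusive boundaries:
neutral within [-2, +2] deg, valgus above +2, varus below -2. The
boundary itself is assigned to neutral because the three published ranges
leave +/-2 ambiguous; inclusive-neutral is the conservative reading.

## Gait cycle machinery

Events are detected from marker coordinates alone (no force plates): a
foot strike is a local minimum of the heel (CA) vertical trajectory
coincident (within 3 frames, configurable) with a zero crossing of the
heel forward velocity; a toe off is a local minimum of the forefoot (SMH)
vertical trajectory coincident with a negative-to-positive forward
velocity crossing. Candidates must be strict minima of a +/-
quarter-cycle window and prominent by at least 1.5 mm on *both* sides --
one-sided prominence is just the edge of a flat foot-on-ground span.
Candidate timing is then refined by re-centering on the raw (unsmoothed)
signal and fitting a quadratic over the +/-2-frame core of the impact
minimum; the smoothed signal locates events robustly but its minimum is
biased toward the adjacent swing slope, while the sharp raw minimum
carries the timing.

Cycles (strike to next strike) are resampled linearly onto 101 points
(0-100% in 1% steps), endpoints preserved exactly; cycles with more than
20% missing samples are rejected with a warning. Ensembles report the
pointwise mean and sample standard deviation (n-1 denominator, 0 for a
single curve). Per-foot ensembles pool all cycles of all trials of that
foot; the report additionally pools across feet.

## The synthetic-data generator

Because no reference motion-capture data ship with the package, a
forward-kinematics simulator provides ground truth for every inverse
computation. Its design goals, in order: exact segment rigidity, exact
knowledge of joint angles and event times, and event signals that exercise
the detector the way real heel/forefoot trajectories do.

The neutral template is a right foot of 240 mm (scalable) with plausible
landmark positions; the shank markers are laid out so the shank anatomical
frame is exactly the identity, which makes a constructed hindfoot tilt
(applied to the calcaneal cluster about the antero-posterior axis through
ST) appear in the measured offset without approximation. The ST height is
solved by monotone root finding so the template realizes any requested
static MLA exactly; matching the adolescent flat-foot range (around
183 +/- 16 deg) places ST near or below the CAp-FMH chord, a direct
consequence of the ground-referenced arch definition.

Walking is rooted at the calcaneus. The heel trajectory and the forefoot
height are authored in closed form as raised-cosine velocity/height bumps
concentrated in swing, each event carrying a small (4-8 mm) sharp "impact
dip" so that it is a unique, curved vertical minimum with a genuine
forward-velocity zero crossing -- a stylization of the impact transients
of real gait. The forefoot advance is derived from a near-constant
heel-forefoot sagittal chord (the foot pitches rather than stretches), and
the root pitch plus a sagittal midfoot "elbow" are solved per frame by
exact two-link inverse kinematics, so all within-segment distances are
rigid to machine precision while both authored trajectories are honoured
exactly. Joint curves for Sha-Cal, Cal-Mid, Mid-Met and Met-Hal are sums
of 2-3 harmonics with configurable amplitudes (defaults a few degrees,
hallux sagittal up to ~14 deg); they are qualitative, not digitized
reproductions of any published curve. Marker noise is i.i.d. isotropic
Gaussian per coordinate, seeded and reproducible.

Two of the model's frames (midfoot and phalanx) borrow a marker from the
neighbouring segment, so their angles are defined *by the marker
construction*, not by any underlying rigid bone; the generator therefore
stores as ground truth the JCS of the frames built from the exact
noise-free marker positions. The decomposition code itself is validated
independently against a brute-force numerical inversion of the forward
composition (coarse multi-start plus BFGS on the Frobenius misfit), so
this does not make the round-trip checks circular.

What the generator does **not** emulate: soft-tissue artifact (markers are
rigid on their segments), double support mechanics of the contralateral
foot, ground reaction forces, physiologically validated joint waveforms,
or inter-trial variability beyond additive noise. Consequently, passing
the validation suite demonstrates correctness of the geometry, algebra and
signal processing -- not that the pipeline is robust to skin motion or to
pathological gait patterns outside the simulated envelope.

## Numerical choices and default parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| Sampling rate | 100 | Hz | standard optoelectronic capture rate |
| Low-pass cutoff | 6 | Hz | conventional gait-lab smoothing; zero-phase 4th-order Butterworth (two passes of order 2), reflected-end padding with mean removal so constants pass exactly |
| Gap filling | <= 10 frames | frames | interior gaps only, local polynomial through up to 2 support samples per side (exact for cubic trajectories); never extrapolates |
| Event coincidence | 3 | frames | vertical minimum vs velocity zero crossing |
| Event prominence | 1.5 | mm | two-sided; rejects noise wiggles on flat spans |
| Cycle grid | 101 | points | 0-100% in 1% steps |
| Cycle missing-data cap | 20 | % | rejected above |
| Neutral band | +/-2 | deg | inclusive boundaries |
| Degeneracy bound | 1e-6 | mm^2 | triangle area |
| Noise model | 0-1 | mm SD | isotropic Gaussian per coordinate |

Validation problem sizes: 1000 random rotations for the decomposition
oracle; three-cycle 100 Hz trials for round trips; a 5 x 3 cadence
(0.8-1.2 Hz) by noise (0-1 mm) grid for event detection; a 10-participant,
20-foot cohort (one static + walking trials per foot) for end-to-end
recovery; 30 noisy copies for ensemble statistics. These sizes give the
statistical checks high power while keeping the whole suite fast on a
single CPU.

## Known limitations

* The hallux axial rotation is undefined by design; only F2Ps/F2Pt are
  reported for the first metatarso-phalangeal joint.
* The precise anatomical rule for placing HL is an open question in the
  underlying protocol; the generator exposes HL placement as a parameter
  (`hl_offset`) so its sensitivity can be studied, but the package cannot
  resolve the placement ambiguity itself.
* The original (pre-modification) frontal offset and two-vector MLA
  definitions are deliberately not implemented; a comparison hook exists
  in the calibration object but computing them is a non-goal.
* Event detection assumes walking with discernible heel strike; running
  and force-platform triggering are out of scope.
* The C3D support covers little-endian files with 3D point data (integer
  or float storage), which is what current capture systems emit; analog
  channels and legacy processor formats are not parsed.
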