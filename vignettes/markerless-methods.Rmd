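---
title: "From smartphone video keypoints to musculoskeletal dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From smartphone video keypoints to musculoskeletal dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`markerless` implements a desk-scale pipeline from multi-camera 2D video
keypoints to muscle-driven musculoskeletal simulations and their clinical
summary statistics. The stages mirror the now-standard markerless
motion-capture workflow:

1. **Camera geometry** — a fifteen-parameter pinhole model (3 rotation +
   3 translation + 2 focal lengths + 2 principal point + 5 distortion
   coefficients k1, k2, p1, p2, k3), with single-image checkerboard
   extrinsic calibration. Intrinsics are inputs; estimating them is out of
   scope.
2. **Multi-view reconstruction** — occlusion gap filling, cross-correlation
   time synchronization of the cameras, and confidence-weighted DLT
   triangulation of a 20-keypoint canon (neck, mid-hip, and left/right
   shoulders, hips, knees, ankles, heels, small and big toes, elbows,
   wrists).
3. **Marker augmentation** — a trainable sequence-regression model mapping
   the 20 triangulated keypoints plus height and mass to 43 anatomical
   markers (35 body + 8 arm), the marker set that inverse kinematics
   actually needs.
4. **Kinematics** — anthropometric model scaling, per-frame weighted
   nonlinear least-squares inverse kinematics, zero-lag Butterworth
   filtering, and differentiation.
5. **Dynamics** — muscle-driven tracking simulations solved by direct
   collocation with implicit skeleton dynamics, Hill-type muscles with
   first-order excitation–activation coupling, smooth compliant
   (Hunt–Crossley) foot–ground contact, and polynomial surrogates for
   muscle geometry.
6. **Analysis** — between-limb symmetry indices, stance detection, peak
   extraction, bodyweight normalization, EMG envelopes, waveform error
   metrics, ROC classification at the Youden threshold, and a
   paired-comparison battery with a Shapiro–Wilk normality gate and
   Benjamini–Hochberg FDR control.

A synthetic acquisition rig generates ground truth for every stage, so the
whole chain is testable with no laboratory data.

# The tracking simulation

The dynamics core solves, per trial, the optimal control problem

$$ J = \int_{t_0}^{t_f} w_1\|a\|^2 + w_2\|e_{tm}\|^2 +
       w_3\|\tilde q - q\|^2 + w_4\|\dot{\tilde q} - \dot q\|^2 +
       w_5\|\ddot{\tilde q} - \ddot q\|^2 \, dt
       \;+\; \text{(small penalty on remaining controls)} $$

subject to skeleton dynamics (enforced implicitly through inverse-dynamics
residuals that include the compliant contact forces), Raasch-style
excitation–activation coupling with separate activation (15 ms) and
deactivation (60 ms) time constants, first-order torque-motor dynamics, and
bounds ($a, e \in [0,1]$, motor excitations in $[-1,1]$). Reference
coordinates are low-pass filtered (fourth-order zero-lag Butterworth; 12 Hz
for gait, 30 Hz for non-gait by default — the squat drivers use 4–6 Hz,
appropriate for sub-1-Hz movements) and differentiated by central
differences before tracking.

**Transcription.** Third-order Radau IIA collocation (2 stages per mesh
interval, stage points 1/3 and 1), 50 intervals per second by default.
States are $q$, $\dot q$, muscle activations, and motor torques;
accelerations enter as per-stage algebraic variables so the skeleton
dynamics can be written as inverse-dynamics residuals, which cost one
vectorized recursive Newton–Euler pass per evaluation.

**Solver.** The environment offers no general nonlinear programming solver,
so the package ships its own: the transcribed problem is a sparse nonlinear
least-squares problem with equality constraints, minimized as
$\|r_{cost}\|^2 + \mu\|c\|^2$ over a geometric ladder of penalty weights
$\mu$ (default $10^3 \to 10^9$, advancing when constraint progress
stagnates), each stage solved by Levenberg–Marquardt with

* Jacobi-scaled normal equations (the stiff compliant-contact columns make
  the raw normal equations numerically unusable),
* an active-set mask freezing variables pinned at bounds,
* a backtracking line search (full Gauss–Newton steps regularly overshoot
  the narrow contact valley), and
* chord refinements that reuse each Cholesky factorization for several
  cheap residual-only steps.

Jacobians combine analytic blocks (collocation defects, activation
dynamics, cost rows, muscle-force linearity in $a$) with central-difference
blocks for the inverse-dynamics residuals (forward differences are visibly
biased by the contact curvature). Convergence is declared when the largest
scaled constraint residual falls below $10^{-4}$ (dynamics rows are scaled
by one tenth of bodyweight, so this corresponds to hundredths of a newton);
converged solutions carry pelvis residual forces below $10^{-2}$ N.

**Weights.** The cost weights are configuration, not constants:
defaults $w_1 = 0.1$, $w_2 = 0.01$, $w_3 = 100$, $w_4 = 1$,
$w_5 = 10^{-4}$, $w_p = 0.01$ were tuned once on the fixture models.

**Tendon.** Rigid by default (the fiber length follows algebraically from
the path length), which keeps the state small; a compliant-tendon
equilibrium residual is available in `hill_equilibrium()` for users who
need it. Hill curves are normalized so that the active force–length curve
peaks at exactly 1, the force–velocity multiplier is exactly 1 at zero
velocity, and the passive curve is exactly 0 at optimal length — the unit
tests rely on these anchors.

**Contact.** Normal force $k\,\delta^{1.5}(1 + c\,\dot\delta)$ with a
smooth-max penetration and a smoothly clipped dissipation factor, plus
tanh-regularized Coulomb friction. Fixture values: stiffness
$2\times10^5\ \mathrm{N/m^{1.5}}$, dissipation 2 s/m, friction 0.8,
friction velocity scale 0.5 m/s. Published full-scale gait models often use
stiffer spheres; the softer desk-scale values give millimetre-to-centimetre
penetrations, which keeps the left/right load split of double stance
well-conditioned against millimetre kinematic errors and keeps the
collocation problem solvable in seconds. The regularized friction behaves
like a damper near zero slip; with squat references constructed so the
whole-body center of mass stays over the feet, the required shear forces
are near zero and the approximation is benign.

# Fixture models

The full 33-DOF, 80-muscle, 13-motor gait model of the source ecosystem is
representable in the YAML model format, but the shipped, tested fixtures
are reduced:

* `demo3d` — 21 DOF (pelvis 6, lumbar 3, hips 2×3, knees 2×1, ankles 2×2)
  carrying the complete 20-keypoint and 43-marker attachment sets; the arms
  are rigid on the torso (enough for the arm augmenter submodel, which maps
  torso-relative motion).
* `demo2d` — a sagittal 9-DOF dynamics fixture (pelvis tx/ty/tilt, hips,
  knees, ankles) with 8 Hill-type muscles (per leg: hip flexor, hip
  extensor, vasti with a patellar via point, soleus), 6 reserve torque
  motors (90 N·m), and 2 contact spheres per foot. Tendon slack lengths are
  set so fibers are optimal in a half-squat posture, where force demands
  peak. The vasti via-point geometry was chosen for a stable 20–40 mm knee
  moment arm across the flexion range; like a real knee, the arm still
  drops at deep flexion.
* a torque-driven single pendulum for solver oracles.

Muscle geometry enters the optimal control problem through per-muscle
polynomial surrogates (total order ≤ 9, fit to 5000 random postures,
order selected by held-out error); moment arms are the analytic derivative
$-\partial\ell/\partial q$ of the fitted length polynomial. On the fixture
muscles the held-out RMSE is well below 1.5 mm for both lengths and moment
arms.

# The synthetic rig

The rig emulates a two-smartphone collection: cameras at ±45°, 1.5 m high,
3 m from the volume center, portrait 720×1280 at 60 Hz, wide-angle
intrinsics (f = 700 px) with mild radial distortion, and unknown integer
inter-camera frame offsets. Five-camera (±70/±45/0°) presets exist.
Keypoint noise is Gaussian with an 18 mm 3D magnitude (per-axis SD
$18/\sqrt3$ mm), injected in 3D before projection. The noise is AR(1) in
time (autocorrelation 0.9, marginal SD unchanged): pose-detector error is
strongly correlated frame to frame, and white noise at 60 Hz would
dominate the velocity signals used for synchronization in a way real
detectors do not. Confidences follow a truncated Gaussian with seeded
dropouts and occlusion intervals that force confidence toward zero.

Motions are constructed kinematically: squats and sit-to-stands anchor the
right foot at its standing position, keep the feet flat, and solve the
trunk lean per frame so the whole-body center of mass stays vertically over
its standing position (which is also what people do); walking is a
parameterized periodic pattern. Squats carry 0.4 s of quiet standing at
both ends so that camera offsets never crop the movement. The standing pose
itself is a true contact equilibrium: pelvis height and ankle pitch are
solved so both the vertical force and the tilt moment balance — using a
non-equilibrium reference would force the tracking solver through a
long-range posture search it cannot make reliably.

Imposed squat asymmetry ("reduce the force under the left foot") is modeled
as extra left-knee flexion whose profile rises steeply at the start of the
descent, so the left foot unloads and lifts before it is loaded at depth —
the staggered-squat strategy. The cohort generator records the imposed
effect; the `effect` parameter is the extra flexion fraction (0.6 in the
"large effect" study, which lifts the left foot by roughly 10 cm at the
bottom).

**What the rig does not emulate:** soft-tissue artifact, pose-detector
failure modes (left/right swaps, person confusion), lens rolling shutter,
or out-of-plane (frontal/transverse) loading asymmetries — the dynamics
fixture is sagittal, so "unweighting" a leg must go through the staggered
stance rather than a lateral weight shift. Passing tests therefore
demonstrate internal consistency of the full chain under controlled
conditions, not field accuracy.

# Pipeline design choices

* **Synchronization signal**: confidence-weighted mean keypoint speed per
  frame (central differences). The driver smooths pixel positions at 8 Hz
  before differencing and trims a few edge frames before
  cross-correlation; both counter detector jitter. Lags are integer frames
  (≤ 8.3 ms residual skew at 60 Hz). For symmetric two-camera rigs the
  recovery is exact at realistic noise; strongly asymmetric rigs (a frontal
  plus an oblique camera) can be off by 1–2 frames on gait because the
  speed-signal shape is genuinely view-dependent.
* **Triangulation**: homogeneous (algebraic) DLT with each camera's two
  equations scaled by its confidence (not squared); below two confident
  cameras the sample is invalid and later bridged by cubic splines if the
  gap is short (≤ 0.5 s).
* **Augmenter**: the source pipeline uses LSTM networks; no deep-learning
  framework is available to this package, and its augmenter is a
  ridge-regularized, lag-stacked linear sequence regressor (context lags
  −4…+4 frames) honoring the same preprocessing contract: root-centering
  at the hip midpoint, height normalization, 60 Hz, non-overlapping 0.5-s
  windows, Gaussian input noise of 18 mm 3D magnitude per time step during
  training, and subject-level ≈80/10/10 splits. Training is a closed-form
  solve, hence bit-reproducible; translation equivariance is exact by
  construction. The training corpus includes staggered/asymmetric squats so
  that asymmetric poses are inside the training distribution. On the
  50-subject rig corpus the held-out RMSE is a few millimetres — far below
  the 27 mm budget, because the rig's rigid-skeleton data are easier than
  human motion-capture corpora; no claim is made to reproduce
  flesh-and-blood error levels.
* **IK**: per-frame damped Gauss–Newton, warm-started, uniform marker
  weights, with a tiny (1e-6) pull toward the previous frame to resolve
  redundancy; it is switchable.
* **Foot–ground correction**: estimated kinematics carry millimetre errors,
  while double-stance load distribution is statically indeterminate and
  contact penetrations are only millimetres; uncorrected, the left/right
  load split of a symmetric squat is essentially random. The pipeline
  therefore applies the standard mocap-to-simulation cleanup: frames whose
  foot is near the ground get that leg's knee and ankle nudged (within the
  kinematic error band) so the foot's contact spheres sit at their standing
  equilibrium heights; clearly airborne feet are untouched and the
  correction blends smoothly in between (full below 15 mm, none above
  30 mm).
* **Symmetry estimation**: peak vasti activations and peak knee extension
  moments are extracted during the deep-squat phase (reference knee beyond
  30% of maximal flexion), excluding stand-still and touchdown transients.
  The knee-extension-moment symmetry index is the primary classifier score
  (as in field use); the activation-based index is also reported.
* **Cohort problem sizes**: the closed-loop studies run 20 subjects × 2
  conditions with one repetition each, IK at 30 Hz, tracking meshes of 12
  intervals/s over a 1.6-s padded squat (0.3-s quiet stands), and a capped
  penalty ladder — sizes
  chosen so a study completes in minutes on one core while leaving the
  separation margins wide. The null-effect study feeds ground-truth-plus-
  noise keypoints directly to the augmenter (no camera rendering): its
  claim is statistical exchangeability of the two conditions, which the
  symmetric camera chain would only dilute with identical noise at double
  the cost.

# Statistics

`paired_comparison()` runs Shapiro–Wilk on the paired differences and picks
a two-sided paired t test (p > .05) or a two-sided Wilcoxon signed-rank
test, reporting Cohen's $d_z$ or the rank-biserial correlation, with
post-hoc power at the observed effect size (noncentral t for the t branch;
the Wilcoxon branch uses the normal approximation with asymptotic relative
efficiency $3/\pi$ and is documented as approximate). Families of
comparisons are corrected by Benjamini–Hochberg. ROC analysis uses the rank
(pair-counting) AUC with tie correction and reports accuracy at the
threshold maximizing TPR − FPR. Degenerate paired tests (all-zero
differences) return p = 1 with a flag; exactly constant non-zero
differences return p = 0.

Stance detection (5% bodyweight threshold with hysteresis at 60% of the
threshold and a 50-ms minimum duration) and the waveform alignment
(integer-delay search minimizing the mean difference, then constant-offset
removal, applied to positions) follow common gait-analysis practice; both
are configurable.

# Known limitations

* The collocation solver is a penalty-continuation Levenberg–Marquardt
  scheme, not an interior-point NLP solver; on hard contact transitions
  (e.g., a foot grazing the ground) it can stall around constraint
  residuals of $10^{-3}$ in scaled units and reports `max_iterations`
  honestly. All physics oracles in the test suite are met by converged
  solutions.
* Multi-camera synchronization is exact only up to the view-dependence of
  the velocity signal (see above).
* The sagittal dynamics fixture cannot represent frontal-plane load shifts;
  the rig's imposed asymmetry is a staggered squat, stronger than the
  subtle weight shift of the source studies.
* Reported augmenter accuracies describe the synthetic corpus, not human
  data.
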