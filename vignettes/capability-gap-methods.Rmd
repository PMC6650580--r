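---
title: "Personalized musculoskeletal models and the capability gap: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized musculoskeletal models and the capability gap: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capgap)
```

## The problem

Children with cerebral palsy who are candidates for single-event multi-level
orthopedic surgery present with three interacting impairments: deformed
musculoskeletal geometry (for example excessive femoral anteversion),
altered muscle-tendon properties (contractures, weakness), and impaired
selective motor control. `capgap` implements a simulation pipeline that (i)
personalizes the muscle-tendon parameters and the motor control of a
musculoskeletal model from routinely collected pre-operative data (gait
kinematics and moments, surface EMG, a clinical range-of-motion exam), (ii)
applies parametric virtual surgeries to the model, and (iii) scores how well
the pre- or post-operative model can reproduce a typically-developing (TD)
gait pattern. The score is the *capability gap* (CG): for each joint $j$,

$$ CG_j \;=\; \frac{\sum_i |\tau^R_{ji}|}{\sum_i |\tau^{ID}_{ji}|}, $$

where $\tau^{ID}_{ji}$ are the joint moments the desired TD motion requires
and $\tau^R_{ji}$ are the *reserve* moments of ideal torque actuators that
must make up whatever the muscles — constrained by the personalized
geometry, parameters and synergies — cannot produce. A CG of zero means the
desired gait is fully achievable; larger values quantify the deficit. The
CG is a measure of how hard a normal gait pattern would be for this
musculoskeletal system; it does not predict the kinematics the patient will
actually adopt.

## Model and muscle mechanics

The skeletal model is a tree of rigid segments connected by rotational
(hinge) joints; muscles are polylines of points fixed in segment frames.
Muscle-tendon length is the polyline length after forward kinematics, and
moment arms follow the tendon-excursion method,
$r_{jm} = -\partial l^{mt}_m/\partial q_j$, evaluated by central finite
differences (step $10^{-6}$ rad) — simple and directly checkable against an
independent length oracle, which the test suite does to $10^{-8}$ m.

Muscle force uses a rigid-tendon Hill model without force-velocity
dependence (all analyses are static). For the *tuned* subset M,

$$ F_m = F^{max}_m\,[\,a_m f^L(\tilde l_m) + f^P(\tilde l_m)\,],
\qquad \tilde l_m = \frac{l^{mt}_m - l^{ts}_m}{l^{mo}_m\cos\alpha_m}, $$

with optimal fiber length $l^{mo}$, tendon slack length $l^{ts}$ and
constant pennation $\alpha$. The remaining muscles (subset N) are
activation-proportional, $F = F^{max} a$: with few measured signals there
is no information to constrain their operating lengths, so a simpler force
model is more honest.

The normalized curve family is a package choice (only its calibration is
anchored): the active curve is a Gaussian bump
$f^L(\tilde l) = \exp(-((\tilde l - 1)/w)^2)$ with width $w = 0.45$,
peaking at 1 at the optimal length; the passive curve is the exponential
toe $f^P(\tilde l) = (e^{k(\tilde l-1)/\epsilon} - 1)/(e^k - 1)$ for
$\tilde l > 1$ (else 0) with $k = 4$, $\epsilon = 0.6$. The anchor is that
a muscle stretched to $1.5\,l^{mo}$ transmits about half its maximum
isometric force passively; with these defaults $f^P(1.5) \approx 0.504$,
and solving $f^P = 0.5$ gives $\tilde l \approx 1.499$. All shape
parameters live in `muscle_curve_set()` and are configurable.

## Muscle-parameter estimation

`tune_muscle_parameters()` estimates $l^{mo}$ and $l^{ts}$ for the tuned
muscles — the two parameters with the largest influence on simulated force —
from one or more gait trials, their EMG envelopes and the clinical exam.
All frames are coupled in a single program whose variables are the
per-frame activations, per-frame reserve moments, the parameters and one
EMG scale factor $\sigma_m$ per mapped muscle. The cost is

$$ \sum_i\Big(\sum_m w_1 a_{mi}^2 + \sum_j w_2 (\tau^R_{ji})^2\Big)
 + \sum_i\sum_{m\in\epsilon} w_3(\sigma_m a_{mi} - \epsilon_{mi})^2
 + \sum_{m\in R} w_4 (\tilde l^{R}_m - 1.5)^2 $$

subject to moment equilibrium at every frame and joint, activation bounds,
and the length constraints that encode the tuning assumptions: during gait
the normalized fiber length must stay within $[0.4, 1.5]$ and must cross 1
(muscles operate around their optimal length); at the clinical-exam
stretch postures the normalized length $\tilde l^R$ must lie in
$(1, 1.5]$, with the $w_4$ term pulling it toward 1.5, where substantial
passive force — the resistance the examiner feels — is produced. The free
scale $\sigma_m$ ties computed activations to EMG *shape* without assuming
a maximum-voluntary-contraction calibration.

Numerical structure. Because reserves are defined as the equilibrium
residual, the equality constraints hold exactly by construction. For fixed
kinematics $\tilde l$ is increasing in $l^{mt}$, so the per-muscle
min/max-over-frames constraints reduce to the precomputed extreme frames
and every length constraint is *linear* in $(l^{mo}, l^{ts})$; strict
inequalities are implemented with a margin $\delta = 10^{-3}$. For fixed
parameters the activations decouple into per-frame strictly convex QPs
(solved with `quadprog`) and $\sigma_m$ has the closed form
$\sum_i a_{mi}\epsilon_{mi} / \sum_i a_{mi}^2$. The package therefore
solves a *reduced* program over the parameters alone: each evaluation
solves the inner convex problem to optimality, the envelope theorem gives
the exact reduced gradient, and an SQP solver (`nloptr::slsqp`) handles
the linear constraints. A naive block alternation between the activation
and parameter blocks was tried first and stalls far from the optimum
(each block re-adapts and the cross-gradient information is lost); the
reduced formulation converges reliably. The reduced landscape is still
nonconvex, so the solver multi-starts from the supplied parameters plus
seeded ±10% perturbations (3 starts by default) and keeps the best
objective.

Weights. The defaults are $w_1 = 0.1$, $w_2 = 10\,(\mathrm{N\,m})^{-2}$,
$w_3 = 5$, $w_4 = 10$, chosen once so that the cost terms are of the same
order on the packaged synthetic fixture. The activation-effort weight is
deliberately the small one: because $\sigma_m$ is free, the EMG term
anchors activation *shape* but not amplitude, and a large effort weight
rewards parameter drift toward configurations that produce the same
moments with systematically smaller activations (flatter normalized-length
trajectories, more passive support), biasing the estimates. With
$w_1 = 0.1$ the EMG-tracking and exam-stretch anchors dominate and
ground-truth recovery on the fixture is unbiased to within a few percent.

## Motor-control personalization

The number of synergies $N_s$ is selected from the measured EMG channels
by non-negative matrix factorization (hand-written multiplicative updates,
seeded multi-restart, Frobenius objective; the update trace is
non-increasing and the factorization quality is summarized by the global
variance accounted for, $VAF = 1 - \|E - WH\|_F^2 / \|E\|_F^2$) combined
with a bootstrap: time instants are resampled with replacement (500 times
by default), consistently in the EMG matrix and in the temporal
activations $H$, and the VAF of each resample under the weights extracted
from the original signal is computed with $W$ held fixed. $N_s$ is the
smallest synergy count whose VAF exceeds 90% in at least 95% of resamples.
The resampling unit is the time instant, and $W$ is never re-fit per
resample.

Because EMG covers only a subset of muscles, the motor-control model used
for the gap computation is built in two further steps: an *EMG-informed*
static optimization (the same per-frame QPs with the $w_3$ tracking term;
$\sigma$ updated in closed form, alternating until the scales or the joint
cost are stationary — the scales can wander along a flat valley of the
cost while the cost itself converges, so both criteria are used) produces
activations for *all* muscles consistent with the measured envelopes and
the gait moments; then a new factorization with $N_s + 1$ synergies is
extracted from that all-muscle activation matrix. The extra synergy gives
muscles without surface EMG a place to load. Weight columns are
max-normalized to 1 with the temporal activations rescaled inversely, so
the reconstruction is unchanged.

## Virtual surgeries

All operators are pure functions from model to model; the result records
the input model as its lineage, so one pre-operative model can fan out to
many post-operative variants.

* **Derotation osteotomy** — one cutting plane in the segment frame; the
  distal side (the half-space away from the segment's own joint center,
  overridable) is rigidly rotated about the plane normal and translated
  in-plane. Path points, landmarks and child joint frames move together.
* **Extension + derotation osteotomy** — two planes bound a resection
  wedge. A *triangular* wedge (non-parallel planes) closes by rotating the
  distal fragment about the plane intersection line by the dihedral angle;
  a *trapezoidal* wedge (parallel planes) closes by translating it by the
  inter-plane offset, a pure shortening. A user derotation about the
  joined-plane normal and an in-plane translation compose on top. A muscle
  path point inside the wedge is an error (transfer it first, silently
  deleting attachments would corrupt the mechanics); landmarks inside the
  wedge are dropped with a warning.
* **Muscle transfer / tendon lengthening** — path-point edits whose
  geometric length change at a reference posture (default: the anatomical
  zero posture) is absorbed into the tendon slack length, so the fiber
  operating state at that posture is untouched: transfers re-route the
  tendon, they do not alter fiber architecture. A canned distal
  rectus-femoris transfer releases the original distal route, pins the
  preserved proximal route with a new thigh-frame via point at the path
  midpoint, and reattaches the insertion on the hamstrings tendon.
* **Patella advancement** — the ligament length (or tibial insertion) is
  changed and the patella's planar path versus knee angle is re-solved:
  the ligament constraint confines the patella attachment to a circle
  around the (knee-angle-dependent) tibial insertion, and the remaining
  two pose parameters minimize the spread of the two patellar surface
  points' distances to the femoral profile curve, with a mild pull toward
  the stored articular clearance. The clearance term is a regularization:
  with the spread term alone the pose could slide along the profile. The
  problem is posed in the plane perpendicular to the knee axis, with the
  3-D femoral surface reduced to a profile curve supplied in the model.
* **Strength scaling** — multiplies the maximum isometric force; scale 0
  encodes a muscle release (the muscle then contributes no moment in any
  later optimization), and intermediate scales model tone-reducing
  injections as pure weakening.

Femoral morphometrics (anteversion as the signed angle between the neck
and condylar axes projected on the plane perpendicular to the shaft axis;
the neck-shaft angle against the distal shaft direction) are recomputed
from named landmarks after every osteotomy, so a derotation can be dosed
to a target anteversion.

## Capability-gap optimization

`compute_capability_gap()` evaluates a model against a desired trial built
by `make_reference_trial()`: template joint moments scale linearly with
body mass, and kinematics are either copied from the template or
re-derived per frame by tracking the template's virtual marker
trajectories (scaled by the height ratio) with the model's landmarks in a
nonlinear least-squares fit (`minpack.lm`). Marker tracking matters when
the model carries torsional deformities: imposing TD joint angles on a
femur with 30° of extra anteversion would point the knee and foot 30°
off, whereas tracking markers re-aims them by adjusting the long-axis
rotation coordinate.

With synergies active, activations are $a_i = (W^{pre} + \Delta W) H_i$
with $H_i \ge 0$ free per frame and one shared, time-invariant deviation
matrix bounded elementwise by 0.05 after max-normalization of $W^{pre}$
(and $W^{pre} + \Delta W \ge 0$). The deviation absorbs the few percent of
signal variance the factorization itself does not capture. Stage 1 fixes
$\Delta W = 0$ and solves per-frame convex QPs in $H_i$ (activation upper
bounds enter as linear constraints); stage 2 alternates convex QPs in the
temporal block and the deviation block (activation caps added by
constraint generation) until the objective stalls; the objective trace is
non-increasing by construction. Activations are additionally clamped to
$[0,1]$ — unbounded synergy products would be non-physiological. With
`use_synergies = FALSE` the activations are optimized freely per frame
(simulating unimpaired selective control), and with
`use_force_length = FALSE` every muscle becomes activation-proportional;
both toggles isolate the contribution of one impairment to the gap.
Because the synergy-constrained feasible set is a subset of the free one,
the constrained gap can only be larger — the package asserts this on its
fixtures.

The per-joint ratio divides by $\sum_i |\tau^{ID}_{ji}|$ with a floor of
1 N m (summed over the cycle) so that joints with near-zero desired
moments (for example long-axis rotation) cannot blow up the ratio; the
floor is recorded in the configuration echo. The summary gap is the
unweighted mean over joints. The muscle report flags, per frame, muscles
whose passive force exceeds half their maximum isometric force
(excessively stretched) and muscles with activation above 0.25 at
normalized lengths below 0.6 (active where little force can be produced);
flags are summarized as maximal consecutive intervals.

## Synthetic fixtures and what they do (not) show

No patient data ships with the package. `make_toy_model()` builds a
planar five-segment, eight-muscle lower-limb analog (three hinge
coordinates plus a long-axis hip-rotation coordinate carried by an
intermediate segment; three biarticular muscles; six tuned, two
activation-proportional; femoral landmarks, retargeting markers and a
patella construct). `generate_synthetic_trial()` produces three gait
cycles at 51 frames each: zero-mean band-limited Fourier kinematics (so
every tuned muscle crosses its optimal length), activations from a
non-negative rank-$k$ synergy model scaled to peak 0.65 (the clamp at 1
is never active, so the stored $W, H$ are exact), muscle forces from the
model's true parameters, and joint moments *defined* as the resulting
muscle-moment sums. A zero-reserve solution therefore exists by
construction and every downstream optimization has a known optimum. EMG
envelopes are the activations of five measured channels (one channel
drives both plantarflexors, mirroring shared surface electrodes) plus
optional Gaussian noise, clipped and peak-normalized. The clinical exam
generator places each stretch posture by maximizing the test group's
stretch and scaling back until the most-stretched muscle reaches a
normalized length of 1.45 — inside the passive band, as end-range testing
is meant to be.

These fixtures validate the machinery: constraint handling, oracle
equivalence of every optimization against independent solvers, recovery of
known parameters and synergy counts, exact invertibility of surgeries.
They do not establish clinical validity: real gait involves 3-D joints,
wrapping muscle paths, marker noise, EMG crosstalk, dynamically consistent
moments and genuinely unknown parameters, none of which the toy chain
emulates. The moments-from-muscles construction in particular guarantees
feasibility that real inverse-dynamics data need not have.

Template scaling uses a reference mass of 35 kg and height of 1.40 m
(typical of the school-age TD cohorts such studies use as reference); the
packaged TD gait template is itself a synthetic Fourier construction on
the reference chain, a labeled stand-in for a clinical TD average, which
is not redistributable.

## Numerical choices and limitations

* Problem sizes: 153-frame trials (three 51-frame cycles) for tuning and
  synergy extraction, 101-frame cycles for the reference template; these
  keep a full pipeline run in minutes on one core while leaving all
  constraint structure intact.
* QPs get a relative ridge of $10^{-9}$ on the Hessian diagonal: the
  extended ($N_s + 1$) weight matrix is legitimately rank-deficient when
  the extra synergy duplicates structure, and the temporal QP must stay
  positive definite.
* The tuning NLP is nonconvex; multi-start is a guard, not a guarantee.
  Non-converged solves are returned flagged, never silently.
* The EMG-informed $\sigma$/activation alternation can wander along a
  flat valley (per-muscle scale freedom); it stops on stationary cost and
  reports convergence honestly.
* The two-stage $H$/$\Delta W$ alternation solves a bilinear problem and
  is only guaranteed to find a stationary point; the seeded,
  deterministic schedule makes runs reproducible.
* Pennation is constant, tendons rigid, force-velocity absent, and path
  points fixed in their segments (no wrapping surfaces); these match the
  static scope of the method and keep every geometric quantity exactly
  differentiable by finite differences.
* Strict inequalities from the tuning assumptions use $\delta = 10^{-3}$;
  gait-band feasibility of the *initial* parameters is restored, when
  needed, by a per-muscle Euclidean projection onto the linear constraint
  polytope.
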