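---
title: "Task-driven models of proprioception: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-driven models of proprioception: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(propriotask)
```

## The scientific question

Muscle spindles report muscle length and its rate of change, not hand
position: any higher-level readout — "where is my hand", "what movement was
that" — must be computed downstream from a distributed, ambiguous code.
`propriotask` implements a task-driven modeling pipeline for asking what
those downstream computations might look like. It synthesizes a labeled
corpus of passive arm movements (an arm tracing single-stroke letters),
converts them into spindle-like inputs through explicit kinematics and a
muscle model, trains small neural networks either to recognize the letter
(action recognition, ART) or to reconstruct the hand path (trajectory
decoding, TDT, plus a position+velocity control TDT-PV), and then asks how
single units and populations in those networks are tuned — direction,
speed, position, acceleration, label — and how that tuning compares
between tasks and against untrained networks.

The pipeline is organized as nine composable stages: character generation,
augmentation, arm kinematics, muscle mapping, dataset assembly, non-neural
baselines, network families and training, single-unit tuning analysis, and
population geometry. The functions, this vignette, and
`scripts/acceptance.R` are the package's interface; `run_pipeline()`
orchestrates the stages end to end from one `experiment_config()`.

## Synthetic characters

The original pen-trajectory corpus (20 single-stroke Latin letters — all
but f, i, j, k, t, x — recorded on a tablet at 200 Hz) is replaced by a
generative stand-in so the pipeline has no external data dependency:
each class is a fixed template of 5–9 spline control points, traced with a
bell-shaped speed profile at 200 Hz in a roughly 1 cm box, with seeded
jitter of control points and duration (`generate_synthetic_characters()`).
A reader/writer for a plain-text velocity-format container
(`load_uci_trajectories()`) accepts externally supplied trajectories with
the same downstream path.

`rescale_and_resample()` maps a trajectory into the 10 × 10 cm² writing
grid and changes the sampling interval from 5 ms to 15 ms (66.7 Hz)
while keeping the sample count — writing on the large grid takes
proportionally longer, and the normalized speed profile is untouched. We
resolved the open choice of how the duration scaling applies by fixing the
per-sample interval change only, which preserves the velocity-profile
shape exactly.

## Augmentation and placement

Every base trajectory is expanded over the study grid: scales
{0.7, 1, 1.3}, rotations and shears {±π/6, ±π/12, 0}, speeds
{0.8, 1, 1.2, 1.4}, and a 3-cm lattice of start points on horizontal
(fixed z) and vertical (fixed x) writing planes. The affine composition
order — scale, then rotate, then shear, about the trajectory centroid —
is not dictated by anything in the problem; we fixed it (and the centroid
convention) once for reproducibility. The identity tuple reproduces the
input bit-exactly, which the tests assert.

Plane counts are emergent from the arm's workspace, not hard-coded:
`compute_start_grid()` retains a start point only when the four corners of
the scaled character bounding box around it pass an inverse-kinematics
feasibility probe. Corner offsets are snapped to the grid spacing so
neighboring start points share (memoized) corner checks.

## Arm model

The arm is a two-link, 4-DoF kinematic chain (elbow flexion, shoulder
rotation, shoulder elevation, elevation plane) with

\[ e = R_S (R_L e_0 + l_0), \qquad
   R_S = R_Y(\theta_{se}) R_Z(\theta_{sep}) R_Y(-\theta_{se}) R_Y(\theta_{sr}),
   \qquad R_L = R_X(\theta_{ef}), \]

where $e_0, l_0$ are the rest positions of hand and elbow and $R_X, R_Y,
R_Z$ are the standard right-handed basic rotations. Axes: x away from the
body, y rightward, z up; the arm hangs along $-z$ at $q = 0$. Link
lengths default to 0.33 m (upper arm) and 0.30 m (forearm + hand) with
physiological joint limits; all four are configuration, since published
upper-limb models differ. We claim internal consistency (orthonormal
rotations to 1e-10, analytic Jacobian equal to finite differences), not
agreement with any specific musculoskeletal implementation's Euler-angle
conventions.

Inverse kinematics solves, frame by frame,
minimize $\lVert q(t) - q(t-1) \rVert$ subject to
$\lVert F(q(t)) - e(t) \rVert \le$ `tol_e` and box limits, warm-started
from the previous frame ($q(-1)$ = the mid-range natural pose). The
equality constraint is relaxed to `tol_e` = 1e-4 m: strict equality is
numerically brittle, and 0.1 mm is far below any kinematic feature the
analyses use. The implementation takes damped least-squares steps (the
minimum-norm update realizes the proximity objective locally) with limit
clamping, a bounded quasi-Newton polish, and a deterministic set of
restart poses for cold starts trapped at limit corners; infeasibility is
reported with the best residual. One thousand random FK/IK round trips
run in about a second with every residual below `tol_e`.

## Muscles and proprioceptive inputs

Equilibrium fiber lengths of 25 upper-arm muscles are produced by a
configurable moment-arm model about the natural pose: $m_i(q) = L_{0,i} +
\sum_j C_{ij}(q_j - q_{\mathrm{ref},j})$, optionally with quadratic
terms. The default geometry assigns physiologically plausible signs and
magnitudes (0.5–4 cm/rad): shoulder muscles span the three shoulder
angles, elbow muscles the flexion angle, the long biceps/triceps heads
both joints, and antagonists carry opposite signs. This is an explicit
stand-in for a full musculoskeletal engine — any function from joint
trajectories to a 25 × T length matrix can replace it — chosen so the
analyses see inputs with the statistics they need (muscle-specific,
biased directional preferences; smooth lengths; velocity obtained by
differentiation) without a heavyweight simulation dependency. What
passing tests show is therefore qualitative: tuning *structure*, not the
specific tuning medians of any particular anatomical model.

The spindle model is the affine rate proxy $k_1 + k_2 l + k_3 l' + k_4
l'' + k_5\,\mathrm{EMG}$; movements are passive, so EMG is forced to
zero, and the network inputs are the pair {length, velocity} per muscle
(25 × T × 2). The acceleration term is computed but defaults to weight
zero. Channels are standardized per (muscle, channel) with training-split
statistics; the switch is exposed because input normalization is a
modeling choice, and it is logged in the dataset manifest.

## Dataset assembly

Candidates are drawn per class from the augmentation grid (seeded),
placed on feasible start points, solved by sequential IK, and filtered by
the integral of joint-space jerk $\int \lVert \dddot q \rVert\,dt$.
About the threshold: dimensional analysis of this integral gives
rad/s², and on the 66.7-Hz grid every smooth letter trace scores
between ~10 and ~270 (letters with many direction reversals, like *m*,
legitimately sit at the top). We therefore calibrated the generator's
threshold at 300 — above the smooth-letter envelope, below the ~355
score of a single-frame 0.01-rad IK discontinuity — so the filter does
what it is for: rejecting kinematic artifacts, not penmanship. The
filter function itself defaults to the conventional threshold of 1 for
callers who work in other units.

Among survivors, the per-class `n/20` candidates with minimal
muscle-space jerk (defined analogously on the 25-dim length trajectory)
are retained, giving an exactly balanced set. Movements are padded to
320 samples (4.8 s at 66.7 Hz) with static start/end postures (zero
velocity channel) and a uniformly drawn onset so movement initiation is
ambiguous; the onset is logged per sample. The split is stratified
72-8-20 by class. Containers round-trip through a versioned `.rds` file
plus a JSON manifest carrying ids, augmentation tuples, planes, onsets,
filter scores, seeds, and the generator config hash.

## Baselines

Character recognition: 190 pairwise linear SVMs (hinge loss), each
cross-validated over nine log-spaced regularization constants between
1e-4 and 1e4 (3-fold; fold count is our choice), aggregated one-against-
one by summed signed confidences with ties broken by class order. Input
flattening subsamples time by 8 by default (logged); full flattening is
available. Trajectory decoding: a single linear map from the 50 per-step
input channels to the 3D hand position, fit as the closed-form ordinary
least-squares solution on standard-scaled features and targets — the
exact optimum that an SGD fit with a small tolerance approximates — with
the error reported as mean Euclidean distance in cm.

## Network families and training

Three families consume the 25 × 320 × 2 input: spatial-temporal (1D
convolutions across muscles, then across time), spatiotemporal (2D
convolutions), and LSTM (spatial convolutions, then a recurrent layer).
Every convolutional layer is convolution → layer normalization → ReLU;
a single fully connected layer reads out 20 logits (ART), 3 coordinates
per kept time step (TDT), or 6 (TDT-PV, min-max scaled per dimension on
the training split). Convolutions use "same" zero padding with output
length ⌈in/stride⌉; this convention reproduces the published layer-shape
table for all three best architectures exactly (asserted as tests), which
is how we resolved the padding ambiguity. For a temporally reduced final
layer the decoding heads read out at the kept time points — the centers
of the units' receptive fields — and targets are aligned to those
input-grid indices.

The search space follows the published grids: 1–4 layers per type
(2–8 total for spatial-temporal, in pairs), filters {8, 16, 32, 64}
sorted so counts never decrease along the hierarchy, kernel sizes
{3, 5, 7, 9} constant across layers, spatial strides {1, 2}, temporal
strides {1, 2, 3}, and 128/256 recurrent units; `sample_architecture()`
draws all of them independently per seed.

Training minimizes softmax cross-entropy (ART) or mean squared error
(TDT/TDT-PV) with Adam (β₁ = 0.9, β₂ = 0.999), initial learning rate
5e-4. Saturation is operationalized as: no new validation-loss minimum
for five consecutive epochs (tolerance 0); the first saturation divides
the learning rate by 4, the second stops training. The engine itself is
plain R on BLAS with compiled im2col/col2im kernels; analytic gradients
are verified against finite differences for every family and head at
relative error below 1e-6.

### Desk-scale study conditions

The full-scale study (10⁶ candidates, 2 × 10⁵ samples, 150 searched
models) is reachable by configuration, but the package's reference
experiments — what the tests and the acceptance script run — use a
desk-scale configuration chosen once: 720 samples (36 per class) on five
horizontal planes (z = −6…6 cm) and five vertical planes (x = 24…36 cm),
candidate oversampling 1.7×, the full augmentation grid, and a small
spatial-temporal model (`desk_architecture()`: spatial 8 @ k5 s2;
temporal 16, 16 @ k5 s3). Training uses batch size 64: the batch is
scaled down with the training set (the full-scale 256-sample batch would
give two optimizer updates per epoch at this size). Recognition models
train 12 epochs at the reference learning rate scaled to 1e-3;
trajectory-decoding models, whose head must traverse a larger parameter
distance under Adam's per-step displacement bound, train 24 epochs at
4e-3, with the regression head bias initialized at the training-target
mean so early updates model movement structure rather than the
workspace offset. At this scale an ART model trains in about a
minute on one CPU; accuracies sit far above chance but far below the
full-scale regime, and all cross-model claims are made as orderings
(trained vs untrained, ART vs TDT, network vs linear baseline), not as
absolute levels.

## Single-unit analysis

Kinematics are computed in the writing plane: first axis rightward,
second away from the body (horizontal) or upward (vertical); direction
0° is rightward and 90° away/up, counterclockwise positive, angles in
(−π, π]. Where the source conventions for the direction reference
conflicted (text vs figure axis naming), we adopted the figure
convention and documented the mapping here. Derivatives use the same
finite-difference scheme as the muscle velocities; frames with speed
below 1e-4 cm/s (the static padding) have no defined direction and are
excluded from direction/velocity fits. Activity is not time-lagged
relative to kinematics (zero lag; the open choice).

Six kinematic tuning models are fit by OLS on linearized designs —
direction (cosine), speed (linear), velocity (speed × cosine), Cartesian
and polar position, acceleration magnitude — with cosine models fit via
the sum/difference expansion (α₁ = α cos θ_PD, α₂ = α sin θ_PD), which
is exactly equivalent to the nonlinear cosine fit (asserted to 1e-8).
Splits are 80-20 *between trajectories*, never within. Test R² uses the
convention that a perfectly predicted constant target scores 1 — such
"dead" units, and scores below −0.1 (non-converged fits), are excluded
before classification; a unit belongs to every kind with test R² > 0.2.
Label selectivity trains per-class one-vs-rest linear SVMs on a single
unit's activity over its kept time points (standardizable feature
vector; the source describes only "based on that unit's firing rates")
and maps the best auROC to the selectivity index 2·(auROC − 0.5).

## Population analyses

Linear CKA compares layers on (samples × flattened unit-time features)
with column centering — the flattening is our choice, as is using 50% of
the test set by default (configurable). RDMs use correlation distance;
oracle similarity is the Spearman rank correlation between a layer RDM's
upper triangle and the ideal block RDM (0 within class, 1 between) —
rank correlation is standard representational-similarity practice and is
our resolution of the unstated statistic. The embedding protocol is PCA
to 50 dimensions then t-SNE (perplexity 40, 300 iterations, fixed seed);
the t-SNE optimizer is implemented in the package (exact O(n²)
affinities, early exaggeration, adaptive gains) because no R
implementation is available in the toolchain we target. Population
decoding is ridge regression (strength 1) from all units of a layer at
single time points to the kinematic variable at the receptive-field
center, trajectory-disjoint, scored by R² (plus mean Euclidean cm error
for joint XY).

Preferred-direction uniformity bins tuned units (R² > 0.2) into 18
equal angular bins and reports the summed absolute deviation from the
mean bin count, normalized by the tuned-unit count (17/9 when all units
share one bin; 0 when exactly uniform). Cross-plane invariance fits
direction tuning per plane, takes each unit's circular absolute PD
deviation from the central plane (z = 0 horizontal, x = 30 cm vertical),
averages over units and planes, and excludes planes with fewer than
three tuned units; all angular differences are wrapped to (−π, π] (the
wrapping is our addition — an unwrapped difference would count a
179°/−179° pair as 358°). Paired t-tests over instantiations (df =
n − 1) with α = 0.05 compare trained against untrained populations;
zero-variance differences are flagged degenerate rather than tested.

## Numerical choices and degenerate inputs

* IK tolerance 1e-4 m; damped least-squares damping 1e-6, trust-region
  step cap 0.5 rad; restart poses at fixed limit fractions.
* Layer-norm ε 1e-5; Adam ε 1e-8; He/Glorot-style initialization with
  per-instantiation seeds; LSTM forget-gate bias 1.
* R² of a constant target: 1 if perfectly predicted, else 0 (matches the
  dead-unit exclusion rule).
* Zero-variance features: scalers fall back to unit scale; CKA and RDMs
  refuse constant inputs explicitly.
* Ties: bottom-k jerk selection breaks ties by sample id; one-against-one
  voting breaks ties by class order.
* Empty validation splits (tiny configs) fall back to the training loss
  for the early-stopping state machine.

## What the synthetic generator does and does not emulate

It emulates: 20 visually distinct single-stroke letter classes with
smooth, bell-profiled pen speeds; tablet-like 200 Hz sampling; the
writing-grid rescale and 66.7 Hz resample; the full affine/speed/plane
augmentation grid; muscle inputs whose velocity channels carry strongly
biased directional preferences (inherited from fixed moment arms), the
key input statistic for the preferred-direction analyses. It does not
emulate: individual handwriting idiosyncrasy across writers, pen
pressure, multi-stroke letters, Hill-type muscle dynamics, tendon
compliance, fusimotor drive, or any specific published musculoskeletal
geometry — so absolute tuning medians and absolute task accuracies are
not comparable to recordings or to full-scale results, and the package
asserts orderings instead.

## Known limitations

* The engine is CPU-bound R; full-scale (2 × 10⁵ samples) training is
  out of its intended range.
* The muscle stand-in has constant moment arms by default; angle-dependent
  polynomial terms are supported but the default geometry does not use
  them. One consequence: because muscle length encodes absolute posture
  and writing starts span the whole workspace, the pooled regression of
  *start-relative* position onto the length channel carries almost no
  signal, so the expectation that the length channel out-scores the
  velocity channel on position tuning does not hold under this geometry
  (the direction-tuning split — velocity channel far more
  direction-tuned — holds for 25/25 muscles). The corresponding check is
  kept, failing, as an honest record of the stand-in's limits.
* The desk-scale qualitative population results are stochastic over
  instantiation seeds and, at this scale, noise-dominated: with ~30–50
  direction-tuned units per layer, the per-pair uniformity deviation has
  sampling noise of the same order as the trained-vs-untrained
  differences, and the per-pair tuned-unit counts fluctuate by tens of
  units across initializations. In the package's own five-seed desk
  experiments the aggregate means move in the expected direction (more
  uniform preferred directions after recognition training; fewer
  direction-tuned units after decoding training), but a per-pair vote
  does not reach 4/5 agreement. Detecting these orderings reliably
  requires populations and training depths of the full-scale regime.
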