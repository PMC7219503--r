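---
title: "Assessing shoulder-exercise sessions from skeleton tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing shoulder-exercise sessions from skeleton tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armrehab)
```

## The assessment problem

A game-playing session is one iteration of a shoulder exercise — flexion,
horizontal abduction/adduction, or adduction of the right arm — recorded
as a sequence of 25 skeleton-joint positions at 15 frames/s. The task is
to decide, for a given participant and exercise, whether the arm
movements in a new session were executed correctly, using only a bank of
that participant's earlier sessions labeled correct/incorrect by a
physiotherapist. Sessions differ in length and pacing even within one
participant, and the sensor may sit anywhere relative to the body, so the
representation must be elastic in time and invariant to the sensor pose.

## The body-attached frame

Eight joints carry the signal: both shoulders (lS, rS), spine shoulder
(SS), spine base (SB), right hip (rHI), and the right elbow, wrist and
hand (rE, rW, rH). Each frame gets its own body-attached coordinate
system with origin at rS:

* the **coronal plane** is spanned by rS, lS, SB; its unit normal,
  oriented anteriorly, is $+z$;
* the **transverse plane** is spanned by rS, lS and the virtual joint
  $\widehat{SS} = SS + 0.2\,\hat z$ (SS is nearly collinear with the
  shoulder line, so it is shifted 0.2 m out of plane); its normal,
  oriented superiorly, is $+y$;
* the **sagittal plane** is spanned by rS, $\widehat{rS} = rS + 0.2\,\hat z$
  and $\widehat{\widehat{rS}}$, the shoulder dropped along $-y$ to the
  right-hip height; its normal is $+x = y \times z$.

Two numerical choices deserve a note. First, the anterior orientation of
$+z$ is resolved *intrinsically* from skeleton chirality — anterior has a
positive projection on $(SS - SB) \times (rS - lS)$ — rather than from
the sensor position. A sensor-referenced sign flips when the subject
turns 180° relative to the camera, which would silently negate the
position, velocity and acceleration features; the chirality rule is
invariant under every rigid motion. Second, the transverse plane defined
through $\widehat{SS}$ is exactly orthogonal to the coronal plane only
when SS lies exactly on the rS–lS line. Real skeletons put it a few
millimeters off, so the transverse normal is Gram–Schmidt-orthogonalized
against the coronal normal before $x$ is formed; the basis is therefore
orthonormal to machine precision for any valid skeleton, and identical to
the raw construction whenever SS is collinear with the shoulders. The
basis is recomputed independently at every frame, with no temporal
smoothing.

## The 38 features

From the arm vectors $\vec{SE}$, $\vec{EW}$, $\vec{WH}$ the per-frame
feature vector contains 9 vector–plane angles
$\theta_P^{\vec V} = \sin^{-1}(|\vec V\cdot\hat n_P|/\lVert\vec V\rVert)$,
2 inter-segment angles
$\theta_{\vec U\vec V} = \cos^{-1}(|\vec U\cdot\vec V|/\lVert\vec U\rVert\lVert\vec V\rVert)$,
and the positions, velocities and accelerations of rE, rW, rH along the
body axes (27 features). Angles are reported in degrees (the natural unit
for anatomical discussion; both formulas fold into $[0°, 90°]$ because of
the absolute values). Internally both angle formulas are evaluated in
their `atan2` forms, which are well-conditioned at 0° and 90° where the
inverse sine/cosine derivatives blow up — this is what keeps the
view-invariance error near machine epsilon instead of $10^{-6}$ degrees.

Velocities use the actual timestamp differences rather than a nominal
$1/15$ s, so dropped frames do not corrupt the kinematics. Boundary
frames are padded with the nearest valid value ($v(1) := v(2)$,
$a(1) := a(2) := a(3)$) so the feature series keeps the session length
$L$ — the warping distance needs a full row for every frame. The nine
$p$ components are positions, not velocities (tabulations of this feature
family sometimes conflate the two labels).

## Classification by average warping distance

The distance between two feature series is multidimensional dynamic time
warping: symmetric steps (1,0), (0,1), (1,1) with unit weights, local
cost the Euclidean distance over the feature dimensions, no warping
window (sessions are at most a few hundred frames, so the exact optimum
is affordable), ties among predecessors broken diagonal-first for
determinism. Three choices are deliberate, since the classical algorithm
leaves its local cost, step pattern and normalization open:

* **Feature z-scoring.** The features mix degrees, m, m/s and m/s²;
  without normalization one unit family dominates the Euclidean cost.
  Mean and SD are pooled over every frame of every member of the current
  gold-standard bank (training data only) and applied to both inputs.
* **Path-length normalization.** Session lengths differ systematically
  between correct and incorrect executions; dividing the accumulated cost
  by the warping-path length removes that confound. Raw cost is available
  via `normalize_by_path = FALSE`.
* **Decision direction.** The nearest bank wins: predict *correct* when
  $\bar d(SFV, GS_C) \le \bar d(SFV, GS_{IC})$, ties to correct. Verbal
  statements of this rule sometimes carry the opposite inequality, which
  inverts every label on separable data and is treated as a transcription
  error; `paper_literal_rule = TRUE` applies the inverted direction for
  comparison.

## Feature selection

Recursive backward elimination starts from all 38 features and repeatedly
removes the feature whose removal yields the highest inner score,
accepting the removal as long as that score is not a reduction (equality
is accepted, so ties favor smaller subsets), stopping when every removal
strictly hurts or one feature remains. Equal-scoring candidates are
resolved by removing the lowest canonical index — the procedure is fully
deterministic given its inputs. The inner score is the leave-one-out
accuracy within the training bank: among the candidate criteria for
wrapper selection, leave-one-out uses all training data without ever
touching the held-out fold.

Leave-one-out is quadratic in bank size and elimination evaluates
hundreds of candidate subsets, so `backward_eliminate()` can score on a
stratified member subsample (`inner_max_per_class`, drawn once per run
from a seed). `run_repeated_cv()` defaults to 8 members per side, which
keeps a full ten-repetition, tenfold evaluation of one participant and
exercise in the tens-of-minutes range on one core; the package's own
tests and the acceptance script keep that default but run two
repetitions, about three minutes per cohort.

## Evaluation protocol

Per participant and exercise: the 60 labeled sessions are split into 10
stratified folds of 3 correct + 3 incorrect; each fold in turn is held
out, the bank is built from the other 9 folds, backward elimination runs
on that bank only (nested selection), and the 6 held-out sessions are
classified, so each repetition classifies all 60 sessions exactly once.
Ten such repetitions (seeded `seed + r`) yield mean ± SD accuracy,
specificity, sensitivity and Cohen's kappa. Assigning the positive class
is a convention; here it is the *correct* sessions, so sensitivity is the
detection rate of correct executions (a config flag flips it). Kappa
bands follow the standard cutpoints — (0.8, 1] almost perfect, (0.6, 0.8]
substantial, (0.4, 0.6] moderate, (0.2, 0.4] fair, (0, 0.2] slight,
below 0 poor — with $\kappa = 0$ (unassigned by the open intervals)
mapped to "slight".

Because selection is nested, a repetition produces ten per-fold subsets
but the occurrence summaries expect one combination per repetition; the
reported combination is the set of features selected in at least half
the folds (falling back to the most frequent features when that set is
empty). `selection_scope = "per_repetition"` implements the literal
one-selection-per-repetition reading instead; it is optimistic because
selection then sees the test sessions, and which variant the original
evaluation used is ambiguous — both are provided, neither asserted.
CBOFF counts, for each feature, the optimized combinations containing it
(maximum = participants × repetitions); PBOFIF counts the participants
for which a feature appears more than twice among their ten combinations
(maximum = number of participants).

## The session simulator

The simulator is the package's stand-in for human tracking data, which is
not publicly available. A seated rigid-segment body (shoulder width
0.35 m, upper arm 0.30 m, forearm 0.25 m, hand 0.08 m — plausible
anthropometry, configurable, not population estimates) keeps the trunk
static while the straight right arm follows each exercise's waypoints in
elevation/azimuth space with minimum-jerk interpolation and a 1–2 s
terminal hold. Star layouts (9, 9, 13) sit on the projection of the ideal
full-range hand path, starting above the resting pose so a motionless
session scores zero; `game_score()` projects the hand orthographically
onto the coronal plane, scaled so the arm reach spans half the unit
screen, with a 0.05 capture radius.

Impairment modes mirror the ways executions fail: limited range of motion
(`rom_fraction` scales the angular excursion), unstable movement
(band-limited 4–8 Hz jitter of a given amplitude on rE/rW/rH), a bent
elbow, slowed pacing, and wrong movement patterns (the movement plane
swapped, or the arm freezing at 60% of the session). Measurement noise is
i.i.d. Gaussian, SD 5 mm per coordinate, on every joint. Tremor signals
are drawn even at zero amplitude so that sessions generated from the same
seed differ only by the amplitude scaling — this is what makes the
acceleration-feature response to tremor exactly monotone in tests.

Cohorts follow the reference acquisition design: 30 correct + 30
incorrect sessions per exercise per participant (180 total), durations
drawn per group — typically-developing-like means 4.4/4.9/6.2 s (SD
1.2/1.6/1.5) and cerebral-palsy-like means 6.8/7.6/11.4 s (SD
5.1/4.4/5.0) for the three exercises — truncated at a 3 s floor so the
terminal hold and movement phases always fit. A participant's motor
limitation is modeled as a stable trait: one impairment style is drawn
per participant and the incorrect sessions jitter around it. This matters
for the classifier: an incorrect class assembled from unrelated
impairment modes is diffuse, and the average-distance rule then drags
every query toward the compact correct bank; consistent per-participant
impairment reflects both how patients actually move and how the control
cohort was instructed to behave. Clinically, correctness is judged
qualitatively by a physiotherapist, so the default parameter ranges
(typically-developing-like: incorrect ROM fraction 0.40–0.65, tremor
15–30 mm; cerebral-palsy-like: overlapping ranges with mild tremor in the
correct class) are documented stand-ins chosen once, not estimates.

## What the synthetic experiments do and do not show

The simulator produces rigid segments, stationary trunks, stereotyped
minimum-jerk pacing and Gaussian sensor noise. Real tracking data adds
soft-tissue and tracking artifacts, trunk compensation, occlusion
dropouts and label noise in the physiotherapist's gold standard. Passing
the package's recovery tests therefore shows that the pipeline is
implemented correctly and behaves as designed in its intended regime —
near-perfect recovery on well-separated cohorts, chance-level accuracy
and near-zero kappa under label permutation, monotone degradation as
impairment separation shrinks — not that any particular accuracy will be
attained on clinical recordings.

## Degenerate inputs and edge rules

Sessions shorter than 3 valid frames are rejected (accelerations need
three). Missing required joints are linearly interpolated across interior
gaps of at most 3 frames, otherwise the frames are dropped
(`missing_joint_policy = "reject-frame"` drops them outright). Collinear
plane-defining joints, zero-length arm vectors, and a hip at shoulder
height raise geometry errors naming the plane and frame. Zero-variance
features get unit SD in the z-scoring so constant dimensions contribute
nothing rather than NaNs. Kappa with chance agreement 1 returns 1 when
observed agreement is also perfect and NA with a warning otherwise.

## Problem sizes used by the tests and the acceptance script

Feature extraction, geometry and oracle checks run at full precision on
small fixtures (series up to 6 frames for the exhaustive warping-path
oracle, 100 random rigid motions, 1000 random confusion tables). The
cross-validation experiments use one typically-developing-like
participant, one exercise, two repetitions with nested elimination at 8
inner members per side, ten label-permutation seeds, and ten seeds per
impairment level for the degradation curve — sizes chosen so the whole
evaluation reruns from scratch in a few minutes on one core while leaving
every qualitative conclusion identical to the full ten-repetition
protocol.
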