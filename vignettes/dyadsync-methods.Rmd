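---
title: "Methods: measuring and modelling perceived dyadic synchrony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring and modelling perceived dyadic synchrony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the scientific and numerical choices behind
`dyadsync`: what each measure assumes, which parameters matter, what the
synthetic-data generator does and does not emulate, and where the design was
genuinely open.

## 1. Kinematic measures

### Pose-distance similarity

Each figure's upper body is tracked at seven joints (neck, shoulders,
elbows, wrists — "hands" are the BODY_25 wrist keypoints; the dedicated
hand sub-model is not used). Per frame we compute the Euclidean distances
between all ordered joint pairs: 7 × 6 = 42 entries. The ordered-pair count
is deliberately redundant — 21 unordered pairs carry the same information,
and a test asserts that the cosine computed from 21 pairs agrees to 1e-12 —
but 42 matches the convention of pose-matrix descriptions of this kind.

The vector is L2-normalized, which makes it *body-centric*: invariant to
the figure's position in the image, its apparent size, and any rigid motion
or reflection. Frame similarity between the two figures is the cosine of
their normalized distance vectors. Because both vectors are elementwise
nonnegative with unit norm, the cosine is guaranteed to lie in [0, 1],
equals 1 exactly when the two poses have proportional distance profiles,
and inherits all the invariances above. The per-clip **measured
similarity** is the mean over valid frames; a frame is valid when every
joint of both figures reaches the confidence threshold (default 0.1), and
the fraction of valid frames is reported as `coverage`.

Two things to note. First, cosine similarity between plausible human poses
is high in absolute terms (even unrelated poses typically score > 0.9,
because all humans share gross limb proportions); what carries information
is the *contrast* between conditions, not the absolute level. Second, the
choice of comparison operator inside the paradigm's published range
[0 = none, 1 = identical] is not uniquely determined; cosine on normalized
nonnegative vectors was chosen because it guarantees that range, the
identity-at-1 property, and isometry/scale invariance. Max-normalization
instead of L2 would rescale both vectors by scalars and leave the cosine
unchanged.

### Predictability (sample entropy)

SampEn(m, r) is the negative log conditional probability that two distinct
length-`m` subsequences within Chebyshev distance `r` of each other remain
within `r` when extended to length `m + 1`. Defaults are the literature
conventions: `m = 2`, `r = 0.2 × SD` of the series, matches counted with
`<= r`, self-matches excluded, and both template sets drawn from the same
`N − m` start positions so the ratio is a genuine conditional probability.
A constant series yields 0 (perfectly predictable); the statistic is
undefined (flagged, never imputed) when no template pair matches at either
length. Per clip, entropy is computed for the x and y series of each
person's two wrists — eight channels — and the defined channels are
averaged; unreliable channels (untracked wrists) are excluded with a
warning. Implementation equals a brute-force O(N²) double-loop oracle to
1e-12 in the tests.

### Smoothing

Trajectories are smoothed per coordinate channel with a Savitzky–Golay
filter, window 13 frames, polynomial order 2 (about 0.2 s at 60 fps). At
the series ends the window is truncated to the available samples and the
local polynomial is evaluated off-centre; consequently the operator
reproduces any quadratic trajectory *exactly*, endpoints included (tested
to 1e-9). Similarity and entropy both operate on smoothed series, matching
a pipeline in which smoothing precedes everything downstream; the
unsmoothed path only triggers a warning, not an error, because the measures
remain well defined.

## 2. Experimental-design machinery

Recordings are segmented into consecutive non-overlapping 10-s clips
(trailing remainder dropped). Condition labels attach from the source
task — mirroring (high synchrony) vs observing (low) — never from a
kinematic threshold. Counterbalancing assigns each clip a leader colour
(red/blue) and side (left/right) so that the four cells differ by at most
one clip overall *and* within each leader; the subset splitter then
produces two 100-clip sets sharing exactly two clips, splitting each
leader's unique clips evenly and keeping every colour-by-side cell within
one clip of even between the sets. The split is solved exactly: clips are
dealt pairwise within (leader, cell) groups, and the odd leftovers are
oriented along Eulerian trails of the leader-by-cell multigraph, which
provably bounds every margin by one. Trial schedules contain each of 50
sampled clips once per question (synchrony, enjoyment, reproducibility) in
fully random order, plus three attention probes at uniformly random,
mutually non-adjacent positions — 153 trials. Attention responses in
[0, 25] count as correct (the slider's "not at all" end); participants are
included with at least 2 of 3 correct. Probe placement and the closed
interval are our choices where the procedure's text is silent.

## 3. Rating models

### Accuracy

Accuracy per trial is `100 × measured similarity − synchrony estimate`, on
the slider scale; positive = underestimation. The similarity is rescaled
by 100 so the difference and the condition intercepts live in slider
units — necessary for intercepts in the high-20s to be dimensionally
sensible. The distributional model gives each condition its own intercept,
covariate slopes, and residual SD, with participant and clip random
intercepts. Covariates are z-scored inside the fitting function — traits
across participants, trial-level covariates across trials — so that slope
scales are comparable.

### Enjoyment

Enjoyment ratings pile up near zero and around the middle of the scale, so
the model is a two-part hurdle at the published cut: ratings ≤ 10 ("very
low enjoyment") follow a Bernoulli-logit regression with participant
random intercepts; ratings 11–100 ("enjoyment per se") follow a Gaussian
regression with participant and clip random intercepts. The two parts
share covariates (measured similarity, predictability, six traits) but are
estimated independently — a test verifies that modifying only
above-threshold ratings leaves the hurdle posteriors draw-for-draw
unchanged. Ratings are modelled raw (not rescaled); an all-one-class
hurdle indicator is reported as degenerate with a warning rather than an
error.

### Priors, sampling, diagnostics

Priors are weakly informative on the response scale: Normal(0, 20) on
intercepts, Normal(0, 10) on slopes of z-scored covariates,
Exponential(0.1) on every SD. One deliberate exception: the continuous
enjoyment intercept gets Normal(0, 100), because that response lives on
11–100 (posterior mean ≈ 50) and a 20-SD prior centred at zero would
shrink it materially; nothing else changes.

No probabilistic-programming backend is assumed. The Gaussian parts are
sampled by Gibbs (conjugate normal draws for coefficients and random
intercepts; adaptive random-walk Metropolis on log-SDs, swept several
times per iteration). The logit part uses adaptive Metropolis with a
Fisher-information preconditioner and vectorized per-participant intercept
updates. Two families of extra moves fix the slow directions of the
posterior: *translation* moves shift mass between a coefficient block and
the random intercepts it is confounded with (valid whenever the covariate
is constant within the grouping factor, including condition-masked columns
within condition-nested clips), and *rescale* moves random-walk log(τ)
holding the standardized intercepts fixed. All moves are exact
Metropolis–Hastings updates.

Defaults: 2 chains × 1000 stored draws (thin 2, warmup 500), seeds always
explicit, bit-identical reruns. Reported parameters must pass split-R̂
≤ 1.05 and ESS ≥ 400; failures set `converged = FALSE` and warn loudly.
HPD intervals are the shortest window of ⌈0.95·n⌉ sorted draws; with
finite draws this is a point estimate of the interval and slightly noisy,
which is why the recovery suites use full-length chains. WAIC uses the
standard pointwise lppd/p_waic decomposition on the Gaussian parts.

## 4. The synthetic world

The generator emulates the stimulus material, not human biomechanics:
10-s, 600-frame clips; a leader whose shoulder/elbow angles are sums of
3–5 random sinusoids in 0.1–1.5 Hz (improvised arm movement band) driven
through forward kinematics with constant bone lengths (upper arm 60 px,
forearm 50 px, tested to 1e-6); a follower that either mirrors with a
100–300 ms lag (default 200 ms) plus Gaussian joint-angle noise (default
0.05 rad), or — in the low-synchrony condition — holds a resting posture
with small jitter, matching the "observing" task semantics rather than an
uncoupled mover. Stimulus pools default to the stated design: 198 clips,
85% high synchrony, 16 leaders round-robin.

The rater simulator draws six correlated traits (pairwise r = 0.2,
empathy–autistic-traits r = −0.3, loosely echoing the instruments), maps
them to instrument-like scales, and generates the three ratings per trial
from exactly the models the fitters assume. Its "stated world" defaults:
underestimation offsets α_high = 26, α_low = 37.5 slider units (chosen so
the 85/15 mixture averages near the high-20s group-level underestimation
this paradigm reports, with low synchrony underestimated more); a
body-competence slope of −2 at low synchrony and an autistic-traits slope
of +1.5 at high; baseline very-low-enjoyment log-odds −1.75 (≈ 15%) pushed
down by similarity (−1) and up by body perception (+1); continuous
enjoyment centred at 50 rising with similarity (+5) and empathy (+3) and
falling with entropy (−2); residual SDs 10/12 (accuracy) and 12
(enjoyment); random-intercept SDs 6/3 (accuracy) and 0.5/5/2 (enjoyment).
These were fixed once from the qualitative effect pattern of the paradigm
and are not tuned to test outcomes.

Two technical points. Covariates are z-standardized *within the generated
panel* before the true slopes are applied, so serialized ground truth is on
exactly the scale the fitters report; with population-scale standardization
the sample-SD error at desk-scale n would silently bias every recovery
target. Ratings are clipped to the slider range, a mild bias source near
the bounds; recovery tests therefore use truths away from the bounds, which
the defaults respect (e.g. low-synchrony similarity ≈ 0.94 keeps estimates
near 56, far from 0).

What a green test does *not* establish: the generator's similarity levels
(high ≈ 0.99, low ≈ 0.94) are not calibrated to any real distribution —
only the ordinal high > low contrast is asserted; angle-space sinusoids
lack pauses, drift, tracking dropouts and re-identification errors of real
OpenPose output; and simulated raters are exactly the fitted model, so
recovery tests validate the inference machinery, not the behavioural
theory.

## 5. Scale of the shipped test suites

The 20-replicate recovery suites run at desk scale — 16-clip pools,
40-rater panels, 2 × 1000 draws — to stay inside a ~10-minute budget on
one CPU; coverage of the 95% HPDs is required to be at least 0.85 for
every true coefficient. Single-property tests use smaller configurations
still. Package defaults remain full-size (198 clips, 153 trials, 2000+
reported draws).

## 6. Known limitations

- Person tracking is by horizontal ordering only; figures that cross sides
  would be mis-assigned (the stimuli fix one figure per side).
- The matrix-comparison operator and normalization inside the published
  [0, 1] range are reasoned choices, not a reconstruction of the original
  scripts; absolute similarity levels are therefore not comparable across
  implementations, contrasts are.
- The hurdle cut treats exactly-10 ratings as "very low"; the original
  instrument's granularity near the boundary is unknown.
- The logit part's intercept is weakly identified when very-low ratings
  are rare; the degenerate-data warning covers the limit case.
- No pose estimation, no video rendering, no frequency-domain synchrony
  measures, no Granger causality — all out of scope by design.
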