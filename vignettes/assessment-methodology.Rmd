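---
title: "Methodology: explainable skill assessment from simulator kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methodology: explainable skill assessment from simulator kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voa)
```

## The assessment problem

Virtual-reality surgical simulators record rich kinematics — instrument tip
positions, applied forces, bleeding — but converting those traces into
actionable teaching is hard. Black-box classifiers can label a trainee
"novice" with high accuracy while offering no guidance on *what* to change.
`voa` takes the opposite route: a deliberately simple linear model whose
decision is an exact sum of per-metric contributions, so every
classification comes with a metric-by-metric explanation and a concrete
practice target.

## Model

For metrics $x_1,\dots,x_k$ with training-cohort means $\mu_i$ and sample
standard deviations $\sigma_i$ (the $n-1$ denominator, the usual unbiased
cohort estimate), define $z_i = (x_i - \mu_i)/\sigma_i$. The classifier is
a linear support-vector machine trained on the z-scores by minimizing

$$J(\theta, b) = \tfrac12\lVert\theta\rVert^2
  + C\sum_j \max\bigl(0,\, 1 - y_j(\theta^\top z_j + b)\bigr),
  \qquad y \in \{+1 \text{ skilled},\ -1 \text{ novice}\}.$$

A new performance is scored as $h = \theta^\top z + b$, labelled skilled
when $h > 0$, and presented as a gradient of expertise through the logistic
transform $P(\text{skilled}) = 1/(1+e^{-h})$.

Assumptions worth stating:

* **Linearity.** Skill differences are assumed monotone in each metric
  after z-scoring. This is what buys exact explainability: the margin
  decomposes as $h = \sum_i \theta_i z_i + b$ with no interaction terms.
* **Frozen normalization.** New trainees are normalized with the training
  $\mu_i, \sigma_i$, never their own; the benchmark $z = 0$ is therefore a
  property of the training cohort, not of the trainee.
* **The bias is a weight without a metric.** It shifts the decision
  boundary and the probabilities but is excluded from per-metric verdicts —
  there is no behaviour a trainee could change to move it.

### Probability calibration

The logistic transform uses unit slope and zero offset on the raw margin.
A Platt-style recalibration (fitting slope/offset on held-out data) would
change the displayed percentages but not the label or the verdicts; with
leave-one-out validation on small cohorts there is no spare data to fit it
cleanly, so the raw-margin form is the default and the displayed
percentages should be read as a monotone expertise gradient, not as
calibrated frequencies.

### Competency verdicts and the mastery gate

A metric is *competent* when its contribution $\theta_i z_i$ is strictly
positive. Two tie rules are deliberately conservative, failing ambiguity
toward further practice: $h = 0$ classifies as novice, and $z_i = 0$
(exactly at the benchmark) is *not yet competent*. The report groups metrics
into ordered steps — by default step 1 = safety metrics (bipolar maximum
force, bleeding rate), step 2 = movement metrics (inter-tip distance, tip
acceleration) — and step 2 unlocks only when **every** step-1 metric is
competent, the mastery-learning rule that safety must be secured before
efficiency is coached. The gate is pure boolean logic over the verdicts and
is tested against a brute-force truth table over all competency patterns.

## Training: monotone iterative cost reduction

The trainer is deterministic subgradient descent on $J$ with backtracking
step halving: a step is accepted only if it strictly reduces the cost, the
step size grows modestly after success and halves after failure, and
training stops on a fixed iteration budget (default 500), 10 consecutive
relative improvements below $10^{-9}$, or 20 consecutive stalls. Properties
that follow by construction, and that the test-suite checks:

* the cost trajectory is non-increasing — every accepted iterate reduces
  $J$;
* initialization at the origin makes the fit exactly antisymmetric under
  label flips (weights and bias negate);
* two runs on identical inputs are bit-identical.

Exact solver identity is *not* a design goal; correctness is defined
behaviourally (separable cohorts are separated, the recovered hyperplane
direction agrees with an independent SVM implementation and with the
generative direction on synthetic data, cosine similarity $\ge 0.95$).

## Validation: leave-one-out cross-validation

Each cohort member is held out once; the normalizer **and** the model are
refit on the remaining $n-1$ members, so no information about the held-out
member leaks into the parameters that score it. Confusion counts aggregate
across folds; sensitivity is the fraction of skilled members correctly
classified, specificity the fraction of novices. A fold whose training set
degenerates to a single class raises an error naming the fold.

## Metric selection

The wrapper search alternates a forward phase (repeatedly add the candidate
metric that maximizes LOOCV accuracy, while it strictly improves) and a
backward phase (repeatedly drop any metric whose removal does not decrease
accuracy), until a full alternation changes nothing. Ties are broken toward
the smaller set, then toward earlier candidate order, making the search
fully deterministic. Every evaluated subset is logged in the trace, and the
reported accuracy always equals the trace maximum. The selection objective
is in-search LOOCV accuracy; on small cohorts this estimate is optimistic
for the *selected* set (selection bias), a known property of wrapper
methods that an outer validation loop would be needed to remove.

## The synthetic-recording generator

No public dataset of raw simulator recordings exists for this task, so the
package generates its own, with two goals: analytic recoverability (each
metric's expected value is controlled by one profile parameter) and
controllable group separation. Channels and defaults:

* **Tip paths.** A constant-velocity drift (start $\sim N(0, 2\,\text{mm})$
  per axis, velocity $\sim N(0, 0.4\,\text{mm/s})$) plus tremor: white
  Gaussian acceleration integrated twice with leaky integration (velocity
  decay 0.90, displacement decay 0.99 per sample). The drift contributes
  zero acceleration, so with `tremor_accel_mm_s2 = 0` the measured mean
  second-difference acceleration is exactly zero — the analytic oracle the
  tests rely on. Pure (undamped) double integration was rejected because
  position variance grows as $t^3$ and the wandering tips would destroy the
  tip-distance channel; the damping keeps tremor displacement bounded while
  the measured acceleration still scales linearly with the parameter (the
  per-axis sd is the parameter divided by $E\lVert N_3(0,I)\rVert =
  \sqrt{2}\,\Gamma(2)/\Gamma(3/2) \approx 1.596$).
* **Tip separation.** The bipolar tip is offset from the aspirator tip by a
  per-trial constant vector of length $\max(0.1, N(\text{mean},
  \text{sd}))$; within-trial variation comes from tremor.
* **Forces.** Per-sample $\max(0, N(\text{mean}, \text{jitter}))$ per
  instrument.
* **Bleeding.** Ten piecewise-constant segments with rates
  $\max(0, N(r, r \cdot \text{bleed\_jitter\_frac}))$, integrated —
  cumulative volume is non-decreasing by construction, and with zero jitter
  the bleeding-rate metric recovers $r$ exactly.
* **Defaults** (chosen once as plausible magnitudes for a bimanual
  resection task): 120 s at 20 Hz; skilled vs novice bipolar force 0.5 vs
  1.0 N, tip separation 8 vs 15 mm, tremor 30 vs 80 mm/s², bleeding 0.04 vs
  0.10 mL/s.

Determinism: member $i$ of a cohort uses seed
$(s \cdot 48271 + i \cdot 8191 + 1) \bmod (2^{31}-1)$ — a portable integer
mixing rule exact in double arithmetic — so cohorts reproduce byte-for-byte
through CSV serialization.

**What the generator does and does not emulate.** It reproduces the
*statistical shape* the assessment pipeline consumes: two groups whose
force, bleeding, tip-distance and acceleration distributions differ in the
direction the validated model's all-negative weights imply (skilled lower on
all four). It does not model tissue deformation, task structure, pauses,
learning within a trial, or between-subject variability beyond seed
randomness — within a group, trials differ only by noise realization, so
synthetic cohorts are more homogeneous than human ones. Consequently,
passing tests demonstrate the pipeline's correctness and statistical
behaviour (perfect separation when groups are far apart, chance-level
accuracy on permuted no-signal cohorts), not that real cohorts of this size
would yield any particular accuracy.

## Metric definitions and numerics

* **Maximum bipolar force**: instantaneous per-sample maximum of the force
  trace (no windowing — the simplest reading of "maximum force applied").
* **Bleeding rate**: net volume over net time. The alternative
  (instantaneous maximum rate) penalizes brief spikes; net rate is the
  simplest definition consistent with a one-line description and is exactly
  recoverable from the generator.
* **Mean tip distance**: mean over all samples of the Euclidean inter-tip
  distance, with no trimming of idle periods (no trimming rule is defined,
  and trimming would add a free parameter).
* **Mean tip acceleration**: mean magnitude of the central second
  difference, endpoints dropped, per-interval time steps
  ($a_k = 2\,[\Delta t_1 p_{k+1} - (\Delta t_1+\Delta t_2) p_k +
  \Delta t_2 p_{k-1}] / [\Delta t_1 \Delta t_2 (\Delta t_1+\Delta t_2)]$);
  exact on quadratic paths, a warning if the sampling interval varies by
  more than 10%.

Degenerate inputs fail loudly with the offending name: constant metric
columns (zero variance) in the normalizer, duplicate registry names,
recordings with fewer than 3 samples for acceleration, zero-duration trials
for bleeding rate.

The registry is deliberately extensible: a metric-development campaign
screens hundreds of candidates, and the wrapper search is written against
an arbitrary ordered registry, not the four shipped metrics.

## Reference model fixture

The package ships the published weights of the validated 4-metric model
(−0.6002 bipolar max force, −0.5106 bleeding rate, −1.4902 tip distance,
−0.2710 bipolar acceleration; safety/safety/movement/movement). The
original training cohort's means, standard deviations and bias were never
published, so the fixture carries identity normalization (the model
consumes z-scores directly, which is how the proficiency benchmarks are
expressed) and zero bias; its JSON records this explicitly. It supports the
worked examples — margin $-2.8720$ at $z = (1,1,1,1)$, tip distance ranked
most influential — and the exact-decomposition checks.

## Problem sizes used by the test suite

Simulation-backed tests use trial durations of 5–20 s at 20 Hz and cohorts
of 8–50 members, sizes at which every statistical property under test
(separability at wide parameter gaps across 10 seeds, chance-level accuracy
on 20 permuted null cohorts, recovery of 2 informative among 5 candidate
metrics across 10 seeds) is already stable; the defaults above describe the
intended realistic operating point.

## Known limitations

* Binary expertise only; multi-group or continuous-skill extensions would
  need a different loss and feedback mapping.
* Raw-margin probabilities are uncalibrated (see above).
* Wrapper selection accuracy is an optimistic estimate for the selected
  set; report it as in-search accuracy, not generalization accuracy.
* The generator's groups are internally homogeneous, so synthetic LOOCV
  accuracies are best-case; real cohorts with overlapping skill
  distributions will sit below them.
* The feedback layer emits message keys (`reinforce`/`improve`) and a text
  rendering; audio/video coaching content is out of scope.
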