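---
title: "Sketch-to-controller gait synthesis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sketch-to-controller gait synthesis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gaitforge turns a coarse, hand-designable description of a walking (or
sitting/standing, or stair) motion into the full training corpus a
DNN-based impedance controller for a powered prosthetic knee and ankle
needs: continuous multichannel gait patterns, 5-ms time series, aligned
impedance-parameter trajectories, and the two trained predictor
networks. This vignette explains the models implemented, the parameters
that matter, and the decisions taken where the design was genuinely
open.

## Data model

Everything is built on four channels in fixed order: vertical load
(kg) and thigh, knee and ankle angles (degrees). A *gait pattern* is a
matrix over gait-cycle phase at 0.5% resolution. It exists in two
explicit forms: the closed grid 0–100% (201 rows, both endpoints, the
natural output of cycle extraction) and the half-open grid 0–99.5%
(200 rows). The half-open form exists because the generator halves the
sequence length three times; 200 is divisible by 8, 201 is not. The
conversion is always explicit (`drop_endpoint()`, `discretize()`), never
guessed from context.

A *sketch* is an 11 × 4 matrix with one value per channel every 10% of
the cycle — coarse enough to design by hand from qualitative knowledge
("load falls to zero during swing", "knee flexes about 60° mid-swing"),
dense enough to condition generation.

All learning happens in normalized units via the affine map

$$v_n = 0.1\,\frac{v}{g} + 0.5,$$

with gain $g = 36$ for the three angle channels and, for the vertical
load, either the subject's body weight (benchmark convention, which
removes between-subject load differences) or the constant 48 kg (bypass
convention, which deliberately keeps them). The map centres each
channel at 0.5 and compresses typical gait excursions into roughly
(0.2, 0.8), comfortably inside the (0, 1) range a sigmoid output can
reach. Values outside (0, 1) are legal in intermediate arithmetic — only
the generator's sigmoid guarantees the bound — and a validation helper
flags them where a stage requires the range.

## Cycle extraction

Raw trials are segmented with a smoothed z-score peak detector: a
rolling mean and standard deviation over the previous `lag` samples of
an influence-damped copy of the signal; a sample more than `threshold`
standard deviations above the rolling mean is flagged, and flagged
samples enter the damped copy with weight `influence` only, so a peak
does not inflate the statistics that detect it. Runs of flagged samples
collapse to the index of the run's maximum value. Defaults are lag 25
samples (125 ms), threshold 3, influence 0.1; all exposed in
`peak_detector_config()` because the right tuning is data-dependent.
Segmentation runs on the vertical load by default: the load transient
at weight acceptance is the most robust periodic landmark across
ambulation modes. Cycles between consecutive peaks are linearly
resampled onto the 201-node grid and reduced by an element-wise median
(even counts average the two central values, the `stats::median()`
convention). No offset removal or normalization happens at this stage.

## The synthetic benchmark generator

The package replaces external motion-capture corpora with a parametric
generator, so every downstream stage can train and be tested without
downloads. Its templates are fixed knot tables — design fixtures, not
measured data — shaped to the qualitative structure of healthy gait:
double-hump load with a zero-load swing window, mono-phasic thigh
excursion, biphasic knee flexion with a large swing peak, small ankle
excursion. Four modes ship: level-ground walking, stairs up, stairs
down, and an integrated sitting-to-standing/standing-to-sitting cycle.

Two conventions matter:

* **Phase 0 sits at the load maximum.** Cycle boundaries are then
  exactly what load-peak segmentation recovers, so extraction
  round-trips are well-defined. A trial starts mid-cycle (phase 50%)
  like a real recording, which puts every boundary strictly inside the
  series.
* **The load template uses monotone Hermite interpolation** between its
  knots, while angle templates use periodic cubic splines. Monotone
  interpolation keeps the swing plateau *exactly* zero (a periodic
  spline wiggles a few tenths of a percent around it, enough to distract
  a z-score detector on noiseless data) and pins the curve maximum at
  the 0% knot rather than letting the spline overshoot past it. Angles
  have no plateaus and benefit from the smoother periodic fit.

Subject variability enters as body weight (drawn uniformly on 55–90 kg,
an ordinary adult range), per-channel amplitude scales (log-normal,
sdlog 0.06, i.e. ±6% typical), smooth phase jitter (a monotone cubic
time warp through perturbed interior knots with fixed endpoints, 1%
standard deviation), and additive sensor noise (1.5 kg load, 1° angles).
The warp's fixed endpoints preserve periodicity, so zero-noise samples
close their cycle exactly. All randomness flows from one explicit seed
per call; with zero jitter, zero noise and unit scales a sample *is* the
template.

What the generator does **not** emulate: inter-stride correlation
structure, asymmetry, fatigue drift, sensor-specific offsets
(goniometer vs motion capture), and genuinely pathological gait. Tests
passing on this corpus demonstrate that the pipeline's machinery is
correct and recoverable at realistic signal scales — not that the GAN
generalizes to clinical data.

## The conditional GAN

The generator is an encoder–decoder over the phase axis: three stride-2
kernel-2 convolutions (16, 32, 64 filters, LeakyReLU) take the 200-row
input to a 25-row bottleneck; three transposed convolutions (32, 16, 4
filters) bring it back; a final width-200 dense layer with sigmoid maps
every channel into (0, 1). The dense layer is applied along the phase
axis and shared across channels — the architecture string ends with a
dense width equal to the sequence length, and this placement is the one
that reproduces the stated 200 × 4 output shape. The discriminator
consumes condition and candidate concatenated on the channel axis
(standard image-to-image practice; the conditioning mechanism is
otherwise unspecified), reduces with the same three convolutions, runs
an 80-unit LSTM with LeakyReLU state activation, and emits one realness
logit from its final state.

Training follows the published recipe: mean-absolute-error
reconstruction weighted by λ = 1000 plus the adversarial term, batch
64, Adam at learning rate 0.01, 500 epochs at full scale. λ = 1000
makes the objective reconstruction-dominated — the adversarial term
contributes sharpness rather than direction — which is why the
aggressive 0.01 rate trains stably here; it is nonetheless exposed in
`gan_config()`, with 1e-3 the documented fallback if training diverges
on user data. Patterns are normalized *before* pairing (load by subject
weight), so the networks only ever see (0, 1)-scaled data; the smoothing
of generated outputs also runs in normalized units, before any
denormalization.

Because the framework here is a compact, purpose-built engine, two
initialization choices do work that larger frameworks leave implicit:
sigmoid-activated layers scale Glorot weights by gain 4 (the inverse of
the sigmoid's slope at zero), preserving signal variance through deep
sigmoid stacks instead of letting it collapse geometrically; and LSTM
recurrent kernels use per-gate orthogonal blocks with a unit forget-gate
bias, the standard recurrent initialization. Both are verified by the
test suite's finite-difference gradient checks and training-closure
properties.

## From pattern to controller corpus

A sketch is multiplied into variations by perturbing every channel-node
value $U$ to $U + 0.4\,\sigma(U)\,r$, with $\sigma(U)$ the population
standard deviation of the channel across its 11 nodes and $r$ drawn
uniformly on $[-1, 1]$ *per node* (the per-node reading of "random
values"; both the σ convention and the per-node draw are configurable).
Each generated, smoothed pattern is expanded to a time series at the 5
ms sample period by linear resampling onto `round(duration / 0.005)`
samples; durations are drawn uniformly from the mode preset (1–1.25 s
for walking, 5–6.25 s for the sit/stand cycle; 60 variations per
dataset, 10 datasets). Consecutive patterns are stitched with one or
two linearly interpolated bridge samples per junction (drawn per
junction), which is precisely why the boundary discontinuity of
generated patterns halves: the inserted midpoint sits half-way across
the end-start gap.

Normalized impedance profiles for knee and ankle — stiffness high under
load and low in swing, damping bumps around the stance–swing
transitions — ship as knot tables evaluated by linear interpolation
(which cannot leave [0, 1]). They are design fixtures shaped to the
published qualitative trajectories; no numeric impedance data exists to
copy. Profiles are sampled at the same duration as their gait pattern
and stitched with the same junction treatment, keeping the two blocks
sample-aligned by construction. Physical units come from linear scaling
onto the hardware ranges: knee 1.5–5 Nm/deg and 0.05–0.5 Nm·s/deg,
ankle 3–8 Nm/deg and 0.05–0.15 Nm·s/deg.

## The controller networks

Both predictors consume 250 ms (50-sample) histories. The equilibrium
network maps (thigh, load) histories to the knee and ankle angles 100
ms (20 samples) ahead — the impedance law's set point is future
posture. The stiffness/damping network maps all four gait-channel
histories to the four normalized impedance values; its targets are
taken at the window's final sample (target alignment is otherwise
unspecified; the choice is configurable). A series of N samples yields
N − 69 windows.

Architecture, per the published strings: Gaussian noise (σ = 0.02,
training only), a 32-filter kernel-8 stride-1 convolution, a 20-unit
LSTM, dense 30 → 10 → output, all sigmoid; 2 outputs for equilibrium, 4
for impedance. Training: MSE, batch 256, 15 epochs; Adam (lr 0.001) for
the equilibrium net, RMSProp (lr 0.001) for the impedance net.

Equilibrium outputs are sigmoids rescaled onto the clamp ranges — knee
0–120°, ankle −8–8° — so the commanded angle satisfies its limits
*structurally*; the published statement gives limits, not a mechanism,
and structural clamping is the variant that cannot emit an out-of-range
command even mid-training. Training targets are clipped into the clamp
range before rescaling: a target beyond the clamp is unreachable by the
head and uninformative, since the commanded equilibrium could never go
there anyway. The final-layer bias starts at the logit of the target
mean, so the first epochs learn structure rather than the prior.

The resulting command feeds the impedance law
$$\tau_i = -K_i\,(\theta_i - \theta_i^{eq}) - b_i\,\dot\theta_i,$$
a spring toward the equilibrium angle plus a velocity damper, evaluated
per joint in `impedance_torque()`. The real-time loop of the physical
leg (5/12/25 ms threads) is not reproduced; `simulate_commands()`
replays a series offline at full speed instead.

## Evaluation metrics

* **R²** about the reference mean and **RMSE** in channel units.
* **1-D SSIM** in unweighted sliding windows (default 11 samples) with
  the image-processing constants $C_1 = (0.01L)^2$, $C_2 = (0.03L)^2$
  and dynamic range $L = 1$ on normalized patterns; computed per
  channel, then averaged — the per-position map (and its complement,
  the dissimilarity map) localizes disagreement along the cycle.
* **Boundary discontinuity** in three modes matching the three pattern
  sources: last-vs-first row on the closed grid, last-vs-first on the
  generated half-open grid, and bridged-midpoint-vs-first — the latter
  is algebraically half the raw gap.
* **RMS jerk** $J = \sqrt{\tfrac12 \sum_p \theta'''(p)^2}$ with the
  third derivative taken by the central stencil
  $(-\tfrac12, 1, 0, -1, \tfrac12)/h^3$ over the phase grid, boundary
  samples excluded. The ½ factor is kept exactly as printed in the
  source formula even though it is unconventional; the differentiation
  variable is gait-cycle percent by default and switchable to seconds
  via the `step` argument. Constant, linear and quadratic signals have
  exactly zero jerk — a property the tests pin down.

## Numerical choices

The output smoother is a cubic smoothing spline in the `csaps`
parameter convention: minimize
$p\sum(y - f)^2 + (1 - p)\int f''^2$, so $p = 1$ interpolates and
$p \to 0$ tends to the least-squares line, with default $p = 0.1$ over
the phase grid in percent. `stats::smooth.spline()` parameterizes the
same trade-off differently (spar, with internal rescaling), so the
Reinsch/De Boor system is solved directly; the two limiting behaviours
are pinned by tests. Smoothing-parameter semantics therefore transfer
unchanged from the published setting.

Problem sizes used by the shipped property tests: the generation
closure trains on a 100-pair corpus (2 modes × 5 subjects × 10
repetitions) for 50 epochs; the controller recovery trains on ~68,000
windows from 300 repetitions of one smoothed sketch pattern at preset
durations for the full 15 epochs. Both are the package's scaled-down
renditions of the full recipe (500 epochs; 10 datasets × 60 variations
per mode) chosen to keep a complete test run on one CPU in minutes
while preserving every structural property of the full-scale runs.

## Known limitations

* The GAN trains per-corpus; there is no transfer or fine-tuning story
  across subject populations.
* The synthetic generator's independence assumptions (noise i.i.d.
  across phase, jitter independent across strides) understate the
  correlation of real gait variability.
* SSIM windowing and the jerk normalization follow declared
  conventions; comparisons against numbers computed with other
  conventions require matching configuration.
* The sitting/standing template is a single integrated cycle; separate
  sit-to-stand and stand-to-sit events are not modelled.
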