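---
title: "Analyzing fast visual learning in immersive VR with chessboard-scan calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing fast visual learning in immersive VR with chessboard-scan calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calciumvr)
```

# The experiment this package models

Head-fixed mice run on a treadmill through an infinite virtual corridor
rendered by an immersive head-mounted display. The corridor is interrupted
by grating zones: one orientation (0°) is aversive — the mouse has 3.5 s to
escape before 0.4-s airpuff pulses arrive every 0.8 s until it leaves — and
the other orientations (45°, 135°) are neutral controls. Teleports into
zones happen on average every 20 s, and a mouse that stands still for 8 s is
teleported to a random zone to prevent passive behavior. Treadmill velocity
is sampled every 3 ms and may be negative (the mouse can step backwards).

During the task, layer 2/3 neurons in V1 are imaged with a 3D
acousto-optical microscope in *chessboard scanning* mode: instead of a full
frame, the microscope acquires a small subfield around each soma (one soma
per subfield in this package's model), at arbitrary 3D positions, at
roughly 11–20 Hz per cell (default 14.31 Hz, ~97 somata).

A separate *abyss test* assays immersion: mice run toward a virtual cliff
and must stop (or recoil, with negative velocity) at its edge; with a flat
monitor they cross at unchanged speed.

Because no recordings ship with the package, a synthetic-data generator
produces sessions, velocity traces, population transients and chessboard
movies with full ground truth, and every analysis is validated by parameter
recovery against that ground truth.

# The pipeline

## From movies to dF/F

`registerSubfields()` rigidly motion-corrects every subfield separately:
per-frame (row, col) shifts are estimated by FFT cross-correlation against
the maximum-intensity projection of the first measurement unit, refined on
a 1/10-pixel grid by a local matrix-multiplication DFT (the upsampling
factor is exposed; 10 gives 0.1-px precision). The applied correction is
the rounded shift; uncovered pixels receive the fill value (zero by
default, NaN selectable). A zero-variance subfield gets shift (0, 0) and a
warning flag rather than an error.

Automatic segmentation masks do not know the chessboard borders, so two
pixel-level cleaning steps precede trace formation:

* `cleanRoiPixels()` drops every soma pixel whose trace contains an invalid
  value (zero or NaN — both fill conventions are treated as invalid), then
  renormalizes the remaining segmentation weights to sum to one. An ROI
  that loses all pixels is flagged invalid and excluded downstream.
* `cleanNeuropilPixels()` removes neuropil pixels outside the home
  subfield's pixel rectangle or overlapping any ROI's soma mask (including
  the ROI's own), and averages the survivors with equal weight. An emptied
  neuropil is flagged and its trace defined as zero, so the correction
  degenerates to the identity.

`neuropilCorrect()` subtracts 60% of the neuropil trace from the raw soma
trace (`mix = 0.6`, matching the contamination fraction the generator
plants), and `computeDFF()` forms `(F - F0)/F0` with `F0` the 8th
percentile of the cell's full day trace. The percentile convention is
linear interpolation between order statistics (the dominant array-library
convention; `quantile()` type 7); a nearest-rank variant is available, and
the choice moves `F0` only marginally. Whether the 60% subtraction precedes
or follows weight renormalization is mathematically irrelevant for fixed
weights; it is applied after trace formation.

## Behavioral learning statistic

Learning is quantified by a label-shuffle bootstrap: per-trial velocity
curves in the 1.5-s window ending at the *scheduled* first airpuff (zone
entry + 3.5 s; in control zones no airpuff occurs but the schedule defines
the same alignment point) are compared between aversive and control trials
through the DTW distance of the two label-group mean curves. The label
vector is shuffled 1,000 times; the score is the proportion of shuffled
differences below the original, with ties counted half — the tie rule keeps
degenerate nulls exactly at the 0.5 chance level. `bootstrapByQuarter()`
splits a training day into four equal parts.

The DTW variant is pinned so the implementation and its enumeration oracle
agree: absolute-difference local cost, steps down/right/diagonal, no window
constraint, unnormalized accumulated cost. A simpler mean-difference
statistic is available behind `statistic = "mean"`; DTW is the default.

The abyss test is scored by `detectEdge()` (edge crossing, else the first
≥2-s standstill at a position with edge visibility, else a failed trial
after 20 s) and `velocityRatio()`, the after/before ratio of mean velocity
in 2-s windows around the edge moment. The orientation is fixed so that
slowing gives a ratio below 1 and recoil a negative ratio; it is
switchable. Failed trials never enter the ratio or the t-test.
`fitVelocityGaussian()` checks approximate normality of the velocity
frequency count with a full-width-at-half-maximum Gaussian peak model
fitted by Levenberg–Marquardt.

## Learning metrics on aligned responses

`alignToZoneEnd()` cuts per-trial segments ending at the zone exit (time
0), right-closed at the frame boundary, with velocity resampled to the
imaging rate; for learning quantification the aversive end is capped at the
scheduled first airpuff so reinforcement responses cannot leak into the
window. The *ramp amplitude* is the window mean of dF/F over (−1, −0.4) s —
reported as a mean rather than a raw integral so the alternative (−1, −0.3)
window is directly comparable; both windows are first-class options and
rank noiseless ramps identically. The *activation ratio* counts neurons
whose response window exceeds baseline either by 2 s.e.m. of the baseline
across trials or by a one-tailed paired test (t or Wilcoxon) at α = 0.05;
fractions are reported raw (for fidelity to the original analysis) and
Benjamini–Hochberg adjusted. The baseline window defaults to the first
second of the aligned axis — choose `preWindow` long enough that it
precedes the ramp onset (with the default 3-s ramp, a 5-s window capped at
the airpuff reaches back into the neutral period.)

Zone preference compares each neuron's aversive and control ramp amplitudes
with a two-tailed two-sample t-test; aversive and control visits are
distinct trials with no natural pairing, so an unpaired test is the
appropriate operationalization. Neurons passing α = 0.05 are labeled by
the sign of the difference.

Reinforcement responses aligned to the first airpuff are decomposed into a
fast exponential (time constant profiled over a 0.2–3 s grid) plus a
normalized-velocity regressor, and a *second component*: the time-integral
of the non-negative residual. A plain least-squares fit would absorb part
of the second component into the exponential, so the first-component fit is
iteratively trimmed — samples whose residual exceeds twice the spread of
the negative residuals are excluded and the fit repeated until the support
stabilizes (at least half the samples are always kept). This
operationalization is isolated in `decomposeReinforcement()` so it can be
swapped. `correlateLearning()` then correlates early second components with
late ramp amplitudes across neurons.

## Assemblies, hub cells and the decoder

`detectAmplitudeThreshold()` formalizes the jump in the sorted
ramp-amplitude distribution: the threshold sits at the largest first
difference whose upper element lies in the top quartile of ranks, accepted
only if it exceeds twice the median first difference, otherwise a no-jump
flag is raised. The rule is invariant under increasing affine transforms
and is deliberately isolated: the original analysis identifies the jump
from the derivative trace visually, so the operational rule is this
package's own and is replaceable.

Hub spatial clustering compares the mean pairwise Euclidean distance of hub
somata to random equal-size subsets of the coding population (one-sided
permutation p). Spontaneous activity is defined as all samples outside
aversive-zone intervals; `spontaneousCrossCorr()` reports the zero-lag
Pearson matrix with within-group means for hubs, the lowest-ramp group and
the rest, optionally normalized to the maximum group.

The few-cell decoder takes the `k` ∈ 3..7 neurons with the largest
aversive-minus-control ramp difference on training trials; its decision
statistic is the member-average dF/F over (−4, −2.5) s, thresholded at the
midpoint of the training-class means ("a given threshold" is otherwise
unspecified; a midpoint is the symmetric choice). With `k = NULL` the
smallest k reaching perfect training accuracy is used, else 7.
`clusterTrials()` 2-means-clusters per-trial ramp scores into high/low-ramp
groups, and `leadLag()` locates the peak of the normalized cross-correlation
between population activity and running speed (positive lag = neuronal
activity leads). Onsets for hub-versus-population timing use the first
crossing of 20% of the baseline-to-peak range on 0.2-s Gaussian-smoothed
traces.

## Tensor component analysis

`buildTensor()` Gaussian-filters the aligned transients along time
(truncated kernel, reflect padding; σ = 0.15 s by default, exposed),
crops to the 5 s before the zone end, and clips negative dF/F at zero —
non-negativity is required by the decomposition and clipping is the
default (a shift-to-minimum variant exists). The per-trial motion integral
is attached for factor interpretation.

`cpDecomposeNonneg()` fits the non-negative canonical polyadic model by
alternating exact NNLS updates, each solved by block principal pivoting
(`nnlsBPP()`): all KKT-violating variables are exchanged between passive
and active sets at once, with a shrinking-exchange backup rule that
guarantees termination; the solver agrees with exhaustive active-set
enumeration to 1e-10 and reduces to unconstrained least squares whenever
that solution is feasible. Alternating exact minimization makes the
objective non-increasing; convergence is declared when the relative
reconstruction error changes by less than 1e-6 (500-iteration cap), and the
best of several seeded restarts is kept. A component whose column zeroes
out in any mode is a known failure mode of alternating NNLS; such dead
components are revived with fresh random draws (at most five times, never
in the last iterations), and the reported objective trace starts after the
last revival. Neuron and time columns are unit L2-normalized with the
component scale absorbed into the trial factors — a convention fixed here
so tests are well-defined. Rank selection follows a cross-trial-split rule
(`selectRank()`): fit on half the trials, refit trial factors on the
held-out half with frozen neuron/time factors, pick the rank with the
lowest held-out error — an operational form of "components must not
overfit".

`interpretFactors()` reports, per component, the Pearson correlation of the
trial factor with the motion integral, aversive-versus-control tests on the
trial factors (t-test and Mann–Whitney, as both are quoted for the ramp
component), and a kinetic tag (ramp / ON / other) from the temporal factor.

## Display distortion model

The head-mounted display optics produce a purely radial Brown–Conrady
distortion: `x_d = x_u (1 + K1 r² + K2 r⁴ + K3 r⁶)` with `r` the
normalized distance from the center (normalization radius conventionally
half the image diagonal — the coefficients rescale with this choice, so it
is exposed). The forward map requires a monotone radial polynomial
(checked); the inverse is a fixed-point iteration on the radius with a
Newton fallback, residual-checked against the forward map. Coefficients
are estimated from calibration-grid correspondences by Levenberg–Marquardt,
and the sign rule classifies the model: all-negative barrel, all-positive
pincushion, mixed mustache. Tangential (decentering) terms are out of
scope. The study's own fitted coefficients are not published, so only
recovery of planted coefficients is testable.

# The synthetic generator: what it emulates and what it does not

`generateSession()` reproduces the event grammar (grace period, pulse
schedule, immobility teleports, neutral intervals averaging 20 s) and an
AR(1)-fluctuating running speed (mean 8 cm/s, SD 2 cm/s, 1-s time
constant) with optional anticipatory speed-ups: with probability given by
a user-supplied learning curve, an aversive trial gains a smooth velocity
increase of `effectSize` running-speed SDs over the 1.5 s before the
scheduled airpuff. With the learning curve at zero the two zone types are
exchangeable by construction — the null the bootstrap calibration uses.

`generateTransients()` composes each neuron's dF/F from latents mirroring
the components the tensor analysis is meant to find: a visual-ON transient
at zone entries (α-kernel, τ = 0.3 s), a linear ramp over the last 3 s of
each zone visit, a two-component reinforcement response at airpuff times
(exponential τ = 0.5 s plus a slower α-kernel, τ = 1 s), a
locomotion-coupled term, and Gaussian noise. The kernel shapes and the 3-s
ramp onset are not published numerically; they are package defaults chosen
to match the described response shapes and are config-exposed. All
component time courses are returned separately, which is what makes exact
recovery oracles possible.

`generateChessboardMovie()` renders one soma disk per subfield whose
intensity follows `F0 (1 + dF/F)` plus `neuropilMix` times a shared
background trace, an annular neuropil carrying that background, optional
rigid motion (rejected if beyond a quarter subfield — registration would be
ill-posed) and Gaussian pixel noise.

Deliberate simplifications: additive Gaussian noise rather than Poisson
shot noise; one soma per subfield (real segmentations occasionally find
several); no photorealistic optics, eye movements or VR-scene rendering;
velocity is generated, not integrated from a physical treadmill model.
Passing recovery tests therefore demonstrates correctness of the analysis
chain under the stated statistical structure, not robustness to every
artifact of in vivo data.

# Reference scales

The in vivo headline numbers (80.1 ± 5.9% / 70.0 ± 7% activation ratios,
97.5 ± 2.5% decoder reliability, r = 0.62 reinforcement–learning
correlation, 44%/14% zone-coding fractions, a 2.45-s neuronal lead over
running) depend on recordings that are not publicly deposited. The test
suite treats each as a scale reference for a property-based analogue on
synthetic data: planted 80% responder populations are recovered within ±5
points, planted separable assemblies are decoded at ≥95% reliability,
planted 44/14/42 population structure is recovered within ±5 points, and a
planted 2.45-s lead is recovered within one sample.

# Problem sizes and reproducibility

The suite runs on deliberately small problems: 6–100 neurons, 5–16 trials
per zone, 72-timepoint windows, tensors up to 80 × 72 × 40, 50-session
bootstrap calibrations. The acceptance script simulates 200 null sessions
(16 trials per zone, 1,000 shuffles each); with scores uniform on (0, 1)
the reported mean then carries a standard error of about 0.02, small
against its 0.05 tolerance. All randomness flows from explicit seeds; the
same seed gives bit-identical sessions, transients, movies and
decompositions.

# Known limitations

* The generator's immobility, licking and reward structures are minimal;
  anticipatory-licking analysis is exercised on constructed event times.
* `nnlsBPP` assumes well-conditioned normal equations; rank-deficient
  designs fall back to a small ridge with a warning.
* The trimmed reinforcement decomposition assumes the second component is
  transient and non-negative; a sustained negative second component would
  be folded into the first.
* HDF5 interchange is not provided; movies travel as multi-page float TIFF
  plus JSON metadata, logs and masks as CSV/JSON.
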