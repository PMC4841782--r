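---
title: "Methods: turn-state analysis of zebrafish exploratory locomotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: turn-state analysis of zebrafish exploratory locomotion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and procedures
it implements, the parameters that matter, the design choices that were
genuinely open, and what the synthetic-data tests do and do not
establish about real recordings.

## The behavior and the analysis chain

Larval zebrafish locomote in discrete swim bouts, roughly one every
1.22 s. Each bout carries a signed reorientation (positive = leftward
throughout this package), and successive turn directions are strongly
correlated: turns chain into *streaks* to one side before the fish
switches. The package quantifies this structure from three kinds of
input — freely swimming trajectories, fictive (paralyzed-preparation)
motor-nerve recordings, and voxel-resolved calcium imaging — and models
it with a two-state hidden Markov chain whose consequences for foraging
are explored by simulation.

## Kinematics

Trajectories are smoothed coordinate-wise with a truncated-Gaussian FIR
kernel: support 400 ms (about 40% of an inter-bout interval),
σ = 70 ms, unit-sum taps. The paper-style parameters give a kernel
truncated at ±2.86σ; the truncation point itself is our choice since
only support and σ are standard. Speed is the central difference of the
smoothed position times the frame rate, so linear motion is preserved
exactly (linear-phase FIR).

Bouts are marked where speed crosses a threshold upward; the event time
is the speed maximum of the supra-threshold epoch (the epoch peak is a
deterministic tie-break; thresholds alone do not define a unique time
point). Presets: 3.3 mm/s (200 fps camera), 1.0 mm/s (100 fps), and
4.5 mm/s for darkest-point tracking at 30 fps, which rides on an
additive baseline velocity we do not otherwise model. Crossings within
200 ms of a previous event are merged — noisy speed traces otherwise
double-mark one bout; the value is ours, sized well below the shortest
plausible inter-bout interval.

The turn angle is `wrap(heading(t_peak + 250 ms) − heading(t_peak − 250 ms))`
into (−π, π]; events whose window leaves the record are dropped and
counted. When no heading channel exists, heading is inferred from
displacement vectors of the smoothed centroid over a ±25 ms span.
A bout is a *turn* when |angle| ≥ 0.17 rad. Turn-sequence analyses use
only events at least 1 cm from the dish wall (thigmotaxis artifacts);
the generator flags wall reflections so this filter is exercised by
tests.

Sign convention: positive = leftward (counter-clockwise) everywhere,
matching "left power minus right power" in fictive decoding. Imaging
conventions that use positive-for-right are a rendering flip
(`render_map(flip_laterality = TRUE)`), never a data flip.

## Turn-state statistics

Streaks are maximal runs of equal sign; their lengths partition the
sequence. Two relative-frequency conventions exist and are both
computed: fraction of *streaks* of each length (count-weighted) and
fraction of *bouts* inside streaks of each length (bout-weighted).
Inside the NRMSE we use the count-weighted form; the formula's source
says only "relative frequency", and the count form is the empirical
CDF convention the ablation comparison plots use. Streaks longer than
15 pool into bin 15 so that both 15-bin vectors keep summing to one
(the 15-bin sum is fixed; an overflow rule is required and unstated).

The null model is a *bias-matched coin flip*: i.i.d. signs with
P(left) equal to the observed fraction of left turns, drawn by
comparing uniform variates to the bias. `nrmse_vs_coinflip()` averages
the null histogram over 100 draws by default — a single draw makes the
statistic noticeably jittery at a few hundred turns — and `n_reps = 1`
reproduces the single-draw construction exactly.

The switch-triggered profile re-signs each post-switch window so the
switch direction is +1, cumulates over lags, averages within fish and
then across fish (so every fish weighs equally), and tests each lag's
increment across fish against zero with a two-sided signed-rank test.
The state length is the last lag of the initial run of significantly
positive increments (p < 0.05); lag 1 equals +1 by construction.

## Fictive decoding

The filtered signal is the standard deviation of the raw voltage in
non-overlapping 10 ms bins. We fix the population (n) denominator: at
≥ 10 samples per bin the difference from n−1 is negligible, but fixing
it makes decoded values bit-reproducible.

Bout segmentation (ours; the source defers to prior work): epochs where
the summed filtered signal exceeds median + 4·MAD for ≥ 30 ms, with
gaps < 100 ms merged. Channels are then normalized by their own mean
bout amplitude, each bout weighted by a normalized *rising* exponential
so the end of the bout — where left/right signals are nearly symmetric —
dominates the gain estimate. The rise constant is unstated at the
source; we mirror the decay constant, τ_r = duration / 3, and expose it.
Decoding weights the normalized signals with a *decaying* exponential
(τ = duration / 3) to emphasize the initial bursts that execute the
turn: turn amplitude = left − right weighted sums, vigor = their sum.
"Power" here means the weighted filtered amplitude, not its square.

Virtual trajectories: the record's largest |amplitude| maps to 150°
(the maximum turn angle observed in free swimming), distance per bout is
√vigor, and positions integrate heading-then-step. Two invariances
define correctness and are tested: swapping channels negates every
amplitude and preserves vigor; per-channel gain rescaling changes
nothing downstream.

## Voxel tuning maps

Behavior enters the regression as two impulse series at bout frames:
amplitude (vigor normalized to a maximum of 1) and signed direction
scaled by the same factor, so |dir| ≤ amp always. Values between bouts
are zero — carrying decaying values before convolution would double-count
the kernel.

The 2-D behavior space (radius = amplitude, angle over [0, π] from full
left to full right via θ = arccos(dir/amp)) is tiled separably with 3
radial × 4 angular raised-cosine bins: equal flat-top and transition
widths, cos² transitions crossing at 0.5 (50% overlap), so profiles sum
to one. The innermost radial bin *ramps up from zero*, so rest frames
carry no regressor weight; the outer radial bin and both angular edge
bins extend their flat tops to the domain edge. With this layout the
partition of unity holds for radii above 1/6, and the angular flat-top
centers sit at π/14, 5π/14, 9π/14, 13π/14.

Each of the 12 basis series is convolved causally (exact FIR, no FFT)
with an impulse kernel reflecting calcium-indicator dynamics: linear
1 s rise, linear 5 s decay, normalized to unit peak. Peak normalization
only scales coefficients — R² and laterality are invariant — and some
normalization must be fixed for coefficients to be comparable. A
constant row completes the 13 × T design matrix, and every voxel is fit
by ordinary least squares on the normal equations. A relative 1e-8
ridge is added only when the Gram matrix is numerically singular (rank
loss from behavior that never visits part of the space); the printed
normal-equation expression is implemented in its standard
dimensionally-consistent form. R² is floored at 0, and zero-variance
voxels get zero coefficients.

The laterality index rectifies coefficients at zero, sums radially
within each angular bin, takes the weighted circular mean of the
angular centers, and maps [0, π] linearly onto [+1, −1]. Rectification
is our resolution of an under-specified "weighted angular mean":
negative OLS coefficients mostly encode suppression and would otherwise
flip the preferred angle of weakly tuned voxels. Voxels with no
positive coefficient get index 0 (undefined preference).

ΔF/F uses a rolling 20th-percentile baseline over 60 s — a standard
slow-baseline choice, unspecified at the source; voxels with
non-positive baselines are masked. Map rendering encodes laterality as
hue (left = green, right = magenta) and R² as brightness, clipped at a
configurable saturation (default 0.06), with maximum-intensity
projections along any axis. Registration across fish is out of scope;
volumes are assumed motion-corrected.

## The two-state turn model

States S_L and S_R with row-stochastic transition and emission
matrices; the canonical example ("fish 16") is transition
[0.86 0.14; 0.15 0.85] and emission [0.85 0.15; 0.10 0.90], giving
stationary distribution (0.5172, 0.4828), a left-turn fraction of
0.488, and a mean S_L dwell of 1/0.14 ≈ 7.1 bouts.

`fit_baum_welch()` runs EM with scaled forward–backward recursions
(compiled, since the recursion is sequential) until the change in
log-likelihood and the Frobenius norms of the transition- and
emission-matrix changes are all below 10⁻⁶, or 2000 iterations; whether
the looser 10⁻⁴ criterion was met is recorded separately in the
diagnostics. Because the toolbox initialization the source relied on is
undocumented, we use five seeded random restarts (transition diagonals
uniform on (0.6, 0.95), emissions initialized with opposite symbol
preferences to break label symmetry) and keep the best likelihood. The
initial-state distribution is treated as a free EM parameter during
fitting (this preserves the EM monotonicity guarantee, which a tied
stationary initialization would not) and generation starts from the
stationary distribution. After fitting, states are relabeled so S_L is
the state that prefers left emissions, which makes fits
label-invariant: fitting the mirrored sequence returns the mirrored
model.

Likelihoods use the scaled forward algorithm; a zero-probability
emission returns −∞ rather than raising. Tests verify the forward
likelihood against exhaustive hidden-path enumeration for n ≤ 10.

## Exploration simulations

Trajectories of 40 unit-length bouts start at the origin with uniform
random heading. Signs come from a model's emission sequence; magnitudes
are drawn i.i.d. from a configurable source. Diffusion is the ensemble
mean of the net displacement after 40 bouts. The uncorrelated
("random") reference model — uniform transitions with deterministic
emissions, i.e. fair i.i.d. coin flips — diffuses *farther* than the
correlated model at equal magnitudes: random signs cancel into
near-straight paths, while persistent signs curve the path into local
arcs. Matching therefore *shrinks* the random model: either its bout
length (step multiplier) or its turn-angle scale (magnitude multiplier
with rejection-resampling above π, since "broadening" must not create
impossible angles). The factor is found by bisection to 0.5% relative
tolerance, with common random numbers across objective evaluations so
the search is deterministic.

Resources are scattered uniformly over a 25 × 25 bout-length square at
0.10 per *square* bout length (≈ 62 resources; the printed unit
"resources/bout length" is ambiguous and we read it as areal density).
A resource is collected at the first bout whose swept segment passes
within 3.25 bout lengths (point-to-segment distance — "passed within"
describes the path, not its endpoints), at most once per trajectory.
Both models in a comparison share each resource field (paired design),
replicated over independent fields.

Efficiency statistics: mean resources versus bout number; total |angle|
turned until the k-th resource over trajectories that succeed in
collecting k, with per-k success rates (summed |angle| is the
energetic-cost reading of "total turn angle"; summed signed angle would
cancel and measure nothing); percent differences between models; a
two-tailed two-sample t-test evaluated at the critical simulation
number; and power from the normal approximation to the two-sample
comparison. The critical number is where the running estimate's local
Fano factor (variance/mean over a 400-simulation moving window) first
drops below 10⁻⁵.

## Synthetic generators: what they emulate, and what they do not

All generators are seeded and bit-reproducible, and each mirrors the
statistical structure its analysis assumes:

- **Free swim**: gamma inter-bout intervals (shape 4, mean 1.22 s — the
  source gives only mean ± SEM, and shape 4 gives the right visual
  spread of bout timing), Markov-driven directions, a configurable
  magnitude distribution, bouts as an instantaneous speed jump
  (20 mm/s) with exponential decay (τ = 150 ms) so that
  smoothed-velocity detection at the printed thresholds fires once per
  bout, heading ramped over 150 ms, and reflective re-orientation at
  the wall with the event flagged. The default magnitude distribution —
  70% forward bouts (half-normal, σ = 4°, below 10°) and 30% turns
  (half-normal, σ = 35°, capped at 150°) — is a *stand-in* with the
  right qualitative shape; no closed form for the empirical
  distribution exists, and analyses that depend on its tails (the
  foraging percentages below) will differ from empirical-data values.
- **Fictive**: burst trains at 25 Hz within 0.3 s bouts at 6 kHz, with
  the left/right amplitude ratio exp(k·θ) at bout onset decaying over
  the bout (τ = duration/3) — turns are executed by the initial bursts,
  which is precisely why decoding start-weights and normalization
  end-weights. k is set so a maximal 150° turn gives a 9:1 onset ratio.
  Under the default 0.01 V noise floor the decoder recovers turn signs
  with ≥ 96% agreement on |θ| ≥ 0.17 rad events, the design target for
  a usable preparation.
- **Imaging**: voxel time series are exactly
  intercept + Σ bⱼ·regressorⱼ(t) + noise with stored ground truth, on a
  default 4 × 8 × 8 grid at 1.87 volumes/s, mixing lateralized, tuned-
  but-symmetric, and silent voxels.

None of the generators model tail biomechanics, optics or photon noise,
struggles/escapes, multi-animal interactions, or motion artifacts.
Passing tests therefore establish the *algorithmic* correctness and
self-consistency of the chain (exact parameter recovery, invariances,
agreement with independent oracles), not robustness to every
real-recording pathology.

## Problem sizes and numerical choices

The test suite and acceptance script run at sizes chosen to keep full
runs comfortably reproducible on a laptop: HMM recovery at 50,000
emissions (10 seeds), exploration comparisons at 2 × 10⁴ trajectories
and 3 resource fields (the full-scale study size is 10⁶ trajectories
and 100 fields; at 2 × 10⁴ the Fano-factor critical numbers, ~1–3 × 10³,
are already well inside the ensemble), property grids at 150–200 points
per axis. Other numerics: EM tolerance 10⁻⁶ on three criteria jointly;
bisection tolerance 0.5% relative; OLS ridge 1e-8 relative, applied
only on near-singularity; angle wrapping onto (−π, π] with the boundary
mapped to +π; population-SD filter bins; 200 ms refractory merge in
bout detection.

## Known limitations

- The foraging-efficiency percentages depend strongly on the tail of
  the turn-magnitude distribution; with the synthetic stand-in they
  reproduce the *direction* of every reported effect (the matched
  random model collects fewer resources and must turn more) but not the
  printed percentage values, which require the empirical magnitude
  sample. `load_source_data()` ingests that MAT container when
  available.
- Fitting the HMM to turn events only (the |angle| ≥ 0.17 filter)
  subsamples the underlying chain wherever forward bouts intervene,
  biasing fitted persistence downward relative to a chain that governs
  every bout. This mirrors the analysis choice of training on valid
  turns and matters when comparing fitted diagonals to generator
  settings.
- The MAT reader covers the level-5 subset (numeric, char, cell,
  struct, zlib-compressed elements), not v7.3/HDF5 containers.
- Per-fish reproduction of fitted matrices from any specific data set
  depends on an initialization that is not documented at the source;
  only recovery from generated data is an exact target.
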