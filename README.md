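# slalom

Larval zebrafish exploring a featureless arena swim in discrete bouts,
and the direction of successive turns is far from independent: fish chain
several turns to the same side before stochastically switching, producing
characteristic slaloming trajectories. `slalom` implements the complete
computational chain for quantifying and modeling that behavior, for
researchers working on behavioral state dynamics, fictive
electrophysiology, or whole-brain functional imaging in small vertebrates:

- **Kinematics** — trajectory smoothing (400 ms truncated-Gaussian FIR,
  σ = 70 ms), velocity-threshold bout detection with camera-specific
  presets, signed turn angles from the heading change across ±250 ms
  around peak swim speed, 1 cm wall exclusion, and the 0.17 rad
  turn/forward classification threshold.
- **Turn-state statistics** — streak (run-length) distributions under
  both count- and bout-weighted conventions, switch-triggered cumulative
  turn-direction profiles with signed-rank state-length estimation, and
  a goodness-of-fit statistic against a bias-matched coin-flip null:
  RMSE = √( Σᵢ₌₁¹⁵ (obsᵢ − coinᵢ)² / 15 ), NRMSE = RMSE / (obs_max − obs_min).
- **Fictive decoding** — two-channel motor-nerve recordings are filtered
  (per-10 ms-bin SD), segmented, gain-normalized per channel (rising-
  exponential bout weighting), and decoded as
  turn = left power − right power, vigor = left + right, with power
  weighted by a decaying exponential (τ = bout duration / 3); virtual
  trajectories via the 150° maximal-turn normalization and
  distance = √vigor.
- **Voxel tuning maps** — behavior is embedded in a 2-D amplitude ×
  laterality space tiled by a 3 (radial) × 4 (angular) raised-cosine
  polar basis (flat tops, 50 % overlap, partition of unity); regressors
  are the basis weights convolved with a 1 s-rise / 5 s-decay impulse
  kernel; every voxel is fit by OLS, b = (XXᵀ)⁻¹X r, yielding R² and a
  laterality index from the rectified-coefficient weighted angular mean.
- **Turn-direction HMM** — a two-state hidden Markov model
  (states S_L, S_R; binary left/right emissions) fitted by Baum–Welch
  with the triple 10⁻⁶ convergence rule (ΔLL, ‖ΔP‖_F, ‖ΔE‖_F) and a
  2000-iteration cap, plus exact forward-algorithm likelihoods and
  analytic stationary summaries.
- **Exploration efficiency** — ensembles of 40-bout correlated vs.
  uncorrelated random-walk trajectories, diffusion matching by
  bout-length shrinkage or turn-angle broadening, uniformly scattered
  virtual resources collected within a 3.25 bout-length detection
  radius, and Fano-factor-based critical simulation numbers for the
  hypothesis tests.
- **Synthetic generators** — seeded, bit-reproducible generators for all
  three input modalities (free-swim trajectories, two-channel fictive
  recordings, voxel × time imaging with known ground-truth tuning), so
  every stage of the chain is testable end to end without any data
  downloads.

## Worked example

Generate an hour of synthetic free swimming driven by the printed
"fish 16" turn model, extract bouts, and quantify turn-state structure:

```r
library(slalom)

sim   <- generate_free_swim(swim_gen_params(duration = 3600, seed = 1))
bouts <- extract_bouts(sim$trajectory)          # smoothing + detection + wall filter
turns <- bouts$turn_angle[bouts$is_turn]        # |angle| >= 0.17 rad
dirs  <- ifelse(turns >= 0, 1L, -1L)            # +1 = left

turn_bias(dirs)
#> [1] 0.4547368
sum(streak_distribution(extract_streaks(dirs))$rel_freq_bout[5:15])
#> [1] 0.4231579
nrmse_vs_coinflip(dirs, seed = 2)
#> NRMSE vs bias-matched coin flips: 0.0635 (RMSE 0.0264, bias 0.455, n 475)

fit_baum_welch(dirs, seed = 3)$model
#> Two-state turn-direction Markov model
#> Transition P(state' | state):
#>        S_L    S_R
#> S_L 0.8000 0.2000
#> S_R 0.3376 0.6624
#> Emission P(turn | state):
#>          L      R
#> S_L 0.7278 0.2722
#> S_R 0.0001 0.9999
```

About 42 % of this fish's turns sit in streaks of five or more — turning
is strongly history-dependent — and the NRMSE against its bias-matched
coin-flip null is correspondingly well above the value an actually
memoryless fish would produce. The fitted transition diagonals (0.80,
0.66) recover the state persistence that generated the data; they sit
below the generating matrix because direction analyses subsample the
chain at turn events only (forward bouts hide intervening steps).

`run_pipeline(out_dir, seed)` executes this chain end to end and writes
every artifact (trajectory/bout CSVs, model JSON, summary JSON) together
with a manifest of seeds and MD5 hashes; rerunning with the same seed
reproduces the hashes bit for bit.

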