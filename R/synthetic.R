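#' Default turn-angle magnitude sampler
#'
#' Stand-in for the empirical free-swimming turn-magnitude distribution:
#' a mixture of a near-zero "forward" component (70% of bouts, half-normal
#' with sigma = 4 degrees truncated below 10 degrees) and a heavy-tailed
#' "turn" component (30%, half-normal with sigma = 35 degrees, capped at
#' 150 degrees, the largest turn angle observed in freely swimming fish).
#'
#' @param n Number of magnitudes to draw.
#' @param p_turn Mixture weight of the turn component (default 0.3).
#' @param forward_sigma,forward_cap Forward-component scale/cap in rad.
#' @param turn_sigma,turn_cap Turn-component scale/cap in rad.
#' @return Vector of `n` magnitudes in rad, all in `[0, turn_cap]`.
#' @export
default_turn_magnitudes <- function(n, p_turn = 0.3,
                                    forward_sigma = 4 * pi / 180,
                                    forward_cap = 10 * pi / 180,
                                    turn_sigma = 35 * pi / 180,
                                    turn_cap = 150 * pi / 180) {
  is_turn <- stats::runif(n) < p_turn
  draw_trunc <- function(m, sigma, cap) {
    out <- abs(stats::rnorm(m, 0, sigma))
    while (any(out > cap)) {
      bad <- out > cap
      out[bad] <- abs(stats::rnorm(sum(bad), 0, sigma))
    }
    out
  }
  mags <- numeric(n)
  if (any(!is_turn)) mags[!is_turn] <- draw_trunc(sum(!is_turn), forward_sigma, forward_cap)
  if (any(is_turn)) mags[is_turn] <- draw_trunc(sum(is_turn), turn_sigma, turn_cap)
  mags
}

#' Parameters for the free-swim trajectory generator
#'
#' @param frame_rate Hz (default 100).
#' @param duration Recording length in s.
#' @param ibi_mean Mean inter-bout interval in s (default 1.22, the
#'   across-fish mean bout period).
#' @param ibi_shape Gamma shape of the inter-bout-interval distribution
#'   (default 4).
#' @param turn_magnitudes Function `n -> magnitudes (rad)`; defaults to
#'   [default_turn_magnitudes()].
#' @param markov `markov_model` driving turn directions (default
#'   [fish16_model()]).
#' @param peak_speed Bout peak speed in mm/s (default 20).
#' @param speed_tau Exponential decay of bout speed in s (default 0.15).
#' @param turn_ramp Time over which the heading change is executed, in s
#'   (default 0.15).
#' @param centroid_noise_sd Tracking noise on recorded position, in mm
#'   (default 0.02).
#' @param arena_radius mm (default 46, a 9.2 cm dish).
#' @param seed Optional integer seed.
#' @return List of class `swim_gen_params`.
#' @export
swim_gen_params <- function(frame_rate = 100, duration = 120,
                            ibi_mean = 1.22, ibi_shape = 4,
                            turn_magnitudes = default_turn_magnitudes,
                            markov = fish16_model(),
                            peak_speed = 20, speed_tau = 0.15,
                            turn_ramp = 0.15,
                            centroid_noise_sd = 0.02,
                            arena_radius = 46, seed = NULL) {
  stopifnot_positive(frame_rate = frame_rate, duration = duration,
                     ibi_mean = ibi_mean, ibi_shape = ibi_shape,
                     peak_speed = peak_speed, speed_tau = speed_tau,
                     turn_ramp = turn_ramp, arena_radius = arena_radius)
  if (centroid_noise_sd < 0) stop("`centroid_noise_sd` must be >= 0", call. = FALSE)
  structure(as.list(environment()), class = "swim_gen_params")
}

#' Generate a synthetic free-swimming trajectory with ground truth
#'
#' Simulates bout-structured swimming: inter-bout intervals are
#' gamma-distributed, turn directions follow the configured two-state
#' Markov chain, magnitudes come from the configured distribution, and
#' each bout executes an instantaneous speed jump with exponential decay
#' while the heading ramps to its new value. The fish never exits the
#' arena: approaching the wall triggers a reflective re-orientation
#' toward the arena center, and bouts adjacent to a wall event are
#' flagged in the ground truth so downstream wall exclusion can be
#' exercised.
#'
#' @param params A `swim_gen_params`.
#' @return List with `trajectory` (a [swim_trajectory()] including a
#'   noiseless heading channel and noisy centroid) and `ground_truth`
#'   (data frame: `t`, `turn_angle` signed rad, `magnitude`, `direction`,
#'   `state`, `wall_event`).
#' @export
generate_free_swim <- function(params = swim_gen_params()) {
  p <- params
  with_seed(p$seed, {
    # bout schedule
    t_margin <- 0.5
    ibis <- numeric(0)
    total <- t_margin
    while (total < p$duration - t_margin) {
      nb <- max(16, ceiling((p$duration - total) / p$ibi_mean * 1.5))
      draw <- stats::rgamma(nb, shape = p$ibi_shape,
                            scale = p$ibi_mean / p$ibi_shape)
      ibis <- c(ibis, draw)
      total <- t_margin + sum(ibis)
    }
    bout_t <- t_margin + cumsum(ibis)
    bout_t <- bout_t[bout_t < p$duration - t_margin]
    n_bouts <- length(bout_t)
    if (n_bouts < 1) {
      stop("duration shorter than one inter-bout interval", call. = FALSE)
    }
    turns <- generate_turns(p$markov, n_bouts)
    mags <- p$turn_magnitudes(n_bouts)
    if (any(mags < 0) || any(mags > pi)) {
      stop("turn magnitudes must lie in [0, pi]", call. = FALSE)
    }
    signed <- turns$directions * mags

    n <- round(p$duration * p$frame_rate)
    dt <- 1 / p$frame_rate
    t <- (seq_len(n) - 1) * dt
    bout_frame <- pmin(round(bout_t * p$frame_rate) + 1L, n)
    x <- numeric(n); y <- numeric(n); heading <- numeric(n)
    v <- 0
    h <- stats::runif(1, 0, 2 * pi)
    pos <- c(stats::runif(1, -5, 5), stats::runif(1, -5, 5))
    wall_events <- logical(n_bouts)
    decay <- exp(-dt / p$speed_tau)
    ramp_frames <- max(1L, round(p$turn_ramp * p$frame_rate))
    ramp_left <- 0L
    ramp_step <- 0
    next_bout <- 1L
    wall_margin <- 1
    wall_hit_since_last <- FALSE
    for (i in seq_len(n)) {
      if (next_bout <= n_bouts && i == bout_frame[next_bout]) {
        v <- p$peak_speed
        ramp_left <- ramp_frames
        ramp_step <- signed[next_bout] / ramp_frames
        wall_events[next_bout] <- wall_hit_since_last
        wall_hit_since_last <- FALSE
        next_bout <- next_bout + 1L
      }
      if (ramp_left > 0L) {
        h <- h + ramp_step
        ramp_left <- ramp_left - 1L
      }
      step <- c(cos(h), sin(h)) * v * dt
      cand <- pos + step
      if (sqrt(sum(cand^2)) > p$arena_radius - wall_margin) {
        # reflective re-orientation: point back toward the center
        h <- atan2(-pos[2], -pos[1]) + stats::runif(1, -0.3, 0.3)
        ramp_left <- 0L
        wall_hit_since_last <- TRUE
        cand <- pos + c(cos(h), sin(h)) * v * dt
      }
      pos <- cand
      v <- v * decay
      x[i] <- pos[1]; y[i] <- pos[2]; heading[i] <- h
    }
    traj <- swim_trajectory(
      t = t,
      x = x + stats::rnorm(n, 0, p$centroid_noise_sd),
      y = y + stats::rnorm(n, 0, p$centroid_noise_sd),
      heading = heading,
      frame_rate = p$frame_rate,
      arena_center = c(0, 0),
      arena_radius = p$arena_radius
    )
    gt <- data.frame(
      t = bout_t,
      turn_angle = signed,
      magnitude = mags,
      direction = turns$directions,
      state = turns$states,
      wall_event = wall_events
    )
    list(trajectory = traj, ground_truth = gt)
  })
}

#' Parameters for the fictive-recording generator
#'
#' @param sampling_rate Hz (default 6000; must be >= 1000).
#' @param burst_freq Within-bout burst frequency in Hz (default 25).
#' @param burst_duty Fraction of the burst cycle spent bursting
#'   (default 0.4).
#' @param bout_duration Function `n -> durations (s)` or a scalar
#'   (default 0.3 s).
#' @param ibi Inter-bout interval in s (default 1.2).
#' @param base_amplitude Burst envelope amplitude in V (default 0.5).
#' @param gain_left,gain_right Channel gains (> 0).
#' @param asymmetry_k Log-slope of the left/right burst-amplitude ratio
#'   per rad of signed turn; the default gives a 9:1 ratio at the 150
#'   degree maximal turn.
#' @param noise_sd Additive sensor noise in V (default 0.01).
#' @param seed Optional integer seed.
#' @return List of class `fictive_gen_params`.
#' @export
fictive_gen_params <- function(sampling_rate = 6000, burst_freq = 25,
                               burst_duty = 0.4, bout_duration = 0.3,
                               ibi = 1.2, base_amplitude = 0.5,
                               gain_left = 1, gain_right = 1,
                               asymmetry_k = log(9) / (150 * pi / 180),
                               noise_sd = 0.01, seed = NULL) {
  stopifnot_positive(sampling_rate = sampling_rate, burst_freq = burst_freq,
                     burst_duty = burst_duty, ibi = ibi,
                     base_amplitude = base_amplitude,
                     gain_left = gain_left, gain_right = gain_right)
  if (sampling_rate < 1000) stop("`sampling_rate` must be >= 1 kHz", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(as.list(environment()), class = "fictive_gen_params")
}

#' Generate a synthetic two-channel fictive recording
#'
#' Each turn produces one burst train per channel. At bout onset the
#' left/right burst-amplitude ratio is `exp(asymmetry_k * theta)` for
#' signed turn angle `theta` (+ = left), a monotone map, so left turns
#' put more power on the left channel; the asymmetry decays over the
#' bout (time constant one third of the bout duration), reflecting that
#' turns are executed by the initial bursts while the tail of the bout
#' is nearly symmetric. A zero-angle bout has equal expected power on
#' both channels. Channel gains multiply the raw signals and cancel in
#' decoding.
#'
#' @param turn_angles Signed turn angles in rad (+ = left).
#' @param params A `fictive_gen_params`.
#' @return List with `recording` (a [fictive_recording()]) and
#'   `ground_truth` (data frame: `onset`, `duration`, `turn_angle`,
#'   `direction`).
#' @export
generate_fictive <- function(turn_angles, params = fictive_gen_params()) {
  if (length(turn_angles) == 0) stop("`turn_angles` is empty", call. = FALSE)
  p <- params
  if (p$asymmetry_k <= 0) {
    stop("asymmetry map must be monotone increasing in the signed turn",
         call. = FALSE)
  }
  with_seed(p$seed, {
    nb <- length(turn_angles)
    durs <- if (is.function(p$bout_duration)) p$bout_duration(nb) else
      rep(p$bout_duration, nb)
    onsets <- 0.5 + cumsum(c(0, durs[-nb] + p$ibi))
    total_dur <- onsets[nb] + durs[nb] + 0.5
    n <- ceiling(total_dur * p$sampling_rate)
    tt <- (seq_len(n) - 1) / p$sampling_rate
    left <- stats::rnorm(n, 0, p$noise_sd)
    right <- stats::rnorm(n, 0, p$noise_sd)
    for (b in seq_len(nb)) {
      i0 <- floor(onsets[b] * p$sampling_rate) + 1L
      i1 <- min(ceiling((onsets[b] + durs[b]) * p$sampling_rate), n)
      idx <- i0:i1
      phase <- (tt[idx] - onsets[b]) * p$burst_freq
      bursting <- (phase %% 1) < p$burst_duty
      # turns shape the start of a bout much more than its end: the
      # left/right asymmetry decays over the bout (tau = duration / 3),
      # leaving the final bursts nearly symmetric
      taper <- exp(-(tt[idx] - onsets[b]) / (durs[b] / 3))
      log_ratio <- p$asymmetry_k * turn_angles[b] * taper
      amp_l <- p$base_amplitude * exp(log_ratio / 2)
      amp_r <- p$base_amplitude * exp(-log_ratio / 2)
      carrier <- stats::rnorm(length(idx))
      carrier2 <- stats::rnorm(length(idx))
      left[idx] <- left[idx] + amp_l * bursting * carrier
      right[idx] <- right[idx] + amp_r * bursting * carrier2
    }
    rec <- fictive_recording(left * p$gain_left, right * p$gain_right,
                             p$sampling_rate)
    list(
      recording = rec,
      ground_truth = data.frame(
        onset = onsets, duration = durs,
        turn_angle = turn_angles,
        direction = ifelse(turn_angles >= 0, 1L, -1L)
      )
    )
  })
}

#' Parameters for the imaging-volume generator
#'
#' @param grid_shape Integer vector `(z, y, x)` of voxel counts
#'   (default `c(4, 8, 8)`).
#' @param frame_rate Volumes per second (default 1.87).
#' @param noise_sd Additive noise in dF/F units (default 0.05).
#' @param intercept Baseline dF/F offset (default 0).
#' @param tuned_fraction Fraction of voxels given lateralized tuning
#'   (default 0.5); an additional `untuned_active_fraction` get equal
#'   weight in every angular bin, and the rest are silent.
#' @param untuned_active_fraction Default 0.2.
#' @param gain_range Range of tuning gains (default `c(0.5, 1.5)`).
#' @param seed Optional integer seed.
#' @return List of class `imaging_gen_params`.
#' @export
imaging_gen_params <- function(grid_shape = c(4, 8, 8), frame_rate = 1.87,
                               noise_sd = 0.05, intercept = 0,
                               tuned_fraction = 0.5,
                               untuned_active_fraction = 0.2,
                               gain_range = c(0.5, 1.5), seed = NULL) {
  if (prod(grid_shape) < 1) stop("grid must contain at least one voxel", call. = FALSE)
  stopifnot_positive(frame_rate = frame_rate)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(as.list(environment()), class = "imaging_gen_params")
}

#' Generate a synthetic voxel x time imaging record with known tuning
#'
#' Forward model of the tuning-map regression: each voxel's time series is
#' `intercept + sum_j b_j regressor_j(t) + noise`, with the regressors
#' built from the supplied behavior signals exactly as the analysis
#' builds them (polar basis weights convolved with the impulse kernel).
#' Ground-truth coefficients are stored for parameter-recovery checks.
#'
#' @param signals A `behavior_signals` object (see [behavior_signals()]).
#' @param params An `imaging_gen_params`.
#' @param basis Optional `polar_basis` (default [polar_basis()]).
#' @param kernel Optional impulse kernel (default
#'   `impulse_kernel(frame_rate = params$frame_rate)`).
#' @return List with `volume` (T x V matrix of dF/F), `grid_shape`,
#'   `frame_rate`, `regressors` (the design matrix used), and
#'   `ground_truth` (list: `b` V x 12 matrix, `intercept`, `laterality`,
#'   `kind` per voxel).
#' @export
generate_imaging <- function(signals, params = imaging_gen_params(),
                             basis = polar_basis(),
                             kernel = impulse_kernel(frame_rate = params$frame_rate)) {
  p <- params
  X <- build_regressors(signals, basis, kernel)
  active <- which(rowSums(X$X[seq_len(12), , drop = FALSE]) > 0)
  if (length(active) < 2) {
    stop("behavior must activate at least 2 of the 12 basis regions",
         call. = FALSE)
  }
  with_seed(p$seed, {
    V <- prod(p$grid_shape)
    kind <- sample(c("tuned", "untuned_active", "silent"), V, replace = TRUE,
                   prob = c(p$tuned_fraction, p$untuned_active_fraction,
                            max(0, 1 - p$tuned_fraction - p$untuned_active_fraction)))
    B <- matrix(0, V, 12)
    for (v in seq_len(V)) {
      gain <- stats::runif(1, p$gain_range[1], p$gain_range[2])
      if (kind[v] == "tuned") {
        m0 <- sample.int(basis$n_angular, 1)
        j <- (m0 - 1) * basis$n_radial + seq_len(basis$n_radial)
        B[v, j] <- gain
      } else if (kind[v] == "untuned_active") {
        B[v, ] <- gain / basis$n_angular
      }
    }
    T_len <- ncol(X$X)
    Y <- t(X$X[seq_len(12), , drop = FALSE]) %*% t(B) + p$intercept
    Y <- Y + matrix(stats::rnorm(T_len * V, 0, p$noise_sd), T_len, V)
    list(
      volume = Y,
      grid_shape = p$grid_shape,
      frame_rate = p$frame_rate,
      regressors = X,
      ground_truth = list(
        b = B,
        intercept = p$intercept,
        laterality = laterality_index(B, basis),
        kind = kind
      )
    )
  })
}
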