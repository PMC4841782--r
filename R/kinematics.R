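#' Kinematics configuration
#'
#' Parameters for trajectory smoothing, bout detection, turn-angle
#' windowing and wall exclusion. Defaults follow the free-swimming
#' analysis: a 400 ms truncated-Gaussian smoothing kernel with
#' sigma = 70 ms, a 250 ms heading window on either side of peak swim
#' velocity, a 1 cm wall-exclusion margin, and a 0.17 rad threshold
#' separating turns from forward bouts. Velocity-threshold presets match
#' the three recording configurations: `"pike200"` (3.3 mm/s at 200 fps),
#' `"mikrotron100"` (1.0 mm/s at 100 fps) and `"pike30"` (4.5 mm/s for
#' darkest-point tracking at 30 fps).
#'
#' @param velocity_threshold Bout-detection threshold in mm/s.
#' @param preset Optional preset name overriding `velocity_threshold`.
#' @param smooth_window Smoothing kernel support in ms (default 400).
#' @param smooth_sigma Gaussian sigma in ms (default 70).
#' @param turn_window Heading half-window around the velocity peak in ms
#'   (default 250).
#' @param wall_exclusion Minimum distance from the arena wall in mm
#'   (default 10).
#' @param turn_classification_threshold Minimum |turn angle| in rad for a
#'   bout to count as a turn (default 0.17).
#' @param refractory Merge window for threshold crossings in ms
#'   (default 200).
#' @return A list of class `kinematics_config`.
#' @export
kinematics_config <- function(velocity_threshold = 3.3,
                              preset = NULL,
                              smooth_window = 400,
                              smooth_sigma = 70,
                              turn_window = 250,
                              wall_exclusion = 10,
                              turn_classification_threshold = 0.17,
                              refractory = 200) {
  if (!is.null(preset)) {
    velocity_threshold <- switch(preset,
      pike200 = 3.3,
      mikrotron100 = 1.0,
      pike30 = 4.5,
      stop("unknown preset: ", preset, call. = FALSE)
    )
  }
  stopifnot_positive(velocity_threshold = velocity_threshold,
                     smooth_window = smooth_window,
                     smooth_sigma = smooth_sigma,
                     turn_window = turn_window,
                     turn_classification_threshold = turn_classification_threshold,
                     refractory = refractory)
  if (wall_exclusion < 0) stop("`wall_exclusion` must be >= 0", call. = FALSE)
  structure(list(
    velocity_threshold = velocity_threshold,
    smooth_window = smooth_window,
    smooth_sigma = smooth_sigma,
    turn_window = turn_window,
    wall_exclusion = wall_exclusion,
    turn_classification_threshold = turn_classification_threshold,
    refractory = refractory
  ), class = "kinematics_config")
}

#' Swim trajectory container
#'
#' A uniformly sampled tracking record: time, centroid position in mm,
#' optional heading in rad (unwrapped), plus arena geometry. When
#' `heading` is absent downstream analyses infer it from displacement
#' vectors of the smoothed centroid.
#'
#' @param t Time stamps in s (strictly increasing, uniform).
#' @param x,y Centroid coordinates in mm.
#' @param heading Optional unwrapped heading in rad (+ = counter-clockwise).
#' @param frame_rate Sampling rate in Hz; inferred from `t` when missing.
#' @param arena_center Length-2 vector, arena center in mm.
#' @param arena_radius Arena radius in mm.
#' @return A data-frame-backed object of class `swim_trajectory`.
#' @export
swim_trajectory <- function(t, x, y, heading = NULL, frame_rate = NULL,
                            arena_center = c(0, 0), arena_radius = 46) {
  n <- length(t)
  if (n < 2 || length(x) != n || length(y) != n) {
    stop("t, x, y must be equal-length vectors (n >= 2)", call. = FALSE)
  }
  dt <- diff(t)
  if (any(dt <= 0)) stop("`t` must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt) + 1e-9) {
    stop("non-uniform sampling: resample the trajectory first", call. = FALSE)
  }
  if (is.null(frame_rate)) frame_rate <- 1 / stats::median(dt)
  stopifnot_positive(frame_rate = frame_rate, arena_radius = arena_radius)
  df <- data.frame(t = t, x = x, y = y)
  if (!is.null(heading)) df$heading <- heading
  structure(list(
    data = df,
    frame_rate = frame_rate,
    arena_center = arena_center,
    arena_radius = arena_radius
  ), class = "swim_trajectory")
}

#' @export
print.swim_trajectory <- function(x, ...) {
  cat(sprintf("Swim trajectory: %d frames at %.1f Hz (%.1f s), arena radius %.1f mm%s\n",
              nrow(x$data), x$frame_rate, nrow(x$data) / x$frame_rate,
              x$arena_radius,
              if ("heading" %in% names(x$data)) ", heading tracked" else ""))
  invisible(x)
}

# truncated-Gaussian FIR taps, unit sum
gaussian_kernel <- function(window_ms, sigma_ms, frame_rate) {
  half_w <- round(window_ms / 2 / 1000 * frame_rate)
  tt <- (-half_w:half_w) / frame_rate * 1000 # ms
  w <- exp(-tt^2 / (2 * sigma_ms^2))
  w / sum(w)
}

# zero-phase FIR filtering with edge replication
fir_smooth <- function(x, w) {
  half <- (length(w) - 1L) / 2L
  padded <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(padded, w, sides = 2))[(half + 1L):(half + length(x))]
}

#' Smooth a trajectory and compute instantaneous speed
#'
#' x and y are independently smoothed with a truncated-Gaussian FIR kernel
#' (support `smooth_window`, sigma `smooth_sigma`, unit-sum taps), and
#' instantaneous linear speed is the magnitude of the central difference of
#' the smoothed position times the frame rate.
#'
#' @param traj A `swim_trajectory`.
#' @param cfg A `kinematics_config`.
#' @return List with `smoothed` (data frame `t`, `x`, `y`, and `heading`
#'   when present) and `speed` (mm/s, same length as `t`).
#' @export
smooth_and_velocity <- function(traj, cfg = kinematics_config()) {
  d <- traj$data
  if (nrow(d) / traj$frame_rate * 1000 < cfg$smooth_window) {
    stop("trajectory shorter than the smoothing window", call. = FALSE)
  }
  w <- gaussian_kernel(cfg$smooth_window, cfg$smooth_sigma, traj$frame_rate)
  xs <- fir_smooth(d$x, w)
  ys <- fir_smooth(d$y, w)
  n <- length(xs)
  dx <- (xs[c(2:n, n)] - xs[c(1, 1:(n - 1))]) / 2
  dy <- (ys[c(2:n, n)] - ys[c(1, 1:(n - 1))]) / 2
  # edge frames use one-sided differences, hence the doubled half-step
  dx[c(1, n)] <- dx[c(1, n)] * 2
  dy[c(1, n)] <- dy[c(1, n)] * 2
  speed <- sqrt(dx^2 + dy^2) * traj$frame_rate
  sm <- data.frame(t = d$t, x = xs, y = ys)
  if ("heading" %in% names(d)) sm$heading <- d$heading
  list(smoothed = sm, speed = speed)
}

#' Detect swim bouts from an instantaneous speed trace
#'
#' Marks one event per upward crossing of the velocity threshold; the
#' event time is the local speed maximum within the supra-threshold epoch.
#' Events closer than the refractory window to the previous event are
#' merged (the higher peak wins).
#'
#' @param speed Speed series in mm/s (from [smooth_and_velocity()]).
#' @param frame_rate Sampling rate in Hz.
#' @param cfg A `kinematics_config`.
#' @return Integer vector of peak frame indices.
#' @export
detect_bouts <- function(speed, frame_rate, cfg = kinematics_config()) {
  thr <- cfg$velocity_threshold
  if (thr <= 0) stop("velocity threshold must be positive", call. = FALSE)
  above <- speed > thr
  if (!any(above)) return(integer(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  epochs <- which(r$values)
  peaks <- vapply(epochs, function(e) {
    i <- starts[e]:ends[e]
    i[which.max(speed[i])]
  }, integer(1))
  # refractory merge: crossings within the window collapse to the larger peak
  refr <- cfg$refractory / 1000 * frame_rate
  merged <- integer(0)
  for (p in peaks) {
    if (length(merged) && (p - merged[length(merged)]) < refr) {
      if (speed[p] > speed[merged[length(merged)]]) merged[length(merged)] <- p
    } else {
      merged <- c(merged, p)
    }
  }
  merged
}

#' Compute signed turn angles for detected bouts
#'
#' The turn angle of a bout is the heading change across the velocity
#' peak: `wrap_angle(heading(t_peak + w) - heading(t_peak - w))` with
#' `w = turn_window` (250 ms). Positive angles are leftward
#' (counter-clockwise). Events whose window extends past the record edges
#' are dropped (and counted). When no heading channel is present, heading
#' is inferred from displacement vectors of the smoothed centroid,
#' evaluated over a short displacement span around the window edges.
#'
#' @param traj A `swim_trajectory`.
#' @param peaks Integer frame indices from [detect_bouts()].
#' @param cfg A `kinematics_config`.
#' @param smoothed Optional smoothed output of [smooth_and_velocity()]
#'   (recomputed when missing).
#' @return Data frame of bout events: `t_peak`, `turn_angle` (rad, signed),
#'   `magnitude` (|rad|), `is_turn`, `displacement` (mm),
#'   `distance_from_wall` (mm). Attribute `n_edge_dropped` counts events
#'   discarded at the record edges.
#' @export
compute_turn_angles <- function(traj, peaks, cfg = kinematics_config(),
                                smoothed = NULL) {
  if (is.null(smoothed)) smoothed <- smooth_and_velocity(traj, cfg)
  sm <- smoothed$smoothed
  n <- nrow(sm)
  fr <- traj$frame_rate
  w <- round(cfg$turn_window / 1000 * fr)
  keep <- peaks - w >= 1 & peaks + w <= n
  n_dropped <- sum(!keep)
  peaks <- peaks[keep]
  if (length(peaks) >= 2 && any(diff(peaks) < 2 * w)) {
    warning("turn windows of adjacent bouts overlap; keeping both")
  }
  heading_at <- function(idx) {
    if ("heading" %in% names(sm)) {
      sm$heading[idx]
    } else {
      # displacement heading over a ~50 ms span centered on the frame
      h <- max(1L, round(0.025 * fr))
      i0 <- pmax(idx - h, 1L)
      i1 <- pmin(idx + h, n)
      atan2(sm$y[i1] - sm$y[i0], sm$x[i1] - sm$x[i0])
    }
  }
  pre <- peaks - w
  post <- peaks + w
  angle <- wrap_angle(heading_at(post) - heading_at(pre))
  disp <- sqrt((sm$x[post] - sm$x[pre])^2 + (sm$y[post] - sm$y[pre])^2)
  r <- sqrt((sm$x[peaks] - traj$arena_center[1])^2 +
              (sm$y[peaks] - traj$arena_center[2])^2)
  out <- data.frame(
    t_peak = sm$t[peaks],
    turn_angle = angle,
    magnitude = abs(angle),
    is_turn = abs(angle) >= cfg$turn_classification_threshold,
    displacement = disp,
    distance_from_wall = pmax(traj$arena_radius - r, 0)
  )
  attr(out, "n_edge_dropped") <- n_dropped
  out
}

#' Exclude bouts executed near the arena wall
#'
#' Keeps events at least `wall_exclusion` (default 1 cm) from the edge of
#' the dish, removing thigmotaxis artifacts from turn-sequence analyses.
#'
#' @param events Bout-event data frame from [compute_turn_angles()].
#' @param cfg A `kinematics_config`.
#' @return Filtered data frame.
#' @export
filter_wall_events <- function(events, cfg = kinematics_config()) {
  events[events$distance_from_wall >= cfg$wall_exclusion, , drop = FALSE]
}

#' Full trajectory-to-bouts pipeline
#'
#' Smoothing, bout detection, turn-angle extraction and wall filtering in
#' one call.
#'
#' @param traj A `swim_trajectory`.
#' @param cfg A `kinematics_config`.
#' @param exclude_wall Apply the wall-exclusion filter (default TRUE).
#' @return Bout-event data frame (see [compute_turn_angles()]).
#' @export
extract_bouts <- function(traj, cfg = kinematics_config(),
                          exclude_wall = TRUE) {
  sv <- smooth_and_velocity(traj, cfg)
  peaks <- detect_bouts(sv$speed, traj$frame_rate, cfg)
  ev <- compute_turn_angles(traj, peaks, cfg, smoothed = sv)
  if (exclude_wall) ev <- filter_wall_events(ev, cfg)
  ev
}
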