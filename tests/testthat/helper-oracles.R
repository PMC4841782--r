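# independent oracles used across tests

# exhaustive hidden-path sum for the HMM likelihood (n <= 10)
brute_force_loglik <- function(model, directions) {
  obs <- ifelse(directions == 1, 1L, 2L)
  n <- length(obs)
  pi0 <- stationary_distribution(model)
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- pi0[s[1]] * model$emission[s[1], obs[1]]
    if (n > 1) {
      for (t in 2:n) {
        p <- p * model$transition[s[t - 1], s[t]] * model$emission[s[t], obs[t]]
      }
    }
    total <- total + p
  }
  unname(log(total))
}

# single-pass run-length count, independent of rle()
brute_force_streaks <- function(directions) {
  out <- integer(0)
  run <- 1L
  for (i in seq_along(directions)[-1]) {
    if (directions[i] == directions[i - 1]) {
      run <- run + 1L
    } else {
      out <- c(out, run)
      run <- 1L
    }
  }
  c(out, run)
}

# all-pairs point-to-segment collection oracle
brute_force_collect <- function(paths, resources, radius) {
  nt <- nrow(paths$x)
  nb <- ncol(paths$x) - 1L
  first <- matrix(Inf, nt, nrow(resources))
  seg_dist <- function(px, py, ax, ay, bx, by) {
    dx <- bx - ax; dy <- by - ay
    l2 <- dx^2 + dy^2
    tt <- if (l2 == 0) 0 else max(0, min(1, ((px - ax) * dx + (py - ay) * dy) / l2))
    sqrt((px - ax - tt * dx)^2 + (py - ay - tt * dy)^2)
  }
  for (i in seq_len(nt)) {
    for (r in seq_len(nrow(resources))) {
      for (b in seq_len(nb)) {
        d <- seg_dist(resources[r, 1], resources[r, 2],
                      paths$x[i, b], paths$y[i, b],
                      paths$x[i, b + 1], paths$y[i, b + 1])
        if (d <= radius) {
          first[i, r] <- b
          break
        }
      }
    }
  }
  first
}

# direct-definition critical-N oracle (O(n * window) loop)
brute_force_critical_n <- function(series, window, threshold) {
  mu <- cumsum(series) / seq_along(series)
  for (i in window:length(series)) {
    w <- mu[(i - window + 1):i]
    if (stats::var(w) / mean(w) < threshold) return(i)
  }
  length(series)
}

# well-separated synthetic bout train with a known smooth speed profile
make_bout_train <- function(bout_times, angles, frame_rate = 100,
                            duration = NULL, peak_speed = 20, tau = 0.15,
                            noise = 0) {
  if (is.null(duration)) duration <- max(bout_times) + 2
  n <- round(duration * frame_rate)
  t <- (seq_len(n) - 1) / frame_rate
  v <- numeric(n)
  heading <- numeric(n)
  h <- 0
  ramp <- round(0.15 * frame_rate)
  for (b in seq_along(bout_times)) {
    i0 <- round(bout_times[b] * frame_rate) + 1
    idx <- i0:n
    v[idx] <- pmax(v[idx], peak_speed * exp(-(t[idx] - t[i0]) / tau))
    ramp_idx <- i0:min(i0 + ramp - 1, n)
    heading[ramp_idx[1]:n] <- heading[ramp_idx[1]:n] +
      angles[b] * pmin(seq_along(ramp_idx[1]:n) / ramp, 1)
  }
  x <- cumsum(v * cos(heading)) / frame_rate
  y <- cumsum(v * sin(heading)) / frame_rate
  swim_trajectory(t, x + rnorm(n, 0, noise), y + rnorm(n, 0, noise),
                  heading = heading, frame_rate = frame_rate,
                  arena_center = c(mean(x), mean(y)), arena_radius = 1000)
}
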