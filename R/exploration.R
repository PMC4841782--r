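#' Configuration of the exploration-efficiency simulation
#'
#' Geometry is expressed in bout lengths. Trajectories of `n_bouts` unit
#' steps start at the origin with a uniformly random initial heading.
#' Virtual resources are scattered uniformly over a square arena of side
#' `area` centered on the start, at `resource_density` resources per
#' square bout length, and are collected when a trajectory passes within
#' `detection_radius` (a remote detection radius, e.g. an odor gradient).
#'
#' @param n_bouts Bouts per trajectory (default 40).
#' @param n_traj Number of simulated trajectories (default 20000;
#'   the full-scale study size is 1e6).
#' @param bout_length Step length in bout lengths (default 1).
#' @param area Side of the square resource field (default 25).
#' @param resource_density Resources per square bout length
#'   (default 0.10).
#' @param detection_radius Collection distance (default 3.25).
#' @param seed Optional integer seed.
#' @return List of class `exploration_config`.
#' @export
exploration_config <- function(n_bouts = 40, n_traj = 20000,
                               bout_length = 1, area = 25,
                               resource_density = 0.10,
                               detection_radius = 3.25, seed = NULL) {
  stopifnot_positive(n_bouts = n_bouts, n_traj = n_traj,
                     bout_length = bout_length, area = area,
                     resource_density = resource_density,
                     detection_radius = detection_radius)
  if (area^2 * resource_density < 1) {
    stop("resource field must contain at least one expected resource",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "exploration_config")
}

# vectorized Markov emission sampling: n_traj independent chains
generate_turns_matrix <- function(model, n_traj, n_bouts) {
  P <- model$transition
  E <- model$emission
  pi0 <- tryCatch(stationary_distribution(model),
                  error = function(e) c(0.5, 0.5))
  states <- matrix(0L, n_traj, n_bouts)
  states[, 1] <- ifelse(stats::runif(n_traj) < pi0[1], 1L, 2L)
  for (b in seq_len(n_bouts - 1L)) {
    p_to1 <- P[states[, b], 1]
    states[, b + 1L] <- ifelse(stats::runif(n_traj) < p_to1, 1L, 2L)
  }
  dirs <- matrix(ifelse(stats::runif(n_traj * n_bouts) <
                          E[states, 1], 1L, -1L), n_traj, n_bouts)
  list(states = states, directions = dirs)
}

# draw |angles| from an empirical sample or generator function, apply a
# multiplicative broadening factor with rejection-resampling above pi
draw_magnitudes <- function(magnitudes, n, angle_scale = 1) {
  draw <- function(m) {
    if (is.function(magnitudes)) magnitudes(m)
    else sample(magnitudes, m, replace = TRUE)
  }
  out <- draw(n) * angle_scale
  while (any(out > pi)) {
    bad <- out > pi
    out[bad] <- draw(sum(bad)) * angle_scale
  }
  out
}

#' Simulate 2-D swim paths from a turn-direction model
#'
#' Each trajectory starts at the origin with heading uniform on
#' `[0, 2 pi)`. Per bout, a turn magnitude is drawn from `magnitudes`,
#' signed by the model's emission sequence, added to the heading, and the
#' fish advances by `bout_length * step_scale`.
#'
#' @param model A `markov_model`.
#' @param cfg An `exploration_config`.
#' @param magnitudes Numeric vector (empirical |angle| sample in rad,
#'   resampled with replacement) or a function `n -> magnitudes`.
#' @param step_scale Multiplier on the bout length (diffusion matching by
#'   bout-length scaling; default 1).
#' @param angle_scale Multiplier on turn magnitudes, with draws above pi
#'   rejection-resampled (diffusion matching by angle broadening;
#'   default 1).
#' @param seed Optional integer seed.
#' @return List of class `path_ensemble`: `x`, `y` (n_traj x
#'   (n_bouts + 1) positions), `angles` (signed, n_traj x n_bouts),
#'   `step` (realized step length).
#' @export
simulate_paths <- function(model, cfg = exploration_config(), magnitudes,
                           step_scale = 1, angle_scale = 1, seed = NULL) {
  with_seed(seed, {
    nt <- cfg$n_traj
    nb <- cfg$n_bouts
    dirs <- generate_turns_matrix(model, nt, nb)$directions
    mags <- matrix(draw_magnitudes(magnitudes, nt * nb, angle_scale), nt, nb)
    angles <- dirs * mags
    h0 <- stats::runif(nt, 0, 2 * pi)
    headings <- h0 + t(apply(angles, 1, cumsum))
    step <- cfg$bout_length * step_scale
    x <- cbind(0, t(apply(step * cos(headings), 1, cumsum)))
    y <- cbind(0, t(apply(step * sin(headings), 1, cumsum)))
    structure(list(x = x, y = y, angles = angles, step = step),
              class = "path_ensemble")
  })
}

#' Mean net displacement after n_bouts
#'
#' The diffusion summary used for matching: the ensemble mean of the
#' distance between the final position and the start.
#'
#' @param model A `markov_model`.
#' @param cfg An `exploration_config`.
#' @param magnitudes Magnitude source (see [simulate_paths()]).
#' @param step_scale,angle_scale Matching factors (see
#'   [simulate_paths()]).
#' @param seed Optional integer seed.
#' @return Mean displacement in bout lengths.
#' @export
mean_diffusion <- function(model, cfg = exploration_config(), magnitudes,
                           step_scale = 1, angle_scale = 1, seed = NULL) {
  paths <- simulate_paths(model, cfg, magnitudes, step_scale, angle_scale,
                          seed = seed)
  nb1 <- ncol(paths$x)
  mean(sqrt(paths$x[, nb1]^2 + paths$y[, nb1]^2))
}

#' Match the diffusion of an uncorrelated model to a correlated one
#'
#' Finds, by bisection, the factor that makes the uncorrelated model's
#' mean 40-bout displacement equal (within `tol_frac`) to the correlated
#' model's. In `"bout_length"` mode the factor shrinks the step size; in
#' `"angle_broadening"` mode it scales the turn magnitudes (draws above
#' pi are rejection-resampled). Both simulations in each comparison share
#' a seed so the objective is deterministic.
#'
#' @param correlated,random `markov_model`s.
#' @param cfg An `exploration_config`.
#' @param magnitudes Magnitude source (see [simulate_paths()]).
#' @param mode `"bout_length"` or `"angle_broadening"`.
#' @param tol_frac Relative matching tolerance (default 0.005).
#' @param seed Optional integer seed.
#' @return List: `factor`; `pct_change`, the bout-length decrease (%) or
#'   mean-turn-angle increase (%) the factor induces; `target` and
#'   `achieved` mean diffusions.
#' @export
match_diffusion <- function(correlated, random, cfg = exploration_config(),
                            magnitudes, mode = c("bout_length", "angle_broadening"),
                            tol_frac = 0.005, seed = 1) {
  mode <- match.arg(mode)
  target <- mean_diffusion(correlated, cfg, magnitudes, seed = seed)
  objective <- function(f) {
    d <- if (mode == "bout_length") {
      mean_diffusion(random, cfg, magnitudes, step_scale = f, seed = seed + 1)
    } else {
      mean_diffusion(random, cfg, magnitudes, angle_scale = f, seed = seed + 1)
    }
    d - target
  }
  if (mode == "bout_length") {
    lo <- 0.1; hi <- 1.5
  } else {
    lo <- 1; hi <- 12
  }
  f_lo <- objective(lo)
  f_hi <- objective(hi)
  # diffusion decreases with broadening, increases with step size
  if (mode == "angle_broadening") {
    tmp <- f_lo; f_lo <- f_hi; f_hi <- tmp
    increasing <- FALSE
  } else {
    increasing <- TRUE
  }
  if (sign(f_lo) == sign(f_hi)) {
    stop("search interval does not bracket the matching factor", call. = FALSE)
  }
  for (it in seq_len(60)) {
    mid <- (lo + hi) / 2
    fm <- objective(mid)
    if (abs(fm) <= tol_frac * target) break
    pos <- fm > 0
    if (increasing) {
      if (pos) hi <- mid else lo <- mid
    } else {
      if (pos) lo <- mid else hi <- mid
    }
  }
  pct_change <- if (mode == "bout_length") {
    (1 - mid) * 100
  } else {
    base <- with_seed(seed + 2, mean(draw_magnitudes(magnitudes, 2e5)))
    broad <- with_seed(seed + 2, mean(draw_magnitudes(magnitudes, 2e5, mid)))
    (broad / base - 1) * 100
  }
  list(factor = mid, pct_change = pct_change,
       target = target, achieved = target + fm, mode = mode)
}

#' Scatter resources and collect them along paths
#'
#' Resources are placed uniformly at random over the square field. A
#' resource is collected by a trajectory at the first bout whose swept
#' segment passes within the detection radius (point-to-segment
#' distance, so passage anywhere along the step counts); each resource
#' is collected at most once per trajectory.
#'
#' @param paths A `path_ensemble`.
#' @param cfg An `exploration_config`.
#' @param resources Optional R x 2 matrix of resource positions
#'   (generated from `seed` when NULL).
#' @param seed Seed for resource placement.
#' @return List: `first_bout` (n_traj x R matrix, bout index of first
#'   collection, `Inf` when never collected), `cum_collected` (n_traj x
#'   n_bouts matrix of resources collected by each bout), `resources`.
#' @export
scatter_and_collect <- function(paths, cfg = exploration_config(),
                                resources = NULL, seed = NULL) {
  if (is.null(resources)) {
    n_res <- max(1L, round(cfg$area^2 * cfg$resource_density))
    resources <- with_seed(seed, {
      matrix(stats::runif(2 * n_res, -cfg$area / 2, cfg$area / 2), ncol = 2)
    })
  }
  n_res <- nrow(resources)
  nt <- nrow(paths$x)
  nb <- ncol(paths$x) - 1L
  first_bout <- matrix(Inf, nt, n_res)
  r2 <- cfg$detection_radius^2
  for (b in seq_len(nb)) {
    ax <- paths$x[, b]; ay <- paths$y[, b]
    bx <- paths$x[, b + 1L]; by <- paths$y[, b + 1L]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx^2 + dy^2
    len2[len2 == 0] <- 1e-300
    for (r in seq_len(n_res)) {
      px <- resources[r, 1] - ax
      py <- resources[r, 2] - ay
      tt <- pmin(pmax((px * dx + py * dy) / len2, 0), 1)
      d2 <- (px - tt * dx)^2 + (py - tt * dy)^2
      hit <- d2 <= r2 & first_bout[, r] == Inf
      first_bout[hit, r] <- b
    }
  }
  cum_collected <- matrix(0L, nt, nb)
  for (b in seq_len(nb)) {
    cum_collected[, b] <- rowSums(first_bout <= b)
  }
  list(first_bout = first_bout, cum_collected = cum_collected,
       resources = resources)
}

# per-trajectory total |angle| turned up to (and including) the bout at
# which the k-th resource is collected; NA when fewer than k collected
angle_to_kth <- function(paths, collected, k) {
  nt <- nrow(paths$angles)
  cum_abs <- t(apply(abs(paths$angles), 1, cumsum))
  kth_bout <- apply(collected$first_bout, 1, function(fb) {
    fb <- sort(fb[is.finite(fb)])
    if (length(fb) >= k) fb[k] else NA_real_
  })
  out <- rep(NA_real_, nt)
  ok <- !is.na(kth_bout)
  out[ok] <- cum_abs[cbind(which(ok), kth_bout[ok])]
  out
}

#' First index at which a Monte-Carlo estimate stabilizes
#'
#' Forms the running mean of the per-simulation series and returns the
#' first index at which the local Fano factor of the running estimate
#' (variance / mean over a trailing moving window) drops below the
#' threshold.
#'
#' @param series Per-simulation metric values, in simulation order.
#' @param window Moving-window width (default 400).
#' @param fano_threshold Stability threshold (default 1e-5).
#' @return Integer index N (series length, with a warning, when the
#'   threshold is never reached).
#' @export
critical_n <- function(series, window = 400, fano_threshold = 1e-5) {
  n <- length(series)
  if (n < window) stop("series shorter than the window", call. = FALSE)
  mu <- cumsum(series) / seq_len(n)
  if (is.infinite(fano_threshold)) return(as.integer(window))
  rm1 <- zoo::rollmean(mu, window, align = "right")
  rm2 <- zoo::rollmean(mu^2, window, align = "right")
  v <- pmax(rm2 - rm1^2, 0) * window / (window - 1)
  fano <- v / rm1
  idx <- which(fano < fano_threshold)
  if (length(idx) == 0) {
    warning("Fano factor never dropped below the threshold")
    return(as.integer(n))
  }
  as.integer(idx[1] + window - 1L)
}

#' Compare exploration efficiency between two turn models
#'
#' Simulates both models on shared resource fields and summarizes: mean
#' resources collected as a function of bout number; total |angle|
#' turned until the k-th resource over 'successful' trajectories (with
#' per-k success rates); the percent differences between models; a
#' two-tailed two-sample t-test at the critical simulation number, with
#' power from a normal approximation; all replicated over `n_fields`
#' independent resource fields.
#'
#' @param model_a Correlated `markov_model` (reference).
#' @param model_b Comparison model (e.g. diffusion-matched
#'   [random_model()]).
#' @param cfg An `exploration_config`.
#' @param magnitudes Magnitude source (see [simulate_paths()]).
#' @param step_scale_b,angle_scale_b Matching factors applied to model B.
#' @param k_resources Resource counts for the turning-cost statistic
#'   (default `c(1, 10)`).
#' @param n_fields Number of independent resource fields (default 3).
#' @param seed Integer seed.
#' @return Object of class `efficiency_result`: list with
#'   `resources_vs_bout` (per-model mean curves, averaged over fields),
#'   `pct_fewer_resources_b` (% fewer resources for model B after the
#'   final bout), `pct_more_turning_b` (named by k, % more turning for
#'   model B), `success_rate` (per model x k), `critical_n`, `t_test`
#'   (statistic, p, df at critical N), `power`, `n_fields`, `n_traj`.
#' @export
efficiency_compare <- function(model_a, model_b, cfg = exploration_config(),
                               magnitudes, step_scale_b = 1,
                               angle_scale_b = 1, k_resources = c(1, 10),
                               n_fields = 3, seed = 1) {
  nb <- cfg$n_bouts
  curves_a <- matrix(0, n_fields, nb)
  curves_b <- matrix(0, n_fields, nb)
  pct_turn <- matrix(NA_real_, n_fields, length(k_resources))
  succ_a <- matrix(NA_real_, n_fields, length(k_resources))
  succ_b <- matrix(NA_real_, n_fields, length(k_resources))
  final_a <- NULL
  final_b <- NULL
  for (f in seq_len(n_fields)) {
    s <- seed + 1000 * (f - 1)
    pa <- simulate_paths(model_a, cfg, magnitudes, seed = s)
    pb <- simulate_paths(model_b, cfg, magnitudes,
                         step_scale = step_scale_b,
                         angle_scale = angle_scale_b, seed = s + 1)
    ca <- scatter_and_collect(pa, cfg, seed = s + 2)
    cb <- scatter_and_collect(pb, cfg, resources = ca$resources)
    curves_a[f, ] <- colMeans(ca$cum_collected)
    curves_b[f, ] <- colMeans(cb$cum_collected)
    for (ki in seq_along(k_resources)) {
      k <- k_resources[ki]
      ta <- angle_to_kth(pa, ca, k)
      tb <- angle_to_kth(pb, cb, k)
      succ_a[f, ki] <- mean(!is.na(ta))
      succ_b[f, ki] <- mean(!is.na(tb))
      if (any(!is.na(ta)) && any(!is.na(tb))) {
        pct_turn[f, ki] <- (mean(tb, na.rm = TRUE) / mean(ta, na.rm = TRUE) - 1) * 100
      }
    }
    if (f == 1) {
      final_a <- ca$cum_collected[, nb]
      final_b <- cb$cum_collected[, nb]
    }
  }
  mean_a <- colMeans(curves_a)
  mean_b <- colMeans(curves_b)
  pct_fewer <- (1 - mean_b[nb] / mean_a[nb]) * 100
  n_crit <- tryCatch(
    max(critical_n(final_a), critical_n(final_b)),
    error = function(e) length(final_a),
    warning = function(w) length(final_a)
  )
  n_use <- min(n_crit, length(final_a))
  tt <- stats::t.test(final_a[seq_len(n_use)], final_b[seq_len(n_use)])
  # normal-approximation power for the two-sample comparison at n_use
  delta <- mean(final_a) - mean(final_b)
  se <- sqrt(stats::var(final_a) / n_use + stats::var(final_b) / n_use)
  power <- stats::pnorm(abs(delta) / se - stats::qnorm(0.975))
  structure(list(
    resources_vs_bout = list(model_a = mean_a, model_b = mean_b),
    pct_fewer_resources_b = pct_fewer,
    pct_more_turning_b = stats::setNames(colMeans(pct_turn, na.rm = TRUE),
                                         paste0("k", k_resources)),
    success_rate = list(model_a = colMeans(succ_a),
                        model_b = colMeans(succ_b)),
    critical_n = n_crit,
    t_test = list(statistic = unname(tt$statistic), p_value = tt$p.value,
                  df = unname(tt$parameter), n = n_use),
    power = power,
    n_fields = n_fields,
    n_traj = cfg$n_traj
  ), class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  nb <- length(x$resources_vs_bout$model_a)
  cat(sprintf("Exploration efficiency over %d trajectories x %d fields:\n",
              x$n_traj, x$n_fields))
  cat(sprintf("  resources after %d bouts: %.3f (correlated) vs %.3f (random): %.1f%% fewer\n",
              nb, x$resources_vs_bout$model_a[nb],
              x$resources_vs_bout$model_b[nb], x$pct_fewer_resources_b))
  for (k in names(x$pct_more_turning_b)) {
    cat(sprintf("  %% more turning for random at %s: %.1f%%\n",
                k, x$pct_more_turning_b[[k]]))
  }
  cat(sprintf("  critical N = %d; t = %.2f, p = %.3g, power = %.3f\n",
              x$critical_n, x$t_test$statistic, x$t_test$p_value, x$power))
  invisible(x)
}
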