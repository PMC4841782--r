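#' Raised-cosine polar basis over behavior space
#'
#' Swim events live in a two-dimensional behavior space: radius encodes
#' normalized swim amplitude (vigor) in (0, 1], and angle encodes
#' laterality over `[0, pi]` (0 = full left, pi = full right). The space
#' is tiled separably and evenly with 3 radial x 4 angular bins; each bin
#' has a flat top and raised-cosine (cos^2) transition regions with 50%
#' overlap, so adjacent profiles cross at 0.5 and the 12 products form a
#' partition of unity on the tiled interior. The innermost radial bin
#' ramps up from zero amplitude, so rest frames carry no regressor
#' weight; the outermost radial bin and both angular edge bins extend
#' their flat tops to the domain boundary.
#'
#' @param n_radial Number of radial bins (default 3).
#' @param n_angular Number of angular bins (default 4).
#' @return Object of class `polar_basis` with fields `n_radial`,
#'   `n_angular`, `n_basis`, `angular_centers` (flat-top midpoints, rad),
#'   and `radial_interior` (radius above which the partition of unity
#'   holds).
#' @export
polar_basis <- function(n_radial = 3, n_angular = 4) {
  structure(list(
    n_radial = n_radial,
    n_angular = n_angular,
    n_basis = n_radial * n_angular,
    # angular layout: flat / ramp alternating, both edges flat
    angular_centers = (4 * seq_len(n_angular) - 3) *
      pi / (2 * (2 * n_angular - 1)),
    radial_interior = 1 / (2 * n_radial)
  ), class = "polar_basis")
}

# cos^2 ramp from 0 at s = 0 to 1 at s = 1
rc_up <- function(s) sin(pi * s / 2)^2

# 1-D tiling with equal flat and transition widths.
# edge = c(left, right), each "ramp" or "flat": whether the first/last bin
# ramps at the domain edge or extends its flat top to it.
rc_tile <- function(x, n, domain, edge = c("flat", "flat")) {
  L <- domain[2] - domain[1]
  n_seg <- 2 * n - 1 + (edge[1] == "ramp") + (edge[2] == "ramp")
  w <- L / n_seg
  # segment index of each bin's flat top
  first_flat <- 1 + (edge[1] == "ramp")
  out <- matrix(0, length(x), n)
  xr <- (x - domain[1]) / w # position in segment units
  for (j in seq_len(n)) {
    f0 <- first_flat + 2 * (j - 1) # flat start (segment units)
    f1 <- f0 + 1                   # flat end
    up0 <- f0 - 1
    dn1 <- f1 + 1
    val <- numeric(length(x))
    in_flat <- xr >= f0 - 1 & xr <= f1 - 1
    val[in_flat] <- 1
    has_up <- j > 1 || edge[1] == "ramp"
    if (has_up) {
      in_up <- xr >= up0 - 1 & xr < f0 - 1
      val[in_up] <- rc_up(xr[in_up] - (up0 - 1))
    } else {
      val[xr < f0 - 1 & xr >= 0] <- 1 # flat extends to the left edge
    }
    has_dn <- j < n || edge[2] == "ramp"
    if (has_dn) {
      in_dn <- xr > f1 - 1 & xr <= dn1 - 1
      val[in_dn] <- rc_up(dn1 - 1 - xr[in_dn])
    } else {
      val[xr > f1 - 1 & xr <= n_seg] <- 1 # flat extends to the right edge
    }
    out[, j] <- val
  }
  out[x < domain[1] | x > domain[2], ] <- 0
  out
}

#' Evaluate the polar basis at behavior-space points
#'
#' Maps `(amp, dir)` to polar coordinates (radius = amp, angle =
#' `acos(dir / amp)` over `[0, pi]`) and returns the 12 basis weights,
#' the product of the radial and angular profiles. Basis `j` indexes
#' radial bin `i` and angular bin `m` as `j = (m - 1) * n_radial + i`.
#' Weights are all zero at `amp = 0` (rest) and sum to 1 for radii in the
#' tiled interior. Amplitudes above 1 are clipped with a warning.
#'
#' @param amp Normalized swim amplitude(s) in `[0, 1]`.
#' @param dir Signed direction value(s), `|dir| <= amp` (+ = left).
#' @param basis A `polar_basis`.
#' @return Matrix `length(amp)` x 12 of non-negative weights.
#' @export
eval_polar_basis <- function(amp, dir, basis = polar_basis()) {
  if (length(dir) != length(amp)) stop("amp and dir lengths differ", call. = FALSE)
  if (any(amp < 0)) stop("`amp` must be >= 0", call. = FALSE)
  if (any(amp > 1)) {
    warning("amplitude > 1 clipped to 1")
    amp <- pmin(amp, 1)
  }
  if (any(abs(dir) > amp + 1e-9)) {
    stop("|dir| must not exceed amp", call. = FALSE)
  }
  theta <- ifelse(amp > 0, acos(pmax(-1, pmin(1, dir / amp))), 0)
  Rw <- rc_tile(amp, basis$n_radial, c(0, 1), edge = c("ramp", "flat"))
  Aw <- rc_tile(theta, basis$n_angular, c(0, pi), edge = c("flat", "flat"))
  Rw[amp == 0, ] <- 0
  out <- matrix(0, length(amp), basis$n_basis)
  for (m in seq_len(basis$n_angular)) {
    cols <- (m - 1) * basis$n_radial + seq_len(basis$n_radial)
    out[, cols] <- Rw * Aw[, m]
  }
  out
}

#' Impulse kernel reflecting calcium-indicator dynamics
#'
#' Piecewise-linear kernel with a 1 s rise and 5 s decay (defaults),
#' normalized to unit peak and sampled at the imaging frame rate.
#'
#' @param rise Rise time in s (default 1).
#' @param decay Decay time in s (default 5).
#' @param frame_rate Samples per second (default 1.87).
#' @return Numeric vector of kernel taps (first tap at lag 0).
#' @export
impulse_kernel <- function(rise = 1, decay = 5, frame_rate = 1.87) {
  stopifnot_positive(rise = rise, decay = decay, frame_rate = frame_rate)
  tt <- seq(0, rise + decay, by = 1 / frame_rate)
  k <- ifelse(tt <= rise, tt / rise, 1 - (tt - rise) / decay)
  k[k < 0] <- 0
  k
}

#' Behavior signals from decoded bouts
#'
#' Converts a bout table into the two instantaneous behavior parameters
#' used by the regression: `amp`, the swim amplitude (vigor normalized so
#' the strongest bout is 1), and `dir`, the signed turn amplitude scaled
#' by the same factor (so `|dir| <= amp`). Both are impulse series: the
#' bout's values at its frame, zero elsewhere. When two bouts collide on
#' one frame the more vigorous one is kept.
#'
#' @param bouts Data frame with `t_peak` (or `onset`) in s,
#'   `vigor` > 0 and `turn_amplitude` columns (as produced by
#'   [decode_fictive()] or convertible from kinematic bouts).
#' @param T_len Number of imaging frames.
#' @param frame_rate Imaging frame rate in Hz.
#' @return Object of class `behavior_signals`: list with `amp`, `dir`
#'   (length `T_len`), `frame_rate`.
#' @export
behavior_signals <- function(bouts, T_len, frame_rate) {
  if (nrow(bouts) < 1) stop("need at least one bout", call. = FALSE)
  t_b <- if ("t_peak" %in% names(bouts)) bouts$t_peak else bouts$onset
  frames <- round(t_b * frame_rate) + 1L
  if (any(frames > T_len)) {
    stop("record shorter than the last bout", call. = FALSE)
  }
  vmax <- max(bouts$vigor)
  if (vmax <= 0) stop("all bouts have zero vigor", call. = FALSE)
  amp <- numeric(T_len)
  dir <- numeric(T_len)
  ord <- order(bouts$vigor) # later assignment wins: most vigorous bout
  for (i in ord) {
    amp[frames[i]] <- bouts$vigor[i] / vmax
    dir[frames[i]] <- bouts$turn_amplitude[i] / vmax
  }
  structure(list(amp = amp, dir = dir, frame_rate = frame_rate),
            class = "behavior_signals")
}

#' Build the 13 x T regressor matrix
#'
#' Each of the 12 basis weights, evaluated at every frame of the behavior
#' signals, is convolved causally with the impulse kernel; a constant row
#' of ones is appended.
#'
#' @param signals A `behavior_signals`.
#' @param basis A `polar_basis`.
#' @param kernel Kernel taps from [impulse_kernel()].
#' @return List of class `regressor_matrix` with `X` (13 x T),
#'   `frame_rate`, `basis`.
#' @export
build_regressors <- function(signals, basis = polar_basis(),
                             kernel = impulse_kernel(frame_rate = signals$frame_rate)) {
  T_len <- length(signals$amp)
  if (length(kernel) > T_len) {
    stop("kernel longer than the record", call. = FALSE)
  }
  W <- eval_polar_basis(signals$amp, signals$dir, basis)
  X <- matrix(0, basis$n_basis + 1L, T_len)
  m <- length(kernel)
  for (j in seq_len(basis$n_basis)) {
    # exact causal FIR convolution (no FFT roundoff)
    padded <- c(rep(0, m - 1L), W[, j])
    conv <- stats::filter(padded, kernel, method = "convolution", sides = 1)
    X[j, ] <- as.numeric(conv[m:(m + T_len - 1L)])
  }
  X[basis$n_basis + 1L, ] <- 1
  structure(list(X = X, frame_rate = signals$frame_rate, basis = basis),
            class = "regressor_matrix")
}

#' Ordinary-least-squares fit of every voxel
#'
#' Solves the linear model `r ~ X` for each voxel time series by OLS on
#' the normal equations (with a 1e-8 relative ridge on the Gram matrix
#' when it is near-singular), and reports the fraction of variance
#' explained and the laterality index per voxel. Voxels are independent:
#' any evaluation order gives identical results. A zero-variance voxel
#' gets zero coefficients and R^2 = 0.
#'
#' @param X A `regressor_matrix`.
#' @param volume T x V matrix of voxel time series (dF/F).
#' @param basis Basis used for the laterality index (defaults to the one
#'   in `X`).
#' @return Object of class `voxel_tuning`: list with `b` (V x 12),
#'   `intercept` (length V), `r2` (length V, in `[0, 1]`), `laterality`
#'   (length V, in `[-1, 1]`).
#' @export
fit_voxels <- function(X, volume, basis = X$basis) {
  M <- X$X
  T_len <- ncol(M)
  if (T_len < nrow(M)) stop("need T >= 13 frames", call. = FALSE)
  volume <- as.matrix(volume)
  if (nrow(volume) != T_len) {
    stop("volume time axis does not match the regressor matrix", call. = FALSE)
  }
  G <- M %*% t(M)
  if (rcond(G) < 1e-10) {
    G <- G + diag(1e-8 * mean(diag(G)), nrow(G))
  }
  B <- solve(G, M %*% volume) # 13 x V
  pred <- t(M) %*% B
  ss_res <- colSums((volume - pred)^2)
  mu <- colMeans(volume)
  ss_tot <- colSums((volume - matrix(mu, T_len, ncol(volume), byrow = TRUE))^2)
  r2 <- ifelse(ss_tot > 0, pmin(pmax(1 - ss_res / ss_tot, 0), 1), 0)
  zero_var <- ss_tot <= 0
  B[, zero_var] <- 0
  b <- t(B[seq_len(nrow(M) - 1L), , drop = FALSE])
  structure(list(
    b = b,
    intercept = as.numeric(B[nrow(M), ]),
    r2 = as.numeric(r2),
    laterality = laterality_index(b, basis)
  ), class = "voxel_tuning")
}

#' Laterality index from tuning coefficients
#'
#' Coefficients are rectified at zero, summed across radial bins within
#' each angular bin, and the weighted circular mean of the angular bin
#' centers is mapped linearly from `[0, pi]` onto `[+1, -1]`
#' (+1 = left-preferring). Voxels whose rectified weights are all zero
#' get index 0.
#'
#' @param b 12-vector of coefficients, or a V x 12 matrix.
#' @param basis A `polar_basis`.
#' @return Scalar or length-V vector in `[-1, 1]`.
#' @export
laterality_index <- function(b, basis = polar_basis()) {
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  if (ncol(b) != basis$n_basis) stop("coefficient dimension mismatch", call. = FALSE)
  bp <- pmax(b, 0)
  U <- matrix(0, nrow(b), basis$n_angular)
  for (m in seq_len(basis$n_angular)) {
    cols <- (m - 1) * basis$n_radial + seq_len(basis$n_radial)
    U[, m] <- rowSums(bp[, cols, drop = FALSE])
  }
  cc <- U %*% cos(basis$angular_centers)
  ss <- U %*% sin(basis$angular_centers)
  theta <- atan2(ss, cc)
  out <- 1 - 2 * theta / pi
  out[rowSums(U) == 0] <- 0
  as.numeric(out)
}

#' Convert raw fluorescence to dF/F
#'
#' `dF/F(t) = (F(t) - F0(t)) / F0(t)` with `F0` a rolling 20th-percentile
#' baseline over a 60 s window (defaults). Voxels whose baseline is not
#' strictly positive are masked (`NA`).
#'
#' @param raw T x V matrix of raw fluorescence.
#' @param frame_rate Frames per second.
#' @param window_s Baseline window in s (default 60).
#' @param prob Baseline percentile (default 0.2).
#' @return T x V matrix of dF/F (masked voxels all `NA`).
#' @export
compute_dff <- function(raw, frame_rate, window_s = 60, prob = 0.2) {
  raw <- as.matrix(raw)
  width <- min(nrow(raw), max(3L, round(window_s * frame_rate)))
  if (nrow(raw) < 3) stop("record shorter than the baseline window", call. = FALSE)
  out <- raw
  for (v in seq_len(ncol(raw))) {
    f0 <- zoo::rollapply(raw[, v], width = width, FUN = stats::quantile,
                         probs = prob, partial = TRUE, align = "center")
    if (any(f0 <= 0)) {
      out[, v] <- NA_real_
    } else {
      out[, v] <- (raw[, v] - f0) / f0
    }
  }
  out
}

#' Render a tuning map volume
#'
#' Composes per-voxel color (hue from the laterality index: left = green,
#' right = magenta) and brightness (R^2, clipped at `saturation`) into an
#' RGB volume, and returns maximum-intensity projections.
#'
#' @param tuning A `voxel_tuning`.
#' @param shape Integer `(z, y, x)` grid shape with `prod(shape)` equal
#'   to the number of voxels.
#' @param saturation R^2 value at which brightness saturates
#'   (default 0.06).
#' @param flip_laterality Flip the left/right color convention
#'   (rendering only; default FALSE).
#' @return List with `rgb` (array z x y x x x 3) and `mip`, a function
#'   `axis -> projected RGB array` for `axis` in 1..3.
#' @export
render_map <- function(tuning, shape, saturation = 0.06,
                       flip_laterality = FALSE) {
  V <- prod(shape)
  if (length(tuning$r2) != V) stop("shape does not match voxel count", call. = FALSE)
  lat <- tuning$laterality
  if (flip_laterality) lat <- -lat
  bright <- pmin(tuning$r2 / saturation, 1)
  wl <- (lat + 1) / 2 # 1 = left (green), 0 = right (magenta)
  col <- cbind(r = (1 - wl), g = wl, b = (1 - wl)) * bright
  rgb_arr <- array(0, dim = c(shape, 3))
  for (ch in 1:3) rgb_arr[, , , ch] <- array(col[, ch], dim = shape)
  mip <- function(axis) {
    stopifnot(axis %in% 1:3)
    apply(rgb_arr, setdiff(1:4, axis), max)
  }
  list(rgb = rgb_arr, mip = mip)
}

#' Write an RGB projection as TIFF
#'
#' @param img 2-D RGB array (values in `[0, 1]`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_projection_tiff <- function(img, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to write TIFF output", call. = FALSE)
  }
  tiff::writeTIFF(img, path)
  invisible(path)
}
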