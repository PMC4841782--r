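#' Streak and switch-triggered statistics of signed turn sequences
#'
#' A "streak" (turn state) is a maximal run of consecutive turns in the
#' same direction. These functions quantify how strongly turn direction
#' depends on turn history, compared against a history-free coin-flip
#' fish whose overall left/right bias is matched to the data.
#'
#' @name turn_stats
NULL

#' Extract streak lengths from a turn sequence
#'
#' @param directions Vector of +1/-1 turn directions.
#' @return Integer vector of run lengths, in order of occurrence; their
#'   sum equals `length(directions)`.
#' @examples
#' extract_streaks(c(1, 1, 1, -1, -1, 1, -1, -1, -1, -1)) # 3 2 1 4
#' @export
extract_streaks <- function(directions) {
  if (length(directions) == 0) stop("empty turn sequence", call. = FALSE)
  if (!all(directions %in% c(-1, 1))) {
    stop("turn directions must be +1 or -1", call. = FALSE)
  }
  rle(as.integer(directions))$lengths
}

#' Fraction of left turns
#'
#' Overall turn bias: number of left turns divided by total turns.
#'
#' @param directions Vector of +1/-1 turn directions (+1 = left).
#' @return Scalar in `[0, 1]`.
#' @export
turn_bias <- function(directions) {
  if (length(directions) == 0) stop("empty turn sequence", call. = FALSE)
  mean(directions == 1)
}

#' Streak-length distribution
#'
#' Computes both relative-frequency conventions for streak lengths
#' `1..max_len` (runs longer than `max_len` are pooled into the top bin):
#' `rel_freq_count`, the fraction of streaks of each length, and
#' `rel_freq_bout`, the fraction of all bouts spent inside streaks of each
#' length. Cumulative forms (`P(streak length >= k)` under each weighting)
#' are included for survival-style histograms.
#'
#' @param streaks Integer vector of streak lengths (from
#'   [extract_streaks()]).
#' @param max_len Top bin (default 15).
#' @return Object of class `streak_distribution`: list with `lengths`,
#'   `counts`, `rel_freq_count`, `rel_freq_bout`, `cum_count`, `cum_bout`,
#'   `n_turns`, `n_streaks`.
#' @export
streak_distribution <- function(streaks, max_len = 15) {
  if (length(streaks) == 0) stop("no streaks supplied", call. = FALSE)
  n_turns <- sum(streaks)
  pooled <- pmin(streaks, max_len)
  counts <- tabulate(pooled, nbins = max_len)
  rel_count <- counts / length(streaks)
  # bout weighting uses the true streak length as mass, assigned to the
  # pooled bin so both vectors keep summing to one
  bout_mass <- vapply(seq_len(max_len), function(k) {
    sum(streaks[pooled == k])
  }, numeric(1)) / n_turns
  structure(list(
    lengths = seq_len(max_len),
    counts = counts,
    rel_freq_count = rel_count,
    rel_freq_bout = bout_mass,
    cum_count = rev(cumsum(rev(rel_count))),
    cum_bout = rev(cumsum(rev(bout_mass))),
    n_turns = n_turns,
    n_streaks = length(streaks)
  ), class = "streak_distribution")
}

#' @export
print.streak_distribution <- function(x, ...) {
  cat(sprintf("Streak distribution: %d streaks over %d turns\n",
              x$n_streaks, x$n_turns))
  print(data.frame(length = x$lengths, count = x$counts,
                   rel_count = round(x$rel_freq_count, 4),
                   rel_bout = round(x$rel_freq_bout, 4)))
  invisible(x)
}

#' Bias-matched coin-flip null sequence
#'
#' Draws `n` i.i.d. turn directions with `P(left) = bias`, mirroring the
#' construction of the history-independent model fish: a uniform random
#' number per turn is compared to the overall turn bias.
#'
#' @param bias Probability of a left turn, in `[0, 1]`.
#' @param n Sequence length.
#' @param seed Optional integer seed.
#' @return Vector of +1/-1 directions.
#' @export
coinflip_null <- function(bias, n, seed = NULL) {
  if (bias < 0 || bias > 1) stop("`bias` must lie in [0, 1]", call. = FALSE)
  with_seed(seed, {
    ifelse(stats::runif(n) <= bias, 1L, -1L)
  })
}

#' Switch-triggered cumulative turn-direction profile
#'
#' For every switch in turn direction (left to right or right to left),
#' subsequent turns are re-signed so the switch direction counts as +1,
#' and the cumulative sum over the following `K` turns is formed. Profiles
#' are averaged within each fish first, then across fish. The per-lag
#' increments (turn at lag k after the switch, re-signed) are tested
#' across fish against zero with a two-sided Wilcoxon signed-rank test;
#' for a memoryless fish every post-switch increment has expectation zero.
#' The state length is the last lag up to which increments remain
#' significantly positive before the first non-significant lag
#' (`p >= 0.05`); lag 1 is +1 by construction and anchors the count.
#'
#' @param seqs List of +1/-1 direction vectors, one per fish.
#' @param K Number of lags after the switch (default 15).
#' @param alpha Significance level for the state-length rule
#'   (default 0.05).
#' @return List with `lags`, `mean_cumulative` (across-fish mean),
#'   `sem_cumulative`, `per_fish_cumulative` (fish x lag matrix),
#'   `increment_p` (p-values for lags 2..K; lag 1 is deterministic),
#'   `state_length`, and `n_fish`.
#' @export
switch_triggered_profile <- function(seqs, K = 15, alpha = 0.05) {
  if (!is.list(seqs)) seqs <- list(seqs)
  per_fish_cum <- list()
  per_fish_inc <- list()
  for (f in seq_along(seqs)) {
    s <- as.integer(seqs[[f]])
    switches <- which(s[-1] != s[-length(s)]) + 1L
    # a switch needs K turns after it (inclusive) to contribute a full window
    switches <- switches[switches + K - 1L <= length(s)]
    if (length(switches) == 0) {
      warning(sprintf("fish %d has no complete switch-triggered window; excluded", f))
      next
    }
    wins <- vapply(switches, function(i) {
      s[i:(i + K - 1L)] * s[i] # re-sign so the switch direction is +1
    }, numeric(K))
    inc <- rowMeans(wins)
    per_fish_inc[[length(per_fish_inc) + 1L]] <- inc
    per_fish_cum[[length(per_fish_cum) + 1L]] <- cumsum(inc)
  }
  n_fish <- length(per_fish_cum)
  if (n_fish == 0) stop("no fish with switch events", call. = FALSE)
  cum_mat <- do.call(rbind, per_fish_cum)
  inc_mat <- do.call(rbind, per_fish_inc)
  p <- rep(NA_real_, K)
  if (n_fish >= 2) {
    for (k in 2:K) {
      p[k] <- stats::wilcox.test(inc_mat[, k], mu = 0, exact = FALSE)$p.value
    }
  }
  state_length <- 1L
  if (n_fish >= 2) {
    for (k in 2:K) {
      if (!is.na(p[k]) && p[k] < alpha && mean(inc_mat[, k]) > 0) {
        state_length <- k
      } else {
        break
      }
    }
  }
  list(
    lags = seq_len(K),
    mean_cumulative = colMeans(cum_mat),
    sem_cumulative = apply(cum_mat, 2, stats::sd) / sqrt(n_fish),
    per_fish_cumulative = cum_mat,
    increment_p = p,
    state_length = state_length,
    n_fish = n_fish
  )
}

#' NRMSE between observed and coin-flip streak distributions
#'
#' Goodness-of-fit between a fish's streak-length histogram and that of a
#' bias-matched coin-flip sequence of equal length:
#' `RMSE = sqrt(sum_{i=1..15} (obs_i - coin_i)^2 / 15)` over the
#' relative frequencies of streak lengths 1..15, and
#' `NRMSE = RMSE / (obs_max - obs_min)`. Values near zero mean the turn
#' sequence is statistically indistinguishable from biased coin flips.
#' The count-weighted relative frequency (fraction of streaks of each
#' length) enters the formula.
#'
#' @param directions Vector of +1/-1 turn directions.
#' @param seed Optional integer seed for the null draw(s).
#' @param n_reps Number of coin-flip draws averaged for the null histogram.
#'   The default 100 stabilizes the null; `n_reps = 1` reproduces the
#'   single-draw construction exactly.
#' @param max_len Number of histogram bins (default 15; longer streaks
#'   pool into the top bin).
#' @return Object of class `nrmse_result`: list with `rmse`, `nrmse`,
#'   `obs`, `coin`, `obs_max`, `obs_min`, `bias`, `n_turns`, `n_reps`.
#' @export
nrmse_vs_coinflip <- function(directions, seed = NULL, n_reps = 100,
                              max_len = 15) {
  if (length(directions) < max_len) {
    stop(sprintf("need at least %d turns", max_len), call. = FALSE)
  }
  obs <- streak_distribution(extract_streaks(directions), max_len)$rel_freq_count
  bias <- turn_bias(directions)
  n <- length(directions)
  coin <- with_seed(seed, {
    draws <- vapply(seq_len(n_reps), function(r) {
      null_seq <- coinflip_null(bias, n)
      streak_distribution(extract_streaks(null_seq), max_len)$rel_freq_count
    }, numeric(max_len))
    rowMeans(draws)
  })
  if (max(obs) == min(obs)) {
    stop("degenerate observed distribution: obs_max equals obs_min",
         call. = FALSE)
  }
  rmse <- sqrt(sum((obs - coin)^2) / max_len)
  structure(list(
    rmse = rmse,
    nrmse = rmse / (max(obs) - min(obs)),
    obs = obs,
    coin = coin,
    obs_max = max(obs),
    obs_min = min(obs),
    bias = bias,
    n_turns = n,
    n_reps = n_reps
  ), class = "nrmse_result")
}

#' @export
print.nrmse_result <- function(x, ...) {
  cat(sprintf("NRMSE vs bias-matched coin flips: %.4f (RMSE %.4f, bias %.3f, n %d)\n",
              x$nrmse, x$rmse, x$bias, x$n_turns))
  invisible(x)
}

#' Fraction of bouts spent in streaks of at least a given length
#'
#' Convenience summary over a cohort: for each fish the fraction of all
#' turns that fall inside streaks of length `>= k`, averaged across fish.
#'
#' @param seqs List of +1/-1 direction vectors, one per fish.
#' @param k Minimum streak length.
#' @return Across-fish mean fraction.
#' @export
fraction_bouts_in_streaks <- function(seqs, k) {
  if (!is.list(seqs)) seqs <- list(seqs)
  per_fish <- vapply(seqs, function(s) {
    st <- extract_streaks(s)
    sum(st[st >= k]) / sum(st)
  }, numeric(1))
  mean(per_fish)
}
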