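#' Two-state Markov model of turn direction
#'
#' Larval zebrafish chain spontaneous turns in one direction before
#' stochastically switching sides. That behavior is captured by a hidden
#' Markov model with two hidden states (a left-turn state `S_L` and a
#' right-turn state `S_R`) and binary emissions (`L` = left turn, `R` =
#' right turn). Rows of both matrices are ordered `(S_L, S_R)`; columns of
#' `emission` are ordered `(L, R)`.
#'
#' @param transition 2x2 row-stochastic state transition matrix,
#'   `transition[i, j] = P(S_j at t+1 | S_i at t)`.
#' @param emission 2x2 row-stochastic emission matrix,
#'   `emission[i, k] = P(symbol k | S_i)`.
#' @return An object of class `markov_model`.
#' @examples
#' m <- markov_model(rbind(c(0.86, 0.14), c(0.15, 0.85)),
#'                   rbind(c(0.85, 0.15), c(0.10, 0.90)))
#' stationary_distribution(m)
#' @export
markov_model <- function(transition, emission) {
  transition <- as.matrix(transition)
  emission <- as.matrix(emission)
  check_stochastic <- function(m, what) {
    if (!all(dim(m) == c(2L, 2L))) {
      stop(sprintf("`%s` must be a 2x2 matrix", what), call. = FALSE)
    }
    if (any(m < 0) || any(m > 1)) {
      stop(sprintf("`%s` entries must lie in [0, 1]", what), call. = FALSE)
    }
    if (any(abs(rowSums(m) - 1) > 1e-12)) {
      stop(sprintf("`%s` rows must each sum to 1", what), call. = FALSE)
    }
  }
  check_stochastic(transition, "transition")
  check_stochastic(emission, "emission")
  dimnames(transition) <- list(c("S_L", "S_R"), c("S_L", "S_R"))
  dimnames(emission) <- list(c("S_L", "S_R"), c("L", "R"))
  structure(list(transition = transition, emission = emission),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat("Two-state turn-direction Markov model\n")
  cat("Transition P(state' | state):\n")
  print(round(x$transition, 4))
  cat("Emission P(turn | state):\n")
  print(round(x$emission, 4))
  invisible(x)
}

#' Reference model for fish 16
#'
#' The best-fit transition and emission matrices for one example fish
#' (fish 16 of the 19-fish free-swimming cohort), used throughout as the
#' canonical correlated-turning model:
#' transition `[0.86 0.14; 0.15 0.85]`, emission `[0.85 0.15; 0.10 0.90]`.
#'
#' @return A `markov_model`.
#' @export
fish16_model <- function() {
  markov_model(rbind(c(0.86, 0.14), c(0.15, 0.85)),
               rbind(c(0.85, 0.15), c(0.10, 0.90)))
}

#' Memoryless coin-flip model
#'
#' Uniform state transitions with deterministic emissions: turn direction
#' is an i.i.d. fair coin flip, the uncorrelated null used in the
#' exploration simulations.
#'
#' @return A `markov_model`.
#' @export
random_model <- function() {
  markov_model(rbind(c(0.5, 0.5), c(0.5, 0.5)),
               rbind(c(1, 0), c(0, 1)))
}

#' Stationary distribution of the hidden chain
#'
#' Solves `pi P = pi`, `sum(pi) = 1` for the two-state transition matrix.
#'
#' @param model A `markov_model`.
#' @return Length-2 probability vector `(pi_L, pi_R)`.
#' @export
stationary_distribution <- function(model) {
  P <- model$transition
  a <- P[1, 2] # P(L -> R)
  b <- P[2, 1] # P(R -> L)
  if (a == 0 && b == 0) {
    # two absorbing states: reducible chain
    stop("transition matrix is reducible; stationary distribution not unique",
         call. = FALSE)
  }
  pi_l <- b / (a + b)
  c(S_L = pi_l, S_R = 1 - pi_l)
}

#' Generate a turn sequence from a Markov model
#'
#' Samples a hidden state path (initial state drawn from the stationary
#' distribution) and a binary emission per step. Emissions are coded
#' `+1` = left, `-1` = right.
#'
#' @param model A `markov_model`.
#' @param n Number of turns to generate.
#' @param seed Optional integer seed for reproducibility.
#' @return List with `states` (integer vector, 1 = `S_L`, 2 = `S_R`) and
#'   `directions` (vector of +1/-1).
#' @export
generate_turns <- function(model, n, seed = NULL) {
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  n <- as.integer(n)
  with_seed(seed, {
    P <- model$transition
    E <- model$emission
    pi0 <- tryCatch(stationary_distribution(model),
                    error = function(e) c(0.5, 0.5))
    states <- integer(n)
    u_state <- stats::runif(n)
    u_emit <- stats::runif(n)
    states[1] <- if (u_state[1] < pi0[1]) 1L else 2L
    for (t in seq_len(n - 1L)) {
      p_stay1 <- P[states[t], 1]
      states[t + 1L] <- if (u_state[t + 1L] < p_stay1) 1L else 2L
    }
    directions <- ifelse(u_emit < E[states, 1], 1L, -1L)
    list(states = states, directions = as.integer(directions))
  })
}

# map +1/-1 directions to symbol indices 1 (L) / 2 (R)
dir_to_symbol <- function(directions) {
  if (!all(directions %in% c(-1L, 1L))) {
    stop("turn directions must be +1 (left) or -1 (right)", call. = FALSE)
  }
  ifelse(directions == 1L, 1L, 2L)
}

# scaled forward pass; returns log-likelihood plus alpha/scale when asked
forward_pass <- function(P, E, pi0, obs, keep = FALSE) {
  n <- length(obs)
  alpha <- matrix(0, n, 2)
  scale <- numeric(n)
  a <- pi0 * E[, obs[1]]
  scale[1] <- sum(a)
  if (scale[1] <= 0) return(list(loglik = -Inf))
  alpha[1, ] <- a / scale[1]
  for (t in 2:n) {
    a <- (alpha[t - 1, ] %*% P) * E[, obs[t]]
    scale[t] <- sum(a)
    if (scale[t] <= 0) return(list(loglik = -Inf))
    alpha[t, ] <- a / scale[t]
  }
  out <- list(loglik = sum(log(scale)))
  if (keep) {
    out$alpha <- alpha
    out$scale <- scale
  }
  out
}

#' Log-likelihood of a turn sequence under a Markov model
#'
#' Scaled forward-algorithm likelihood. The initial hidden state is taken
#' from the stationary distribution of the transition matrix. A sequence
#' containing a zero-probability emission returns `-Inf` rather than an
#' error.
#'
#' @param model A `markov_model`.
#' @param directions Vector of +1/-1 turn directions.
#' @return Log-likelihood (scalar, possibly `-Inf`).
#' @export
loglikelihood <- function(model, directions) {
  obs <- dir_to_symbol(directions)
  pi0 <- tryCatch(stationary_distribution(model),
                  error = function(e) c(0.5, 0.5))
  forward_pass(model$transition, model$emission, pi0, obs)$loglik
}

# one full Baum-Welch EM run from a given starting point; the E-step
# recursions run in compiled code (see src/hmm.cpp)
baum_welch_run <- function(obs, P, E, pi0, tol, max_iter) {
  loglik_trace <- numeric(0)
  prev_ll <- -Inf
  converged <- FALSE
  converged_1e4 <- FALSE
  iter_1e4 <- NA_integer_
  for (iter in seq_len(max_iter)) {
    step <- .hmm_em_step(as.integer(obs), P, E, as.numeric(pi0))
    if (!is.finite(step$loglik)) break
    P_new <- step$P
    E_new <- step$E
    # degenerate all-same-symbol input leaves an emission column empty
    if (any(!is.finite(P_new)) || any(!is.finite(E_new))) {
      warning("degenerate sequence: emission/transition row pinned during EM")
      P_new[!is.finite(P_new)] <- P[!is.finite(P_new)]
      E_new[!is.finite(E_new)] <- E[!is.finite(E_new)]
    }
    pi_new <- step$pi
    d_ll <- abs(step$loglik - prev_ll)
    d_P <- sqrt(sum((P_new - P)^2))
    d_E <- sqrt(sum((E_new - E)^2))
    loglik_trace <- c(loglik_trace, step$loglik)
    P <- P_new
    E <- E_new
    pi0 <- pi_new
    prev_ll <- step$loglik
    if (!converged_1e4 && d_ll < 1e-4 && d_P < 1e-4 && d_E < 1e-4) {
      converged_1e4 <- TRUE
      iter_1e4 <- iter
    }
    if (d_ll < tol && d_P < tol && d_E < tol) {
      converged <- TRUE
      break
    }
  }
  list(P = P, E = E, pi0 = pi0, loglik_trace = loglik_trace,
       n_iter = length(loglik_trace), converged = converged,
       converged_1e4 = converged_1e4, iter_1e4 = iter_1e4)
}

#' Fit a two-state turn-direction HMM by Baum-Welch
#'
#' Expectation-maximization with scaled forward-backward recursions.
#' Iteration stops when the change in log-likelihood, the Frobenius norm of
#' the transition-matrix change, and the Frobenius norm of the
#' emission-matrix change are all below `tol`, or after `max_iter`
#' iterations. Whether the looser 1e-4 criterion was met is recorded in the
#' diagnostics as well. Several random restarts guard against local optima;
#' the restart with the best final log-likelihood wins. After fitting,
#' states are canonicalized so that `S_L` is the state with the higher
#' probability of emitting a left turn.
#'
#' @param directions Vector of +1/-1 turn directions (+1 = left).
#' @param init Optional `markov_model` used as the single starting point
#'   (suppresses random restarts).
#' @param tol Convergence tolerance applied to all three criteria
#'   (default 1e-6).
#' @param max_iter Maximum EM iterations (default 2000).
#' @param n_restarts Number of random restarts when `init` is NULL
#'   (default 5). Transition diagonals are drawn uniformly from
#'   (0.6, 0.95); initial emissions favor opposite symbols in the two
#'   states to break label symmetry.
#' @param seed Optional seed controlling the restart draws.
#' @return List with `model` (a `markov_model`) and `diagnostics` (fields
#'   `loglik_trace`, `n_iter`, `converged`, `converged_1e4`, `tol`,
#'   `max_iter`, `initial_distribution`).
#' @examples
#' turns <- generate_turns(fish16_model(), 2000, seed = 1)
#' fit <- fit_baum_welch(turns$directions, seed = 1)
#' fit$model
#' @export
fit_baum_welch <- function(directions, init = NULL, tol = 1e-6,
                           max_iter = 2000, n_restarts = 5, seed = NULL) {
  obs <- dir_to_symbol(directions)
  if (length(obs) < 10) stop("need at least 10 turns to fit", call. = FALSE)
  if (length(unique(obs)) == 1L) {
    warning("all turns share one direction; fit is degenerate")
  }
  starts <- if (!is.null(init)) {
    list(list(P = init$transition, E = init$emission))
  } else {
    with_seed(seed, {
      lapply(seq_len(n_restarts), function(i) {
        d <- stats::runif(2, 0.6, 0.95)
        e <- stats::runif(2, 0.6, 0.95)
        list(P = rbind(c(d[1], 1 - d[1]), c(1 - d[2], d[2])),
             E = rbind(c(e[1], 1 - e[1]), c(1 - e[2], e[2])))
      })
    })
  }
  best <- NULL
  for (s in starts) {
    pi0 <- c(0.5, 0.5)
    run <- baum_welch_run(obs, s$P, s$E, pi0, tol, max_iter)
    if (is.null(best) ||
        (length(run$loglik_trace) &&
         utils::tail(run$loglik_trace, 1) > utils::tail(best$loglik_trace, 1))) {
      best <- run
    }
  }
  P <- best$P
  E <- best$E
  pi0 <- best$pi0
  # canonical label order: S_L emits left turns preferentially
  if (E[2, 1] > E[1, 1]) {
    P <- P[2:1, 2:1]
    E <- E[2:1, , drop = FALSE]
    pi0 <- pi0[2:1]
  }
  list(
    model = markov_model(P, E),
    diagnostics = list(
      loglik_trace = best$loglik_trace,
      n_iter = best$n_iter,
      converged = best$converged,
      converged_1e4 = best$converged_1e4,
      tol = tol,
      max_iter = max_iter,
      initial_distribution = as.numeric(pi0)
    )
  )
}
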