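#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and afterwards restores the global
#' `.Random.seed` to whatever it was before the call, so seeded package
#' functions do not perturb the caller's random stream. With `seed = NULL`
#' the expression runs on the ambient stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Wrap angles into (-pi, pi]
#'
#' @param theta Numeric vector of angles in radians.
#' @return Angles mapped to the half-open interval (-pi, pi].
#' @examples
#' wrap_angle(6)    # -0.283..., i.e. 6 - 2*pi
#' wrap_angle(-pi)  # pi
#' @export
wrap_angle <- function(theta) {
  out <- theta %% (2 * pi)
  out[out > pi] <- out[out > pi] - 2 * pi
  # boundary: map -pi to +pi so the interval is (-pi, pi]
  out[out == -pi] <- pi
  out
}

# scalar positivity check used across configs
stopifnot_positive <- function(...) {
  args <- list(...)
  nms <- names(args)
  for (i in seq_along(args)) {
    x <- args[[i]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop(sprintf("`%s` must be a single positive number", nms[i]), call. = FALSE)
    }
  }
  invisible(TRUE)
}
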