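#' Piecewise-constant input signal
#'
#' The experimentally controlled input \eqn{S(t)} of every motif model is a
#' step function: on each half-open interval `[breakpoints[i],
#' breakpoints[i+1])` it takes the value `levels[i]`, and it holds the last
#' level beyond the final breakpoint. `pre_level` is the value before the
#' first breakpoint; it matters only for the delay models, whose lagged
#' signal lookups can reach before the start of a step experiment (there it
#' is the complementary step's level).
#'
#' @param breakpoints Strictly increasing vector of switch times.
#' @param levels Signal level on each interval; same length as `breakpoints`.
#' @param pre_level Level before the first breakpoint (default 0).
#'
#' @return An object of class `signal_profile`.
#' @examples
#' sig <- signal_profile(c(0, 2, 6, 10), c(0, 1, 2, 0))
#' signal_level(sig, c(1, 3, 7, 12)) # 0 1 2 0
#' @export
signal_profile <- function(breakpoints, levels, pre_level = 0) {
  stopifnot(length(breakpoints) == length(levels), length(breakpoints) >= 1)
  if (any(diff(breakpoints) <= 0)) {
    abort("`breakpoints` must be strictly increasing.")
  }
  structure(
    list(
      breakpoints = as.numeric(breakpoints),
      levels = as.numeric(levels),
      pre_level = as.numeric(pre_level)
    ),
    class = "signal_profile"
  )
}

#' Evaluate a signal profile
#'
#' @param signal A [signal_profile()].
#' @param t Times at which to evaluate (vectorised).
#' @return Numeric vector of signal levels.
#' @export
signal_level <- function(signal, t) {
  stopifnot(inherits(signal, "signal_profile"))
  idx <- findInterval(t, signal$breakpoints)
  out <- ifelse(idx == 0, signal$pre_level, signal$levels[pmax(idx, 1)])
  as.numeric(out)
}

#' @export
print.signal_profile <- function(x, ...) {
  cat("<signal_profile>\n")
  cat("  t >=", format(x$breakpoints), "\n")
  cat("  S  =", format(x$levels), "  (pre:", x$pre_level, ")\n")
  invisible(x)
}

#' The four-motif study input protocol
#'
#' Step signal S = {0, 1, 2, 0} switching at t = {0, 2, 6, 10}.
#' @return A [signal_profile()].
#' @export
motif_grid_signal <- function() {
  signal_profile(c(0, 2, 6, 10), c(0, 1, 2, 0), pre_level = 0)
}
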