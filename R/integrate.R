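#' Integrate a motif model to a trajectory
#'
#' Solves the model's differential equations over an output grid and returns
#' the trajectory in tidy form. Non-delay models are integrated with an
#' adaptive embedded Runge-Kutta (Cash-Karp 4/5) scheme that restarts at the
#' signal's breakpoints so step discontinuities are handled exactly. Delay
#' models are integrated by the method of steps with a fixed-step classical
#' Runge-Kutta scheme whose step never exceeds the lag (the pre-initial
#' history is constant at the initial state; the signal history before the
#' start is the profile's `pre_level`).
#'
#' A failed solve (divergence, non-finite states) is not an error: the
#' returned trajectory has `NA` values and attribute `ok = FALSE`, carrying
#' the failing parameter draw, so callers such as the MCMC sampler can treat
#' it as an infeasible draw.
#'
#' @param model A [motif_model()] or model name.
#' @param params Ordered or named parameter vector (no noise variance).
#' @param signal A [signal_profile()].
#' @param times Output time grid (non-decreasing, within the signal domain).
#' @param initial_state State at `times` start (default: all zeros, the
#'   resting state). The integration starts at `t0`.
#' @param t0 Start of integration (default: the signal's first breakpoint).
#' @param s2 Secondary constant input for control models (model default used
#'   when `NULL`).
#' @param rtol,atol Relative and absolute solver tolerances.
#'
#' @return A tibble with columns `time`, `variable`, `value`, of class
#'   `motif_trajectory`, with attributes `model`, `params`, `solver`, `ok`.
#' @examples
#' tr <- integrate_model("SIM", c(1, 1, 1, 1),
#'   signal = signal_profile(0, 1),
#'   times = seq(0, 5, by = 0.5)
#' )
#' head(tr)
#' @export
integrate_model <- function(model, params, signal, times, initial_state = NULL,
                            t0 = NULL, s2 = NULL, rtol = 1e-8, atol = 1e-10) {
  model <- as_motif_model(model)
  stopifnot(inherits(signal, "signal_profile"), !is.unsorted(times))
  p <- align_params(model, params)
  if (is.null(initial_state)) initial_state <- rep(0, length(model$states))
  if (is.null(t0)) t0 <- signal$breakpoints[1]
  if (is.null(s2)) s2 <- secondary_input(model)
  m <- cpp_integrate(
    model$code, unname(p), signal$breakpoints, signal$levels,
    signal$pre_level, s2, t0, as.numeric(initial_state), as.numeric(times),
    rtol, atol
  )
  ok <- isTRUE(attr(m, "ok"))
  if (!ok) {
    warn("solver failure; returning flagged non-finite trajectory")
    m[] <- NA_real_
  }
  out <- tibble(
    time = rep(as.numeric(times), times = length(model$states)),
    variable = rep(model$states, each = length(times)),
    value = as.numeric(m)
  )
  structure(out,
    class = c("motif_trajectory", class(out)),
    model = model$name, params = p,
    solver = list(rtol = rtol, atol = atol), ok = ok
  )
}

align_params <- function(model, params) {
  if (!is.null(names(params)) && all(model$params %in% names(params))) {
    params <- params[model$params]
  }
  if (length(params) != length(model$params)) {
    abort(paste0(
      "model ", model$name, " expects ", length(model$params),
      " parameters (", paste(model$params, collapse = ", "), ")"
    ))
  }
  setNames(as.numeric(params), model$params)
}

#' Spread a tidy trajectory to wide form
#'
#' @param trajectory A `motif_trajectory` tibble.
#' @return A tibble with one column per state variable.
#' @export
trajectory_wide <- function(trajectory) {
  tidyr::pivot_wider(as_tibble(trajectory),
    names_from = "variable", values_from = "value"
  )
}

#' @export
autoplot.motif_trajectory <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$time, y = .data$value, colour = .data$variable)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time", y = "concentration",
      title = paste0("Model ", attr(object, "model"), " trajectory")
    )
}
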