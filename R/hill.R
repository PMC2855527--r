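#' Hill rate laws and promoter logic gates
#'
#' Saturating transcription rate laws used throughout the motif models.
#' `hill_activation()` is the activating form \eqn{f^+(s) = s^h / (\theta^h +
#' s^h)}, `hill_repression()` the repressing form \eqn{f^-(s) = \theta^h /
#' (\theta^h + s^h)}; the two sum to one for shared \eqn{(\theta, h)}.
#' `gate()` combines two regulatory inputs at a promoter: an `"AND"` gate
#' multiplies the fractional activities, an `"OR"` gate uses the
#' probabilistic sum \eqn{f_s + f_y - f_s f_y}, which stays in \eqn{[0,1]}
#' and reduces to boolean logic at saturation.
#'
#' @param s Input level (signal or regulator concentration), non-negative.
#'   Vectorised.
#' @param theta Activation/repression threshold, strictly positive.
#' @param h Hill coefficient, strictly positive.
#' @param kind Gate type, `"AND"` or `"OR"`.
#' @param f_s,f_y Fractional promoter activities in `[0, 1]` contributed by
#'   the direct signal and the intermediate regulator.
#'
#' @return A numeric vector of fractional activities in `[0, 1]`.
#' @examples
#' hill_activation(1, theta = 0.5, h = 2) # 0.8
#' hill_activation(0.7, 0.5, 2) + hill_repression(0.7, 0.5, 2) # 1
#' gate("AND", 0.8, 0.5) # 0.4
#' gate("OR", 0.8, 0.5) # 0.9
#' @export
hill_activation <- function(s, theta, h) {
  check_hill_args(s, theta, h)
  sh <- s^h
  sh / (theta^h + sh)
}

#' @rdname hill_activation
#' @export
hill_repression <- function(s, theta, h) {
  check_hill_args(s, theta, h)
  thh <- theta^h
  thh / (thh + s^h)
}

check_hill_args <- function(s, theta, h) {
  if (any(!is.finite(theta)) || any(theta <= 0)) {
    abort("`theta` must be strictly positive.", class = "motifcompare_invalid_parameter")
  }
  if (any(!is.finite(h)) || any(h <= 0)) {
    abort("`h` must be strictly positive.", class = "motifcompare_invalid_parameter")
  }
  if (any(s < 0)) {
    abort("`s` must be non-negative.", class = "motifcompare_invalid_parameter")
  }
  invisible(NULL)
}

#' @rdname hill_activation
#' @export
gate <- function(kind, f_s, f_y) {
  if (any(f_s < 0 | f_s > 1) || any(f_y < 0 | f_y > 1)) {
    abort("gate inputs must lie in [0, 1].", class = "motifcompare_invalid_parameter")
  }
  switch(match.arg(kind, c("AND", "OR")),
    AND = f_s * f_y,
    OR = f_s + f_y - f_s * f_y
  )
}
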