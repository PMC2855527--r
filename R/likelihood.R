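#' Gaussian observation log-likelihood
#'
#' The probability of the observed records given a model and parameters:
#' independent, homoscedastic Gaussian errors around the deterministic
#' solution of the model's differential equations,
#' \deqn{\log p(Y \mid \theta, \sigma^2) = \sum_{ki} \log
#'   N(y_{ki};\; \hat y_k(t_i, \theta),\; \sigma^2).}
#' Predictions come from integrating the model under the dataset's design
#' (signal protocol, initial levels, observation times per step). A failed
#' integration yields `-Inf`, signalling an infeasible parameter draw.
#'
#' @param data A `motif_dataset` (must carry a design; see
#'   [simulate_motif_dataset()] / [read_dataset()]).
#' @param model Candidate [motif_model()] or name; its states must include
#'   every observed variable in `data`.
#' @param params Named or ordered kinetic parameter vector.
#' @param sigma2 Observation noise variance (> 0).
#' @param rtol,atol Solver tolerances (defaults match the sampler's).
#' @return Scalar log-likelihood.
#' @examples
#' d <- simulate_motif_dataset("SIM", seed = 1)
#' log_likelihood(d, "SIM", c(1, 1, 1, 1), sigma2 = 0.05^2)
#' @export
log_likelihood <- function(data, model, params, sigma2,
                           rtol = 1e-6, atol = 1e-8) {
  model <- as_motif_model(model)
  p <- align_params(model, params)
  plan <- likelihood_plan(data, model)
  cpp_loglik(model$code, unname(p), sigma2, plan, rtol, atol)
}

# precompute the per-step structures the compiled likelihood consumes
likelihood_plan <- function(data, model) {
  design <- attr(data, "design")
  if (is.null(design)) {
    abort("`data` carries no design metadata; cannot form predictions.",
      class = "motifcompare_contract_violation"
    )
  }
  vars <- unique(data$variable)
  if (!all(vars %in% model$states)) {
    abort(paste0(
      "model ", model$name, " has no state(s) ",
      paste(setdiff(vars, model$states), collapse = ", ")
    ), class = "motifcompare_contract_violation")
  }
  n_states <- length(model$states)
  s2 <- secondary_input(model)
  steps <- split(as_tibble(data), data$step)
  purrr::map(names(steps), function(nm) {
    st <- design$steps[[nm]]
    if (is.null(st)) {
      abort(paste0("design has no step '", nm, "'"),
        class = "motifcompare_contract_violation"
      )
    }
    sub <- steps[[nm]]
    obs_t <- sort(unique(sub$time))
    list(
      sig_t = st$signal$breakpoints,
      sig_lvl = st$signal$levels,
      sig_pre = st$signal$pre_level,
      s2 = s2,
      t0 = st$signal$breakpoints[1],
      y0 = rep(st$init_level, n_states),
      obs_t = obs_t,
      obs_tidx = match(sub$time, obs_t) - 1L,
      obs_state = match(sub$variable, model$states) - 1L,
      obs_val = sub$value
    )
  })
}

# fast closure used by the sampler: takes natural-scale params and sigma2
make_loglik <- function(data, model, rtol = 1e-6, atol = 1e-8) {
  model <- as_motif_model(model)
  plan <- likelihood_plan(data, model)
  code <- model$code
  function(params, sigma2) cpp_loglik(code, params, sigma2, plan, rtol, atol)
}

# model predictions aligned with the dataset rows (used by least squares and
# posterior-predictive plotting)
predict_records <- function(data, model, params, rtol = 1e-6, atol = 1e-8) {
  model <- as_motif_model(model)
  p <- align_params(model, params)
  design <- attr(data, "design")
  steps <- split(as_tibble(data), data$step)
  out <- numeric(nrow(data))
  split_idx <- split(seq_len(nrow(data)), data$step)
  for (nm in names(steps)) {
    st <- design$steps[[nm]]
    sub <- steps[[nm]]
    obs_t <- sort(unique(sub$time))
    m <- cpp_integrate(
      model$code, unname(p), st$signal$breakpoints, st$signal$levels,
      st$signal$pre_level, secondary_input(model), st$signal$breakpoints[1],
      rep(st$init_level, length(model$states)), obs_t, rtol, atol
    )
    if (!isTRUE(attr(m, "ok"))) {
      return(rep(NA_real_, nrow(data)))
    }
    out[split_idx[[nm]]] <-
      m[cbind(match(sub$time, obs_t), match(sub$variable, model$states))]
  }
  out
}
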