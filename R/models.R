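#' Motif model registry
#'
#' The sixteen named dynamical models of the study. Four linear motif
#' architectures driven by a controlled signal S --- single input (SIM),
#' regulatory chain (RC), feed-forward loop (FF) and negative feedback (FB)
#' --- their cooperative Hill-production variants (suffix `.H`), the
#' feed-forward subtypes with explicit promoter logic (coherent type 1 with
#' AND or OR gates, incoherent type 1 with an AND gate), two delay-equation
#' extensions of the OR-gated loop, and the simpler non-feed-forward control
#' circuits of the arabinose, flagella and galactose systems.
#'
#' All models combine production terms with linear first-order degradation.
#' Hill coefficients are fixed at \eqn{h = 2} and are never estimated; the
#' cooperative `.H` variants also fix their thresholds at 0.5, whereas the
#' feed-forward subtypes estimate their three activation thresholds alongside
#' the rate constants. The delay models carry one extra estimated lag
#' \eqn{\tau}. `aic_param_count` is the number of estimated rate, threshold
#' and delay parameters (the observation noise variance is excluded from
#' information-criterion penalties).
#'
#' @param name Model name, e.g. `"SIM"`, `"FF.C1.OR.2"`. Case sensitive.
#' @return `motif_model()` returns a `motif_model` object (a list with
#'   fields `name`, `states`, `params`, `roles`, `observed`, `delayed`,
#'   `aic_param_count`, `default_params`, `code`). `motif_models()` returns a
#'   tibble summarising the registry.
#' @examples
#' motif_model("SIM")
#' motif_models()
#' @export
motif_model <- function(name) {
  reg <- motif_registry()
  if (!name %in% names(reg)) {
    abort(paste0("unknown model '", name, "'; see motif_models()"),
      class = "motifcompare_unknown_model"
    )
  }
  reg[[name]]
}

#' @rdname motif_model
#' @export
motif_models <- function() {
  reg <- motif_registry()
  tibble(
    name = names(reg),
    states = purrr::map_chr(reg, ~ paste(.x$states, collapse = ",")),
    n_params = purrr::map_int(reg, ~ length(.x$params)),
    aic_param_count = purrr::map_int(reg, ~ .x$aic_param_count),
    observed = purrr::map_chr(reg, ~ paste(.x$observed, collapse = ",")),
    delayed = purrr::map_lgl(reg, ~ .x$delayed)
  )
}

new_motif_model <- function(name, code, states, params, roles, observed,
                            delayed, default_params) {
  stopifnot(
    length(params) == length(roles), all(observed %in% states),
    !anyDuplicated(params), length(default_params) == length(params)
  )
  structure(
    list(
      name = name, code = code, states = states, params = params,
      roles = roles, observed = observed, delayed = delayed,
      aic_param_count = length(params),
      default_params = setNames(default_params, params)
    ),
    class = "motif_model"
  )
}

#' @export
print.motif_model <- function(x, ...) {
  cat("<motif_model ", x$name, ">\n", sep = "")
  cat("  states:   ", paste(x$states, collapse = ", "),
    "  (observed: ", paste(x$observed, collapse = ", "), ")\n",
    sep = ""
  )
  cat("  params:   ", paste(x$params, collapse = ", "), "\n", sep = "")
  cat("  delayed:  ", x$delayed, ";  AIC parameter count: ",
    x$aic_param_count, "\n",
    sep = ""
  )
  invisible(x)
}

motif_registry <- function() {
  if (!is.null(.motif_env$registry)) {
    return(.motif_env$registry)
  }
  lin <- c("production", "degradation", "production", "degradation")
  ff_par <- c("beta_y", "alpha_y", "beta_z", "alpha_z",
              "theta_sy", "theta_sz", "theta_yz")
  ff_rol <- c(lin, "threshold", "threshold", "threshold")
  ff_def <- c(1, 1, 1, 1, 0.5, 0.5, 0.5)
  reg <- list(
    SIM = new_motif_model("SIM", 1L, c("y", "z"),
      c("beta_y", "alpha_y", "beta_z", "alpha_z"), lin,
      c("y", "z"), FALSE, c(1, 1, 1, 1)
    ),
    RC = new_motif_model("RC", 2L, c("y", "z"),
      c("beta_y", "alpha_y", "beta_z", "alpha_z"), lin,
      c("y", "z"), FALSE, c(1, 1, 1, 1)
    ),
    FF = new_motif_model("FF", 3L, c("y", "z"),
      c("beta_y", "alpha_y", "beta_zs", "beta_zy", "alpha_z"),
      c("production", "degradation", "production", "production", "degradation"),
      c("y", "z"), FALSE, c(1, 1, 1, 1, 1)
    ),
    FB = new_motif_model("FB", 4L, c("y", "z"),
      c("beta_y", "alpha_y", "beta_z", "alpha_z", "theta_zy"),
      c(lin, "threshold"),
      c("y", "z"), FALSE, c(1, 1, 1, 1, 0.5)
    ),
    SIM.H = new_motif_model("SIM.H", 5L, c("y", "z"),
      c("beta_y", "alpha_y", "beta_z", "alpha_z"), lin,
      c("y", "z"), FALSE, c(1, 1, 1, 1)
    ),
    RC.H = new_motif_model("RC.H", 6L, c("y", "z"),
      c("beta_y", "alpha_y", "beta_z", "alpha_z"), lin,
      c("y", "z"), FALSE, c(1, 1, 1, 1)
    ),
    FF.H = new_motif_model("FF.H", 7L, c("y", "z"),
      c("beta_y", "alpha_y", "beta_zs", "beta_zy", "alpha_z"),
      c("production", "degradation", "production", "production", "degradation"),
      c("y", "z"), FALSE, c(1, 1, 1, 1, 1)
    ),
    FB.H = new_motif_model("FB.H", 8L, c("y", "z"),
      c("beta_y", "alpha_y", "beta_z", "alpha_z", "theta_zy"),
      c(lin, "threshold"),
      c("y", "z"), FALSE, c(1, 1, 1, 1, 0.5)
    ),
    FF.C1.AND = new_motif_model("FF.C1.AND", 9L, c("y", "z"),
      ff_par, ff_rol, "z", FALSE, ff_def
    ),
    CONTROL.ARA = new_motif_model("CONTROL.ARA", 10L, "z",
      c("beta_z", "alpha_z", "theta_s", "theta_l"),
      c("production", "degradation", "threshold", "threshold"),
      "z", FALSE, c(1, 1, 0.5, 0.5)
    ),
    FF.C1.OR.1 = new_motif_model("FF.C1.OR.1", 11L, c("y", "z"),
      ff_par, ff_rol, "z", FALSE, ff_def
    ),
    CONTROL.FLA = new_motif_model("CONTROL.FLA", 12L, "z",
      c("beta_z", "alpha_z"), c("production", "degradation"),
      "z", FALSE, c(1, 1)
    ),
    FF.C1.OR.2 = new_motif_model("FF.C1.OR.2", 13L, c("y", "z"),
      c(ff_par, "tau"), c(ff_rol, "delay"), "z", TRUE, c(ff_def, 0.5)
    ),
    FF.C1.OR.3 = new_motif_model("FF.C1.OR.3", 14L, c("y", "z"),
      c(ff_par, "tau"), c(ff_rol, "delay"), "z", TRUE, c(ff_def, 0.5)
    ),
    FF.I1.AND = new_motif_model("FF.I1.AND", 15L, c("y", "z"),
      ff_par, ff_rol, "z", FALSE, ff_def
    ),
    CONTROL.GAL = new_motif_model("CONTROL.GAL", 16L, "z",
      c("beta_z", "alpha_z", "theta_s", "theta_l"),
      c("production", "degradation", "threshold", "threshold"),
      "z", FALSE, c(1, 1, 0.5, 0.5)
    )
  )
  .motif_env$registry <- reg
  reg
}

.motif_env <- new.env(parent = emptyenv())

as_motif_model <- function(model) {
  if (inherits(model, "motif_model")) model else motif_model(model)
}

# secondary constant input (lactose/IPTG for the ara-style controls, LacI for
# the gal control); irrelevant for the other models
secondary_input <- function(model) {
  if (model$name %in% c("CONTROL.ARA", "CONTROL.GAL")) 1 else 0
}

#' Evaluate a model's rate of change
#'
#' Plain-R evaluation of the right-hand side \eqn{dz/dt = f(z, t, \theta)} of
#' a motif model. This is the readable reference form of the dynamics (the
#' integrator uses an equivalent compiled version). For the delay models a
#' `history` accessor must be supplied.
#'
#' @param model A [motif_model()] or model name.
#' @param state Named or ordered numeric state vector.
#' @param t Time.
#' @param params Named or ordered numeric parameter vector (no noise
#'   variance).
#' @param signal A [signal_profile()].
#' @param history For delay models: `function(t)` returning the state vector
#'   at a past time.
#' @param s2 Secondary constant input for the control models (defaults to the
#'   model's convention).
#' @return Numeric vector of state derivatives.
#' @examples
#' eval_rhs("SIM", c(y = 0, z = 0),
#'   t = 3, params = c(1, 1, 1, 1),
#'   signal = motif_grid_signal()
#' ) # c(1, 1)
#' @export
eval_rhs <- function(model, state, t, params, signal, history = NULL,
                     s2 = NULL) {
  model <- as_motif_model(model)
  p <- setNames(as.numeric(params), model$params)
  rolepos <- model$roles %in% c("production", "degradation", "threshold", "delay")
  if (any(p[rolepos] <= 0)) {
    abort("rate, threshold and delay parameters must be positive.",
      class = "motifcompare_invalid_parameter"
    )
  }
  if (model$delayed && is.null(history)) {
    abort("delay models require a `history` accessor.",
      class = "motifcompare_contract_violation"
    )
  }
  if (is.null(s2)) s2 <- secondary_input(model)
  x <- setNames(as.numeric(state), model$states)
  S <- signal_level(signal, t)
  h <- 2
  fp <- function(s, th) hill_activation(max(s, 0), th, h)
  fn <- function(s, th) hill_repression(max(s, 0), th, h)
  d <- switch(model$name,
    SIM = c(p["beta_y"] * S - p["alpha_y"] * x["y"],
            p["beta_z"] * S - p["alpha_z"] * x["z"]),
    RC = c(p["beta_y"] * S - p["alpha_y"] * x["y"],
           p["beta_z"] * x["y"] - p["alpha_z"] * x["z"]),
    FF = c(p["beta_y"] * S - p["alpha_y"] * x["y"],
           p["beta_zs"] * S + p["beta_zy"] * x["y"] - p["alpha_z"] * x["z"]),
    FB = c(p["beta_y"] * S * fn(x["z"], p["theta_zy"]) - p["alpha_y"] * x["y"],
           p["beta_z"] * x["y"] - p["alpha_z"] * x["z"]),
    SIM.H = c(p["beta_y"] * fp(S, 0.5) - p["alpha_y"] * x["y"],
              p["beta_z"] * fp(S, 0.5) - p["alpha_z"] * x["z"]),
    RC.H = c(p["beta_y"] * fp(S, 0.5) - p["alpha_y"] * x["y"],
             p["beta_z"] * fp(x["y"], 0.5) - p["alpha_z"] * x["z"]),
    FF.H = c(p["beta_y"] * fp(S, 0.5) - p["alpha_y"] * x["y"],
             p["beta_zs"] * fp(S, 0.5) + p["beta_zy"] * fp(x["y"], 0.5) -
               p["alpha_z"] * x["z"]),
    FB.H = c(p["beta_y"] * fp(S, 0.5) * fn(x["z"], p["theta_zy"]) -
               p["alpha_y"] * x["y"],
             p["beta_z"] * fp(x["y"], 0.5) - p["alpha_z"] * x["z"]),
    FF.C1.AND = c(p["beta_y"] * fp(S, p["theta_sy"]) - p["alpha_y"] * x["y"],
                  p["beta_z"] * gate("AND", fp(S, p["theta_sz"]),
                                     fp(x["y"], p["theta_yz"])) -
                    p["alpha_z"] * x["z"]),
    CONTROL.ARA = p["beta_z"] * gate("AND", fp(S, p["theta_s"]),
                                     fp(s2, p["theta_l"])) -
      p["alpha_z"] * x["z"],
    FF.C1.OR.1 = c(p["beta_y"] * fp(S, p["theta_sy"]) - p["alpha_y"] * x["y"],
                   p["beta_z"] * gate("OR", fp(S, p["theta_sz"]),
                                      fp(x["y"], p["theta_yz"])) -
                     p["alpha_z"] * x["z"]),
    CONTROL.FLA = p["beta_z"] * S - p["alpha_z"] * x["z"],
    FF.C1.OR.2 = {
      ylag <- history(t - p["tau"])[1]
      c(p["beta_y"] * fp(S, p["theta_sy"]) - p["alpha_y"] * x["y"],
        p["beta_z"] * gate("OR", fp(S, p["theta_sz"]),
                           fp(ylag, p["theta_yz"])) - p["alpha_z"] * x["z"])
    },
    FF.C1.OR.3 = {
      ylag <- history(t - p["tau"])[1]
      Slag <- signal_level(signal, t - p["tau"])
      c(p["beta_y"] * fp(Slag, p["theta_sy"]) - p["alpha_y"] * x["y"],
        p["beta_z"] * gate("OR", fp(S, p["theta_sz"]),
                           fp(ylag, p["theta_yz"])) - p["alpha_z"] * x["z"])
    },
    FF.I1.AND = c(p["beta_y"] * fp(S, p["theta_sy"]) - p["alpha_y"] * x["y"],
                  p["beta_z"] * fp(S, p["theta_sz"]) *
                    fn(x["y"], p["theta_yz"]) - p["alpha_z"] * x["z"]),
    CONTROL.GAL = p["beta_z"] * fp(S, p["theta_s"]) * fn(s2, p["theta_l"]) -
      p["alpha_z"] * x["z"]
  )
  setNames(as.numeric(d), model$states)
}
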