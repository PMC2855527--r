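#' Experimental designs for the two simulation studies
#'
#' A design bundles the step protocol(s) under which a system is observed:
#' for each experimental step, the controlled-signal profile, the common
#' initial level of all state variables, and the observation times. The
#' four-motif study uses a single time course driven by the staircase signal
#' S = {0, 1, 2, 0}; the feed-forward subtype studies use ON/OFF step
#' experiments (ON: signal 1, states start at 0; OFF: signal 0, states start
#' at 1) with the design sizes of the original bacterial experiments.
#'
#' @param n_points Number of equally spaced observations of the four-motif
#'   time course.
#' @param t_max Length of the four-motif time course (the signal's window).
#' @keywords internal
motif_grid_design <- function(n_points = 30, t_max = 10) {
  list(steps = list(
    main = list(
      name = "main", signal = motif_grid_signal(), init_level = 0,
      times = seq(0, t_max, length.out = n_points)
    )
  ))
}

#' @param system `"ara"`, `"flagella"` or `"gal"`.
#' @param step_duration Duration of each ON/OFF step (dimensionless time).
#' @rdname motif_grid_design
#' @keywords internal
ff_design <- function(system, step_duration = 10) {
  n <- switch(system,
    ara = c(ON = 30, OFF = 30),
    flagella = c(ON = 20, OFF = 17),
    gal = c(ON = 15),
    abort(paste0("unknown system '", system, "'"),
      class = "motifcompare_unknown_system"
    )
  )
  steps <- purrr::imap(as.list(n), function(np, nm) {
    on <- identical(nm, "ON")
    list(
      name = nm,
      signal = signal_profile(0, if (on) 1 else 0, pre_level = if (on) 0 else 1),
      init_level = if (on) 0 else 1,
      times = seq(0, step_duration, length.out = np)
    )
  })
  list(steps = steps)
}

ff_generating_model <- function(system) {
  switch(system,
    ara = "FF.C1.AND", flagella = "FF.C1.OR.1", gal = "FF.I1.AND",
    abort(paste0("unknown system '", system, "'"),
      class = "motifcompare_unknown_system"
    )
  )
}

ff_control_model <- function(system) {
  switch(system,
    ara = "CONTROL.ARA", flagella = "CONTROL.FLA", gal = "CONTROL.GAL"
  )
}

# integrate `model` under one design step; returns wide matrix of observed
# variables at the step's times
simulate_step <- function(model, params, step, observed,
                          rtol = 1e-8, atol = 1e-10) {
  init <- rep(step$init_level, length(model$states))
  tr <- integrate_model(model, params,
    signal = step$signal, times = step$times,
    initial_state = init, rtol = rtol, atol = atol
  )
  w <- trajectory_wide(tr)
  w[, c("time", observed), drop = FALSE]
}

new_motif_dataset <- function(records, design, model, params, noise_sd, seed,
                              system = NA_character_) {
  structure(records,
    class = c("motif_dataset", class(records)),
    design = design, generating_model = model$name,
    true_params = params, noise_sd = noise_sd, seed = seed, system = system
  )
}

#' Simulate a four-motif study dataset
#'
#' Generates one noisy time course from a motif model under the study design:
#' staircase input S = {0, 1, 2, 0} switching at t = {0, 2, 6, 10}, all rate
#' constants 1 (Hill thresholds 0.5 where present), both state variables y
#' and z observed at `n_points` equally spaced times, and additive Gaussian
#' observation noise of standard deviation `noise_sd` on every record.
#'
#' @param model Generating model: one of SIM, RC, FF, FB or their `.H`
#'   cooperative variants (a name or [motif_model()]).
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @param noise_sd Observation noise standard deviation (default 0.05).
#' @param n_points Observations per state variable (default 30).
#' @param params Optional named vector of generating parameters (defaults to
#'   the registry defaults: all rates 1).
#' @return A `motif_dataset` tibble with columns `step`, `time`, `variable`,
#'   `value` and design metadata in attributes.
#' @examples
#' d <- simulate_motif_dataset("SIM", seed = 1)
#' nrow(d) # 60 records: 30 per observed variable
#' @export
simulate_motif_dataset <- function(model, seed = 1L, noise_sd = 0.05,
                                   n_points = 30, params = NULL) {
  model <- as_motif_model(model)
  if (!model$name %in% c("SIM", "RC", "FF", "FB",
                         "SIM.H", "RC.H", "FF.H", "FB.H")) {
    abort("`model` must belong to the four-motif family (optionally .H).",
      class = "motifcompare_unknown_model"
    )
  }
  design <- motif_grid_design(n_points = n_points)
  simulate_dataset(model, design, seed, noise_sd, params)
}

#' Simulate a feed-forward subtype dataset
#'
#' Emulates the artificial counterparts of the three bacterial feed-forward
#' experiments: the arabinose design (generating model FF.C1.AND; 30 points
#' in an ON step and 30 in an OFF step), the flagella design (FF.C1.OR.1;
#' 20 ON + 17 OFF) and the galactose design (FF.I1.AND; 15 points, ON step
#' only). Only the target variable z is observed; the intermediate regulator
#' y is hidden. Generating rates are 1 and thresholds 0.5, with additive
#' Gaussian noise of standard deviation `noise_sd`.
#'
#' @param system `"ara"`, `"flagella"` or `"gal"`.
#' @inheritParams simulate_motif_dataset
#' @param step_duration Length of each ON/OFF step (default 10).
#' @return A `motif_dataset` tibble (see [simulate_motif_dataset()]).
#' @examples
#' nrow(simulate_ff_dataset("gal", seed = 1)) # 15
#' @export
simulate_ff_dataset <- function(system = c("ara", "flagella", "gal"),
                                seed = 1L, noise_sd = 0.05,
                                step_duration = 10, params = NULL) {
  system <- match.arg(system)
  model <- motif_model(ff_generating_model(system))
  design <- ff_design(system, step_duration = step_duration)
  simulate_dataset(model, design, seed, noise_sd, params, system = system)
}

simulate_dataset <- function(model, design, seed, noise_sd, params,
                             system = NA_character_) {
  params <- if (is.null(params)) {
    model$default_params
  } else {
    align_params(model, params)
  }
  observed <- model$observed
  clean <- purrr::map(design$steps, function(step) {
    w <- simulate_step(model, params, step, observed)
    tidyr::pivot_longer(w, -"time", names_to = "variable", values_to = "value") |>
      dplyr::arrange(.data$variable, .data$time) |>
      dplyr::mutate(step = step$name, .before = 1)
  }) |>
    purrr::list_rbind()
  set.seed(seed)
  records <- dplyr::mutate(clean,
    value = .data$value + rnorm(dplyr::n(), mean = 0, sd = noise_sd)
  )
  new_motif_dataset(records, design, model, params, noise_sd, seed, system)
}

#' @export
print.motif_dataset <- function(x, ...) {
  cat(
    "<motif_dataset> generated from", attr(x, "generating_model"),
    "| noise sd", attr(x, "noise_sd"), "| seed", attr(x, "seed"), "\n"
  )
  NextMethod()
}

#' @export
autoplot.motif_dataset <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$time, y = .data$value, colour = .data$variable)
  ) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~step) +
    ggplot2::labs(
      x = "time", y = "observed value",
      title = paste("Data generated from", attr(object, "generating_model"))
    )
}
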