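#' Tidy a chain archive
#'
#' One row per parameter: posterior mean, standard deviation, the 95%
#' credible interval (the 2.5% and 97.5% sample quantiles of the retained
#' draws) and the Gelman-Rubin statistic.
#'
#' @param x A `chain_archive`.
#' @param ... Unused.
#' @return A tibble with columns `param`, `mean`, `sd`, `conf.low`,
#'   `conf.high`, `rhat`.
#' @export
tidy.chain_archive <- function(x, ...) {
  pn <- attr(x, "param_names")
  tab <- as_tibble(x)
  rh <- if (dplyr::n_distinct(tab$chain) >= 2) {
    gelman_rubin(x)$rhat
  } else {
    rep(NA_real_, length(pn))
  }
  purrr::map2(pn, rh, function(p, r) {
    v <- tab[[p]]
    tibble(
      param = p, mean = mean(v), sd = sd(v),
      conf.low = unname(quantile(v, 0.025)),
      conf.high = unname(quantile(v, 0.975)),
      rhat = r
    )
  }) |>
    purrr::list_rbind()
}

#' Chain-archive summary
#'
#' @param x A `chain_archive`.
#' @param ... Unused.
#' @return A one-row tibble: model, chain counts, acceptance, maximum stored
#'   log-likelihood, infeasible-draw count.
#' @export
glance.chain_archive <- function(x, ...) {
  tab <- as_tibble(x)
  tibble(
    model = attr(x, "model"),
    n_chains = dplyr::n_distinct(tab$chain),
    n_draws = nrow(tab),
    acceptance = mean(attr(x, "acceptance")),
    max_loglik = max(tab$log_lik),
    n_infeasible = sum(attr(x, "n_infeasible")),
    max_rhat = if (dplyr::n_distinct(tab$chain) >= 2) {
      max(gelman_rubin(x)$rhat)
    } else {
      NA_real_
    }
  )
}

#' @export
autoplot.chain_archive <- function(object, params = NULL, ...) {
  params <- params %||% attr(object, "param_names")
  long <- as_tibble(object) |>
    dplyr::select(dplyr::all_of(c("chain", "iteration", params))) |>
    tidyr::pivot_longer(dplyr::all_of(params),
      names_to = "param", values_to = "value"
    )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$iteration, y = .data$value,
                 colour = factor(.data$chain))
  ) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~param, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      colour = "chain",
      title = paste("Retained draws,", attr(object, "model"))
    )
}

#' Posterior-predictive trajectory bands
#'
#' Integrates the fitted model at a subsample of posterior draws and plots
#' the pointwise posterior-mean solution with a 95% credible band (2.5% and
#' 97.5% pointwise quantiles), overlaid on the observations.
#'
#' @param archive A `chain_archive`.
#' @param data The fitted dataset.
#' @param n_draws Posterior draws to integrate (subsampled evenly).
#' @param n_grid Time-grid resolution per step.
#' @return A ggplot object.
#' @export
plot_fit_bands <- function(archive, data, n_draws = 100, n_grid = 60) {
  model <- motif_model(attr(archive, "model"))
  design <- attr(data, "design")
  tab <- as_tibble(archive)
  idx <- unique(round(seq(1, nrow(tab), length.out = min(n_draws, nrow(tab)))))
  np <- length(model$params)
  bands <- purrr::map(design$steps, function(st) {
    times <- seq(min(st$times), max(st$times), length.out = n_grid)
    sims <- purrr::map(idx, function(i) {
      p <- as.numeric(tab[i, model$params])
      tr <- integrate_model(model, p,
        signal = st$signal, times = times,
        initial_state = rep(st$init_level, length(model$states)),
        rtol = 1e-6, atol = 1e-8
      )
      dplyr::mutate(as_tibble(tr), draw = i)
    }) |>
      purrr::list_rbind()
    sims |>
      dplyr::group_by(.data$time, .data$variable) |>
      dplyr::summarise(
        mean = mean(.data$value),
        lower = quantile(.data$value, 0.025),
        upper = quantile(.data$value, 0.975),
        .groups = "drop"
      ) |>
      dplyr::mutate(step = st$name)
  }) |>
    purrr::list_rbind() |>
    dplyr::filter(.data$variable %in% unique(data$variable))
  ggplot2::ggplot(bands, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper, fill = .data$variable),
      alpha = 0.25
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean, colour = .data$variable)) +
    ggplot2::geom_point(
      data = as_tibble(data),
      ggplot2::aes(y = .data$value, colour = .data$variable), size = 1
    ) +
    ggplot2::facet_wrap(~step) +
    ggplot2::labs(
      y = "concentration",
      title = paste("Posterior predictive,", attr(archive, "model"))
    )
}
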