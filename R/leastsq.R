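#' Least-squares (maximum-likelihood) fit of a motif model
#'
#' Frequentist counterpart of the MCMC fit: minimises the residual sum of
#' squares \eqn{\mathrm{RSS}(\theta) = \sum_{ki} (y_{ki} - \hat y_{ki})^2}
#' over the kinetic parameters, which is equivalent to maximising the
#' Gaussian likelihood. The noise variance is estimated without bias as
#' \eqn{\hat\sigma^2 = \mathrm{RSS} / (N - p)}. Approximate 95% confidence
#' intervals \eqn{\hat\theta_j \pm 1.96\,\mathrm{SE}_j} come from the
#' curvature of the objective: the parameter covariance is
#' \eqn{\hat\sigma^2 (H/2)^{-1}} with \eqn{H} the Hessian of the RSS at the
#' optimum. A singular Hessian leaves the point estimate intact and reports
#' the intervals as unavailable, with a warning.
#'
#' Optimisation runs in log-parameter space (enforcing positivity) from
#' multiple starts: the registry defaults plus `n_starts - 1` prior draws.
#'
#' @param data A `motif_dataset`.
#' @param model Candidate model (name or [motif_model()]).
#' @param n_starts Number of optimisation starts.
#' @param seed Seed for the random starts.
#' @param priors [prior_set()] the random starts are drawn from.
#' @param rtol,atol Solver tolerances.
#' @return An `ls_fit` list: `estimate` (named), `se`, `conf_low`,
#'   `conf_high`, `sigma2_hat`, `rss`, `n`, `p`, `max_loglik` (at the ML
#'   variance RSS/N), `convergence`.
#' @examples
#' \donttest{
#' d <- simulate_motif_dataset("SIM", seed = 1, noise_sd = 0)
#' fit <- least_squares_fit(d, "SIM")
#' tidy(fit)
#' }
#' @export
least_squares_fit <- function(data, model, n_starts = 10, seed = 1L,
                              priors = prior_set(), rtol = 1e-8, atol = 1e-10) {
  model <- as_motif_model(model)
  y <- data$value
  n <- length(y)
  p <- length(model$params)
  if (n <= p) abort("more records than parameters are required")
  rss_nat <- function(theta) {
    pred <- predict_records(data, model, theta, rtol = rtol, atol = atol)
    if (anyNA(pred)) {
      return(1e12)
    }
    sum((y - pred)^2)
  }
  rss_log <- function(u) rss_nat(exp(u))
  set.seed(as.integer(seed))
  starts <- c(
    list(log(unname(model$default_params))),
    purrr::map(seq_len(max(n_starts - 1, 0)), function(i) {
      rnorm(p, priors$meanlog, priors$sdlog)
    })
  )
  runs <- purrr::map(starts, function(u0) {
    tryCatch(
      optim(u0, rss_log, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL
    )
  }) |> purrr::compact()
  if (length(runs) == 0) abort("all optimisation starts failed")
  best <- runs[[which.min(purrr::map_dbl(runs, "value"))]]
  # polish with a gradient-based pass
  polished <- tryCatch(
    optim(best$par, rss_log, method = "BFGS",
          control = list(maxit = 500, reltol = 1e-14)),
    error = function(e) best
  )
  if (polished$value <= best$value) best <- polished
  theta_hat <- setNames(exp(best$par), model$params)
  rss <- best$value
  sigma2_hat <- rss / (n - p)
  hess <- tryCatch(pracma::hessian(rss_nat, unname(theta_hat)),
    error = function(e) NULL
  )
  se <- rep(NA_real_, p)
  if (!is.null(hess)) {
    cov_theta <- tryCatch(sigma2_hat * solve(hess / 2), error = function(e) NULL)
    if (!is.null(cov_theta) && all(is.finite(diag(cov_theta))) &&
        all(diag(cov_theta) >= 0)) {
      se <- sqrt(diag(cov_theta))
    }
  }
  if (anyNA(se)) {
    warn("Hessian is singular or indefinite; confidence intervals unavailable")
  }
  sigma2_ml <- rss / n
  max_loglik <- -n / 2 * (log(2 * pi * sigma2_ml) + 1)
  structure(
    list(
      model = model$name,
      estimate = theta_hat,
      se = setNames(se, model$params),
      conf_low = theta_hat - 1.96 * se,
      conf_high = theta_hat + 1.96 * se,
      sigma2_hat = sigma2_hat, rss = rss, n = n, p = p,
      max_loglik = max_loglik,
      convergence = best$convergence
    ),
    class = "ls_fit"
  )
}

#' @export
print.ls_fit <- function(x, ...) {
  cat("<ls_fit> model", x$model, "| RSS", format(x$rss, digits = 4),
      "| sigma2_hat", format(x$sigma2_hat, digits = 4), "\n")
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.ls_fit <- function(x, ...) {
  tibble(
    term = names(x$estimate),
    estimate = unname(x$estimate),
    std.error = unname(x$se),
    conf.low = unname(x$conf_low),
    conf.high = unname(x$conf_high)
  )
}

#' @export
glance.ls_fit <- function(x, ...) {
  tibble(
    model = x$model, rss = x$rss, sigma2_hat = x$sigma2_hat,
    max_loglik = x$max_loglik, aic = aic(x$max_loglik, x$p),
    nobs = x$n, n_params = x$p, convergence = x$convergence
  )
}
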