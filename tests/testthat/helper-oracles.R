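# Independent oracles and shared fixtures.

# Closed-form solution of the linear motifs (SIM, RC, FF) under a
# piecewise-constant signal, via the matrix exponential: on each segment
# dx/dt = A x + b(S) with constant S, so
#   x(t0 + dt) = expm(A dt) (x0 + A^-1 b) - A^-1 b.
# Deliberately independent of the package's Runge-Kutta integrator.
linear_motif_closed_form <- function(model_name, params, signal, times,
                                     init = c(0, 0)) {
  p <- params
  mats <- switch(model_name,
    SIM = function(S) {
      list(
        A = matrix(c(-p[["alpha_y"]], 0, 0, -p[["alpha_z"]]), 2, byrow = TRUE),
        b = c(p[["beta_y"]] * S, p[["beta_z"]] * S)
      )
    },
    RC = function(S) {
      list(
        A = matrix(c(-p[["alpha_y"]], 0, p[["beta_z"]], -p[["alpha_z"]]),
                   2, byrow = TRUE),
        b = c(p[["beta_y"]] * S, 0)
      )
    },
    FF = function(S) {
      list(
        A = matrix(c(-p[["alpha_y"]], 0, p[["beta_zy"]], -p[["alpha_z"]]),
                   2, byrow = TRUE),
        b = c(p[["beta_y"]] * S, p[["beta_zs"]] * S)
      )
    },
    stop("no closed form registered for ", model_name)
  )
  bp <- signal$breakpoints
  lv <- signal$levels
  grid <- sort(unique(c(times, bp)))
  grid <- grid[grid >= bp[1]]
  x <- init
  out <- matrix(NA_real_, length(times), 2)
  t_cur <- bp[1]
  record <- function(tt, x) {
    hit <- which(abs(times - tt) < 1e-12)
    if (length(hit)) out[hit, ] <<- rep(x, each = length(hit))
  }
  record(t_cur, x)
  for (tt in grid[grid > bp[1]]) {
    S <- lv[findInterval((t_cur + tt) / 2, bp)]
    ab <- mats(S)
    ainv_b <- solve(ab$A, ab$b)
    ex <- as.matrix(Matrix::expm(ab$A * (tt - t_cur)))
    x <- drop(ex %*% (x + ainv_b)) - ainv_b
    record(tt, x)
    t_cur <- tt
  }
  colnames(out) <- c("y", "z")
  out
}

# conjugate toy: y_i ~ N(mu, s0^2) with known s0, prior mu ~ N(0, tau^2)
conjugate_toy <- function(n = 12, s0 = 1, tau = 1, seed = 42) {
  set.seed(seed)
  y <- rnorm(n, 0.7, s0)
  post_var <- 1 / (n / s0^2 + 1 / tau^2)
  post_mean <- post_var * sum(y) / s0^2
  # log marginal likelihood: y ~ N(0, s0^2 I + tau^2 J)
  Sig <- diag(s0^2, n) + tau^2
  log_evidence <- -0.5 * (n * log(2 * pi) +
    determinant(Sig)$modulus[1] + drop(y %*% solve(Sig, y)))
  list(
    y = y, s0 = s0, tau = tau,
    post_mean = post_mean, post_sd = sqrt(post_var),
    log_evidence = log_evidence,
    log_lik = function(mu) sum(dnorm(y, mu, s0, log = TRUE)),
    log_prior = function(mu) dnorm(mu, 0, tau, log = TRUE)
  )
}

# lazy cache shared across test files (full-protocol fits are expensive)
fit_cache <- local({
  env <- new.env(parent = emptyenv())
  function(key, maker) {
    if (is.null(env[[key]])) env[[key]] <- maker()
    env[[key]]
  }
})

full_sim_fit <- function() {
  fit_cache("sim_full", function() {
    d <- simulate_motif_dataset("SIM", seed = 1)
    list(data = d, fit = run_metropolis(d, "SIM", seed = 1))
  })
}

full_rc_fit <- function() {
  fit_cache("rc_full", function() {
    d <- simulate_motif_dataset("RC", seed = 1)
    list(data = d, fit = run_metropolis(d, "RC", seed = 1))
  })
}

full_ff_fit <- function() {
  fit_cache("ff_full", function() {
    d <- simulate_motif_dataset("FF", seed = 1)
    list(data = d, fit = run_metropolis(d, "FF", seed = 1))
  })
}

# small shared reduced fit on SIM data (module-level tests)
small_sim_fit <- function() {
  fit_cache("sim_small", function() {
    d <- simulate_motif_dataset("SIM", seed = 5)
    cfg <- chain_config(n_chains = 3, n_iterations = 4000, burn_in = 2000,
                        thinning = 5)
    list(data = d, fit = run_metropolis(d, "SIM", config = cfg, seed = 5))
  })
}
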