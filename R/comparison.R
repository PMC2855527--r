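#' Deviance information criterion and effective parameters
#'
#' With deviance \eqn{D(y, \theta) = -2 \log p(y \mid \theta, M)}, the mean
#' posterior deviance \eqn{\bar D} is averaged over the retained draws, the
#' deviance at the posterior mean \eqn{D(\bar\theta)} is evaluated at the
#' vector of posterior parameter means (natural scale by default), and
#' \deqn{p_D = \bar D - D(\bar\theta), \qquad \mathrm{DIC} = \bar D + p_D.}
#' \eqn{p_D} estimates the effective number of parameters actually
#' constrained by the data.
#'
#' By default the deviance is the *concentrated* (profile) deviance in which
#' the noise variance is replaced, draw by draw, by its conditional maximum
#' \eqn{\mathrm{RSS}(\theta)/N}: the deviance is then a function of the
#' kinetic parameters alone and \eqn{p_D} counts effective kinetic
#' parameters, mirroring the convention that information-criterion penalties
#' exclude \eqn{\sigma^2}. Set `deviance = "joint"` for the textbook deviance
#' in which the sampled \eqn{\sigma^2} is part of \eqn{\theta} (a
#' well-identified noise parameter then adds about one unit to \eqn{p_D}).
#' DIC calculations can be unstable; a failed integration at
#' \eqn{\bar\theta} is flagged rather than silently dropped.
#'
#' @param archive A `chain_archive` from [run_metropolis()].
#' @param data The dataset the archive was fitted to.
#' @param model The fitted model (name or [motif_model()]; default: the
#'   archive's).
#' @param deviance `"profile"` (noise variance concentrated out, the
#'   default) or `"joint"`.
#' @param mean_scale Scale on which posterior means are taken: `"natural"`
#'   (default) or `"log"` (back-transformed geometric means).
#' @return A list with `dic`, `pd`, `mean_deviance`, `deviance_at_mean`,
#'   `unstable`.
#' @export
dic_pd <- function(archive, data, model = NULL,
                   deviance = c("profile", "joint"),
                   mean_scale = c("natural", "log")) {
  deviance <- match.arg(deviance)
  mean_scale <- match.arg(mean_scale)
  model <- as_motif_model(model %||% attr(archive, "model"))
  tab <- as_tibble(archive)
  n <- nrow(data)
  m <- archive_matrix(archive, log_scale = (mean_scale == "log"))
  theta_bar <- colMeans(m)
  if (mean_scale == "log") theta_bar <- exp(theta_bar)
  np <- length(model$params)
  solver <- attr(archive, "solver") %||% list(rtol = 1e-6, atol = 1e-8)
  ll_bar <- log_likelihood(
    data, model, theta_bar[seq_len(np)], theta_bar[["sigma2"]],
    rtol = solver$rtol, atol = solver$atol
  )
  unstable <- !is.finite(ll_bar)
  if (deviance == "joint") {
    mean_dev <- mean(-2 * tab$log_lik)
    dev_at_mean <- -2 * ll_bar
  } else {
    # recover the residual sum of squares of each draw from its stored
    # log-likelihood, then concentrate: D = N log(RSS/N) + N (1 + log 2pi)
    rss_s <- tab$sigma2 * (-2 * tab$log_lik - n * log(2 * pi * tab$sigma2))
    rss_s <- pmax(rss_s, .Machine$double.xmin)
    prof <- function(rss) n * log(2 * pi * rss / n) + n
    mean_dev <- mean(prof(rss_s))
    rss_bar <- theta_bar[["sigma2"]] *
      (-2 * ll_bar - n * log(2 * pi * theta_bar[["sigma2"]]))
    dev_at_mean <- prof(max(rss_bar, .Machine$double.xmin))
  }
  if (unstable) {
    warn("integration failed at the posterior mean; DIC flagged unstable")
    dev_at_mean <- NA_real_
    pd <- NA_real_
    dic <- NA_real_
  } else {
    pd <- mean_dev - dev_at_mean
    dic <- mean_dev + pd
  }
  list(
    dic = dic, pd = pd, mean_deviance = mean_dev,
    deviance_at_mean = dev_at_mean, unstable = unstable
  )
}

#' Akaike's information criterion
#'
#' \eqn{\mathrm{AIC} = -2 \log p(Y \mid \theta_{ML}, M) + 2p}, with `p` the
#' number of estimated kinetic parameters (the noise variance is excluded
#' from the penalty). Lower is better; applicable to non-nested models.
#'
#' @param max_loglik Maximum log-likelihood.
#' @param p Penalized parameter count (>= 0).
#' @return Scalar AIC.
#' @examples
#' aic(102.99, 4) # -197.98
#' @export
aic <- function(max_loglik, p) {
  stopifnot(p >= 0)
  -2 * max_loglik + 2 * p
}

#' Likelihood-ratio test for nested models
#'
#' Under the null that the simple model is adequate, twice the log-likelihood
#' gain of the nested complex model is asymptotically chi-squared with
#' degrees of freedom equal to the difference in parameter counts.
#'
#' @param loglik_simple,loglik_complex Maximised log-likelihoods.
#' @param p_simple,p_complex Parameter counts; the models must be nested with
#'   `p_complex > p_simple`.
#' @param tol Tolerance for a slightly negative statistic (sampling-based
#'   maxima); larger violations are an error.
#' @return A list with `statistic`, `df`, `p_value`.
#' @examples
#' lrt(102.99, 4, 103.45, 5) # statistic 0.92, df 1, p 0.34
#' @export
lrt <- function(loglik_simple, p_simple, loglik_complex, p_complex,
                tol = 1e-8) {
  if (p_complex <= p_simple) {
    abort("models must be nested with p_complex > p_simple; the LRT does not apply",
      class = "motifcompare_not_nested"
    )
  }
  stat <- 2 * (loglik_complex - loglik_simple)
  if (stat < -tol) {
    abort("complex model fits worse than the simple one beyond tolerance; fits are inconsistent with nesting")
  }
  stat <- max(stat, 0)
  df <- p_complex - p_simple
  list(
    statistic = stat, df = df,
    p_value = pchisq(stat, df, lower.tail = FALSE)
  )
}

#' Bayes factor with interpretation
#'
#' \eqn{BF = p(Y \mid M_i) / p(Y \mid M_j)} from two log-evidences, with the
#' conventional qualitative categories: above 1 weak, above 3 substantial,
#' above 10 decisive, above 100 overwhelming evidence for model i over model
#' j; at or below 1 the data favour model j.
#'
#' @param log_evidence_i,log_evidence_j Log model evidences.
#' @return A list with `bf` and `category`.
#' @examples
#' bayes_factor(log(58.55), 0)$category # "decisive"
#' @export
bayes_factor <- function(log_evidence_i, log_evidence_j) {
  if (is.na(log_evidence_i) || is.na(log_evidence_j)) {
    abort("log-evidences must be available")
  }
  if (identical(log_evidence_j, -Inf) && is.finite(log_evidence_i)) {
    return(list(bf = Inf, category = "overwhelming"))
  }
  bf <- exp(log_evidence_i - log_evidence_j)
  category <- if (bf > 100) {
    "overwhelming"
  } else if (bf > 10) {
    "decisive"
  } else if (bf > 3) {
    "substantial"
  } else if (bf >= 1) {
    "weak"
  } else {
    "favours other model"
  }
  list(bf = bf, category = category)
}

# nested pairs (simple, complex): zeroing the extra feed-forward branch or
# letting the feedback/delay parameter vanish recovers the simple model
nested_pairs <- function() {
  list(
    c("SIM", "FF"), c("RC", "FF"), c("RC", "FB"),
    c("SIM.H", "FF.H"), c("RC.H", "FF.H"), c("RC.H", "FB.H"),
    c("FF.C1.OR.1", "FF.C1.OR.2"), c("FF.C1.OR.1", "FF.C1.OR.3")
  )
}

#' Rank candidate models fitted to one dataset
#'
#' Assembles the per-model comparison table: Gelfand-Dey log-evidence (with
#' Monte-Carlo standard error), DIC and effective parameters, maximum
#' log-likelihood from the chains, and AIC. The highest-evidence model is
#' flagged; models whose log-evidence is within 1 unit of the best are
#' reported as ties (with the pragmatic fewer-parameters preference noted,
#' not enforced). Nested candidate pairs are annotated with likelihood-ratio
#' tests.
#'
#' @param fits Named list of `chain_archive` objects, all fitted to `data`
#'   (names are model names; `NULL` entries yield a flagged gap row).
#' @param data The common dataset.
#' @param t_dof Degrees of freedom of the evidence estimator's auxiliary t.
#' @return A `comparison_report` tibble with one row per model and attributes
#'   `best`, `ties`, `lrt` (tibble of nested-pair tests) and `data_source`.
#' @export
rank_models <- function(fits, data, t_dof = 4) {
  stopifnot(is.list(fits), !is.null(names(fits)))
  rows <- purrr::imap(fits, function(fit, nm) {
    spec <- motif_model(nm)
    if (is.null(fit)) {
      warn(paste0("no fit for model ", nm, "; reporting a gap row"))
      return(tibble(
        model = nm, log_evidence = NA_real_, log_evidence_se = NA_real_,
        dic = NA_real_, pd = NA_real_, max_loglik = NA_real_,
        aic = NA_real_, n_params = spec$aic_param_count
      ))
    }
    ev <- log_evidence_gd(fit, t_dof = t_dof)
    dc <- dic_pd(fit, data, spec)
    ml <- max_likelihood_from_chains(fit)
    tibble(
      model = nm,
      log_evidence = ev$log_evidence, log_evidence_se = ev$se,
      dic = dc$dic, pd = dc$pd,
      max_loglik = ml$log_lik,
      aic = aic(ml$log_lik, spec$aic_param_count),
      n_params = spec$aic_param_count
    )
  })
  report <- purrr::list_rbind(rows)
  best <- report$model[which.max(report$log_evidence)]
  ties <- report$model[
    !is.na(report$log_evidence) &
      abs(report$log_evidence - max(report$log_evidence, na.rm = TRUE)) < 1
  ]
  lrt_tab <- purrr::map(nested_pairs(), function(pr) {
    if (!all(pr %in% report$model)) {
      return(NULL)
    }
    s <- report[report$model == pr[1], ]
    cx <- report[report$model == pr[2], ]
    if (is.na(s$max_loglik) || is.na(cx$max_loglik)) {
      return(NULL)
    }
    stat <- max(2 * (cx$max_loglik - s$max_loglik), 0)
    df <- cx$n_params - s$n_params
    tibble(
      simple = pr[1], complex = pr[2], statistic = stat, df = df,
      p_value = pchisq(stat, df, lower.tail = FALSE)
    )
  }) |>
    purrr::compact() |>
    purrr::list_rbind()
  structure(report,
    class = c("comparison_report", class(report)),
    best = best, ties = ties, lrt = lrt_tab,
    data_source = attr(data, "generating_model")
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  src <- attr(x, "data_source")
  if (!is.null(src)) cat("<comparison_report> data generated from", src, "\n")
  cat(
    "best model by evidence:", attr(x, "best"),
    if (length(attr(x, "ties")) > 1) {
      paste0("(tied within 1 log unit: ", paste(attr(x, "ties"), collapse = ", "),
             "; pragmatically, prefer the fewer-parameter model)")
    } else {
      ""
    }, "\n"
  )
  NextMethod()
  lt <- attr(x, "lrt")
  if (!is.null(lt) && nrow(lt) > 0) {
    cat("likelihood-ratio tests (nested pairs):\n")
    print(as_tibble(lt))
  }
  invisible(x)
}
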