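#' Read and write time-series datasets
#'
#' Datasets are stored as tidy CSV (columns `step`, `time`, `variable`,
#' `value`) with a JSON sidecar (`<path>.json`) holding the design metadata:
#' per-step signal profiles and initial levels, the generating model, true
#' parameters, noise level and seed. `read_dataset()` restores a full
#' `motif_dataset` when the sidecar is present; without it the records alone
#' are returned (useful for externally supplied series) and a design must be
#' attached before fitting.
#'
#' @param data A `motif_dataset` (or compatible tibble).
#' @param path CSV file path.
#' @return `write_dataset()` invisibly returns `path`; `read_dataset()`
#'   returns a tibble, of class `motif_dataset` when metadata is available.
#' @export
write_dataset <- function(data, path) {
  readr::write_csv(as_tibble(data)[, c("step", "time", "variable", "value")], path)
  design <- attr(data, "design")
  if (!is.null(design)) {
    meta <- list(
      generating_model = attr(data, "generating_model"),
      true_params = as.list(attr(data, "true_params")),
      noise_sd = attr(data, "noise_sd"),
      seed = attr(data, "seed"),
      system = attr(data, "system"),
      steps = purrr::map(design$steps, function(s) {
        list(
          name = s$name,
          breakpoints = s$signal$breakpoints,
          levels = s$signal$levels,
          pre_level = s$signal$pre_level,
          init_level = s$init_level,
          times = s$times
        )
      })
    )
    jsonlite::write_json(meta, paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  records <- readr::read_csv(path, show_col_types = FALSE)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    return(records)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  steps <- purrr::map(seq_len(nrow_or_len(meta$steps)), function(i) {
    s <- step_row(meta$steps, i)
    list(
      name = s$name,
      signal = signal_profile(s$breakpoints, s$levels, s$pre_level),
      init_level = s$init_level,
      times = s$times
    )
  })
  names(steps) <- purrr::map_chr(steps, "name")
  model <- motif_model(meta$generating_model)
  new_motif_dataset(
    records, list(steps = steps), model,
    unlist(meta$true_params), meta$noise_sd, meta$seed,
    system = meta$system %||% NA_character_
  )
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

step_row <- function(steps, i) {
  if (is.data.frame(steps)) as.list(steps[i, ]) else steps[[i]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Persist a chain archive
#'
#' One CSV row per retained draw (chain, iteration, natural-scale parameters,
#' noise variance, log-likelihood, log-prior) plus a JSON sidecar echoing the
#' chain configuration.
#'
#' @param archive A `chain_archive` from [run_metropolis()].
#' @param path CSV file path.
#' @export
write_chain_archive <- function(archive, path) {
  readr::write_csv(as_tibble(archive), path)
  cfg <- attr(archive, "config")
  meta <- list(
    model = attr(archive, "model"),
    param_names = attr(archive, "param_names"),
    config = cfg[setdiff(names(cfg), "class")],
    seed = attr(archive, "seed"),
    acceptance = attr(archive, "acceptance")
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_chain_archive
#' @export
read_chain_archive <- function(path) {
  draws <- readr::read_csv(path, show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(draws,
    class = c("chain_archive", class(draws)),
    model = meta$model, param_names = meta$param_names,
    config = meta$config, seed = meta$seed, acceptance = meta$acceptance
  )
}
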