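# CSV/JSON interchange: trial tables, fit tables, report serialization and
# run-configuration validation. CSV for flat tables (diff-able), JSON for
# nested reports; no binary formats.

.TRIAL_COLS <- c("observer_id", "experiment_id", "condition", "block",
                 "delta_ms", "standard_is_communicative",
                 "communicative_first", "chose_communicative_longer")

#' Write a trial table to CSV
#'
#' @param trials Trial tibble from [simulate_trials()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(.TRIAL_COLS, names(trials))
  if (length(missing)) {
    abort(paste0("Trial table lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "durpsych_validation_error")
  }
  readr::write_csv(trials[, .TRIAL_COLS], path)
  invisible(path)
}

#' Read and validate a trial CSV
#'
#' Enforces the trial schema: all columns present, `delta_ms` restricted to
#' the design levels, binary response. Malformed rows are reported with
#' their row numbers.
#'
#' @param path CSV file with the header written by [write_trials()].
#' @param levels_ms Permitted stimulus levels; defaults to the standard
#'   -600..600 ms design.
#' @return A typed trial tibble.
#' @export
read_trials <- function(path, levels_ms = seq(-600, 600, by = 200)) {
  if (!file.exists(path)) {
    abort(paste0("No such file: ", path), class = "durpsych_io_error")
  }
  tr <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          observer_id = readr::col_character(),
                          experiment_id = readr::col_character(),
                          condition = readr::col_character(),
                          block = readr::col_integer(),
                          delta_ms = readr::col_double(),
                          standard_is_communicative = readr::col_logical(),
                          communicative_first = readr::col_logical(),
                          chose_communicative_longer = readr::col_integer()))
  missing <- setdiff(.TRIAL_COLS, names(tr))
  if (length(missing)) {
    abort(paste0(path, ": missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "durpsych_parse_error")
  }
  if (nrow(tr) == 0) return(tr)
  bad_delta <- which(!(tr$delta_ms %in% levels_ms))
  if (length(bad_delta)) {
    abort(paste0(path, ": `delta_ms` outside design levels at row(s) ",
                 paste(utils::head(bad_delta, 5), collapse = ", "),
                 if (length(bad_delta) > 5) ", ..." else ""),
          class = "durpsych_parse_error")
  }
  bad_resp <- which(!(tr$chose_communicative_longer %in% c(0L, 1L)))
  if (length(bad_resp)) {
    abort(paste0(path, ": non-binary response at row(s) ",
                 paste(utils::head(bad_resp, 5), collapse = ", ")),
          class = "durpsych_parse_error")
  }
  tr
}

#' Write per-observer fit results to CSV
#'
#' @param fits Fit tibble from [fit_observers()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fits <- function(fits, path) {
  readr::write_csv(fits, path)
  invisible(path)
}

#' Read a fit-results CSV
#'
#' @param path File written by [write_fits()].
#' @return Fit tibble.
#' @export
read_fits <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

.jsonable <- function(x) {
  if (inherits(x, "bootstrap_cloud")) {
    list(n_boot = x$n_boot, seed = x$seed, n = x$n,
         pre_mean = x$resampled_means$pre_mean,
         post_mean = x$resampled_means$post_mean)
  } else if (inherits(x, "skipped_contrast")) {
    list(skipped = TRUE, reason = x$reason)
  } else if (inherits(x, c("ttest_result", "anova_result"))) {
    out <- unclass(x)
    out <- out[!vapply(out, is.null, logical(1))]
    eff <- if (!is.null(out$d)) out$d else out$cohen_f
    out$effect_display <- format_effect(eff)
    out
  } else if (is.data.frame(x)) {
    as.data.frame(x)
  } else if (is.list(x)) {
    lapply(x, .jsonable)
  } else x
}

#' Serialize a report or fit table to JSON
#'
#' Keys keep a fixed (insertion) order and floats are written at full
#' precision; effect sizes additionally carry a 2-decimal `effect_display`
#' field. Writing the same object twice yields byte-identical files.
#'
#' @param x An `experiment_report`, a summary, or a fit tibble.
#' @param path Output `.json` file.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  payload <- if (inherits(x, "experiment_report")) {
    list(experiment_id = x$experiment_id, kind = x$kind,
         provenance = x$provenance,
         fits = as.data.frame(x$fits),
         contrasts = .jsonable(x$contrasts),
         bootstrap = if (is.null(x$bootstrap)) NULL
                     else .jsonable(x$bootstrap))
  } else {
    .jsonable(x)
  }
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort(paste0("Failed to write ", path, ": ", conditionMessage(ok)),
          class = "durpsych_io_error")
  }
  invisible(path)
}

#' Read back a JSON results file
#'
#' @param path File written by [write_results()].
#' @return Nested list.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("No such file: ", path), class = "durpsych_io_error")
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

.RUN_CONFIG_KEYS <- c("experiment", "n_observers", "reps_per_level",
                      "method", "n_boot", "seed", "out_dir", "log_level")

#' Validate a run configuration list
#'
#' Checks a (typically JSON-sourced) run configuration against the known
#' schema before any computation: unknown keys are rejected, the experiment
#' template must exist, and numeric fields must be positive.
#'
#' @param config Named list.
#' @return The validated config, with defaults filled in.
#' @export
validate_run_config <- function(config) {
  unknown <- setdiff(names(config), .RUN_CONFIG_KEYS)
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "durpsych_config_error")
  }
  if (is.null(config$experiment)) {
    abort("Config must name an `experiment` template.",
          class = "durpsych_config_error")
  }
  if (!config$experiment %in% paste0("exp", 1:6)) {
    abort(paste0("Unknown experiment template: ", config$experiment),
          class = "durpsych_config_error")
  }
  config$method <- config$method %||% "mle"
  config$n_boot <- config$n_boot %||% 1000
  config$seed <- config$seed %||% 1
  for (k in c("n_observers", "reps_per_level", "n_boot", "seed")) {
    if (!is.null(config[[k]]) && (!is.numeric(config[[k]]) ||
                                  config[[k]] < 1)) {
      abort(paste0("Config key `", k, "` must be a positive number."),
            class = "durpsych_config_error")
    }
  }
  config
}
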