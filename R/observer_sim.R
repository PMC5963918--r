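# Synthetic observer populations and trial-level choice simulation for
# two-interval duration comparison with the method of constant stimuli.

#' Define a constant-stimuli experiment design
#'
#' The default design presents signed duration differences (communicative
#' minus noncommunicative sequence) from -600 ms to +600 ms in 200 ms steps,
#' 20 repetitions per level per condition: 140 trials per condition, i.e.
#' 4 blocks of 35 trials.
#'
#' @param levels_ms Ordered signed duration differences in ms; must be
#'   symmetric about 0.
#' @param reps_per_level Trials per level per condition.
#' @param conditions Character vector of condition labels.
#' @param experiment_id Label, e.g. `"exp1"`.
#' @param trials_per_block Block size used to assign block numbers.
#' @return An object of class `experiment_design`.
#' @export
#' @examples
#' experiment_design()
experiment_design <- function(levels_ms = seq(-600, 600, by = 200),
                              reps_per_level = 20,
                              conditions = c("upright", "inverted"),
                              experiment_id = "exp1",
                              trials_per_block = 35) {
  levels_ms <- sort(as.numeric(levels_ms))
  if (length(levels_ms) < 3 || anyDuplicated(levels_ms)) {
    abort("`levels_ms` must contain at least 3 distinct values.",
          class = "durpsych_config_error")
  }
  if (!isTRUE(all.equal(levels_ms, -rev(levels_ms)))) {
    abort("`levels_ms` must be symmetric about 0.",
          class = "durpsych_config_error")
  }
  if (reps_per_level < 1) {
    abort("`reps_per_level` must be >= 1.", class = "durpsych_config_error")
  }
  structure(
    list(levels_ms = levels_ms,
         reps_per_level = as.integer(reps_per_level),
         conditions = as.character(conditions),
         experiment_id = experiment_id,
         trials_per_block = as.integer(trials_per_block)),
    class = "experiment_design")
}

#' Specify a synthetic observer population
#'
#' Observers carry an integer trait score (AQ, drawn from a rounded truncated
#' normal), a latent PSE per condition, and a shared psychometric slope
#' parameter `omega`. The latent PSE for condition `c` is
#' `pse_intercept_ms[c] + pse_slope_ms_per_aq * aq + b_i + e_ic`, with
#' `b_i ~ N(0, pse_shared_sd_ms)` an observer-level effect common to all
#' conditions and `e_ic ~ N(0, pse_resid_sd_ms)` condition-specific noise.
#'
#' @param n_observers Number of observers (>= 2).
#' @param pse_intercept_ms Scalar or named vector (condition -> intercept, ms).
#' @param aq_mean,aq_sd Parent parameters of the trait distribution.
#' @param aq_range Inclusive truncation bounds for the trait score.
#' @param pse_slope_ms_per_aq Linear trait-to-PSE link (ms per AQ point).
#' @param pse_shared_sd_ms SD of the observer-level PSE effect shared across
#'   conditions (controls the within-observer, between-condition correlation).
#' @param pse_resid_sd_ms Condition-specific residual SD (ms).
#' @param omega_mean_ms,omega_sd_ms Slope-parameter distribution (ms).
#' @param omega_range_ms Truncation bounds for omega; must stay positive.
#' @param lapse Stimulus-independent error rate in `[0, 0.1]`.
#' @param drug One of `"none"`, `"oxytocin"`, `"atosiban"`, `"saline"`.
#' @param drug_shift_mean_ms,drug_shift_sd_ms Additive post-treatment change
#'   of the latent PSE (ms).
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_observers,
                            pse_intercept_ms,
                            aq_mean = 19, aq_sd = 6, aq_range = c(10, 36),
                            pse_slope_ms_per_aq = 0,
                            pse_shared_sd_ms = 0,
                            pse_resid_sd_ms = 0,
                            omega_mean_ms = 150, omega_sd_ms = 40,
                            omega_range_ms = c(50, 400),
                            lapse = 0,
                            drug = c("none", "oxytocin", "atosiban", "saline"),
                            drug_shift_mean_ms = 0,
                            drug_shift_sd_ms = 0) {
  drug <- match.arg(drug)
  if (!is.numeric(n_observers) || n_observers < 2) {
    abort("`n_observers` must be >= 2.", class = "durpsych_config_error")
  }
  if (aq_range[1] > aq_range[2] || omega_range_ms[1] > omega_range_ms[2]) {
    abort("Truncation bounds must be ordered.",
          class = "durpsych_config_error")
  }
  if (omega_range_ms[1] <= 0) {
    abort("`omega_range_ms` must be strictly positive.",
          class = "durpsych_config_error")
  }
  if (min(aq_sd, pse_resid_sd_ms, pse_shared_sd_ms, omega_sd_ms,
          drug_shift_sd_ms) < 0) {
    abort("Standard deviations must be non-negative.",
          class = "durpsych_config_error")
  }
  if (lapse < 0 || lapse > 0.1) {
    abort("`lapse` must lie in [0, 0.1].", class = "durpsych_config_error")
  }
  if (is.null(names(pse_intercept_ms)) && length(pse_intercept_ms) > 1) {
    abort("A multi-condition `pse_intercept_ms` must be named.",
          class = "durpsych_config_error")
  }
  structure(
    list(n_observers = as.integer(n_observers),
         pse_intercept_ms = pse_intercept_ms,
         aq_mean = aq_mean, aq_sd = aq_sd, aq_range = aq_range,
         pse_slope_ms_per_aq = pse_slope_ms_per_aq,
         pse_shared_sd_ms = pse_shared_sd_ms,
         pse_resid_sd_ms = pse_resid_sd_ms,
         omega_mean_ms = omega_mean_ms, omega_sd_ms = omega_sd_ms,
         omega_range_ms = omega_range_ms,
         lapse = lapse,
         drug = drug,
         drug_shift_mean_ms = drug_shift_mean_ms,
         drug_shift_sd_ms = drug_shift_sd_ms),
    class = "population_spec")
}

#' Calibrate the trait-to-PSE link to a target correlation
#'
#' Moment matching: given a target Pearson correlation between the trait
#' score and the latent PSE and a target total between-observer PSE SD,
#' returns the regression slope and residual SD that achieve them under the
#' truncated-normal trait distribution of `spec`.
#'
#' @param target_r Target correlation (e.g. -0.40).
#' @param pse_sd_ms Target total between-observer SD of the latent PSE.
#' @param spec A [population_spec()] providing the trait distribution.
#' @return List with `slope_ms_per_aq` and `resid_sd_ms`.
#' @export
calibrate_aq_pse <- function(target_r, pse_sd_ms, spec) {
  stopifnot(abs(target_r) < 1, pse_sd_ms > 0)
  mom <- truncnorm_moments(spec$aq_mean, spec$aq_sd,
                           spec$aq_range[1], spec$aq_range[2])
  # integer rounding of the trait adds ~1/12 to its variance
  sd_aq <- sqrt(mom$sd^2 + 1 / 12)
  slope <- target_r * pse_sd_ms / sd_aq
  resid <- sqrt(pse_sd_ms^2 * (1 - target_r^2))
  list(slope_ms_per_aq = slope, resid_sd_ms = resid)
}

#' Sample a synthetic observer population
#'
#' @param spec A [population_spec()].
#' @param conditions Conditions for which latent PSEs are generated; defaults
#'   to the conditions named in `spec$pse_intercept_ms` (or `"upright"`).
#' @param seed Integer seed; output is deterministic given `(spec, seed)`.
#' @param id_prefix Prefix for observer identifiers.
#' @return A tibble of observer profiles with columns `observer_id`, `aq`,
#'   `omega_ms`, `lapse` and a list-column `pse_ms` holding a named vector of
#'   latent PSEs (ms) per condition.
#' @export
#' @examples
#' spec <- population_spec(5, pse_intercept_ms = c(upright = 69.3),
#'                         pse_resid_sd_ms = 45)
#' sample_population(spec, seed = 1)
sample_population <- function(spec, seed, conditions = NULL,
                              id_prefix = "obs") {
  stopifnot(inherits(spec, "population_spec"))
  conditions <- conditions %||%
    (names(spec$pse_intercept_ms) %||% "upright")
  intercepts <- spec$pse_intercept_ms
  if (is.null(names(intercepts))) {
    intercepts <- setNames(rep(intercepts, length(conditions)), conditions)
  }
  missing_cond <- setdiff(conditions, names(intercepts))
  if (length(missing_cond)) {
    abort(paste0("No PSE intercept for condition(s): ",
                 paste(missing_cond, collapse = ", ")),
          class = "durpsych_config_error")
  }
  n <- spec$n_observers
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(substream_seed(seed, "population"))

  aq <- as.integer(round(rnorm_trunc(n, spec$aq_mean, spec$aq_sd,
                                     spec$aq_range[1], spec$aq_range[2])))
  aq <- pmin(pmax(aq, as.integer(spec$aq_range[1])),
             as.integer(spec$aq_range[2]))
  omega <- rnorm_trunc(n, spec$omega_mean_ms, spec$omega_sd_ms,
                       spec$omega_range_ms[1], spec$omega_range_ms[2])
  b <- rnorm(n, 0, spec$pse_shared_sd_ms)
  pse <- lapply(seq_len(n), function(i) {
    e <- rnorm(length(conditions), 0, spec$pse_resid_sd_ms)
    setNames(intercepts[conditions] + spec$pse_slope_ms_per_aq * aq[i] +
               b[i] + e, conditions)
  })
  tibble::tibble(
    observer_id = sprintf("%s%03d", id_prefix, seq_len(n)),
    aq = aq,
    omega_ms = omega,
    lapse = spec$lapse,
    pse_ms = pse)
}

# set.seed() inside functions must not disturb the caller's RNG state
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate trial-level two-interval choices for one condition
#'
#' Each trial presents a communicative and a noncommunicative motion sequence
#' whose signed duration difference `delta_ms` is one of the design levels.
#' The probability of judging the communicative sequence longer is
#' `lapse/2 + (1 - lapse) * F(delta; x0 = pse, omega)`, with `F` the
#' increasing Boltzmann curve ([boltzmann()]). Presentation order and
#' standard-assignment flags are drawn uniformly and recorded but do not
#' enter the choice model.
#'
#' @param profiles Observer profile tibble from [sample_population()]
#'   (one or more rows).
#' @param design An [experiment_design()].
#' @param condition Condition label; must be present in every profile's
#'   `pse_ms`.
#' @param seed Integer seed.
#' @return A tibble of trial records with columns `observer_id`,
#'   `experiment_id`, `condition`, `block`, `delta_ms`,
#'   `standard_is_communicative`, `communicative_first`,
#'   `chose_communicative_longer`.
#' @export
simulate_trials <- function(profiles, design, condition, seed) {
  stopifnot(inherits(design, "experiment_design"))
  has_cond <- vapply(profiles$pse_ms, function(p) condition %in% names(p),
                     logical(1))
  if (!all(has_cond)) {
    abort(paste0("Condition '", condition,
                 "' missing from profile(s): ",
                 paste(profiles$observer_id[!has_cond], collapse = ", ")),
          class = "durpsych_key_error")
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(substream_seed(seed, paste0("trials:", condition)))

  n_lev <- length(design$levels_ms)
  reps <- design$reps_per_level
  per_obs <- n_lev * reps
  n_obs <- nrow(profiles)

  delta <- rep(rep(design$levels_ms, each = reps), times = n_obs)
  pse <- rep(vapply(profiles$pse_ms, function(p) p[[condition]], numeric(1)),
             each = per_obs)
  omega <- rep(profiles$omega_ms, each = per_obs)
  lapse <- rep(profiles$lapse, each = per_obs)
  p <- lapse / 2 + (1 - lapse) * plogis((delta - pse) / omega)
  resp <- rbinom(length(p), 1L, p)
  # levels are spread evenly over blocks: reps per level split across blocks
  n_blocks <- max(1L, (per_obs %/% design$trials_per_block))
  block <- rep(rep(seq_len(n_blocks), length.out = reps), times = n_lev * n_obs)
  tibble::tibble(
    observer_id = rep(profiles$observer_id, each = per_obs),
    experiment_id = design$experiment_id,
    condition = condition,
    block = as.integer(block),
    delta_ms = delta,
    standard_is_communicative = runif(length(p)) < 0.5,
    communicative_first = runif(length(p)) < 0.5,
    chose_communicative_longer = as.integer(resp))
}

#' Apply a drug treatment to an observer population
#'
#' Returns post-treatment profiles whose latent PSE in every condition is
#' shifted by an observer-specific draw from
#' `N(drug_shift_mean_ms, drug_shift_sd_ms)`. The slope parameter omega is
#' unchanged: the treatment is modeled as a pure bias shift, leaving temporal
#' sensitivity (the difference limen) untouched. `drug = "saline"` or
#' `"none"` uses a zero mean shift unless the spec says otherwise.
#'
#' @param profiles Profile tibble from [sample_population()].
#' @param spec The [population_spec()] carrying the drug-shift distribution.
#' @param seed Integer seed.
#' @return A profile tibble of the same shape with shifted `pse_ms`.
#' @export
apply_drug_effect <- function(profiles, spec, seed) {
  stopifnot(inherits(spec, "population_spec"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(substream_seed(seed, paste0("drug:", spec$drug)))
  shift_mean <- if (spec$drug %in% c("saline", "none")) {
    spec$drug_shift_mean_ms * 0
  } else {
    spec$drug_shift_mean_ms
  }
  shift <- rnorm(nrow(profiles), shift_mean, spec$drug_shift_sd_ms)
  out <- profiles
  out$pse_ms <- lapply(seq_len(nrow(profiles)),
                       function(i) profiles$pse_ms[[i]] + shift[i])
  out
}

#' Standard error of the fitted PSE under a constant-stimuli design
#'
#' Asymptotic (Fisher-information) standard error of the maximum-likelihood
#' PSE estimate for a Boltzmann observer run on a given design. Used by the
#' experiment templates to back out latent between-observer SDs from printed
#' group statistics, which describe *fitted* PSEs and therefore include this
#' estimation noise on top of true between-observer variability.
#'
#' @param design An [experiment_design()].
#' @param omega_ms Generating slope parameter (ms).
#' @param pse_ms Generating PSE (ms); the information is evaluated there.
#' @return Standard error in ms.
#' @export
pse_fit_se <- function(design, omega_ms = 150, pse_ms = 0) {
  p <- plogis((design$levels_ms - pse_ms) / omega_ms)
  info <- design$reps_per_level * sum(p * (1 - p)) / omega_ms^2
  1 / sqrt(info)
}
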