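# End-to-end synthetic replication of the six duration-judgment experiments:
# simulate a population, fit every observer x condition cell, run the
# experiment's statistical contrasts, and collect everything in a report.
#
# Template calibration. Group means and t statistics printed for each
# experiment pin down the observed between-observer SD of fitted PSEs
# (sd = mean * sqrt(n) / t). Fitted PSEs carry estimation noise on top of
# true between-observer variability, so the generating (latent) SD is
# back-solved by subtracting the asymptotic estimation variance of the
# fitting stage (see pse_fit_se()), floored at 10 ms. Where a printed
# statistic constrains only a difference (e.g. upright - inverted), the
# latent SD of the difference fixes the condition-specific residual and the
# remainder is assigned to an observer-level effect shared across
# conditions.

.MIN_LATENT_SD <- 10

.latent_sd <- function(obs_sd, se_fit, n_se = 1) {
  sqrt(max(obs_sd^2 - n_se * se_fit^2, .MIN_LATENT_SD^2))
}

# printed group statistics used to calibrate the generating populations
.TEMPLATE_STATS <- list(
  exp1 = list(n = 24, mean_upright = 69.3, t_upright = 5.60,
              t_paired = 5.82, mean_inverted = 0),
  exp4 = list(n = 90, mean = 38.5, t = 6.07, r_aq = -0.40),
  exp5 = list(n_per_arm = 40, aq = c(mean = 24.9, sd = 4.3, lo = 20, hi = 36),
              oxytocin = list(base_mean = 13.3, base_t = 1.34,
                              shift = 36.9, shift_t = 3.68),
              atosiban = list(base_mean = 9.7, base_t = 1.14,
                              shift = -19.1, shift_t = 2.24)),
  exp6 = list(n_per_arm = 40, aq = c(mean = 15.5, sd = 2.7, lo = 10, hi = 19),
              atosiban = list(base_mean = 48.6, base_t = 4.32,
                              shift = -31.1, shift_t = 3.90),
              saline = list(base_mean = 54.5, base_t = 5.94,
                            shift = 0, shift_t = NA,
                            shift_sd_obs = 7.7 * sqrt(40) / 1.13)))

#' Build a replication template for one of the six experiments
#'
#' Templates encode the published sample sizes (24, 24, 24, 90, 40+40,
#' 40+40) and generating group means, with between-observer SDs back-solved
#' from the printed t statistics (corrected for psychometric-fit estimation
#' noise). Experiments 2 and 3 share Experiment 1's variance structure with
#' null generating means in both orientations; Experiment 4 links the PSE to
#' the AQ trait score with a target correlation of -0.40; Experiments 5 and
#' 6 are pre/post two-arm drug designs (oxytocin vs atosiban in high-AQ
#' observers; atosiban vs saline in low-AQ observers).
#'
#' @param id One of `"exp1"`..`"exp6"`.
#' @param n_observers Optional override of observers per arm.
#' @param reps_per_level Optional override of trials per level per condition.
#' @return A `run_config` list understood by [run_experiment()].
#' @export
#' @examples
#' experiment_template("exp1")$arms$main$spec$pse_intercept_ms
experiment_template <- function(id = c("exp1", "exp2", "exp3", "exp4",
                                       "exp5", "exp6"),
                                n_observers = NULL, reps_per_level = NULL) {
  id <- match.arg(id)
  reps <- reps_per_level %||% 20
  switch(
    id,
    exp1 = .orientation_template("exp1", n_observers,
                                 reps, upright_mean = 69.3),
    exp2 = .orientation_template("exp2", n_observers, reps, upright_mean = 0),
    exp3 = .orientation_template("exp3", n_observers, reps, upright_mean = 0),
    exp4 = .trait_template(n_observers, reps),
    exp5 = .drug_template("exp5", c("oxytocin", "atosiban"),
                          n_observers, reps),
    exp6 = .drug_template("exp6", c("atosiban", "saline"), n_observers, reps))
}

.orientation_template <- function(id, n_observers, reps, upright_mean) {
  st <- .TEMPLATE_STATS$exp1
  n <- n_observers %||% st$n
  design <- experiment_design(reps_per_level = reps,
                              conditions = c("upright", "inverted"),
                              experiment_id = id)
  se <- pse_fit_se(design, omega_ms = 150)
  sd_obs <- st$mean_upright * sqrt(st$n) / st$t_upright
  sd_diff_obs <- st$mean_upright * sqrt(st$n) / st$t_paired
  total <- .latent_sd(sd_obs, se, 1)
  resid <- .latent_sd(sd_diff_obs, se, 2) / sqrt(2)
  shared <- sqrt(max(total^2 - resid^2, .MIN_LATENT_SD^2))
  spec <- population_spec(
    n_observers = n,
    pse_intercept_ms = c(upright = upright_mean, inverted = 0),
    pse_shared_sd_ms = shared, pse_resid_sd_ms = resid)
  structure(list(experiment_id = id, kind = "orientation", design = design,
                 arms = list(main = list(spec = spec))),
            class = "run_config")
}

.trait_template <- function(n_observers, reps) {
  st <- .TEMPLATE_STATS$exp4
  n <- n_observers %||% st$n
  design <- experiment_design(reps_per_level = reps, conditions = "upright",
                              experiment_id = "exp4")
  se <- pse_fit_se(design, omega_ms = 150)
  sd_obs <- st$mean * sqrt(st$n) / st$t
  total <- .latent_sd(sd_obs, se, 1)
  base <- population_spec(n, pse_intercept_ms = c(upright = st$mean))
  mom <- truncnorm_moments(base$aq_mean, base$aq_sd,
                           base$aq_range[1], base$aq_range[2])
  sd_aq <- sqrt(mom$sd^2 + 1 / 12)
  # printed correlation is between the trait and *fitted* PSEs; preserve the
  # covariance so the fitted-scale correlation reproduces the target
  slope <- st$r_aq * sd_obs / sd_aq
  resid <- sqrt(max(total^2 - slope^2 * sd_aq^2, .MIN_LATENT_SD^2))
  spec <- population_spec(
    n_observers = n,
    pse_intercept_ms = c(upright = st$mean - slope * mom$mean),
    pse_slope_ms_per_aq = slope, pse_resid_sd_ms = resid)
  structure(list(experiment_id = "exp4", kind = "trait", design = design,
                 arms = list(main = list(spec = spec)),
                 target_r = st$r_aq),
            class = "run_config")
}

.drug_template <- function(id, drugs, n_observers, reps) {
  st <- .TEMPLATE_STATS[[id]]
  n <- n_observers %||% st$n_per_arm
  design <- experiment_design(reps_per_level = reps,
                              conditions = c("pre", "post"),
                              experiment_id = id)
  se <- pse_fit_se(design, omega_ms = 150)
  arms <- lapply(drugs, function(drug) {
    a <- st[[drug]]
    base_sd_obs <- if (a$base_t > 0) abs(a$base_mean) * sqrt(st$n_per_arm) / a$base_t else 60
    shift_sd_obs <- if (!is.null(a$shift_sd_obs)) a$shift_sd_obs
                    else abs(a$shift) * sqrt(st$n_per_arm) / a$shift_t
    spec <- population_spec(
      n_observers = n,
      pse_intercept_ms = c(pre = a$base_mean),
      aq_mean = st$aq[["mean"]], aq_sd = st$aq[["sd"]],
      aq_range = c(st$aq[["lo"]], st$aq[["hi"]]),
      pse_resid_sd_ms = .latent_sd(base_sd_obs, se, 1),
      drug = drug,
      drug_shift_mean_ms = a$shift,
      drug_shift_sd_ms = .latent_sd(shift_sd_obs, se, 2))
    list(spec = spec)
  })
  names(arms) <- drugs
  structure(list(experiment_id = id, kind = "drug", design = design,
                 arms = arms),
            class = "run_config")
}

#' Generic two-condition template
#'
#' For designs comparing two stimulus classes without the orientation
#' manipulation (e.g. event-causality displays): a single arm with two
#' conditions and configurable generating means.
#'
#' @param means_ms Named length-2 numeric: condition -> generating mean PSE.
#' @param n_observers Observers.
#' @param reps_per_level Trials per level per condition.
#' @param experiment_id Label.
#' @return A `run_config`.
#' @export
two_condition_template <- function(means_ms, n_observers = 24,
                                   reps_per_level = 20,
                                   experiment_id = "custom") {
  stopifnot(length(means_ms) == 2, !is.null(names(means_ms)))
  design <- experiment_design(reps_per_level = reps_per_level,
                              conditions = names(means_ms),
                              experiment_id = experiment_id)
  st <- .TEMPLATE_STATS$exp1
  se <- pse_fit_se(design, omega_ms = 150)
  total <- .latent_sd(st$mean_upright * sqrt(st$n) / st$t_upright, se, 1)
  resid <- .latent_sd(st$mean_upright * sqrt(st$n) / st$t_paired, se, 2) /
    sqrt(2)
  spec <- population_spec(
    n_observers = n_observers, pse_intercept_ms = means_ms,
    pse_shared_sd_ms = sqrt(max(total^2 - resid^2, .MIN_LATENT_SD^2)),
    pse_resid_sd_ms = resid)
  structure(list(experiment_id = experiment_id, kind = "orientation",
                 design = design, arms = list(main = list(spec = spec))),
            class = "run_config")
}

.simulate_arm <- function(arm_name, arm, design, kind, seed) {
  arm_seed <- substream_seed(seed, paste0("arm:", arm_name))
  profiles <- sample_population(arm$spec, seed = arm_seed,
                                id_prefix = paste0(design$experiment_id, "_",
                                                   arm_name, "_"))
  if (kind == "drug") {
    post_profiles <- apply_drug_effect(profiles, arm$spec, seed = arm_seed)
    post_profiles$pse_ms <- lapply(post_profiles$pse_ms,
                                   function(p) setNames(p, "post"))
    trials <- dplyr::bind_rows(
      simulate_trials(profiles, design, "pre", seed = arm_seed),
      simulate_trials(post_profiles, design, "post", seed = arm_seed))
  } else {
    trials <- dplyr::bind_rows(lapply(
      design$conditions,
      function(cond) simulate_trials(profiles, design, cond,
                                     seed = arm_seed)))
  }
  list(profiles = profiles, trials = trials)
}

#' Run one synthetic experiment end to end
#'
#' Simulates the template's population(s), simulates all trials, fits every
#' observer-by-condition psychometric function, and computes the
#' experiment's statistical contrasts. Non-converged fits are excluded from
#' group statistics and the exclusion count is reported.
#'
#' @param config A `run_config` from [experiment_template()] /
#'   [two_condition_template()], or a template id string.
#' @param seed Master integer seed; the full report is reproducible from
#'   `(config, seed)`.
#' @param method Fitting method, `"mle"` or `"lsq"`.
#' @param n_boot Bootstrap resamples for drug experiments.
#' @return An `experiment_report` list: `experiment_id`, `kind`, `fits`
#'   (tidy tibble with `arm`, `aq`, fitted parameters), `contrasts` (named
#'   list of test results), `bootstrap` (per-arm clouds for drug designs),
#'   `provenance`.
#' @export
#' @examples
#' \donttest{
#' rep1 <- run_experiment("exp1", seed = 1)
#' rep1$contrasts$pse_upright_vs0
#' }
run_experiment <- function(config, seed, method = "mle", n_boot = 1000) {
  if (is.character(config)) config <- experiment_template(config)
  stopifnot(inherits(config, "run_config"))
  design <- config$design

  sims <- lapply(names(config$arms), function(a)
    .simulate_arm(a, config$arms[[a]], design, config$kind, seed))
  names(sims) <- names(config$arms)

  fits <- dplyr::bind_rows(lapply(names(sims), function(a) {
    f <- fit_observers(sims[[a]]$trials, method = method,
                       levels_ms = design$levels_ms)
    prof <- sims[[a]]$profiles
    f$arm <- a
    f$aq <- prof$aq[match(f$observer_id, prof$observer_id)]
    f
  }))

  n_excluded <- sum(!fits$converged)
  ok <- fits[fits$converged, , drop = FALSE]
  low_power <- any(vapply(config$arms,
                          function(a) a$spec$n_observers < 10, logical(1))) ||
    design$reps_per_level < 5
  if (low_power) {
    warn("Low-power configuration (few observers or trials); estimates will be noisy.",
         class = "durpsych_low_power")
  }

  contrasts <- switch(config$kind,
    orientation = .orientation_contrasts(ok, design),
    trait = .trait_contrasts(ok, config),
    drug = .drug_contrasts(ok))
  bootstrap <- NULL
  if (config$kind == "drug") {
    bootstrap <- lapply(split(ok, ok$arm), function(f) {
      w <- .paired_wide(f)
      tryCatch(
        bootstrap_bivariate_mean(w$pre, w$post, n_boot = n_boot, seed = seed),
        error = function(e) NULL)
    })
  }

  structure(
    list(experiment_id = config$experiment_id, kind = config$kind,
         fits = fits, contrasts = contrasts, bootstrap = bootstrap,
         provenance = list(seed = seed, method = method,
                           config_hash = rlang::hash(config),
                           package_version = as.character(
                             utils::packageVersion("durpsych")),
                           n_fits = nrow(fits), n_excluded = n_excluded,
                           low_power = low_power),
         config = config),
    class = "experiment_report")
}

# wide (one row per observer) PSE/DL tables for paired contrasts
.paired_wide <- function(fits, cond = c("pre", "post"), var = "pse_ms") {
  a <- fits[fits$condition == cond[1], ]
  b <- fits[fits$condition == cond[2], ]
  common <- intersect(a$observer_id, b$observer_id)
  list(pre = a[[var]][match(common, a$observer_id)],
       post = b[[var]][match(common, b$observer_id)],
       observer_id = common)
}

# a contrast that cannot be computed (e.g. too few converged fits) is
# reported as skipped, never a crash
.try_contrast <- function(expr) {
  tryCatch(expr, error = function(e) {
    structure(list(reason = conditionMessage(e)),
              class = "skipped_contrast")
  })
}

.orientation_contrasts <- function(fits, design) {
  cond <- design$conditions
  up <- fits[fits$condition == cond[1], ]
  inv <- fits[fits$condition == cond[2], ]
  w_pse <- .paired_wide(fits, cond = c(cond[2], cond[1]))
  w_dl <- .paired_wide(fits, cond = c(cond[2], cond[1]), var = "dl_ms")
  out <- list(.try_contrast(one_sample_t(up$pse_ms)),
              .try_contrast(one_sample_t(inv$pse_ms)),
              .try_contrast(paired_t(pre = w_pse$pre, post = w_pse$post)),
              .try_contrast(paired_t(pre = w_dl$pre, post = w_dl$post)))
  names(out) <- c(paste0("pse_", cond[1], "_vs0"),
                  paste0("pse_", cond[2], "_vs0"),
                  paste0("pse_paired_", cond[1], "_minus_", cond[2]),
                  paste0("dl_paired_", cond[1], "_minus_", cond[2]))
  out
}

.trait_contrasts <- function(fits, config) {
  split_res <- median_split(fits$aq, fits$pse_ms)
  dl_split <- median_split(fits$aq, fits$dl_ms)
  list(
    pse_vs0 = .try_contrast(one_sample_t(fits$pse_ms)),
    corr_aq_pse = .try_contrast(pearson_r(fits$aq, fits$pse_ms)),
    median_split = split_res,
    pse_low_aq_vs0 = .try_contrast(one_sample_t(split_res$low$value)),
    pse_high_aq_vs0 = .try_contrast(one_sample_t(split_res$high$value)),
    pse_low_vs_high = .try_contrast(
      independent_t(split_res$low$value, split_res$high$value)),
    dl_low_vs_high = .try_contrast(
      independent_t(dl_split$low$value, dl_split$high$value)))
}

.drug_contrasts <- function(fits) {
  arms <- split(fits, fits$arm)
  per_arm <- lapply(arms, function(f) {
    w <- .paired_wide(f)
    wd <- .paired_wide(f, var = "dl_ms")
    list(pse_pre_vs0 = .try_contrast(one_sample_t(w$pre)),
         pse_post_vs0 = .try_contrast(one_sample_t(w$post)),
         pse_change = .try_contrast(paired_t(pre = w$pre, post = w$post)),
         dl_change = .try_contrast(paired_t(pre = wd$pre, post = wd$post)))
  })
  changes <- lapply(arms, function(f) {
    w <- .paired_wide(f)
    w$post - w$pre
  })
  out <- list(arms = per_arm)
  if (length(changes) == 2) {
    out$change_between_arms <- .try_contrast(
      independent_t(changes[[1]], changes[[2]]))
    names(out$change_between_arms$kind) <- NULL
    out$arm_order <- names(changes)
  }
  out
}

#' Omnibus orientation-by-experiment interaction across pooled reports
#'
#' Pools the per-observer PSEs of several two-condition reports and tests
#' the within-observer condition effect against the between-observer
#' experiment factor with [mixed_anova_interaction()]. With three
#' experiments of 24 observers each, the interaction has df (2, 69).
#'
#' @param reports List of `experiment_report`s with a common pair of
#'   conditions.
#' @return An `anova_result`.
#' @export
omnibus_interaction <- function(reports) {
  pooled <- dplyr::bind_rows(lapply(reports, function(r) {
    stopifnot(inherits(r, "experiment_report"))
    f <- r$fits[r$fits$converged, ]
    conds <- unique(f$condition)
    if (length(conds) != 2) {
      abort(paste0("Report ", r$experiment_id,
                   " does not have exactly two conditions."),
            class = "durpsych_validation_error")
    }
    keep <- names(which(table(f$observer_id) == 2))
    f <- f[f$observer_id %in% keep, ]
    tibble::tibble(observer_id = paste0(r$experiment_id, ":", f$observer_id),
                   experiment = r$experiment_id,
                   condition = f$condition, pse_ms = f$pse_ms)
  }))
  mixed_anova_interaction(pooled)
}

#' Summarize an experiment report
#'
#' Tabulates every contrast (estimate, statistic, df, p, effect size with a
#' 2-decimal display field) and flags exclusions.
#'
#' @param report An `experiment_report`.
#' @return List with `table` (tidy tibble), `text` (character lines),
#'   `n_excluded`.
#' @export
summarize_report <- function(report) {
  stopifnot(inherits(report, "experiment_report"))
  rows <- list()
  add <- function(name, x) {
    if (inherits(x, "ttest_result")) {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        contrast = name, type = paste0("t_", x$kind),
        estimate = x$estimate %||% NA_real_,
        statistic = x$t, df = x$df, p = x$p,
        effect = x$d, effect_display = format_effect(x$d))
    } else if (inherits(x, "anova_result")) {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        contrast = name, type = "anova_interaction", estimate = NA_real_,
        statistic = x$F, df = x$df2, p = x$p,
        effect = x$cohen_f, effect_display = format_effect(x$cohen_f))
    } else if (is.list(x) && !is.null(x$r)) {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        contrast = name, type = "pearson", estimate = x$r,
        statistic = x$t, df = x$df, p = x$p,
        effect = x$r, effect_display = format_effect(x$r))
    }
  }
  walk_contrasts <- function(cl, prefix = "") {
    for (nm in names(cl)) {
      x <- cl[[nm]]
      full <- paste0(prefix, nm)
      if (inherits(x, c("ttest_result", "anova_result")) ||
          (is.list(x) && !is.null(x$r))) {
        add(full, x)
      } else if (is.list(x) && nm == "arms") {
        for (arm in names(x)) walk_contrasts(x[[arm]], paste0(arm, "."))
      }
    }
  }
  walk_contrasts(report$contrasts)
  tab <- dplyr::bind_rows(rows)
  text <- c(
    sprintf("Experiment %s (%s design), seed %s",
            report$experiment_id, report$kind, report$provenance$seed),
    sprintf("Fits: %d (%d excluded as non-converged)",
            report$provenance$n_fits, report$provenance$n_excluded),
    sprintf("  %-38s stat = %8.3f  df = %6.1f  p = %-9.3g effect = %s",
            tab$contrast, tab$statistic, tab$df, tab$p, tab$effect_display))
  ms <- report$contrasts$median_split
  if (!is.null(ms)) {
    text <- c(text, sprintf(
      "  median split at %d: n_low = %d, n_high = %d",
      ms$threshold, ms$n_low, ms$n_high))
  }
  list(table = tab, text = text, n_excluded = report$provenance$n_excluded)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(summarize_report(x)$text, sep = "\n")
  invisible(x)
}
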