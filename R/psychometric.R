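# Choice-proportion aggregation and Boltzmann psychometric-function fitting.
#
# The fitted curve is the increasing logistic
#   F(x) = 1 / (1 + exp(-(x - x0) / omega)),  omega > 0,
# with x the signed duration difference (communicative - noncommunicative).
# x0 is the point of subjective equality (PSE); the difference limen is half
# the interquartile range of F, which is omega * log(3) in closed form.

# optimizer box constraints and convergence tolerance
.X0_BOUNDS <- c(-1200, 1200)
.OMEGA_BOUNDS <- c(0.5, 2000)
.FIT_TOL <- 1e-8

#' Evaluate the Boltzmann (logistic) psychometric function
#'
#' `F(x) = 1 / (1 + exp(-(x - x0) / omega))`, increasing in `x` for
#' `omega > 0`, with `F(x0) = 0.5`. The same curve is sometimes written with
#' the opposite sign in the exponent and a negative slope parameter; the two
#' parameterizations are equivalent under `omega -> -omega` and the
#' difference limen uses `|omega| * log(3)` either way.
#'
#' @param x_ms Signed duration difference(s) in ms.
#' @param x0_ms Location parameter (the PSE) in ms.
#' @param omega_ms Slope parameter in ms; must be non-zero.
#' @return Choice probabilities in (0, 1).
#' @export
#' @examples
#' boltzmann(0, x0_ms = 0, omega_ms = 100)        # 0.5
#' boltzmann(100 * log(3), 0, 100)                # 0.75
boltzmann <- function(x_ms, x0_ms, omega_ms) {
  if (any(omega_ms == 0)) {
    abort("`omega_ms` must be non-zero (degenerate slope).",
          class = "durpsych_degenerate_slope")
  }
  plogis((x_ms - x0_ms) / omega_ms)
}

#' Aggregate trial records into per-level choice proportions
#'
#' Counts, per design level, the trials on which the communicative sequence
#' was judged longer. Input must come from a single observer and (if present
#' in the data) a single condition.
#'
#' @param trials Trial tibble as produced by [simulate_trials()] or read by
#'   [read_trials()].
#' @param condition Optional condition label to filter on.
#' @param levels_ms Optional full set of design levels; defaults to the
#'   levels present in the data.
#' @return A `proportion_table` tibble with columns `delta_ms`, `n_chose`,
#'   `n_total`.
#' @export
aggregate_proportions <- function(trials, condition = NULL, levels_ms = NULL) {
  if (!is.null(condition)) {
    trials <- trials[trials$condition == condition, , drop = FALSE]
  }
  if (nrow(trials) == 0) {
    abort("No trials to aggregate.", class = "durpsych_validation_error")
  }
  if (length(unique(trials$observer_id)) > 1) {
    abort("Trials from multiple observers; aggregate one observer at a time.",
          class = "durpsych_validation_error")
  }
  if (!is.null(trials$condition) && length(unique(trials$condition)) > 1) {
    abort("Trials from multiple conditions; pass `condition` to select one.",
          class = "durpsych_validation_error")
  }
  levels_ms <- sort(levels_ms %||% unique(trials$delta_ms))
  counts <- vapply(levels_ms, function(l) {
    sel <- trials$delta_ms == l
    c(sum(trials$chose_communicative_longer[sel]), sum(sel))
  }, numeric(2))
  out <- tibble::tibble(delta_ms = levels_ms,
                        n_chose = as.integer(counts[1, ]),
                        n_total = as.integer(counts[2, ]))
  class(out) <- c("proportion_table", class(out))
  out
}

#' Build a proportion table directly from counts
#'
#' @param delta_ms Stimulus levels (strictly increasing).
#' @param n_chose Count of "communicative judged longer" per level.
#' @param n_total Trials per level.
#' @return A `proportion_table` tibble.
#' @export
proportion_table <- function(delta_ms, n_chose, n_total) {
  if (is.unsorted(delta_ms, strictly = TRUE)) {
    abort("`delta_ms` must be strictly increasing.",
          class = "durpsych_validation_error")
  }
  n_total <- as.integer(rep(n_total, length.out = length(delta_ms)))
  n_chose <- as.integer(n_chose)
  if (any(n_chose < 0) || any(n_chose > n_total)) {
    abort("Counts must satisfy 0 <= n_chose <= n_total.",
          class = "durpsych_validation_error")
  }
  out <- tibble::tibble(delta_ms = as.numeric(delta_ms),
                        n_chose = n_chose, n_total = n_total)
  class(out) <- c("proportion_table", class(out))
  out
}

# Bernoulli negative log-likelihood and analytic gradient on a count table
.nll_boltzmann <- function(par, delta, k, n) {
  z <- (delta - par[1]) / par[2]
  p <- plogis(z)
  # clamp away from 0/1 for numerical safety at extreme parameters
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(k * log(p) + (n - k) * log(1 - p))
}

.nll_grad_boltzmann <- function(par, delta, k, n) {
  z <- (delta - par[1]) / par[2]
  p <- plogis(z)
  r <- k - n * p
  c(sum(r) / par[2], sum(r * z) / par[2])
}

.ss_boltzmann <- function(par, delta, k, n) {
  p <- plogis((delta - par[1]) / par[2])
  sum((k / n - p)^2)
}

# Heuristic starting values: x0 at the level whose proportion is nearest
# 0.5; omega from the empirical 25-75% span.
.fit_starts <- function(delta, k, n) {
  prop <- k / n
  x0_0 <- delta[which.min(abs(prop - 0.5))]
  lo <- delta[which(prop >= 0.25)[1]]
  hi <- delta[which(prop >= 0.75)[1]]
  span <- if (!is.na(lo) && !is.na(hi) && hi > lo) (hi - lo) / (2 * log(3))
          else diff(range(delta)) / 4
  span <- min(max(span, .OMEGA_BOUNDS[1] * 2), .OMEGA_BOUNDS[2] / 2)
  list(c(x0_0, span),
       c(0, diff(range(delta)) / 4),
       c(x0_0, span * 3))
}

#' Fit the Boltzmann psychometric function to a proportion table
#'
#' The default estimator maximizes the Bernoulli likelihood of the per-level
#' counts; `method = "lsq"` minimizes squared error on the proportions
#' instead (a sensitivity check). Maximization starts from a logistic-GLM
#' solution where available, plus heuristic multi-starts, and is polished by
#' box-constrained quasi-Newton steps with an analytic gradient
#' (`x0` in `[-1200, 1200]` ms, `omega` in `(0, 2000]` ms, objective
#' tolerance 1e-8).
#'
#' Degenerate data (all responses identical, a flat proportion profile, or
#' perfect separation driving `omega` to a bound) are flagged with
#' `converged = FALSE` and a warning; finite fallback estimates are still
#' returned, never silently dropped.
#'
#' @param table A `proportion_table` (or tibble with `delta_ms`, `n_chose`,
#'   `n_total`).
#' @param method `"mle"` (default) or `"lsq"`.
#' @return A `psychometric_fit` list with elements `x0_ms`, `omega_ms`,
#'   `pse_ms` (alias of `x0_ms`), `dl_ms`, `loglik`, `converged`, `method`.
#' @export
#' @examples
#' tab <- proportion_table(seq(-600, 600, 200),
#'                         n_chose = c(1, 2, 6, 10, 15, 18, 19), n_total = 20)
#' fit_boltzmann(tab)
fit_boltzmann <- function(table, method = c("mle", "lsq")) {
  method <- match.arg(method)
  delta <- table$delta_ms
  k <- table$n_chose
  n <- table$n_total
  keep <- n > 0
  delta <- delta[keep]; k <- k[keep]; n <- n[keep]
  if (length(delta) < 3) {
    abort("Need at least 3 levels with trials to fit.",
          class = "durpsych_insufficient_data")
  }

  degenerate <- sum(k) == 0 || sum(k) == sum(n) ||
    length(unique(k / n)) == 1

  obj <- if (method == "mle") .nll_boltzmann else .ss_boltzmann
  grad <- if (method == "mle") .nll_grad_boltzmann else NULL

  starts <- .fit_starts(delta, k, n)
  if (method == "mle") {
    glm_start <- tryCatch({
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, delta), cbind(k, n - k),
                       family = stats::binomial()))
      b <- fit$coefficients
      if (all(is.finite(b)) && b[2] > 0) c(-b[1] / b[2], 1 / b[2]) else NULL
    }, error = function(e) NULL)
    if (!is.null(glm_start)) {
      glm_start[1] <- min(max(glm_start[1], .X0_BOUNDS[1]), .X0_BOUNDS[2])
      glm_start[2] <- min(max(glm_start[2], .OMEGA_BOUNDS[1]), .OMEGA_BOUNDS[2])
      starts <- c(list(glm_start), starts)
    }
  }

  run_optim <- function(par) {
    par[1] <- min(max(par[1], .X0_BOUNDS[1]), .X0_BOUNDS[2])
    par[2] <- min(max(par[2], .OMEGA_BOUNDS[1]), .OMEGA_BOUNDS[2])
    tryCatch(
      optim(par, obj, gr = grad, delta = delta, k = k, n = n,
            method = "L-BFGS-B",
            lower = c(.X0_BOUNDS[1], .OMEGA_BOUNDS[1]),
            upper = c(.X0_BOUNDS[2], .OMEGA_BOUNDS[2]),
            control = list(factr = .FIT_TOL / .Machine$double.eps,
                           maxit = 200)),
      error = function(e) NULL)
  }
  best <- NULL
  for (s in starts) {
    res <- run_optim(s)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }
  if (is.null(best)) {
    abort("Optimization failed from every start.",
          class = "durpsych_fit_error")
  }
  # one polish pass from the incumbent; L-BFGS-B occasionally reports an
  # abnormal line-search exit while already sitting at the optimum
  polish <- run_optim(best$par)
  if (!is.null(polish) && polish$value <= best$value) best <- polish

  x0 <- unname(best$par[1])
  omega <- unname(best$par[2])
  at_bound <- omega <= .OMEGA_BOUNDS[1] * 1.01 ||
    omega >= .OMEGA_BOUNDS[2] * 0.99 ||
    x0 <= .X0_BOUNDS[1] + 1 || x0 >= .X0_BOUNDS[2] - 1
  # stationarity is judged by the gradient, not the optimizer exit code
  opt_ok <- if (method == "mle") {
    max(abs(.nll_grad_boltzmann(best$par, delta, k, n))) < 1e-3
  } else {
    best$convergence == 0
  }
  converged <- !degenerate && !at_bound && opt_ok
  if (!converged) {
    warn(paste0("Degenerate or boundary psychometric fit (x0 = ",
                signif(x0, 4), ", omega = ", signif(omega, 4),
                "); flagged converged = FALSE."),
         class = "durpsych_degenerate_fit")
  }
  loglik <- -.nll_boltzmann(c(x0, omega), delta, k, n)
  structure(
    list(x0_ms = x0, omega_ms = omega, pse_ms = x0,
         dl_ms = omega * log(3), loglik = loglik,
         converged = converged, method = method),
    class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "Boltzmann fit (%s): PSE = %.1f ms, omega = %.1f ms, DL = %.1f ms%s\n",
    x$method, x$pse_ms, x$omega_ms, x$dl_ms,
    if (x$converged) "" else " [NOT converged]"))
  invisible(x)
}

#' Difference limen of a fitted psychometric function
#'
#' Half the interquartile range of the fitted curve: `(x_{0.75} - x_{0.25})/2`
#' with `F(x_q) = q`, which equals `omega * log(3)` in closed form for the
#' logistic. Non-converged fits propagate `NA` with a warning rather than a
#' spurious number.
#'
#' @param fit A `psychometric_fit`, or a positive numeric omega in ms.
#' @return Difference limen in ms.
#' @export
#' @examples
#' difference_limen(100)  # 109.8612...
difference_limen <- function(fit) {
  if (is.numeric(fit)) return(abs(fit) * log(3))
  stopifnot(inherits(fit, "psychometric_fit"))
  if (!isTRUE(fit$converged)) {
    warn("Difference limen requested from a non-converged fit; returning NA.",
         class = "durpsych_degenerate_fit")
    return(NA_real_)
  }
  abs(fit$omega_ms) * log(3)
}

#' Fit every observer-by-condition cell of a trial table
#'
#' @param trials Trial tibble (any number of observers and conditions).
#' @param method Passed to [fit_boltzmann()].
#' @param levels_ms Optional design levels for aggregation.
#' @return Tidy tibble with one row per observer and condition:
#'   `observer_id`, `condition`, `pse_ms`, `omega_ms`, `dl_ms`, `loglik`,
#'   `converged`, `method`.
#' @export
fit_observers <- function(trials, method = "mle", levels_ms = NULL) {
  cells <- split(trials,
                 list(trials$observer_id, trials$condition), drop = TRUE)
  rows <- lapply(cells, function(tr) {
    tab <- aggregate_proportions(tr, levels_ms = levels_ms)
    fit <- withCallingHandlers(
      fit_boltzmann(tab, method = method),
      durpsych_degenerate_fit = function(w) invokeRestart("muffleWarning"))
    tibble::tibble(observer_id = tr$observer_id[1],
                   condition = tr$condition[1],
                   pse_ms = fit$pse_ms, omega_ms = fit$omega_ms,
                   dl_ms = fit$dl_ms, loglik = fit$loglik,
                   converged = fit$converged, method = fit$method)
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$observer_id, out$condition), ]
  rownames(out) <- NULL
  out
}

#' Brute-force grid maximizer of the Boltzmann likelihood
#'
#' Exhaustive evaluation of the Bernoulli log-likelihood on a dense
#' `(x0, omega)` grid. This is a validation tool: it shares no code with
#' [fit_boltzmann()] and serves as an independent check that the optimizer
#' finds the global maximum.
#'
#' @param table A proportion table.
#' @param x0_grid,omega_grid Grid vectors; defaults cover
#'   `x0 in [-600, 600]`, `omega in [1, 1000]` at 1 ms resolution.
#' @return List with `x0_ms`, `omega_ms`, `loglik` at the grid maximum.
#' @export
boltzmann_grid_max <- function(table,
                               x0_grid = seq(-600, 600, by = 1),
                               omega_grid = seq(1, 1000, by = 1)) {
  delta <- table$delta_ms
  k <- table$n_chose
  n <- table$n_total
  nx <- length(x0_grid)
  ll <- numeric(nx * length(omega_grid))
  x0m <- rep(x0_grid, times = length(omega_grid))
  omm <- rep(omega_grid, each = nx)
  for (i in seq_along(delta)) {
    p <- plogis((delta[i] - x0m) / omm)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    ll <- ll + k[i] * log(p) + (n[i] - k[i]) * log(1 - p)
  }
  j <- which.max(ll)
  list(x0_ms = x0m[j], omega_ms = omm[j], loglik = ll[j])
}
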