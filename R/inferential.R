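# Group-level statistics on fitted PSEs and difference limens: t tests with
# Cohen's d, mixed-design ANOVA with partial eta squared and Cohen's f,
# Pearson correlation, median split, and bivariate bootstrap.
#
# Effect-size conventions: d = t / sqrt(n) for one-sample and paired tests;
# d = t * sqrt(1/n1 + 1/n2) for independent (pooled-variance) tests;
# f = sqrt(eta_p^2 / (1 - eta_p^2)) from partial eta squared. Independent
# tests use the pooled-variance (not Welch) statistic, matching degrees of
# freedom n1 + n2 - 2. All p-values are two-sided; no multiplicity
# correction is applied.

.ttest_result <- function(ht, d, kind, n = NULL, n1 = NULL, n2 = NULL,
                          estimate = NULL) {
  structure(
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, d = d, n = n, n1 = n1, n2 = n2,
         estimate = estimate, kind = kind),
    class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  ns <- if (x$kind == "independent") sprintf("n1 = %d, n2 = %d", x$n1, x$n2)
        else sprintf("n = %d", x$n)
  cat(sprintf("%s t-test: t(%g) = %.2f, p = %.3g, Cohen's d = %.2f (%s)\n",
              x$kind, x$df, x$t, x$p, x$d, ns))
  invisible(x)
}

.check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    abort(paste0("Non-finite values in ", what, "."),
          class = "durpsych_validation_error")
  }
}

#' One-sample t test with Cohen's d
#'
#' @param values Numeric vector (e.g. per-observer PSEs in ms).
#' @param mu0 Null mean.
#' @return A `ttest_result` with `t`, `df`, two-sided `p`,
#'   `d = (mean - mu0)/sd = t/sqrt(n)`, and `n`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  .check_finite(values, "`values`")
  n <- length(values)
  if (n < 2) abort("Need n >= 2.", class = "durpsych_validation_error")
  if (sd(values) == 0) {
    abort("Zero variance: t statistic undefined.",
          class = "durpsych_undefined_statistic")
  }
  ht <- t.test(values, mu = mu0)
  .ttest_result(ht, d = (mean(values) - mu0) / sd(values),
                kind = "one_sample", n = n, estimate = mean(values))
}

#' Paired t test with Cohen's d
#'
#' A one-sample t test on the within-observer differences `post - pre`;
#' `d = mean(diff)/sd(diff)`.
#'
#' @param pre,post Equal-length numeric vectors.
#' @return A `ttest_result`; `estimate` is the mean difference.
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post)) {
    abort("`pre` and `post` must have equal length.",
          class = "durpsych_validation_error")
  }
  d <- post - pre
  .check_finite(d, "differences")
  n <- length(d)
  if (n < 2) abort("Need n >= 2 pairs.", class = "durpsych_validation_error")
  if (sd(d) == 0 && mean(d) == 0) {
    # exact null difference: report the degenerate zero-effect result
    return(structure(list(t = 0, df = n - 1, p = 1, d = 0, n = n,
                          n1 = NULL, n2 = NULL, estimate = 0,
                          kind = "paired"),
                     class = "ttest_result"))
  }
  if (sd(d) == 0) {
    abort("Zero variance of differences: t statistic undefined.",
          class = "durpsych_undefined_statistic")
  }
  ht <- t.test(d, mu = 0)
  .ttest_result(ht, d = mean(d) / sd(d), kind = "paired", n = n,
                estimate = mean(d))
}

#' Independent-samples t test (pooled variance) with Cohen's d
#'
#' @param group1,group2 Numeric vectors, each of length >= 2.
#' @return A `ttest_result` with `df = n1 + n2 - 2` and
#'   `d = t * sqrt(1/n1 + 1/n2)`; `estimate` is `mean(group1) - mean(group2)`.
#' @export
independent_t <- function(group1, group2) {
  if (length(group1) < 2 || length(group2) < 2) {
    abort("Each group needs n >= 2.", class = "durpsych_validation_error")
  }
  .check_finite(c(group1, group2), "groups")
  n1 <- length(group1); n2 <- length(group2)
  if (sd(c(group1, group2)) == 0) {
    return(structure(list(t = 0, df = n1 + n2 - 2, p = 1, d = 0,
                          n = NULL, n1 = n1, n2 = n2, estimate = 0,
                          kind = "independent"),
                     class = "ttest_result"))
  }
  ht <- t.test(group1, group2, var.equal = TRUE)
  .ttest_result(ht, d = unname(ht$statistic) * sqrt(1 / n1 + 1 / n2),
                kind = "independent", n1 = n1, n2 = n2,
                estimate = mean(group1) - mean(group2))
}

#' Cohen's d from a t statistic and sample size(s)
#'
#' `d = t/sqrt(n)` for one-sample and paired designs;
#' `d = t * sqrt(1/n1 + 1/n2)` for independent (pooled-variance) designs.
#'
#' @param t t statistic.
#' @param n Sample size (one-sample/paired).
#' @param n1,n2 Group sizes (independent).
#' @param kind `"one_sample"`, `"paired"` or `"independent"`.
#' @return Cohen's d.
#' @export
#' @examples
#' cohens_d_from_t(5.60, n = 24)                      # 1.14
#' cohens_d_from_t(3.51, n1 = 46, n2 = 44, kind = "independent")
cohens_d_from_t <- function(t, n = NULL, n1 = NULL, n2 = NULL,
                            kind = c("one_sample", "paired", "independent")) {
  kind <- match.arg(kind)
  if (kind == "independent") {
    stopifnot(n1 > 0, n2 > 0)
    t * sqrt(1 / n1 + 1 / n2)
  } else {
    stopifnot(n > 0)
    t / sqrt(n)
  }
}

#' Cohen's f from an F statistic or partial eta squared
#'
#' `eta_p^2 = F * df1 / (F * df1 + df2)`; `f = sqrt(eta_p^2 / (1 - eta_p^2))`.
#'
#' @param F_stat F statistic.
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return Cohen's f.
#' @export
#' @examples
#' cohens_f_from_F(9.98, 2, 69)  # 0.54
cohens_f_from_F <- function(F_stat, df1, df2) {
  eta <- F_stat * df1 / (F_stat * df1 + df2)
  sqrt(eta / (1 - eta))
}

#' Round an effect size for display
#'
#' Effect sizes are reported to two decimals in this literature; the
#' underlying value is kept at full precision.
#'
#' @param x Numeric.
#' @return Character, e.g. `"1.14"`.
#' @export
format_effect <- function(x) sprintf("%.2f", round(x, 2))

#' Mixed-design ANOVA interaction (within x between)
#'
#' Two-way mixed ANOVA with one within-observer factor (e.g. orientation:
#' upright vs inverted) and one between-observer factor (e.g. experiment),
#' fitted via [stats::aov()] with an observer error stratum. Returns the
#' interaction effect with partial eta squared and Cohen's f.
#'
#' @param data Data frame with columns named by the `observer`, `between`,
#'   `within`, `value` arguments.
#' @param observer,between,within,value Column names (strings).
#' @return An `anova_result` list: `F`, `df1`, `df2`, `p`, `eta_p2`,
#'   `cohen_f`, `term`.
#' @export
mixed_anova_interaction <- function(data, observer = "observer_id",
                                    between = "experiment",
                                    within = "condition",
                                    value = "pse_ms") {
  d <- data.frame(obs = factor(data[[observer]]),
                  btw = factor(data[[between]]),
                  wth = factor(data[[within]]),
                  y = data[[value]])
  .check_finite(d$y, "`value`")
  counts <- table(d$obs, d$wth)
  if (any(counts != 1)) {
    abort("Each observer needs exactly one value per within-level.",
          class = "durpsych_validation_error")
  }
  if (nlevels(d$btw) < 2) {
    abort("Need at least 2 between-observer groups.",
          class = "durpsych_validation_error")
  }
  fit <- aov(y ~ btw * wth + Error(obs / wth), data = d)
  within_tab <- summary(fit)[["Error: obs:wth"]][[1]]
  row <- grep("btw:wth", rownames(within_tab))
  res <- grep("Residuals", rownames(within_tab))
  ss_int <- within_tab[row, "Sum Sq"]
  ss_err <- within_tab[res, "Sum Sq"]
  Fv <- within_tab[row, "F value"]
  ss_scale <- max(sum((d$y - mean(d$y))^2), 1)
  if (!is.finite(Fv) || ss_int <= 1e-9 * ss_scale) {
    # no interaction variance at all (e.g. all cells equal)
    return(structure(list(F = 0, df1 = within_tab[row, "Df"],
                          df2 = within_tab[res, "Df"], p = 1,
                          eta_p2 = 0, cohen_f = 0,
                          term = "between:within"),
                     class = "anova_result"))
  }
  eta <- ss_int / (ss_int + ss_err)
  structure(
    list(F = Fv,
         df1 = within_tab[row, "Df"], df2 = within_tab[res, "Df"],
         p = within_tab[row, "Pr(>F)"],
         eta_p2 = eta, cohen_f = sqrt(eta / (1 - eta)),
         term = "between:within"),
    class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Mixed ANOVA interaction: F(%g, %g) = %.2f, p = %.3g, Cohen's f = %.2f\n",
              x$df1, x$df2, x$F, x$p, x$cohen_f))
  invisible(x)
}

#' Pearson correlation with two-sided t-based p-value
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return List with `r`, `n`, `p`, `t`, `df`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length.",
          class = "durpsych_validation_error")
  }
  if (length(x) < 3) abort("Need n >= 3.", class = "durpsych_validation_error")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Zero variance: correlation undefined.",
          class = "durpsych_undefined_statistic")
  }
  ht <- cor.test(x, y)
  list(r = unname(ht$estimate), n = length(x), p = ht$p.value,
       t = unname(ht$statistic), df = unname(ht$parameter))
}

#' Median split of observers by trait score
#'
#' Splits into a low group (`score < threshold`) and a high group
#' (`score >= threshold`). When the sample median is itself an attained
#' integer score, the threshold is the smallest integer strictly above it
#' (a median of 19 yields groups `< 20` and `>= 20`); otherwise the median
#' is rounded up.
#'
#' @param scores Trait scores (e.g. AQ).
#' @param values Values to carry along (e.g. PSEs), same length.
#' @return List with tibbles `low` and `high` (columns `score`, `value`),
#'   `threshold`, `median`, `n_low`, `n_high`.
#' @export
median_split <- function(scores, values) {
  if (length(scores) != length(values)) {
    abort("`scores` and `values` must have equal length.",
          class = "durpsych_validation_error")
  }
  med <- median(scores)
  threshold <- if (any(scores == med)) floor(med) + 1 else ceiling(med)
  low <- scores < threshold
  if (!any(low) || all(low)) {
    warn("Median split produced an empty group.",
         class = "durpsych_empty_group")
  }
  list(low = tibble::tibble(score = scores[low], value = values[low]),
       high = tibble::tibble(score = scores[!low], value = values[!low]),
       threshold = threshold, median = med,
       n_low = sum(low), n_high = sum(!low))
}

#' Bivariate bootstrap of (pre, post) sample means
#'
#' Standard nonparametric bootstrap over observers: whole (pre, post) pairs
#' are resampled with replacement `n_boot` times and each resample
#' contributes its pair of means, producing the "cloud" of bootstrapped
#' bivariate sample means used to display a group's central tendency.
#'
#' @param pre,post Equal-length numeric vectors (n >= 2 pairs).
#' @param n_boot Number of resamples (default 1000).
#' @param seed Integer seed.
#' @return A `bootstrap_cloud` list: `resampled_means` (tibble with columns
#'   `pre_mean`, `post_mean`), `n_boot`, `seed`, `n`.
#' @export
bootstrap_bivariate_mean <- function(pre, post, n_boot = 1000, seed = 1) {
  if (length(pre) != length(post)) {
    abort("`pre` and `post` must have equal length.",
          class = "durpsych_validation_error")
  }
  n <- length(pre)
  if (n < 2) abort("Need n >= 2 pairs.", class = "durpsych_validation_error")
  if (n_boot < 1) abort("`n_boot` must be >= 1.",
                        class = "durpsych_validation_error")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(substream_seed(seed, "bootstrap"))
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  structure(
    list(resampled_means = tibble::tibble(
           pre_mean = rowMeans(matrix(pre[idx], nrow = n_boot)),
           post_mean = rowMeans(matrix(post[idx], nrow = n_boot))),
         n_boot = as.integer(n_boot), seed = seed, n = n),
    class = "bootstrap_cloud")
}
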