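# t tests, effect sizes, mixed ANOVA, correlation, median split, bootstrap.

test_that("one-sample t matches its effect-size identity", {
  set.seed(101)
  for (i in 1:5) {
    x <- rnorm(sample(5:50, 1), mean = runif(1, -1, 1))
    res <- one_sample_t(x)
    expect_equal(res$d * sqrt(res$n), res$t, tolerance = 1e-12)
    expect_equal(res$df, res$n - 1)
    ht <- t.test(x)
    expect_equal(res$p, ht$p.value)
  }
  expect_error(one_sample_t(rep(3, 10), mu0 = 3),
               class = "durpsych_undefined_statistic")
  expect_error(one_sample_t(1), class = "durpsych_validation_error")
})

test_that("paired t agrees with a by-hand spreadsheet computation", {
  pre <- c(10, 25, 31, 4, 18)
  post <- c(22, 31, 30, 19, 27)
  d <- post - pre                           # 12, 6, -1, 15, 9
  m <- sum(d) / 5                           # 8.2
  s <- sqrt(sum((d - m)^2) / 4)             # sample SD of differences
  t_manual <- m / (s / sqrt(5))
  res <- paired_t(pre, post)
  expect_equal(res$t, t_manual, tolerance = 1e-12)
  expect_equal(res$d, m / s, tolerance = 1e-12)
  expect_equal(res$estimate, m)
  expect_equal(res$df, 4)

  null <- paired_t(pre, pre)
  expect_equal(null$t, 0)
  expect_equal(null$d, 0)
  expect_error(paired_t(1:3, 1:4), class = "durpsych_validation_error")
})

test_that("independent t uses pooled variance and its d identity", {
  set.seed(202)
  g1 <- rnorm(46); g2 <- rnorm(44, 0.5)
  res <- independent_t(g1, g2)
  expect_equal(res$df, 46 + 44 - 2)
  expect_equal(res$d, res$t * sqrt(1 / 46 + 1 / 44), tolerance = 1e-12)
  ht <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(res$t, unname(ht$statistic))

  same <- independent_t(c(1, 1, 1), c(1, 1))
  expect_equal(same$t, 0)
  expect_error(independent_t(1, c(1, 2)),
               class = "durpsych_validation_error")
})

test_that("effect-size converters apply the documented formulas", {
  expect_equal(cohens_d_from_t(0, n = 24), 0)
  expect_equal(cohens_d_from_t(5.60, n = 24), 5.60 / sqrt(24))
  expect_equal(cohens_d_from_t(3.51, n1 = 46, n2 = 44, kind = "independent"),
               3.51 * sqrt(1 / 46 + 1 / 44))
  eta <- 9.98 * 2 / (9.98 * 2 + 69)
  expect_equal(cohens_f_from_F(9.98, 2, 69), sqrt(eta / (1 - eta)))
  expect_equal(format_effect(1.143095), "1.14")
  expect_equal(format_effect(-1.655), "-1.66")
})

test_that("mixed ANOVA interaction matches a from-scratch SS decomposition", {
  # 3 groups x 4 observers x 2 within-levels toy dataset
  set.seed(33)
  d <- expand.grid(observer = 1:4, group = c("a", "b", "c"),
                   cond = c("w1", "w2"))
  d$observer_id <- paste0(d$group, d$observer)
  d$y <- rnorm(nrow(d)) + ifelse(d$group == "a" & d$cond == "w2", 1, 0)

  res <- mixed_anova_interaction(d, observer = "observer_id",
                                 between = "group", within = "cond",
                                 value = "y")

  # manual sum-of-squares decomposition of the within-subject stratum
  m <- mean(d$y)
  mk <- tapply(d$y, d$cond, mean)
  mik <- tapply(d$y, list(d$group, d$cond), mean)
  mi <- tapply(d$y, d$group, mean)
  mij <- tapply(d$y, d$observer_id, mean)
  S <- 12; I <- 3; K <- 2; J <- 4
  ss_within_total <- sum((d$y - mij[d$observer_id])^2)
  ss_w <- S * sum((mk - m)^2)
  ss_bw <- J * sum((mik - outer(mi, rep(1, K)) -
                      outer(rep(1, I), mk) + m)^2)
  ss_err <- ss_within_total - ss_w - ss_bw
  F_manual <- (ss_bw / ((I - 1) * (K - 1))) / (ss_err / ((S - I) * (K - 1)))
  expect_equal(res$F, F_manual, tolerance = 1e-9)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 9)
  expect_equal(res$eta_p2, ss_bw / (ss_bw + ss_err), tolerance = 1e-9)
  expect_equal(res$cohen_f, sqrt(res$eta_p2 / (1 - res$eta_p2)))

  # all cells equal: no interaction variance at all
  d0 <- d; d0$y <- 5
  res0 <- mixed_anova_interaction(d0, observer = "observer_id",
                                  between = "group", within = "cond",
                                  value = "y")
  expect_equal(res0$F, 0)
  expect_equal(res0$cohen_f, 0)

  # unbalanced within-observer data is a validation error
  expect_error(
    mixed_anova_interaction(d[-1, ], observer = "observer_id",
                            between = "group", within = "cond", value = "y"),
    class = "durpsych_validation_error")
})

test_that("pearson_r handles exact and degenerate relationships", {
  x <- c(1, 3, 7, 9, 15)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -x + 4)$r, -1)
  res <- pearson_r(x, c(2, 1, 5, 4, 9))
  ht <- cor.test(x, c(2, 1, 5, 4, 9))
  expect_equal(res$r, unname(ht$estimate))
  expect_equal(res$p, ht$p.value)
  expect_error(pearson_r(x, rep(1, 5)),
               class = "durpsych_undefined_statistic")
  expect_error(pearson_r(1:3, 1:4), class = "durpsych_validation_error")
})

test_that("median split reproduces the integer-threshold convention", {
  # attained integer median 19 -> threshold 20 (groups < 20 and >= 20)
  scores <- c(15, 17, 19, 19, 21, 25, 30)
  sp <- median_split(scores, scores * 0)
  expect_equal(sp$threshold, 20)
  expect_equal(sp$n_low, 4)
  expect_equal(sp$n_high, 3)

  # 90 scores with 46 below 20 and 44 at or above
  set.seed(9)
  scores90 <- c(sample(10:19, 46, replace = TRUE),
                sample(20:36, 44, replace = TRUE))
  sp90 <- median_split(scores90, seq_along(scores90))
  expect_equal(sp90$n_low, 46)
  expect_equal(sp90$n_high, 44)
  # disjoint and exhaustive, order-independent
  expect_equal(sp90$n_low + sp90$n_high, 90)
  expect_length(intersect(sp90$low$value, sp90$high$value), 0)
  perm <- sample(90)
  sp_perm <- median_split(scores90[perm], seq_along(scores90)[perm])
  expect_equal(sp_perm$threshold, sp90$threshold)
  expect_setequal(sp_perm$low$value, sp90$low$value)

  expect_warning(median_split(rep(20, 5), 1:5),
                 class = "durpsych_empty_group")
})

test_that("the bivariate bootstrap resamples whole observer pairs", {
  set.seed(12)
  pre <- rnorm(20, 10, 5); post <- rnorm(20, 40, 5)
  cloud <- bootstrap_bivariate_mean(pre, post, n_boot = 1000, seed = 3)
  expect_equal(nrow(cloud$resampled_means), 1000)
  expect_identical(cloud$resampled_means,
                   bootstrap_bivariate_mean(pre, post, seed = 3)$resampled_means)
  # resampling consistency: grand mean near the sample mean
  se_pre <- sd(cloud$resampled_means$pre_mean)
  expect_lt(abs(mean(cloud$resampled_means$pre_mean) - mean(pre)), 3 * se_pre)
  se_post <- sd(cloud$resampled_means$post_mean)
  expect_lt(abs(mean(cloud$resampled_means$post_mean) - mean(post)),
            3 * se_post)

  # a single repeated pair collapses every resampled mean onto that pair
  one <- bootstrap_bivariate_mean(rep(7, 5), rep(9, 5), n_boot = 50, seed = 1)
  expect_true(all(one$resampled_means$pre_mean == 7))
  expect_true(all(one$resampled_means$post_mean == 9))

  expect_error(bootstrap_bivariate_mean(pre, post, n_boot = 0),
               class = "durpsych_validation_error")
  expect_error(bootstrap_bivariate_mean(1, 1),
               class = "durpsych_validation_error")
})
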