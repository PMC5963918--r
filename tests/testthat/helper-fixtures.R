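# Shared fixtures, all generated in code.

default_levels <- seq(-600, 600, by = 200)

# one-row observer-profile tibble with explicit latent parameters
make_profile <- function(pse, omega = 150, lapse = 0, aq = 20L,
                         id = "obs1") {
  tibble::tibble(observer_id = id, aq = as.integer(aq), omega_ms = omega,
                 lapse = lapse, pse_ms = list(pse))
}

# proportion table whose counts are the (rounded) expected counts under the
# generating curve -- binomial noise vanishes as n grows
exact_counts <- function(x0, omega, n = 1e6, levels = default_levels) {
  p <- 1 / (1 + exp(-(levels - x0) / omega))
  proportion_table(levels, n_chose = round(n * p), n_total = n)
}

# quietly fit (degenerate-fit warnings are part of tested behavior elsewhere)
fit_quiet <- function(tab, ...) {
  suppressWarnings(fit_boltzmann(tab, ...))
}
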