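## shared fixtures and independent oracles for the test suite

## small balanced trial table built directly (no generator involved)
make_trials <- function(n_participants = 2, levels = c(1, 2, 3),
                        trials_per_cell = 2, conditions = c("direct",
                                                            "indirect")) {
  rows <- list()
  for (p in seq_len(n_participants)) {
    for (cond in conditions) {
      k <- 0L
      for (rep in seq_len(trials_per_cell)) {
        for (l in levels) {
          k <- k + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            participant_id = sprintf("S%02d", p), subgroup = "test",
            condition = cond, gain = 1, target_force_N = l,
            matching_force_N = l * ifelse(cond == "direct", 1.5, 1) +
              0.01 * k,
            trial_index = k, stringsAsFactors = FALSE)
        }
      }
    }
  }
  as_fm_trials(do.call(rbind, rows))
}

## exact density of the product of two independent normals, by adaptive
## quadrature over the first factor (test oracle; never used in fitting)
product_normal_density <- function(z, mean_K, sd_K, mean_FI, sd_FI) {
  vapply(z, function(zz) stats::integrate(function(u)
    stats::dnorm(u, mean_K, sd_K) * stats::dnorm(zz / u, mean_FI, sd_FI) /
      abs(u),
    mean_K - 10 * sd_K, mean_K + 10 * sd_K, rel.tol = 1e-10)$value,
    numeric(1))
}

## independent JZS Bayes factor oracle: direct integration over the
## standardized effect size with the noncentral-t density
jzs_bf_delta_oracle <- function(t, n, scale = sqrt(2) / 2) {
  nu <- n - 1
  m1 <- stats::integrate(function(delta)
    suppressWarnings(stats::dt(t, nu, ncp = delta * sqrt(n))) *
      stats::dcauchy(delta, 0, scale), -Inf, Inf, rel.tol = 1e-9)$value
  m1 / stats::dt(t, nu)
}

## desk-scale MCMC settings for unit tests
test_control <- function(seed = 1L)
  fm_control(n_chains = 3L, samples_per_chain = 400L, burn_in = 400L,
             thin = 1L, seed = seed)
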