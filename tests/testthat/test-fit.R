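## small cohort shared by the fitting tests
small_cohort <- local({
  pop <- fm_population("divisive")
  des <- fm_design(1, 3.5, 6, 36)
  simulate_study(pop, des, n_participants = 6, seed = 31)
})

small_fit <- fm_fit(small_cohort$trials, "divisive",
                    control = test_control(seed = 2))

test_that("the fit carries the expected parameter bookkeeping", {
  P <- 6; L <- 6
  ## 2 attenuation + 2 per level per participant, plus 3 population params
  expect_equal(length(small_fit$par_names), 3 + 2 * P + 2 * P * L)
  expect_true(all(c("pop.mean_K", "pop.sd_mean_K", "pop.scale_sd_K") %in%
                    small_fit$par_names))
  ## subtractive and divisive fits expose identical parameter name sets
  fs <- fm_fit(small_cohort$trials, "subtractive",
               control = test_control(seed = 2))
  expect_identical(small_fit$par_names, fs$par_names)
  ## draws have the configured shape
  expect_equal(dim(small_fit$chains[[1]]),
               c(400L, length(small_fit$par_names)))
  expect_equal(length(small_fit$chains), 3L)
})

test_that("sampling is deterministic under the seed", {
  f2 <- fm_fit(small_cohort$trials, "divisive",
               control = test_control(seed = 2))
  expect_identical(small_fit$chains, f2$chains)
  f3 <- fm_fit(small_cohort$trials, "divisive",
               control = test_control(seed = 3))
  expect_false(identical(small_fit$chains, f3$chains))
})

test_that("DIC decomposition is internally consistent", {
  d <- small_fit$dic
  expect_equal(d$DIC, d$D_bar + d$p_D, tolerance = 1e-9)
  expect_equal(d$DIC, d$D_hat + 2 * d$p_D, tolerance = 1e-9)
  expect_gt(d$p_D, 0)
})

test_that("the divisive log-likelihood peaks near the generating truth", {
  ## local consistency: on a large single-participant dataset the joint
  ## direct likelihood is higher at the truth than at perturbed values
  set.seed(40)
  y <- sample_direct(5000, 1.6, 0.15, 2.0, 0.3, "divisive")
  ll_true <- direct_force_loglik(y, 1.6, 0.15, 2.0, 0.3, "divisive")
  for (pert in list(c(1.8, 0.15), c(1.4, 0.15), c(1.6, 0.3), c(1.6, 0.05)))
    expect_gt(ll_true,
              direct_force_loglik(y, pert[1], pert[2], 2.0, 0.3, "divisive"))
})

test_that("posterior summaries and methods are coherent", {
  s <- summary(small_fit)
  expect_equal(nrow(s$population), 3L)
  expect_true(all(s$population$hdi_lower <= s$population$median &
                    s$population$median <= s$population$hdi_upper))
  cf <- coef(small_fit)
  expect_equal(length(cf), length(small_fit$par_names))
  ## predictions exist for every participant x condition x level
  pr <- predict(small_fit)
  expect_equal(nrow(pr), 6 * 6 * 2)
  expect_true(all(pr$sd > 0))
  ## direct predictions exceed indirect at the same level (attenuation > 1)
  agg <- tapply(pr$mean, pr$condition, mean)
  expect_gt(agg[["direct"]], agg[["indirect"]])
  ## residuals are centred near zero
  r <- residuals(small_fit, small_cohort$trials)
  expect_lt(abs(mean(r$residual)), 0.1)
  ## long-format draw export
  pd <- posterior_draws(small_fit, "pop.mean_K")
  expect_equal(nrow(pd), 3 * 400)
  expect_named(pd, c("chain", "iteration", "parameter", "value"))
})

test_that("fixed-indirect fitting enforces its contract and recovers", {
  des4 <- fm_design(1, 3, 5, 30, conditions = "direct")
  part <- data.frame(participant_id = sprintf("G%02d", 1:5), mean_K = 1.3,
                     sd_K = 0.1, perceptual_noise_sd = 0,
                     memory_contraction = 0, memory_noise_sd = 0,
                     comparison_noise_sd = 0.25, signal_dependent_coef = 0)
  set.seed(12)
  tr <- do.call(rbind, lapply(1:5, function(i)
    simulate_direct(as.list(part[i, ]), des4, "divisive")))
  truth_fi <- data.frame(target_force_N = target_levels(des4),
                         mean_FI = target_levels(des4), sd_FI = 0.25)
  fg <- fit_gain_condition(tr, truth_fi, "divisive",
                           control = test_control(seed = 4))
  med <- summary(fg)$population
  expect_equal(med$median[med$parameter == "pop.mean_K"], 1.3,
               tolerance = 0.05)
  ## no indirect parameters are sampled
  expect_false(any(startsWith(fg$par_names, "mu_I")))

  ## a missing level in the fixed parameters is an error
  expect_error(fit_gain_condition(tr, truth_fi[-3, ], "divisive",
                                  control = test_control()),
               "missing level")
  ## direct-only data without fixed parameters is an error
  expect_error(fm_fit(tr, "divisive", control = test_control()),
               "no indirect trials")
})
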