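## shared small fit for predictive checks
ppc_cohort <- local({
  pop <- fm_population("divisive")
  des <- fm_design(1, 3.5, 6, 36)
  simulate_study(pop, des, n_participants = 5, seed = 77)
})
ppc_fit <- fm_fit(ppc_cohort$trials, "divisive",
                  control = test_control(seed = 5))
ppc_ens <- pp_replicate(ppc_fit, ppc_cohort$trials, n_sims = 300, seed = 9)

test_that("replication preserves structure and is seed-deterministic", {
  cells <- ppc_ens$cells
  expect_equal(sum(cells$n_trials), nrow(ppc_cohort$trials))
  expect_equal(nrow(cells), 5 * 2 * 6)
  expect_true(all(vapply(ppc_ens$draws, nrow, integer(1)) == 300L))
  expect_equal(length(ppc_ens$draw_index), 300L)

  e2 <- pp_replicate(ppc_fit, ppc_cohort$trials, n_sims = 300, seed = 9)
  expect_identical(ppc_ens$draws, e2$draws)
  e3 <- pp_replicate(ppc_fit, ppc_cohort$trials, n_sims = 300, seed = 10)
  expect_false(identical(ppc_ens$draws, e3$draws))

  bad <- ppc_cohort$trials
  bad$participant_id[1] <- "nobody"
  expect_error(pp_replicate(ppc_fit, bad, 10, 1), "absent from the fit")
})

test_that("Bayesian p-values hit the degenerate benchmarks", {
  ## observed data equal to the ensemble cell-wise average: zero observed
  ## discrepancy under the ensemble reference, p ~ 1
  avg <- vapply(ppc_ens$draws, function(d) mean(d), numeric(1))
  mimic <- ppc_cohort$trials
  key <- paste(mimic$participant_id, mimic$condition,
               round(mimic$target_force_N, 9))
  ckey <- paste(ppc_ens$cells$participant_id, ppc_ens$cells$condition,
                round(ppc_ens$cells$target_force_N, 9))
  mimic$matching_force_N <- avg[match(key, ckey)]
  p_avg <- bayesian_p(mimic, ppc_ens, discrepancy = "mean",
                      reference = "ensemble")
  expect_gte(p_avg[["pooled"]], 0.99)

  ## a +10 N shift in all cells is an extreme misfit in every variant
  shifted <- ppc_cohort$trials
  shifted$matching_force_N <- shifted$matching_force_N + 10
  expect_lt(bayesian_p(shifted, ppc_ens)[["pooled"]], 0.01)
  expect_lt(bayesian_p(shifted, ppc_ens, discrepancy = "mean",
                       reference = "ensemble")[["pooled"]], 0.01)
  ## p is a proportion
  p <- bayesian_p(ppc_cohort$trials, ppc_ens)
  expect_true(all(p >= 0 & p <= 1))
  expect_named(p, c("direct", "indirect", "pooled"))
})

test_that("p-values are invariant under a common force rescaling", {
  scale_ens <- ppc_ens
  scale_ens$draws <- lapply(ppc_ens$draws, function(d) 2 * d)
  scale_ens$pred_mean <- 2 * ppc_ens$pred_mean
  scale_ens$pred_sd <- 2 * ppc_ens$pred_sd
  scaled <- ppc_cohort$trials
  scaled$matching_force_N <- 2 * scaled$matching_force_N
  expect_equal(bayesian_p(scaled, scale_ens),
               bayesian_p(ppc_cohort$trials, ppc_ens))
})

test_that("predictive summaries honour degenerate and ordering cases", {
  ## degenerate ensemble: all replicated values equal to a constant
  cells <- data.frame(participant_id = "a", condition = "direct",
                      target_force_N = 2, n_trials = 3,
                      stringsAsFactors = FALSE)
  degen <- structure(list(cells = cells,
                          draws = list(matrix(4.2, 50, 3)),
                          draw_index = rep(1L, 50),
                          pred_mean = matrix(4.2, 50, 1),
                          pred_sd = matrix(0.1, 50, 1),
                          n_sims = 50L, model = "divisive"),
                     class = "fm_ppc")
  s <- predictive_summary(degen)
  expect_equal(s$median, 4.2)
  expect_equal(c(s$hdi_lower, s$hdi_upper), c(4.2, 4.2))

  ## replicate order invariance
  perm <- ppc_ens
  perm$draws <- lapply(ppc_ens$draws, function(d) d[300:1, , drop = FALSE])
  expect_equal(predictive_summary(perm)$median,
               predictive_summary(ppc_ens)$median)

  ## pooled summaries show the positive direct-condition skew of the
  ## divisive model
  ps <- predictive_summary(ppc_ens, pooled = TRUE)
  expect_true(all(c("cells", "pooled") %in% names(ps)))
  dir_draws <- unlist(lapply(which(ppc_ens$cells$condition == "direct"),
                             function(j) as.vector(ppc_ens$draws[[j]])))
  lvl <- rep(ppc_ens$cells$target_force_N[ppc_ens$cells$condition ==
                                            "direct"],
             each = 300 * ppc_ens$cells$n_trials[1])
  sk <- tapply(dir_draws, lvl, function(v)
    mean((v - mean(v))^3) / sd(v)^3)
  expect_true(all(sk > 0))
})
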