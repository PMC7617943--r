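test_that("population draws respect degenerate and distributional limits", {
  pop0 <- fm_population("divisive", mean_K_mean = 1.6, mean_K_sd = 0,
                        sd_K_scale = 0,
                        pathway_spread = fm_pathway(0, 0, 0, 0, 0))
  set.seed(1)
  p <- draw_participants(pop0, 5)
  expect_true(all(p$mean_K == 1.6))
  expect_true(all(p$sd_K == 0))
  expect_true(all(p$memory_contraction == pop0$pathway$memory_contraction))

  ## CLT check on the population mean (mild truncation bias allowed for)
  set.seed(2)
  big <- draw_participants(fm_population("divisive"), 500)
  expect_equal(mean(big$mean_K), 1.6, tolerance = 3 * 0.25 / sqrt(500) + 0.01)

  ## determinism
  set.seed(3); a <- draw_participants(fm_population("divisive"), 4)
  set.seed(3); b <- draw_participants(fm_population("divisive"), 4)
  expect_identical(a, b)
})

test_that("noiseless pathway reproduces targets; contraction shrinks slopes", {
  des <- fm_design(1, 3, 5, 50)
  part <- list(participant_id = "p1", mean_K = 1.6, sd_K = 0,
               perceptual_noise_sd = 0, memory_contraction = 0,
               memory_noise_sd = 0, comparison_noise_sd = 0,
               signal_dependent_coef = 0)
  set.seed(1)
  ind <- simulate_indirect(part, des)
  expect_equal(ind$matching_force_N, ind$target_force_N)

  ## full contraction: output pinned at the level mean
  part$memory_contraction <- 1
  set.seed(1)
  ind1 <- simulate_indirect(part, des)
  expect_true(all(ind1$matching_force_N == mean(target_levels(des))))

  ## c = 0.3: regression of indirect output on target has slope 0.7 and
  ## intercept 0.3 * level mean (analytic expectation of linear shrinkage)
  des_big <- fm_design(1, 3, 5, 10000, conditions = "indirect")
  part2 <- part
  part2$memory_contraction <- 0.3
  part2$comparison_noise_sd <- 0.2
  set.seed(9)
  ind2 <- simulate_indirect(part2, des_big)
  b <- coef(lm(matching_force_N ~ target_force_N, ind2))
  expect_equal(unname(b[2]), 0.7, tolerance = 0.02)
  expect_equal(unname(b[1]), 0.3 * 2, tolerance = 0.04)
})

test_that("direct simulation applies the attenuation factor generatively", {
  des <- fm_design(1, 3, 5, 50, conditions = "direct")
  part <- list(participant_id = "p1", mean_K = 1.5, sd_K = 0,
               perceptual_noise_sd = 0, memory_contraction = 0,
               memory_noise_sd = 0, comparison_noise_sd = 0,
               signal_dependent_coef = 0)
  set.seed(1)
  d <- simulate_direct(part, des, "divisive")
  expect_equal(d$matching_force_N, 1.5 * d$target_force_N)

  ## with noise, per-level direct variance exceeds indirect variance
  des2 <- fm_design(1, 3, 5, 2000)
  part2 <- list(participant_id = "p1", mean_K = 1.6, sd_K = 0.15,
                perceptual_noise_sd = 0.15, memory_contraction = 0.15,
                memory_noise_sd = 0.15, comparison_noise_sd = 0.15,
                signal_dependent_coef = 0.08)
  set.seed(4)
  dd <- simulate_direct(part2, des2, "divisive")
  ii <- simulate_indirect(part2, des2)
  sv <- function(x) tapply(x$matching_force_N, x$target_force_N, sd)
  expect_true(all(sv(dd) > sv(ii)))
  ## per-level direct mean tracks mean_K * latent mean
  mv <- function(x) tapply(x$matching_force_N, x$target_force_N, mean)
  lat_mean <- 0.85 * target_levels(des2) + 0.15 * 2
  expect_equal(as.numeric(mv(dd)), 1.6 * lat_mean, tolerance = 0.05)
  expect_equal(as.numeric(mv(ii)), lat_mean, tolerance = 0.05)
})

test_that("simulate_study produces conforming, reproducible cohorts", {
  pop <- fm_population("divisive")
  des <- fm_design_preset("study1")
  co <- simulate_study(pop, des, n_participants = 3, seed = 5)
  expect_equal(nrow(co$trials), 3 * 72)
  expect_equal(nrow(validate_trials(co$trials, des)), 0L)
  expect_equal(nrow(co$truth$participants), 3L)
  co2 <- simulate_study(pop, des, n_participants = 3, seed = 5)
  expect_identical(co$trials, co2$trials)
  co3 <- simulate_study(pop, des, n_participants = 3, seed = 6)
  expect_false(identical(co$trials, co3$trials))
})

test_that("gain studies match passive forces and divide active forces", {
  pop <- fm_population("divisive", mean_K_mean = 1.2, mean_K_sd = 0.1)
  des <- fm_design_preset("study4")
  g <- simulate_gain_study(pop, des, n_participants = 4, seed = 8)
  expect_equal(nrow(g$trials), 4 * 150)
  expect_true("active_force_N" %in% names(g$trials))
  ## active = passive / gain, trial-wise
  expect_equal(g$trials$active_force_N,
               g$trials$matching_force_N / g$trials$gain)
  ## passive matching force distribution matched across gains
  ms <- tapply(g$trials$matching_force_N, g$trials$gain, mean)
  expect_lt(max(ms) - min(ms), 0.15)
  expect_equal(nrow(validate_trials(g$trials, des)), 0L)
})

test_that("simulated traces recover the matching force in the window", {
  trial <- list(matching_force_N = 2.4)
  tr <- simulate_trace(trial, rate = 100)
  expect_equal(nrow(tr), 300L)
  expect_equal(extract_matching_force(tr), 2.4, tolerance = 1e-9)
  ## plateau noise is mean-centred in the analysis window
  set.seed(2)
  trn <- simulate_trace(trial, rate = 60, plateau_noise_sd = 0.1)
  expect_equal(extract_matching_force(trn), 2.4, tolerance = 1e-9)
  expect_error(simulate_trace(trial, rate = 10), "rate")
})
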