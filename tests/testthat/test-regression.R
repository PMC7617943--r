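## per-level summaries with exactly linear structure for two participants
exact_summaries <- function() {
  lv <- c(1, 2, 3)
  do.call(rbind, lapply(c("a", "b"), function(pid)
    data.frame(participant_id = pid,
               condition = rep(c("direct", "indirect"), each = 3),
               gain = 1, target_force_N = rep(lv, 2), n = 6,
               mean_match = c(1.2 * lv + 0.3, lv),
               sd_match = c(0.2 * lv + 0.1, 0.1 * lv + 0.1),
               stringsAsFactors = FALSE)))
}

test_that("per-participant OLS is exact on linear data", {
  s <- exact_summaries()
  f <- per_participant_fit(s, "target", "mean_direct")
  expect_equal(f$coefficients$slope, c(1.2, 1.2), tolerance = 1e-10)
  expect_equal(f$coefficients$intercept, c(0.3, 0.3), tolerance = 1e-10)

  ## constant y: slope 0
  s2 <- s
  s2$mean_match[s2$condition == "direct"] <- 2
  f2 <- per_participant_fit(s2, "target", "mean_direct")
  expect_equal(f2$coefficients$slope, c(0, 0))

  ## direct-vs-indirect pairing by level: slope equals the ratio structure
  f3 <- per_participant_fit(s, "mean_indirect", "mean_direct")
  expect_equal(f3$coefficients$slope, c(1.2, 1.2), tolerance = 1e-10)

  ## fewer than two distinct x values is an error
  expect_error(per_participant_fit(s[s$target_force_N == 1, ],
                                   "target", "mean_direct"), "fewer than 2")
})

test_that("population regression aggregates coefficients with JZS tests", {
  set.seed(1)
  lv <- c(1, 2, 3, 4)
  mk <- function(slopes) do.call(rbind, lapply(seq_along(slopes), function(i)
    data.frame(participant_id = sprintf("p%02d", i), condition = "direct",
               gain = 1, target_force_N = lv, n = 6,
               mean_match = slopes[i] * lv + 0.2 + rnorm(4, 0, 1e-6),
               sd_match = 0.2, stringsAsFactors = FALSE)))
  ## coefficients essentially equal to the references: evidence for null
  f_null <- per_participant_fit(mk(rep(1, 12) + rnorm(12, 0, 1e-3)),
                                "target", "mean_direct")
  r_null <- population_regression(f_null, slope_ref = 1, intercept_ref = 0.2)
  expect_lt(r_null$bf10_slope, 1)
  expect_true(r_null$slope_ci95[1] <= r_null$slope &&
                r_null$slope <= r_null$slope_ci95[2])
  expect_true(r_null$r_squared >= 0 && r_null$r_squared <= 1)

  ## strong offset: decisive evidence
  f_alt <- per_participant_fit(mk(rnorm(20, 1.5, 0.05)),
                               "target", "mean_direct")
  r_alt <- population_regression(f_alt, slope_ref = 1)
  expect_gt(r_alt$bf10_slope, 100)
  expect_error(population_regression(
    per_participant_fit(mk(c(1, 1)), "target", "mean_direct")), "at least 3")
})

test_that("JZS Bayes factor matches the effect-size integration oracle", {
  ## frozen value, computed before the build from both quadrature routes
  expect_equal(jzs_bf_onesample(5, 20), 341.4393, tolerance = 1e-4)
  expect_lt(jzs_bf_onesample(0, 20), 1)
  ## agreement with the independent delta-integration oracle
  for (t in c(0, 1, 2.5, 5, 8))
    expect_equal(jzs_bf_onesample(t, 20), jzs_bf_delta_oracle(t, 20),
                 tolerance = 1e-6)
  ## strictly increasing in |t|; BF10(0, n) decreasing in n
  bfs <- sapply(0:3, jzs_bf_onesample, n = 20)
  expect_true(all(diff(bfs) > 0))
  expect_gt(jzs_bf_onesample(0, 10), jzs_bf_onesample(0, 100))
  expect_identical(jzs_bf_onesample(Inf, 20), Inf)
})

test_that("condition contrasts are symmetric and handle identical input", {
  s <- exact_summaries()
  fd <- per_participant_fit(s, "target", "sd_direct")
  fi <- per_participant_fit(s, "target", "sd_indirect")
  cc <- condition_contrast(fd, fi, "slope")
  expect_equal(cc$mean_diff, 0.1, tolerance = 1e-10)

  ## identical conditions: all differences zero, null supported
  c0 <- condition_contrast(fd, fd, "slope")
  expect_equal(c0$mean_diff, 0)
  expect_lt(c0$bf10, 1)

  ## sign flip changes the summary sign, not the Bayes factor
  cc_rev <- condition_contrast(fi, fd, "slope")
  expect_equal(cc_rev$mean_diff, -cc$mean_diff)
  expect_equal(cc_rev$bf10, cc$bf10, tolerance = 1e-9)

  fi_bad <- fi
  fi_bad$coefficients$participant_id <- c("a", "zz")
  expect_error(condition_contrast(fd, fi_bad), "participant sets differ")
})
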