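test_that("subtractive moments are the sum-of-normals moments", {
  expect_equal(unlist(subtractive_moments(0, 0, 2, 0.3)),
               c(mean = 2, sd = 0.3, skew = 0))
  ## frozen against a 1e6-draw Monte-Carlo sum-of-normals oracle
  m <- subtractive_moments(0.5, 0.1, 2.0, 0.3)
  expect_equal(m$mean, 2.5)
  expect_equal(m$sd, 0.316228, tolerance = 1e-6)
  expect_equal(m$skew, 0)
  ## commutativity of the sum
  expect_equal(subtractive_moments(0.5, 0.1, 2.0, 0.3),
               subtractive_moments(2.0, 0.3, 0.5, 0.1))
})

test_that("divisive moments match the product-of-normals closed forms", {
  ## degenerate attenuation noise: a scaled normal
  expect_equal(unlist(divisive_moments(1.5, 0, 2, 0.3)),
               c(mean = 3, sd = 0.45, skew = 0))
  expect_equal(unlist(divisive_moments(1, 0, 2, 0.3)),
               c(mean = 2, sd = 0.3, skew = 0))
  ## frozen against a 1e7-draw Monte-Carlo product oracle
  m <- divisive_moments(1.61, 0.152, 2.0, 0.3)
  expect_equal(m$mean, 3.22, tolerance = 1e-12)
  expect_equal(m$sd, 0.57254, tolerance = 1e-4)
  expect_equal(m$skew, 0.21405, tolerance = 1e-4)
})

test_that("the explicit and delta-form divisive SDs and skews agree", {
  grid <- expand.grid(mK = c(1.2, 1.6, 2.0), sK = c(0.05, 0.15, 0.3),
                      mF = c(1, 2, 3.5), sF = c(0.2, 0.4))
  m <- divisive_moments(grid$mK, grid$sK, grid$mF, grid$sF)
  dK <- grid$mK / grid$sK
  dF <- grid$mF / grid$sF
  expect_equal(m$sd, grid$sK * grid$sF * sqrt(1 + dK^2 + dF^2),
               tolerance = 1e-12)
  expect_equal(m$skew, 6 * dK * dF / (1 + dK^2 + dF^2)^1.5,
               tolerance = 1e-12)
  ## positivity of skew and the excess-variability bound sd >= mean_K*sd_FI
  expect_true(all(m$skew > 0))
  expect_true(all(m$sd > grid$mK * grid$sF))
  expect_equal(divisive_moments(1.5, 0, 2, 0.3)$sd, 1.5 * 0.3)
})

test_that("skew-normal moment matching round-trips and clips at the bound", {
  ## symmetric case
  p0 <- skewnormal_from_moments(0, 1, 0)
  expect_equal(unlist(p0), c(xi = 0, omega = 1, alpha = 0))

  ## frozen values from the shape-equation root-find oracle
  p <- skewnormal_from_moments(3.22, 0.57254, 0.21405)
  expect_equal(p$xi, 2.766, tolerance = 1e-3)
  expect_equal(p$omega, 0.7307, tolerance = 1e-4)
  expect_equal(p$alpha, 1.241, tolerance = 1e-3)

  ## round-trip identity across the admissible skewness range
  for (g in c(-0.99, -0.5, -0.1, 0, 0.05, 0.3, 0.7, 0.99)) {
    pp <- skewnormal_from_moments(1.7, 0.4, g)
    mm <- skewnormal_moments(pp$xi, pp$omega, pp$alpha)
    expect_equal(unlist(mm), c(mean = 1.7, sd = 0.4, skew = g),
                 tolerance = 1e-8)
  }

  ## clipping with warning beyond the distributional supremum
  expect_warning(pc <- skewnormal_from_moments(0, 1, 2.0), "clipped")
  mc <- skewnormal_moments(pc$xi, pc$omega, pc$alpha)
  expect_equal(mc$skew, 0.995, tolerance = 1e-8)
  expect_error(skewnormal_from_moments(0, 0, 0), "sd")
})

test_that("skew-normal log-density is a density and reduces to the normal", {
  x <- seq(-4, 6, by = 0.5)
  expect_equal(skewnormal_logdensity(x, 1, 2, 0),
               dnorm(x, 1, 2, log = TRUE))
  expect_equal(skewnormal_logdensity(0, 0, 1, 0), log(1 / sqrt(2 * pi)))
  for (a in c(-3, 0.5, 4)) {
    z <- integrate(function(v) exp(skewnormal_logdensity(v, 0.5, 1.3, a)),
                   -Inf, Inf, rel.tol = 1e-10)$value
    expect_equal(z, 1, tolerance = 1e-6)
  }
})

test_that("divisive log-likelihood tracks the exact product density", {
  ## subtractive: peak value at the mean for one observation
  m <- subtractive_moments(0.5, 0.1, 2, 0.3)
  expect_equal(direct_force_loglik(m$mean, 0.5, 0.1, 2, 0.3, "subtractive"),
               dnorm(0, sd = m$sd, log = TRUE))
  ## divisive with sd_K = 0 reduces to a scaled normal likelihood
  y <- c(2.8, 3.1, 3.4)
  expect_equal(direct_force_loglik(y, 1.5, 0, 2, 0.3, "divisive"),
               sum(dnorm(y, 3, 0.45, log = TRUE)))
  ## per-observation agreement with the quadrature oracle at the
  ## empirically relevant parameters
  set.seed(42)
  yy <- sample_direct(500, 1.6, 0.15, 2, 0.3, "divisive")
  ll <- direct_force_loglik(yy, 1.6, 0.15, 2, 0.3, "divisive")
  ll_exact <- sum(log(product_normal_density(yy, 1.6, 0.15, 2, 0.3)))
  expect_lt(abs(ll - ll_exact) / length(yy), 0.01)
})

test_that("generative sampling matches the closed-form moments", {
  set.seed(7)
  expect_equal(sample_direct(5, 1.5, 0, 3, 0, "divisive"), rep(4.5, 5))
  set.seed(11)
  y <- sample_direct(2e5, 1.61, 0.152, 2, 0.3, "divisive")
  m <- divisive_moments(1.61, 0.152, 2, 0.3)
  expect_equal(mean(y), m$mean, tolerance = 3 * m$sd / sqrt(2e5) / m$mean)
  expect_equal(sd(y), m$sd, tolerance = 3 / sqrt(4e5))
  sk <- mean((y - mean(y))^3) / sd(y)^3
  expect_equal(sk, m$skew, tolerance = 3 * sqrt(6 / 2e5) / m$skew)
  ## determinism under seed
  set.seed(5); a <- sample_direct(10, 1.6, 0.15, 2, 0.3, "divisive")
  set.seed(5); b <- sample_direct(10, 1.6, 0.15, 2, 0.3, "divisive")
  expect_identical(a, b)
})

test_that("attenuation fraction is 1 - 1/mean_K", {
  expect_equal(round(attenuation_fraction(1.61), 2), 0.38)
  expect_equal(attenuation_fraction(1), 0)
  expect_equal(attenuation_fraction(2), 0.5)
  expect_error(attenuation_fraction(0), "> 0")
})
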