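#' Split-chain Gelman-Rubin convergence diagnostic
#'
#' Each chain is split in half and the potential scale reduction factor is
#' computed over the resulting half-chains. Values near 1 indicate
#' convergence. Returns `NaN` with a warning when the draws have zero total
#' variance (e.g. constant identical chains).
#'
#' @param x Draws of one parameter: a matrix with one column per chain, or
#'   a list of equal-length numeric vectors. At least 2 chains of at least
#'   4 draws.
#' @return The split-chain R-hat statistic.
#' @export
rhat <- function(x) {
  if (is.list(x)) x <- do.call(cbind, x)
  stopifnot(is.matrix(x), ncol(x) >= 2L, nrow(x) >= 4L)
  n <- nrow(x) %/% 2L
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(j)
    cbind(x[seq_len(n), j], x[n + seq_len(n), j])))
  w <- mean(apply(halves, 2L, stats::var))
  b <- n * stats::var(colMeans(halves))
  if (w == 0) {
    warning("zero within-chain variance; R-hat undefined")
    return(NaN)
  }
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Effective sample size from within-chain autocorrelation
#'
#' Initial-monotone-sequence estimator: lag autocorrelations averaged over
#' chains are summed in adjacent pairs, truncated at the first negative
#' pair sum, and the pair sums are forced non-increasing before summing.
#'
#' @param x Draws of one parameter, as in [rhat()]; a plain vector is
#'   treated as a single chain.
#' @return Estimated effective sample size (finite, positive).
#' @export
ess_autocorr <- function(x) {
  if (is.list(x)) x <- do.call(cbind, x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  n <- nrow(x); m <- ncol(x)
  stopifnot(n >= 2L)
  if (all(apply(x, 2L, stats::var) == 0)) return(n * m)
  lag_max <- min(n - 1L, max(4L, floor(10 * log10(n))) * 5L)
  rho <- rowMeans(vapply(seq_len(m), function(j)
    stats::acf(x[, j], lag.max = lag_max, plot = FALSE,
               demean = TRUE)$acf[, 1L, 1L],
    numeric(lag_max + 1L)))
  ## pair sums P_k = rho_{2k} + rho_{2k+1}, k = 0, 1, ...
  np <- (lag_max + 1L) %/% 2L
  p <- rho[2 * seq_len(np) - 1L] + rho[2 * seq_len(np)]
  neg <- which(p < 0)
  if (length(neg)) p <- p[seq_len(neg[1L] - 1L)]
  if (length(p) > 1L) p <- cummin(p)
  tau <- max(2 * sum(p) - 1, 1 / (n * m))  # rho_0 counted once
  min(n * m / tau, n * m)
}

#' Highest density interval from posterior draws
#'
#' The shortest interval containing `ceiling(mass * n)` of the sorted
#' draws; ties are broken by the smallest lower bound.
#'
#' @param draws Numeric vector of posterior draws.
#' @param mass Probability mass in (0, 1); 0.90 by default, matching the
#'   reporting convention for single posteriors (0.95 is used for group
#'   differences).
#' @return Numeric vector `c(lower, upper)`.
#' @export
hdi <- function(draws, mass = 0.90) {
  stopifnot(length(draws) >= 1L, mass > 0, mass < 1)
  s <- sort(draws)
  n <- length(s)
  m <- min(n, ceiling(mass * n))
  if (m == n) return(c(s[1L], s[n]))
  width <- s[seq.int(m, n)] - s[seq_len(n - m + 1L)]
  i <- which.min(width)  # which.min takes the first minimum: smallest lower
  c(s[i], s[i + m - 1L])
}

#' Deviance information criterion from posterior draws
#'
#' `D(theta) = -2 loglik(theta)`; `p_D = mean(D) - D(theta_bar)` with
#' `theta_bar` the posterior mean of the draws (on the scale in which they
#' are supplied — the fitting routines pass positive parameters on the log
#' scale); `DIC = mean(D) + p_D`. Lower is better.
#'
#' @param samples Matrix of posterior draws (rows = draws, columns =
#'   parameters) or a numeric vector for a single parameter.
#' @param loglik Function mapping one parameter vector to the data
#'   log-likelihood.
#' @param point Point estimate at which the plug-in deviance is evaluated;
#'   defaults to the column means of `samples`.
#' @return List with elements `DIC`, `p_D`, `D_bar` and `D_hat`.
#' @export
dic <- function(samples, loglik, point = NULL) {
  if (!is.matrix(samples)) samples <- matrix(samples, ncol = 1L)
  if (is.null(point)) point <- colMeans(samples)
  dev <- -2 * vapply(seq_len(nrow(samples)),
                     function(i) loglik(samples[i, ]), numeric(1))
  if (any(!is.finite(dev))) stop("non-finite deviance in posterior draws")
  d_hat <- -2 * loglik(point)
  if (!is.finite(d_hat)) stop("non-finite deviance at the posterior mean")
  d_bar <- mean(dev)
  p_d <- d_bar - d_hat
  list(DIC = d_bar + p_d, p_D = p_d, D_bar = d_bar, D_hat = d_hat)
}

#' Difference between two groups' posterior distributions
#'
#' The difference distribution is formed by paired subtraction of the two
#' groups' draws, resampled (seeded, with replacement) to a common length
#' when the chains are of unequal length. Reported are the median
#' difference (MD), the 95% HDI, and whether the HDI excludes zero — the
#' decision rule for rejecting a zero group difference.
#'
#' @param draws_a,draws_b Posterior draws of the same parameter in groups A
#'   and B; the difference is A - B.
#' @param mass HDI mass (0.95 by default, the group-difference convention).
#' @param seed Seed for the resampling when lengths differ.
#' @return List of class `fm_group_difference` with elements `MD`, `hdi`,
#'   `excludes_zero`, `mass`.
#' @export
group_difference <- function(draws_a, draws_b, mass = 0.95, seed = 1L) {
  na <- length(draws_a); nb <- length(draws_b)
  stopifnot(na >= 1L, nb >= 1L)
  if (na != nb) {
    n <- max(na, nb)
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(seed)
    if (na < n) draws_a <- sample(draws_a, n, replace = TRUE)
    if (nb < n) draws_b <- sample(draws_b, n, replace = TRUE)
  }
  d <- draws_a - draws_b
  h <- hdi(d, mass)
  structure(list(MD = stats::median(d), hdi = h,
                 excludes_zero = h[1L] > 0 || h[2L] < 0, mass = mass),
            class = "fm_group_difference")
}

#' @export
print.fm_group_difference <- function(x, ...) {
  cat(sprintf("MD = %.4g, %.0f%% HDI [%.4g, %.4g] — %s\n", x$MD,
              100 * x$mass, x$hdi[1], x$hdi[2],
              if (x$excludes_zero) "HDI excludes zero"
              else "HDI includes zero"))
  invisible(x)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Adaptive random-walk Metropolis sampler for a generic target
#'
#' A single-chain Gaussian random-walk Metropolis sampler with
#' Robbins-Monro adaptation of the proposal scale during burn-in (target
#' acceptance 0.35). This is the same kernel the hierarchical fitter uses
#' for its parameter blocks, exposed for validation against analytically
#' known posteriors.
#'
#' @param logpost Function of a numeric parameter vector returning the log
#'   target density (up to a constant).
#' @param init Initial parameter vector (finite `logpost`).
#' @param n_keep Draws to return after burn-in and thinning.
#' @param burn_in Burn-in iterations (adaptation happens only here).
#' @param thin Thinning factor.
#' @param scale Initial proposal SD.
#' @return Matrix of `n_keep` rows of draws.
#' @export
rw_metropolis <- function(logpost, init, n_keep = 2000L, burn_in = 500L,
                          thin = 1L, scale = 1) {
  d <- length(init)
  cur <- init
  lp <- logpost(cur)
  if (!is.finite(lp)) stop("non-finite log-posterior at init")
  total <- burn_in + n_keep * thin
  out <- matrix(NA_real_, n_keep, d)
  kept <- 0L
  for (t in seq_len(total)) {
    prop <- cur + scale * stats::rnorm(d)
    lpp <- logpost(prop)
    acc <- is.finite(lpp) && log(stats::runif(1)) < lpp - lp
    if (acc) { cur <- prop; lp <- lpp }
    if (t <= burn_in)
      scale <- scale * exp(min(0.25, t^-0.6) * ((if (acc) 1 else 0) - 0.35))
    if (t > burn_in && (t - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      out[kept, ] <- cur
    }
  }
  out
}
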