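## Closed-form predicted distributions of directly reproduced forces under
## the two attenuation mechanisms.
##
## Both models take the indirectly reproduced matching force at a given
## target level, F_I ~ N(mean_FI, sd_FI), as the unattenuated reference:
## it carries all perceptual, memory and comparison components except
## attenuation. The trial-level attenuation factor K ~ N(mean_K, sd_K) then
## maps F_I to the direct-condition matching force:
##   subtractive:  F_D = K + F_I     (fixed offset, any force level)
##   divisive:     F_D = K * F_I     (attenuation scales with intensity)

#' Predicted direct-force moments under subtractive attenuation
#'
#' The sum of two independent normals: mean `mean_K + mean_FI`, SD
#' `sqrt(sd_K^2 + sd_FI^2)`, skewness identically zero.
#'
#' @param mean_K,sd_K Mean and SD of the trial-level attenuation factor
#'   (newtons for the subtractive model).
#' @param mean_FI,sd_FI Mean and SD of the indirect matching force at the
#'   target level (newtons); `sd_FI > 0`.
#' @return Data frame with columns `mean`, `sd`, `skew` (one row per
#'   parameter combination; arguments are recycled).
#' @export
subtractive_moments <- function(mean_K, sd_K, mean_FI, sd_FI) {
  stopifnot(all(sd_K >= 0), all(sd_FI > 0))
  n <- max(length(mean_K), length(sd_K), length(mean_FI), length(sd_FI))
  data.frame(mean = rep_len(mean_K + mean_FI, n),
             sd = rep_len(sqrt(sd_K^2 + sd_FI^2), n),
             skew = rep_len(0, n))
}

#' Predicted direct-force moments under divisive attenuation
#'
#' The product of two independent normals `K * F_I` has mean
#' `mean_K * mean_FI`, variance
#' `mean_FI^2 sd_K^2 + (mean_K^2 + sd_K^2) sd_FI^2` and skewness
#' `6 mean_K mean_FI sd_K^2 sd_FI^2 / var^{3/2}`; in terms of the
#' signal-to-noise ratios `d_K = mean_K/sd_K` and `d_FI = mean_FI/sd_FI`
#' the SD is `sd_K sd_FI sqrt(1 + d_K^2 + d_FI^2)` and the skewness
#' `6 d_K d_FI / (1 + d_K^2 + d_FI^2)^{3/2}`. The explicit forms are used,
#' so `sd_K = 0` (a degenerate, scaled normal) is handled exactly.
#'
#' @inheritParams subtractive_moments
#' @return Data frame with columns `mean`, `sd`, `skew`.
#' @export
divisive_moments <- function(mean_K, sd_K, mean_FI, sd_FI) {
  stopifnot(all(mean_K > 0), all(sd_K >= 0), all(sd_FI > 0))
  n <- max(length(mean_K), length(sd_K), length(mean_FI), length(sd_FI))
  mean_K <- rep_len(mean_K, n); sd_K <- rep_len(sd_K, n)
  mean_FI <- rep_len(mean_FI, n); sd_FI <- rep_len(sd_FI, n)
  v <- mean_FI^2 * sd_K^2 + (mean_K^2 + sd_K^2) * sd_FI^2
  data.frame(mean = mean_K * mean_FI, sd = sqrt(v),
             skew = 6 * mean_K * mean_FI * sd_K^2 * sd_FI^2 / v^1.5)
}

## Supremum of the absolute skewness attainable by a skew-normal
## distribution; moment matching clips just below it.
.sn_skew_sup <- 0.9952717
.sn_skew_clip <- 0.995

#' Skew-normal distribution matched to given moments
#'
#' Returns the location `xi`, scale `omega` and shape `alpha` of the
#' skew-normal distribution whose analytic mean, SD and skewness equal the
#' inputs. The shape is obtained from the exact inversion of the skewness
#' equation: with `t = |skew|^(2/3)` and `b = ((4-pi)/2)^(2/3)`,
#' `delta^2 = (pi/2) t/(t + b)` and `alpha = delta/sqrt(1-delta^2)`.
#' Skewness magnitudes at or above 0.995 (just below the distributional
#' supremum ~0.9953) are clipped to 0.995 with a warning, so that
#' likelihood evaluation remains defined in extreme parameter corners.
#'
#' @param mean,sd,skew Target moments; `sd > 0`. Vectorised.
#' @return Data frame with columns `xi`, `omega`, `alpha`.
#' @seealso [skewnormal_moments()] for the inverse mapping.
#' @export
skewnormal_from_moments <- function(mean, sd, skew) {
  if (any(sd <= 0)) stop("sd must be > 0")
  n <- max(length(mean), length(sd), length(skew))
  mean <- rep_len(mean, n); sd <- rep_len(sd, n); skew <- rep_len(skew, n)
  clip <- abs(skew) >= .sn_skew_clip
  if (any(clip)) {
    warning("skewness magnitude >= ", .sn_skew_clip,
            " clipped to the skew-normal bound (", sum(clip), " value(s))")
    skew[clip] <- sign(skew[clip]) * .sn_skew_clip
  }
  t23 <- abs(skew)^(2 / 3)
  b23 <- ((4 - pi) / 2)^(2 / 3)
  delta <- sign(skew) * sqrt(pi / 2 * t23 / (t23 + b23))
  alpha <- delta / sqrt(1 - delta^2)
  mz <- delta * sqrt(2 / pi)           # mean of the standardised variate
  omega <- sd / sqrt(1 - mz^2)
  data.frame(xi = mean - omega * mz, omega = omega, alpha = alpha)
}

#' Analytic moments of a skew-normal distribution
#'
#' @param xi,omega,alpha Location, scale (> 0) and shape. Vectorised.
#' @return Data frame with columns `mean`, `sd`, `skew`.
#' @export
skewnormal_moments <- function(xi, omega, alpha) {
  stopifnot(all(omega > 0))
  delta <- alpha / sqrt(1 + alpha^2)
  mz <- delta * sqrt(2 / pi)
  data.frame(mean = xi + omega * mz,
             sd = omega * sqrt(1 - mz^2),
             skew = (4 - pi) / 2 * mz^3 / (1 - mz^2)^1.5)
}

#' Skew-normal log-density
#'
#' `log(2/omega * dnorm(z) * pnorm(alpha z))` with `z = (x - xi)/omega`.
#' Reduces to the normal log-density at `alpha = 0`.
#'
#' @param x Quantiles.
#' @param xi,omega,alpha Skew-normal parameters; `omega > 0`.
#' @return Log-density values.
#' @export
skewnormal_logdensity <- function(x, xi, omega, alpha) {
  stopifnot(all(omega > 0))
  z <- (x - xi) / omega
  log(2) - log(omega) + stats::dnorm(z, log = TRUE) +
    stats::pnorm(alpha * z, log.p = TRUE)
}

#' Log-likelihood of direct-condition matching forces
#'
#' Under the subtractive model the direct forces are normal with the
#' [subtractive_moments()] mean and SD; under the divisive model they follow
#' the moment-matched skew-normal approximation to the product of normals
#' ([divisive_moments()] then [skewnormal_from_moments()]).
#'
#' @param forces Observed direct matching forces (newtons), non-empty.
#' @inheritParams subtractive_moments
#' @param model `"subtractive"` or `"divisive"`.
#' @return Total log-likelihood (scalar).
#' @export
direct_force_loglik <- function(forces, mean_K, sd_K, mean_FI, sd_FI,
                                model = c("divisive", "subtractive")) {
  stopifnot(length(forces) >= 1L)
  model <- match.arg(model)
  if (model == "subtractive") {
    m <- subtractive_moments(mean_K, sd_K, mean_FI, sd_FI)
    sum(stats::dnorm(forces, m$mean, m$sd, log = TRUE))
  } else {
    m <- divisive_moments(mean_K, sd_K, mean_FI, sd_FI)
    p <- skewnormal_from_moments(m$mean, m$sd, m$skew)
    sum(skewnormal_logdensity(forces, p$xi, p$omega, p$alpha))
  }
}

#' Sample direct matching forces from the exact generative process
#'
#' Draws `K_i ~ N(mean_K, sd_K)` and `F_I,i ~ N(mean_FI, sd_FI)`
#' independently and returns `K_i * F_I,i` (divisive) or `K_i + F_I,i`
#' (subtractive). These are exact draws from the generative model, not from
#' the skew-normal approximation; negative draws are retained (defaults in
#' the synthetic generator keep their probability negligible). Uses R's
#' global RNG; seed with [set.seed()] for reproducibility.
#'
#' @param n Number of draws.
#' @inheritParams subtractive_moments
#' @param model `"divisive"` or `"subtractive"`.
#' @return Numeric vector of `n` simulated forces.
#' @export
sample_direct <- function(n, mean_K, sd_K, mean_FI, sd_FI,
                          model = c("divisive", "subtractive")) {
  stopifnot(n >= 1L, sd_K >= 0, sd_FI >= 0)
  model <- match.arg(model)
  k <- stats::rnorm(n, mean_K, sd_K)
  fi <- stats::rnorm(n, mean_FI, sd_FI)
  if (model == "divisive") k * fi else k + fi
}

#' Attenuation expressed as a fraction of the perceived force
#'
#' For a divisive attenuation factor `mean_K`, a directly self-generated
#' force is perceived at `1/mean_K` of its indirect counterpart, i.e.
#' attenuated by `1 - 1/mean_K`.
#'
#' @param mean_K Mean attenuation factor, > 0.
#' @return Attenuated fraction in (-Inf, 1).
#' @examples
#' attenuation_fraction(1.61)  # ~0.38
#' @export
attenuation_fraction <- function(mean_K) {
  if (any(mean_K <= 0)) stop("mean_K must be > 0")
  1 - 1 / mean_K
}
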