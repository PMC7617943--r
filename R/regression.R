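## Descriptive per-level regressions and default Bayes factors.
##
## The mixed-effects analyses of the original descriptive results are
## implemented as a transparent two-stage procedure: ordinary least squares
## per participant on the per-level summaries, followed by one-sample
## Jeffreys-Zellner-Siow tests on the participant coefficients against the
## reference values (slope 1 / intercept 0 for force regressions, slope 0
## for SD regressions). For balanced designs the two-stage estimates agree
## asymptotically with the mixed-model ones.

.reg_specs <- c("target", "mean_direct", "mean_indirect", "sd_direct",
                "sd_indirect")

## wide per-participant-per-level table from a level summary
.wide_levels <- function(summaries) {
  key <- paste(summaries$participant_id, round(summaries$target_force_N, 9))
  ids <- !duplicated(key)
  wide <- data.frame(participant_id = summaries$participant_id[ids],
                     target = summaries$target_force_N[ids],
                     stringsAsFactors = FALSE)
  wkey <- paste(wide$participant_id, round(wide$target, 9))
  for (cond in c("direct", "indirect")) {
    rows <- summaries[summaries$condition == cond, ]
    i <- match(wkey, paste(rows$participant_id,
                           round(rows$target_force_N, 9)))
    wide[[paste0("mean_", cond)]] <- rows$mean_match[i]
    wide[[paste0("sd_", cond)]] <- rows$sd_match[i]
  }
  wide
}

#' Per-participant ordinary least squares on level summaries
#'
#' Regresses one per-level quantity on another, separately for each
#' participant. Pairing of direct and indirect quantities is by target
#' force level — comparing matching forces in the two conditions for the
#' same target force isolates the attenuation component from shared memory
#' and comparison biases.
#'
#' @param summaries A level summary from [summarize_levels()].
#' @param x_spec,y_spec One of `"target"`, `"mean_direct"`,
#'   `"mean_indirect"`, `"sd_direct"`, `"sd_indirect"`.
#' @return Object of class `fm_pp_fit`: list with `coefficients` (one row
#'   per participant: `intercept`, `slope`, `n_levels`) and `points` (the
#'   underlying per-level x/y pairs).
#' @export
per_participant_fit <- function(summaries, x_spec, y_spec) {
  x_spec <- match.arg(x_spec, .reg_specs)
  y_spec <- match.arg(y_spec, .reg_specs)
  wide <- .wide_levels(summaries)
  coefs <- list(); pts <- list()
  for (pid in unique(wide$participant_id)) {
    w <- wide[wide$participant_id == pid, ]
    x <- w[[x_spec]]; y <- w[[y_spec]]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(unique(x)) < 2L)
      stop("participant ", pid, " has fewer than 2 distinct x values for ",
           x_spec)
    b <- stats::coef(stats::lm(y ~ x))
    coefs[[pid]] <- data.frame(participant_id = pid, intercept = b[[1]],
                               slope = b[[2]], n_levels = length(x),
                               stringsAsFactors = FALSE)
    pts[[pid]] <- data.frame(participant_id = pid, x = x, y = y,
                             stringsAsFactors = FALSE)
  }
  out <- list(coefficients = do.call(rbind, coefs),
              points = do.call(rbind, pts),
              x_spec = x_spec, y_spec = y_spec)
  rownames(out$coefficients) <- rownames(out$points) <- NULL
  class(out) <- "fm_pp_fit"
  out
}

#' @export
print.fm_pp_fit <- function(x, ...) {
  cat(sprintf("Per-participant OLS of %s on %s (%d participants)\n",
              x$y_spec, x$x_spec, nrow(x$coefficients)))
  cat(sprintf("  mean slope %.3f, mean intercept %.3f\n",
              mean(x$coefficients$slope), mean(x$coefficients$intercept)))
  invisible(x)
}

#' Population-level regression summary with default Bayes factors
#'
#' Averages the per-participant coefficients, attaches t-based 95%
#' confidence intervals, and tests each coefficient against its reference
#' value with a one-sample JZS Bayes factor. The R-squared is that of the
#' pooled OLS over all per-level points.
#'
#' @param ppfit An [per_participant_fit()] result; at least 3 participants.
#' @param slope_ref,intercept_ref Reference values for the hypothesis
#'   tests (defaults 1 and 0, the equality line).
#' @param scale JZS Cauchy prior scale (default `sqrt(2)/2`).
#' @return Object of class `fm_regression` with slope/intercept estimates,
#'   CIs, `r_squared`, `n_participants` and `bf10_slope`/`bf10_intercept`.
#' @export
population_regression <- function(ppfit, slope_ref = 1, intercept_ref = 0,
                                  scale = sqrt(2) / 2) {
  stopifnot(inherits(ppfit, "fm_pp_fit"))
  cf <- ppfit$coefficients
  n <- nrow(cf)
  if (n < 3L) stop("need at least 3 participants")
  est <- function(v, ref) {
    m <- mean(v); s <- stats::sd(v); sem <- s / sqrt(n)
    ci <- m + c(-1, 1) * stats::qt(0.975, n - 1) * sem
    t <- if (s == 0) { if (m == ref) 0 else sign(m - ref) * Inf }
         else (m - ref) / sem
    list(mean = m, ci = ci, t = t, bf10 = jzs_bf_onesample(t, n, scale))
  }
  sl <- est(cf$slope, slope_ref)
  ic <- est(cf$intercept, intercept_ref)
  pooled <- stats::lm(y ~ x, data = ppfit$points)
  structure(list(slope = sl$mean, intercept = ic$mean,
                 slope_ci95 = sl$ci, intercept_ci95 = ic$ci,
                 r_squared = summary(pooled)$r.squared,
                 n_participants = n,
                 bf10_slope = sl$bf10, bf10_intercept = ic$bf10,
                 slope_ref = slope_ref, intercept_ref = intercept_ref,
                 x_spec = ppfit$x_spec, y_spec = ppfit$y_spec),
            class = "fm_regression")
}

#' @export
print.fm_regression <- function(x, ...) {
  cat(sprintf("Regression of %s on %s (%d participants, R^2 = %.3f)\n",
              x$y_spec, x$x_spec, x$n_participants, x$r_squared))
  cat(sprintf("  slope     %.3f [%.3f, %.3f]  BF10 vs %g: %.3g\n",
              x$slope, x$slope_ci95[1], x$slope_ci95[2], x$slope_ref,
              x$bf10_slope))
  cat(sprintf("  intercept %.3f [%.3f, %.3f]  BF10 vs %g: %.3g\n",
              x$intercept, x$intercept_ci95[1], x$intercept_ci95[2],
              x$intercept_ref, x$bf10_intercept))
  invisible(x)
}

#' One-sample Jeffreys-Zellner-Siow Bayes factor
#'
#' The default Bayes factor for a one-sample t-test: a Cauchy(0, `scale`)
#' prior on the standardised effect size against the point null, computed
#' by adaptive quadrature over the scale mixture representation
#' (`g ~ InverseGamma(1/2, scale^2/2)`).
#'
#' @param t Observed t-statistic.
#' @param n Sample size (>= 2).
#' @param scale Cauchy prior scale, default `sqrt(2)/2`.
#' @return `BF10` (> 1 favours the alternative). `Inf` for infinite `t`.
#' @examples
#' jzs_bf_onesample(0, 20)   # < 1: null supported
#' jzs_bf_onesample(5, 20)   # ~341: strong evidence
#' @export
jzs_bf_onesample <- function(t, n, scale = sqrt(2) / 2) {
  stopifnot(n >= 2, scale > 0)
  if (!is.finite(t)) return(Inf)
  nu <- n - 1
  h0 <- -(nu + 1) / 2 * log1p(t^2 / nu)
  ## log-integrand over u = log(g) (mixture weight times likelihood
  ## ratio), integrated in a mode-centred form for numerical stability at
  ## large |t|
  logf <- function(u) {
    g <- exp(u)
    -0.5 * log1p(n * g) -
      (nu + 1) / 2 * log1p(t^2 / ((1 + n * g) * nu)) - h0 +
      0.5 * log(scale^2 / 2) - lgamma(0.5) - 1.5 * u -
      scale^2 / (2 * g) + u                     # Jacobian g du
  }
  peak <- stats::optimize(logf, c(-40, 40), maximum = TRUE)
  fmax <- peak$objective
  bf <- stats::integrate(function(u) exp(logf(u) - fmax), -40, 40,
                         rel.tol = 1e-10, abs.tol = 0)
  if (!is.finite(bf$value) || bf$value <= 0)
    stop("JZS integral did not converge")
  out <- fmax + log(bf$value)
  if (out > log(.Machine$double.xmax)) Inf else exp(out)
}

#' Paired direct-vs-indirect contrast of regression coefficients
#'
#' Computes per-participant differences (direct minus indirect) of a
#' regression coefficient and tests them against zero with a one-sample
#' JZS Bayes factor.
#'
#' @param pp_direct,pp_indirect [per_participant_fit()] results for the
#'   direct and indirect conditions, same participants.
#' @param quantity `"slope"` or `"intercept"`.
#' @param scale JZS Cauchy prior scale.
#' @return Object of class `fm_contrast`: list with `mean_diff`, `sd_diff`,
#'   `t`, `n`, `bf10` and the per-participant `diffs`.
#' @export
condition_contrast <- function(pp_direct, pp_indirect,
                               quantity = c("slope", "intercept"),
                               scale = sqrt(2) / 2) {
  quantity <- match.arg(quantity)
  a <- pp_direct$coefficients; b <- pp_indirect$coefficients
  if (!setequal(a$participant_id, b$participant_id))
    stop("participant sets differ between conditions")
  b <- b[match(a$participant_id, b$participant_id), ]
  d <- a[[quantity]] - b[[quantity]]
  n <- length(d)
  m <- mean(d); s <- stats::sd(d)
  t <- if (s == 0) { if (m == 0) 0 else sign(m) * Inf }
       else m / (s / sqrt(n))
  structure(list(quantity = quantity, mean_diff = m, sd_diff = s, t = t,
                 n = n, bf10 = jzs_bf_onesample(t, n, scale), diffs = d),
            class = "fm_contrast")
}

#' @export
print.fm_contrast <- function(x, ...) {
  cat(sprintf("Direct - indirect %s: mean %.3f (sd %.3f, n = %d), BF10 = %.3g\n",
              x$quantity, x$mean_diff, x$sd_diff, x$n, x$bf10))
  invisible(x)
}
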