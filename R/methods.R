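#' @export
print.fm_fit <- function(x, ...) {
  cat(sprintf("Hierarchical %s attenuation model fit\n", x$model))
  cat(sprintf("  %d participants, %d direct + %d indirect trials, %d levels\n",
              length(x$data$pids), x$data$n_direct, x$data$n_indirect,
              length(x$data$levels)))
  cat(sprintf("  %d chains x %d kept draws (burn-in %d, thin %d)\n",
              x$control$n_chains, x$control$samples_per_chain,
              x$control$burn_in, x$control$thin))
  cat(sprintf("  DIC = %.1f (p_D = %.1f); max population R-hat = %.3f%s\n",
              x$dic$DIC, x$dic$p_D,
              max(x$rhat[startsWith(x$par_names, "pop.")], na.rm = TRUE),
              if (x$converged) "" else "  ** not converged **"))
  invisible(x)
}

#' Summarise a fitted attenuation model
#'
#' Posterior medians, 90% HDIs and convergence diagnostics for the
#' population-level parameters, plus the DIC decomposition. For the
#' divisive model, the population median attenuation factor is also
#' reported as an attenuated fraction, `1 - 1/mean_K`.
#'
#' @param object An `fm_fit`.
#' @param mass HDI mass for the parameter table.
#' @param ... Unused.
#' @return An object of class `summary.fm_fit` with a `population` table.
#' @export
summary.fm_fit <- function(object, mass = 0.90, ...) {
  m <- .fm_draw_matrix(object)
  pop <- object$par_names[startsWith(object$par_names, "pop.")]
  tab <- do.call(rbind, lapply(pop, function(p) {
    h <- hdi(m[, p], mass)
    data.frame(parameter = p, median = stats::median(m[, p]),
               hdi_lower = h[1], hdi_upper = h[2],
               rhat = object$rhat[[p]], ess = object$ess[[p]],
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(model = object$model, population = tab, dic = object$dic,
                 mass = mass, converged = object$converged,
                 attenuation_fraction = if (object$model == "divisive")
                   attenuation_fraction(tab$median[tab$parameter ==
                                                     "pop.mean_K"])
                 else NA_real_,
                 n_participants = length(object$data$pids)),
            class = "summary.fm_fit")
}

#' @export
print.summary.fm_fit <- function(x, ...) {
  cat(sprintf("%s attenuation model — population parameters (%d%% HDI)\n",
              tools::toTitleCase(x$model), round(100 * x$mass)))
  tab <- x$population
  tab$median <- signif(tab$median, 4)
  tab$hdi_lower <- signif(tab$hdi_lower, 4)
  tab$hdi_upper <- signif(tab$hdi_upper, 4)
  tab$rhat <- round(tab$rhat, 3)
  tab$ess <- round(tab$ess)
  print(tab, row.names = FALSE)
  if (!is.na(x$attenuation_fraction))
    cat(sprintf("Attenuated fraction at the population median: %.2f\n",
                x$attenuation_fraction))
  cat(sprintf("DIC = %.1f  (D_bar = %.1f, p_D = %.1f)\n",
              x$dic$DIC, x$dic$D_bar, x$dic$p_D))
  if (!x$converged) cat("Warning: population-level R-hat >= 1.1\n")
  invisible(x)
}

#' Posterior medians of all parameters
#'
#' @param object An `fm_fit`.
#' @param ... Unused.
#' @return Named numeric vector of posterior medians.
#' @export
coef.fm_fit <- function(object, ...) {
  m <- .fm_draw_matrix(object)
  apply(m, 2L, stats::median)
}

#' Predicted matching-force distributions at the posterior medians
#'
#' For each participant and target level, the predicted mean, SD and
#' skewness of the matching force in each condition, evaluated at the
#' posterior medians of the participant's parameters.
#'
#' @param object An `fm_fit`.
#' @param ... Unused.
#' @return Data frame with one row per participant, condition and level.
#' @export
predict.fm_fit <- function(object, ...) {
  cf <- coef(object)
  lv <- object$data$levels
  rows <- list()
  for (pid in object$data$pids) {
    K <- cf[paste0("K[", pid, "]")]
    sK <- if (object$control$share_sd_K) cf["sd_K"]
          else cf[paste0("sd_K[", pid, "]")]
    for (l in lv) {
      ip <- .indirect_pars_for(object, cf, pid, l)
      mom <- if (object$model == "divisive")
        divisive_moments(K, sK, ip$mu, ip$sig)
      else subtractive_moments(K, sK, ip$mu, ip$sig)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pid, target_force_N = l,
        condition = c("direct", "indirect"),
        mean = c(mom$mean, ip$mu), sd = c(mom$sd, ip$sig),
        skew = c(mom$skew, 0), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## indirect (mu, sigma) for one participant/level from a coefficient vector,
## honouring fixed_indirect fits
.indirect_pars_for <- function(fit, cf, pid, level) {
  if (!is.null(fit$fixed_indirect)) {
    i <- which(abs(fit$fixed_indirect$target_force_N - level) < 1e-9)
    list(mu = fit$fixed_indirect$mean_FI[i],
         sig = fit$fixed_indirect$sd_FI[i])
  } else {
    lab <- paste0("[", pid, ",", .lv_lab(level), "]")
    list(mu = unname(cf[paste0("mu_I", lab)]),
         sig = unname(cf[paste0("sigma_I", lab)]))
  }
}

#' Residual per-level mean matching forces
#'
#' Observed per-level mean matching force minus the model prediction at
#' the posterior medians, per participant, condition and level.
#'
#' @param object An `fm_fit`.
#' @param trials The `fm_trials` data the model was fitted to.
#' @param ... Unused.
#' @return Data frame with a `residual` column (newtons).
#' @export
residuals.fm_fit <- function(object, trials, ...) {
  obs <- summarize_levels(trials)
  pred <- predict(object)
  key <- function(d) paste(d$participant_id, d$condition,
                           round(d$target_force_N, 9))
  i <- match(key(obs), key(pred))
  out <- obs[!is.na(i), c("participant_id", "condition", "target_force_N",
                          "mean_match")]
  out$predicted <- pred$mean[i[!is.na(i)]]
  out$residual <- out$mean_match - out$predicted
  rownames(out) <- NULL
  out
}

#' Posterior predictive replication (simulate method)
#'
#' Convenience wrapper around [pp_replicate()].
#'
#' @param object An `fm_fit`.
#' @param nsim Number of posterior predictive simulations.
#' @param seed Integer seed.
#' @param trials The observed `fm_trials` whose structure is replicated.
#' @param ... Unused.
#' @return An `fm_ppc` ensemble; see [pp_replicate()].
#' @export
simulate.fm_fit <- function(object, nsim = 1000L, seed = 1L, trials, ...) {
  pp_replicate(object, trials, n_sims = nsim, seed = seed)
}

#' Plot a fitted attenuation model
#'
#' `which = "posterior"` draws the posterior densities of the population
#' mean and SD of the attenuation factor with their medians;
#' `which = "ppc"` overlays observed matching-force histograms with
#' posterior predictive densities per condition (requires `trials` and an
#' ensemble from [pp_replicate()]).
#'
#' @param x An `fm_fit`.
#' @param which `"posterior"` or `"ppc"`.
#' @param trials,ensemble Required for `which = "ppc"`.
#' @param ... Passed to plotting primitives.
#' @return Invisibly, `x`.
#' @export
plot.fm_fit <- function(x, which = c("posterior", "ppc"), trials = NULL,
                        ensemble = NULL, ...) {
  which <- match.arg(which)
  m <- .fm_draw_matrix(x)
  if (which == "posterior") {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
    for (p in c("pop.mean_K", "pop.scale_sd_K")) {
      dd <- stats::density(m[, p])
      graphics::plot(dd, main = p, xlab = "value", ...)
      graphics::abline(v = stats::median(m[, p]), lty = 2)
    }
  } else {
    if (is.null(trials) || is.null(ensemble))
      stop("which = 'ppc' needs trials and ensemble")
    conds <- unique(ensemble$cells$condition)
    op <- graphics::par(mfrow = c(1, length(conds)))
    on.exit(graphics::par(op))
    for (cond in conds) {
      oc <- trials$matching_force_N[trials$condition == cond]
      idx <- which(ensemble$cells$condition == cond)
      rep_all <- unlist(lapply(ensemble$draws[idx], as.vector))
      graphics::hist(oc, breaks = 30, freq = FALSE,
                     main = paste(cond, "condition"),
                     xlab = "matching force (N)", ...)
      graphics::lines(stats::density(rep_all), lwd = 2)
    }
  }
  invisible(x)
}
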