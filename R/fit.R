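## Hierarchical Bayesian fitting of the attenuation models.
##
## Likelihood: indirect trials of participant i at level l are
## N(mu_I[i,l], sigma_I[i,l]); direct trials are normal (subtractive) or
## moment-matched skew-normal (divisive) with moments determined by the
## participant's attenuation parameters (mean_K, sd_K) and the same
## indirect level parameters. Attenuation parameters are tied across
## participants by a population prior (truncated-normal location for
## mean_K, half-normal scale for sd_K). Positive parameters are sampled on
## the log scale. The sampler is adaptive random-walk Metropolis within
## Gibbs over blocks: one 2-d block per participant (attenuation), one 2-d
## block per participant-level cell (indirect), and scalar blocks for the
## population parameters; proposal scales adapt during burn-in only.

#' Prior specification for the hierarchical attenuation model
#'
#' Defaults: the population location of the mean attenuation factor has a
#' Normal(1, 1) prior truncated to positive values under the divisive model
#' and Normal(0, 2) under the subtractive model; all population scales and
#' noise SDs have half-Normal(1) priors; indirect level means have
#' Normal(level, 2 N) priors.
#'
#' @param model `"divisive"` or `"subtractive"`.
#' @param mean_K_loc,mean_K_scale Normal hyperprior on the population
#'   location of `mean_K`.
#' @param tau_scale Half-normal scale of the between-participant SD of
#'   `mean_K`.
#' @param sdK_scale Half-normal scale of the population scale of `sd_K`.
#' @param muI_scale SD (N) of the normal prior centring each indirect level
#'   mean on its target level.
#' @param sigI_scale Half-normal scale (N) for the indirect level SDs.
#' @return List of class `fm_priors`.
#' @export
fm_priors <- function(model = c("divisive", "subtractive"),
                      mean_K_loc = if (model == "divisive") 1 else 0,
                      mean_K_scale = if (model == "divisive") 1 else 2,
                      tau_scale = 1, sdK_scale = 1, muI_scale = 2,
                      sigI_scale = 1) {
  model <- match.arg(model)
  stopifnot(mean_K_scale > 0, tau_scale > 0, sdK_scale > 0, muI_scale > 0,
            sigI_scale > 0)
  structure(list(model = model, mean_K_loc = mean_K_loc,
                 mean_K_scale = mean_K_scale, tau_scale = tau_scale,
                 sdK_scale = sdK_scale, muI_scale = muI_scale,
                 sigI_scale = sigI_scale),
            class = "fm_priors")
}

#' MCMC settings
#'
#' Defaults are a desk-scale configuration (3 chains, 2000 kept draws per
#' chain after 1000 burn-in, thinning 2) adequate for simulation studies;
#' `samples_per_chain = 10000` gives the full-scale configuration used for
#' final inference.
#'
#' @param n_chains Number of parallel chains.
#' @param samples_per_chain Kept draws per chain (after burn-in/thinning).
#' @param burn_in Discarded initial iterations per chain; proposal
#'   adaptation happens only here.
#' @param thin Thinning factor.
#' @param seed Integer seed; all chains derive their streams from it.
#' @param share_sd_K If `TRUE`, a single `sd_K` is shared by all
#'   participants instead of the hierarchical per-participant version
#'   (sensitivity switch).
#' @return List of class `fm_control`.
#' @export
fm_control <- function(n_chains = 3L, samples_per_chain = 2000L,
                       burn_in = 1000L, thin = 2L, seed = 1L,
                       share_sd_K = FALSE) {
  stopifnot(n_chains >= 1L, samples_per_chain >= 1L, burn_in >= 0L,
            thin >= 1L)
  structure(list(n_chains = as.integer(n_chains),
                 samples_per_chain = as.integer(samples_per_chain),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), share_sd_K = isTRUE(share_sd_K)),
            class = "fm_control")
}

## ---- internal: vectorised trial log-densities ----

.b23 <- ((4 - pi) / 2)^(2 / 3)

## canonical label for a target level inside parameter names
.lv_lab <- function(l) sprintf("%.6g", l)

## skew-normal log-density for moment triples (m, s, g), silently clipping
## |skew| at the representable bound (hot path of the sampler)
.sn_ll <- function(y, m, s, g) {
  g <- pmax(pmin(g, .sn_skew_clip), -.sn_skew_clip)
  t23 <- abs(g)^(2 / 3)
  delta <- sign(g) * sqrt(pi / 2 * t23 / (t23 + .b23))
  mz <- delta * sqrt(2 / pi)
  om <- s / sqrt(1 - mz^2)
  xi <- m - om * mz
  z <- (y - xi) / om
  log(2) - log(om) + stats::dnorm(z, log = TRUE) +
    stats::pnorm((delta / sqrt(1 - delta^2)) * z, log.p = TRUE)
}

## direct-trial log-density under either model, all arguments per-trial
.direct_ll <- function(y, K, sK, mu, sig, divisive) {
  if (!divisive)
    return(stats::dnorm(y, K + mu, sqrt(sK^2 + sig^2), log = TRUE))
  v <- mu^2 * sK^2 + (K^2 + sK^2) * sig^2
  .sn_ll(y, K * mu, sqrt(v), 6 * K * mu * sK^2 * sig^2 / v^1.5)
}

.half_norm_lp <- function(x, s) 0.5 * log(2 / pi) - log(s) - x^2 / (2 * s^2)

## fixed-length group sums
.sum_by <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s
  out
}

## ---- internal: data preparation ----

.fm_prep <- function(trials, model, fixed_indirect) {
  trials <- as_fm_trials(trials)
  pids <- sort(unique(trials$participant_id))
  P <- length(pids)
  lv <- sort(unique(round(trials$target_force_N, 9)))
  L <- length(lv)
  pidx <- match(trials$participant_id, pids)
  lidx <- match(round(trials$target_force_N, 9), lv)
  dir <- trials$condition == "direct"
  if (!any(dir)) stop("dataset contains no direct-condition trials")
  if (!any(!dir) && is.null(fixed_indirect))
    stop("dataset contains no indirect trials; supply fixed_indirect ",
         "parameters to fit direct-only data")
  fixed <- !is.null(fixed_indirect)
  if (fixed) {
    stopifnot(is.data.frame(fixed_indirect),
              all(c("target_force_N", "mean_FI", "sd_FI") %in%
                    names(fixed_indirect)))
    fl <- round(fixed_indirect$target_force_N, 9)
    miss <- setdiff(lv[unique(lidx[dir])], fl)
    if (length(miss))
      stop("fixed indirect parameters missing level(s): ",
           paste(format(miss), collapse = ", "))
    ford <- match(lv, fl)
  }
  list(trials = trials, pids = pids, P = P, lv = lv, L = L,
       yd = trials$matching_force_N[dir], pd = pidx[dir],
       cd = (pidx[dir] - 1L) * L + lidx[dir],
       yi = trials$matching_force_N[!dir], pi_ = pidx[!dir],
       ci = (pidx[!dir] - 1L) * L + lidx[!dir],
       fixed = fixed,
       f_mu = if (fixed) fixed_indirect$mean_FI[ford] else NULL,
       f_sig = if (fixed) fixed_indirect$sd_FI[ford] else NULL)
}

## ---- the fitter ----

#' Fit a hierarchical attenuation model to force-matching trials
#'
#' Estimates, for each participant, the mean and SD of the trial-level
#' attenuation factor together with per-level indirect matching
#' distributions, tied by population-level parameters, using adaptive
#' Metropolis-within-Gibbs MCMC. See the package vignette for the model
#' specification.
#'
#' @param trials An `fm_trials` data frame with direct (and normally
#'   indirect) condition trials.
#' @param model `"divisive"` or `"subtractive"`.
#' @param priors An [fm_priors()] specification.
#' @param control An [fm_control()] MCMC configuration.
#' @param fixed_indirect Optional data frame with columns
#'   `target_force_N`, `mean_FI`, `sd_FI`: per-level indirect parameters to
#'   hold fixed for all participants (used to fit direct-only gain-block
#'   data); see [indirect_level_params()].
#' @param verbose Print progress per chain.
#' @return An object of class `fm_fit`; see [summary.fm_fit()],
#'   [coef.fm_fit()], [simulate.fm_fit()].
#' @export
fm_fit <- function(trials, model = c("divisive", "subtractive"),
                   priors = fm_priors(model), control = fm_control(),
                   fixed_indirect = NULL, verbose = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(priors, "fm_priors"), inherits(control, "fm_control"))
  if (priors$model != model) priors <- fm_priors(model)
  d <- .fm_prep(trials, model, fixed_indirect)
  div <- model == "divisive"
  P <- d$P; L <- d$L; C <- P * L
  lv_cell <- rep(d$lv, P)           # level value for each cell
  shared <- control$share_sd_K

  ## empirical initial values
  emp_mu <- rep(lv_cell); emp_sig <- rep(0.2, C)
  if (length(d$yi)) {
    cnt <- .sum_by(rep(1, length(d$yi)), d$ci, C)
    smu <- .sum_by(d$yi, d$ci, C)
    emp_mu[cnt > 0] <- smu[cnt > 0] / cnt[cnt > 0]
    ssq <- .sum_by(d$yi^2, d$ci, C)
    ok <- cnt >= 2
    s2 <- pmax((ssq[ok] - cnt[ok] * emp_mu[ok]^2) / (cnt[ok] - 1), 1e-4)
    emp_sig[ok] <- pmax(sqrt(s2), 0.05)
  }
  if (d$fixed) {
    emp_mu <- rep(d$f_mu, P)
    emp_sig <- rep(d$f_sig, P)
  }
  md <- .sum_by(d$yd, d$pd, P) / .sum_by(rep(1, length(d$yd)), d$pd, P)
  mi <- .sum_by(emp_mu[d$cd], d$pd, P) /
    .sum_by(rep(1, length(d$yd)), d$pd, P)
  K0 <- if (div) pmin(pmax(md / mi, 0.2, na.rm = TRUE), 5) else md - mi

  n_keep <- control$samples_per_chain
  par_names <- c("pop.mean_K", "pop.sd_mean_K", "pop.scale_sd_K",
                 paste0("K[", d$pids, "]"),
                 if (shared) "sd_K" else paste0("sd_K[", d$pids, "]"),
                 if (!d$fixed) c(
                   paste0("mu_I[", rep(d$pids, each = L), ",",
                          .lv_lab(lv_cell), "]"),
                   paste0("sigma_I[", rep(d$pids, each = L), ",",
                          .lv_lab(lv_cell), "]")))
  npar <- length(par_names)

  chains <- vector("list", control$n_chains)
  logliks <- vector("list", control$n_chains)
  state_sum <- NULL; state_n <- 0L

  run_chain <- function(chain) {
    set.seed(control$seed + 977L * chain)
    ## initial state (sampling scale), jittered per chain, with retries on
    ## a non-finite posterior
    for (try in 1:20) {
      j <- function(x, s = 0.05) x + stats::rnorm(length(x), 0, s)
      aK <- j(if (div) log(K0) else K0)
      aS <- j(rep(log(0.1), if (shared) 1L else P))
      bM <- j(emp_mu); bS <- j(log(emp_sig))
      if (d$fixed) { bM <- rep(d$f_mu, P); bS <- log(rep(d$f_sig, P)) }
      Kn <- if (div) exp(aK) else aK
      hm <- if (div) log(max(mean(Kn), 1e-3)) else mean(Kn)
      ht <- log(max(stats::sd(Kn), 0.05))
      hs <- log(0.1)
      sKn <- exp(aS); if (shared) sKn <- rep(sKn, P)
      tld <- .direct_ll(d$yd, Kn[d$pd], sKn[d$pd], bM[d$cd],
                        exp(bS)[d$cd], div)
      tli <- if (length(d$yi))
        stats::dnorm(d$yi, bM[d$ci], exp(bS)[d$ci], log = TRUE)
      else numeric(0)
      if (all(is.finite(c(tld, tli)))) break
      if (try == 20) stop("could not find a finite initial posterior")
    }
    saK <- rep(0.1, P)                    # attenuation mean proposal scales
    saS <- rep(0.3, P)                    # attenuation SD proposal scales
    sb <- rep(0.1, C)                     # indirect cell block scales
    sh <- rep(0.1, 4L)                    # pop.mean, pop.tau, pop.s, shared sd_K
    draws <- matrix(NA_real_, n_keep, npar,
                    dimnames = list(NULL, par_names))
    ll_keep <- numeric(n_keep)
    total <- control$burn_in + n_keep * control$thin
    kept <- 0L

    pop_lp <- function(Kn_, mu, tau) {
      out <- sum(stats::dnorm(Kn_, mu, tau, log = TRUE))
      if (div) out <- out - P * stats::pnorm(mu / tau, log.p = TRUE)
      out
    }

    for (t in seq_len(total)) {
      adapting <- t <= control$burn_in
      gam <- if (adapting) min(0.25, t^-0.6) else 0
      sig_cell <- exp(bS)
      sKn <- exp(aS); if (shared) sKn <- rep(sKn, P)
      mu_pop <- if (div) exp(hm) else hm
      tau_pop <- exp(ht); s_pop <- exp(hs)

      ## -- attenuation mean blocks (per participant, 1-d, parallel) --
      aKp <- aK + saK * stats::rnorm(P)
      Kp <- if (div) exp(aKp) else aKp
      tldp <- .direct_ll(d$yd, Kp[d$pd], sKn[d$pd], bM[d$cd],
                         sig_cell[d$cd], div)
      tldp[!is.finite(tldp)] <- -Inf
      llp <- .sum_by(tldp, d$pd, P); llc <- .sum_by(tld, d$pd, P)
      Kn <- if (div) exp(aK) else aK
      prc <- stats::dnorm(Kn, mu_pop, tau_pop, log = TRUE) +
        (if (div) aK else 0)
      prp <- stats::dnorm(Kp, mu_pop, tau_pop, log = TRUE) +
        (if (div) aKp else 0)
      acc <- log(stats::runif(P)) < (llp + prp) - (llc + prc)
      acc[!is.finite(llp)] <- FALSE
      if (any(acc)) {
        aK[acc] <- aKp[acc]
        at <- acc[d$pd]
        tld[at] <- tldp[at]
      }
      saK <- saK * exp(gam * (as.numeric(acc) - 0.35))

      ## -- attenuation SD blocks (per participant, 1-d, parallel) --
      if (!shared) {
        Kn <- if (div) exp(aK) else aK
        aSp <- aS + saS * stats::rnorm(P)
        sKp <- exp(aSp)
        tldp <- .direct_ll(d$yd, Kn[d$pd], sKp[d$pd], bM[d$cd],
                           sig_cell[d$cd], div)
        tldp[!is.finite(tldp)] <- -Inf
        llp <- .sum_by(tldp, d$pd, P); llc <- .sum_by(tld, d$pd, P)
        prc <- .half_norm_lp(sKn, s_pop) + aS
        prp <- .half_norm_lp(sKp, s_pop) + aSp
        acc <- log(stats::runif(P)) < (llp + prp) - (llc + prc)
        acc[!is.finite(llp)] <- FALSE
        if (any(acc)) {
          aS[acc] <- aSp[acc]
          at <- acc[d$pd]
          tld[at] <- tldp[at]
        }
        saS <- saS * exp(gam * (as.numeric(acc) - 0.35))
        sKn <- exp(aS)
      }

      ## -- shared sd_K scalar block --
      if (shared) {
        aSp1 <- aS + sh[4] * stats::rnorm(1)
        Kn <- if (div) exp(aK) else aK
        tldp <- .direct_ll(d$yd, Kn[d$pd], rep(exp(aSp1), length(d$pd)),
                           bM[d$cd], sig_cell[d$cd], div)
        tldp[!is.finite(tldp)] <- -Inf
        la <- sum(tldp) + .half_norm_lp(exp(aSp1), s_pop) + aSp1 -
          (sum(tld) + .half_norm_lp(exp(aS), s_pop) + aS)
        acc1 <- log(stats::runif(1)) < la
        if (acc1) { aS <- aSp1; tld <- tldp }
        sh[4] <- sh[4] * exp(gam * (as.numeric(acc1) - 0.35))
      }

      ## -- indirect cell blocks --
      if (!d$fixed) {
        Kn <- if (div) exp(aK) else aK
        sKn <- exp(aS); if (shared) sKn <- rep(sKn, P)
        bMp <- bM + sb * stats::rnorm(C)
        bSp <- bS + sb * stats::rnorm(C)
        sigp <- exp(bSp)
        tlip <- stats::dnorm(d$yi, bMp[d$ci], sigp[d$ci], log = TRUE)
        tldp <- .direct_ll(d$yd, Kn[d$pd], sKn[d$pd], bMp[d$cd],
                           sigp[d$cd], div)
        tldp[!is.finite(tldp)] <- -Inf
        tlip[!is.finite(tlip)] <- -Inf
        llp <- .sum_by(tlip, d$ci, C) + .sum_by(tldp, d$cd, C)
        llc <- .sum_by(tli, d$ci, C) + .sum_by(tld, d$cd, C)
        prc <- stats::dnorm(bM, lv_cell, priors$muI_scale, log = TRUE) +
          .half_norm_lp(sig_cell, priors$sigI_scale) + bS
        prp <- stats::dnorm(bMp, lv_cell, priors$muI_scale, log = TRUE) +
          .half_norm_lp(sigp, priors$sigI_scale) + bSp
        acc <- log(stats::runif(C)) < (llp + prp) - (llc + prc)
        acc[!is.finite(llp)] <- FALSE
        if (any(acc)) {
          bM[acc] <- bMp[acc]; bS[acc] <- bSp[acc]
          ai <- acc[d$ci]; ad <- acc[d$cd]
          tli[ai] <- tlip[ai]; tld[ad] <- tldp[ad]
        }
        sb <- sb * exp(gam * (as.numeric(acc) - 0.35))
      }

      ## -- population blocks (scalar RW each; several sweeps per
      ## iteration, as these conditionals are cheap and mix the
      ## hierarchy) --
      Kn <- if (div) exp(aK) else aK
      for (sweep in 1:3) {
      ## location of mean_K
      hmp <- hm + sh[1] * stats::rnorm(1)
      mu_p <- if (div) exp(hmp) else hmp
      la <- pop_lp(Kn, mu_p, tau_pop) - pop_lp(Kn, mu_pop, tau_pop) +
        stats::dnorm(mu_p, priors$mean_K_loc, priors$mean_K_scale,
                     log = TRUE) -
        stats::dnorm(mu_pop, priors$mean_K_loc, priors$mean_K_scale,
                     log = TRUE) + (if (div) hmp - hm else 0)
      acc1 <- is.finite(la) && log(stats::runif(1)) < la
      if (acc1) { hm <- hmp; mu_pop <- mu_p }
      sh[1] <- sh[1] * exp(gam * (as.numeric(acc1) - 0.35))
      ## between-participant SD of mean_K
      htp <- ht + sh[2] * stats::rnorm(1)
      tau_p <- exp(htp)
      la <- pop_lp(Kn, mu_pop, tau_p) - pop_lp(Kn, mu_pop, tau_pop) +
        .half_norm_lp(tau_p, priors$tau_scale) -
        .half_norm_lp(tau_pop, priors$tau_scale) + htp - ht
      acc1 <- is.finite(la) && log(stats::runif(1)) < la
      if (acc1) { ht <- htp; tau_pop <- tau_p }
      sh[2] <- sh[2] * exp(gam * (as.numeric(acc1) - 0.35))
      ## population scale of sd_K
      if (!shared) {
        sKn <- exp(aS)
        hsp <- hs + sh[3] * stats::rnorm(1)
        la <- sum(.half_norm_lp(sKn, exp(hsp))) -
          sum(.half_norm_lp(sKn, exp(hs))) +
          .half_norm_lp(exp(hsp), priors$sdK_scale) -
          .half_norm_lp(exp(hs), priors$sdK_scale) + hsp - hs
        acc1 <- is.finite(la) && log(stats::runif(1)) < la
        if (acc1) hs <- hsp
        sh[3] <- sh[3] * exp(gam * (as.numeric(acc1) - 0.35))
      }
      }

      ## -- record --
      if (!adapting && (t - control$burn_in) %% control$thin == 0L) {
        kept <- kept + 1L
        Kn <- if (div) exp(aK) else aK
        nat <- c(if (div) exp(hm) else hm, exp(ht), exp(hs), Kn, exp(aS),
                 if (!d$fixed) c(bM, exp(bS)))
        draws[kept, ] <- nat
        ll_keep[kept] <- sum(tld) + sum(tli)
        samp <- c(hm, ht, hs, aK, aS, if (!d$fixed) c(bM, bS))
        if (is.null(state_sum)) state_sum <<- numeric(length(samp))
        state_sum <<- state_sum + samp
        state_n <<- state_n + 1L
      }
    }
    if (verbose)
      message(sprintf("chain %d done (%d kept draws)", chain, kept))
    list(draws = draws, ll = ll_keep)
  }

  t0 <- proc.time()[["elapsed"]]
  for (ch in seq_len(control$n_chains)) {
    res <- run_chain(ch)
    chains[[ch]] <- res$draws
    logliks[[ch]] <- res$ll
  }
  runtime <- proc.time()[["elapsed"]] - t0

  ## deviance at the posterior mean (sampling scale)
  sbar <- state_sum / state_n
  i <- 0L
  take <- function(k) { out <- sbar[i + seq_len(k)]; i <<- i + k; out }
  hm_b <- take(1L); ht_b <- take(1L); hs_b <- take(1L)
  aK_b <- take(P); aS_b <- take(if (shared) 1L else P)
  if (!d$fixed) { bM_b <- take(C); bS_b <- take(C) }
  else { bM_b <- rep(d$f_mu, P); bS_b <- log(rep(d$f_sig, P)) }
  Kb <- if (div) exp(aK_b) else aK_b
  sKb <- exp(aS_b); if (shared) sKb <- rep(sKb, P)
  ll_hat <- sum(.direct_ll(d$yd, Kb[d$pd], sKb[d$pd], bM_b[d$cd],
                           exp(bS_b)[d$cd], div)) +
    (if (length(d$yi))
      sum(stats::dnorm(d$yi, bM_b[d$ci], exp(bS_b)[d$ci], log = TRUE))
     else 0)
  d_bar <- mean(-2 * unlist(logliks))
  d_hat <- -2 * ll_hat
  p_d <- d_bar - d_hat
  dic_out <- list(DIC = d_bar + p_d, p_D = p_d, D_bar = d_bar, D_hat = d_hat)

  rh <- vapply(seq_len(npar), function(j)
    suppressWarnings(rhat(vapply(chains, function(m) m[, j],
                                 numeric(n_keep)))),
    numeric(1))
  names(rh) <- par_names
  pop_pars <- par_names[startsWith(par_names, "pop.")]
  ess <- vapply(pop_pars, function(p)
    ess_autocorr(vapply(chains, function(m) m[, p], numeric(n_keep))),
    numeric(1))

  structure(list(model = model, chains = chains, logliks = logliks,
                 par_names = par_names, rhat = rh, ess = ess,
                 dic = dic_out, priors = priors, control = control,
                 data = list(pids = d$pids, levels = d$lv,
                             n_direct = length(d$yd),
                             n_indirect = length(d$yi)),
                 fixed_indirect = fixed_indirect,
                 converged = all(rh[pop_pars] < 1.1, na.rm = TRUE),
                 runtime_s = runtime),
            class = "fm_fit")
}

## stacked draw matrix (all chains)
.fm_draw_matrix <- function(fit) do.call(rbind, fit$chains)

#' Extract posterior draws in long format
#'
#' @param fit An `fm_fit`.
#' @param pars Optional character vector of parameter names to keep.
#' @return Data frame with columns `chain`, `iteration`, `parameter`,
#'   `value`, suitable for CSV export.
#' @export
posterior_draws <- function(fit, pars = NULL) {
  stopifnot(inherits(fit, "fm_fit"))
  keep <- if (is.null(pars)) fit$par_names else intersect(fit$par_names, pars)
  out <- do.call(rbind, lapply(seq_along(fit$chains), function(ch) {
    m <- fit$chains[[ch]][, keep, drop = FALSE]
    data.frame(chain = ch, iteration = seq_len(nrow(m)),
               parameter = rep(keep, each = nrow(m)),
               value = as.vector(m), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Population-level indirect parameters from a reference fit
#'
#' Summarises a fitted model's per-participant indirect level parameters to
#' one `(mean_FI, sd_FI)` pair per target level (posterior median pooled
#' over participants), in the format `fixed_indirect` expects — used to fit
#' gain-block data whose design lacks an indirect condition.
#'
#' @param fit An `fm_fit` of a dataset with indirect trials.
#' @return Data frame with columns `target_force_N`, `mean_FI`, `sd_FI`.
#' @export
indirect_level_params <- function(fit) {
  stopifnot(inherits(fit, "fm_fit"))
  m <- .fm_draw_matrix(fit)
  lv <- fit$data$levels
  out <- lapply(lv, function(l) {
    lab <- paste0(",", .lv_lab(l), "]")
    mu_cols <- fit$par_names[startsWith(fit$par_names, "mu_I[") &
                               endsWith(fit$par_names, lab)]
    sd_cols <- fit$par_names[startsWith(fit$par_names, "sigma_I[") &
                               endsWith(fit$par_names, lab)]
    if (!length(mu_cols)) stop("fit has no indirect parameters")
    data.frame(target_force_N = l,
               mean_FI = stats::median(m[, mu_cols]),
               sd_FI = stats::median(m[, sd_cols]))
  })
  do.call(rbind, out)
}

#' Fit attenuation parameters to a gain block with fixed indirect parameters
#'
#' For gain-manipulation designs without an indirect condition, the
#' per-level indirect parameters are held at reference values (typically
#' [indirect_level_params()] of a fit to a matched-design study) and only
#' the attenuation parameters are sampled.
#'
#' @param trials Direct-condition trials of one gain block.
#' @param fixed_indirect Data frame `target_force_N`, `mean_FI`, `sd_FI`
#'   covering every level in `trials`.
#' @inheritParams fm_fit
#' @return An `fm_fit`.
#' @export
fit_gain_condition <- function(trials, fixed_indirect,
                               model = c("divisive", "subtractive"),
                               priors = fm_priors(model),
                               control = fm_control(), verbose = FALSE) {
  model <- match.arg(model)
  fm_fit(trials, model, priors, control, fixed_indirect = fixed_indirect,
         verbose = verbose)
}
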