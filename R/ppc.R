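#' Posterior predictive replication of a trial dataset
#'
#' Each simulation draws one joint posterior sample and replays the exact
#' generative process — normal draws for indirect trials, the product
#' (divisive) or sum (subtractive) of normals for direct trials — for
#' every participant-condition-level cell of the observed dataset,
#' preserving each cell's trial count. Replicates are indexed by
#' simulation, with the posterior draw index recorded for provenance.
#'
#' @param fit An [fm_fit()].
#' @param trials The observed `fm_trials` whose structure is replicated
#'   (every participant must be present in the fit).
#' @param n_sims Number of posterior predictive simulations (the full-scale
#'   convention is 10000; smaller ensembles are adequate for checks).
#' @param seed Integer seed.
#' @return An object of class `fm_ppc`: list with `cells` (data frame of
#'   cell metadata), `draws` (per cell, an `n_sims x n_trials` matrix) and
#'   `draw_index` (posterior draw used by each simulation).
#' @export
pp_replicate <- function(fit, trials, n_sims = 1000L, seed = 1L) {
  stopifnot(inherits(fit, "fm_fit"), n_sims >= 1L)
  trials <- as_fm_trials(trials)
  missing_p <- setdiff(unique(trials$participant_id), fit$data$pids)
  if (length(missing_p))
    stop("participant(s) absent from the fit: ",
         paste(missing_p, collapse = ", "))
  m <- .fm_draw_matrix(fit)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  draw_index <- sample.int(nrow(m), n_sims, replace = TRUE)
  key <- paste(trials$participant_id, trials$condition,
               round(trials$target_force_N, 9))
  idx <- split(seq_len(nrow(trials)), key)
  cells <- do.call(rbind, lapply(idx, function(i)
    data.frame(participant_id = trials$participant_id[i[1]],
               condition = trials$condition[i[1]],
               target_force_N = trials$target_force_N[i[1]],
               n_trials = length(i), stringsAsFactors = FALSE)))
  rownames(cells) <- NULL
  div <- fit$model == "divisive"
  draws <- vector("list", nrow(cells))
  pred_mean <- matrix(NA_real_, n_sims, nrow(cells))
  pred_sd <- matrix(NA_real_, n_sims, nrow(cells))
  for (j in seq_len(nrow(cells))) {
    pid <- cells$participant_id[j]
    l <- cells$target_force_N[j]
    n <- cells$n_trials[j]
    if (!is.null(fit$fixed_indirect)) {
      i <- which(abs(fit$fixed_indirect$target_force_N - l) < 1e-9)
      mu <- rep(fit$fixed_indirect$mean_FI[i], n_sims)
      sig <- rep(fit$fixed_indirect$sd_FI[i], n_sims)
    } else {
      lab <- paste0("[", pid, ",", .lv_lab(l), "]")
      mu <- m[draw_index, paste0("mu_I", lab)]
      sig <- m[draw_index, paste0("sigma_I", lab)]
    }
    if (cells$condition[j] == "indirect") {
      x <- stats::rnorm(n_sims * n, mu, sig)
      pred_mean[, j] <- mu
      pred_sd[, j] <- sig
    } else {
      K <- m[draw_index, paste0("K[", pid, "]")]
      sK <- if (fit$control$share_sd_K) m[draw_index, "sd_K"]
            else m[draw_index, paste0("sd_K[", pid, "]")]
      kk <- stats::rnorm(n_sims * n, K, sK)
      fi <- stats::rnorm(n_sims * n, mu, sig)
      x <- if (div) kk * fi else kk + fi
      if (div) {
        pred_mean[, j] <- K * mu
        pred_sd[, j] <- sqrt(mu^2 * sK^2 + (K^2 + sK^2) * sig^2)
      } else {
        pred_mean[, j] <- K + mu
        pred_sd[, j] <- sqrt(sK^2 + sig^2)
      }
    }
    draws[[j]] <- matrix(x, n_sims, n)
  }
  structure(list(cells = cells, draws = draws, draw_index = draw_index,
                 pred_mean = pred_mean, pred_sd = pred_sd,
                 n_sims = n_sims, model = fit$model),
            class = "fm_ppc")
}

#' @export
print.fm_ppc <- function(x, ...) {
  cat(sprintf("Posterior predictive ensemble: %d simulations x %d cells (%s model)\n",
              x$n_sims, nrow(x$cells), x$model))
  invisible(x)
}

## per-cell statistic of observed data and of each replicate
.cell_stat <- function(values, stat) {
  if (stat == "mean") mean(values) else stats::sd(values)
}

#' Bayesian p-value from a posterior predictive ensemble
#'
#' Quantifies whether the observed data deviate from the model's
#' predictions more than the model's own replicates do: the p-value is the
#' proportion of replicates whose discrepancy exceeds the observed one.
#' A value near 0.5 indicates that observed and simulated data deviate
#' equally around the model's prediction; if the predictions are biased —
#' too extreme in either direction — the value approaches zero or one.
#'
#' Discrepancy statistics (per participant-condition-level cell, averaged
#' over cells):
#' \describe{
#'   \item{`"bias"` (default)}{the signed deviation of the cell mean from
#'     the predicted cell mean. Predictions that are systematically too
#'     high drive p toward 1, too low toward 0; for well-specified data p
#'     is close to 0.5.}
#'   \item{`"mean"`, `"sd"`}{the absolute deviation of the cell mean or
#'     cell SD from its predicted value — an omnibus misfit measure.
#'     Because the hierarchical posterior tracks the observed cells more
#'     closely than it tracks fresh replicates, these variants sit above
#'     0.5 even for well-specified data; they are useful for detecting
#'     gross misfit, not as calibrated p-values.}
#' }
#'
#' With the default `reference = "draw"`, each replicate (and the observed
#' data) is compared against the predicted cell statistics of the
#' posterior draw that generated that replicate — the joint
#' parameter-and-replicate form of the posterior predictive check.
#' `reference = "ensemble"` compares both against the ensemble-average
#' statistic instead.
#'
#' @param trials Observed `fm_trials`.
#' @param ensemble An `fm_ppc` from [pp_replicate()] covering the observed
#'   cells.
#' @param discrepancy `"bias"` (default), `"mean"` or `"sd"`.
#' @param reference `"draw"` (default) or `"ensemble"`; see Details.
#' @return Named numeric vector: one p per condition present, plus
#'   `"pooled"`.
#' @export
bayesian_p <- function(trials, ensemble,
                       discrepancy = c("bias", "mean", "sd"),
                       reference = c("draw", "ensemble")) {
  stopifnot(inherits(ensemble, "fm_ppc"))
  discrepancy <- match.arg(discrepancy)
  reference <- match.arg(reference)
  trials <- as_fm_trials(trials)
  cells <- ensemble$cells
  n_sims <- ensemble$n_sims
  stat <- if (discrepancy == "sd") "sd" else "mean"
  key <- paste(trials$participant_id, trials$condition,
               round(trials$target_force_N, 9))
  ckey <- paste(cells$participant_id, cells$condition,
                round(cells$target_force_N, 9))
  obs_stat <- vapply(seq_len(nrow(cells)), function(j) {
    v <- trials$matching_force_N[key == ckey[j]]
    if (!length(v)) stop("ensemble cell not present in observed data: ",
                         ckey[j])
    .cell_stat(v, stat)
  }, numeric(1))
  rep_stat <- vapply(seq_len(nrow(cells)), function(j) {
    d <- ensemble$draws[[j]]
    if (stat == "mean") rowMeans(d) else apply(d, 1L, stats::sd)
  }, numeric(n_sims))               # n_sims x n_cells
  ref <- if (reference == "draw") {
    if (stat == "mean") ensemble$pred_mean else ensemble$pred_sd
  } else {
    matrix(colMeans(rep_stat), n_sims, nrow(cells), byrow = TRUE)
  }
  obs_mat <- matrix(obs_stat, n_sims, nrow(cells), byrow = TRUE)
  dev_fun <- if (discrepancy == "bias") identity else abs
  p_for <- function(keep) {
    d_obs <- rowMeans(dev_fun(obs_mat[, keep, drop = FALSE] -
                                ref[, keep, drop = FALSE]))
    d_rep <- rowMeans(dev_fun(rep_stat[, keep, drop = FALSE] -
                                ref[, keep, drop = FALSE]))
    mean(d_rep > d_obs)
  }
  conds <- unique(cells$condition)
  out <- vapply(conds, function(cc) p_for(cells$condition == cc), numeric(1))
  c(out, pooled = p_for(rep(TRUE, nrow(cells))))
}

#' Summaries of a posterior predictive ensemble
#'
#' Per-cell median and HDI of the replicated matching forces, and
#' optionally the pooled-across-participants version per condition and
#' level (the figure-style histogram summary).
#'
#' @param ensemble An `fm_ppc`.
#' @param mass HDI mass (default 0.90).
#' @param pooled If `TRUE`, also return summaries pooled across
#'   participants per condition-level.
#' @return A data frame (or a list of two data frames if `pooled`).
#' @export
predictive_summary <- function(ensemble, mass = 0.90, pooled = FALSE) {
  stopifnot(inherits(ensemble, "fm_ppc"))
  cells <- ensemble$cells
  out <- cells
  sm <- t(vapply(ensemble$draws, function(d) {
    v <- as.vector(d)
    c(stats::median(v), hdi(v, mass))
  }, numeric(3)))
  out$median <- sm[, 1]; out$hdi_lower <- sm[, 2]; out$hdi_upper <- sm[, 3]
  if (!pooled) return(out)
  grp <- paste(cells$condition, round(cells$target_force_N, 9))
  pooled_rows <- lapply(unique(grp), function(g) {
    i <- which(grp == g)
    v <- unlist(lapply(ensemble$draws[i], as.vector))
    h <- hdi(v, mass)
    data.frame(condition = cells$condition[i[1]],
               target_force_N = cells$target_force_N[i[1]],
               median = stats::median(v), hdi_lower = h[1],
               hdi_upper = h[2], stringsAsFactors = FALSE)
  })
  list(cells = out, pooled = do.call(rbind, pooled_rows))
}
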