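## Synthetic force-matching cohorts.
##
## The generator emulates the noise pathway of the task model explicitly:
## perception of the target, a noisy memory with linear contraction toward
## the session mean, comparison noise when adjusting the output, and
## signal-dependent output noise. These components are identifiable only in
## simulation; when fitting, they are absorbed into the per-level indirect
## matching distribution, exactly as in the fitted model.

#' Noise-pathway parameters shared by both reproduction conditions
#'
#' @param perceptual_noise_sd SD (N) of the noise corrupting tactile
#'   perception of a force.
#' @param memory_contraction Contraction coefficient `c` in `[0, 1]`:
#'   the remembered target is `(1-c) F_T + c * mean(levels)`, the classical
#'   contraction bias toward the session mean.
#' @param memory_noise_sd SD (N) of the noise added while the target
#'   sensation is held in memory.
#' @param comparison_noise_sd SD (N) of the noise in matching the output
#'   sensation to the remembered target.
#' @param signal_dependent_coef Dimensionless coefficient of
#'   signal-dependent output noise: an SD component proportional to the
#'   expected output, added in quadrature with the constant components.
#' @return An object of class `fm_pathway`.
#' @export
fm_pathway <- function(perceptual_noise_sd = 0.15, memory_contraction = 0.15,
                       memory_noise_sd = 0.15, comparison_noise_sd = 0.15,
                       signal_dependent_coef = 0.08) {
  stopifnot(perceptual_noise_sd >= 0, memory_noise_sd >= 0,
            comparison_noise_sd >= 0, signal_dependent_coef >= 0,
            memory_contraction >= 0, memory_contraction <= 1)
  structure(list(perceptual_noise_sd = perceptual_noise_sd,
                 memory_contraction = memory_contraction,
                 memory_noise_sd = memory_noise_sd,
                 comparison_noise_sd = comparison_noise_sd,
                 signal_dependent_coef = signal_dependent_coef),
            class = "fm_pathway")
}

#' Population-level ground truth for cohort simulation
#'
#' Individual mean attenuation factors are drawn from a normal distribution
#' truncated at zero; individual attenuation-factor SDs from a half-normal;
#' pathway parameters from normals truncated to their valid ranges.
#'
#' @param model `"divisive"` or `"subtractive"` — fixes the scale and
#'   default location of the attenuation factor (dimensionless ~1.6 for
#'   divisive; newtons ~1 for subtractive).
#' @param mean_K_mean,mean_K_sd Population mean and between-participant SD
#'   of the mean attenuation factor.
#' @param sd_K_scale Half-normal scale of the individual attenuation-factor
#'   SDs.
#' @param pathway An [fm_pathway()] of population means.
#' @param pathway_spread An [fm_pathway()]-shaped list of
#'   between-participant SDs for the pathway parameters.
#' @return An object of class `fm_population`.
#' @export
fm_population <- function(model = c("divisive", "subtractive"),
                          mean_K_mean = if (model == "divisive") 1.6 else 1.0,
                          mean_K_sd = if (model == "divisive") 0.25 else 0.2,
                          sd_K_scale = 0.15,
                          pathway = fm_pathway(),
                          pathway_spread = fm_pathway(
                            perceptual_noise_sd = 0.03,
                            memory_contraction = 0.05,
                            memory_noise_sd = 0.03,
                            comparison_noise_sd = 0.03,
                            signal_dependent_coef = 0.02)) {
  model <- match.arg(model)
  stopifnot(mean_K_mean > 0, mean_K_sd >= 0, sd_K_scale >= 0,
            inherits(pathway, "fm_pathway"))
  structure(list(model = model, mean_K_mean = mean_K_mean,
                 mean_K_sd = mean_K_sd, sd_K_scale = sd_K_scale,
                 pathway = pathway, pathway_spread = pathway_spread),
            class = "fm_population")
}

## normal truncated to [lo, hi], by inverse-CDF (vectorised in n)
.rtruncnorm <- function(n, mean, sd, lo = 0, hi = Inf) {
  if (all(sd == 0)) return(rep_len(pmin(pmax(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Draw individual ground-truth parameters from a population
#'
#' @param pop An [fm_population()].
#' @param n Number of participants.
#' @param ids Optional participant ids (default `"P001"...`).
#' @return Data frame of class `fm_participants`: one row per participant
#'   with columns `participant_id`, `mean_K`, `sd_K` and the five pathway
#'   parameters. Deterministic given the RNG state; seed with [set.seed()].
#' @export
draw_participants <- function(pop, n, ids = sprintf("P%03d", seq_len(n))) {
  stopifnot(inherits(pop, "fm_population"), n >= 1L, length(ids) == n)
  pw <- pop$pathway; sp <- pop$pathway_spread
  out <- data.frame(
    participant_id = ids,
    mean_K = .rtruncnorm(n, pop$mean_K_mean, pop$mean_K_sd, lo = 0),
    sd_K = abs(stats::rnorm(n, 0, pop$sd_K_scale)),
    perceptual_noise_sd = .rtruncnorm(n, pw$perceptual_noise_sd,
                                      sp$perceptual_noise_sd, lo = 0),
    memory_contraction = .rtruncnorm(n, pw$memory_contraction,
                                     sp$memory_contraction, lo = 0, hi = 1),
    memory_noise_sd = .rtruncnorm(n, pw$memory_noise_sd,
                                  sp$memory_noise_sd, lo = 0),
    comparison_noise_sd = .rtruncnorm(n, pw$comparison_noise_sd,
                                      sp$comparison_noise_sd, lo = 0),
    signal_dependent_coef = .rtruncnorm(n, pw$signal_dependent_coef,
                                        sp$signal_dependent_coef, lo = 0),
    stringsAsFactors = FALSE)
  class(out) <- c("fm_participants", "data.frame")
  out
}

## target sequence: per-condition blocks, each a concatenation of random
## permutations of the level grid (pseudorandomised, equal frequency)
.target_sequence <- function(levels, n_trials) {
  reps <- n_trials / length(levels)
  unlist(lapply(seq_len(reps), function(i) sample(levels)))
}

## draw the latent "indirect-equivalent" force for given targets: the
## remembered target plus comparison/perceptual noise, with the
## signal-dependent SD component in quadrature
.latent_indirect <- function(part, targets, level_mean) {
  cc <- part$memory_contraction
  mu_out <- (1 - cc) * targets + cc * level_mean
  m_t <- mu_out + stats::rnorm(length(targets), 0, part$memory_noise_sd)
  noise_sd <- sqrt(part$perceptual_noise_sd^2 + part$comparison_noise_sd^2 +
                     (part$signal_dependent_coef * mu_out)^2)
  m_t + stats::rnorm(length(targets), 0, noise_sd)
}

#' Simulate indirect-condition trials for one participant
#'
#' The remembered target is contracted toward the mean of the design levels
#' and corrupted by memory noise; the reproduced force adds comparison and
#' perceptual noise plus a signal-dependent component proportional to the
#' expected output. Levels are tested equally often in pseudorandom order.
#'
#' @param part One row of an `fm_participants` frame (or an equivalent
#'   list).
#' @param design An [fm_design()] including the indirect condition.
#' @param subgroup Subgroup label written into the records.
#' @return An `fm_trials` data frame of indirect trials.
#' @export
simulate_indirect <- function(part, design, subgroup = "synthetic") {
  stopifnot("indirect" %in% design$conditions)
  lv <- target_levels(design)
  n <- design$trials_per_participant / length(design$conditions)
  targets <- .target_sequence(lv, n)
  fi <- .latent_indirect(part, targets, mean(lv))
  as_fm_trials(data.frame(
    participant_id = part$participant_id, subgroup = subgroup,
    condition = "indirect", gain = 1, target_force_N = targets,
    matching_force_N = fi, trial_index = seq_len(n),
    stringsAsFactors = FALSE))
}

#' Simulate direct-condition trials for one participant
#'
#' Each trial draws a latent indirect-equivalent force exactly as in
#' [simulate_indirect()], plus an attenuation factor
#' `K ~ N(mean_K, sd_K)`; the output is `K * latent` (divisive) or
#' `K + latent` (subtractive).
#'
#' @inheritParams simulate_indirect
#' @param model `"divisive"` or `"subtractive"`.
#' @param gain Gain factor of the block (the recorded matching force is
#'   the passive-finger force; see [simulate_gain_study()]).
#' @param trial_offset Starting offset for `trial_index` (for multi-block
#'   designs).
#' @return An `fm_trials` data frame of direct trials.
#' @export
simulate_direct <- function(part, design, model = c("divisive", "subtractive"),
                            subgroup = "synthetic", gain = 1,
                            trial_offset = 0L) {
  stopifnot("direct" %in% design$conditions)
  model <- match.arg(model)
  lv <- target_levels(design)
  n <- design$trials_per_participant /
    (length(design$conditions) * length(design$gains))
  targets <- .target_sequence(lv, n)
  latent <- .latent_indirect(part, targets, mean(lv))
  k <- stats::rnorm(n, part$mean_K, part$sd_K)
  fd <- if (model == "divisive") k * latent else k + latent
  df <- data.frame(
    participant_id = part$participant_id, subgroup = subgroup,
    condition = "direct", gain = gain, target_force_N = targets,
    matching_force_N = fd, trial_index = trial_offset + seq_len(n),
    stringsAsFactors = FALSE)
  if (gain != 1 || length(design$gains) > 1L)
    df$active_force_N <- df$matching_force_N / gain
  as_fm_trials(df)
}

#' Simulate a full cohort under a study design
#'
#' Draws `n_participants` ground-truth parameter sets from the population,
#' simulates every trial of the design for each, and returns the dataset
#' together with a truth sidecar for recovery studies. Fully reproducible
#' given `seed`; the result passes [validate_trials()] by construction.
#'
#' @param pop An [fm_population()].
#' @param design An [fm_design()].
#' @param model `"divisive"` or `"subtractive"` (defaults to `pop$model`).
#' @param n_participants Cohort size.
#' @param seed Integer seed.
#' @param subgroup Subgroup label.
#' @return An object of class `fm_cohort`: list with elements `trials`
#'   (`fm_trials`), `truth` (list of `population` and `participants`),
#'   `design`, `model` and `seed`.
#' @export
simulate_study <- function(pop, design, model = pop$model, n_participants,
                           seed = 1L, subgroup = "synthetic") {
  stopifnot(inherits(pop, "fm_population"), inherits(design, "fm_design"))
  model <- match.arg(model, c("divisive", "subtractive"))
  set.seed(seed)
  parts <- draw_participants(pop, n_participants)
  blocks <- lapply(seq_len(n_participants), function(i) {
    part <- as.list(parts[i, ])
    out <- list()
    if ("direct" %in% design$conditions)
      out$direct <- simulate_direct(part, design, model, subgroup)
    if ("indirect" %in% design$conditions)
      out$indirect <- simulate_indirect(part, design, subgroup)
    do.call(rbind, out)
  })
  trials <- as_fm_trials(do.call(rbind, blocks))
  rownames(trials) <- NULL
  structure(list(trials = trials,
                 truth = list(population = pop, participants = parts),
                 design = design, model = model, seed = seed),
            class = "fm_cohort")
}

#' Simulate a gain-manipulation study (direct condition only)
#'
#' In a gain block the torque motor transmits `gain` times the active-finger
#' force to the passive finger. Attenuation applies to the predicted
#' passive-finger force, so the passive-finger matching force distribution
#' is matched across gains while the recorded active force equals
#' `passive / gain`. `matching_force_N` holds the passive-finger force;
#' `active_force_N` the active-finger force.
#'
#' @param pop An [fm_population()].
#' @param design A direct-only [fm_design()] with the gain factors in
#'   `design$gains` (e.g. `fm_design_preset("study4")`).
#' @inheritParams simulate_study
#' @return An `fm_cohort` (trials carry the `active_force_N` column).
#' @export
simulate_gain_study <- function(pop, design, model = pop$model,
                                n_participants, seed = 1L,
                                subgroup = "synthetic") {
  stopifnot(identical(design$conditions, "direct"), length(design$gains) >= 1L)
  model <- match.arg(model, c("divisive", "subtractive"))
  set.seed(seed)
  parts <- draw_participants(pop, n_participants)
  n_block <- design$trials_per_participant / length(design$gains)
  blocks <- lapply(seq_len(n_participants), function(i) {
    part <- as.list(parts[i, ])
    gb <- lapply(seq_along(design$gains), function(g)
      simulate_direct(part, design, model, subgroup, gain = design$gains[g],
                      trial_offset = (g - 1L) * n_block))
    do.call(rbind, gb)
  })
  trials <- as_fm_trials(do.call(rbind, blocks))
  rownames(trials) <- NULL
  structure(list(trials = trials,
                 truth = list(population = pop, participants = parts),
                 design = design, model = model, seed = seed),
            class = "fm_cohort")
}

#' @export
print.fm_cohort <- function(x, ...) {
  cat(sprintf("Synthetic force-matching cohort (%s model, seed %d)\n",
              x$model, x$seed))
  cat(sprintf("  %d participants, %d trials\n",
              nrow(x$truth$participants), nrow(x$trials)))
  print(x$design)
  invisible(x)
}

#' Simulate a force trace for one trial
#'
#' A 3-second trace sampled at `rate` Hz: a 1-second ramp to a plateau at
#' the trial's matching force, optionally with plateau noise. The noise
#' within the `[2.0, 2.5)` s analysis window is mean-centred, so
#' [extract_matching_force()] recovers `matching_force_N` exactly when
#' `plateau_noise_sd = 0` and to machine precision in the window mean
#' otherwise.
#'
#' @param trial One row of an `fm_trials` frame (or a list with
#'   `matching_force_N`).
#' @param rate Sampling rate in Hz, >= 20.
#' @param plateau_noise_sd SD (N) of additive noise on the plateau.
#' @return Data frame with columns `time_s`, `force_N` (`3 * rate` rows).
#' @export
simulate_trace <- function(trial, rate = 100, plateau_noise_sd = 0) {
  stopifnot(rate >= 20)
  f <- trial$matching_force_N
  t <- (seq_len(3 * rate) - 1L) / rate
  force <- f * pmin(t, 1)
  if (plateau_noise_sd > 0) {
    plat <- t >= 1
    eps <- stats::rnorm(sum(plat), 0, plateau_noise_sd)
    win <- t[plat] >= 2.0 & t[plat] < 2.5
    eps[win] <- eps[win] - mean(eps[win])
    force[plat] <- force[plat] + eps
  }
  data.frame(time_s = t, force_N = force)
}
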