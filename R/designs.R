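#' Define a force-matching study design
#'
#' A design specifies the grid of target force levels, the number of trials
#' per participant, which reproduction conditions are run (direct and/or
#' indirect), and the gain factors relating the force produced by the active
#' finger to the force transmitted to the passive finger.
#'
#' Target levels are the `n_levels` equally spaced values spanning
#' `[force_min, force_max]`, each tested equally often.
#' `trials_per_participant` must be divisible by
#' `n_levels * length(conditions) * length(gains)`.
#'
#' @param force_min,force_max Range of target forces in newtons.
#' @param n_levels Number of equally spaced target levels.
#' @param trials_per_participant Total trials per participant.
#' @param conditions Character subset of `c("direct", "indirect")`.
#' @param gains Positive gain factors (active-to-passive force ratio);
#'   usually `1`.
#' @return An object of class `fm_design`.
#' @seealso [fm_design_preset()] for bundled published designs.
#' @examples
#' d <- fm_design(1, 3.5, n_levels = 6, trials_per_participant = 72)
#' target_levels(d)
#' @export
fm_design <- function(force_min, force_max, n_levels, trials_per_participant,
                      conditions = c("direct", "indirect"), gains = 1) {
  stopifnot(is.numeric(force_min), is.numeric(force_max),
            force_min > 0, force_max > force_min)
  n_levels <- as.integer(n_levels)
  trials_per_participant <- as.integer(trials_per_participant)
  stopifnot(n_levels >= 2L, trials_per_participant >= 1L)
  conditions <- match.arg(conditions, c("direct", "indirect"),
                          several.ok = TRUE)
  if (anyDuplicated(conditions)) stop("duplicated conditions")
  stopifnot(is.numeric(gains), all(gains > 0), !anyDuplicated(gains))
  denom <- n_levels * length(conditions) * length(gains)
  if (trials_per_participant %% denom != 0L)
    stop("trials_per_participant (", trials_per_participant,
         ") not divisible by n_levels x conditions x gains (", denom, ")")
  structure(list(force_min = force_min, force_max = force_max,
                 n_levels = n_levels,
                 trials_per_participant = trials_per_participant,
                 conditions = conditions, gains = as.numeric(gains)),
            class = "fm_design")
}

#' Bundled study designs
#'
#' Presets encoding the designs of four published force-matching datasets:
#' `"study1"` (6 levels spanning 1-3.5 N, 72 trials, direct + indirect),
#' `"study2"` (4 levels, 1-2.5 N, 64 trials, direct + indirect),
#' `"study3"` (5 levels, 0.5-2.75 N, 160 trials, direct + indirect), and
#' `"study4"` (5 levels, 1-3 N, direct only, 50 trials in each of three
#' gain blocks: 0.5x, 1x and 2x).
#'
#' @param name Preset name.
#' @return An `fm_design`.
#' @export
fm_design_preset <- function(name) {
  presets <- c("study1", "study2", "study3", "study4")
  if (!is.character(name) || length(name) != 1L || !name %in% presets)
    stop("unknown preset ", deparse(name), "; available: ",
         paste(presets, collapse = ", "))
  switch(name,
    study1 = fm_design(1, 3.5, 6L, 72L),
    study2 = fm_design(1, 2.5, 4L, 64L),
    study3 = fm_design(0.5, 2.75, 5L, 160L),
    study4 = fm_design(1, 3, 5L, 150L, conditions = "direct",
                       gains = c(0.5, 1, 2)))
}

#' @export
print.fm_design <- function(x, ...) {
  cat("Force-matching study design\n")
  cat(sprintf("  target levels : %d levels, %.3g-%.3g N (%s)\n",
              x$n_levels, x$force_min, x$force_max,
              paste(format(target_levels(x), digits = 3), collapse = ", ")))
  cat(sprintf("  trials        : %d per participant\n",
              x$trials_per_participant))
  cat(sprintf("  conditions    : %s\n", paste(x$conditions, collapse = ", ")))
  cat(sprintf("  gains         : %s\n", paste(x$gains, collapse = ", ")))
  invisible(x)
}

#' Target force levels of a design
#'
#' @param design An `fm_design`.
#' @return Numeric vector of the equally spaced target levels in newtons.
#' @export
target_levels <- function(design) {
  stopifnot(inherits(design, "fm_design"))
  seq(design$force_min, design$force_max, length.out = design$n_levels)
}

#' Check a trial dataset against a study design
#'
#' Report-only validation: lists, per participant, deviations from the
#' design — wrong total trial count, target forces off the level grid,
#' conditions or gains not in the design, and unequal trials per
#' level-condition-gain cell. An empty report means full conformance.
#'
#' @param trials An `fm_trials` data frame (see [read_trials()]).
#' @param design An `fm_design`.
#' @return Data frame with columns `participant_id`, `check`, `detail`;
#'   zero rows iff the dataset conforms.
#' @export
validate_trials <- function(trials, design) {
  trials <- as_fm_trials(trials)
  stopifnot(inherits(design, "fm_design"))
  lv <- target_levels(design)
  out <- list()
  add <- function(pid, check, detail)
    out[[length(out) + 1L]] <<- data.frame(participant_id = pid,
                                           check = check, detail = detail,
                                           stringsAsFactors = FALSE)
  per_cell <- design$trials_per_participant /
    (design$n_levels * length(design$conditions) * length(design$gains))
  for (pid in unique(trials$participant_id)) {
    tr <- trials[trials$participant_id == pid, ]
    if (nrow(tr) != design$trials_per_participant)
      add(pid, "trial_count", sprintf("%d != %d", nrow(tr),
                                      design$trials_per_participant))
    off <- abs(outer(tr$target_force_N, lv, "-"))
    bad <- apply(off, 1L, min) > 1e-6
    if (any(bad))
      add(pid, "off_grid_level",
          paste("targets:", paste(unique(format(tr$target_force_N[bad])),
                                  collapse = ", ")))
    badc <- setdiff(unique(tr$condition), design$conditions)
    if (length(badc))
      add(pid, "condition", paste("unexpected:", paste(badc, collapse = ", ")))
    badg <- unique(tr$gain)[vapply(unique(tr$gain), function(g)
      min(abs(g - design$gains)) > 1e-9, logical(1))]
    if (length(badg))
      add(pid, "gain", paste("unexpected:", paste(format(badg), collapse = ", ")))
    if (nrow(tr) == design$trials_per_participant && !any(bad) &&
        !length(badc) && !length(badg)) {
      lidx <- apply(off, 1L, which.min)
      cnt <- table(lidx, tr$condition, factor(tr$gain))
      if (any(cnt != per_cell))
        add(pid, "cell_balance",
            sprintf("cells range %d-%d, expected %d", min(cnt), max(cnt),
                    as.integer(per_cell)))
    }
  }
  if (!length(out))
    return(data.frame(participant_id = character(), check = character(),
                      detail = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
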