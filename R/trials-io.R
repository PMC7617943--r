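## Canonical trial-table schema. Forces are in newtons throughout; no unit
## column. `active_force_N` is optional and only present for gain studies.
.fm_cols <- c("participant_id", "subgroup", "condition", "gain",
              "target_force_N", "matching_force_N", "trial_index")

#' Coerce and validate a trial-level data frame
#'
#' Checks the canonical columns, normalises condition labels to lower case,
#' and enforces the row-level invariants: `target_force_N > 0`, `gain > 0`,
#' condition in `{direct, indirect}`, and uniqueness of
#' `(participant_id, condition, trial_index)`.
#'
#' @param x A data frame with the canonical columns (see [read_trials()]).
#' @return The validated data frame with class `fm_trials`.
#' @export
as_fm_trials <- function(x) {
  if (inherits(x, "fm_trials")) return(x)
  stopifnot(is.data.frame(x))
  miss <- setdiff(.fm_cols, names(x))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  x$participant_id <- as.character(x$participant_id)
  x$subgroup <- as.character(x$subgroup)
  x$condition <- tolower(as.character(x$condition))
  bad <- which(!x$condition %in% c("direct", "indirect"))
  if (length(bad))
    stop("unknown condition label ", deparse(x$condition[bad[1]]),
         " at row ", bad[1])
  for (col in c("gain", "target_force_N", "matching_force_N", "trial_index")) {
    v <- x[[col]]
    if (is.character(v) || is.factor(v)) {
      vn <- suppressWarnings(as.numeric(as.character(v)))
      if (anyNA(vn) & !anyNA(v))
        stop("unparseable numeric in column ", col, " at row ",
             which(is.na(vn))[1])
      v <- vn
    }
    if (anyNA(v)) stop("missing value in column ", col, " at row ",
                       which(is.na(v))[1])
    x[[col]] <- v
  }
  if (any(x$target_force_N <= 0))
    stop("target_force_N must be > 0 (row ",
         which(x$target_force_N <= 0)[1], ")")
  if (any(x$gain <= 0))
    stop("gain must be > 0 (row ", which(x$gain <= 0)[1], ")")
  if (any(x$trial_index < 0))
    stop("trial_index must be non-negative (row ",
         which(x$trial_index < 0)[1], ")")
  key <- paste(x$participant_id, x$condition, x$trial_index, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (participant_id, condition, trial_index) at row ",
         which(duplicated(key))[1])
  class(x) <- c("fm_trials", "data.frame")
  x
}

#' Read a trial-level CSV
#'
#' Reads a force-matching trial table with the canonical header
#' `participant_id,subgroup,condition,gain,target_force_N,matching_force_N,trial_index`
#' (an optional `active_force_N` column is retained when present).
#' Condition labels are case-normalised; malformed rows are rejected with
#' their row number. Row order is preserved.
#'
#' @param path Path to a CSV file.
#' @return An `fm_trials` data frame.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  as_fm_trials(x)
}

#' Write a trial-level CSV
#'
#' Writes the canonical column order (plus `active_force_N` if present).
#' `read_trials(write_trials(x, f))` returns a dataset equal to `x` up to
#' floating-point formatting.
#'
#' @param trials An `fm_trials` data frame (validated on the way out).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  trials <- as_fm_trials(trials)
  cols <- c(.fm_cols, intersect("active_force_N", names(trials)))
  utils::write.csv(trials[, cols, drop = FALSE], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Extract the matching force from a force trace
#'
#' The matching force of a trial is defined as the mean force exerted in the
#' window from 2 to 2.5 seconds after the go signal. The window is half-open,
#' `[2.0, 2.5)` s, on sample timestamps, which is unambiguous at the
#' boundaries for any sampling rate.
#'
#' @param trace Either a data frame with columns `time_s` and `force_N`
#'   (the trace CSV interchange format) or a numeric vector of forces, in
#'   which case `time_s` must be supplied.
#' @param time_s Sample times in seconds (ignored when `trace` is a data
#'   frame).
#' @return The matching force in newtons.
#' @export
extract_matching_force <- function(trace, time_s = NULL) {
  if (is.data.frame(trace)) {
    stopifnot(all(c("time_s", "force_N") %in% names(trace)))
    time_s <- trace$time_s
    force <- trace$force_N
  } else {
    force <- trace
    if (is.null(time_s)) stop("time_s required when trace is a vector")
  }
  stopifnot(length(force) == length(time_s))
  if (max(time_s) < 2.5)
    stop("trace ends at ", format(max(time_s)),
         " s; must cover the [2.0, 2.5] s window")
  keep <- time_s >= 2.0 & time_s < 2.5
  if (!any(keep)) stop("no samples in the [2.0, 2.5) s window")
  mean(force[keep])
}

#' Exclude participants whose matching forces do not track the target
#'
#' Participants whose matching forces do not correlate with the target
#' forces likely did not perform the task as instructed. The Pearson
#' correlation between target and matching force is computed per participant,
#' pooled across conditions; participants with `r <= min_r` or with an
#' undefined correlation (e.g. constant output) are excluded.
#'
#' @param trials An `fm_trials` data frame.
#' @param min_r Correlation threshold (default 0).
#' @return List with elements `kept` (an `fm_trials` data frame) and
#'   `excluded` (data frame of `participant_id` and `r`, `NA` when
#'   undefined).
#' @export
qc_exclude <- function(trials, min_r = 0) {
  trials <- as_fm_trials(trials)
  ids <- unique(trials$participant_id)
  r <- vapply(ids, function(pid) {
    tr <- trials[trials$participant_id == pid, ]
    suppressWarnings(stats::cor(tr$target_force_N, tr$matching_force_N))
  }, numeric(1))
  drop <- is.na(r) | r <= min_r
  list(kept = trials[!trials$participant_id %in% ids[drop], ],
       excluded = data.frame(participant_id = ids[drop], r = unname(r[drop]),
                             stringsAsFactors = FALSE))
}

#' Per-level summary of matching forces
#'
#' Computes, for each participant, condition, gain and target force level,
#' the number of trials and the mean and standard deviation of the matching
#' forces. The SD uses the n-1 denominator and is `NA` for singleton cells.
#'
#' @param trials An `fm_trials` data frame.
#' @return Data frame with columns `participant_id`, `condition`, `gain`,
#'   `target_force_N`, `n`, `mean_match`, `sd_match`, sorted by participant,
#'   condition, gain and level.
#' @export
summarize_levels <- function(trials) {
  trials <- as_fm_trials(trials)
  key <- interaction(trials$participant_id, trials$condition, trials$gain,
                     trials$target_force_N, drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(trials)), key)
  rows <- lapply(idx, function(i) {
    y <- trials$matching_force_N[i]
    data.frame(participant_id = trials$participant_id[i[1]],
               condition = trials$condition[i[1]],
               gain = trials$gain[i[1]],
               target_force_N = trials$target_force_N[i[1]],
               n = length(i), mean_match = mean(y),
               sd_match = if (length(i) >= 2L) stats::sd(y) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$participant_id, out$condition, out$gain,
            out$target_force_N), , drop = FALSE]
}
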