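#' @title Task schedules for the volatile tone-rotation task
#'
#' @description
#' `generate_run()` builds one run of the audio-visual associative-learning
#' task: a high or low tone precedes a clockwise (CW) or counterclockwise
#' (CCW) rotation of a dot pair, with a hidden 75% tone-rotation contingency
#' that reverses every 16, 24 or 32 trials. Every disjoint block of 8 trials
#' contains 6 expected, 1 unexpected and 1 ambiguous trial (ambiguous probes
#' carry no objective rotation). `generate_session()` concatenates five such
#' runs (360 trials).
#'
#' @param seed integer seed; the same seed reproduces the schedule exactly.
#' @param n_trials number of trials in the run, a multiple of 8 (default 72).
#' @param reversal_lengths admissible distances (in trials) between
#'   contingency reversals; multiples of 8, default `c(16, 24, 32)`.
#'
#' @details
#' The hidden contingency takes one of two states: under `"c1"` the high tone
#' predicts CW and the low tone CCW; `"c2"` is the reverse. The initial state
#' is drawn uniformly. Reversal segment lengths are drawn uniformly from
#' `reversal_lengths` under the constraint that they fit inside the run;
#' remaining trials keep the final contingency. Trial types are permuted
#' uniformly within each 8-trial block and tones are drawn uniformly per
#' trial.
#'
#' @return A data frame of class `"task_schedule"` with columns `session`,
#'   `run`, `trial`, `block`, `tone`, `contingency`, `trial_type`,
#'   `rotation`, and attributes `seed` and `reversal_points` (trial indices
#'   at which the new contingency takes effect).
#' @examples
#' run <- generate_run(seed = 1)
#' table(run$trial_type)
#' @export
generate_run <- function(seed, n_trials = 72L, reversal_lengths = c(16L, 24L, 32L)) {
  n_trials <- as.integer(n_trials)
  reversal_lengths <- as.integer(reversal_lengths)
  if (length(n_trials) != 1L || is.na(n_trials) || n_trials <= 0L || n_trials %% 8L != 0L)
    stop("`n_trials` must be a positive multiple of 8", call. = FALSE)
  if (length(reversal_lengths) < 1L || anyNA(reversal_lengths) ||
      any(reversal_lengths <= 0L) || any(reversal_lengths %% 8L != 0L))
    stop("`reversal_lengths` must be positive multiples of 8", call. = FALSE)
  if (any(reversal_lengths > n_trials))
    stop("reversal lengths must not exceed `n_trials`", call. = FALSE)

  with_seed(seed, {
    ## contingency segments: uniform draws that fit inside the run
    start_state <- sample(c("c1", "c2"), 1L)
    seg <- integer(0)
    pos <- 0L
    repeat {
      ok <- reversal_lengths[reversal_lengths <= n_trials - pos]
      if (length(ok) == 0L) break
      len <- ok[sample.int(length(ok), 1L)]
      seg <- c(seg, len)
      pos <- pos + len
    }
    states <- c("c1", "c2")
    first <- match(start_state, states)
    contingency <- character(n_trials)
    bounds <- cumsum(c(0L, seg))
    n_seg <- length(seg) + 1L  # last (possibly empty) segment keeps final state
    reversal_points <- integer(0)
    upper <- c(bounds[-1L], n_trials)
    for (s in seq_len(n_seg)) {
      lo <- bounds[s] + 1L
      hi <- upper[s]
      if (lo <= hi)
        contingency[lo:hi] <- states[1L + (first - 1L + s - 1L) %% 2L]
      if (s > 1L && lo <= n_trials) reversal_points <- c(reversal_points, lo)
    }

    ## per-block 6/1/1 composition, uniformly permuted
    n_blocks <- n_trials %/% 8L
    trial_type <- unlist(lapply(seq_len(n_blocks), function(b) {
      sample(c(rep("expected", 6L), "unexpected", "ambiguous"))
    }), use.names = FALSE)

    tone <- sample(c("low", "high"), n_trials, replace = TRUE)
    implied <- implied_rotation(tone, contingency)
    rotation <- ifelse(trial_type == "ambiguous", "none",
                       ifelse(trial_type == "expected", implied,
                              ifelse(implied == "CW", "CCW", "CW")))

    out <- data.frame(
      session = 1L, run = 1L, trial = seq_len(n_trials),
      block = rep(seq_len(n_blocks), each = 8L),
      tone = tone, contingency = contingency,
      trial_type = trial_type, rotation = rotation,
      stringsAsFactors = FALSE)
    attr(out, "seed") <- seed
    attr(out, "reversal_points") <- reversal_points
    class(out) <- c("task_schedule", "data.frame")
    out
  })
}

#' @rdname generate_run
#' @param n_runs number of runs in the session (default 5).
#' @export
generate_session <- function(seed, n_runs = 5L, n_trials = 72L,
                             reversal_lengths = c(16L, 24L, 32L)) {
  n_runs <- as.integer(n_runs)
  if (n_runs < 1L) stop("`n_runs` must be >= 1", call. = FALSE)
  run_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_runs))
  runs <- lapply(seq_len(n_runs), function(r) {
    sched <- generate_run(run_seeds[r], n_trials = n_trials,
                          reversal_lengths = reversal_lengths)
    sched$run <- r
    sched
  })
  out <- do.call(rbind, lapply(runs, as.data.frame))
  attr(out, "seed") <- seed
  attr(out, "reversal_points") <- lapply(runs, attr, "reversal_points")
  class(out) <- c("task_schedule", "data.frame")
  out
}

#' Contingency-implied rotation direction
#'
#' Direction the current hidden contingency predicts for a given tone:
#' under `"c1"` high maps to CW and low to CCW; `"c2"` is the reverse.
#'
#' @param tone character vector of `"low"`/`"high"`.
#' @param contingency character vector of `"c1"`/`"c2"`.
#' @return character vector of `"CW"`/`"CCW"`.
#' @export
implied_rotation <- function(tone, contingency) {
  stopifnot(all(tone %in% c("low", "high")), all(contingency %in% c("c1", "c2")))
  ifelse((tone == "high") == (contingency == "c1"), "CW", "CCW")
}

#' Binary HGF input coding of a schedule
#'
#' Codes each trial as `u = 1` if its tone-rotation pair is congruent with
#' contingency state `"c1"` (high tone followed by CW, or low tone followed
#' by CCW) and `u = 0` otherwise, so that the level-2 belief tracks the
#' hidden association rather than the raw rotation. Trials without an
#' objective rotation contribute `NA` (no belief update) unless
#' `ambiguous = "percept"`, in which case the reported percept stands in for
#' the missing outcome.
#'
#' @param schedule a `task_schedule`.
#' @param responses optional aligned response table (required for
#'   `ambiguous = "percept"`).
#' @param ambiguous `"missing"` (default) or `"percept"`.
#' @return numeric vector of 0/1/`NA`, one per trial.
#' @export
hgf_inputs <- function(schedule, responses = NULL,
                       ambiguous = c("missing", "percept")) {
  ambiguous <- match.arg(ambiguous)
  rot <- schedule$rotation
  if (ambiguous == "percept") {
    if (is.null(responses) || nrow(responses) != nrow(schedule))
      stop("`responses` aligned with `schedule` required for percept coding",
           call. = FALSE)
    amb <- rot == "none"
    rot[amb] <- as.character(responses$perception[amb])
  }
  u <- ifelse(rot == "none" | is.na(rot), NA_real_,
              as.numeric((schedule$tone == "high") == (rot == "CW")))
  u
}

#' Validate the structural invariants of a task schedule
#'
#' Checks run length, the 6/1/1 composition of every 8-trial block, the
#' consistency of rotations with trial types, and reversal spacing.
#' Errors on the first violated invariant, returns the schedule invisibly
#' otherwise.
#'
#' @param schedule a `task_schedule`.
#' @param reversal_lengths admissible reversal spacings.
#' @export
validate_schedule <- function(schedule, reversal_lengths = c(16L, 24L, 32L)) {
  runs <- split(as.data.frame(schedule), schedule$run)
  revp <- attr(schedule, "reversal_points")
  if (!is.list(revp)) revp <- list(revp)
  for (i in seq_along(runs)) {
    run <- runs[[i]]
    n <- nrow(run)
    if (n %% 8L != 0L) stop("run length not a multiple of 8")
    for (b in split(run, run$block)) {
      tab <- table(factor(b$trial_type,
                          levels = c("expected", "unexpected", "ambiguous")))
      if (!all(tab == c(6L, 1L, 1L)))
        stop("block composition is not 6 expected / 1 unexpected / 1 ambiguous")
    }
    if (!all((run$rotation == "none") == (run$trial_type == "ambiguous")))
      stop("rotation 'none' must coincide with ambiguous trials")
    implied <- implied_rotation(run$tone, run$contingency)
    unamb <- run$trial_type != "ambiguous"
    exp_ok <- run$rotation[unamb] == implied[unamb]
    if (!all(exp_ok == (run$trial_type[unamb] == "expected")))
      stop("trial types inconsistent with contingency-implied rotations")
    rp <- revp[[min(i, length(revp))]]
    if (length(rp) > 0) {
      gaps <- diff(c(1L, rp))
      if (!all(gaps %in% reversal_lengths))
        stop("reversal spacing outside the admissible lengths")
      flips <- which(diff(run$contingency != "c1") != 0L) + 1L
      if (!identical(as.integer(flips), as.integer(rp)))
        stop("recorded reversal points disagree with the contingency column")
    }
  }
  invisible(schedule)
}

## evaluate `code` under `seed` without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
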