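#' Simulate an agent's dual reports on a task schedule
#'
#' Generates trial-by-trial prediction and perception reports from exactly
#' the likelihood that model inversion evaluates: predictions are sampled
#' from [prediction_probability()] and percepts sequentially from
#' [perception_probability()], with the agent's own earlier percepts
#' feeding the priming and sensory-memory terms. With `lapse > 0` each
#' report is independently replaced by a missing response with that
#' probability.
#'
#' @param schedule a `task_schedule` (one or more runs).
#' @param hgf an [hgf_params()] object (contingency model).
#' @param resp a [response_params()] object.
#' @param config a [model_config()] variant.
#' @param seed integer seed; reports are deterministic given the seed.
#' @param lapse probability of a missing report (default 0).
#' @return A data frame of class `"trial_responses"` with columns
#'   `prediction`, `perception` (`"CW"`/`"CCW"`/`NA`) and `confidence`
#'   (all `NA`; confidence is only collected in the rating task).
#' @examples
#' sess <- generate_session(1)
#' resp <- simulate_agent(sess, hgf_params(), response_params(pi_a = 1.4),
#'                        model_config("A"), seed = 2)
#' @export
simulate_agent <- function(schedule, hgf = hgf_params(),
                           resp = response_params(),
                           config = model_config("A"), seed, lapse = 0) {
  stopifnot(inherits(hgf, "hgf_params"), inherits(resp, "response_params"),
            inherits(config, "response_config"))
  if (lapse < 0 || lapse >= 1) stop("`lapse` must be in [0, 1)", call. = FALSE)
  u <- hgf_inputs(schedule)
  n <- nrow(schedule)
  prediction <- character(n)
  perception <- character(n)
  with_seed(seed, {
    for (r in unique(schedule$run)) {
      i <- which(schedule$run == r)
      traj <- hgf_filter(u[i], hgf)
      mu_a <- schedule_mu_a(schedule[i, , drop = FALSE], traj)
      p_pred <- prediction_probability(mu_a, resp)
      prediction[i] <- ifelse(runif(length(i)) < p_pred, "CW", "CCW")
      rot <- schedule$rotation[i]
      percepts <- rep(NA_character_, length(i))
      for (t in seq_along(i)) {
        lo <- .perception_logodds(rot[seq_len(t)], mu_a[seq_len(t)],
                                  percepts[seq_len(t)], config, resp)[t]
        p <- clamp01(plogis(lo))
        percepts[t] <- if (runif(1) < p) "CW" else "CCW"
      }
      perception[i] <- percepts
    }
    if (lapse > 0) {
      prediction[runif(n) < lapse] <- NA_character_
      perception[runif(n) < lapse] <- NA_character_
    }
  })
  structure(data.frame(prediction = prediction, perception = perception,
                       confidence = NA_integer_, stringsAsFactors = FALSE),
            class = c("trial_responses", "data.frame"))
}

#' Write / read per-trial tables
#'
#' The canonical on-disk format is a tab-separated table with one row per
#' trial and columns `session`, `run`, `trial`, `tone`, `contingency`,
#' `trial_type`, `rotation`, `prediction`, `perception`, `confidence`,
#' preceded by a `# key: value` metadata header (seed, generator version).
#' `read_trial_table()` also serves as the adapter point for externally
#' deposited behavioural tables: any tab-separated file with (at least)
#' these columns, after renaming, can be read with `col_map`.
#'
#' @param schedule a `task_schedule`.
#' @param responses an aligned response table (optional; missing columns
#'   are written as `NA`).
#' @param path file path.
#' @param metadata named character vector of extra header fields.
#' @return `read_trial_table()` returns a list with elements `schedule`
#'   (a `task_schedule`), `responses` (a `trial_responses` data frame) and
#'   `metadata` (named character vector).
#' @export
write_trial_table <- function(schedule, responses = NULL, path,
                              metadata = character()) {
  tab <- data.frame(session = schedule$session, run = schedule$run,
                    trial = schedule$trial, tone = schedule$tone,
                    contingency = schedule$contingency,
                    trial_type = schedule$trial_type,
                    rotation = schedule$rotation,
                    stringsAsFactors = FALSE)
  if (is.null(responses)) {
    tab$prediction <- NA_character_
    tab$perception <- NA_character_
    tab$confidence <- NA_integer_
  } else {
    tab$prediction <- responses$prediction
    tab$perception <- responses$perception
    tab$confidence <- responses$confidence
  }
  meta <- c(seed = as.character(attr(schedule, "seed")),
            generator = paste0("hgflearn ",
                               as.character(utils::packageVersion("hgflearn"))),
            metadata)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), meta), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_trial_table
#' @param col_map optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(perception = "percept_resp")`.
#' @export
read_trial_table <- function(path, col_map = NULL) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- character()
  if (any(hdr)) {
    kv <- sub("^#\\s*", "", lines[hdr])
    keys <- sub(":.*$", "", kv)
    vals <- sub("^[^:]*:\\s*", "", kv)
    meta <- setNames(vals, keys)
  }
  tab <- read.delim(text = lines[!hdr], sep = "\t",
                    stringsAsFactors = FALSE, na.strings = "NA")
  if (!is.null(col_map))
    for (canon in names(col_map)) {
      j <- match(col_map[[canon]], names(tab))
      if (!is.na(j)) names(tab)[j] <- canon
    }
  need <- c("session", "run", "trial", "tone", "contingency", "trial_type",
            "rotation")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("trial table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  sched <- tab[need]
  sched$block <- (as.integer(sched$trial) - 1L) %/% 8L + 1L
  attr(sched, "seed") <- suppressWarnings(as.integer(meta["seed"]))
  class(sched) <- c("task_schedule", "data.frame")
  resp <- data.frame(
    prediction = if ("prediction" %in% names(tab)) as.character(tab$prediction) else NA_character_,
    perception = if ("perception" %in% names(tab)) as.character(tab$perception) else NA_character_,
    confidence = if ("confidence" %in% names(tab)) as.integer(tab$confidence) else NA_integer_,
    stringsAsFactors = FALSE)
  class(resp) <- c("trial_responses", "data.frame")
  list(schedule = sched, responses = resp, metadata = meta)
}
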