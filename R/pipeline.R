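#' Behavioural scoring of one subject
#'
#' Scores the dual reports against the schedule. Predictions are scored
#' against the presented rotation on unambiguous trials and against the
#' contingency-implied rotation on ambiguous trials (set
#' `prediction_scoring = "contingency"` to score every trial against the
#' contingency-implied direction). Ambiguous congruency is the fraction of
#' ambiguous-trial percepts matching the direction the current contingency
#' implies for the trial's tone; perception accuracy is computed on
#' unambiguous trials only. With no ambiguous trials the congruency is
#' reported as `NA`. Confidence ratings, when present, are rescaled to
#' percent certainty and averaged separately for ambiguous and unambiguous
#' trials.
#'
#' @param responses aligned response table.
#' @param schedule a `task_schedule`.
#' @param prediction_scoring `"presented"` (default) or `"contingency"`.
#' @return A one-row data frame with `prop_correct_prediction`,
#'   `prop_ambiguous_congruent`, `prop_correct_perception_unambiguous`,
#'   `mean_certainty_ambiguous`, `mean_certainty_unambiguous`.
#' @export
score_behavior <- function(responses, schedule,
                           prediction_scoring = c("presented", "contingency")) {
  prediction_scoring <- match.arg(prediction_scoring)
  if (nrow(responses) != nrow(schedule))
    stop("`responses` and `schedule` must align", call. = FALSE)
  implied <- implied_rotation(schedule$tone, schedule$contingency)
  amb <- schedule$trial_type == "ambiguous"
  target <- if (prediction_scoring == "contingency") implied else
    ifelse(amb, implied, schedule$rotation)
  pred_ok <- responses$prediction == target
  perc_cong <- responses$perception[amb] == implied[amb]
  perc_ok <- responses$perception[!amb] == schedule$rotation[!amb]

  cert <- rep(NA_real_, nrow(responses))
  has_conf <- !is.na(responses$confidence)
  if (any(has_conf))
    cert[has_conf] <- rescale_confidence(responses$confidence[has_conf])

  prop <- function(x) if (sum(!is.na(x)) == 0L) NA_real_ else mean(x, na.rm = TRUE)
  data.frame(
    prop_correct_prediction = prop(pred_ok),
    prop_ambiguous_congruent = prop(perc_cong),
    prop_correct_perception_unambiguous = prop(perc_ok),
    mean_certainty_ambiguous = prop(cert[amb]),
    mean_certainty_unambiguous = prop(cert[!amb]))
}

#' Rescale 1-4 confidence ratings to percent certainty
#'
#' Affine map of the rating scale (1 = very sure ... 4 = very unsure) onto
#' a 100% to 0% certainty scale: `(4 - rating) * 100 / 3`.
#'
#' @param ratings integer vector with values in 1..4.
#' @return numeric vector of certainty percentages.
#' @examples
#' rescale_confidence(c(1, 2, 4))  # 100, 66.67, 0
#' @export
rescale_confidence <- function(ratings) {
  if (!all(ratings %in% 1:4))
    stop("ratings must be integers in 1..4", call. = FALSE)
  (4 - ratings) * 100 / 3
}

#' One- and two-sample t tests with Cohen's d
#'
#' With `group = NULL`, tests `values` against `mu` (one-sample, two-sided)
#' and reports `d = (mean - mu) / sd`. With a two-level `group`, compares
#' the groups with a Student t test (pooled variance) and reports d with
#' the pooled standard deviation. Degenerate (zero-variance) inputs yield
#' `NA` statistics.
#'
#' @param values numeric vector.
#' @param group optional factor-like vector with two levels.
#' @param mu null value for the one-sample test (default 0.5, chance
#'   level for the accuracy measures).
#' @return one-row data frame with `estimate`, `t`, `df`, `p`, `cohens_d`.
#' @export
group_tests <- function(values, group = NULL, mu = 0.5) {
  if (is.null(group)) {
    if (length(values) < 2L) stop("need >= 2 observations", call. = FALSE)
    s <- sd(values)
    if (!is.finite(s) || s == 0) {
      est <- mean(values)
      return(data.frame(estimate = est, t = if (est == mu) 0 else NA_real_,
                        df = length(values) - 1L,
                        p = if (est == mu) 1 else NA_real_,
                        cohens_d = if (est == mu) 0 else NA_real_))
    }
    tt <- t.test(values, mu = mu)
    return(data.frame(estimate = unname(tt$estimate),
                      t = unname(tt$statistic), df = unname(tt$parameter),
                      p = tt$p.value, cohens_d = (mean(values) - mu) / s))
  }
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("`group` must have two levels", call. = FALSE)
  x <- values[group == levels(group)[1L]]
  y <- values[group == levels(group)[2L]]
  if (length(x) < 2L || length(y) < 2L)
    stop("need >= 2 observations per group", call. = FALSE)
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  if (!is.finite(sp2) || sp2 == 0) {
    same <- mean(x) == mean(y)
    return(data.frame(estimate = mean(x) - mean(y),
                      t = if (same) 0 else NA_real_,
                      df = length(x) + length(y) - 2L,
                      p = if (same) 1 else NA_real_,
                      cohens_d = if (same) 0 else NA_real_))
  }
  tt <- t.test(x, y, var.equal = TRUE)
  data.frame(estimate = mean(x) - mean(y), t = unname(tt$statistic),
             df = unname(tt$parameter), p = tt$p.value,
             cohens_d = (mean(x) - mean(y)) / sqrt(sp2))
}

#' Repeated-measures test of confidence by ambiguity and group
#'
#' Two-way mixed ANOVA on per-subject mean certainty with ambiguity
#' (within-subject) and group (between-subject) factors, as used for the
#' confidence-rating task.
#'
#' @param data data frame with columns `subject`, `group`, `ambiguity`
#'   (two levels each per subject) and `certainty`.
#' @return data frame of effects with `F`, `df1`, `df2`, `p`.
#' @export
confidence_anova <- function(data) {
  stopifnot(all(c("subject", "group", "ambiguity", "certainty") %in% names(data)))
  data$subject <- as.factor(data$subject)
  data$group <- as.factor(data$group)
  data$ambiguity <- as.factor(data$ambiguity)
  fit <- stats::aov(certainty ~ ambiguity * group + Error(subject / ambiguity),
                    data = data)
  s <- summary(fit)
  rows <- list()
  for (stratum in s) {
    tab <- stratum[[1L]]
    keep <- rownames(tab) != "Residuals"
    if (!any(keep)) next
    resid_df <- tab["Residuals", "Df"]
    for (i in which(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        effect = trimws(rownames(tab)[i]), F = tab[i, "F value"],
        df1 = tab[i, "Df"], df2 = resid_df, p = tab[i, "Pr(>F)"])
    }
  }
  do.call(rbind, rows)
}

#' Pearson correlations with Benjamini-Hochberg FDR control
#'
#' Tests each declared variable pair with Pearson's correlation test and
#' adjusts the p values within the family with the Benjamini-Hochberg
#' step-up procedure. Pairs with fewer than 3 complete observations or a
#' constant variable are reported with `NA` and excluded from the family.
#'
#' @param data data frame holding the variables.
#' @param pairs two-column character matrix or data frame of variable
#'   names; each row is one test of the family.
#' @return data frame with `var1`, `var2`, `n`, `r`, `p`, `p_fdr`.
#' @export
correlate_with_fdr <- function(data, pairs) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("`pairs` must have two columns", call. = FALSE)
  out <- data.frame(var1 = pairs[, 1L], var2 = pairs[, 2L],
                    n = NA_integer_, r = NA_real_, p = NA_real_,
                    p_fdr = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    x <- data[[pairs[i, 1L]]]
    y <- data[[pairs[i, 2L]]]
    ok <- stats::complete.cases(x, y)
    out$n[i] <- sum(ok)
    if (sum(ok) < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    out$r[i] <- unname(ct$estimate)
    out$p[i] <- ct$p.value
  }
  fam <- !is.na(out$p)
  out$p_fdr[fam] <- p.adjust(out$p[fam], method = "BH")
  out
}

#' Names of the nine trial-wise parametric modulators
#'
#' Five tone-locked quantities (the pre-update prediction precisions and
#' absolute means at levels 3 and 2, and the conditional CW prediction
#' `mu_a`) and four rotation-locked quantities (the absolute
#' precision-weighted prediction errors at levels 3 and 2, the absolute
#' perceptual prediction error and the posterior CW-percept probability).
#'
#' @return named list with elements `tone_locked` and `rotation_locked`.
#' @export
modulator_names <- function() {
  list(tone_locked = c("pihat3", "abs_muhat3", "pihat2", "abs_muhat2", "mu_a"),
       rotation_locked = c("abs_eps3", "abs_eps2", "abs_delta_q", "P_theta1"))
}

#' Export the trial-wise parametric modulators
#'
#' Builds the nine-modulator table used as parametric modulators of the
#' tone and rotation events in an event-related GLM. Tone-locked columns
#' are the pre-update (hatted) belief quantities of the trial;
#' rotation-locked columns derive from the trial's outcome and the fitted
#' perceptual model. `abs_delta_q` is `NA` on trials with a missing
#' percept.
#'
#' @param traj [hgf_filter()] trajectories for the schedule.
#' @param responses aligned response table.
#' @param schedule a `task_schedule`.
#' @param config,params the fitted response-model variant and parameters.
#' @return A data frame of class `"modulator_table"` with identifier
#'   columns `session`, `run`, `trial`, `trial_type` and the nine
#'   modulator columns of [modulator_names()].
#' @export
export_modulators <- function(traj, responses, schedule,
                              config = model_config("A"),
                              params = response_params()) {
  stopifnot(nrow(traj) == nrow(schedule), nrow(responses) == nrow(schedule))
  pq <- perceptual_quantities(responses, schedule, traj, config, params)
  out <- data.frame(
    session = schedule$session, run = schedule$run, trial = schedule$trial,
    trial_type = schedule$trial_type,
    pihat3 = traj$pihat3, abs_muhat3 = abs(traj$muhat3),
    pihat2 = traj$pihat2, abs_muhat2 = abs(traj$muhat2),
    mu_a = pq$mu_a,
    abs_eps3 = abs(traj$eps3), abs_eps2 = abs(traj$eps2),
    abs_delta_q = abs(pq$delta_q), P_theta1 = pq$P_theta1)
  class(out) <- c("modulator_table", "data.frame")
  out
}

#' Simulate a cohort of synthetic subjects
#'
#' Draws subject-level parameters in estimation space around the given
#' group means and simulates each subject's session from the chosen
#' response-model variant. The defaults emulate the study population that
#' the winning associative-learning model describes: `omega2 ~ N(-0.72,
#' 0.86^2)`, `omega3 ~ N(-6.23, 0.09^2)` and `log(pi_a) ~ N(log(1.37),
#' 0.2^2)` across subjects, with the prediction noise fixed at the
#' unit-square-sigmoid default.
#'
#' @param n_subjects number of synthetic subjects.
#' @param seed integer seed (drives schedules, parameter draws and
#'   response sampling).
#' @param model generating variant name.
#' @param n_runs runs per session.
#' @param omega2_mean,omega2_sd,omega3_mean,omega3_sd between-subject
#'   distribution of the HGF volatilities.
#' @param pi_a_mean,pi_a_log_sd between-subject distribution of the
#'   associative precision (log-normal; ignored unless the variant uses A).
#' @param priming_weight,sensory_memory_weight,decision_noise fixed values
#'   for the remaining response parameters.
#' @return A list of class `"synthetic_cohort"`: per-subject elements with
#'   `schedule`, `responses`, `hgf`, `resp`, and attribute `model`.
#' @export
simulate_cohort <- function(n_subjects, seed, model = "A", n_runs = 5L,
                            omega2_mean = -0.72, omega2_sd = 0.86,
                            omega3_mean = -6.23, omega3_sd = 0.09,
                            pi_a_mean = 1.37, pi_a_log_sd = 0.2,
                            priming_weight = 0.5,
                            sensory_memory_weight = 0.5,
                            decision_noise = 1 / 48) {
  config <- model_config(model)
  seeds <- with_seed(seed,
                     matrix(sample.int(.Machine$integer.max - 100L,
                                       3L * n_subjects), ncol = 3L))
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    schedule <- generate_session(seeds[s, 1L], n_runs = n_runs)
    ## volatility draws outside the filter's stable regime for this
    ## schedule are rejected and redrawn (deterministically)
    for (attempt in 1:50) {
      par_draw <- with_seed(seeds[s, 2L] + attempt, {
        list(omega2 = rnorm(1, omega2_mean, omega2_sd),
             omega3 = rnorm(1, omega3_mean, omega3_sd),
             pi_a = exp(rnorm(1, log(pi_a_mean), pi_a_log_sd)))
      })
      hgf <- hgf_params(omega2 = par_draw$omega2, omega3 = par_draw$omega3)
      resp <- response_params(
        pi_a = if (config$use_associative) par_draw$pi_a else 0,
        priming_weight = if (config$use_priming) priming_weight else 0,
        sensory_memory_weight =
          if (config$use_sensory_memory) sensory_memory_weight else 0,
        decision_noise = decision_noise)
      responses <- tryCatch(
        simulate_agent(schedule, hgf, resp, config, seed = seeds[s, 3L]),
        hgflearn_instability = function(e) NULL)
      if (!is.null(responses)) break
    }
    if (is.null(responses))
      stop("could not draw stable volatility parameters for subject ", s,
           call. = FALSE)
    subjects[[s]] <- list(schedule = schedule, responses = responses,
                          hgf = hgf, resp = resp)
  }
  structure(subjects, class = "synthetic_cohort", model = model, seed = seed)
}

#' Fit a cohort and run group-level model selection
#'
#' Convenience driver: [fit_subject()] for every cohort member, the
#' subjects-by-models evidence matrix, and [rfx_bms()] on it.
#'
#' @param cohort a [simulate_cohort()] result (or any list of elements
#'   with `schedule` and `responses`).
#' @param models model names to fit.
#' @param opts an [invert_control()].
#' @param bms_samples,bms_seed exceedance Monte-Carlo settings.
#' @return list with `fits`, `evidence` (subjects x models) and `bms`.
#' @export
fit_cohort <- function(cohort, models = model_space(),
                       opts = invert_control(), bms_samples = 1e5,
                       bms_seed = 1) {
  fits <- vector("list", length(cohort))
  for (s in seq_along(cohort)) {
    o <- opts
    o$seed <- opts$seed + s
    fits[[s]] <- fit_subject(cohort[[s]]$responses, cohort[[s]]$schedule,
                             models = models, opts = o)
  }
  evidence <- do.call(rbind, lapply(fits, `[[`, "evidence"))
  rownames(evidence) <- paste0("s", seq_along(fits))
  bms <- rfx_bms(evidence, n_samples = bms_samples, seed = bms_seed)
  list(fits = fits, evidence = evidence, bms = bms)
}

#' Parameter and model recovery study
#'
#' Simulates cohorts from a generating variant over a grid of associative
#' precisions, refits the full model space, and summarizes (i) parameter
#' recovery (correlation, bias, RMSE between generating and recovered
#' subject-level BMA parameters) and (ii) model recovery (the BMS winner
#' and protected exceedance probabilities per replicate). All stages are
#' seeded; `n_replicates = 0` returns empty report tables.
#'
#' @param generating_model variant the agents are simulated from.
#' @param pi_a_grid generating associative precisions, recycled across the
#'   subjects of each replicate cohort.
#' @param n_subjects,n_runs cohort size per replicate.
#' @param n_replicates number of replicate cohorts.
#' @param seed master seed.
#' @param models model space to refit.
#' @param opts an [invert_control()].
#' @param ... passed to [simulate_cohort()].
#' @return A list of class `"recovery_report"` with `parameters` (per
#'   parameter: correlation, bias, RMSE), `models` (per replicate: winner
#'   and PXP of the generating model), and `details` (per-subject
#'   generating vs recovered values).
#' @export
run_recovery <- function(generating_model = "A",
                         pi_a_grid = c(0.8, 1.2, 1.6),
                         n_subjects = 20L, n_runs = 5L, n_replicates = 1L,
                         seed = 1L, models = model_space(),
                         opts = invert_control(n_restarts = 3L), ...) {
  empty <- structure(list(
    parameters = data.frame(param = character(), correlation = numeric(),
                            bias = numeric(), rmse = numeric()),
    models = data.frame(replicate = integer(), winner = character(),
                        pxp_generating = numeric()),
    details = data.frame()), class = "recovery_report")
  if (n_replicates < 1L) return(empty)

  rep_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_replicates))
  details <- list()
  model_rows <- list()
  for (rep in seq_len(n_replicates)) {
    pi_true <- rep_len(pi_a_grid, n_subjects)
    cohort <- simulate_cohort(n_subjects, seed = rep_seeds[rep],
                              model = generating_model, n_runs = n_runs,
                              pi_a_mean = 1, pi_a_log_sd = 0, ...)
    ## impose the grid values exactly (resimulate with the grid precision)
    for (s in seq_len(n_subjects)) {
      cohort[[s]]$resp$pi_a <- pi_true[s]
      cohort[[s]]$responses <- simulate_agent(
        cohort[[s]]$schedule, cohort[[s]]$hgf, cohort[[s]]$resp,
        model_config(generating_model), seed = rep_seeds[rep] + s)
    }
    fc <- fit_cohort(cohort, models = models, opts = opts,
                     bms_seed = rep_seeds[rep] %% 1e6)
    est <- bma(fc$fits, fc$bms)
    pxp <- fc$bms$protected_exceedance_probability
    model_rows[[rep]] <- data.frame(
      replicate = rep, winner = names(pxp)[which.max(pxp)],
      pxp_generating = unname(pxp[generating_model]))
    details[[rep]] <- data.frame(
      replicate = rep, subject = seq_len(n_subjects),
      pi_a_true = pi_true,
      omega2_true = vapply(cohort, function(x) x$hgf$omega2, 0),
      omega3_true = vapply(cohort, function(x) x$hgf$omega3, 0),
      pi_a_hat = est$pi_a, omega2_hat = est$omega2, omega3_hat = est$omega3)
  }
  details <- do.call(rbind, details)
  recover_stats <- function(true, hat) {
    data.frame(correlation = if (sd(true) == 0) NA_real_ else cor(true, hat),
               bias = mean(hat - true),
               rmse = sqrt(mean((hat - true)^2)))
  }
  parameters <- rbind(
    cbind(param = "pi_a", recover_stats(details$pi_a_true, details$pi_a_hat)),
    cbind(param = "omega2",
          recover_stats(details$omega2_true, details$omega2_hat)),
    cbind(param = "omega3",
          recover_stats(details$omega3_true, details$omega3_hat)))
  structure(list(parameters = parameters,
                 models = do.call(rbind, model_rows),
                 details = details), class = "recovery_report")
}
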