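#' The eight perceptual response-model variants
#'
#' `model_space()` lists the names of the eight variants obtained by
#' switching associative learning (A), priming (P) and sensory memory (S)
#' on or off: `"0"`, `"A"`, `"P"`, `"S"`, `"AP"`, `"AS"`, `"PS"`, `"APS"`.
#' `model_config()` turns a name into a flag set.
#'
#' @param name a model-name string from `model_space()`.
#' @return `model_config()`: a list of class `"response_config"` with
#'   logical fields `use_associative`, `use_priming`, `use_sensory_memory`
#'   and the `name`.
#' @examples
#' model_space()
#' model_config("AP")
#' @export
model_space <- function() c("0", "A", "P", "S", "AP", "AS", "PS", "APS")

#' @rdname model_space
#' @export
model_config <- function(name) {
  name <- match.arg(name, model_space())
  structure(list(name = name,
                 use_associative = grepl("A", name, fixed = TRUE),
                 use_priming = grepl("P", name, fixed = TRUE),
                 use_sensory_memory = grepl("S", name, fixed = TRUE)),
            class = "response_config")
}

#' Response-model parameters
#'
#' Parameters mapping the contingency-model beliefs to the two reports.
#' `pi_a` scales how strongly the inferred conditional probability of a CW
#' rotation biases perception (associative-learning precision, on the
#' log-odds scale); `priming_weight` weights the preceding trial's percept;
#' `sensory_memory_weight` weights the preceding ambiguous trial's percept
#' on the next ambiguous trial; `decision_noise` is the noise of the
#' prediction report (the report follows a unit-square sigmoid of `mu_a`
#' with exponent `1/decision_noise`, so large noise pushes the report
#' probability to 0.5).
#'
#' @param pi_a non-negative associative-learning precision.
#' @param priming_weight,sensory_memory_weight finite log-odds weights.
#' @param decision_noise positive prediction-report noise.
#' @return a validated list of class `"response_params"`.
#' @export
response_params <- function(pi_a = 1, priming_weight = 0,
                            sensory_memory_weight = 0,
                            decision_noise = 1 / 48) {
  p <- list(pi_a = pi_a, priming_weight = priming_weight,
            sensory_memory_weight = sensory_memory_weight,
            decision_noise = decision_noise)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                  logical(1L))))
    stop("all response parameters must be finite scalars", call. = FALSE)
  if (p$pi_a < 0) stop("`pi_a` must be non-negative", call. = FALSE)
  if (p$decision_noise <= 0) stop("`decision_noise` must be positive", call. = FALSE)
  structure(p, class = "response_params")
}

## log-odds of the stimulus evidence on unambiguous trials; chosen so that
## perception of an unambiguous rotation is correct with probability
## 1 - 1e-4 under the null model (observed accuracy was near- but not
## exactly perfect)
.stimulus_evidence <- qlogis(1 - 1e-4)

signed_percept <- function(percept) {
  s <- ifelse(is.na(percept), 0, ifelse(percept == "CW", 1, -1))
  as.numeric(s)
}

#' Perceptual posterior probability of a CW percept
#'
#' Combines, additively in log-odds before a logistic squash: (i) the
#' stimulus evidence (decisive for unambiguous rotations, null for
#' ambiguous probes), (ii) the contingency prediction `mu_a` weighted by
#' `pi_a` when associative learning is on, (iii) the preceding trial's
#' percept weighted by `priming_weight` when priming is on, and (iv) the
#' preceding ambiguous trial's percept weighted by `sensory_memory_weight`
#' on ambiguous trials when sensory memory is on. History never crosses run
#' boundaries and first-trial history terms contribute zero.
#'
#' @param schedule a `task_schedule` (one or more runs).
#' @param traj the matching [hgf_filter()] trajectories.
#' @param config a [model_config()].
#' @param params a [response_params()].
#' @param percept_history character vector (`"CW"`/`"CCW"`/`NA`), one entry
#'   per trial, supplying the percepts that condition the history terms
#'   (observed reports when evaluating a likelihood). Entry `t` is only
#'   ever used on trials after `t`. Defaults to all-missing history.
#' @return A data frame with columns `P_theta1` (posterior probability of
#'   perceiving CW, equal to the CW-report probability) and `mu_a`.
#' @export
perception_probability <- function(schedule, traj, config, params,
                                   percept_history = NULL) {
  stopifnot(inherits(config, "response_config"),
            inherits(params, "response_params"),
            nrow(schedule) == nrow(traj))
  if (is.null(percept_history))
    percept_history <- rep(NA_character_, nrow(schedule))
  stopifnot(length(percept_history) == nrow(schedule))
  mu_a <- schedule_mu_a(schedule, traj)
  idx <- seq_len(nrow(schedule))
  out <- numeric(nrow(schedule))
  for (r in unique(schedule$run)) {
    i <- idx[schedule$run == r]
    out[i] <- .perception_logodds(schedule$rotation[i], mu_a[i],
                                  percept_history[i], config, params)
  }
  data.frame(P_theta1 = clamp01(plogis(out)), mu_a = mu_a)
}

## log-odds of a CW percept for one run
.perception_logodds <- function(rotation, mu_a, percepts, config, params) {
  n <- length(rotation)
  evid <- ifelse(rotation == "CW", .stimulus_evidence,
                 ifelse(rotation == "CCW", -.stimulus_evidence, 0))
  lo <- evid
  if (config$use_associative)
    lo <- lo + params$pi_a * qlogis(clamp01(mu_a))
  s <- signed_percept(percepts)
  if (config$use_priming)
    lo <- lo + params$priming_weight * c(0, s[-n])[seq_len(n)]
  if (config$use_sensory_memory) {
    amb <- rotation == "none"
    prev_amb <- rep(0, n)
    last <- 0
    for (t in seq_len(n)) {
      if (amb[t]) {
        prev_amb[t] <- last
        last <- s[t]
      }
    }
    lo <- lo + params$sensory_memory_weight * prev_amb
  }
  lo
}

#' Probability of predicting a CW rotation
#'
#' The prediction report follows a unit-square sigmoid of the conditional
#' prediction: `p = mu_a^z / (mu_a^z + (1 - mu_a)^z)` with exponent
#' `z = 1/decision_noise`. The probability is 0.5 at `mu_a = 0.5`, strictly
#' increasing in `mu_a`, and collapses to 0.5 as the noise grows.
#'
#' @param mu_a conditional CW probability (vectorized).
#' @param params a [response_params()].
#' @return numeric vector of CW-prediction probabilities.
#' @export
prediction_probability <- function(mu_a, params) {
  stopifnot(inherits(params, "response_params"))
  clamp01(plogis(qlogis(clamp01(mu_a)) / params$decision_noise))
}

#' Joint log-likelihood of the dual reports
#'
#' Sums the log probabilities of the observed prediction and perception
#' reports under the given response-model variant; missing reports
#' contribute zero.
#'
#' @param responses a data frame with `prediction` and `perception` columns
#'   (`"CW"`/`"CCW"`/`NA`), aligned with `schedule`.
#' @inheritParams perception_probability
#' @return the scalar log-likelihood.
#' @export
log_likelihood <- function(responses, schedule, traj, config, params) {
  if (nrow(responses) != nrow(schedule))
    stop("`responses` and `schedule` must have the same number of trials",
         call. = FALSE)
  mu_a <- schedule_mu_a(schedule, traj)
  p_pred <- prediction_probability(mu_a, params)
  pp <- perception_probability(schedule, traj, config, params,
                               percept_history = responses$perception)
  ll <- 0
  pred <- responses$prediction
  ok <- !is.na(pred)
  ll <- ll + sum(log(ifelse(pred[ok] == "CW", p_pred[ok], 1 - p_pred[ok])))
  perc <- responses$perception
  ok <- !is.na(perc)
  ll <- ll + sum(log(ifelse(perc[ok] == "CW", pp$P_theta1[ok], 1 - pp$P_theta1[ok])))
  ll
}

#' Trial-wise perceptual quantities for a fitted model
#'
#' Returns `P_theta1`, the perceptual prediction error
#' `delta_q = P_theta1 - y_perception` (with `y = 1` for a CW report) and
#' `mu_a` for each trial; `delta_q` is `NA` on trials with a missing
#' percept.
#'
#' @inheritParams log_likelihood
#' @return data frame with columns `P_theta1`, `delta_q`, `mu_a`.
#' @export
perceptual_quantities <- function(responses, schedule, traj, config, params) {
  pp <- perception_probability(schedule, traj, config, params,
                               percept_history = responses$perception)
  y <- ifelse(is.na(responses$perception), NA_real_,
              as.numeric(responses$perception == "CW"))
  data.frame(P_theta1 = pp$P_theta1, delta_q = pp$P_theta1 - y, mu_a = pp$mu_a)
}
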