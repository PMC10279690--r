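#' Prior specification for model inversion
#'
#' One row per model parameter, giving the prior mean and variance in
#' estimation space, the estimation-space transform (`"identity"` or
#' `"log"`) and whether the parameter is fixed (`prior_variance == 0`).
#' The defaults follow common three-level binary-HGF practice: wide
#' Gaussian priors on the tonic volatilities (`omega2 ~ N(-3, 16)`,
#' `omega3 ~ N(-6, 16)`), a standard-normal prior on `log(pi_a)` and on the
#' priming and sensory-memory log-odds weights, and
#' `log(decision_noise) ~ N(log(1/48), 1)` (the unit-square-sigmoid
#' convention). `kappa` and the initial states are fixed.
#'
#' @param config a [model_config()]; variants only receive priors for the
#'   weights they use.
#' @return a data frame of class `"prior_spec"` with columns `param`,
#'   `prior_mean`, `prior_variance`, `transform`, `fixed`.
#' @export
default_priors <- function(config) {
  stopifnot(inherits(config, "response_config"))
  rows <- list(
    list("omega2", -3, 16, "identity"),
    list("omega3", -6, 16, "identity"),
    list("decision_noise", log(1 / 48), 1, "log"))
  if (config$use_associative) rows <- c(rows, list(list("pi_a", 0, 1, "log")))
  if (config$use_priming)
    rows <- c(rows, list(list("priming_weight", 0, 1, "identity")))
  if (config$use_sensory_memory)
    rows <- c(rows, list(list("sensory_memory_weight", 0, 1, "identity")))
  out <- data.frame(param = vapply(rows, `[[`, "", 1L),
                    prior_mean = vapply(rows, `[[`, 0, 2L),
                    prior_variance = vapply(rows, `[[`, 0, 3L),
                    transform = vapply(rows, `[[`, "", 4L),
                    stringsAsFactors = FALSE)
  out$fixed <- out$prior_variance == 0
  class(out) <- c("prior_spec", "data.frame")
  out
}

#' @rdname default_priors
#' @param param,prior_mean,prior_variance,transform vectors defining a
#'   custom prior table (recycled to common length).
#' @export
prior_spec <- function(param, prior_mean, prior_variance,
                       transform = "identity") {
  out <- data.frame(param = param, prior_mean = prior_mean,
                    prior_variance = prior_variance, transform = transform,
                    stringsAsFactors = FALSE)
  if (any(out$prior_variance < 0))
    stop("prior variances must be >= 0", call. = FALSE)
  if (!all(out$transform %in% c("identity", "log")))
    stop("supported transforms: identity, log", call. = FALSE)
  out$fixed <- out$prior_variance == 0
  class(out) <- c("prior_spec", "data.frame")
  out
}

to_native <- function(est, transform)
  ifelse(transform == "log", exp(est), est)

#' Optimizer options for model inversion
#'
#' @param n_restarts number of optimizer starts: one at the prior mean plus
#'   `n_restarts - 1` draws from the prior.
#' @param seed seed for the restart draws.
#' @param maxit,reltol BFGS iteration cap and relative tolerance on the
#'   objective.
#' @export
invert_control <- function(n_restarts = 8L, seed = 1L, maxit = 500L,
                           reltol = 1e-6) {
  list(n_restarts = as.integer(n_restarts), seed = as.integer(seed),
       maxit = as.integer(maxit), reltol = reltol)
}

## precompute everything the likelihood needs that does not depend on the
## parameter proposal; returns a closure evaluating the negative log-joint
## in estimation space over the free parameters
make_objective <- function(responses, schedule, config, priors) {
  u <- hgf_inputs(schedule)
  tone_high <- schedule$tone == "high"
  rot <- schedule$rotation
  evid <- ifelse(rot == "CW", .stimulus_evidence,
                 ifelse(rot == "CCW", -.stimulus_evidence, 0))
  y_pred <- ifelse(is.na(responses$prediction), NA_real_,
                   as.numeric(responses$prediction == "CW"))
  y_perc <- ifelse(is.na(responses$perception), NA_real_,
                   as.numeric(responses$perception == "CW"))
  ## history terms depend only on the observed percepts: precompute
  n <- nrow(schedule)
  s <- signed_percept(responses$perception)
  s_prev <- rep(0, n)
  prev_amb <- rep(0, n)
  for (r in unique(schedule$run)) {
    i <- which(schedule$run == r)
    s_prev[i] <- c(0, s[i][-length(i)])
    last <- 0
    for (t in i) {
      if (rot[t] == "none") {
        prev_amb[t] <- last
        last <- s[t]
      }
    }
  }
  free <- priors[!priors$fixed, , drop = FALSE]
  fixed <- priors[priors$fixed, , drop = FALSE]
  fixed_native <- setNames(to_native(fixed$prior_mean, fixed$transform),
                           fixed$param)
  prior_sd <- sqrt(free$prior_variance)

  natives_of <- function(est) {
    v <- setNames(to_native(est, free$transform), free$param)
    c(v, fixed_native)
  }
  get_par <- function(v, name, default) if (name %in% names(v)) v[[name]] else default

  neg_log_joint <- function(est) {
    v <- natives_of(est)
    raw <- hgf_filter_cpp(u, get_par(v, "omega2", -3), get_par(v, "omega3", -6),
                          get_par(v, "kappa", 1), get_par(v, "mu2_0", 0),
                          get_par(v, "sigma2_0", 0.1), get_par(v, "mu3_0", 1),
                          get_par(v, "sigma3_0", 1))
    if (!raw$stable) return(1e10)
    mu_a <- clamp01(plogis(raw$muhat2))
    mu_a[!tone_high] <- 1 - mu_a[!tone_high]
    lmu <- qlogis(mu_a)
    p_pred <- clamp01(plogis(lmu / v[["decision_noise"]]))
    lo <- evid
    if (config$use_associative) lo <- lo + v[["pi_a"]] * lmu
    if (config$use_priming) lo <- lo + v[["priming_weight"]] * s_prev
    if (config$use_sensory_memory)
      lo <- lo + v[["sensory_memory_weight"]] * prev_amb
    p_th <- clamp01(plogis(lo))
    ll <- sum(y_pred * log(p_pred) + (1 - y_pred) * log1p(-p_pred), na.rm = TRUE) +
      sum(y_perc * log(p_th) + (1 - y_perc) * log1p(-p_th), na.rm = TRUE)
    lp <- if (nrow(free) > 0)
      sum(dnorm(est, free$prior_mean, prior_sd, log = TRUE)) else 0
    nlj <- -(ll + lp)
    if (!is.finite(nlj)) 1e10 else nlj
  }
  list(fn = neg_log_joint, free = free, fixed_native = fixed_native,
       natives_of = natives_of)
}

#' Fit one model variant to one run by MAP estimation
#'
#' Maximizes the log-joint (log-likelihood plus log-prior) over the free
#' parameters in estimation space with multi-start BFGS, and approximates
#' the log model evidence by a Laplace correction at the mode. Parameter
#' proposals that destabilize the HGF are rejected with an essentially
#' infinite objective.
#'
#' @param responses aligned response table with at least one non-missing
#'   report.
#' @param schedule a single-run `task_schedule`.
#' @param config a [model_config()].
#' @param priors a [default_priors()]-style prior table covering the free
#'   parameters of `config`.
#' @param opts an [invert_control()] list.
#' @return A list of class `"hgf_fit"` with `map_estimates` (native space,
#'   including fixed parameters), `est` (estimation space),
#'   `posterior_covariance` (estimation space, eigenvalue-floored),
#'   `log_evidence`, `log_joint`, `converged`, `n_restarts_used`,
#'   `model_name`, `run_id` and the `priors` used.
#' @export
invert <- function(responses, schedule, config,
                   priors = default_priors(config), opts = invert_control()) {
  stopifnot(inherits(config, "response_config"))
  if (nrow(responses) != nrow(schedule))
    stop("`responses` and `schedule` must align", call. = FALSE)
  if (all(is.na(responses$prediction)) && all(is.na(responses$perception)))
    stop("unfittable run: all reports are missing", call. = FALSE)
  obj <- make_objective(responses, schedule, config, priors)
  free <- obj$free
  d <- nrow(free)

  if (d == 0L) {
    est <- numeric(0)
    val <- obj$fn(est)
    fit <- list(map_estimates = as.list(obj$natives_of(est)), est = est,
                posterior_covariance = matrix(0, 0, 0),
                log_evidence = -val, log_joint = -val, converged = TRUE,
                n_restarts_used = 0L, model_name = config$name,
                run_id = schedule$run[1], priors = priors)
    class(fit) <- "hgf_fit"
    return(fit)
  }

  starts <- with_seed(opts$seed, {
    s <- matrix(rnorm((opts$n_restarts - 1L) * d,
                      mean = rep(free$prior_mean, each = opts$n_restarts - 1L),
                      sd = rep(sqrt(free$prior_variance),
                               each = opts$n_restarts - 1L)),
                ncol = d)
    rbind(free$prior_mean, s)
  })

  best <- NULL
  n_used <- 0L
  for (k in seq_len(nrow(starts))) {
    n_used <- k
    o <- tryCatch(
      optim(starts[k, ], obj$fn, method = "BFGS",
            control = list(maxit = opts$maxit, reltol = opts$reltol)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best))
    stop("optimizer failed on every restart", call. = FALSE)

  H <- pracma::hessian(obj$fn, best$par)
  H <- (H + t(H)) / 2
  ev <- eigen(H, symmetric = TRUE)
  lam <- pmax(ev$values, 1e-8)
  cov <- ev$vectors %*% diag(1 / lam, d) %*% t(ev$vectors)
  dimnames(cov) <- list(free$param, free$param)
  log_evidence <- -best$value + 0.5 * d * log(2 * pi) - 0.5 * sum(log(lam))

  fit <- list(map_estimates = as.list(obj$natives_of(best$par)),
              est = setNames(best$par, free$param),
              posterior_covariance = cov,
              log_evidence = log_evidence, log_joint = -best$value,
              converged = best$convergence == 0L,
              n_restarts_used = n_used, model_name = config$name,
              run_id = schedule$run[1], priors = priors)
  class(fit) <- "hgf_fit"
  fit
}

#' Fit all model variants to every run of a session
#'
#' Runs [invert()] for each (run, model) pair and aggregates per-subject
#' log evidence as the sum of per-run evidences (runs are fitted
#' independently). Unfittable runs are recorded as `NULL` cells and left
#' out of the sums.
#'
#' @param responses session-level response table aligned with `schedule`.
#' @param schedule a multi-run `task_schedule`.
#' @param models character vector of model names (default all eight).
#' @param priors_fun function mapping a [model_config()] to its prior table.
#' @param opts an [invert_control()]; per-(run, model) restart seeds are
#'   derived deterministically from `opts$seed`.
#' @return A list of class `"subject_fits"` with `fits` (list indexed
#'   `[[model]][[run]]`), `run_evidence` (runs x models matrix) and
#'   `evidence` (named per-model sums).
#' @export
fit_subject <- function(responses, schedule, models = model_space(),
                        priors_fun = default_priors, opts = invert_control()) {
  runs <- unique(schedule$run)
  seeds <- with_seed(opts$seed,
                     matrix(sample.int(.Machine$integer.max,
                                       length(runs) * length(models)),
                            nrow = length(runs)))
  fits <- setNames(vector("list", length(models)), models)
  run_ev <- matrix(NA_real_, length(runs), length(models),
                   dimnames = list(paste0("run", runs), models))
  for (m in seq_along(models)) {
    config <- model_config(models[m])
    priors <- priors_fun(config)
    fits[[m]] <- vector("list", length(runs))
    for (r in seq_along(runs)) {
      i <- schedule$run == runs[r]
      o <- opts
      o$seed <- seeds[r, m]
      fit <- tryCatch(
        invert(responses[i, , drop = FALSE], schedule[i, , drop = FALSE],
               config, priors, o),
        error = function(e) NULL)
      fits[[m]][[r]] <- fit
      if (!is.null(fit)) run_ev[r, m] <- fit$log_evidence
    }
  }
  structure(list(fits = fits,
                 run_evidence = run_ev,
                 evidence = colSums(run_ev, na.rm = TRUE)),
            class = "subject_fits")
}
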