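#' Random-effects Bayesian model selection
#'
#' Group-level inference on model frequencies from a subjects-by-models
#' matrix of log model evidences, treating the generating model of each
#' subject as a random variable with Dirichlet-distributed population
#' frequencies. The Dirichlet posterior is obtained by the usual
#' variational scheme; exceedance probabilities (the probability that a
#' model is the most frequent) are estimated by seeded Monte-Carlo sampling
#' from that posterior; the Bayes omnibus risk (posterior probability that
#' all models are equally frequent) protects them:
#' `PXP_k = EP_k * (1 - BOR) + BOR / K`.
#'
#' @param evidence numeric matrix, subjects in rows and models in columns
#'   (column names are used as model names); all entries finite, at least
#'   two models.
#' @param alpha0 Dirichlet prior count per model (default 1, uniform).
#' @param n_samples Monte-Carlo samples for the exceedance probabilities
#'   (default 1e6).
#' @param seed seed for the exceedance sampling.
#' @param tol,max_iter convergence tolerance on the alpha update and
#'   iteration cap of the variational loop.
#' @return A list of class `"bms_result"`: `dirichlet_alpha`,
#'   `expected_frequency`, `exceedance_probability`,
#'   `bayes_omnibus_risk`, `protected_exceedance_probability`,
#'   `subject_posteriors` (subjects x models), `free_energy` (of the
#'   random-effects model) and `null_free_energy`.
#' @references Stephan et al. (2009) NeuroImage 46:1004-17;
#'   Rigoux et al. (2014) NeuroImage 84:971-85.
#' @export
rfx_bms <- function(evidence, alpha0 = 1, n_samples = 1e6, seed = 1,
                    tol = 1e-6, max_iter = 1000L) {
  evidence <- as.matrix(evidence)
  K <- ncol(evidence)
  n <- nrow(evidence)
  if (K < 2L) stop("at least two models are required", call. = FALSE)
  if (!all(is.finite(evidence)))
    stop("`evidence` must be finite", call. = FALSE)
  models <- colnames(evidence)
  if (is.null(models)) models <- paste0("m", seq_len(K))

  alpha <- rep(alpha0, K)
  u <- matrix(1 / K, n, K)
  for (it in seq_len(max_iter)) {
    lu <- sweep(evidence, 2L, digamma(alpha) - digamma(sum(alpha)), `+`)
    lu <- lu - apply(lu, 1L, max)
    u <- exp(lu)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }

  ep <- exceedance_mc(alpha, n_samples, seed)

  ## free energy of the random-effects model (for the omnibus risk)
  psi <- digamma(alpha) - digamma(sum(alpha))
  f1 <- sum(u * evidence) + sum(u %*% psi) - sum(u * log(pmax(u, 1e-300))) +
    lgamma(K * alpha0) - K * lgamma(alpha0) + sum((alpha0 - 1) * psi) -
    (lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * psi))
  ## null model: every model equally frequent
  f0 <- sum(apply(evidence, 1L, function(l) {
    m <- max(l)
    m + log(mean(exp(l - m)))
  }))
  bor <- 1 / (1 + exp(f1 - f0))
  pxp <- ep * (1 - bor) + bor / K

  structure(list(
    dirichlet_alpha = setNames(alpha, models),
    expected_frequency = setNames(alpha / sum(alpha), models),
    exceedance_probability = setNames(ep, models),
    bayes_omnibus_risk = bor,
    protected_exceedance_probability = setNames(pxp, models),
    subject_posteriors = structure(u, dimnames = list(rownames(evidence), models)),
    free_energy = f1, null_free_energy = f0,
    n_iterations = it), class = "bms_result")
}

## Monte-Carlo exceedance probabilities of a Dirichlet posterior
exceedance_mc <- function(alpha, n_samples, seed) {
  K <- length(alpha)
  with_seed(seed, {
    counts <- integer(K)
    chunk <- 1e5
    left <- n_samples
    while (left > 0) {
      m <- min(chunk, left)
      g <- matrix(rgamma(m * K, shape = rep(alpha, each = m)), nrow = m)
      w <- max.col(g, ties.method = "first")
      counts <- counts + tabulate(w, K)
      left <- left - m
    }
    counts / n_samples
  })
}

#' Bayesian model averaging of fitted parameters
#'
#' Averages each subject's MAP parameter estimates across the model
#' variants, weighted by that subject's posterior model probabilities from
#' [rfx_bms()]. A parameter absent from a variant contributes that
#' variant's prior mean (in native space), so that averages are defined
#' over the full model space. Subjects' missing fit cells are excluded and
#' the remaining weights renormalized (with a message).
#'
#' @param fits list of [fit_subject()] results, one per subject, covering
#'   the models in `bms`.
#' @param bms a [rfx_bms()] result on the matching evidence matrix.
#' @return data frame with one row per subject and one column per
#'   parameter (plus `subject`).
#' @export
bma <- function(fits, bms) {
  stopifnot(inherits(bms, "bms_result"))
  models <- colnames(bms$subject_posteriors)
  n <- length(fits)
  if (n != nrow(bms$subject_posteriors))
    stop("`fits` must have one element per BMS subject", call. = FALSE)

  ## union of native parameters over the model space, and per-model prior
  ## means in native space (taken from the first subject's prior tables)
  prior_native <- lapply(models, function(m) {
    pr <- NULL
    for (s in seq_len(n)) {
      f <- fits[[s]]$fits[[m]]
      f <- Filter(Negate(is.null), f)
      if (length(f) > 0) { pr <- f[[1]]$priors; break }
    }
    if (is.null(pr)) return(NULL)
    setNames(to_native(pr$prior_mean, pr$transform), pr$param)
  })
  names(prior_native) <- models
  params <- unique(unlist(lapply(prior_native, names)))
  ## fallback value for a parameter a variant does not carry: the prior
  ## mean (native space) taken from the variants that do
  prior_fill <- vapply(params, function(p) {
    for (m in models)
      if (!is.null(prior_native[[m]]) && p %in% names(prior_native[[m]]))
        return(prior_native[[m]][[p]])
    NA_real_
  }, numeric(1L))

  out <- matrix(NA_real_, n, length(params),
                dimnames = list(NULL, params))
  dropped <- 0L
  for (s in seq_len(n)) {
    w <- bms$subject_posteriors[s, ]
    vals <- matrix(NA_real_, length(models), length(params),
                   dimnames = list(models, params))
    for (m in models) {
      runs <- Filter(Negate(is.null), fits[[s]]$fits[[m]])
      if (length(runs) == 0L) next
      ## per-subject MAP: average of per-run MAP estimates
      for (p in params) {
        per_run <- vapply(runs, function(f) {
          if (p %in% names(f$map_estimates)) f$map_estimates[[p]]
          else prior_fill[[p]]
        }, numeric(1L))
        vals[m, p] <- mean(per_run, na.rm = TRUE)
      }
    }
    have <- apply(!is.na(vals), 1L, any)
    if (!all(have)) {
      dropped <- dropped + sum(!have)
      w <- w[have] / sum(w[have])
      vals <- vals[have, , drop = FALSE]
    }
    for (p in params) {
      v <- vals[, p]
      ok <- !is.na(v)
      out[s, p] <- sum(w[ok] * v[ok]) / sum(w[ok])
    }
  }
  if (dropped > 0L)
    message("bma: excluded ", dropped,
            " missing model cells (weights renormalized)")
  data.frame(subject = seq_len(n), out, check.names = FALSE)
}
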