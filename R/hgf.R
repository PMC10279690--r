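#' Parameters of the three-level binary HGF
#'
#' Container for the contingency-model parameters. The filter tracks a
#' binary contingency state through three coupled levels: level 1 is the
#' trial outcome, level 2 the log-odds tendency of the association, and
#' level 3 its log-volatility. `omega2` and `omega3` are the tonic
#' log-volatilities (learning rates) of levels 2 and 3; `kappa` couples
#' level 3 to the level-2 step variance and is conventionally fixed at 1.
#'
#' @param omega2,omega3 tonic log-volatility of levels 2 and 3.
#' @param kappa positive level-2/3 coupling strength.
#' @param mu2_0,sigma2_0 initial level-2 mean and variance.
#' @param mu3_0,sigma3_0 initial level-3 mean and variance.
#' @return a validated list of class `"hgf_params"`.
#' @examples
#' p <- hgf_params(omega2 = -3, omega3 = -6)
#' @export
hgf_params <- function(omega2 = -3, omega3 = -6, kappa = 1,
                       mu2_0 = 0, sigma2_0 = 0.1, mu3_0 = 1, sigma3_0 = 1) {
  p <- list(omega2 = omega2, omega3 = omega3, kappa = kappa,
            mu2_0 = mu2_0, sigma2_0 = sigma2_0,
            mu3_0 = mu3_0, sigma3_0 = sigma3_0)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                  logical(1L))))
    stop("all HGF parameters must be finite scalars", call. = FALSE)
  if (p$kappa <= 0) stop("`kappa` must be positive", call. = FALSE)
  if (p$sigma2_0 <= 0 || p$sigma3_0 <= 0)
    stop("initial variances must be positive", call. = FALSE)
  structure(p, class = "hgf_params")
}

#' Filter a binary input sequence through the three-level HGF
#'
#' Runs the forward belief updates over a 0/1 input sequence (with `NA`
#' marking trials without an objective outcome, on which the belief state is
#' frozen) and returns the full trial-wise trajectory table. Prediction
#' ("hatted") quantities are computed before each trial's input, posterior
#' states after it.
#'
#' @param inputs numeric vector of 0, 1 and `NA`.
#' @param params an [hgf_params()] object.
#' @return A data frame of class `"hgf_trajectories"` with one row per
#'   trial and columns `muhat1`, `muhat2`, `muhat3`, `pihat2`, `pihat3`,
#'   `delta1`, `eps2`, `eps3`, `mu2`, `mu3`, `sigma2`, `sigma3`.
#'   `eps2`/`eps3` are the precision-weighted prediction errors (the belief
#'   update at that level); `delta1` is the outcome prediction error.
#' @section Model instability:
#'   Parameter regimes in which a posterior precision becomes non-positive
#'   raise an error of class `"hgflearn_instability"` naming the trial, so
#'   that model inversion can reject the proposal.
#' @examples
#' run <- generate_run(1)
#' traj <- hgf_filter(hgf_inputs(run), hgf_params())
#' head(traj)
#' @export
hgf_filter <- function(inputs, params = hgf_params()) {
  stopifnot(inherits(params, "hgf_params"))
  inputs <- as.numeric(inputs)
  if (length(inputs) == 0L) stop("`inputs` must be nonempty", call. = FALSE)
  if (!all(is.na(inputs) | inputs %in% c(0, 1)))
    stop("`inputs` must contain only 0, 1 or NA", call. = FALSE)
  res <- hgf_filter_raw(inputs, params)
  if (!res$stable) {
    stop(structure(class = c("hgflearn_instability", "error", "condition"),
                   list(message = sprintf(
                     "HGF update unstable at trial %d (omega2=%.3g, omega3=%.3g, kappa=%.3g)",
                     res$bad_trial, params$omega2, params$omega3, params$kappa),
                     call = sys.call(-1))))
  }
  traj <- as.data.frame(res[c("muhat1", "muhat2", "muhat3", "pihat2", "pihat3",
                              "delta1", "eps2", "eps3",
                              "mu2", "mu3", "sigma2", "sigma3")])
  class(traj) <- c("hgf_trajectories", "data.frame")
  traj
}

## thin wrapper over the compiled filter; returns the raw list incl. the
## stability flag (used by the inversion objective to reject proposals
## without the cost of a condition)
hgf_filter_raw <- function(inputs, params) {
  hgf_filter_cpp(inputs, params$omega2, params$omega3, params$kappa,
                 params$mu2_0, params$sigma2_0, params$mu3_0, params$sigma3_0)
}

#' Conditional rotation prediction given the tone
#'
#' Maps the pre-trial level-2 belief to `mu_a`, the inferred conditional
#' probability of a clockwise rotation given the presented tone: the
#' logistic of `muhat2` when the tone is the CW-associated cue under
#' contingency coding `"c1"` (the high tone), and its complement otherwise.
#' Values are clamped to (1e-8, 1 - 1e-8).
#'
#' @param muhat2 numeric vector of pre-trial level-2 means.
#' @param tone character vector of `"low"`/`"high"`, recycled to the length
#'   of `muhat2`.
#' @return numeric vector of probabilities in (0, 1).
#' @examples
#' conditional_prediction(0, "high")    # 0.5
#' conditional_prediction(4, "high")    # ~0.982
#' @export
conditional_prediction <- function(muhat2, tone) {
  stopifnot(all(tone %in% c("low", "high")))
  p <- clamp01(plogis(muhat2))
  ifelse(rep_len(tone, length(p)) == "high", p, 1 - p)
}

## per-trial mu_a for a whole schedule
schedule_mu_a <- function(schedule, traj) {
  conditional_prediction(traj$muhat2, schedule$tone)
}

clamp01 <- function(p, eps = 1e-8) pmin(pmax(p, eps), 1 - eps)
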