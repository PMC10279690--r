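sim_fixture <- function(seed, pi_a = 1.4, model = "A") {
  run <- generate_run(seed = seed)
  resp <- simulate_agent(run, hgf_params(), response_params(pi_a = pi_a),
                         model_config(model), seed = seed + 1000L)
  list(run = run, resp = resp)
}

test_that("degenerate zero-variance priors pin the MAP at the prior means with evidence = log-likelihood", {
  fx <- sim_fixture(1)
  config <- model_config("A")
  pr <- prior_spec(param = c("omega2", "omega3", "decision_noise", "pi_a"),
                   prior_mean = c(-3, -6, log(1 / 48), log(1.4)),
                   prior_variance = 0,
                   transform = c("identity", "identity", "log", "log"))
  fit <- invert(fx$resp, fx$run, config, priors = pr)
  expect_equal(fit$map_estimates$omega2, -3)
  expect_equal(fit$map_estimates$pi_a, 1.4)
  traj <- hgf_filter(hgf_inputs(fx$run), hgf_params())
  ll <- log_likelihood(fx$resp, fx$run, traj, config,
                       response_params(pi_a = 1.4))
  expect_equal(fit$log_evidence, ll, tolerance = 1e-10)
})

test_that("the MAP improves on the prior mean and repeated inversion is deterministic", {
  fx <- sim_fixture(2)
  config <- model_config("A")
  priors <- default_priors(config)
  opts <- invert_control(n_restarts = 3, seed = 9)
  fit1 <- invert(fx$resp, fx$run, config, priors, opts)
  fit2 <- invert(fx$resp, fx$run, config, priors, opts)
  expect_identical(fit1$est, fit2$est)
  expect_identical(fit1$log_evidence, fit2$log_evidence)
  obj <- hgflearn:::make_objective(fx$resp, fx$run, config, priors)
  expect_lte(-fit1$log_joint, obj$fn(priors$prior_mean[!priors$fixed]))
  expect_true(fit1$converged)
  # covariance is symmetric positive definite after flooring
  ev <- eigen(fit1$posterior_covariance, symmetric = TRUE)$values
  expect_true(all(ev > 0))
  expect_equal(fit1$posterior_covariance, t(fit1$posterior_covariance))
})

test_that("runs with no usable reports are rejected", {
  run <- generate_run(seed = 3)
  none <- make_responses(rep(NA_character_, 72), rep(NA_character_, 72))
  expect_error(invert(none, run, model_config("0")), "unfittable")
})

test_that("the generating pi_a is recovered within the 95% Laplace interval in most simulated runs", {
  hits <- 0L
  n_sim <- 25L
  for (i in seq_len(n_sim)) {
    sess <- generate_session(seed = 300 + i, n_runs = 2)
    resp <- simulate_agent(sess, hgf_params(), response_params(pi_a = 1.4),
                           model_config("A"), seed = 400 + i)
    # per-session fit: pool the two runs by fitting each and averaging in
    # estimation space weighted by precision would overreach; use run 1+2
    # jointly via a single schedule (runs share the same agent parameters)
    config <- model_config("A")
    fit <- invert(resp, sess, config, opts = invert_control(n_restarts = 3,
                                                            seed = i))
    est <- fit$est["pi_a"]
    se <- sqrt(fit$posterior_covariance["pi_a", "pi_a"])
    hits <- hits + (log(1.4) >= est - 1.96 * se && log(1.4) <= est + 1.96 * se)
  }
  expect_gte(hits / n_sim, 0.8)
})

test_that("the Occam penalty keeps the simpler generating model competitive", {
  # data generated from the null model: the full model's extra parameters
  # must not buy evidence on average
  d0 <- dA <- numeric(12)
  for (i in 1:12) {
    run <- generate_run(seed = 500 + i)
    resp <- simulate_agent(run, hgf_params(),
                           response_params(pi_a = 0), model_config("0"),
                           seed = 600 + i)
    opts <- invert_control(n_restarts = 2, seed = i)
    d0[i] <- invert(resp, run, model_config("0"), opts = opts)$log_evidence
    dA[i] <- invert(resp, run, model_config("APS"), opts = opts)$log_evidence
  }
  expect_gte(mean(d0), mean(dA) - 1)
})

test_that("widening the prior on an irrelevant parameter lowers the evidence", {
  run <- generate_run(seed = 700)
  resp <- simulate_agent(run, hgf_params(), response_params(pi_a = 0),
                         model_config("0"), seed = 701)
  config <- model_config("A")  # pi_a is irrelevant for these data
  ev <- vapply(c(0.25, 1, 4, 16), function(v) {
    pr <- prior_spec(param = c("omega2", "omega3", "decision_noise", "pi_a"),
                     prior_mean = c(-3, -6, log(1 / 48), 0),
                     prior_variance = c(0, 0, 0, v),
                     transform = c("identity", "identity", "log", "log"))
    invert(resp, run, config, priors = pr,
           opts = invert_control(n_restarts = 2, seed = 3))$log_evidence
  }, numeric(1))
  expect_true(all(diff(ev) < 0))
})

test_that("fit_subject covers every run-model pair deterministically", {
  sess <- generate_session(seed = 17, n_runs = 2)
  resp <- simulate_agent(sess, seed = 18)
  models <- c("0", "A", "P")
  opts <- invert_control(n_restarts = 2, seed = 5)
  fs <- fit_subject(resp, sess, models = models, opts = opts)
  expect_equal(dim(fs$run_evidence), c(2L, 3L))
  expect_true(all(is.finite(fs$run_evidence)))
  expect_equal(fs$evidence, colSums(fs$run_evidence))
  expect_equal(length(fs$fits[["A"]]), 2L)
  fs2 <- fit_subject(resp, sess, models = models, opts = opts)
  expect_identical(fs$run_evidence, fs2$run_evidence)
})
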