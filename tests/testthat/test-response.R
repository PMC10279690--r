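make_mini_schedule <- function(rotation, tone = NULL, contingency = "c1") {
  n <- length(rotation)
  if (is.null(tone)) tone <- rep("high", n)
  structure(data.frame(
    session = 1L, run = 1L, trial = seq_len(n),
    block = (seq_len(n) - 1L) %/% 8L + 1L,
    tone = tone, contingency = rep_len(contingency, n),
    trial_type = ifelse(rotation == "none", "ambiguous", "unamb"),
    rotation = rotation, stringsAsFactors = FALSE),
    class = c("task_schedule", "data.frame"))
}

flat_traj <- function(n, muhat2 = 0) {
  structure(data.frame(muhat1 = plogis(muhat2), muhat2 = muhat2, muhat3 = 1,
                       pihat2 = 1, pihat3 = 1, delta1 = 0, eps2 = 0, eps3 = 0,
                       mu2 = muhat2, mu3 = 1, sigma2 = 1, sigma3 = 1),
            class = c("hgf_trajectories", "data.frame"))[rep(1, n), ]
}

test_that("the null model is indifferent on ambiguous trials and decisive on unambiguous ones", {
  sch <- make_mini_schedule(c("none", "CW", "CCW", "none"))
  pp <- perception_probability(sch, flat_traj(4), model_config("0"),
                               response_params())
  expect_equal(pp$P_theta1[c(1, 4)], c(0.5, 0.5))
  expect_equal(pp$P_theta1[2], 1 - 1e-4, tolerance = 1e-10)
  expect_equal(pp$P_theta1[3], 1e-4, tolerance = 1e-10)
})

test_that("all eight variants collapse to the null model at zero weights", {
  sess <- generate_session(seed = 21, n_runs = 1)
  resp <- simulate_agent(sess, seed = 22)
  traj <- hgf_filter(hgf_inputs(sess), hgf_params())
  p0 <- response_params(pi_a = 0, priming_weight = 0,
                        sensory_memory_weight = 0)
  ll0 <- log_likelihood(resp, sess, traj, model_config("0"), p0)
  for (m in model_space()) {
    expect_equal(log_likelihood(resp, sess, traj, model_config(m), p0), ll0,
                 label = m)
    pp <- perception_probability(sess, traj, model_config(m), p0,
                                 percept_history = resp$perception)
    expect_equal(pp$P_theta1,
                 perception_probability(sess, traj, model_config("0"), p0,
                                        percept_history = resp$perception)$P_theta1)
  }
})

test_that("per-trial report probabilities are normalized for all configs under random parameters", {
  sess <- generate_session(seed = 31, n_runs = 1)
  traj <- hgf_filter(hgf_inputs(sess), hgf_params())
  resp <- simulate_agent(sess, seed = 32)
  set.seed(5)
  for (i in 1:200) {
    m <- sample(model_space(), 1)
    pars <- response_params(pi_a = exp(rnorm(1)), priming_weight = rnorm(1),
                            sensory_memory_weight = rnorm(1),
                            decision_noise = exp(rnorm(1, -3)))
    pp <- perception_probability(sess, traj, model_config(m), pars,
                                 percept_history = resp$perception)
    expect_true(all(pp$P_theta1 > 0 & pp$P_theta1 < 1))
    ppred <- prediction_probability(pp$mu_a, pars)
    expect_true(all(ppred > 0 & ppred < 1))
    # complement symmetry: the CCW probabilities are the complements
    expect_equal(pp$P_theta1 + (1 - pp$P_theta1), rep(1, nrow(sess)))
  }
})

test_that("associative bias on ambiguous trials is monotone in pi_a on both sides of indifference", {
  sch <- make_mini_schedule("none")
  for (mu2 in c(1.2, -1.2)) {
    tr <- flat_traj(1, muhat2 = mu2)
    p <- vapply(seq(0, 4, by = 0.25), function(pa) {
      perception_probability(sch, tr, model_config("A"),
                             response_params(pi_a = pa))$P_theta1
    }, numeric(1))
    if (mu2 > 0) expect_true(all(diff(p) > 0)) else expect_true(all(diff(p) < 0))
    expect_equal(p[1], 0.5)  # pi_a = 0: unbiased
  }
})

test_that("priming and sensory memory pull toward the remembered percept with zero first-trial influence", {
  sch <- make_mini_schedule(c("none", "none", "CW", "none"))
  tr <- flat_traj(4)
  hist <- c("CW", "CCW", "CW", NA)
  pp <- perception_probability(sch, tr, model_config("P"),
                               response_params(priming_weight = 1),
                               percept_history = hist)
  expect_equal(pp$P_theta1[1], 0.5)            # no history yet
  expect_equal(pp$P_theta1[2], plogis(1))      # previous percept CW
  expect_equal(pp$P_theta1[4], plogis(1))      # previous percept CW (trial 3)

  pp_s <- perception_probability(sch, tr, model_config("S"),
                                 response_params(sensory_memory_weight = 2),
                                 percept_history = hist)
  expect_equal(pp_s$P_theta1[1], 0.5)          # first ambiguous: no memory
  expect_equal(pp_s$P_theta1[2], plogis(2))    # previous ambiguous percept CW
  expect_equal(pp_s$P_theta1[4], plogis(-2))   # previous ambiguous percept CCW
})

test_that("prediction probabilities are monotone in mu_a and collapse to 0.5 under heavy noise", {
  pars <- response_params(decision_noise = 1)
  expect_equal(prediction_probability(0.5, pars), 0.5)
  grid <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(prediction_probability(grid, pars)) > 0))
  expect_gt(prediction_probability(0.9, pars), prediction_probability(0.6, pars))
  # the near-deterministic default saturates on decisive beliefs
  expect_gt(prediction_probability(0.75, response_params()), 0.999)
  noisy <- response_params(decision_noise = 1e6)
  expect_equal(prediction_probability(c(0.1, 0.9), noisy), c(0.5, 0.5),
               tolerance = 1e-4)
})

test_that("the joint log-likelihood sums the two report channels and skips missing reports", {
  run <- generate_run(seed = 41)
  traj <- hgf_filter(hgf_inputs(run), hgf_params())
  all_missing <- make_responses(rep(NA_character_, 72), rep(NA_character_, 72))
  expect_identical(
    log_likelihood(all_missing, run, traj, model_config("0"), response_params()),
    0)

  # constructed null-model run: correct unambiguous percepts, missing
  # predictions -> 63 log(1 - 1e-4) + 9 log(0.5)
  amb <- run$trial_type == "ambiguous"
  perc <- ifelse(amb, "CW", run$rotation)
  resp <- make_responses(rep(NA_character_, 72), perc)
  ll <- log_likelihood(resp, run, traj, model_config("0"), response_params())
  expect_equal(ll, 63 * log(1 - 1e-4) + 9 * log(0.5), tolerance = 1e-10)

  expect_error(
    log_likelihood(resp[1:10, ], run, traj, model_config("0"), response_params()),
    "same number of trials")
})

test_that("data simulated with associative learning are better explained by model A than model 0", {
  wins <- 0L
  for (i in 1:20) {
    run <- generate_run(seed = 100 + i)
    traj <- hgf_filter(hgf_inputs(run), hgf_params())
    pars <- response_params(pi_a = 2)
    resp <- simulate_agent(run, hgf_params(), pars, model_config("A"),
                           seed = 200 + i)
    llA <- log_likelihood(resp, run, traj, model_config("A"), pars)
    ll0 <- log_likelihood(resp, run, traj, model_config("0"), pars)
    wins <- wins + (llA > ll0)
  }
  expect_gt(wins, 15L)
})

test_that("delta_q is the posterior percept probability minus the binary report", {
  sch <- make_mini_schedule(c("CW", "none", "CCW"))
  tr <- flat_traj(3)
  resp <- make_responses(rep(NA_character_, 3), c("CW", "CCW", NA))
  pq <- perceptual_quantities(resp, sch, tr, model_config("0"), response_params())
  expect_equal(pq$delta_q[1], pq$P_theta1[1] - 1)
  expect_equal(pq$delta_q[2], pq$P_theta1[2] - 0)
  expect_true(is.na(pq$delta_q[3]))
  expect_true(all(abs(pq$delta_q) <= 1, na.rm = TRUE))
})
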