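test_that("identical evidence columns give uniform frequencies and PXP = 1/K", {
  lme <- matrix(rnorm(30, -100, 5), 10, 3)
  lme <- lme[, c(1, 1, 1)]  # all models identical per subject
  colnames(lme) <- c("a", "b", "c")
  b <- rfx_bms(lme, n_samples = 2e5, seed = 1)
  expect_equal(unname(b$expected_frequency), rep(1 / 3, 3), tolerance = 1e-6)
  expect_equal(unname(b$protected_exceedance_probability), rep(1 / 3, 3),
               tolerance = 0.02)
  expect_gt(b$bayes_omnibus_risk, 0.5)  # nothing distinguishes the models
})

test_that("a dominant model reaches PXP >= 0.99", {
  K <- 4L
  lme <- matrix(rnorm(20 * K, -120, 1), 20, K)
  lme[, 2] <- lme[, 2] + 10
  colnames(lme) <- c("m1", "m2", "m3", "m4")
  b <- rfx_bms(lme, n_samples = 2e5, seed = 2)
  expect_gte(b$protected_exceedance_probability[["m2"]], 0.99)
  expect_equal(names(which.max(b$expected_frequency)), "m2")
})

test_that("exceedance probabilities agree with the exact-posterior oracle on decisive 2-model toys", {
  # symmetric case: EP = 1/2 exactly
  lme0 <- cbind(c(0, 0, 0), 0)
  b0 <- rfx_bms(lme0, n_samples = 2e5, seed = 3)
  expect_equal(unname(b0$exceedance_probability), c(0.5, 0.5), tolerance = 0.01)
  # decisive per-subject evidence: variational and exact posteriors agree
  for (d in list(c(5, 4, 3), c(8, 6, 7), c(4, 4, 4))) {
    lme <- cbind(d, 0)
    b <- rfx_bms(lme, n_samples = 2e5, seed = 4)
    expect_equal(unname(b$exceedance_probability[1]), oracle_ep_2models(lme),
                 tolerance = 0.02, label = paste(d, collapse = ","))
  }
})

test_that("probability vectors normalize and the PXP identity holds exactly", {
  set.seed(8)
  lme <- matrix(rnorm(40, -80, 3), 8, 5)
  colnames(lme) <- paste0("m", 1:5)
  b <- rfx_bms(lme, n_samples = 1e5, seed = 5)
  expect_equal(sum(b$expected_frequency), 1, tolerance = 1e-6)
  expect_equal(sum(b$exceedance_probability), 1, tolerance = 1e-6)
  expect_equal(unname(rowSums(b$subject_posteriors)), rep(1, 8),
               tolerance = 1e-6)
  expect_equal(b$protected_exceedance_probability,
               b$exceedance_probability * (1 - b$bayes_omnibus_risk) +
                 b$bayes_omnibus_risk / 5)
  expect_true(b$bayes_omnibus_risk >= 0 && b$bayes_omnibus_risk <= 1)
  # seeded sampling is bit-reproducible
  b2 <- rfx_bms(lme, n_samples = 1e5, seed = 5)
  expect_identical(b$exceedance_probability, b2$exceedance_probability)
})

test_that("duplicating a model column splits its mass but preserves the family frequency", {
  set.seed(9)
  lme <- matrix(rnorm(60, -100, 2), 20, 3)
  lme[, 1] <- lme[, 1] + 3
  colnames(lme) <- c("m1", "m2", "m3")
  b3 <- rfx_bms(lme, n_samples = 1e5, seed = 6)
  lme4 <- cbind(lme, m1b = lme[, 1])
  b4 <- rfx_bms(lme4, n_samples = 1e5, seed = 6)
  fam <- b4$expected_frequency[["m1"]] + b4$expected_frequency[["m1b"]]
  expect_equal(fam, b3$expected_frequency[["m1"]], tolerance = 0.05)
  expect_equal(b4$expected_frequency[["m1"]], b4$expected_frequency[["m1b"]],
               tolerance = 0.02)
})

test_that("degenerate evidence matrices are rejected", {
  expect_error(rfx_bms(matrix(0, 5, 1)), "two models")
  expect_error(rfx_bms(matrix(c(0, Inf), 1, 2)), "finite")
})

test_that("BMA reduces to the MAP under a certain model and averages under equal weights", {
  sess <- generate_session(seed = 51, n_runs = 2)
  resp <- simulate_agent(sess, hgf_params(), response_params(pi_a = 1.4),
                         model_config("A"), seed = 52)
  fs <- fit_subject(resp, sess, models = c("0", "A"),
                    opts = invert_control(n_restarts = 2, seed = 3))
  # force a degenerate BMS: model A certain
  b <- rfx_bms(rbind(c(-1000, 0)), n_samples = 1e4, seed = 1)
  colnames(b$subject_posteriors) <- c("0", "A")
  est <- bma(list(fs), b)
  map_pi_a <- mean(vapply(fs$fits[["A"]], function(f) f$map_estimates$pi_a, 0))
  expect_equal(est$pi_a, map_pi_a, tolerance = 1e-8)

  # equal weights: parameters shared by both models average; pi_a mixes the
  # MAP with the prior mean contributed by the model that lacks it
  beq <- b
  beq$subject_posteriors[1, ] <- c(0.5, 0.5)
  est_eq <- bma(list(fs), beq)
  expect_equal(est_eq$pi_a, 0.5 * map_pi_a + 0.5 * 1, tolerance = 1e-8)
  map_om2 <- vapply(c("0", "A"), function(m)
    mean(vapply(fs$fits[[m]], function(f) f$map_estimates$omega2, 0)), 0)
  expect_equal(est_eq$omega2, unname(mean(map_om2)), tolerance = 1e-8)
})
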