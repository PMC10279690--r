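# Independent oracles, written as literal step-by-step transcriptions of the
# published procedures; they deliberately share no code with the package.

# Three-level binary HGF forward pass, one explicit update at a time.
oracle_hgf <- function(u, omega2, omega3, kappa = 1,
                       mu2_0 = 0, sigma2_0 = 0.1, mu3_0 = 1, sigma3_0 = 1) {
  n <- length(u)
  cols <- c("muhat1", "muhat2", "muhat3", "pihat2", "pihat3",
            "delta1", "eps2", "eps3", "mu2", "mu3", "sigma2", "sigma3")
  out <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  m2 <- mu2_0; s2 <- sigma2_0; m3 <- mu3_0; s3 <- sigma3_0
  for (t in seq_len(n)) {
    muhat2 <- m2
    muhat3 <- m3
    muhat1 <- 1 / (1 + exp(-muhat2))
    muhat1 <- min(max(muhat1, 1e-8), 1 - 1e-8)
    v2 <- exp(kappa * m3 + omega2)
    pihat2 <- 1 / (s2 + v2)
    pihat3 <- 1 / (s3 + exp(omega3))
    if (is.na(u[t])) {
      out[t, ] <- c(muhat1, muhat2, muhat3, pihat2, pihat3,
                    NA, 0, 0, m2, m3, s2, s3)
      next
    }
    delta1 <- u[t] - muhat1
    pi2 <- pihat2 + muhat1 * (1 - muhat1)
    mu2 <- muhat2 + delta1 / pi2
    sigma2 <- 1 / pi2
    w2 <- v2 / (s2 + v2)
    da2 <- (sigma2 + (mu2 - muhat2)^2) / (s2 + v2) - 1
    pi3 <- pihat3 + 0.5 * kappa^2 * w2 * (w2 + (2 * w2 - 1) * da2)
    stopifnot(pi3 > 0)
    mu3 <- muhat3 + 0.5 * kappa * w2 * da2 / pi3
    sigma3 <- 1 / pi3
    out[t, ] <- c(muhat1, muhat2, muhat3, pihat2, pihat3,
                  delta1, mu2 - muhat2, mu3 - muhat3, mu2, mu3, sigma2, sigma3)
    m2 <- mu2; s2 <- sigma2; m3 <- mu3; s3 <- sigma3
  }
  as.data.frame(out)
}

# Benjamini-Hochberg step-up, from the definition: find the largest i with
# p_(i) <= i/m * q; here returned as adjusted p values by inverting the rule.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(ranked[i:m])
  adj <- pmin(adj, 1)
  adj[order(o)]
}

# Exact exceedance probability for 2 models under the random-effects BMS
# generative model: p(r | Y) is proportional to prod_n (r a_n1 + (1-r) a_n2)
# under a uniform prior; EP(model 1) = P(r > 1/2 | Y) by 1-D quadrature.
oracle_ep_2models <- function(lme) {
  a <- exp(lme - apply(lme, 1, max))
  f <- function(r1) vapply(r1, function(r) prod(r * a[, 1] + (1 - r) * a[, 2]),
                           numeric(1))
  stats::integrate(f, 0.5, 1)$value / stats::integrate(f, 0, 1)$value
}

# one-sample t statistic from the closed form
oracle_t1 <- function(m, s, n, mu) (m - mu) * sqrt(n) / s

# small aligned response table of explicit reports
make_responses <- function(prediction, perception, confidence = NA_integer_) {
  data.frame(prediction = prediction, perception = perception,
             confidence = confidence, stringsAsFactors = FALSE)
}

# deterministic contingency-following oracle agent
oracle_agent <- function(schedule) {
  implied <- implied_rotation(schedule$tone, schedule$contingency)
  make_responses(prediction = implied,
                 perception = ifelse(schedule$rotation == "none",
                                     implied, schedule$rotation))
}
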