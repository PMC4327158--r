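test_that("rate matrix construction follows the s_ij * pi_j decomposition", {
  m <- equal_rates_model()                      # uniform pi, equal s
  q <- rate_matrix(m)
  # with normalization the equal model has s = 20/19, q_ij = s/20
  expect_equal(q[1, 2], (20 / 19) / 20, tolerance = 1e-12)
  expect_equal(diag(q), rep(-19 * (20 / 19) / 20, 20),
               ignore_attr = TRUE, tolerance = 1e-12)
  # unnormalized: all s = 1, uniform pi -> off-diagonal 0.05, diagonal -0.95
  m1 <- aa_model(matrix(1, 20, 20) - diag(20), rep(1 / 20, 20),
                 normalize = FALSE)
  q1 <- rate_matrix(m1)
  expect_equal(q1[3, 5], 0.05)
  expect_equal(q1[3, 3], -0.95)
  # generator property and detailed balance on random models
  for (s in 1:5) {
    mr <- random_model(seed = s)
    qr <- rate_matrix(mr)
    expect_lt(max(abs(rowSums(qr))), 1e-10)
    flux <- mr$pi * qr
    expect_lt(max(abs(flux - t(flux))), 1e-10)
  }
})

test_that("total rate after normalization is one", {
  m <- normalize_model(aa_model(matrix(1, 20, 20) - diag(20),
                                rep(1 / 20, 20), normalize = FALSE))
  q <- rate_matrix(m)
  expect_equal(-sum(m$pi * diag(q)), 1, tolerance = 1e-12)
})

test_that("normalization rescales by the hand-computed constant and is
           idempotent and scale invariant", {
  S1 <- matrix(1, 20, 20) - diag(20)
  m <- aa_model(S1, rep(1 / 20, 20), normalize = FALSE)
  # sum_{i != j} 1 * (1/400) = 380/400 = 0.95 -> c = 20/19
  n1 <- normalize_model(m)
  expect_equal(n1$S[1, 2], 20 / 19, tolerance = 1e-12)
  expect_equal(as.numeric(n1$pi %*% n1$S %*% n1$pi), 1, tolerance = 1e-12)
  expect_equal(normalize_model(n1)$S, n1$S, tolerance = 1e-14)
  m7 <- aa_model(7 * S1, rep(1 / 20, 20), normalize = FALSE)
  expect_equal(normalize_model(m7)$S, n1$S, tolerance = 1e-12)
  expect_error(normalize_model(aa_model(matrix(0, 20, 20), rep(1 / 20, 20),
                                        normalize = FALSE)),
               "degenerate")
})

test_that("model validation names offending entries", {
  S <- matrix(1, 20, 20) - diag(20)
  S[2, 3] <- 5                                  # asymmetric
  expect_error(aa_model(S, rep(1 / 20, 20)), "not symmetric")
  expect_error(aa_model(matrix(1, 20, 20) - diag(20), rep(1 / 19, 20)),
               "sum to 1")
  expect_error(aa_model(matrix(1, 19, 19), rep(1 / 20, 20)), "20x20")
})

test_that("transition probabilities match the equal-rates closed form and
           behave at the boundaries", {
  m <- equal_rates_model()
  expect_equal(transition_prob(m, 0), diag(20), tolerance = 1e-12)
  # 20-state equal-rates chain: P_ii(t) = 1/20 + (19/20) exp(-20 t / 19)
  for (t in c(0.1, 0.5, 2)) {
    P <- transition_prob(m, t)
    expect_equal(diag(P), rep(1 / 20 + (19 / 20) * exp(-20 * t / 19), 20),
                 tolerance = 1e-10)
    expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-10)
    expect_true(all(P >= 0 & P <= 1))
  }
  # ergodic limit: rows converge to pi
  mr <- random_model(seed = 9)
  P_inf <- transition_prob(mr, 500)
  expect_lt(max(abs(sweep(P_inf, 2, mr$pi))), 1e-8)
  expect_error(transition_prob(m, -0.1), "negative time")
})

test_that("Chapman-Kolmogorov holds on random models", {
  for (s in c(2, 4)) {
    m <- random_model(seed = s)
    P1 <- transition_prob(m, 0.3)
    P2 <- transition_prob(m, 0.7)
    expect_equal(P1 %*% P2, transition_prob(m, 1.0), tolerance = 1e-8)
  }
})

test_that("exchangeability transform inverts rate-matrix construction", {
  m <- random_model(seed = 6)
  Q <- rate_matrix(m)
  back <- as_exchangeability(Q, m$pi)
  expect_equal(back$S, m$S, tolerance = 1e-10)
  expect_equal(rate_matrix(back), Q, tolerance = 1e-10)
  # uniform-pi equal-rate Q (q_ij = 1/19): s = 20/19 everywhere
  Qe <- matrix(1 / 19, 20, 20)
  diag(Qe) <- -1
  se <- as_exchangeability(Qe, rep(1 / 20, 20))
  expect_equal(se$S[2, 17], 20 / 19, tolerance = 1e-12)
  # numerically perturbed reversible Q: output still exactly symmetric
  Qp <- Q
  Qp[1, 2] <- Qp[1, 2] + 1e-9
  sp <- as_exchangeability(Qp, m$pi)
  expect_identical(max(abs(sp$S - t(sp$S))), 0)
  expect_error(as_exchangeability(Q, c(0, rep(1 / 19, 19))),
               "strictly positive")
})

test_that("relative difference diagnostic averages over unordered pairs", {
  S <- matrix(2, 20, 20); diag(S) <- 0
  Sstar <- matrix(1, 20, 20); diag(Sstar) <- 0
  rd <- relative_difference(S, Sstar)
  expect_equal(rd$mean_abs, 0.5)
  expect_equal(relative_difference(S, S)$mean_abs, 0)
  S1 <- matrix(1, 20, 20); diag(S1) <- 0
  expect_equal(relative_difference(S1, 1.1 * S1)$mean_abs, 0.1,
               tolerance = 1e-12)
  S0 <- S; S0[1, 2] <- S0[2, 1] <- 0
  expect_error(relative_difference(S0, Sstar), "A-C")
})

test_that("discrete gamma + invariant site-rate model has mean rate one", {
  # near-degenerate gamma: all category rates ~ 1
  r <- site_rates(1e6, 0)
  expect_equal(r$rates[1:4], rep(1, 4), tolerance = 1e-3)
  # invariant half: non-invariant categories average to 2
  r5 <- site_rates(0.7, 0.5)
  expect_equal(mean(r5$rates[1:4]), 2, tolerance = 1e-10)
  # mean-one property across parameter grid
  for (a in c(0.05, 0.5, 1, 7)) for (p in c(0, 0.2, 0.8)) {
    r <- site_rates(a, p)
    expect_equal(sum(r$rates * r$weights), 1, tolerance = 1e-10)
    expect_equal(sum(r$weights), 1, tolerance = 1e-12)
  }
  expect_error(site_rates(0), "alpha")
  expect_error(site_rates(1, 1), "p_inv")
})

test_that("gamma discretization matches a numerical-quadrature oracle", {
  # oracle: mean of each quantile bin of Gamma(1,1) = Exp(1) by integration
  k <- 4L
  breaks <- qgamma(seq(0, 1, length.out = k + 1), shape = 1, rate = 1)
  oracle <- vapply(seq_len(k), function(i)
    integrate(function(x) x * dgamma(x, 1, 1), breaks[i], breaks[i + 1])$value * k,
    numeric(1))
  r <- site_rates(1, 0, k)
  expect_equal(r$rates[1:4], oracle, tolerance = 1e-6)
})
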