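test_that("expected statistics behave in the short- and long-branch limits", {
  m <- random_model(seed = 15)
  # same residue at both tips of a tiny branch: essentially no events
  msa_same <- hom_msa(c(a = "WWWWW", b = "WWWWW", c = "WWWWW"))
  tree_tiny <- ape::read.tree(text = "(a:1e-4,b:1e-4,c:1e-4);")
  st <- expected_stats(msa_same, tree_tiny, m)
  expect_lt(sum(st$C), 1e-3)
  # distinct tip states on a shrinking branch: at least the minimum number
  # of events persists while dwell vanishes
  msa_diff <- hom_msa(c(a = "W", b = "C", c = "W"))
  st_small <- expected_stats(msa_diff,
                             ape::read.tree(text = "(a:1e-4,b:1e-4,c:1e-4);"),
                             m)
  st_large <- expected_stats(msa_diff,
                             ape::read.tree(text = "(a:1e-2,b:1e-2,c:1e-2);"),
                             m)
  expect_gte(sum(st_small$C), 1 - 1e-6)
  expect_lt(sum(st_small$W), sum(st_large$W))
})

test_that("dwell times sum to tree length times effective site count", {
  fx <- toy_msa(n_seq = 6L, sites = c(5L, 3L, 5L, 3L, 8L, 4L, 2L),
                seed = 23, model = random_model(seed = 23))
  rates <- site_rates(1.2, 0.3, 4L)
  st <- expected_stats(fx$msa, fx$tree, fx$model, rates)
  ll <- log_likelihood(fx$msa, fx$tree, fx$model, rates)
  expect_equal(st$loglik, ll$loglik, tolerance = 1e-8)
  # effective sites: posterior expected rate summed over sites; bounded by
  # the nominal site count times the fastest category
  expect_lt(sum(st$W), sum(fx$tree$edge.length) * ll$n_sites *
              max(rates$rates))
  expect_gt(sum(st$W), 0)
  # without heterogeneity the identity is exact
  st1 <- expected_stats(fx$msa, fx$tree, fx$model)
  expect_equal(sum(st1$W), sum(fx$tree$edge.length) * ll$n_sites,
               tolerance = 1e-6)
})

test_that("expected statistics satisfy the Fisher identity (gradient of the
           log-likelihood)", {
  # d logL / d s_ij must equal (C_ij + C_ji)/s_ij - (W_i pi_j + W_j pi_i);
  # this pins both the count and dwell expectations to the likelihood
  fx <- toy_msa(n_seq = 5L, seed = 31, alpha = 1, p_inv = 0.2, gamma_k = 3L,
                model = random_model(seed = 31))
  rates <- site_rates(1, 0.2, 3L)
  st <- expected_stats(fx$msa, fx$tree, fx$model, rates)
  eps <- 1e-6
  for (pair in list(c(1L, 2L), c(4L, 18L), c(7L, 11L))) {
    i <- pair[1L]; j <- pair[2L]
    perturb <- function(h) {
      S <- fx$model$S
      S[i, j] <- S[j, i] <- S[i, j] + h
      m2 <- aa_model(S, fx$model$pi, normalize = FALSE)
      log_likelihood(fx$msa, fx$tree, m2, rates)$loglik
    }
    numeric_grad <- (perturb(eps) - perturb(-eps)) / (2 * eps)
    analytic <- (st$C[i, j] + st$C[j, i]) / fx$model$S[i, j] -
      (st$W[i] * fx$model$pi[j] + st$W[j] * fx$model$pi[i])
    # absolute comparison: finite differencing limits precision to ~1e-6
    expect_lt(abs(numeric_grad - analytic), 2e-5)
  }
})

test_that("expected counts and dwell match a Monte-Carlo endpoint-
           conditioned path oracle", {
  set.seed(77)
  m <- random_model(seed = 2)
  Q <- rate_matrix(m)
  a <- 3L; b <- 7L; t_br <- 0.4
  nsim <- 40000L
  acc <- 0L
  n_tot <- 0
  n_sq <- 0
  dwell <- numeric(20)
  for (i in seq_len(nsim)) {
    s <- a; tt <- 0; jumps <- 0L; dw <- numeric(20)
    repeat {
      hold <- rexp(1, -Q[s, s])
      if (tt + hold >= t_br) { dw[s] <- dw[s] + (t_br - tt); break }
      dw[s] <- dw[s] + hold
      tt <- tt + hold
      s <- sample.int(20L, 1L, prob = pmax(Q[s, ], 0) * (seq_len(20) != s))
      jumps <- jumps + 1L
    }
    if (s == b) {
      acc <- acc + 1L
      n_tot <- n_tot + jumps
      n_sq <- n_sq + jumps^2
      dwell <- dwell + dw
    }
  }
  mc_mean <- n_tot / acc
  mc_se <- sqrt((n_sq / acc - mc_mean^2) / acc)
  # analytic expectation through the package E-step on a two-tip tree
  msa <- hom_msa(stats::setNames(c(AA_ALPHABET[a], AA_ALPHABET[b],
                                   AA_ALPHABET[a]), c("x", "y", "z")))
  tree <- ape::read.tree(text = sprintf("(x:0,z:0,y:%g);", t_br))
  st <- expected_stats(msa, tree, m)
  expect_lt(abs(sum(st$C) - mc_mean), 3 * mc_se)
  # dwell on the most-occupied states agrees within Monte-Carlo error
  expect_equal(sum(st$W), t_br, tolerance = 1e-8)
  top <- order(dwell, decreasing = TRUE)[1:3]
  expect_equal(st$W[top], dwell[top] / acc, tolerance = 0.15,
               ignore_attr = TRUE)
})

test_that("M-step estimates are symmetric, positive, and collapse to the
           uniform model without data", {
  fx <- toy_msa(n_seq = 8L, seed = 41, model = random_model(seed = 41))
  st <- expected_stats(fx$msa, fx$tree, fx$model)
  est <- m_step(st, fx$model$pi)
  expect_identical(est$S, t(est$S))
  expect_true(all(est$S[upper.tri(est$S)] > 0))
  expect_equal(as.numeric(est$pi %*% est$S %*% est$pi), 1,
               tolerance = 1e-10)
  # all counts zero: every pair unobserved, uniform estimator
  st0 <- st
  st0$C <- matrix(0, 20, 20)
  est0 <- m_step(st0, fx$model$pi, pseudocount = 0.1)
  expect_equal(max(est0$S[upper.tri(est0$S)]),
               min(est0$S[upper.tri(est0$S)]), tolerance = 1e-12)
  # frequency-learning mode returns dwell-proportional frequencies
  estf <- m_step(st, fx$model$pi, update_frequencies = TRUE)
  expect_equal(estf$pi, validate_frequencies(st$W / sum(st$W)),
               tolerance = 1e-9)
})

test_that("EM is monotone, stops at a fixed point, and improves on the
           initial model", {
  truth <- random_model(seed = 52)
  spec <- repertoire_spec(n_msas = 3L, n_seq = 10L, model = truth,
                          alpha = 1e6, p_inv = 0, gamma_k = 1L, seed = 8)
  rep <- simulate_repertoire(spec)
  trees <- lapply(rep$truth, `[[`, "tree")
  init <- equal_rates_model(empirical_frequencies(rep$msas))
  em <- em_fit(rep$msas, trees, init, max_iter = 40L)
  expect_true(all(diff(em$trace$loglik) > -1e-6))
  expect_gt(utils::tail(em$trace$loglik, 1), em$trace$loglik[1])
  # closer to the truth than the equal-rates start, by relative difference
  d_init <- relative_difference(truth, init)$mean_abs
  d_fit <- relative_difference(truth, em$model)$mean_abs
  expect_lt(d_fit, d_init)
  # restarting from the converged estimate terminates almost immediately
  em2 <- em_fit(rep$msas, em$trees, em$model, max_iter = 40L)
  expect_lte(nrow(em2$trace), 2L)
})

test_that("estimator consistency: recovery improves with more data", {
  truth <- random_model(seed = 60)
  r_at <- function(n_msas, n_seq, seed) {
    spec <- repertoire_spec(n_msas = n_msas, n_seq = n_seq, model = truth,
                            alpha = 1e6, p_inv = 0, gamma_k = 1L,
                            seed = seed)
    rep <- simulate_repertoire(spec)
    em <- em_fit(rep$msas, lapply(rep$truth, `[[`, "tree"),
                 equal_rates_model(empirical_frequencies(rep$msas)),
                 max_iter = 30L)
    exchangeability_correlation(em$model, truth)
  }
  r_small <- r_at(1L, 4L, seed = 71)
  r_large <- r_at(6L, 12L, seed = 72)
  expect_gt(r_large, r_small)
  expect_gt(r_large, 0.75)
})
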