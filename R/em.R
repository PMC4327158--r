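#' E-step: expected substitution counts and dwell times
#'
#' For every branch, site and rate category, computes the conditional
#' expectations of the number of \eqn{i \to j} replacement events and of the
#' time spent in each amino-acid state, given the tip data.  The
#' expectations use the closed-form eigendecomposition integrals for
#' reversible generators
#' \deqn{E[N_{ij}] = q_{ij} \sum_{a,b} w_{ab} \int_0^\tau P_{ai}(s)
#'   P_{jb}(\tau - s)\, ds,}
#' with the endpoint weights \eqn{w_{ab}} given by the joint posterior of
#' the branch's end states; gamma categories contribute in proportion to
#' their posterior membership, and times are measured on the
#' category-rescaled clock (category \eqn{c} over branch \eqn{t} uses
#' \eqn{\tau = r_c t}), which is the scale on which the M-step estimator is
#' defined.  The invariant class (rate 0) contributes neither events nor
#' dwell time.
#'
#' @inheritParams log_likelihood
#' @return object of class `suff_stats`: list with `C` (20x20 expected
#'   counts, zero diagonal), `W` (20 expected dwell times), `loglik` (the
#'   data log-likelihood under the supplied model, a by-product of the same
#'   pass), `n_sites`.
#' @export
expected_stats <- function(msa, tree, model, rates = site_rates(1e6, 0, 1L),
                           freqs = "model") {
  pi <- resolve_freqs(freqs, model, msa)
  m <- if (identical(pi, model$pi)) model else
    aa_model(model$S, pi, name = model$name, normalize = TRUE)
  Q <- rate_matrix(m)
  bal <- max(abs(m$pi * Q - t(m$pi * Q)))
  if (bal > 1e-8)
    stop("rate matrix is not reversible (detailed-balance residual ",
         format(bal), "); expected a model built from exchangeabilities")
  td <- .tree_data(tree, msa)
  decomp <- q_eigen(Q, m$pi)
  k <- rates$k
  gamma_rates <- rates$rates[seq_len(k)]

  posts <- pres <- Plists <- vector("list", k)
  cat_ll <- matrix(0, td$S, k)
  for (ci in seq_len(k)) {
    Plists[[ci]] <- .edge_P(td, decomp, gamma_rates[ci])
    posts[[ci]] <- .partials_post(td, Plists[[ci]], m$pi)
    pres[[ci]] <- .partials_pre(td, Plists[[ci]], m$pi, posts[[ci]])
    cat_ll[, ci] <- posts[[ci]]$site_loglik
  }
  cs <- .constant_sites(td)
  site_ll <- .mix_site_loglik(cat_ll, rates$weights, rates$p_inv,
                              cs$const, cs$state, m$pi)

  lam <- decomp$values
  C <- matrix(0, 20L, 20L)
  W <- numeric(20L)
  tU <- t(decomp$U)
  tUinv <- t(decomp$Uinv)
  for (ci in seq_len(k)) {
    w_c <- rates$weights[ci]
    if (w_c == 0) next
    for (e in seq_len(nrow(td$edge))) {
      tau <- gamma_rates[ci] * td$el[e]
      if (tau <= 0) next
      ch <- td$edge[e, 2L]
      fac <- exp(pres[[ci]]$lse[e] + posts[[ci]]$lsc[ch] - site_ll) * w_c
      Wab <- (pres[[ci]]$Gexcl[[e]] * rep(fac, each = 20L)) %*%
        t(posts[[ci]]$F[[ch]])
      elam <- exp(lam * tau)
      dl <- outer(lam, lam, "-")
      J <- (outer(elam, elam, "-")) / dl
      near <- abs(dl) < 1e-9
      J[near] <- tau * rep(elam, times = 20L)[near]
      M <- tU %*% Wab %*% tUinv
      H <- tUinv %*% (J * M) %*% tU
      W <- W + pmax(diag(H), 0)
      NH <- Q * H
      diag(NH) <- 0
      C <- C + pmax(NH, 0)
    }
  }
  dimnames(C) <- list(AA_ALPHABET, AA_ALPHABET)
  names(W) <- AA_ALPHABET
  structure(list(C = C, W = W, loglik = sum(site_ll), n_sites = td$S),
            class = "suff_stats")
}

# Sum several suff_stats objects (pooling over MSAs).
pool_stats <- function(stats_list) {
  out <- stats_list[[1L]]
  for (s in stats_list[-1L]) {
    out$C <- out$C + s$C
    out$W <- out$W + s$W
    out$loglik <- out$loglik + s$loglik
    out$n_sites <- out$n_sites + s$n_sites
  }
  out
}

#' M-step: exchangeability estimates from sufficient statistics
#'
#' Maximizes the expected complete-data log-likelihood of the reversible
#' model:
#' \deqn{\hat s_{ij} = \frac{C_{ij} + C_{ji}}
#'   {W_i \pi_j + W_j \pi_i},}
#' with a positivity guard for unobserved exchanges: pairs whose expected
#' counts are numerically zero receive the floor
#' \eqn{\lambda \cdot \min_{\mathrm{observed}} \hat s}, so every estimate is
#' strictly positive (as required by the relative-difference diagnostic and
#' by downstream division) while the exact M-step maximizer — and with it
#' the EM ascent property — is preserved for all data-supported pairs.
#' When no exchange at all is observed the estimator degenerates to the
#' uniform (equal-rates) model.  The result is normalized to
#' the unit-mean-rate convention; the attribute `"rate_scale"` records the
#' pre-normalization mean rate so callers can rescale branch lengths and
#' keep the likelihood invariant.
#'
#' @param stats a `suff_stats` object (possibly pooled over MSAs).
#' @param pi stationary frequencies to pair with the estimates; if
#'   `update_frequencies = TRUE` they are re-estimated as the normalized
#'   dwell times \eqn{W/\sum W} instead.
#' @param pseudocount floor multiplier \eqn{\lambda} for unobserved
#'   exchanges (default 0.05).
#' @param update_frequencies re-estimate frequencies from dwell times
#'   (frequency-learning mode).
#' @return an [aa_model()] (normalized, with attribute `rate_scale`).
#' @export
m_step <- function(stats, pi, pseudocount = 0.05,
                   update_frequencies = FALSE) {
  stopifnot(inherits(stats, "suff_stats"))
  if (update_frequencies)
    pi <- validate_frequencies(stats$W / sum(stats$W))
  else
    pi <- validate_frequencies(pi)
  W <- stats$W
  denom <- outer(W, pi) + t(outer(W, pi))   # W_i pi_j + W_j pi_i
  num <- stats$C + t(stats$C)
  diag(denom) <- 1
  if (any(denom[upper.tri(denom)] == 0)) {
    bad <- which(denom == 0 & upper.tri(denom), arr.ind = TRUE)[1L, ]
    stop("zero dwell-time denominator for pair ",
         AA_ALPHABET[bad[1L]], "-", AA_ALPHABET[bad[2L]])
  }
  S <- num / denom
  diag(S) <- 0
  unobserved <- num < 1e-9 & upper.tri(num, diag = FALSE)
  unobserved <- unobserved | t(unobserved)
  if (any(unobserved)) {
    observed_s <- S[num >= 1e-9 & upper.tri(num)]
    # The floor sits far below the smallest data-supported rate: it keeps
    # every estimate strictly positive (for the relative-difference
    # diagnostic and downstream division) while leaving the likelihood,
    # and with it the EM ascent, numerically untouched.
    floor_s <- if (length(observed_s))
      pseudocount * 1e-6 * min(observed_s) else
      pseudocount                       # no data at all: uniform model
    S[unobserved] <- floor_s
  }
  m <- aa_model(S, pi, name = "em_estimate", normalize = FALSE)
  scale <- total_rate(m)
  m <- normalize_model(m)
  attr(m, "rate_scale") <- scale
  m
}

#' EM estimation of an exchangeability model over a set of MSAs
#'
#' Alternates [expected_stats()] (pooled over all alignments) with
#' [m_step()] until the joint log-likelihood gain drops below `tol`.  After
#' every M-step the model is renormalized and all branch lengths are
#' multiplied by the pre-normalization mean rate, so the renormalization is
#' likelihood-neutral and the EM ascent property holds exactly; a
#' log-likelihood decrease beyond `1e-6` aborts with a diagnostic (it would
#' signal an E-step defect).
#'
#' @param msas list of [hom_msa()] objects.
#' @param trees list of `phylo` trees, one per MSA.
#' @param initial_model starting [aa_model()].
#' @param rates a single [site_rates()] or a list, one per MSA.
#' @param freq_policy `"fixed"` keeps the frequencies of `initial_model`
#'   throughout; `"learn"` re-estimates them each M-step from dwell times.
#' @param pseudocount passed to [m_step()].
#' @param max_iter,tol iteration cap and joint log-likelihood tolerance.
#' @return object of class `em_fit`: list with `model`, `trees` (branch
#'   lengths rescaled to the final normalization), `trace` (data.frame:
#'   iteration, loglik, mean_delta), `converged`.
#' @export
em_fit <- function(msas, trees, initial_model, rates = site_rates(1e6, 0, 1L),
                   freq_policy = c("fixed", "learn"), pseudocount = 0.05,
                   max_iter = 100L, tol = 1e-4) {
  freq_policy <- match.arg(freq_policy)
  if (inherits(msas, "hom_msa")) msas <- list(msas)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(msas) != length(trees))
    stop("need one tree per MSA (", length(msas), " MSAs, ",
         length(trees), " trees)")
  if (inherits(rates, "site_rates"))
    rates <- rep(list(rates), length(msas))
  model <- initial_model
  trace <- data.frame(iteration = integer(), loglik = numeric(),
                      mean_delta = numeric())
  prev_ll <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    stats <- pool_stats(lapply(seq_along(msas), function(i)
      expected_stats(msas[[i]], trees[[i]], model, rates[[i]])))
    ll <- stats$loglik
    if (ll < prev_ll - 1e-6)
      stop(sprintf(paste0("joint log-likelihood decreased at iteration %d ",
                          "(%.8f -> %.8f); E-step inconsistency"),
                   it, prev_ll, ll))
    new_model <- m_step(stats, model$pi, pseudocount = pseudocount,
                        update_frequencies = freq_policy == "learn")
    scale <- attr(new_model, "rate_scale")
    trees <- lapply(trees, function(tr) {
      tr$edge.length <- tr$edge.length * scale
      tr
    })
    delta <- tryCatch(relative_difference(model, new_model)$mean_abs,
                      error = function(e) NA_real_)
    trace <- rbind(trace, data.frame(iteration = it, loglik = ll,
                                     mean_delta = delta))
    gain <- ll - prev_ll
    prev_ll <- ll
    model <- new_model
    if (is.finite(gain) && gain < tol) { converged <- TRUE; break }
  }
  model$name <- "AB_estimate"
  structure(list(model = model, trees = trees, trace = trace,
                 converged = converged),
            class = "em_fit")
}
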