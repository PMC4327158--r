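#' Fit an antibody-specific substitution model to a repertoire
#'
#' The package's main estimator.  Runs the iterative alternating learning
#' scheme over a set of homogeneous antibody alignments: in each round,
#' (1) genealogies are (re)inferred under the current best model — NJ
#' starting trees, branch lengths optimized, gamma shape and invariant
#' proportion fitted per alignment — and (2) the exchangeability matrix is
#' re-estimated by [em_fit()] over all alignments given those genealogies.
#' Training-set empirical frequencies are used throughout under the
#' recommended `"train"` policy.  The procedure halts early when the
#' held-out (or, absent a test set, training) log-likelihood ceases to
#' increase; each round's estimate is kept as a candidate model.
#'
#' @param msas list of [hom_msa()] objects (the training repertoire).
#' @param initial_model starting [aa_model()]; published general models
#'   ([lg_model()], [wag_model()]) or [equal_rates_model()] are the usual
#'   choices.
#' @param rounds maximum number of learning rounds (default 3).
#' @param freq_policy `"train"`: empirical frequencies pooled over the
#'   training alignments, held fixed (recommended); `"learn"`: frequencies
#'   re-estimated inside EM; `"model"`: keep the initial model's
#'   frequencies.
#' @param gamma_k gamma categories for the site-rate model (default 4).
#' @param test_msas optional held-out alignments monitored for the stopping
#'   rule.
#' @param pseudocount symmetric pseudocount for unobserved exchanges.
#' @param optimize_branches optimize branch lengths of the NJ starting trees
#'   each round (default TRUE; turning it off speeds up exploratory runs).
#' @param em_max_iter,em_tol passed to [em_fit()].
#' @param verbose print per-round progress.
#' @return object of class `ab_fit`; see [print.ab_fit()].  Key fields:
#'   `model` (final [aa_model()]), `candidates` (per-round models),
#'   `rounds` (data.frame: round, joint and per-site log-likelihood, mean
#'   relative difference to the previous round's model), `em_traces`,
#'   `trees`, `site_rates`, `frequencies`.
#' @examples
#' \donttest{
#' spec <- repertoire_spec(n_msas = 3, n_seq = c(8, 8), seed = 1)
#' rep <- simulate_repertoire(spec)
#' fit <- fit_ab_model(rep$msas, equal_rates_model(), rounds = 1)
#' coef(fit)[1:3, 1:3]
#' }
#' @export
fit_ab_model <- function(msas, initial_model = lg_model(), rounds = 3L,
                         freq_policy = c("train", "learn", "model"),
                         gamma_k = 4L, test_msas = NULL, pseudocount = 0.05,
                         optimize_branches = TRUE, em_max_iter = 100L,
                         em_tol = 1e-4, verbose = FALSE) {
  freq_policy <- match.arg(freq_policy)
  if (inherits(msas, "hom_msa")) msas <- list(msas)
  if (length(msas) < 1L) stop("need at least one MSA")
  cl <- match.call()

  pi_train <- empirical_frequencies(msas)
  model <- switch(freq_policy,
    train = aa_model(initial_model$S, pi_train,
                     name = initial_model$name, normalize = TRUE),
    learn = ,
    model = initial_model)

  candidates <- list()
  em_traces <- list()
  round_tab <- data.frame()
  best_crit <- -Inf
  trees <- NULL
  rate_fits <- NULL
  prev_model <- model

  for (r in seq_len(rounds)) {
    trees <- vector("list", length(msas))
    rate_fits <- vector("list", length(msas))
    for (i in seq_along(msas)) {
      tr <- starting_tree(msas[[i]], model)
      sr <- fit_site_rates(msas[[i]], tr, model, k = gamma_k)
      if (optimize_branches) {
        opt <- optimize_branch_lengths(msas[[i]], tr, model, sr$rates)
        tr <- opt$tree
        sr <- fit_site_rates(msas[[i]], tr, model, k = gamma_k)
      }
      trees[[i]] <- tr
      rate_fits[[i]] <- sr
    }
    em <- em_fit(msas, trees, model,
                 rates = lapply(rate_fits, `[[`, "rates"),
                 freq_policy = if (freq_policy == "learn") "learn" else
                   "fixed",
                 pseudocount = pseudocount,
                 max_iter = em_max_iter, tol = em_tol)
    new_model <- em$model
    delta <- tryCatch(relative_difference(prev_model, new_model)$mean_abs,
                      error = function(e) NA_real_)
    train_ll <- utils::tail(em$trace$loglik, 1L)
    n_total <- sum(vapply(msas, n_sites, 0L))
    crit <- if (is.null(test_msas)) train_ll else
      heldout_loglik(test_msas, new_model, gamma_k = gamma_k,
                     optimize_branches = optimize_branches)
    round_tab <- rbind(round_tab, data.frame(
      round = r, loglik = train_ll, per_site = train_ll / n_total,
      criterion = crit, mean_delta = delta))
    if (verbose)
      message(sprintf(
        "round %d: joint logL %.4f (%.4f/site), mean delta %.4g",
        r, train_ll, train_ll / n_total, delta))
    candidates[[r]] <- new_model
    em_traces[[r]] <- em$trace
    prev_model <- model <- new_model
    trees <- em$trees
    if (crit <= best_crit) break
    best_crit <- crit
  }

  structure(list(model = model, candidates = candidates,
                 rounds = round_tab, em_traces = em_traces,
                 trees = trees,
                 site_rates = lapply(rate_fits, function(s)
                   s[c("alpha", "p_inv")]),
                 frequencies = model$pi, freq_policy = freq_policy,
                 n_msas = length(msas), msas = msas, call = cl),
            class = "ab_fit")
}

# Mean per-site log-likelihood of held-out alignments under a model, with
# trees and rate parameters re-fit per alignment.
heldout_loglik <- function(msas, model, gamma_k = 4L,
                           optimize_branches = TRUE) {
  tot <- 0
  n <- 0L
  for (m in msas) {
    tr <- starting_tree(m, model)
    sr <- fit_site_rates(m, tr, model, k = gamma_k)
    if (optimize_branches) {
      opt <- optimize_branch_lengths(m, tr, model, sr$rates)
      tr <- opt$tree
      sr <- fit_site_rates(m, tr, model, k = gamma_k)
    }
    tot <- tot + log_likelihood(m, tr, model, sr$rates)$loglik
    n <- n + n_sites(m)
  }
  tot / n
}

#' Print method for fitted antibody substitution models
#'
#' @param x an `ab_fit` object.
#' @param ... ignored.
#' @export
print.ab_fit <- function(x, ...) {
  cat("Antibody-specific substitution model fit\n")
  cat(sprintf("  %d alignments, %d sites total, frequency policy \"%s\"\n",
              x$n_msas, sum(vapply(x$msas, n_sites, 0L)), x$freq_policy))
  cat(sprintf("  %d learning round(s); final joint logL %.4f (%.4f/site)\n",
              nrow(x$rounds), utils::tail(x$rounds$loglik, 1L),
              utils::tail(x$rounds$per_site, 1L)))
  if (nrow(x$rounds) > 1L)
    cat(sprintf("  round-over-round mean |delta_ij|: %s\n",
                paste(sprintf("%.3g", x$rounds$mean_delta), collapse = " -> ")))
  invisible(x)
}

#' @export
summary.ab_fit <- function(object, ...) {
  s <- object$model$S[upper.tri(object$model$S)]
  out <- list(rounds = object$rounds,
              exchangeability_quartiles = stats::quantile(s),
              frequencies = object$model$pi,
              site_rates = do.call(rbind, lapply(object$site_rates,
                                                 as.data.frame)))
  class(out) <- "summary.ab_fit"
  out
}

#' @export
print.summary.ab_fit <- function(x, ...) {
  cat("Learning rounds:\n")
  print(x$rounds, row.names = FALSE)
  cat("\nExchangeability quartiles:\n")
  print(signif(x$exchangeability_quartiles, 4))
  cat("\nPer-alignment site-rate estimates (first 6):\n")
  print(utils::head(x$site_rates))
  invisible(x)
}

#' @export
coef.ab_fit <- function(object, what = c("exchangeabilities", "frequencies"),
                        ...) {
  what <- match.arg(what)
  if (what == "frequencies") object$model$pi else object$model$S
}

#' @export
logLik.ab_fit <- function(object, ...) {
  ll <- utils::tail(object$rounds$loglik, 1L)
  n <- sum(vapply(object$msas, n_sites, 0L))
  structure(ll, df = 190L + if (object$freq_policy == "learn") 19L else 0L,
            nobs = n, class = "logLik")
}

#' @export
plot.ab_fit <- function(x, ...) {
  tr <- do.call(rbind, lapply(seq_along(x$em_traces), function(r)
    cbind(round = r, x$em_traces[[r]])))
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::plot(seq_len(nrow(tr)), tr$loglik, type = "b", pch = 16,
                 col = tr$round, xlab = "EM iteration (all rounds)",
                 ylab = "joint log-likelihood", ...)
  graphics::plot(seq_len(nrow(tr)), tr$mean_delta, type = "b", pch = 16,
                 col = tr$round, log = "y", xlab = "EM iteration",
                 ylab = expression(bar(abs(Delta[ij]))), ...)
  invisible(x)
}

#' Simulate repertoires from a fitted model
#'
#' Draws synthetic homogeneous alignments from the fitted exchangeability
#' model using the genealogy sizes and site-rate estimates of the fit.
#'
#' @param object an `ab_fit`.
#' @param nsim number of repertoires.
#' @param seed integer seed.
#' @param ... passed to [repertoire_spec()] to override defaults.
#' @return a list of `nsim` repertoires as returned by
#'   [simulate_repertoire()].
#' @export
simulate.ab_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  alpha <- stats::median(vapply(object$site_rates, `[[`, 0, "alpha"))
  p_inv <- stats::median(vapply(object$site_rates, `[[`, 0, "p_inv"))
  lapply(seq_len(nsim), function(i) {
    spec <- repertoire_spec(n_msas = object$n_msas,
                            model = object$model,
                            alpha = alpha, p_inv = p_inv,
                            seed = sample.int(2^31 - 1L, 1L), ...)
    simulate_repertoire(spec)
  })
}
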