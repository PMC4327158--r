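#' Starting genealogy for a homogeneous MSA
#'
#' Neighbor-joining topology built on pairwise maximum-likelihood distances
#' under the supplied substitution model.  Zero or negative branch lengths
#' (arising from identical sequences or NJ negative estimates) are clamped
#' to `min_branch` with a warning.  Genealogies within homogeneous antibody
#' alignments are shallow, so the fixed NJ topology with subsequently
#' re-optimized branch lengths serves as the tree estimate; externally
#' inferred Newick trees can be supplied wherever a tree argument is
#' accepted.
#'
#' @param msa a [hom_msa()] with at least 3 sequences.
#' @param model an [aa_model()].
#' @param min_branch clamp for non-positive branch lengths (default 1e-6).
#' @param max_dist upper bound of the pairwise distance search (default 10).
#' @return an unrooted `phylo` tree with branch lengths in expected
#'   substitutions per site.
#' @export
starting_tree <- function(msa, model, min_branch = 1e-6, max_dist = 10) {
  n <- length(msa$seqs)
  if (n < 3L) stop("need at least 3 sequences, got ", n)
  X <- msa_encode(msa)
  decomp <- q_eigen(rate_matrix(model), model$pi)
  lpi <- log(model$pi)
  D <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  any_clamped <- FALSE
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    cnt <- table(factor(X[i, ], levels = 1:20),
                 factor(X[j, ], levels = 1:20))
    cnt <- matrix(as.numeric(cnt), 20L, 20L)
    if (sum(cnt * (1 - diag(20L))) == 0) {       # identical sequences
      D[i, j] <- D[j, i] <- min_branch
      any_clamped <- TRUE
      next
    }
    nll <- function(t) {
      P <- transition_prob(NULL, t, decomp = decomp)
      -sum(cnt * (lpi + log(P)))
    }
    D[i, j] <- D[j, i] <- stats::optimize(nll, c(min_branch, max_dist))$minimum
  }
  tree <- ape::unroot(ape::nj(stats::as.dist(D)))
  if (any(tree$edge.length < min_branch) || any_clamped) {
    tree$edge.length[tree$edge.length < min_branch] <- min_branch
    warning("branch lengths below ", min_branch, " clamped", call. = FALSE)
  }
  tree
}

#' Phylogenetic log-likelihood of a homogeneous MSA
#'
#' Felsenstein pruning under a reversible amino-acid model with discrete
#' gamma rate categories plus an invariant-sites class.  Each site's
#' likelihood mixes the gamma categories (weights \eqn{(1-p_{inv})/K}) with
#' the invariant class, which contributes \eqn{p_{inv}\pi_x} for columns
#' where all sequences share residue \eqn{x}.
#'
#' @param msa a [hom_msa()].
#' @param tree `phylo` tree whose tips match the MSA ids.
#' @param model an [aa_model()].
#' @param rates a [site_rates()] object (default: single rate 1, no
#'   invariant class).
#' @param freqs stationary frequencies used for the likelihood root term and
#'   rate matrix: `"model"` (frequencies carried by `model`) or a numeric
#'   vector of 20 (e.g. training or per-MSA empirical frequencies, the
#'   `+F`-style options).
#' @return object of class `ab_loglik`: list with `loglik`, `per_site`
#'   (length = number of sites), `n_sites`, `model`, `alpha`, `p_inv`.
#' @export
log_likelihood <- function(msa, tree, model, rates = site_rates(1e6, 0, 1L),
                           freqs = "model") {
  pi <- resolve_freqs(freqs, model, msa)
  m <- if (identical(pi, model$pi)) model else
    aa_model(model$S, pi, name = model$name, normalize = TRUE)
  td <- .tree_data(tree, msa)
  per_site <- .loglik_td(td, m, rates)
  structure(list(loglik = sum(per_site), per_site = per_site,
                 n_sites = td$S, model = model$name,
                 alpha = rates$alpha, p_inv = rates$p_inv,
                 freq_mode = if (is.character(freqs)) freqs else "custom"),
            class = "ab_loglik")
}

# Per-site log-likelihood given a prebuilt tree/alignment bundle.
.loglik_td <- function(td, m, rates, decomp = NULL) {
  if (is.null(decomp)) decomp <- q_eigen(rate_matrix(m), m$pi)
  k <- rates$k
  cat_ll <- matrix(0, td$S, k)
  for (ci in seq_len(k)) {
    post <- .partials_post(td, .edge_P(td, decomp, rates$rates[ci]), m$pi)
    cat_ll[, ci] <- post$site_loglik
  }
  cs <- .constant_sites(td)
  .mix_site_loglik(cat_ll, rates$weights, rates$p_inv,
                   cs$const, cs$state, m$pi)
}

# Frequency-mode resolution shared by the likelihood-facing functions.
resolve_freqs <- function(freqs, model, msa) {
  if (is.numeric(freqs)) return(validate_frequencies(freqs))
  if (identical(freqs, "model")) return(model$pi)
  if (identical(freqs, "msa")) return(empirical_frequencies(msa))
  stop("freqs must be \"model\", \"msa\", or a frequency vector")
}

#' @export
print.ab_loglik <- function(x, ...) {
  cat(sprintf("log-likelihood %.4f over %d sites (%.4f per site)\n",
              x$loglik, x$n_sites, x$loglik / x$n_sites))
  cat(sprintf("  model %s, alpha = %.4g, p_inv = %.4g\n",
              x$model, x$alpha, x$p_inv))
  invisible(x)
}

#' Optimize branch lengths by coordinate ascent
#'
#' Cycles over branches, maximizing the log-likelihood in each branch length
#' by bounded scalar optimization (`[min_branch, max_branch]`) with all
#' other branches held fixed, until the gain over a full cycle falls below
#' `tol`.  The log-likelihood is non-decreasing across cycles by
#' construction.
#'
#' @inheritParams log_likelihood
#' @param tol convergence tolerance on the per-cycle log-likelihood gain
#'   (default 1e-4).
#' @param max_cycles cycle cap (default 50); hitting it returns the best
#'   tree found with a warning.
#' @param min_branch,max_branch box constraints for each branch length.
#' @return list with `tree` (optimized), `loglik`, `cycles`.
#' @export
optimize_branch_lengths <- function(msa, tree, model,
                                    rates = site_rates(1e6, 0, 1L),
                                    freqs = "model", tol = 1e-4,
                                    max_cycles = 50L,
                                    min_branch = 1e-8, max_branch = 10) {
  pi <- resolve_freqs(freqs, model, msa)
  m <- if (identical(pi, model$pi)) model else
    aa_model(model$S, pi, name = model$name, normalize = TRUE)
  decomp <- q_eigen(rate_matrix(m), m$pi)
  tree <- stats::reorder(tree, "postorder")
  td <- .tree_data(tree, msa)
  k <- rates$k
  cs <- .constant_sites(td)
  gamma_rates <- rates$rates[seq_len(k)]

  total_ll <- function(el) {
    td$el <- el
    cat_ll <- matrix(0, td$S, k)
    for (ci in seq_len(k)) {
      post <- .partials_post(td, .edge_P(td, decomp, gamma_rates[ci]), m$pi)
      cat_ll[, ci] <- post$site_loglik
    }
    sum(.mix_site_loglik(cat_ll, rates$weights, rates$p_inv,
                         cs$const, cs$state, m$pi))
  }

  el <- td$el
  ll <- total_ll(el)
  cycles <- 0L
  ne <- nrow(td$edge)
  child_edges <- split(seq_len(ne), td$edge[, 1L])
  trans <- function(rate, t) {
    P <- decomp$U %*% (exp(decomp$values * (rate * t)) * decomp$Uinv)
    P[P < 0] <- 0
    P
  }
  repeat {
    cycles <- cycles + 1L
    # Exact one-pass coordinate ascent: a post-order pass fixes the below-
    # edge partials; a pre-order sweep then visits each edge with the
    # above-edge partials kept current as lengths update, so every 1-D
    # search maximizes the exact likelihood given all other branches.
    td$el <- el
    posts <- vector("list", k)
    contribs <- vector("list", k)     # per category, per edge
    for (ci in seq_len(k)) {
      posts[[ci]] <- .partials_post(td, .edge_P(td, decomp,
                                                gamma_rates[ci]), m$pi)
      contribs[[ci]] <- posts[[ci]]$contrib
    }
    G <- lapply(seq_len(k), function(ci) {
      g <- vector("list", td$n_node)
      g[[td$root]] <- matrix(m$pi, 20L, td$S)
      g
    })
    lsg <- matrix(0, k, td$n_node)
    for (e in rev(seq_len(ne))) {
      p <- td$edge[e, 1L]; ch <- td$edge[e, 2L]
      sibs <- setdiff(child_edges[[as.character(p)]], e)
      Gex <- vector("list", k)
      lse <- numeric(k)
      for (ci in seq_len(k)) {
        H <- G[[ci]][[p]]
        ls <- lsg[ci, p]
        for (se in sibs) {
          H <- H * contribs[[ci]][[se]]
          ls <- ls + posts[[ci]]$lsc[td$edge[se, 2L]]
        }
        mx <- max(H)
        if (mx < .SCALE_FLOOR && mx > 0) { H <- H / mx; ls <- ls + log(mx) }
        Gex[[ci]] <- H
        lse[ci] <- ls
      }
      edge_ll <- function(t) {
        cat_ll <- matrix(0, td$S, k)
        for (ci in seq_len(k)) {
          P <- trans(gamma_rates[ci], t)
          lik <- colSums(Gex[[ci]] * (P %*% posts[[ci]]$F[[ch]]))
          cat_ll[, ci] <- log(lik) + lse[ci] + posts[[ci]]$lsc[ch]
        }
        sum(.mix_site_loglik(cat_ll, rates$weights, rates$p_inv,
                             cs$const, cs$state, m$pi))
      }
      opt <- stats::optimize(edge_ll, c(min_branch, max_branch),
                             maximum = TRUE, tol = 1e-4)
      if (opt$objective > edge_ll(el[e])) el[e] <- opt$maximum
      for (ci in seq_len(k)) {
        P <- trans(gamma_rates[ci], el[e])
        contribs[[ci]][[e]] <- P %*% posts[[ci]]$F[[ch]]
        if (ch > td$n_tip) {
          G[[ci]][[ch]] <- crossprod(P, Gex[[ci]])
          lsg[ci, ch] <- lse[ci]
        }
      }
    }
    ll_new <- total_ll(el)
    if (ll_new - ll < tol) { ll <- max(ll, ll_new); break }
    ll <- ll_new
    if (cycles >= max_cycles) {
      warning("branch-length optimization stopped after ", max_cycles,
              " cycles without meeting tolerance", call. = FALSE)
      break
    }
  }
  tree$edge.length <- el
  list(tree = tree, loglik = ll, cycles = cycles)
}

#' Fit gamma shape and invariant proportion for one alignment
#'
#' Joint bounded maximization of the log-likelihood over
#' \eqn{\log\alpha \in [\log 0.02, \log 100]} and
#' \eqn{p_{inv} \in [0, 0.99]}, with tree and model fixed.
#'
#' @inheritParams log_likelihood
#' @param k number of gamma categories (default 4).
#' @return list with `alpha`, `p_inv`, `rates` (a [site_rates()]), `loglik`.
#' @export
fit_site_rates <- function(msa, tree, model, freqs = "model", k = 4L) {
  pi <- resolve_freqs(freqs, model, msa)
  m <- if (identical(pi, model$pi)) model else
    aa_model(model$S, pi, name = model$name, normalize = TRUE)
  td <- .tree_data(tree, msa)
  decomp <- q_eigen(rate_matrix(m), m$pi)
  obj <- function(par) {
    # L-BFGS-B probes finite-difference steps that can poke just past the
    # box; clamp before building the rate model
    r <- site_rates(min(max(exp(par[1L]), 0.02), 100),
                    min(max(par[2L], 0), 0.9899), k)
    -sum(.loglik_td(td, m, r, decomp))
  }
  fit <- stats::optim(c(0, 0.1), obj, method = "L-BFGS-B",
                      lower = c(log(0.02), 0), upper = c(log(100), 0.99))
  alpha <- exp(fit$par[1L])
  p_inv <- fit$par[2L]
  list(alpha = alpha, p_inv = p_inv, rates = site_rates(alpha, p_inv, k),
       loglik = -fit$value)
}
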