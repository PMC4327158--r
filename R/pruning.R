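# Internal pruning engine.
#
# Likelihoods are computed on the tree as stored (any rooting gives the same
# value for a reversible model).  Partial-likelihood matrices are rescaled
# per node by a scalar whenever their magnitude drifts low, with the log of
# the factor accumulated; a uniform factor per node keeps per-site values
# exact while avoiding per-column bookkeeping in the hot loop.
# The pre-order ("rest of tree") partials produced here are reused by the
# EM E-step and by per-branch length optimization.

.SCALE_FLOOR <- 1e-150

# Static tree/alignment bundle reused across likelihood evaluations.
.tree_data <- function(tree, msa) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  X <- msa_encode(msa)
  extra <- setdiff(tree$tip.label, rownames(X))
  miss <- setdiff(rownames(X), tree$tip.label)
  if (length(extra) || length(miss))
    stop("tree/MSA leaf mismatch; in tree only: ",
         paste(extra, collapse = ", "), "; in MSA only: ",
         paste(miss, collapse = ", "))
  po <- stats::reorder(tree, "postorder")
  n_tip <- length(po$tip.label)
  list(edge = po$edge, el = po$edge.length,
       n_tip = n_tip, n_node = n_tip + po$Nnode,
       root = po$edge[nrow(po$edge), 1L],
       X = X[po$tip.label, , drop = FALSE],
       S = ncol(X))
}

# Post-order partials for one rate category.
# P_list: per-edge transition matrices (row = parent state).
# Returns F (per-node 20 x S), scalar log-scalers, per-edge child
# contributions (P_e %*% F_child), and per-site logLik.
.partials_post <- function(td, P_list, pi) {
  Fm <- vector("list", td$n_node)
  lsc <- numeric(td$n_node)
  contrib <- vector("list", nrow(td$edge))
  for (i in seq_len(td$n_tip)) {
    Fi <- matrix(0, 20L, td$S)
    Fi[cbind(td$X[i, ], seq_len(td$S))] <- 1
    Fm[[i]] <- Fi
  }
  for (e in seq_len(nrow(td$edge))) {
    p <- td$edge[e, 1L]; ch <- td$edge[e, 2L]
    contrib[[e]] <- P_list[[e]] %*% Fm[[ch]]
    if (is.null(Fm[[p]])) {
      Fm[[p]] <- contrib[[e]]
      lsc[p] <- lsc[ch]
    } else {
      Fm[[p]] <- Fm[[p]] * contrib[[e]]
      lsc[p] <- lsc[p] + lsc[ch]
    }
    mx <- max(Fm[[p]])
    if (mx < .SCALE_FLOOR && mx > 0) {
      Fm[[p]] <- Fm[[p]] / mx
      lsc[p] <- lsc[p] + log(mx)
    }
  }
  root_like <- colSums(pi * Fm[[td$root]])
  list(F = Fm, lsc = lsc, contrib = contrib,
       site_loglik = log(root_like) + lsc[td$root])
}

# Pre-order partials: for each edge e = (p, child), the "exclusion" partial
# at p — the likelihood of everything outside the child subtree, including
# the stationary prior at the root — plus its scalar log-scaler.
.partials_pre <- function(td, P_list, pi, post) {
  ne <- nrow(td$edge)
  G <- vector("list", td$n_node)      # rest-of-tree partial at each node
  lsg <- numeric(td$n_node)
  G[[td$root]] <- matrix(pi, 20L, td$S)
  Gexcl <- vector("list", ne)
  lse <- numeric(ne)
  child_edges <- split(seq_len(ne), td$edge[, 1L])
  for (e in rev(seq_len(ne))) {       # reverse postorder = preorder
    p <- td$edge[e, 1L]; ch <- td$edge[e, 2L]
    sibs <- setdiff(child_edges[[as.character(p)]], e)
    H <- G[[p]]
    ls <- lsg[p]
    for (se in sibs) {
      H <- H * post$contrib[[se]]
      ls <- ls + post$lsc[td$edge[se, 2L]]
    }
    mx <- max(H)
    if (mx < .SCALE_FLOOR && mx > 0) {
      H <- H / mx
      ls <- ls + log(mx)
    }
    Gexcl[[e]] <- H
    lse[e] <- ls
    if (ch > td$n_tip) {
      G[[ch]] <- crossprod(P_list[[e]], H)
      lsg[ch] <- ls
    }
  }
  list(Gexcl = Gexcl, lse = lse)
}

# Per-edge transition matrices for one category rate.
.edge_P <- function(td, decomp, rate) {
  lapply(td$el, function(t) {
    P <- decomp$U %*% (exp(decomp$values * (rate * t)) * decomp$Uinv)
    P[P < 0] <- 0
    P
  })
}

# Which alignment columns are constant (invariant-eligible), and their state.
.constant_sites <- function(td) {
  state <- td$X[1L, ]
  const <- colSums(td$X != rep(state, each = nrow(td$X))) == 0L
  list(const = const, state = state)
}

# Mixture per-site log-likelihood over gamma categories + invariant class.
# cat_loglik: S x k matrix of per-category per-site logLik (gamma cats only).
.mix_site_loglik <- function(cat_loglik, weights, p_inv, const, state, pi) {
  k <- ncol(cat_loglik)
  lx <- cat_loglik + rep(log(weights[seq_len(k)]), each = nrow(cat_loglik))
  m <- lx[, 1L]
  if (k > 1L) for (j in 2:k) m <- pmax(m, lx[, j])
  acc <- exp(lx[, 1L] - m)
  if (k > 1L) for (j in 2:k) acc <- acc + exp(lx[, j] - m)
  out <- m + log(acc)
  if (p_inv > 0) {
    li <- rep(-Inf, length(out))
    li[const] <- log(p_inv) + log(pi[state[const]])
    mm <- pmax(out, li)
    both <- is.finite(mm)
    out[both] <- mm[both] + log(exp(out[both] - mm[both]) +
                                  exp(li[both] - mm[both]))
  }
  out
}
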