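# Independent oracles used across the suite.  These are deliberately naive
# (enumeration, quadrature, dynamic programming written from the textbook
# definitions) and share no code with the implementation they check.

# Exhaustive phylogenetic likelihood: sums over every assignment of states
# to the internal nodes, per site, mixing rate categories explicitly.
brute_force_loglik <- function(msa, tree, model, rates = site_rates(1e6, 0, 1L)) {
  X <- t(vapply(strsplit(msa$seqs, ""), function(s) match(s, AA_ALPHABET),
                integer(nchar(msa$seqs[1L]))))
  rownames(X) <- msa$ids
  po <- reorder(tree, "postorder")
  X <- X[po$tip.label, , drop = FALSE]
  n_tip <- nrow(X)
  n_node <- n_tip + po$Nnode
  root <- po$edge[nrow(po$edge), 1L]
  ints <- (n_tip + 1L):n_node
  grid <- as.matrix(expand.grid(rep(list(1:20), length(ints))))
  per_site <- vapply(seq_len(ncol(X)), function(s) {
    tot <- 0
    for (ci in seq_along(rates$rates)) {
      r <- rates$rates[ci]
      w <- rates$weights[ci]
      if (w == 0) next
      if (r == 0) {
        tot <- tot + w * (if (length(unique(X[, s])) == 1L)
          model$pi[X[1L, s]] else 0)
        next
      }
      Ps <- lapply(po$edge.length, function(t)
        transition_prob(model, r * t))
      lik <- 0
      for (g in seq_len(nrow(grid))) {
        st <- integer(n_node)
        st[seq_len(n_tip)] <- X[, s]
        st[ints] <- grid[g, ]
        p <- model$pi[st[root]]
        for (e in seq_len(nrow(po$edge)))
          p <- p * Ps[[e]][st[po$edge[e, 1L]], st[po$edge[e, 2L]]]
        lik <- lik + p
      }
      tot <- tot + w * lik
    }
    log(tot)
  }, numeric(1L))
  sum(per_site)
}

# Smith-Waterman local alignment score by dynamic programming; affine gaps
# (open includes the first extension, as in Biostrings' convention).
sw_score <- function(a, b, submat, gap_open = 11, gap_extend = 1) {
  a <- strsplit(a, "")[[1L]]
  b <- strsplit(b, "")[[1L]]
  n <- length(a); m <- length(b)
  M <- Ix <- Iy <- matrix(-Inf, n + 1L, m + 1L)
  M[1L, ] <- M[, 1L] <- 0
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sub <- submat[a[i], b[j]]
    M[i + 1L, j + 1L] <- max(0,
                             M[i, j] + sub, Ix[i, j] + sub, Iy[i, j] + sub)
    Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] - gap_open - gap_extend,
                              Ix[i, j + 1L] - gap_extend)
    Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] - gap_open - gap_extend,
                              Iy[i + 1L, j] - gap_extend)
    best <- max(best, M[i + 1L, j + 1L])
  }
  best
}

# All set partitions of 1..n (Bell-number enumeration by recursion).
set_partitions <- function(n) {
  if (n == 1L) return(list(list(1L)))
  out <- list()
  for (p in set_partitions(n - 1L)) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(q[[k]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# Exhaustive modularity maximum over all partitions of a small network.
exhaustive_modularity <- function(network) {
  n <- nrow(network$W)
  best <- -Inf
  best_p <- NULL
  for (p in set_partitions(n)) {
    lab <- integer(n)
    for (k in seq_along(p)) lab[p[[k]]] <- k
    m <- modularity_score(network, lab)
    if (m > best) { best <- m; best_p <- lab }
  }
  list(modularity = best, partition = best_p)
}

# A random small homogeneous MSA simulated under a given model.
toy_msa <- function(n_seq = 4L, sites = c(2L, 1L, 2L, 1L, 2L, 1L, 1L),
                    model = random_model(seed = 3), alpha = 1e6, p_inv = 0,
                    gamma_k = 1L, seed = 5L, branch_mean = 0.1) {
  spec <- repertoire_spec(n_msas = 1L, n_seq = n_seq,
                          fragment_sites = sites, model = model,
                          alpha = alpha, p_inv = p_inv, gamma_k = gamma_k,
                          branch_mean = branch_mean, seed = seed)
  rep <- simulate_repertoire(spec)
  list(msa = rep$msas[[1L]], tree = rep$truth[[1L]]$tree, model = model)
}
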