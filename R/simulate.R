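#' Specification of a synthetic antibody repertoire
#'
#' Describes the study conditions for simulated homogeneous repertoires:
#' sets of same-length sequences descended from a common germline-like root
#' along a random genealogy, evolved under a known reversible model with
#' discrete-gamma-plus-invariant site rates and region-structured rate
#' multipliers (CDR columns evolve faster than FR columns, mimicking the
#' concentration of somatic hypermutation in the binding loops).
#'
#' Defaults: seven fragment lengths (13, 8, 17, 8, 38, 12, 4) summing to 100
#' sites — the repertoire-average variable-region length; 20 alignments of
#' 25 sequences; exponential branch lengths with mean 0.05 substitutions per
#' site (shallow hypermutation divergence); gamma shape 1 with 10%
#' invariant sites; CDR:FR rate multipliers 3:0.5 rescaled so their
#' length-weighted mean is 1.
#'
#' @param n_msas number of alignments.
#' @param n_seq sequences per alignment: a single count or a `c(min, max)`
#'   range sampled uniformly per alignment.
#' @param fragment_sites 7 region lengths (FR1, CDR1, FR2, CDR2, FR3, CDR3,
#'   FR4) in residues.
#' @param model generating [aa_model()] (default [lg_model()] with uniform-
#'   leaning frequencies left as published).
#' @param alpha,p_inv gamma shape and invariant proportion.
#' @param gamma_k gamma categories.
#' @param cdr_multiplier,fr_multiplier raw region rate multipliers before
#'   rescaling to length-weighted mean 1.
#' @param branch_mean mean of the exponential branch-length law.
#' @param seed master seed.
#' @return object of class `repertoire_spec`.
#' @export
repertoire_spec <- function(n_msas = 20L, n_seq = c(25L, 25L),
                            fragment_sites = c(13L, 8L, 17L, 8L, 38L, 12L, 4L),
                            model = lg_model(), alpha = 1, p_inv = 0.1,
                            gamma_k = 4L, cdr_multiplier = 3,
                            fr_multiplier = 0.5, branch_mean = 0.05,
                            seed = 1L) {
  if (length(n_seq) == 1L) n_seq <- rep(n_seq, 2L)
  stopifnot(n_msas >= 1L, all(n_seq >= 3L), length(fragment_sites) == 7L,
            all(fragment_sites >= 0L), cdr_multiplier > 0, fr_multiplier > 0,
            branch_mean > 0)
  is_cdr <- c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  raw <- ifelse(is_cdr, cdr_multiplier, fr_multiplier)
  # rescale so the length-weighted mean multiplier is exactly 1
  raw <- raw * sum(fragment_sites) / sum(raw * fragment_sites)
  structure(list(n_msas = as.integer(n_msas), n_seq = as.integer(n_seq),
                 fragment_sites = as.integer(fragment_sites),
                 model = model, alpha = alpha, p_inv = p_inv,
                 gamma_k = as.integer(gamma_k),
                 region_multipliers = raw, branch_mean = branch_mean,
                 seed = as.integer(seed)),
            class = "repertoire_spec")
}

#' Simulate a random genealogy
#'
#' Random binary topology grown by sequential random attachment of leaves;
#' branch lengths i.i.d. exponential with the given mean.
#'
#' @param n_leaves number of leaves (>= 3).
#' @param branch_mean mean branch length (expected substitutions per site).
#' @param seed optional integer seed.
#' @param labels optional tip labels (default `t1..tn`).
#' @return an unrooted `phylo` tree.
#' @export
simulate_genealogy <- function(n_leaves, branch_mean = 0.05, seed = NULL,
                               labels = NULL) {
  if (n_leaves < 3L) stop("need at least 3 leaves, got ", n_leaves)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rtree(n_leaves, rooted = FALSE,
                     tip.label = labels %||%
                       paste0("t", seq_len(n_leaves)))
  tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 1 / branch_mean)
  tree
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a homogeneous MSA along a genealogy
#'
#' The root sequence is drawn from the model's stationary frequencies and
#' evolved along each branch with transition probabilities
#' \eqn{P(r \cdot m \cdot t)}, where \eqn{r} is the site's gamma-category
#' rate (0 for invariant sites) and \eqn{m} its region multiplier.
#'
#' @param tree `phylo` genealogy (its tips name the simulated sequences).
#' @param model generating [aa_model()].
#' @param spec a [repertoire_spec()] carrying site counts, rates and
#'   multipliers.
#' @param seed optional integer seed.
#' @param id alignment id.
#' @return list with `msa` (a [hom_msa()]) and `truth` (list: `tree`,
#'   `site_rates` — the realized per-site rate factors —, `site_category`,
#'   `model_name`).
#' @export
simulate_msa <- function(tree, model, spec, seed = NULL, id = "sim") {
  if (!is.null(seed)) set.seed(seed)
  n_sites <- sum(spec$fragment_sites)
  region <- rep(seq_len(7L), spec$fragment_sites)
  mult <- spec$region_multipliers[region]
  sr <- site_rates(spec$alpha, spec$p_inv, spec$gamma_k)
  cat_idx <- sample.int(spec$gamma_k + 1L, n_sites, replace = TRUE,
                        prob = sr$weights)
  r_site <- sr$rates[cat_idx] * mult

  Q <- rate_matrix(model)
  decomp <- q_eigen(Q, model$pi)
  po <- stats::reorder(tree, "postorder")
  n_tip <- length(po$tip.label)
  n_node <- n_tip + po$Nnode
  root <- po$edge[nrow(po$edge), 1L]
  states <- matrix(NA_integer_, n_node, n_sites)
  states[root, ] <- sample.int(20L, n_sites, replace = TRUE,
                               prob = model$pi)
  # preorder = reverse postorder: parents are assigned before children
  for (e in rev(seq_len(nrow(po$edge)))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    t_e <- po$edge.length[e]
    child <- states[p, ]
    for (rv in unique(r_site)) {
      idx <- which(r_site == rv)
      if (rv == 0 || t_e == 0) { states[ch, idx] <- states[p, idx]; next }
      P <- transition_prob(NULL, rv * t_e, decomp = decomp)
      Pc <- t(apply(P, 1L, cumsum))
      u <- stats::runif(length(idx))
      child[idx] <- max.col(Pc[states[p, idx], , drop = FALSE] >=
                              u, ties.method = "first")
    }
    states[ch, ] <- child
  }
  seqs <- apply(states[seq_len(n_tip), , drop = FALSE], 1L,
                function(s) paste(AA_ALPHABET[s], collapse = ""))
  names(seqs) <- po$tip.label
  msa <- hom_msa(seqs, signature = spec$fragment_sites, id = id)
  list(msa = msa,
       truth = list(tree = tree, site_rates = r_site,
                    site_category = cat_idx, model_name = model$name))
}

#' Simulate a whole repertoire of homogeneous alignments
#'
#' Applies [simulate_genealogy()] and [simulate_msa()] `n_msas` times under
#' the master seed of the spec.  Fully reproducible: identical specs give
#' identical repertoires.
#'
#' @param spec a [repertoire_spec()].
#' @return list with `msas` (list of [hom_msa()]), `truth` (per-MSA truth
#'   records), `spec`.
#' @export
simulate_repertoire <- function(spec) {
  stopifnot(inherits(spec, "repertoire_spec"))
  set.seed(spec$seed)
  msas <- vector("list", spec$n_msas)
  truth <- vector("list", spec$n_msas)
  for (i in seq_len(spec$n_msas)) {
    n <- spec$n_seq[1L] +
      sample.int(spec$n_seq[2L] - spec$n_seq[1L] + 1L, 1L) - 1L
    tree <- simulate_genealogy(n, spec$branch_mean,
                               labels = sprintf("msa%03d_s%03d", i,
                                                seq_len(n)))
    sim <- simulate_msa(tree, spec$model, spec, id = sprintf("msa%03d", i))
    msas[[i]] <- sim$msa
    truth[[i]] <- sim$truth
  }
  list(msas = msas, truth = truth, spec = spec)
}

#' Write a simulated repertoire to disk
#'
#' One FASTA per alignment plus a JSON truth manifest (trees in Newick,
#' per-site rate factors, spec parameters).
#'
#' @param rep result of [simulate_repertoire()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_repertoire <- function(rep, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(rep$msas))
  for (i in seq_along(rep$msas)) {
    files[i] <- file.path(dir, paste0(rep$msas[[i]]$id, ".fa"))
    write_fasta(stats::setNames(rep$msas[[i]]$seqs, rep$msas[[i]]$ids),
                files[i])
  }
  manifest <- list(
    n_msas = rep$spec$n_msas,
    seed = rep$spec$seed,
    fragment_sites = rep$spec$fragment_sites,
    alpha = rep$spec$alpha, p_inv = rep$spec$p_inv,
    branch_mean = rep$spec$branch_mean,
    region_multipliers = rep$spec$region_multipliers,
    model_name = rep$spec$model$name,
    msas = lapply(seq_along(rep$msas), function(i) list(
      id = rep$msas[[i]]$id, fasta = basename(files[i]),
      newick = ape::write.tree(rep$truth[[i]]$tree),
      site_rates = rep$truth[[i]]$site_rates)))
  jsonlite::write_json(manifest, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Draw a random heterogeneous exchangeability model
#'
#' Exchangeabilities i.i.d. log-normal (meanlog 0, sdlog 1) and a
#' gamma-perturbed frequency vector; used as a generating truth in
#' simulation studies.
#'
#' @param seed integer seed.
#' @param sdlog spread of the log-normal exchangeabilities.
#' @return a normalized [aa_model()].
#' @export
random_model <- function(seed = NULL, sdlog = 1) {
  if (!is.null(seed)) set.seed(seed)
  S <- matrix(0, 20L, 20L)
  S[upper.tri(S)] <- stats::rlnorm(190L, 0, sdlog)
  S <- S + t(S)
  pi <- stats::rgamma(20L, shape = 5, rate = 1)
  pi <- pi / sum(pi)
  aa_model(S, pi, name = "random", normalize = TRUE)
}
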