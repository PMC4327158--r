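#' Per-site log-likelihood table over MSAs and models
#'
#' For every alignment x model cell: a genealogy is inferred (or taken from
#' `trees`), branch lengths and the gamma/invariant parameters are
#' optimized, and the optimized total log-likelihood is divided by the site
#' count.  Column means summarize each model's fit.
#'
#' @param msas list of [hom_msa()] objects.
#' @param models list of [aa_model()] objects (at least 2 for a
#'   comparison).
#' @param freqs frequency option applied to every model: `"model"`,
#'   `"msa"`, or a numeric vector (e.g. training frequencies).
#' @param trees optional list of fixed trees (one per MSA); when `NULL` a
#'   NJ tree is inferred per cell under the cell's model.
#' @param gamma_k gamma categories.
#' @param optimize_branches optimize branch lengths per cell (default
#'   TRUE).
#' @return object of class `fit_table`: matrix (MSA x model) of per-site
#'   log-likelihoods with a `"means"` attribute.
#' @export
fit_table <- function(msas, models, freqs = "model", trees = NULL,
                      gamma_k = 4L, optimize_branches = TRUE) {
  if (inherits(msas, "hom_msa")) msas <- list(msas)
  if (inherits(models, "aa_model")) models <- list(models)
  model_names <- make.unique(vapply(models, `[[`, "", "name"))
  out <- matrix(NA_real_, length(msas), length(models),
                dimnames = list(vapply(msas, `[[`, "", "id"), model_names))
  for (j in seq_along(models)) {
    for (i in seq_along(msas)) {
      m <- msas[[i]]
      tr <- if (is.null(trees)) starting_tree(m, models[[j]]) else
        trees[[i]]
      sr <- fit_site_rates(m, tr, models[[j]], freqs = freqs, k = gamma_k)
      if (optimize_branches) {
        opt <- optimize_branch_lengths(m, tr, models[[j]], sr$rates,
                                       freqs = freqs)
        tr <- opt$tree
        sr <- fit_site_rates(m, tr, models[[j]], freqs = freqs, k = gamma_k)
      }
      ll <- log_likelihood(m, tr, models[[j]], sr$rates, freqs = freqs)
      stopifnot(abs(ll$loglik - sum(ll$per_site)) < 1e-8 * abs(ll$loglik))
      out[i, j] <- ll$loglik / ll$n_sites
    }
  }
  attr(out, "means") <- colMeans(out)
  class(out) <- c("fit_table", class(out))
  out
}

#' @export
print.fit_table <- function(x, ...) {
  cat("Per-site log-likelihoods (alignments x models):\n")
  print(round(unclass(x), 4))
  cat("\nModel means:\n")
  print(round(attr(x, "means"), 4))
  invisible(x)
}

#' Paired Wilcoxon signed-rank test between two models
#'
#' Two-sided (by default) signed-rank test on paired per-alignment values
#' (per-site log-likelihoods); the pairing unit is the alignment.  Zero
#' differences are dropped (signed-rank convention); an exact null
#' distribution is used for up to 25 non-zero pairs, the normal
#' approximation with continuity correction beyond.
#'
#' @param a,b paired numeric vectors of equal length.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return list with `statistic` (V, the positive-rank sum), `p_value`,
#'   `n` (non-zero pairs).
#' @export
wilcoxon_signed_rank <- function(a, b, alternative = "two.sided") {
  if (length(a) != length(b))
    stop("paired vectors of unequal length (", length(a), " vs ",
         length(b), ")")
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0L)
    stop("degenerate pairing: all differences are zero")
  if (length(d) < 5L)
    warning("only ", length(d), " non-zero pairs; test has little power",
            call. = FALSE)
  ht <- suppressWarnings(stats::wilcox.test(
    d, alternative = alternative, exact = length(d) <= 25L,
    correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n = length(d))
}

#' Pearson correlation of two models' exchangeabilities
#'
#' Correlation over the 190 unordered off-diagonal pairs, after normalizing
#' both models (so rescaling either matrix has no effect).
#'
#' @param model_a,model_b [aa_model()] objects.
#' @return the correlation coefficient.
#' @export
exchangeability_correlation <- function(model_a, model_b) {
  sa <- normalize_model(model_a)$S[upper.tri(model_a$S)]
  sb <- normalize_model(model_b)$S[upper.tri(model_b$S)]
  if (stats::sd(sa) == 0 || stats::sd(sb) == 0)
    stop("constant exchangeability matrix: correlation undefined")
  stats::cor(sa, sb)
}

#' Compare substitution models on a set of alignments
#'
#' Convenience wrapper building the [fit_table()] and running pairwise
#' Wilcoxon signed-rank tests of every model against the first.
#'
#' @inheritParams fit_table
#' @param alternative passed to [wilcoxon_signed_rank()].
#' @return list with `table` (the fit table), `tests` (data.frame of
#'   pairwise tests vs the first model).
#' @export
compare_models <- function(msas, models, freqs = "model", trees = NULL,
                           gamma_k = 4L, optimize_branches = TRUE,
                           alternative = "two.sided") {
  tab <- fit_table(msas, models, freqs = freqs, trees = trees,
                   gamma_k = gamma_k, optimize_branches = optimize_branches)
  tests <- NULL
  if (ncol(tab) >= 2L && nrow(tab) >= 5L) {
    tests <- do.call(rbind, lapply(2:ncol(tab), function(j) {
      wt <- tryCatch(wilcoxon_signed_rank(tab[, 1L], tab[, j],
                                          alternative = alternative),
                     error = function(e) list(statistic = NA, p_value = NA,
                                              n = 0L))
      data.frame(model_a = colnames(tab)[1L], model_b = colnames(tab)[j],
                 statistic = wt$statistic, p_value = wt$p_value, n = wt$n)
    }))
  }
  list(table = tab, tests = tests)
}
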