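#' Column bootstrap of a homogeneous MSA
#'
#' Draws alignment columns i.i.d. uniformly with replacement, preserving
#' the alignment dimensions.  Reproducible under `seed`.
#'
#' @param msa a [hom_msa()].
#' @param seed optional integer seed.
#' @return a [hom_msa()] of the same dimensions (fragment signature is
#'   dropped: resampled columns no longer map to contiguous fragments).
#' @export
bootstrap_msa <- function(msa, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- msa_matrix(msa)
  cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
  b <- m[, cols, drop = FALSE]
  hom_msa(stats::setNames(apply(b, 1L, paste, collapse = ""), msa$ids),
          id = paste0(msa$id, "_boot"))
}

#' Bootstrap ensemble of re-estimated models
#'
#' For each of `B` replicates, every MSA in the training set is column-
#' bootstrapped independently and the full estimation pipeline
#' ([fit_ab_model()]) is re-run on the replicate set.  Per-replicate seeds
#' are derived from the master seed by replicate index, so replicates are
#' independent and could be computed concurrently with identical results.
#' Replicates whose estimation fails are recorded and excluded.
#'
#' @param msas list of [hom_msa()] training alignments.
#' @param B number of bootstrap replicates (default 100).
#' @param seed master seed.
#' @param ... estimation options passed on to [fit_ab_model()] (e.g.
#'   `initial_model`, `rounds`, `optimize_branches`).
#' @return object of class `bootstrap_ensemble`: list with `models`
#'   (normalized [aa_model()]s), `B_requested`, `B_effective`, `failed`
#'   (replicate indices), `seed`.
#' @export
bootstrap_models <- function(msas, B = 100L, seed = 1L, ...) {
  if (inherits(msas, "hom_msa")) msas <- list(msas)
  models <- list()
  failed <- integer()
  for (b in seq_len(B)) {
    rep_seed <- (seed + 104729L * b) %% .Machine$integer.max
    set.seed(rep_seed)
    boot <- lapply(msas, bootstrap_msa)
    fit <- tryCatch(fit_ab_model(boot, ...),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning("bootstrap replicate ", b, " failed: ",
              conditionMessage(fit), call. = FALSE)
      failed <- c(failed, b)
    } else {
      models[[length(models) + 1L]] <- normalize_model(fit$model)
    }
  }
  structure(list(models = models, B_requested = B,
                 B_effective = length(models), failed = failed,
                 seed = seed),
            class = "bootstrap_ensemble")
}

#' Per-pair bootstrap distribution of exchangeabilities
#'
#' @param ensemble a `bootstrap_ensemble` (or plain list of `aa_model`s).
#' @return 190 x B matrix of normalized exchangeabilities; rows named
#'   `"A-C"` etc. over the unordered amino-acid pairs.
#' @export
ensemble_matrix <- function(ensemble) {
  models <- if (inherits(ensemble, "bootstrap_ensemble")) ensemble$models
            else ensemble
  ut <- upper.tri(matrix(0, 20L, 20L))
  pair_names <- outer(AA_ALPHABET, AA_ALPHABET, paste, sep = "-")[ut]
  out <- vapply(models, function(m) normalize_model(m)$S[ut],
                numeric(sum(ut)))
  rownames(out) <- pair_names
  out
}

#' Flag exchangeabilities that differ from a reference model
#'
#' A pair is declared significantly different when the reference value lies
#' outside the central bootstrap interval: `"higher"` if the reference falls
#' below the `lo` quantile of the bootstrap distribution of that pair (the
#' estimated rate is higher than the reference), `"lower"` if it exceeds
#' the `hi` quantile, `"ns"` otherwise.  Quantiles use the interpolated
#' order-statistic convention (type 7); both ensemble and reference are
#' normalized before comparison, so joint rescaling cannot change verdicts.
#'
#' @param ensemble a `bootstrap_ensemble` (B >= 40 for the default
#'   quantiles).
#' @param reference an [aa_model()].
#' @param lo,hi quantile levels (defaults 0.025 / 0.975).
#' @return data.frame with one row per unordered pair: `aa_i`, `aa_j`,
#'   `ref_value`, `q_lo`, `q_hi`, `verdict`.
#' @export
significance_vs_reference <- function(ensemble, reference,
                                      lo = 0.025, hi = 0.975) {
  E <- ensemble_matrix(ensemble)
  B <- ncol(E)
  need <- ceiling(1 / min(lo, 1 - hi))
  if (B < need)
    stop("ensemble has ", B, " replicates; need at least ", need,
         " for quantiles (", lo, ", ", hi, ")")
  ref <- normalize_model(reference)$S
  ut <- upper.tri(ref)
  idx <- which(ut, arr.ind = TRUE)
  q <- t(apply(E, 1L, stats::quantile, probs = c(lo, hi), type = 7))
  ref_v <- ref[ut]
  verdict <- rep("ns", nrow(E))
  verdict[ref_v < q[, 1L]] <- "higher"
  verdict[ref_v > q[, 2L]] <- "lower"
  data.frame(aa_i = AA_ALPHABET[idx[, 1L]], aa_j = AA_ALPHABET[idx[, 2L]],
             ref_value = ref_v, q_lo = q[, 1L], q_hi = q[, 2L],
             verdict = verdict, stringsAsFactors = FALSE)
}
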