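#' Reversible amino-acid substitution models
#'
#' An `aa_model` couples a symmetric matrix of exchangeabilities `S`
#' (\eqn{s_{ij}}, zero diagonal) with a vector of stationary frequencies
#' \eqn{\pi}.  Under time reversibility every instantaneous replacement rate
#' decomposes as \eqn{q_{ij} = s_{ij}\pi_j} for \eqn{i \neq j}; the diagonal
#' is fixed by the generator constraint \eqn{q_{ii} = -\sum_{j\neq i} q_{ij}}.
#' Models are conventionally normalized so that
#' \eqn{\sum_{i \neq j} s_{ij}\pi_i\pi_j = 1}, i.e. one expected substitution
#' per site per unit time at stationarity.
#'
#' @param S 20x20 symmetric non-negative matrix of exchangeabilities with
#'   zero diagonal.  Rows/columns follow [AA_ALPHABET] order.
#' @param pi stationary frequency vector of length 20, strictly positive,
#'   summing to 1.  Frequencies at or below `freq_floor` are floored and the
#'   vector renormalized (with a message), since downstream transforms divide
#'   by \eqn{\pi}.
#' @param name label for the model.
#' @param normalize if `TRUE` (default) the exchangeabilities are rescaled to
#'   the unit-mean-rate convention.
#' @param freq_floor lower bound applied to frequencies (default `1e-6`).
#' @return An object of class `aa_model`: a list with elements `S`, `pi`,
#'   `name`.
#' @examples
#' m <- aa_model(matrix(1, 20, 20) - diag(20), rep(1 / 20, 20), "equal")
#' q <- rate_matrix(m)
#' range(rowSums(q))  # zero row sums
#' @export
aa_model <- function(S, pi, name = "custom", normalize = TRUE,
                     freq_floor = 1e-6) {
  S <- as.matrix(S)
  if (!all(dim(S) == c(20L, 20L)))
    stop("S must be a 20x20 matrix, got ", paste(dim(S), collapse = "x"))
  if (any(S < 0)) {
    bad <- which(S < 0, arr.ind = TRUE)[1L, ]
    stop("negative exchangeability s[", bad[1L], ",", bad[2L], "]")
  }
  asym <- abs(S - t(S))
  if (max(asym) > 1e-8 * max(1, max(S))) {
    bad <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
    stop("S is not symmetric at entry [", bad[1L], ",", bad[2L], "]: ",
         S[bad[1L], bad[2L]], " vs ", S[bad[2L], bad[1L]])
  }
  S <- (S + t(S)) / 2
  diag(S) <- 0
  pi <- validate_frequencies(pi, freq_floor = freq_floor)
  dimnames(S) <- list(AA_ALPHABET, AA_ALPHABET)
  m <- structure(list(S = S, pi = pi, name = name), class = "aa_model")
  if (normalize) m <- normalize_model(m)
  m
}

#' Validate (and floor) a stationary frequency vector
#'
#' @param pi numeric vector of length 20.
#' @param freq_floor frequencies at or below this value are raised to it and
#'   the vector renormalized; a message reports how many entries were floored.
#' @return named, validated frequency vector.
#' @keywords internal
validate_frequencies <- function(pi, freq_floor = 1e-6) {
  pi <- as.numeric(pi)
  if (length(pi) != 20L)
    stop("pi must have length 20, got ", length(pi))
  if (any(pi < 0)) stop("negative frequency pi[", which(pi < 0)[1L], "]")
  if (abs(sum(pi) - 1) > 1e-6)
    stop("frequencies must sum to 1 (got ", format(sum(pi)), ")")
  pi <- pi / sum(pi)
  low <- pi < freq_floor
  if (any(low)) {
    message(sum(low), " stationary frequenc",
            if (sum(low) == 1L) "y" else "ies",
            " below ", freq_floor, "; floored and renormalized")
    pi[low] <- freq_floor
    pi <- pi / sum(pi)
  }
  names(pi) <- AA_ALPHABET
  pi
}

#' Normalize a model to one expected substitution per unit time
#'
#' Rescales the exchangeabilities by a single constant \eqn{c} so that
#' \eqn{\sum_{i\neq j} s_{ij}\pi_i\pi_j = 1}.  Idempotent and invariant to
#' prior rescaling of `S`.
#'
#' @param model an [aa_model()].
#' @return the normalized `aa_model`.
#' @export
normalize_model <- function(model) {
  stopifnot(inherits(model, "aa_model"))
  rate <- total_rate(model)
  if (rate <= 0) stop("degenerate model: all exchangeabilities are zero")
  model$S <- model$S / rate
  model
}

# Sum_{i != j} s_ij pi_i pi_j: the expected substitution rate at stationarity.
total_rate <- function(model) {
  as.numeric(model$pi %*% model$S %*% model$pi)
}

#' Build the instantaneous rate matrix Q from a model
#'
#' \eqn{q_{ij} = s_{ij}\pi_j} off the diagonal; diagonal entries make rows
#' sum to zero.  The result satisfies detailed balance
#' \eqn{\pi_i q_{ij} = \pi_j q_{ji}}.
#'
#' @param model an [aa_model()].
#' @return 20x20 rate matrix (substitutions per unit time).
#' @export
rate_matrix <- function(model) {
  stopifnot(inherits(model, "aa_model"))
  Q <- model$S * rep(model$pi, each = 20L)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Recover the exchangeability decomposition of a reversible rate matrix
#'
#' Inverts \eqn{q_{ij} = s_{ij}\pi_j} by the symmetrized transform
#' \eqn{s_{ij} = (q_{ij}/\pi_j + q_{ji}/\pi_i)/2}.  When `Q` is exactly
#' reversible with respect to `pi` the two summands agree and the round trip
#' through [rate_matrix()] reproduces `Q`; averaging absorbs small numerical
#' asymmetries.
#'
#' @param Q 20x20 rate matrix.
#' @param pi strictly positive stationary frequency vector.
#' @param name label for the resulting model.
#' @param normalize passed to [aa_model()].
#' @return an [aa_model()].
#' @export
as_exchangeability <- function(Q, pi, name = "from_Q", normalize = FALSE) {
  if (any(pi <= 0)) stop("pi must be strictly positive (pi[",
                         which(pi <= 0)[1L], "] = ", pi[which(pi <= 0)[1L]], ")")
  pi <- pi / sum(pi)
  A <- Q / rep(pi, each = 20L)      # q_ij / pi_j
  S <- (A + t(A)) / 2
  diag(S) <- 0
  aa_model(S, pi, name = name, normalize = normalize)
}

#' Mean absolute relative difference between two exchangeability matrices
#'
#' The convergence diagnostic used to monitor successive estimates:
#' \eqn{\Delta_{ij} = |(s_{ij} - s^*_{ij})/s_{ij}|}, averaged over the 190
#' unordered amino-acid pairs.
#'
#' @param S reference exchangeability matrix (or `aa_model`); must be
#'   strictly positive off the diagonal.
#' @param S_star comparison matrix (or `aa_model`).
#' @return list with `delta` (20x20 matrix, NA on the diagonal) and
#'   `mean_abs` (mean of \eqn{|\Delta_{ij}|} over unordered pairs).
#' @export
relative_difference <- function(S, S_star) {
  if (inherits(S, "aa_model")) S <- S$S
  if (inherits(S_star, "aa_model")) S_star <- S_star$S
  off <- upper.tri(S)
  if (any(S[off] == 0)) {
    bad <- which(S == 0 & upper.tri(S), arr.ind = TRUE)[1L, ]
    stop("zero reference exchangeability for pair ",
         AA_ALPHABET[bad[1L]], "-", AA_ALPHABET[bad[2L]],
         "; relative difference undefined")
  }
  delta <- (S - S_star) / S
  diag(delta) <- NA_real_
  list(delta = delta, mean_abs = mean(abs(delta[off])))
}

#' Discrete gamma + invariant-sites rate model
#'
#' `K` equal-probability gamma rate categories (category rate = mean of its
#' quantile bin), each carrying weight \eqn{(1 - p_{inv})/K}, plus an
#' invariant category at rate 0 with weight \eqn{p_{inv}}.  Non-invariant
#' rates are rescaled so the overall mean rate is exactly 1.
#'
#' @param alpha gamma shape parameter (> 0).
#' @param p_inv proportion of invariant sites, in [0, 1).
#' @param k number of gamma categories (default 4).
#' @return object of class `site_rates`: list with `rates`, `weights`
#'   (each length `k + 1`, invariant category last), `alpha`, `p_inv`, `k`.
#' @export
site_rates <- function(alpha, p_inv = 0, k = 4L) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  if (p_inv < 0 || p_inv >= 1) stop("p_inv must lie in [0, 1)")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  # Mean of each equal-probability bin of Gamma(shape = alpha, rate = alpha):
  # E[X | bin] = alpha/alpha * [F_{alpha+1}(b) - F_{alpha+1}(a)] * k
  breaks <- stats::qgamma(seq(0, 1, length.out = k + 1L),
                          shape = alpha, rate = alpha)
  cdf1 <- stats::pgamma(breaks, shape = alpha + 1, rate = alpha)
  rates <- diff(cdf1) * k
  rates <- rates / sum(rates) * k        # guard rounding: exact mean 1
  if (p_inv > 0) rates <- rates / (1 - p_inv)
  structure(list(rates = c(rates, 0),
                 weights = c(rep((1 - p_inv) / k, k), p_inv),
                 alpha = alpha, p_inv = p_inv, k = k),
            class = "site_rates")
}

# Symmetric eigendecomposition of a reversible Q.  B = D^{1/2} Q D^{-1/2}
# is symmetric, so the eigenvalues are real; P(t) = U exp(Lambda t) Uinv
# with U = D^{-1/2} V, Uinv = t(V) D^{1/2}.  Reused by the EM integrals.
q_eigen <- function(Q, pi) {
  sq <- sqrt(pi)
  B <- Q * (sq / rep(sq, each = 20L))    # B_ij = sqrt(pi_i) q_ij / sqrt(pi_j)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       U = e$vectors / sq,
       Uinv = t(e$vectors) * rep(sq, each = 20L))
}

#' Transition probability matrix P(t) = exp(tQ)
#'
#' Computed through the symmetric eigendecomposition of the
#' \eqn{\pi^{1/2}}-similarity transform of `Q` (real eigenvalues for
#' reversible models).
#'
#' @param Q 20x20 rate matrix, or an [aa_model()] (converted via
#'   [rate_matrix()]).
#' @param t elapsed time (branch length), must be >= 0.
#' @param pi stationary frequencies; required when `Q` is a bare matrix.
#' @param decomp optional precomputed decomposition from an earlier call
#'   (internal reuse).
#' @return 20x20 row-stochastic matrix.
#' @export
transition_prob <- function(Q, t, pi = NULL, decomp = NULL) {
  if (t < 0) stop("negative time t = ", t)
  if (inherits(Q, "aa_model")) {
    pi <- Q$pi
    Q <- rate_matrix(Q)
  }
  if (is.null(decomp)) {
    if (is.null(pi)) stop("pi required when Q is a bare matrix")
    decomp <- q_eigen(Q, pi)
  }
  P <- decomp$U %*% (exp(decomp$values * t) * decomp$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' @export
print.aa_model <- function(x, ...) {
  cat("Reversible amino-acid substitution model:", x$name, "\n")
  cat(sprintf("  mean rate at stationarity: %.6f\n", total_rate(x)))
  s <- x$S[upper.tri(x$S)]
  cat(sprintf("  exchangeabilities: range [%.4g, %.4g], mean %.4g\n",
              min(s), max(s), mean(s)))
  top <- order(x$pi, decreasing = TRUE)[1:3]
  cat(sprintf("  frequencies: most common %s\n",
              paste(sprintf("%s=%.3f", AA_ALPHABET[top], x$pi[top]),
                    collapse = ", ")))
  invisible(x)
}
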