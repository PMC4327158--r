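#' Read a substitution model from a PAML-style .dat file
#'
#' The format carries 19 lines of lower-triangular exchangeabilities (line
#' \eqn{i} holds the \eqn{i} entries of row \eqn{i+1}) followed by the 20
#' stationary frequencies, all in the historical PAML amino-acid order
#' (A, R, N, D, ...).  Entries may be split across lines arbitrarily; lines
#' starting with `#` are comments.  Matrices are re-mapped to the package's
#' canonical alphabetical order on load.
#'
#' @param path file to read.
#' @param name model label; defaults to the file name without extension.
#' @param normalize passed to [aa_model()]; published matrices are kept as
#'   printed by default.
#' @return an [aa_model()].
#' @export
read_paml_dat <- function(path, name = NULL,
                          normalize = FALSE) {
  if (!file.exists(path)) stop("no such model file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  tokens <- scan(text = paste(lines, collapse = "\n"), what = numeric(),
                 quiet = TRUE)
  if (length(tokens) < 210)
    stop("model file ", path, " holds ", length(tokens),
         " numbers; expected at least 210 (190 exchangeabilities + 20 frequencies)")
  S_paml <- matrix(0, 20L, 20L)
  S_paml[lower.tri(S_paml)] <- NA  # fill row-wise below
  idx <- 1L
  for (i in 2:20) for (j in 1:(i - 1L)) {
    S_paml[i, j] <- tokens[idx]
    idx <- idx + 1L
  }
  S_paml[upper.tri(S_paml)] <- t(S_paml)[upper.tri(S_paml)]
  pi_paml <- tokens[idx:(idx + 19L)]
  ord <- match(AA_ALPHABET, AA_PAML_ORDER)
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  aa_model(S_paml[ord, ord], pi_paml[ord], name = name,
           normalize = normalize)
}

#' Write a model to PAML .dat format
#'
#' Inverse of [read_paml_dat()]: emits the lower-triangular exchangeabilities
#' and frequencies in PAML order with 6 significant digits.
#'
#' @param model an [aa_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_paml_dat <- function(model, path) {
  stopifnot(inherits(model, "aa_model"))
  ord <- match(AA_PAML_ORDER, AA_ALPHABET)
  S <- model$S[ord, ord]
  pi <- model$pi[ord]
  rows <- vapply(2:20, function(i)
    paste(formatC(S[i, 1:(i - 1L)], format = "g", digits = 6),
          collapse = " "), character(1L))
  writeLines(c(rows, "",
               paste(formatC(pi, format = "g", digits = 6), collapse = " ")),
             path)
  invisible(path)
}

#' Published general amino-acid models
#'
#' The LG and WAG exchangeability matrices with their published stationary
#' frequencies, bundled as fixed constants in PAML `.dat` format.  They serve
#' as initialization points for model estimation and as general-protein
#' references in model comparison and modularity analysis.
#'
#' @return an [aa_model()].
#' @export
lg_model <- function() {
  read_paml_dat(system.file("extdata", "lg.dat", package = "absubst"),
                name = "LG")
}

#' @rdname lg_model
#' @export
wag_model <- function() {
  read_paml_dat(system.file("extdata", "wag.dat", package = "absubst"),
                name = "WAG")
}

#' The uniform (equal-rates) model
#'
#' All 190 exchangeabilities equal, combined with the supplied frequencies;
#' the conventional uninformative starting point for estimation.
#'
#' @param pi stationary frequencies (default uniform).
#' @return an [aa_model()], normalized.
#' @export
equal_rates_model <- function(pi = rep(1 / 20, 20)) {
  aa_model(matrix(1, 20L, 20L) - diag(20L), pi, name = "equal",
           normalize = TRUE)
}
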