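#' The canonical amino-acid alphabet
#'
#' All matrices and frequency vectors in this package are indexed by the 20
#' standard amino acids in alphabetical one-letter-code order.  Published
#' model files in PAML \code{.dat} format use a different historical order
#' (A, R, N, D, ...); those are re-mapped on load, see [read_paml_dat()].
#'
#' @format A character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Historical order used by PAML-style .dat model files.
AA_PAML_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Characters treated as ambiguity codes by the quality filter.
AA_AMBIGUOUS <- c("X", "B", "Z", "J", "U", "O")

#' Map amino-acid one-letter codes to canonical indices
#'
#' @param x character vector of single letters.
#' @return integer vector of indices into [AA_ALPHABET]; NA for letters that
#'   are not standard amino acids.
#' @keywords internal
aa_index <- function(x) {
  match(toupper(x), AA_ALPHABET)
}
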