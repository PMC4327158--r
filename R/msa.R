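#' Homogeneous (gapless) antibody alignment
#'
#' A homogeneous MSA is a set of same-length antibody variable-region
#' sequences whose seven structural fragments (FR1, CDR1, FR2, CDR2, FR3,
#' CDR3, FR4) all have identical lengths, so the sequences are positionally
#' aligned by construction without any gap characters.
#'
#' @param seqs named character vector of amino-acid sequences (all the same
#'   length, standard 20-letter alphabet only).
#' @param signature integer vector of the 7 fragment lengths
#'   (FR1, CDR1, FR2, CDR2, FR3, CDR3, FR4); may be `NULL` for simulated or
#'   externally aligned data, in which case the whole sequence counts as one
#'   segment.
#' @param germlines optional character vector of shared germline segment ids
#'   (NGS grouping mode).
#' @param id alignment identifier.
#' @return object of class `hom_msa` with fields `ids`, `seqs`, `signature`,
#'   `germlines`, `id`.
#' @export
hom_msa <- function(seqs, signature = NULL, germlines = NULL, id = "msa") {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    stop("sequences have unequal lengths: ", paste(len, collapse = ", "))
  if (any(grepl("-", seqs, fixed = TRUE)))
    stop("gap characters are not allowed in a homogeneous MSA")
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), seqs)
  if (any(bad))
    stop("non-standard residues in: ",
         paste(names(seqs)[bad], collapse = ", "))
  if (!is.null(signature)) {
    signature <- as.integer(signature)
    if (length(signature) != 7L)
      stop("signature must give the 7 fragment lengths")
    if (sum(signature) != len)
      stop("signature sums to ", sum(signature),
           " but sequences have ", len, " residues")
  }
  structure(list(ids = names(seqs), seqs = unname(seqs),
                 signature = signature, germlines = germlines, id = id),
            class = "hom_msa")
}

#' @export
print.hom_msa <- function(x, ...) {
  cat("Homogeneous MSA", x$id, ":", length(x$seqs), "sequences x",
      nchar(x$seqs[1L]), "sites\n")
  if (!is.null(x$signature))
    cat("  fragment lengths (FR1,CDR1,FR2,CDR2,FR3,CDR3,FR4):",
        paste(x$signature, collapse = ","), "\n")
  invisible(x)
}

#' Character-matrix view of a homogeneous MSA
#'
#' @param msa a [hom_msa()].
#' @return n_sequences x n_sites character matrix, rownames = sequence ids.
#' @export
msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(msa$seqs, ""))
  rownames(m) <- msa$ids
  m
}

# Integer encoding (1..20 in canonical order), n_taxa x n_sites.
msa_encode <- function(msa) {
  m <- msa_matrix(msa)
  x <- matrix(aa_index(m), nrow = nrow(m),
              dimnames = list(rownames(m), NULL))
  if (anyNA(x)) stop("MSA contains non-standard residues")
  x
}

#' Number of sites in an MSA
#' @param msa a [hom_msa()].
#' @return integer site count.
#' @export
n_sites <- function(msa) nchar(msa$seqs[1L])

#' Empirical amino-acid frequencies of one or more MSAs
#'
#' Counts residues over all sequences of all supplied alignments; this is
#' the "training frequencies" vector used by the recommended frequency
#' policy.
#'
#' @param msas a [hom_msa()] or list of them.
#' @param freq_floor floor applied before renormalization (see
#'   [aa_model()]); counts of rare residues in small repertoires can be
#'   zero, and downstream transforms divide by the frequencies.
#' @return frequency vector of length 20 in canonical order.
#' @export
empirical_frequencies <- function(msas, freq_floor = 1e-6) {
  if (inherits(msas, "hom_msa")) msas <- list(msas)
  counts <- numeric(20L)
  for (m in msas) {
    tab <- table(factor(unlist(strsplit(m$seqs, "")), levels = AA_ALPHABET))
    counts <- counts + as.numeric(tab)
  }
  validate_frequencies(counts / sum(counts), freq_floor = freq_floor)
}
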