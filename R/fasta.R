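#' Read amino-acid sequences from FASTA
#'
#' Thin wrapper over Biostrings that enforces the package's conventions:
#' residues are uppercased, record order is preserved, and duplicate ids are
#' an error.
#'
#' @param path FASTA file.
#' @return named character vector of sequences (names = record ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such FASTA file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- names(set)
  # Record id = first whitespace-delimited token of the header.
  ids <- sub("\\s.*$", "", ids)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA ids: ", paste(dup, collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA (60-column wrap)
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named")
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
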