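#' Quality-filter antibody sequences
#'
#' Drops sequences that cannot enter a homogeneous alignment: stop codons
#' (`*`), ambiguity codes (X, B, Z, J, U, O), any other non-standard
#' character, and (when fragment annotations are supplied) missing — i.e.
#' zero-length — FR or CDR fragments other than FR1/FR4, which may be
#' truncated by the curator.
#'
#' @param seqs named character vector of amino-acid sequences.
#' @param annotations optional annotation table as returned by
#'   [read_annotations()]; used to check fragment completeness.
#' @return list with `kept` (named character vector) and `rejected`
#'   (data.frame with columns `id`, `reason`; reasons are `stop_codon`,
#'   `ambiguity`, `invalid_residue`, `missing_segment`, `unannotated`).
#' @export
quality_filter <- function(seqs, annotations = NULL) {
  ids <- names(seqs)
  reason <- rep(NA_character_, length(seqs))
  up <- toupper(seqs)
  reason[grepl("*", up, fixed = TRUE)] <- "stop_codon"
  amb <- grepl(paste0("[", paste(AA_AMBIGUOUS, collapse = ""), "]"), up)
  reason[is.na(reason) & amb] <- "ambiguity"
  ok <- paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$")
  reason[is.na(reason) & !grepl(ok, up)] <- "invalid_residue"
  if (!is.null(annotations)) {
    row <- match(ids, annotations$id)
    reason[is.na(reason) & is.na(row)] <- "unannotated"
    seg <- as.matrix(annotations[, SEGMENT_NAMES])
    # CDR1..CDR3 and FR2/FR3 must be present; FR1/FR4 may be truncated away.
    core <- c("cdr1", "fr2", "cdr2", "fr3", "cdr3")
    miss <- rowSums(seg[, core, drop = FALSE] == 0L) > 0L
    has <- is.na(reason) & !is.na(row)
    reason[has][miss[row[has]]] <- "missing_segment"
  }
  keep <- is.na(reason)
  list(kept = stats::setNames(up[keep], ids[keep]),
       rejected = data.frame(id = ids[!keep], reason = reason[!keep],
                             stringsAsFactors = FALSE))
}

SEGMENT_NAMES <- c("fr1", "cdr1", "fr2", "cdr2", "fr3", "cdr3", "fr4")

#' Read a fragment-length annotation sidecar (TSV)
#'
#' Expected columns: `id` then the seven fragment lengths
#' `fr1 cdr1 fr2 cdr2 fr3 cdr3 fr4` (residue counts).
#'
#' @param path TSV file with a header line.
#' @return data.frame with `id` and the seven integer length columns.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", SEGMENT_NAMES)
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("annotation file lacks columns: ", paste(missing, collapse = ", "))
  tab[SEGMENT_NAMES] <- lapply(tab[SEGMENT_NAMES], as.integer)
  tab[, need]
}

#' Sort sequences into homogeneous gapless alignments
#'
#' Groups sequences by their 7-fragment length signature (and, when present,
#' their assigned germline set); each group with at least `min_size` members
#' becomes one gapless alignment, positionally aligned by construction.
#' Groups are ordered by descending size, then lexicographically by
#' signature, for deterministic output.
#'
#' @param seqs named character vector of quality-filtered sequences.
#' @param annotations annotation table ([read_annotations()]); every sequence
#'   must be annotated and its fragment lengths must sum to its residue
#'   count.
#' @param germline_hits optional data.frame (`id`, `v`, `d`, `j`) from
#'   [assign_germlines()]; if given, the germline triple joins the grouping
#'   key (NGS mode).
#' @param min_size minimum sequences per alignment (default 3).
#' @return list of [hom_msa()] objects.
#' @export
group_homogeneous <- function(seqs, annotations, germline_hits = NULL,
                              min_size = 3L) {
  ids <- names(seqs)
  row <- match(ids, annotations$id)
  if (anyNA(row))
    stop("unannotated sequences: ",
         paste(ids[is.na(row)], collapse = ", "))
  seg <- as.matrix(annotations[row, SEGMENT_NAMES, drop = FALSE])
  bad <- rowSums(seg) != nchar(seqs)
  if (any(bad))
    stop("fragment lengths do not sum to sequence length for: ",
         paste(ids[bad], collapse = ", "))
  key <- apply(seg, 1L, paste, collapse = ",")
  germ <- NULL
  if (!is.null(germline_hits)) {
    g <- germline_hits[match(ids, germline_hits$id), c("v", "d", "j")]
    germ <- apply(as.matrix(g), 1L, function(r)
      paste(ifelse(is.na(r), ".", r), collapse = "|"))
    key <- paste(key, germ, sep = ";")
  }
  groups <- split(seq_along(ids), key)
  groups <- groups[lengths(groups) >= min_size]
  ord <- order(-lengths(groups), names(groups))
  groups <- groups[ord]
  out <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    idx <- groups[[i]]
    out[[i]] <- hom_msa(seqs[idx],
                        signature = seg[idx[1L], ],
                        germlines = if (is.null(germ)) NULL else
                          strsplit(germ[idx[1L]], "|", fixed = TRUE)[[1L]],
                        id = sprintf("msa%03d", i))
  }
  out
}

#' Enforce NGS alignment-size limits
#'
#' Alignments larger than `max_size` are split into near-equal contiguous
#' chunks (input order preserved); alignments smaller than `min_size` are
#' dropped with a message.
#'
#' @param msas list of [hom_msa()] objects.
#' @param max_size maximum sequences per alignment (default 850).
#' @param min_size minimum sequences per alignment (default 175).
#' @return list of [hom_msa()] objects, each with
#'   `min_size <= n <= max_size`.
#' @export
split_large_groups <- function(msas, max_size = 850L, min_size = 175L) {
  out <- list()
  for (m in msas) {
    n <- length(m$seqs)
    if (n < min_size) {
      message("dropping ", m$id, ": ", n, " sequences < ", min_size)
      next
    }
    n_chunks <- ceiling(n / max_size)
    sizes <- rep(n %/% n_chunks, n_chunks)
    sizes[seq_len(n %% n_chunks)] <- sizes[seq_len(n %% n_chunks)] + 1L
    start <- cumsum(c(1L, sizes[-n_chunks]))
    for (ci in seq_len(n_chunks)) {
      idx <- seq(start[ci], length.out = sizes[ci])
      part <- stats::setNames(m$seqs[idx], m$ids[idx])
      out[[length(out) + 1L]] <-
        hom_msa(part, signature = m$signature, germlines = m$germlines,
                id = if (n_chunks == 1L) m$id else
                  paste0(m$id, letters[ci]))
    }
  }
  out
}

#' Germline segment library
#'
#' Reference V, D and J gene-segment protein sequences plus the relative
#' position window in which each segment class is expected within a
#' variable-region sequence (local alignment is restricted to the window).
#'
#' @param v,d,j named character vectors of segment sequences; `d` may be
#'   `NULL` (light chains).
#' @param windows list of `c(start_frac, end_frac)` per class; defaults:
#'   V in the first 75% of the query, J in the last 40%, D between them.
#' @return object of class `germline_library`.
#' @export
germline_library <- function(v, d = NULL, j,
                             windows = list(v = c(0, 0.75),
                                            d = NULL,
                                            j = c(0.60, 1))) {
  if (length(v) == 0L || length(j) == 0L)
    stop("V and J germline sets must be non-empty")
  structure(list(v = v, d = d, j = j, windows = windows),
            class = "germline_library")
}

# Best local alignment of each library member against a window of the query.
.best_hit <- function(query, library, window, scoring) {
  if (nchar(query) == 0L || length(library) == 0L)
    return(list(id = NA_character_, score = NA_real_, range = c(NA, NA)))
  scores <- vapply(library, function(ref) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(query), Biostrings::AAString(ref),
      type = "local",
      substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
      scoreOnly = TRUE)
    as.numeric(al)
  }, numeric(1L))
  best <- max(scores)
  if (best <= 0)
    return(list(id = NA_character_, score = best, range = c(NA, NA)))
  hits <- which(scores == best)
  if (length(hits) > 1L)
    warning("germline score tie between ",
            paste(names(library)[hits], collapse = ", "),
            "; keeping first in library order", call. = FALSE)
  pick <- hits[1L]
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(library[[pick]]),
    type = "local", substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  rng <- c(Biostrings::start(Biostrings::pattern(al)),
           Biostrings::end(Biostrings::pattern(al))) + window[1L] - 1L
  list(id = names(library)[pick], score = best, range = rng)
}

#' Assign germline V, (D), J segments by local alignment
#'
#' For each segment class the library member with the highest local
#' (Smith-Waterman) alignment score against the query, restricted to the
#' class's expected position window, is selected.  Ties are broken by
#' library order (first wins) with a warning.  Default scoring is BLOSUM62
#' with gap open 11 / extend 1; a custom substitution matrix may be
#' supplied.
#'
#' @param seq amino-acid query sequence (one antibody variable region).
#' @param library a [germline_library()].
#' @param scoring list with `matrix` (a substitution matrix name or matrix
#'   accepted by Biostrings), `gap_open`, `gap_extend`.
#' @return list with elements `v`, `d`, `j` (each `list(id, score, range)`,
#'   id `NA` when unassigned).
#' @export
assign_germlines <- function(seq, library,
                             scoring = list(matrix = "BLOSUM62",
                                            gap_open = 11, gap_extend = 1)) {
  stopifnot(inherits(library, "germline_library"))
  n <- nchar(seq)
  win <- function(fr) substr(seq, max(1L, ceiling(fr[1L] * n)),
                             floor(fr[2L] * n))
  wv <- library$windows$v
  wj <- library$windows$j
  v_hit <- .best_hit(win(wv), library$v, c(max(1L, ceiling(wv[1L] * n)), 0),
                     scoring)
  j_hit <- .best_hit(win(wj), library$j, c(max(1L, ceiling(wj[1L] * n)), 0),
                     scoring)
  d_hit <- list(id = NA_character_, score = NA_real_, range = c(NA, NA))
  if (!is.null(library$d)) {
    # D lies between the end of the V hit and the start of the J hit.
    d_from <- if (!is.na(v_hit$range[2L])) v_hit$range[2L] + 1L
              else floor(0.4 * n)
    d_to <- if (!is.na(j_hit$range[1L])) j_hit$range[1L] - 1L else n
    if (d_from <= d_to)
      d_hit <- .best_hit(substr(seq, d_from, d_to), library$d,
                         c(d_from, 0), scoring)
  }
  list(v = v_hit, d = d_hit, j = j_hit)
}

#' Assign germlines for a whole sequence set
#'
#' @param seqs named character vector.
#' @inheritParams assign_germlines
#' @return data.frame with columns `id`, `v`, `d`, `j`, `v_score`,
#'   `d_score`, `j_score`.
#' @export
assign_germlines_all <- function(seqs, library,
                                 scoring = list(matrix = "BLOSUM62",
                                                gap_open = 11,
                                                gap_extend = 1)) {
  rows <- lapply(names(seqs), function(id) {
    h <- assign_germlines(seqs[[id]], library, scoring)
    data.frame(id = id, v = h$v$id, d = h$d$id, j = h$j$id,
               v_score = h$v$score, d_score = h$d$score,
               j_score = h$j$score, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
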