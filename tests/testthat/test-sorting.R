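make_fa <- function(seqs) {
  f <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  write_fasta(seqs, f)
  f
}

test_that("FASTA round trip preserves order, ids and residues", {
  seqs <- c(ab1 = "MKVLT", ab2 = "GGSTY")
  f <- make_fa(seqs)
  expect_identical(read_fasta(f), seqs)
  # lowercase residues are uppercased on read
  writeLines(c(">x", "mkvlt"), f)
  expect_identical(read_fasta(f), c(x = "MKVLT"))
  writeLines(c(">a", "MK", ">a", "GG"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(character(), f)
  expect_error(read_fasta(f), "empty")
})

test_that("long sequences wrap at 60 columns on write", {
  seqs <- c(long = paste(rep("ACDEFGHIKL", 15), collapse = ""))
  f <- make_fa(seqs)
  lines <- readLines(f)
  expect_true(all(nchar(lines[-1]) <= 60))
  expect_identical(read_fasta(f), seqs)
})

test_that("quality filter rejects with reason codes and keeps clean input", {
  seqs <- c(ok1 = "MKVLT", stop1 = "MK*LT", amb1 = "MKXLT",
            ok2 = "GGSTY", bad = "MK1LT", ok3 = "AAAAA",
            ok4 = "CCCCC", ok5 = "DDDDD")
  qf <- quality_filter(seqs)
  expect_setequal(names(qf$kept), c("ok1", "ok2", "ok3", "ok4", "ok5"))
  expect_equal(qf$rejected$reason[qf$rejected$id == "stop1"], "stop_codon")
  expect_equal(qf$rejected$reason[qf$rejected$id == "amb1"], "ambiguity")
  expect_equal(qf$rejected$reason[qf$rejected$id == "bad"],
               "invalid_residue")
})

test_that("quality filter flags missing core fragments when annotated", {
  ann <- data.frame(id = c("a", "b"),
                    fr1 = c(2L, 2L), cdr1 = c(1L, 0L), fr2 = c(2L, 3L),
                    cdr2 = c(1L, 1L), fr3 = c(2L, 2L), cdr3 = c(1L, 1L),
                    fr4 = c(1L, 1L))
  seqs <- c(a = "MKVLTAAGGC", b = "MKVLTAAGGC")
  qf <- quality_filter(seqs, ann)
  expect_identical(names(qf$kept), "a")
  expect_equal(qf$rejected$reason, "missing_segment")
})

sig_ann <- function(ids, sigs) {
  cbind(data.frame(id = ids),
        as.data.frame(do.call(rbind, sigs)) |>
          stats::setNames(c("fr1", "cdr1", "fr2", "cdr2", "fr3", "cdr3",
                            "fr4")))
}

test_that("homogeneous grouping applies the minimum-size rule and
           partitions the retained input", {
  sigA <- c(2L, 1L, 2L, 1L, 2L, 1L, 1L)   # 10 residues
  sigB <- c(3L, 1L, 2L, 1L, 2L, 1L, 1L)   # 11 residues
  seqs <- c(s1 = "AAAAAAAAAA", s2 = "CCCCCCCCCC", s3 = "DDDDDDDDDD",
            s4 = "EEEEEEEEEEE", s5 = "FFFFFFFFFFF")
  ann <- sig_ann(names(seqs), list(sigA, sigA, sigA, sigB, sigB))
  msas <- group_homogeneous(seqs, ann)
  expect_length(msas, 1L)                   # the B pair is below min size
  expect_setequal(msas[[1]]$ids, c("s1", "s2", "s3"))
  expect_identical(msas[[1]]$signature, sigA)
  # all identical signatures: one MSA containing everything
  ann_all <- sig_ann(names(seqs)[1:3], list(sigA, sigA, sigA))
  expect_length(group_homogeneous(seqs[1:3], ann_all), 1L)
  expect_error(group_homogeneous(seqs, sig_ann(names(seqs)[1:4],
                                               list(sigA, sigA, sigA, sigB))),
               "unannotated.*s5")
})

test_that("a synthetic 40-sequence set over 6 signatures groups losslessly", {
  sizes <- c(10L, 9L, 8L, 7L, 3L, 3L)
  sigs <- lapply(seq_along(sizes), function(k) c(2L + k, 1L, 2L, 1L, 2L, 1L, 1L))
  seqs <- character(); ann_rows <- list()
  set.seed(1)
  for (k in seq_along(sizes)) for (i in seq_len(sizes[k])) {
    id <- sprintf("g%d_%02d", k, i)
    seqs[id] <- paste(sample(AA_ALPHABET, sum(sigs[[k]]), replace = TRUE),
                      collapse = "")
    ann_rows[[length(ann_rows) + 1L]] <- c(id, sigs[[k]])
  }
  ann <- sig_ann(vapply(ann_rows, `[[`, "", 1L),
                 lapply(ann_rows, function(r) as.integer(r[-1L])))
  msas <- group_homogeneous(seqs, ann)
  expect_length(msas, 6L)
  expect_equal(sum(lengths(lapply(msas, `[[`, "ids"))), 40L)
  expect_equal(vapply(msas, function(m) length(m$ids), 0L),
               sort(sizes, decreasing = TRUE))
  # every kept sequence appears in exactly one MSA
  all_ids <- unlist(lapply(msas, `[[`, "ids"))
  expect_setequal(all_ids, names(seqs))
  expect_false(anyDuplicated(all_ids) > 0)
  # determinism: re-running yields identical structures
  expect_identical(msas, group_homogeneous(seqs, ann))
})

test_that("oversize groups split into near-equal chunks and undersized
           groups are dropped", {
  mk <- function(n) {
    seqs <- stats::setNames(rep("AAAAAAAAAA", n), sprintf("q%04d", seq_len(n)))
    hom_msa(seqs, signature = c(2L, 1L, 2L, 1L, 2L, 1L, 1L), id = "big")
  }
  out <- split_large_groups(list(mk(1700L)))
  expect_equal(vapply(out, function(m) length(m$ids), 0L), c(850L, 850L))
  expect_message(out2 <- split_large_groups(list(mk(174L))), "dropping")
  expect_length(out2, 0L)
  out3 <- split_large_groups(list(mk(900L)))
  expect_equal(vapply(out3, function(m) length(m$ids), 0L), c(450L, 450L))
  # order is preserved across the split
  expect_identical(unlist(lapply(out3, `[[`, "ids")), mk(900L)$ids)
})

test_that("germline assignment picks exact substrings and honors the
           first-wins tie rule", {
  v_lib <- c(V1 = "MKVLTQSPG", V2 = "MKWWWQSPG")
  j_lib <- c(J1 = "WGQGTLV", J2 = "FGQGTKV")
  lib <- germline_library(v = v_lib, j = j_lib)
  q <- paste0("MKVLTQSPG", "AARGY", "WGQGTLV")
  hit <- assign_germlines(q, lib)
  expect_equal(hit$v$id, "V1")
  expect_equal(hit$j$id, "J1")
  # duplicate library entries tie; first in order wins with a warning
  lib2 <- germline_library(v = c(Va = "MKVLTQSPG", Vb = "MKVLTQSPG"),
                           j = j_lib)
  expect_warning(hit2 <- assign_germlines(q, lib2), "tie")
  expect_equal(hit2$v$id, "Va")
})

test_that("local alignment scores equal a Smith-Waterman oracle", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  v_lib <- c(V1 = "MKVLTQSPGSS", V2 = "MKVATQSPGSS")
  lib <- germline_library(v = v_lib, j = c(J1 = "WGQGT"),
                          windows = list(v = c(0, 1), d = NULL,
                                         j = c(0, 1)))
  queries <- c("MKVLTQSPGSS",            # exact
               "MKVCTQSPGSS",            # one mismatch
               "MKVLTSPGSS")             # one deletion
  for (q in queries) {
    hit <- assign_germlines(q, lib)
    oracle <- max(sw_score(q, v_lib[["V1"]], BLOSUM62),
                  sw_score(q, v_lib[["V2"]], BLOSUM62))
    expect_equal(hit$v$score, oracle)
  }
})
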