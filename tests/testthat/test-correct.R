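test_that("self-chimera rules: full-length repeat splits, tandem discards", {
  set.seed(401)
  B <- rseq(500)
  # rule (i): footprint 1000/1000 >= 60% -> split at the downstream copy
  call <- classify_self_chimera(contig_set("bb", paste0(B, B)))
  expect_identical(call$action, "split")
  expect_identical(call$rule, "longest-match-60")
  expect_identical(call$breakpoint, 500L)

  # no matches -> keep
  expect_identical(classify_self_chimera(contig_set("r", rseq(1000)))$action,
                   "keep")

  # 50-nt unit x 20: repetition of a short block -> discard
  call2 <- classify_self_chimera(contig_set("t", strrep(rseq(50), 20)))
  expect_identical(call2$action, "discard")
  expect_identical(call2$rule, "repeat-block-80")

  # partial suffix duplication (60% footprint construction)
  t0 <- rseq(800)
  sc <- paste0(t0, substr(t0, 401, 800))
  call3 <- classify_self_chimera(contig_set("s", sc))
  expect_identical(call3$action, "split")
  # chance end-extension can nibble a few bases around the junction
  expect_lte(abs(call3$breakpoint - 800L), 10L)
})

test_that("chimera calls split, filter fragments and keep contigs intact", {
  set.seed(402)
  cs <- contig_set("x", rseq(1000))
  call <- tibble::tibble(contig_id = "x", rule = "longest-match-60",
                         action = "split", breakpoint = 500L)
  out <- apply_chimera_calls(cs, call)
  expect_identical(nchar(out$seq), c(500L, 500L))
  expect_identical(out$id, c("x.1", "x.2"))
  expect_identical(out$parent, c("x", "x"))

  call150 <- dplyr::mutate(call, breakpoint = 150L)
  out2 <- apply_chimera_calls(cs, call150, min_fragment_len = 200L)
  expect_identical(nchar(out2$seq), 850L)

  keepcall <- tibble::tibble(contig_id = "x", rule = "none",
                             action = "keep", breakpoint = NA_integer_)
  expect_identical(apply_chimera_calls(cs, keepcall)$seq, cs$seq)

  badcall <- dplyr::mutate(call, breakpoint = 1000L)
  expect_error(apply_chimera_calls(cs, badcall), "breakpoint")
})

test_that("majority correction needs depth and a strict majority", {
  cs <- contig_set("c", strrep("A", 20))
  mk_aln <- function(n, base, pos = 10) {
    dplyr::bind_rows(purrr::map(seq_len(n), function(i)
      aln_row(paste0("r", i), "c", pos, "1M", base)))
  }
  # depth 9 below min_depth: unchanged
  r <- majority_correct(cs, build_pileup(cs, mk_aln(9, "G")))
  expect_identical(nrow(r$edits), 0L)
  expect_identical(r$contig$seq, cs$seq)

  # depth 12, 9xG vs consensus A -> substitution
  aln <- dplyr::bind_rows(mk_aln(9, "G"), mk_aln(3, "A"))
  r2 <- majority_correct(cs, build_pileup(cs, aln))
  expect_identical(r2$edits$kind, "substitution")
  expect_identical(r2$edits$position, 10L)
  expect_identical(r2$edits$from_allele, "A")
  expect_identical(r2$edits$to_allele, "G")
  expect_identical(r2$edits$support, 9L)
  expect_identical(substr(r2$contig$seq, 11, 11), "G")

  # depth 13, 11 reads show a 1-nt deletion -> base removed
  del <- dplyr::bind_rows(purrr::map(1:11, function(i)
    aln_row(paste0("d", i), "c", 9, "1M1D1M", "AA")))
  aln3 <- dplyr::bind_rows(del, mk_aln(2, "A"))
  r3 <- majority_correct(cs, build_pileup(cs, aln3))
  expect_identical(r3$edits$kind, "deletion")
  expect_identical(nchar(r3$contig$seq), 19L)

  # 6 vs 6 tie keeps the consensus
  aln4 <- dplyr::bind_rows(mk_aln(6, "G"), mk_aln(6, "A"))
  r4 <- majority_correct(cs, build_pileup(cs, aln4))
  expect_identical(nrow(r4$edits), 0L)

  # N never wins even with a majority
  aln5 <- dplyr::bind_rows(mk_aln(9, "N"), mk_aln(3, "A"))
  r5 <- majority_correct(cs, build_pileup(cs, aln5))
  expect_identical(nrow(r5$edits), 0L)
})

test_that("majority insertions need to outnumber gap-free junction reads", {
  cs <- contig_set("c", strrep("A", 30))
  ins <- dplyr::bind_rows(purrr::map(1:8, function(i)
    aln_row(paste0("i", i), "c", 5, "5M1I5M", "AAAAAGAAAAA")))
  plain <- dplyr::bind_rows(purrr::map(1:3, function(i)
    aln_row(paste0("p", i), "c", 5, "10M", "AAAAAAAAAA")))
  r <- majority_correct(cs, build_pileup(cs, dplyr::bind_rows(ins, plain)))
  expect_identical(r$edits$kind, "insertion")
  expect_identical(r$edits$to_allele, "G")
  expect_identical(nchar(r$contig$seq), 31L)

  # 5 with insertion vs 6 without: no strict majority
  plain6 <- dplyr::bind_rows(purrr::map(1:6, function(i)
    aln_row(paste0("q", i), "c", 5, "10M", "AAAAAAAAAA")))
  r2 <- majority_correct(cs, build_pileup(cs, dplyr::bind_rows(ins[1:5, ],
                                                               plain6)))
  expect_identical(nrow(r2$edits), 0L)
})

test_that("two-pass correction restores planted errors then converges", {
  set.seed(403)
  tx <- gen_transcriptome(n = 3, len_range = c(600, 900),
                          multi_isoform_fraction = 0, seed = 43)
  reads <- sim_reads(tx$transcripts, depth_mean = 25, error_rate = 0.01,
                     expression_dispersion = 0, seed = 43)
  clean <- contig_set(tx$transcripts$id, tx$transcripts$seq)

  # error-free consensus: zero edits in both passes
  res0 <- two_pass_correct(clean, reads)
  expect_identical(nrow(res0$pass1_edits), 0L)
  expect_identical(nrow(res0$pass2_edits), 0L)
  expect_identical(res0$contigs$seq, clean$seq)

  # planted substitution + insertion: fixed, and pass 2 is quiet
  chars <- strsplit(clean$seq[1], "")[[1]]
  chars[250] <- setdiff(BASES, chars[250])[1]
  chars <- append(chars, "G", after = 400)
  bad <- clean
  bad$seq[1] <- paste(chars, collapse = "")
  res <- two_pass_correct(bad, reads)
  expect_identical(res$contigs$seq[1], clean$seq[1])
  expect_gte(nrow(res$pass1_edits), 2L)
  expect_identical(nrow(res$pass2_edits), 0L)
})

test_that("TSA cleaning trims tails and Ns, splits on N runs, keeps clean input", {
  set.seed(404)
  body <- paste0(rseq(799), "G")
  out <- tsa_clean(contig_set("a", paste0(body, strrep("A", 25))))
  expect_identical(out$seq, body)

  clean <- contig_set("b", paste0("G", rseq(498), "C"))
  expect_identical(tsa_clean(clean)$seq, clean$seq)

  polyt <- paste0(strrep("T", 20), "G", strrep("ACGC", 100))
  expect_identical(nchar(tsa_clean(contig_set("c", polyt))$seq), 401L)

  withN <- paste0(rseq(300), strrep("N", 30), rseq(170))
  out2 <- tsa_clean(contig_set("d", withN))
  expect_identical(nrow(out2), 1L)
  expect_identical(nchar(out2$seq), 300L)

  # terminal N trimming
  expect_identical(
    nchar(tsa_clean(contig_set("e", paste0("NNNN", "G", rseq(300), "C",
                                           "NNN")))$seq), 302L)

  # property: no qualifying tail or long N run survives
  for (i in 1:10) {
    s <- paste0(strrep("T", sample(0:30, 1)), "G", rseq(400), "C",
                strrep("N", sample(0:20, 1)), "C",
                strrep("A", sample(0:30, 1)))
    res <- tsa_clean_set(contig_set("p", s))
    for (sq in res$seq) {
      expect_false(grepl("N{14,}", sq))
      expect_false(grepl("A{10,}$", sq))
      expect_false(grepl("^T{10,}", sq))
    }
  }
})
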