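test_that("FASTA write/read round-trips a contig set and uppercases input", {
  set.seed(101)
  cs <- contig_set(c("c1", "c2"), c(rseq(120), rseq(80)))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(cs, fa)
  back <- read_fasta(fa)
  expect_identical(back$id, cs$id)
  expect_identical(back$seq, cs$seq)

  writeLines(c(">soft", "acgtACGTacgt"), fa)
  expect_identical(read_fasta(fa)$seq, "ACGTACGTACGT")

  writeLines(character(0), fa)
  expect_identical(nrow(read_fasta(fa)), 0L)

  writeLines(c(">dup", "ACGT", ">dup", "ACGT"), fa)
  expect_error(read_fasta(fa), "duplicate")
})

test_that("Oases headers parse into locus keys; foreign ids are lenient", {
  p <- parse_oases_header(c(
    "Locus_7_Transcript_2/5_Confidence_0.600_Length_1342",
    "contig_001",
    "Locus_7_Transcript_1/5_Confidence_0.800_Length_900"))
  expect_identical(p$locus, c("Locus_7", NA, "Locus_7"))
  expect_identical(p$declared_length, c(1342L, NA, 900L))
  expect_identical(p$locus[1], p$locus[3])

  cs <- contig_set(c("Locus_1_Transcript_1/2_Confidence_1.000_Length_100",
                     "plain"), c(strrep("A", 10), strrep("C", 10)))
  ann <- annotate_loci(cs)
  expect_identical(ann$locus, c("Locus_1", "plain"))
})

test_that("SAM reading converts to 0-based starts and keeps unmapped records", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:ctg1\tLN:60",
    paste("r1", 0, "ctg1", 1, 60, "10M", "*", 0, 0,
          "ACGTACGTAC", "IIIIIIIIII", sep = "\t"),
    paste("r2", 4, "*", 0, 0, "*", "*", 0, 0,
          "ACGTACGTAC", "IIIIIIIIII", sep = "\t"),
    paste("r3", 0, "ctg1", 11, 60, "10M2D5M", "*", 0, 0,
          "ACGTACGTACGTACG", "IIIIIIIIIIIIIII", sep = "\t")),
    sam)
  a <- read_sam(sam)
  expect_identical(a$start[a$read_id == "r1"], 0L)
  expect_false(a$mapped[a$read_id == "r2"])
  # CIGAR 10M2D5M at POS=11: reference span [10, 27)
  r3 <- a[a$read_id == "r3", ]
  expect_identical(r3$start, 10L)
  expect_identical(r3$start + contigpolish:::cigar_ref_length(r3$cigar), 27L)
})

test_that("SAM round-trip preserves POS and CIGAR", {
  set.seed(102)
  cs <- contig_set("ctg1", rseq(300))
  reads <- tibble::tibble(
    read_id = c("a", "b"),
    seq = c(substr(cs$seq, 51, 150), substr(cs$seq, 201, 300)))
  aln <- map_reads_simple(reads, cs)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, cs, sam)
  back <- read_sam(sam)
  expect_identical(back$start, aln$start)
  expect_identical(back$cigar, aln$cigar)
})

test_that("pileup counts bases, deletions and insertions per position", {
  cs <- contig_set("c", "AAAAAAAAAA")
  expect_identical(pileup_depth(build_pileup(cs, aln_row(character(0),
    character(0), integer(0), character(0), character(0)))),
    rep(0L, 10))

  # 3 reads cover position 4 (0-based): bases G, G, A
  aln <- dplyr::bind_rows(
    aln_row("r1", "c", 2, "5M", "AAGAA"),
    aln_row("r2", "c", 3, "3M", "AGA"),
    aln_row("r3", "c", 4, "2M", "AA"))
  p <- build_pileup(cs, aln)
  expect_identical(unname(p$bases["G", 5]), 2L)
  expect_identical(unname(p$bases["A", 5]), 1L)
  expect_identical(pileup_depth(p)[5], 3L)

  # 1-base deletion at position 4 contributes to depth there
  aln2 <- dplyr::bind_rows(aln, aln_row("r4", "c", 2, "2M1D3M", "AAAAA"))
  p2 <- build_pileup(cs, aln2)
  expect_identical(p2$dels$pos, 4L)
  expect_identical(p2$dels$len, 1L)
  expect_identical(p2$dels$count, 1L)
  expect_identical(pileup_depth(p2)[5], 4L)

  # soft clips contribute nothing
  p3 <- build_pileup(cs, aln_row("r5", "c", 0, "3S4M", "GGGAAAA"))
  expect_identical(sum(p3$bases), 4L)
  # overrun is an error
  expect_error(build_pileup(cs, aln_row("r6", "c", 8, "5M", "AAAAA")),
               "overrun")
})

test_that("pileup depth equals per-position read span coverage", {
  set.seed(103)
  cs <- contig_set("c", rseq(400))
  starts <- sample(0:300, 40, replace = TRUE)
  aln <- dplyr::bind_rows(purrr::map(seq_along(starts), function(i) {
    aln_row(paste0("r", i), "c", starts[i], "100M",
            substr(cs$seq, starts[i] + 1, starts[i] + 100))
  }))
  p <- build_pileup(cs, aln)
  expected <- vapply(seq_len(400), function(pos)
    sum(starts < pos & pos <= starts + 100), integer(1))
  expect_identical(pileup_depth(p), expected)
})
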