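test_that("the transcriptome generator is seeded, ORF-complete and exon-true", {
  a <- gen_transcriptome(n = 30, seed = 9)
  b <- gen_transcriptome(n = 30, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a$transcripts$seq,
                         gen_transcriptome(n = 30, seed = 10)$transcripts$seq))

  expect_identical(nrow(a$transcripts), 30L)
  # orf_fraction 1: every gene's primary transcript has a complete ORF
  prim <- a$transcripts[a$transcripts$has_orf, ]
  expect_gt(nrow(prim), 0L)
  for (s in prim$seq) {
    o <- find_orfs(s, 200)
    expect_true(any(o$complete5 & o$complete3 & o$nt_len >= 200))
  }
  # exons reassemble their transcript and ranks are consistent
  for (tid in a$transcripts$id) {
    ex <- a$exons[a$exons$transcript_id == tid, ]
    expect_identical(paste(ex$seq[order(ex$exon_rank)], collapse = ""),
                     a$transcripts$seq[a$transcripts$id == tid])
    expect_identical(ex$end - ex$start, nchar(ex$seq))
  }
  # multi_isoform_fraction 0: one transcript per gene
  solo <- gen_transcriptome(n = 20, multi_isoform_fraction = 0, seed = 9)
  expect_identical(anyDuplicated(solo$gene_map$gene_id), 0L)

  expect_error(gen_transcriptome(n = 5, len_range = c(220, 250), seed = 1),
               "ORF")
})

test_that("read simulation is exact at zero error and scales with depth", {
  tx <- gen_transcriptome(n = 10, len_range = c(600, 1200), seed = 21)
  r0 <- sim_reads(tx$transcripts, depth_mean = 10, error_rate = 0,
                  expression_dispersion = 0, seed = 21)
  expect_identical(r0, sim_reads(tx$transcripts, depth_mean = 10,
                                 error_rate = 0, expression_dispersion = 0,
                                 seed = 21))
  # every errorless read is an exact substring of its transcript
  for (i in sample(nrow(r0), 50)) {
    t <- tx$transcripts$seq[tx$transcripts$id == r0$truth_transcript[i]]
    probe <- if (r0$mate[i] == 2L) revcomp(r0$seq[i]) else r0$seq[i]
    expect_true(grepl(probe, t, fixed = TRUE))
  }
  # mates sit on opposite strands within the fragment
  m1 <- r0[r0$mate == 1L, ]; m2 <- r0[r0$mate == 2L, ]
  m2 <- m2[match(m1$pair_id, m2$pair_id), ]
  expect_true(all(m2$truth_pos >= m1$truth_pos))
  expect_true(all(m2$truth_pos - m1$truth_pos <= 400))

  # fragment counts near expectation: total bases / (2 * read_len) per
  # transcript at dispersion 0, within 3 sigma of Poisson
  lens <- nchar(tx$transcripts$seq)
  expected <- 10 * lens / 200
  got <- table(factor(m1$truth_transcript, levels = tx$transcripts$id))
  expect_true(all(abs(as.numeric(got) - expected) <=
                    3 * sqrt(expected) + 1))

  # substitution errors appear at roughly the requested rate
  r1 <- sim_reads(tx$transcripts, depth_mean = 10, error_rate = 0.02,
                  expression_dispersion = 0, seed = 21)
  n_check <- min(nrow(r1), 300)
  mm <- vapply(seq_len(n_check), function(i) {
    t <- tx$transcripts$seq[tx$transcripts$id == r1$truth_transcript[i]]
    probe <- if (r1$mate[i] == 2L) revcomp(r1$seq[i]) else r1$seq[i]
    truth <- substr(t, r1$truth_pos[i] + 1, r1$truth_pos[i] + nchar(probe))
    contigpolish:::hamming(probe, truth)
  }, numeric(1))
  rate <- sum(mm) / (n_check * 100)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.03)
})

test_that("defect injection is exact, truthful and detectable by design", {
  tx <- gen_transcriptome(n = 60, seed = 33)
  # all rates zero: contigs are the transcripts, all truth records none
  none <- corrupt_assembly(tx$transcripts, rates = c(duplicate = 0), seed = 3)
  expect_identical(none$contigs$seq, tx$transcripts$seq)
  expect_true(all(none$truth$defect == "none"))

  corr <- corrupt_assembly(tx$transcripts, seed = 33)
  expect_identical(corrupt_assembly(tx$transcripts, seed = 33)$truth,
                   corr$truth)
  # one truth record per contig
  expect_identical(sort(corr$truth$contig_id), sort(corr$contigs$id))

  # seeded counts: 6 per 10% class on 60 transcripts (chimera pairs may
  # shrink by one for parity)
  tab <- table(corr$truth$defect)
  expect_identical(as.integer(tab[["duplicate"]]), 6L)
  expect_identical(as.integer(tab[["self_chimera"]]), 6L)

  # every injected self-chimera trips rule (i)
  sc <- corr$truth$contig_id[corr$truth$defect == "self_chimera"]
  for (id in sc) {
    call <- classify_self_chimera(corr$contigs[corr$contigs$id == id, ])
    expect_identical(call$action, "split")
    expect_identical(call$rule, "longest-match-60")
  }

  # multi-transcript chimeras carry two complete ORFs and split apart
  mtc <- corr$truth[corr$truth$defect == "multi_transcript_chimera", ]
  for (i in seq_len(nrow(mtc))) {
    ct <- corr$contigs[corr$contigs$id == mtc$contig_id[i], ]
    pieces <- split_multi_orf(ct)
    expect_identical(nrow(pieces), 2L)
    parents <- strsplit(mtc$parent_transcripts[i], ",")[[1]]
    # each piece links back to one parent with high coverage
    for (p in parents) {
      pt <- tx$transcripts$seq[tx$transcripts$id == p]
      best <- purrr::map_dbl(pieces$seq, function(s) {
        hit <- containment(substr(pt, 1, min(nchar(pt), nchar(s))), s,
                           min_identity = 0.9, min_short_cov = 0.5)
        if (is.null(hit)) 0 else hit$short_coverage
      })
      expect_gt(max(best), 0.5)
    }
  }

  # polyA truth records really end in A-tails
  pa <- corr$truth[corr$truth$defect == "polya_tail", ]
  for (id in pa$contig_id) {
    expect_match(corr$contigs$seq[corr$contigs$id == id], "A{15,}$")
  }

  expect_error(corrupt_assembly(tx$transcripts,
                                rates = c(duplicate = 0.7, truncation = 0.7),
                                seed = 1), "at most 1")
})
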