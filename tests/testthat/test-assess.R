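test_that("N50/L50 match hand computation and the cumulative oracle", {
  m <- contig_metrics(c(6L, 5L, 4L, 3L, 2L))
  expect_identical(m$n50_nt, 5L)
  expect_identical(m$l50_count, 2L)
  expect_identical(m$sum_nt, 20)
  expect_identical(m$median_len_nt, 4L)

  one <- contig_metrics(c(123L))
  expect_identical(one$n50_nt, 123L)
  expect_identical(one$l50_count, 1L)

  for (n in c(4L, 7L)) {
    eq <- contig_metrics(rep(50L, n))
    expect_identical(eq$n50_nt, 50L)
    expect_identical(eq$l50_count, as.integer(ceiling(n / 2)))
  }

  set.seed(701)
  for (trial in 1:25) {
    lens <- sample(100:5000, sample(1:200, 1), replace = TRUE)
    m <- contig_metrics(lens)
    o <- oracle_n50(lens)
    expect_identical(m$n50_nt, o$n50)
    expect_identical(m$l50_count, o$l50)
    expect_true(m$n50_nt %in% lens)
    expect_lte(m$l50_count, m$n_contigs)
  }
  expect_error(contig_metrics(integer(0)), "non-empty")
})

test_that("mapping rates count mapped and properly paired reads", {
  aln <- tibble::tibble(
    read_id = paste0("r", 1:10), contig_id = "c", start = 0L, cigar = "10M",
    strand = "+", mapped = c(rep(TRUE, 8), FALSE, FALSE), paired = TRUE,
    proper_pair = c(rep(TRUE, 6), rep(FALSE, 4)), first_in_pair = TRUE,
    seq = strrep("A", 10))
  mr <- mapping_rates(aln)
  expect_equal(mr$pct_mapped, 80)
  expect_equal(mr$pct_properly_paired, 60)

  none <- dplyr::mutate(aln, mapped = FALSE, proper_pair = FALSE)
  expect_equal(mapping_rates(none)$pct_mapped, 0)

  se <- dplyr::mutate(aln, paired = FALSE, proper_pair = FALSE)
  expect_true(is.na(mapping_rates(se)$pct_properly_paired))
})

test_that("protein reconstruction applies strict 80/80 bounds", {
  hits <- tibble::tibble(
    protein_id = c("p1", "p2", "p3"), contig_id = c("c1", "c1", "c2"),
    identity = c(0.95, 0.80, 0.85), protein_coverage = c(0.95, 0.95, 0.79),
    score = c(10, 9, 8))
  pr <- protein_reconstruction(hits, n_proteins = 3, n_contigs = 2)
  # p2 fails identity (exactly 0.80 is not over), p3 fails coverage
  expect_identical(pr$n_proteins_reconstructed, 1L)
  expect_equal(pr$pct_contigs_1_prot, 50)
  expect_equal(pr$pct_contigs_0_prot, 50)
  expect_equal(pr$pct_multi_prot, 0)

  none <- protein_reconstruction(hits[0, ], 3, 2)
  expect_identical(none$n_proteins_reconstructed, 0L)
  expect_equal(none$pct_contigs_0_prot, 100)
})

test_that("translated protein search finds planted ORF products", {
  set.seed(702)
  orfs <- purrr::map_chr(1:3, function(i) orf_seq(sample(90:150, 1)))
  cs <- contig_set(paste0("c", 1:3),
                   purrr::map_chr(orfs, function(o)
                     paste0(rseq(60), o, rseq(60))))
  prots <- tibble::tibble(
    id = paste0("p", 1:3),
    seq = purrr::map_chr(orfs, function(o) find_orfs(o, 100)$protein[1]))
  hits <- align_proteins(prots, cs)
  pr <- protein_reconstruction(hits, nrow(prots), nrow(cs))
  expect_identical(pr$n_proteins_reconstructed, 3L)
  # best hit of each protein is its own contig with identity ~1
  best <- hits |> dplyr::group_by(protein_id) |>
    dplyr::slice_max(score, n = 1) |> dplyr::ungroup()
  expect_identical(best$contig_id[order(best$protein_id)],
                   paste0("c", 1:3))
  expect_true(all(best$identity > 0.99))
  # one reverse-strand contig still hits
  cs_rc <- contig_set("c1", revcomp(cs$seq[1]))
  h_rc <- align_proteins(prots[1, ], cs_rc)
  expect_true(any(h_rc$identity > 0.99 & h_rc$protein_coverage > 0.99))
})

test_that("transcript linking keeps the best hit over strict 90/90", {
  set.seed(703)
  t1 <- rseq(1000)
  cs <- contig_set(c("full", "part"), c(t1, rseq(800)))
  tx <- tibble::tibble(id = c("t1", "t2", "t3"),
                       seq = c(t1, substr(t1, 1, 850), rseq(900)))
  links <- link_transcripts(tx, cs)
  l1 <- links[links$transcript_id == "t1", ]
  expect_true(l1$linked)
  expect_identical(l1$contig_id, "full")
  expect_equal(l1$query_identity, 1)
  expect_equal(l1$query_coverage, 1)
  # t2 is an 85%-piece of the contig: contained, still coverage 1 of itself
  expect_true(links$linked[links$transcript_id == "t2"])
  # unrelated transcript does not link
  expect_false(links$linked[links$transcript_id == "t3"])

  # best hit with coverage 0.85 -> no link
  cs2 <- contig_set("short", substr(t1, 1, 850))
  l850 <- link_transcripts(tibble::tibble(id = "t1", seq = t1), cs2)
  expect_false(l850$linked)
  expect_lt(l850$query_coverage, 0.9)
})

test_that("gene representation counts multi-isoform genes on distinct contigs", {
  links <- tibble::tibble(
    transcript_id = c("a.t1", "a.t2", "b.t1", "b.t2", "c.t1"),
    contig_id = c("c1", "c2", "c3", "c3", NA),
    query_identity = 1, query_coverage = 1, strand = "+",
    linked = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  gm <- tibble::tibble(transcript_id = links$transcript_id,
                       gene_id = sub("\\..*", "", links$transcript_id))
  gr <- gene_representation(links, gm)
  expect_identical(gr$n_genes, 3L)
  expect_identical(gr$n_genes_represented, 2L)
  # gene a: two isoforms on two contigs; gene b: both on one contig
  expect_identical(gr$n_multi_isoform_genes, 1L)
})

test_that("exon fidelity is perfect on identical sets, degrades as built", {
  set.seed(704)
  tx <- gen_transcriptome(n = 8, seed = 74)
  cs <- contig_set(tx$transcripts$id, tx$transcripts$seq)
  fid <- exon_fidelity(tx$exons, cs, transcripts = tx$transcripts,
                       gene_map = tx$gene_map)
  expect_equal(fid$pct_exons_retrieved, 100)
  expect_equal(fid$pct_exons_right_contig, 100)
  expect_equal(fid$pct_exons_right_order, 100)

  # one transcript split across two contigs: retrieved stays 100,
  # right-contig drops
  t1 <- tx$transcripts[1, ]
  ex1 <- tx$exons[tx$exons$transcript_id == t1$id, ]
  if (nrow(ex1) >= 2) {
    half <- ex1$end[ceiling(nrow(ex1) / 2)]
    css <- contig_set(c("p1", "p2"), c(substr(t1$seq, 1, half),
                                       substr(t1$seq, half + 1, nchar(t1$seq))))
    fid2 <- exon_fidelity(ex1, css,
                          links = tibble::tibble(
                            transcript_id = t1$id, contig_id = "p1",
                            query_identity = 1, query_coverage = 1,
                            strand = "+", linked = TRUE))
    expect_equal(fid2$pct_exons_retrieved, 100)
    expect_lt(fid2$pct_exons_right_contig, 100)
  }

  # reversing half the exon order breaks right-order but not retrieval
  t2 <- tx$transcripts[2, ]
  ex2 <- tx$exons[tx$exons$transcript_id == t2$id, ]
  if (nrow(ex2) >= 4) {
    shuffled <- paste(ex2$seq[c(rev(seq_len(nrow(ex2) %/% 2)),
                                (nrow(ex2) %/% 2 + 1):nrow(ex2))],
                      collapse = "")
    csr <- contig_set("r", shuffled)
    fidr <- exon_fidelity(ex2, csr,
                          links = tibble::tibble(
                            transcript_id = t2$id, contig_id = "r",
                            query_identity = 1, query_coverage = 1,
                            strand = "+", linked = TRUE))
    expect_equal(fidr$pct_exons_retrieved, 100)
    expect_lt(fidr$pct_exons_right_order, 100)
  }
})

test_that("defect rates report planted defects and clean sets as zero", {
  set.seed(705)
  clean <- contig_set(paste0("c", 1:10),
                      purrr::map_chr(1:10, function(i) rseq(800)))
  dr <- defect_rates(clean)
  expect_equal(dr$pct_included, 0)
  expect_equal(dr$pct_chimeric, 0)

  B <- rseq(500)
  with_chim <- dplyr::bind_rows(clean,
                                contig_set("chim", paste0(B, B)))
  dr2 <- defect_rates(with_chim)
  expect_equal(dr2$pct_chimeric, 100 / 11)

  with_inc <- dplyr::bind_rows(clean,
                               contig_set("inc", substr(clean$seq[1], 100, 600)))
  expect_equal(defect_rates(with_inc)$pct_included, 100 / 11)
})

test_that("reports round-trip through JSON and compare across assemblies", {
  set.seed(706)
  cs1 <- contig_set(paste0("a", 1:5), purrr::map_chr(1:5, function(i) rseq(600)))
  cs2 <- contig_set(paste0("b", 1:3), purrr::map_chr(1:3, function(i) rseq(900)))
  r1 <- assess_assembly(cs1, name = "one")
  r2 <- assess_assembly(cs2, name = "two")
  f <- withr::local_tempfile(fileext = ".json")
  write_report(r1, f)
  back <- read_report(f)
  expect_identical(back$n_contigs, r1$n_contigs)
  expect_identical(back$n50_nt, r1$n50_nt)
  expect_equal(back$pct_included, r1$pct_included)
  # optional fields survive as nulls
  expect_true(is.na(back$pct_reads_mapped) || is.null(back$pct_reads_mapped))

  cmp <- compare_reports(list(one = r1, two = r2))
  expect_identical(nrow(cmp), 2L)
  expect_identical(cmp$n_contigs, c(5L, 3L))

  td <- tidy(r1)
  expect_true(all(c("metric", "value") %in% names(td)))
  gl <- glance(r1)
  expect_identical(gl$n_contigs, 5L)
  # all report percentages bounded
  pct <- td$value[grepl("^pct_|^fid_pct_", td$metric) & !is.na(td$value)]
  expect_true(all(pct >= 0 & pct <= 100))
})
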