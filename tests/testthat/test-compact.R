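test_that("best-per-locus selection orders by length, then depth, then id", {
  set.seed(301)
  cs <- contig_set(c("a", "b", "c", "d", "e"),
                   c(rseq(1200), rseq(800), rseq(500), rseq(500), rseq(500)),
                   locus = c("L1", "L1", "L2", "L2", "L3"),
                   asm_depth = c(30, 50, 10, 20, 5))
  best <- choose_best_per_locus(cs)
  expect_identical(sort(best$id), c("a", "d", "e"))
  expect_identical(nrow(best), 3L)  # one per distinct locus
  # singleton locus keeps its only member
  expect_true("e" %in% best$id)
})

test_that("inclusion removal matches the all-pairs containment oracle", {
  set.seed(302)
  # two identical contigs: one kept
  twin <- rseq(400)
  r <- remove_included(contig_set(c("x", "y"), c(twin, twin)))
  expect_identical(nrow(r$kept), 1L)
  expect_identical(r$removed$absorbed_by, r$kept$id)

  # exact substring removed
  long <- rseq(900)
  r2 <- remove_included(contig_set(c("L", "s"),
                                   c(long, substr(long, 101, 500))))
  expect_identical(r2$kept$id, "L")

  # planted containments agree with the oracle
  for (trial in 1:5) {
    base <- replicate(4, rseq(sample(500:900, 1)))
    extras <- purrr::map_chr(1:6, function(i) {
      src <- sample(base, 1)
      st <- sample(1:100, 1)
      w <- sample(300:(nchar(src) - st), 1)
      piece <- substr(src, st, st + w - 1)
      if (runif(1) < 0.5) revcomp(piece) else piece
    })
    cs <- contig_set(sprintf("c%02d", 1:10), c(base, extras))
    kept <- remove_included(cs)$kept
    expect_identical(sort(kept$id), oracle_included(cs))
    # invariant: no kept contig contained in another kept contig
    for (i in seq_len(nrow(kept))) for (j in seq_len(nrow(kept))) {
      if (i == j || nchar(kept$seq[i]) > nchar(kept$seq[j])) next
      expect_null(containment(kept$seq[i], kept$seq[j]))
    }
  }
})

test_that("overlap merging joins chains and is order-independent", {
  set.seed(303)
  A <- rseq(400); B <- rseq(100); C <- rseq(400)
  ab <- paste0(A, B); bc <- paste0(B, C)
  m <- overlap_merge(contig_set(c("ab", "bc"), c(ab, bc)))
  expect_identical(nrow(m), 1L)
  expect_identical(m$seq, paste0(A, B, C))
  expect_identical(m$source, "merged")

  # nothing overlapping: identity
  cs <- contig_set(c("p", "q"), c(rseq(300), rseq(300)))
  expect_identical(sort(overlap_merge(cs)$seq), sort(cs$seq))

  # three-way chain reaches the same fixpoint from any input order
  D <- rseq(80)
  chain <- c(paste0(A, B), paste0(B, C), paste0(C, D, rseq(200)))
  perms <- list(1:3, c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))
  results <- purrr::map(perms, function(p) {
    sort(overlap_merge(contig_set(paste0("k", p), chain[p]))$seq)
  })
  for (r in results[-1]) expect_identical(r, results[[1]])

  # distinct 31-mer content never decreases
  kmers <- function(set) unique(unlist(lapply(set$seq, function(s)
    substring(s, 1:(nchar(s) - 30), 31:nchar(s)))))
  cs2 <- contig_set(c("u", "v"), c(ab, bc))
  expect_true(all(kmers(cs2) %in% kmers(overlap_merge(cs2))))
})

test_that("meta merge pools, deduplicates and clusters by protein identity", {
  set.seed(304)
  s1 <- contig_set(c("a", "b"), c(rseq(600), rseq(700)))
  s2 <- contig_set(c("c", "d"), c(rseq(650), rseq(750)))
  un <- meta_merge(list(s1, s2))
  expect_identical(nrow(un), 4L)

  # same transcript, one truncated: the longer representative survives
  t <- rseq(900)
  m2 <- meta_merge(list(contig_set("full", t),
                        contig_set("trunc", substr(t, 101, 800))))
  expect_identical(m2$id, "full")

  # synonymous recoding: low nucleotide identity, protein identity 1
  aa_codons <- list(A = c("GCT", "GCC", "GCA", "GCG"),
                    G = c("GGT", "GGC", "GGA", "GGG"),
                    L = c("CTT", "CTC", "CTA", "CTG"),
                    P = c("CCT", "CCC", "CCA", "CCG"),
                    T = c("ACT", "ACC", "ACA", "ACG"),
                    V = c("GTT", "GTC", "GTA", "GTG"))
  prot <- sample(names(aa_codons), 120, replace = TRUE)
  code <- function(p, pick) paste(vapply(p, function(a) aa_codons[[a]][pick],
                                         character(1)), collapse = "")
  v1 <- paste0("ATG", code(prot, 1), "TAA")
  v2 <- paste0("ATG", code(prot, 3), "TAA")
  nt_ident <- 1 - contigpolish:::hamming(v1, v2) / nchar(v1)
  expect_lt(nt_ident, 0.96)
  m3 <- meta_merge(list(contig_set("v1", v1), contig_set("v2", v2)))
  expect_identical(nrow(m3), 1L)

  # idempotence
  pool <- list(s1, s2, contig_set("dup", substr(t, 1, 600)),
               contig_set("t", t))
  once <- meta_merge(pool)
  twice <- meta_merge(list(once))
  expect_identical(sort(once$seq), sort(twice$seq))

  expect_error(meta_merge(list()), "at least one")
})
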