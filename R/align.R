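#' Local self-alignment of a contig
#'
#' Finds local matches of a contig against itself and its reverse
#' complement by k-mer diagonal seeding, run merging and exact end
#' extension. The trivial full-length identity diagonal is never
#' reported, and symmetric duplicates are collapsed so
#' `q_start < s_start`. This is the evidence feed for self-chimera
#' classification.
#'
#' @param seq a nucleotide string (or a one-row contig-set tibble).
#' @param min_identity identity floor for emitted matches (matches /
#'   aligned columns). Default 0.96.
#' @param min_match_len minimum aligned length in nt. Default 60;
#'   shorter repeats cannot drive the chimera coverage rules on
#'   realistically sized contigs.
#' @param k seed length.
#' @param max_seed_gap maximum gap between seed starts merged into one
#'   run on a diagonal.
#' @return tibble of matches, sorted by length descending: `q_start`,
#'   `q_end`, `s_start`, `s_end` (0-based half-open), `strand` (`"+"`
#'   forward, `"-"` reverse-complement), `identity`, `length`.
#' @export
self_local_matches <- function(seq, min_identity = 0.96, min_match_len = 60L,
                               k = 15L, max_seed_gap = 120L) {
  if (is.data.frame(seq)) seq <- seq$seq[[1]]
  n <- nchar(seq)
  empty <- tibble(q_start = integer(), q_end = integer(),
                  s_start = integer(), s_end = integer(),
                  strand = character(), identity = numeric(),
                  length = integer())
  if (n < max(min_match_len, k)) return(empty)

  kmers <- seq_kmers(seq, k)                 # position i (1-based) -> word
  pos_by_word <- split(seq_along(kmers), kmers)
  pos_by_word <- pos_by_word[lengths(pos_by_word) >= 1L]

  out <- list()

  # ---- forward matches: pairs of occurrences of the same word ----
  multi <- pos_by_word[lengths(pos_by_word) >= 2L]
  if (length(multi)) {
    seeds_i <- integer(0); seeds_d <- integer(0)
    for (p in multi) {
      if (length(p) > 100L) p <- p[seq_len(100L)]  # low-complexity guard
      cmb <- utils::combn(p, 2L)
      seeds_i <- c(seeds_i, cmb[1L, ])
      seeds_d <- c(seeds_d, cmb[2L, ] - cmb[1L, ])
    }
    runs <- merge_diag_runs(seeds_i, seeds_d, k, max_seed_gap)
    for (r in seq_len(nrow(runs))) {
      q0 <- runs$lo[r]; q1 <- runs$hi[r] + k; d <- runs$d[r]   # 1-based [q0, q1)
      # exact end extension, never crossing into the partner copy
      while (q0 > 1L && q1 - q0 < d &&
             substr(seq, q0 - 1L, q0 - 1L) == substr(seq, q0 + d - 1L, q0 + d - 1L)) {
        q0 <- q0 - 1L
      }
      while (q1 + d <= n && q1 - q0 < d &&
             substr(seq, q1, q1) == substr(seq, q1 + d, q1 + d)) {
        q1 <- q1 + 1L
      }
      len <- q1 - q0
      if (len < min_match_len) next
      ident <- 1 - hamming(substr(seq, q0, q1 - 1L),
                           substr(seq, q0 + d, q1 + d - 1L)) / len
      if (ident < min_identity) next
      out[[length(out) + 1L]] <- tibble(
        q_start = q0 - 1L, q_end = q0 - 1L + len,
        s_start = q0 + d - 1L, s_end = q0 + d - 1L + len,
        strand = "+", identity = ident, length = len)
    }
  }

  # ---- reverse-complement matches: words shared with revcomp(seq) ----
  rc <- revcomp(seq)
  rkmers <- seq_kmers(rc, k)
  rpos_by_word <- split(seq_along(rkmers), rkmers)
  shared <- intersect(names(pos_by_word), names(rpos_by_word))
  if (length(shared)) {
    seeds_i <- integer(0); seeds_j <- integer(0)
    for (w in shared) {
      pi <- pos_by_word[[w]]; pj <- rpos_by_word[[w]]
      if (length(pi) * length(pj) > 400L) {
        pi <- pi[seq_len(min(20L, length(pi)))]
        pj <- pj[seq_len(min(20L, length(pj)))]
      }
      g <- expand.grid(i = pi, j = pj)
      seeds_i <- c(seeds_i, g$i); seeds_j <- c(seeds_j, g$j)
    }
    # collinear reverse matches keep i - j constant
    runs <- merge_diag_runs(seeds_i, seeds_i - seeds_j, k, max_seed_gap)
    for (r in seq_len(nrow(runs))) {
      i0 <- runs$lo[r]; i1 <- runs$hi[r]; d <- runs$d[r]
      j0 <- i0 - d; j1 <- i1 - d
      q0 <- i0; q1 <- i1 + k                      # on seq, 1-based [q0, q1)
      s0 <- n - (j1 + k) + 2L; s1 <- n - j0 + 2L  # on seq, 1-based [s0, s1)
      len <- q1 - q0
      if (len < min_match_len) next
      ident <- 1 - hamming(substr(seq, q0, q1 - 1L),
                           substr(rc, j0, j1 + k - 1L)) / len
      if (ident < min_identity) next
      qi <- c(q0 - 1L, q0 - 1L + len)
      si <- c(s0 - 1L, s0 - 1L + len)
      if (qi[1] == si[1] && qi[2] == si[2]) {
        # full self-mirror (palindromic contig): report the two halves
        mid <- qi[1] + (qi[2] - qi[1]) %/% 2L
        half <- tibble(q_start = qi[1], q_end = mid, s_start = mid,
                       s_end = qi[2], strand = "-", identity = ident,
                       length = mid - qi[1])
        if (half$length >= min_match_len) out[[length(out) + 1L]] <- half
        next
      }
      if (si[1] < qi[1]) { tmp <- qi; qi <- si; si <- tmp }
      out[[length(out) + 1L]] <- tibble(
        q_start = qi[1], q_end = qi[2], s_start = si[1], s_end = si[2],
        strand = "-", identity = ident, length = len)
    }
  }

  if (!length(out)) return(empty)
  res <- bind_rows(out)
  res <- dplyr::distinct(res, .data$q_start, .data$q_end, .data$s_start,
                         .data$s_end, .data$strand, .keep_all = TRUE)
  res <- dplyr::filter(res, !(.data$q_start == .data$s_start &
                              .data$q_end == .data$s_end))
  dplyr::arrange(res, desc(.data$length), .data$q_start, .data$s_start)
}

# group seeds (position i on diagonal d) into maximal runs with gaps <= max_gap
merge_diag_runs <- function(i, d, k, max_gap) {
  if (!length(i)) return(tibble(d = integer(), lo = integer(), hi = integer()))
  ord <- order(d, i)
  i <- i[ord]; d <- d[ord]
  new_run <- c(TRUE, diff(d) != 0L | diff(i) > max_gap)
  run_id <- cumsum(new_run)
  tibble(
    d = d[new_run],
    lo = as.integer(tapply(i, run_id, min)),
    hi = as.integer(tapply(i, run_id, max))
  )
}

#' Containment alignment of a short contig within a longer one
#'
#' Best local alignment of the shorter sequence against the longer one on
#' both strands (exact-substring fast path first, then
#' `Biostrings::pairwiseAlignment`). A hit is returned only when identity
#' (matches over aligned columns, gaps counted) and coverage of the
#' shorter sequence both reach their floors.
#'
#' @param short,long nucleotide strings or one-row contig-set tibbles;
#'   `short` must not be longer than `long`.
#' @param min_identity identity floor.
#' @param min_short_cov minimum fraction of the shorter sequence aligned.
#' @return one-row tibble (`identity`, `short_coverage`, `strand`) or
#'   `NULL` when no qualifying alignment exists.
#' @export
containment <- function(short, long, min_identity = 0.96,
                        min_short_cov = 0.99) {
  if (is.data.frame(short)) short <- short$seq[[1]]
  if (is.data.frame(long)) long <- long$seq[[1]]
  stopifnot(nchar(short) <= nchar(long))
  ns <- nchar(short)
  # exact fast paths
  if (grepl(short, long, fixed = TRUE)) {
    return(tibble(identity = 1, short_coverage = 1, strand = "+"))
  }
  rc <- revcomp(short)
  if (grepl(rc, long, fixed = TRUE)) {
    return(tibble(identity = 1, short_coverage = 1, strand = "-"))
  }
  best <- NULL
  for (strand in c("+", "-")) {
    qry <- if (strand == "+") short else rc
    aln <- Biostrings::pairwiseAlignment(
      qry, long, type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2, baseOnly = FALSE),
      gapOpening = 3, gapExtension = 2)
    cols <- nchar(as.character(Biostrings::pattern(aln)))
    if (cols == 0) next
    ident <- Biostrings::nmatch(aln) / cols
    span <- IRanges::width(Biostrings::pattern(aln)@range)
    cov <- span / ns
    hit <- tibble(identity = ident, short_coverage = cov, strand = strand,
                  score = Biostrings::score(aln))
    if (is.null(best) || hit$score > best$score) best <- hit
  }
  if (is.null(best)) return(NULL)
  if (best$identity >= min_identity && best$short_coverage >= min_short_cov) {
    return(dplyr::select(best, -"score"))
  }
  NULL
}

#' Deterministic k-mer read mapper
#'
#' Exact k-mer seeding on an index of all contigs with ungapped
#' extension; the best placement is chosen by mismatch count with ties
#' broken by (contig id, position, strand) in lexicographic order.
#' Reads whose best ungapped placement exceeds `max_mismatch` get a
#' single-pass 1-nt-indel rescue (one `1D`/`1I` CIGAR op), which is what
#' lets downstream pileups carry the deletion/insertion alleles that
#' majority-vote consensus correction needs. Unmapped reads are emitted
#' with `mapped = FALSE`. Pure function of its inputs.
#'
#' @param reads tibble with `read_id` and `seq`; optional `pair_id` and
#'   `mate` columns enable proper-pair flagging.
#' @param contigs contig-set tibble.
#' @param k seed length (reads shorter than `k` stay unmapped).
#' @param max_mismatch maximum mismatches for a reported placement.
#' @param gap_rescue whether to attempt the 1-nt-indel rescue.
#' @param max_insert maximum mate distance for the proper-pair flag.
#' @return alignment tibble in [read_sam()] schema.
#' @export
map_reads_simple <- function(reads, contigs, k = 21L, max_mismatch = 3L,
                             gap_rescue = TRUE, max_insert = 1000L) {
  ord <- order(contigs$id, method = "radix")
  cs <- contigs[ord, ]
  res <- map_reads_cpp(reads$seq, cs$seq, as.integer(k),
                       as.integer(max_mismatch), isTRUE(gap_rescue))
  aln <- tibble(
    read_id = reads$read_id,
    contig_id = ifelse(is.na(res$contig), NA_character_, cs$id[res$contig]),
    start = res$start,
    cigar = res$cigar,
    strand = res$strand,
    mapped = res$mapped,
    paired = if ("pair_id" %in% names(reads)) !is.na(reads$pair_id) else FALSE,
    proper_pair = FALSE,
    first_in_pair = if ("mate" %in% names(reads))
      !is.na(reads$mate) & reads$mate == 1L else FALSE,
    seq = ifelse(res$mapped, res$seq, reads$seq),
    mismatches = res$mismatches
  )
  if ("pair_id" %in% names(reads) && any(aln$paired)) {
    key <- reads$pair_id
    m1 <- match(paste0(key, ":1"), paste0(key, ":", reads$mate))
    m2 <- match(paste0(key, ":2"), paste0(key, ":", reads$mate))
    ok <- !is.na(m1) & !is.na(m2) &
      aln$mapped[m1] & aln$mapped[m2] &
      aln$contig_id[m1] == aln$contig_id[m2] &
      aln$strand[m1] != aln$strand[m2] &
      abs(aln$start[m1] - aln$start[m2]) <= max_insert
    aln$proper_pair <- !is.na(ok) & ok
  }
  aln
}
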