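# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately written as plain, slow reference
# implementations, independent of the package code paths they check.

BASES <- c("A", "C", "G", "T")

rseq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

NONSTOP <- setdiff(apply(expand.grid(BASES, BASES, BASES), 1, paste,
                         collapse = ""), c("TAA", "TAG", "TGA"))

# ATG + n_codons non-stop codons + stop (total (n_codons + 2) * 3 nt)
orf_seq <- function(n_codons, stop = "TAA") {
  paste0("ATG", paste(sample(NONSTOP, n_codons, replace = TRUE),
                      collapse = ""), stop)
}

mutate_at <- function(seq, positions) {
  chars <- strsplit(seq, "")[[1]]
  for (p in positions) chars[p] <- setdiff(BASES, chars[p])[1]
  paste(chars, collapse = "")
}

# ---- N50/L50 oracle: direct cumulative walk --------------------------------
oracle_n50 <- function(lens) {
  s <- sort(lens, decreasing = TRUE)
  half <- sum(as.numeric(s)) / 2
  acc <- 0
  for (i in seq_along(s)) {
    acc <- acc + s[i]
    if (acc >= half) return(list(n50 = s[i], l50 = i))
  }
}

# ---- six-frame ORF oracle: per-ATG forward walk ----------------------------
# Independent of find_orfs: walks forward from every candidate start and
# reports ATG->stop ORFs (first ATG after the previous stop), plus
# edge-open partials, in forward-strand coordinates.
oracle_orfs <- function(seq, min_len = 200L) {
  n <- nchar(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    for (f in 0:2) {
      ncod <- (n - f) %/% 3
      if (ncod < 1) next
      cod <- substring(s, f + 1 + 3 * (0:(ncod - 1)), f + 3 + 3 * (0:(ncod - 1)))
      is_stop <- cod %in% c("TAA", "TAG", "TGA")
      prev_stop <- 0
      i <- 1
      while (i <= ncod) {
        if (is_stop[i]) { prev_stop <- i; i <- i + 1; next }
        if (cod[i] == "ATG") {
          # only the first ATG since the previous stop
          earlier <- FALSE
          j <- prev_stop + 1
          while (j < i) {
            if (cod[j] == "ATG") { earlier <- TRUE; break }
            j <- j + 1
          }
          if (!earlier) {
            j <- i
            while (j <= ncod && !is_stop[j]) j <- j + 1
            complete3 <- j <= ncod
            hi <- if (complete3) j else ncod
            nt_len <- (hi - i + 1) * 3
            if (nt_len >= min_len) {
              st <- f + (i - 1) * 3
              en <- f + hi * 3
              if (strand == "-") { tmp <- st; st <- n - en; en <- n - tmp }
              out[[length(out) + 1]] <- data.frame(
                start = st, end = en, strand = strand,
                complete5 = TRUE, complete3 = complete3)
            }
          }
        }
        i <- i + 1
      }
      # edge-open 5' partial: frame start to first stop with no ATG before it
      first_stop <- which(is_stop)[1]
      hi <- if (is.na(first_stop)) ncod else first_stop
      body_hi <- if (is.na(first_stop)) ncod else first_stop - 1
      has_atg <- body_hi >= 1 && any(cod[1:body_hi] == "ATG")
      if (!has_atg && hi >= 1) {
        nt_len <- hi * 3
        if (nt_len >= min_len) {
          st <- f; en <- f + hi * 3
          if (strand == "-") { tmp <- st; st <- n - en; en <- n - tmp }
          out[[length(out) + 1]] <- data.frame(
            start = st, end = en, strand = strand,
            complete5 = FALSE, complete3 = !is.na(first_stop))
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), complete5 = logical(),
                      complete3 = logical()))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end, res$strand), , drop = FALSE]
}

# ---- all-pairs containment oracle ------------------------------------------
# length-descending sweep testing every candidate against every kept
# contig, via direct containment() calls without the k-mer prefilter
oracle_included <- function(contigs, min_identity = 0.96,
                            min_short_cov = 0.99) {
  ord <- order(-nchar(contigs$seq), contigs$id)
  cs <- contigs[ord, ]
  kept <- logical(nrow(cs))
  for (i in seq_len(nrow(cs))) {
    contained <- FALSE
    for (j in which(kept)) {
      if (!is.null(containment(cs$seq[i], cs$seq[j], min_identity,
                               min_short_cov))) {
        contained <- TRUE
        break
      }
    }
    kept[i] <- !contained
  }
  sort(cs$id[kept])
}

# hand-rolled alignment tibble row for pileup tests
aln_row <- function(read_id, contig_id, start, cigar, seq, strand = "+",
                    mapped = TRUE) {
  tibble::tibble(read_id = read_id, contig_id = contig_id,
                 start = as.integer(start), cigar = cigar, strand = strand,
                 mapped = mapped, paired = FALSE, proper_pair = FALSE,
                 first_in_pair = FALSE, seq = seq)
}

# ---- exhaustive 80/80 protein reconstruction oracle ------------------------
# independent translated search: all six frame translations, split at
# stops, every (protein, segment) pair aligned, no prefilter
oracle_protein_8080 <- function(prots, contigs, id_floor = 0.80,
                                cov_floor = 0.80) {
  seg_list <- function(seq) {
    n <- nchar(seq)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    segs <- character(0)
    for (s in c(seq, rc)) for (f in 0:2) {
      ncod <- (n - f) %/% 3
      if (ncod < 10) next
      tr <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::DNAString(substr(s, f + 1, f + 3 * ncod)),
        if.fuzzy.codon = "X")))
      segs <- c(segs, strsplit(tr, "*", fixed = TRUE)[[1]])
    }
    segs[nchar(segs) >= 10]
  }
  all_segs <- lapply(contigs$seq, seg_list)
  n_rec <- 0L
  for (p in seq_len(nrow(prots))) {
    pseq <- Biostrings::AAString(prots$seq[p])
    hit <- FALSE
    for (segs in all_segs) {
      for (sg in segs) {
        al <- Biostrings::pairwiseAlignment(
          pseq, Biostrings::AAString(sg), type = "local",
          substitutionMatrix = "BLOSUM62", gapOpening = 10,
          gapExtension = 0.5)
        cols <- nchar(as.character(Biostrings::pattern(al)))
        if (cols == 0) next
        ident <- Biostrings::nmatch(al) / cols
        cov <- IRanges::width(Biostrings::pattern(al)@range) /
          nchar(prots$seq[p])
        if (ident > id_floor && cov > cov_floor) { hit <- TRUE; break }
      }
      if (hit) break
    }
    if (hit) n_rec <- n_rec + 1L
  }
  n_rec
}

# ---- exhaustive 90/90 transcript linking oracle ----------------------------
oracle_linked_9090 <- function(transcripts, contigs, floor = 0.90) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -2,
                                                     baseOnly = FALSE)
  n_linked <- 0L
  for (t in seq_len(nrow(transcripts))) {
    tq <- transcripts$seq[t]
    best <- NULL
    for (c in seq_len(nrow(contigs))) {
      for (q in c(tq, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(tq))))) {
        al <- Biostrings::pairwiseAlignment(q, contigs$seq[c],
                                            type = "local",
                                            substitutionMatrix = submat,
                                            gapOpening = 3, gapExtension = 2)
        if (is.null(best) || Biostrings::score(al) > Biostrings::score(best)) {
          best <- al
        }
      }
    }
    cols <- nchar(as.character(Biostrings::pattern(best)))
    ident <- Biostrings::nmatch(best) / cols
    cov <- IRanges::width(Biostrings::pattern(best)@range) / nchar(tq)
    if (ident > floor && cov > floor) n_linked <- n_linked + 1L
  }
  n_linked
}
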