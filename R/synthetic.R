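.BASES <- c("A", "C", "G", "T")
.NONSTOP_CODONS <- setdiff(
  apply(expand.grid(.BASES, .BASES, .BASES), 1L, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

.rand_seq <- function(n) {
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

# exon boundaries with a minimum exon length; always yields n_exons
# exons when len >= n_exons * min_exon (else as many as fit)
.exon_cuts <- function(len, n_exons, min_exon = 60L) {
  n_exons <- max(1L, min(n_exons, len %/% min_exon))
  if (n_exons == 1L) return(integer(0))
  extra <- len - min_exon * n_exons
  w <- stats::runif(n_exons)
  add <- floor(w / sum(w) * extra)
  lens <- as.integer(min_exon + add)
  lens[n_exons] <- lens[n_exons] + (len - sum(lens))
  as.integer(cumsum(lens)[-n_exons])
}

#' Generate a ground-truthed synthetic transcriptome
#'
#' Transcripts with planted complete ORFs, recorded exon structure and a
#' transcript-to-gene map; a fraction of genes carry a second,
#' exon-skipping isoform. Fully determined by the seed.
#'
#' @param n total number of transcripts (at least 1).
#' @param len_range transcript length range in nt.
#' @param orf_fraction fraction of genes with a planted complete ORF
#'   (ATG through stop, at least 210 nt, spanning most of the
#'   transcript). The default 1 models an mRNA-only reference; lowering
#'   it adds noncoding transcripts, which may contain chance ORFs.
#' @param multi_isoform_fraction fraction of genes carrying a second
#'   isoform that skips one internal exon.
#' @param n_exons_range exons per transcript.
#' @param seed integer seed; same seed, same output.
#' @return list: `transcripts` (tibble `id`, `seq`, `has_orf`),
#'   `exons` (tibble `transcript_id`, `exon_rank`, `start`, `end`
#'   0-based half-open on the transcript, `seq`), `gene_map`
#'   (tibble `transcript_id`, `gene_id`).
#' @export
gen_transcriptome <- function(n = 100L, len_range = c(500L, 2500L),
                              orf_fraction = 1, multi_isoform_fraction = 0.2,
                              n_exons_range = c(2L, 8L), seed = 1L) {
  stopifnot(n >= 1L)
  if (orf_fraction > 0 && len_range[1] < 280L) {
    stop("len_range too short to plant a complete ORF (need >= 280 nt)")
  }
  withr::with_seed(derive_seed(seed, 11L), {
    n_genes <- max(1L, round(n / (1 + multi_isoform_fraction)))
    n_iso2 <- n - n_genes
    iso2_genes <- if (n_iso2 > 0) sample(n_genes, n_iso2) else integer(0)
    # isoform-bearing genes need an internal exon to skip
    n_ex_gene <- purrr::map_int(seq_len(n_genes), function(g)
      if (g %in% iso2_genes)
        sample(seq.int(max(3L, n_exons_range[1]), max(3L, n_exons_range[2])), 1L)
      else sample(seq.int(n_exons_range[1], n_exons_range[2]), 1L))

    transcripts <- list(); exons <- list(); gene_map <- list()
    for (g in seq_len(n_genes)) {
      gid <- sprintf("g%04d", g)
      L <- sample(seq.int(len_range[1], len_range[2]), 1L)
      has_orf <- stats::runif(1) < orf_fraction
      if (has_orf) {
        orf_nt <- 3L * floor(stats::runif(1, 0.80, 0.90) * L / 3)
        orf_nt <- max(210L, orf_nt)
        utr5 <- max(10L, floor((L - orf_nt) * stats::runif(1, 0.3, 0.6)))
        utr3 <- L - orf_nt - utr5
        ncod <- orf_nt %/% 3L - 2L   # minus ATG and stop
        seq <- paste0(
          .rand_seq(utr5), "ATG",
          paste(sample(.NONSTOP_CODONS, ncod, replace = TRUE), collapse = ""),
          sample(c("TAA", "TAG", "TGA"), 1L), .rand_seq(utr3))
      } else {
        seq <- .rand_seq(L)
      }
      tid <- paste0(gid, ".t1")
      cuts <- .exon_cuts(L, n_ex_gene[g])
      if (has_orf && length(cuts)) {
        # snap exon boundaries inside the ORF to codon boundaries so that
        # exon skipping preserves the reading frame (as it mostly does in
        # real transcripts); codons then never straddle exon junctions
        orf_lo <- utr5; orf_hi <- utr5 + orf_nt
        inside <- cuts > orf_lo + 3L & cuts < orf_hi - 3L
        cuts[inside] <- orf_lo + 3L * pmax(1L, as.integer(round((cuts[inside] - orf_lo) / 3)))
        cuts <- sort(unique(as.integer(pmin(pmax(cuts, 1L), L - 1L))))
      }
      lo <- c(0L, cuts); hi <- c(cuts, L)
      transcripts[[tid]] <- tibble(id = tid, seq = seq, has_orf = has_orf)
      exons[[tid]] <- tibble(
        transcript_id = tid, exon_rank = seq_along(lo), start = lo, end = hi,
        seq = substring(seq, lo + 1L, hi))
      gene_map[[tid]] <- tibble(transcript_id = tid, gene_id = gid)

      if (g %in% iso2_genes && length(lo) >= 3L) {
        skip <- sample(seq.int(2L, length(lo) - 1L), 1L)
        keep <- setdiff(seq_along(lo), skip)
        seq2 <- paste(exons[[tid]]$seq[keep], collapse = "")
        tid2 <- paste0(gid, ".t2")
        lens2 <- nchar(exons[[tid]]$seq[keep])
        hi2 <- cumsum(lens2); lo2 <- c(0L, hi2[-length(hi2)])
        transcripts[[tid2]] <- tibble(id = tid2, seq = seq2, has_orf = FALSE)
        exons[[tid2]] <- tibble(
          transcript_id = tid2, exon_rank = seq_along(keep),
          start = lo2, end = hi2, seq = exons[[tid]]$seq[keep])
        gene_map[[tid2]] <- tibble(transcript_id = tid2, gene_id = gid)
      }
    }
    list(transcripts = bind_rows(transcripts),
         exons = bind_rows(exons),
         gene_map = bind_rows(gene_map))
  })
}

# apply substitution errors at a per-base rate; vectorised over reads
.mutate_seqs <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  lens <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), lens, error_rate)
  idx <- which(n_err > 0L)
  for (i in idx) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(lens[i], n_err[i])
    for (p in pos) {
      chars[p] <- sample(setdiff(.BASES, chars[p]), 1L)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Simulate RNA-Seq reads from a transcript set
#'
#' Per-transcript expression is drawn log-normally, fragment positions
#' are uniform, and each base is substituted independently at
#' `error_rate`. Paired mode emits opposite-strand mates from the two
#' fragment ends. Truth (transcript of origin and 0-based fragment
#' start) travels in extra columns.
#'
#' @param transcripts tibble `id`, `seq`.
#' @param depth_mean target mean per-transcript coverage (x).
#' @param read_len read length in nt (must not exceed the shortest
#'   transcript).
#' @param paired emit read pairs?
#' @param error_rate per-base substitution error rate.
#' @param expression_dispersion sdlog of the log-normal expression
#'   weights (0 = uniform expression).
#' @param fragment_len,fragment_sd mean and sd of fragment length
#'   (paired mode).
#' @param seed integer seed.
#' @return read tibble: `read_id`, `seq`, `pair_id`, `mate`,
#'   `truth_transcript`, `truth_pos`.
#' @export
sim_reads <- function(transcripts, depth_mean = 20, read_len = 100L,
                      paired = TRUE, error_rate = 0.01,
                      expression_dispersion = 1, fragment_len = 250L,
                      fragment_sd = 25, seed = 1L) {
  lens <- nchar(transcripts$seq)
  if (read_len > min(lens)) stop("read_len exceeds the shortest transcript")
  withr::with_seed(derive_seed(seed, 23L), {
    w <- stats::rlnorm(nrow(transcripts), 0, expression_dispersion)
    cov <- depth_mean * w / mean(w)
    frag_bases <- if (paired) 2L * read_len else read_len
    n_frag <- stats::rpois(nrow(transcripts), cov * lens / frag_bases)
    out <- list()
    counter <- 0L
    for (t in seq_len(nrow(transcripts))) {
      nf <- n_frag[t]
      if (nf == 0L) next
      L <- lens[t]; s <- transcripts$seq[t]
      if (paired) {
        fl <- pmin(L, pmax(read_len,
                           round(stats::rnorm(nf, fragment_len, fragment_sd))))
        st <- purrr::map_int(fl, function(f)
          sample.int(L - f + 1L, 1L))                       # 1-based
        r1 <- substring(s, st, st + read_len - 1L)
        r2 <- revcomp(substring(s, st + fl - read_len, st + fl - 1L))
        pid <- sprintf("f%07d", counter + seq_len(nf))
        out[[length(out) + 1L]] <- tibble(
          read_id = c(paste0(pid, "/1"), paste0(pid, "/2")),
          seq = .mutate_seqs(c(r1, r2), error_rate),
          pair_id = c(pid, pid), mate = rep(c(1L, 2L), each = nf),
          truth_transcript = transcripts$id[t],
          truth_pos = c(st - 1L, st + fl - read_len - 1L))
      } else {
        st <- sample.int(L - read_len + 1L, nf, replace = TRUE)
        pid <- sprintf("f%07d", counter + seq_len(nf))
        out[[length(out) + 1L]] <- tibble(
          read_id = pid, seq = .mutate_seqs(substring(s, st, st + read_len - 1L),
                                            error_rate),
          pair_id = NA_character_, mate = NA_integer_,
          truth_transcript = transcripts$id[t], truth_pos = st - 1L)
      }
      counter <- counter + nf
    }
    if (!length(out)) {
      return(tibble(read_id = character(), seq = character(),
                    pair_id = character(), mate = integer(),
                    truth_transcript = character(), truth_pos = integer()))
    }
    bind_rows(out)
  })
}

#' Corrupt a transcript set into a defect-injected assembly
#'
#' Injects the classic de novo assembly defect classes at fixed
#' per-class fractions (rounded counts, assigned to a seeded random
#' permutation of the transcripts): redundant copies (`duplicate`,
#' half of them truncated), extra truncated copies (`truncation`,
#' 50-90% windows), self-chimeras (a transcript followed by a cis or
#' trans copy of its own 3' part, built to satisfy the 60% footprint
#' rule), multi-transcript chimeras (two ORF-bearing transcripts
#' concatenated, cis or trans), consensus errors (2-4 substitutions
#' plus, half the time, a 1-nt indel) and 15-40 nt polyA tails. Every
#' emitted contig has exactly one truth record.
#'
#' @param transcripts tibble `id`, `seq`, optionally `has_orf` (used to
#'   pick multi-transcript chimera partners).
#' @param rates named fractions for
#'   `duplicate`, `truncation`, `self_chimera`,
#'   `multi_transcript_chimera`, `consensus_error`, `polya_tail`;
#'   must sum to at most 1. The remainder stays defect-free.
#' @param seed integer seed.
#' @return list: `contigs` (contig-set tibble) and `truth` (tibble
#'   `contig_id`, `defect`, `parent_transcripts`, `breakpoint`,
#'   `detail`).
#' @export
corrupt_assembly <- function(transcripts,
                             rates = c(duplicate = 0.1, truncation = 0.1,
                                       self_chimera = 0.1,
                                       multi_transcript_chimera = 0.1,
                                       consensus_error = 0.1,
                                       polya_tail = 0.1),
                             seed = 1L) {
  defects <- c("duplicate", "truncation", "self_chimera",
               "multi_transcript_chimera", "consensus_error", "polya_tail")
  rates <- rates[intersect(defects, names(rates))]
  if (sum(rates) > 1 + 1e-9) stop("defect rates must sum to at most 1")
  n <- nrow(transcripts)
  withr::with_seed(derive_seed(seed, 37L), {
    counts <- round(rates * n)
    perm <- sample.int(n)
    assign <- rep("none", n)
    at <- 1L
    for (d in names(counts)) {
      if (counts[[d]] == 0L) next
      take <- perm[seq.int(at, length.out = counts[[d]])]
      assign[take] <- d
      at <- at + counts[[d]]
    }
    # multi-transcript chimeras consume pairs of ORF-bearing transcripts
    has_orf <- if ("has_orf" %in% names(transcripts)) transcripts$has_orf
               else rep(TRUE, n)
    mtc <- which(assign == "multi_transcript_chimera")
    assign[mtc[!has_orf[mtc]]] <- "none"
    mtc <- which(assign == "multi_transcript_chimera")
    if (length(mtc) %% 2L == 1L) {
      assign[mtc[length(mtc)]] <- "none"
      mtc <- mtc[-length(mtc)]
    }
    mtc_partner <- integer(0)
    if (length(mtc)) {
      mtc_partner <- stats::setNames(
        rep(NA_integer_, length(mtc)), mtc)
      pairs <- matrix(mtc, ncol = 2L, byrow = TRUE)
    } else {
      pairs <- matrix(integer(0), ncol = 2L)
    }
    consumed_second <- if (nrow(pairs)) pairs[, 2L] else integer(0)

    contigs <- list(); truth <- list()
    cid <- 0L
    next_id <- function() {
      cid <<- cid + 1L
      sprintf("ctg_%04d", cid)
    }
    emit <- function(seq, defect, parents, breakpoint = NA_integer_,
                     detail = NA_character_) {
      id <- next_id()
      contigs[[length(contigs) + 1L]] <<- tibble(
        id = id, seq = seq, locus = NA_character_, asm_depth = NA_real_,
        source = "original", parent = NA_character_)
      truth[[length(truth) + 1L]] <<- tibble(
        contig_id = id, defect = defect,
        parent_transcripts = paste(parents, collapse = ","),
        breakpoint = breakpoint, detail = detail)
    }
    truncate_seq <- function(s) {
      L <- nchar(s)
      w <- floor(L * stats::runif(1, 0.5, 0.9))
      st <- sample.int(L - w + 1L, 1L)
      substr(s, st, st + w - 1L)
    }

    for (t in seq_len(n)) {
      if (t %in% consumed_second) next
      s <- transcripts$seq[t]; tid <- transcripts$id[t]
      d <- assign[t]
      if (d == "duplicate") {
        emit(s, "none", tid)
        dup <- if (stats::runif(1) < 0.5) truncate_seq(s) else s
        emit(dup, "duplicate", tid,
             detail = sprintf("len=%d", nchar(dup)))
      } else if (d == "truncation") {
        emit(s, "none", tid)
        tr <- truncate_seq(s)
        emit(tr, "truncation", tid, detail = sprintf("len=%d", nchar(tr)))
      } else if (d == "self_chimera") {
        p <- stats::runif(1, 0.5, 0.9)
        L <- nchar(s)
        block <- substr(s, floor(L * (1 - p)) + 1L, L)
        trans <- stats::runif(1) < 0.5
        extra <- if (trans) revcomp(block) else block
        emit(paste0(s, extra), "self_chimera", tid, breakpoint = L,
             detail = if (trans) "trans" else "cis")
      } else if (d == "multi_transcript_chimera") {
        j <- pairs[pairs[, 1L] == t, 2L]
        s2 <- transcripts$seq[j]
        trans <- stats::runif(1) < 0.5
        emit(paste0(s, if (trans) revcomp(s2) else s2),
             "multi_transcript_chimera",
             c(tid, transcripts$id[j]), breakpoint = nchar(s),
             detail = if (trans) "trans" else "cis")
      } else if (d == "consensus_error") {
        L <- nchar(s)
        chars <- strsplit(s, "", fixed = TRUE)[[1]]
        n_sub <- sample(2:4, 1L)
        pos <- sort(sample(seq.int(5L, L - 5L), n_sub))
        det <- character(0)
        for (p in pos) {
          old <- chars[p]
          chars[p] <- sample(setdiff(.BASES, old), 1L)
          det <- c(det, sprintf("%d:sub:%s>%s", p - 1L, old, chars[p]))
        }
        if (stats::runif(1) < 0.5) {
          ip <- sample(seq.int(5L, length(chars) - 5L), 1L)
          if (stats::runif(1) < 0.5) {
            ins <- sample(.BASES, 1L)
            chars <- append(chars, ins, after = ip)
            det <- c(det, sprintf("%d:ins:%s", ip - 1L, ins))
          } else {
            det <- c(det, sprintf("%d:del:%s", ip - 1L, chars[ip]))
            chars <- chars[-ip]
          }
        }
        emit(paste(chars, collapse = ""), "consensus_error", tid,
             detail = paste(det, collapse = ";"))
      } else if (d == "polya_tail") {
        tail_len <- sample(15:40, 1L)
        emit(paste0(s, strrep("A", tail_len)), "polya_tail", tid,
             detail = sprintf("tail=%d", tail_len))
      } else {
        emit(s, "none", tid)
      }
    }
    list(contigs = validate_contig_set(bind_rows(contigs)),
         truth = bind_rows(truth))
  })
}
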