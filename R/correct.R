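# union length of a set of [start, end) intervals
.interval_union_len <- function(starts, ends) {
  if (!length(starts)) return(0L)
  ir <- IRanges::reduce(IRanges::IRanges(start = starts + 1L, end = ends))
  sum(IRanges::width(ir))
}

#' Classify a contig as self-chimeric
#'
#' Applies the two published coverage rules to the self-alignment
#' evidence (matches at the 96% identity floor from
#' [self_local_matches()]):
#'
#' * rule (i), `longest-match-60`: the longest self-match whose two
#'   copies are disjoint has a union footprint of at least `cov_single`
#'   of the contig length; the contig is split at the start of the
#'   downstream copy, keeping the 5'-most copy intact.
#' * rule (ii), `repeat-block-80`: greedily picked non-overlapping
#'   match footprints (descending length) cover at least `cov_sum` of
#'   the contig; the contig is only a repetition of a short block and is
#'   discarded. Matches with mutually overlapping copies (tandem
#'   periodicity) are handled here, not by rule (i).
#'
#' Everything else is kept.
#'
#' @param contig one-row contig-set tibble.
#' @param matches self-match tibble; computed internally when `NULL`.
#' @param cov_single rule (i) footprint fraction.
#' @param cov_sum rule (ii) footprint fraction.
#' @param min_identity identity floor passed to [self_local_matches()].
#' @return one-row tibble: `contig_id`, `rule`
#'   (`longest-match-60` / `repeat-block-80` / `none`), `action`
#'   (`split` / `discard` / `keep`), `breakpoint` (0-based, `NA` unless
#'   split), `footprint` (fraction driving the decision), `n_matches`.
#' @export
classify_self_chimera <- function(contig, matches = NULL, cov_single = 0.60,
                                  cov_sum = 0.80, min_identity = 0.96) {
  stopifnot(nrow(contig) == 1L)
  if (is.null(matches)) {
    matches <- self_local_matches(contig$seq, min_identity = min_identity)
  }
  n <- nchar(contig$seq)
  call <- function(rule, action, breakpoint, footprint) {
    tibble(contig_id = contig$id, rule = rule, action = action,
           breakpoint = breakpoint, footprint = footprint,
           n_matches = nrow(matches))
  }
  if (!nrow(matches)) return(call("none", "keep", NA_integer_, 0))

  # rule (i): the longest match, but only when its two copies are
  # (essentially) disjoint; a chance end-extension can nibble a few bases
  # into the downstream copy, while heavily overlapping copies are tandem
  # periodicity and fall through to rule (ii)
  m <- matches[1L, ]
  if (m$q_end - m$s_start <= max(10L, 0.05 * m$length)) {
    fp <- .interval_union_len(c(m$q_start, m$s_start),
                              c(m$q_end, m$s_end)) / n
    if (fp >= cov_single) {
      return(call("longest-match-60", "split", as.integer(m$s_start), fp))
    }
  }

  # rule (ii): greedy non-overlapping footprints
  picked_s <- integer(0); picked_e <- integer(0)
  for (i in seq_len(nrow(matches))) {
    m <- matches[i, ]
    fs <- c(m$q_start, m$s_start); fe <- c(m$q_end, m$s_end)
    overlaps <- any(fs[1] < picked_e & fe[1] > picked_s) ||
      any(fs[2] < picked_e & fe[2] > picked_s)
    if (!overlaps) {
      picked_s <- c(picked_s, fs); picked_e <- c(picked_e, fe)
    }
  }
  fp2 <- .interval_union_len(picked_s, picked_e) / n
  if (fp2 >= cov_sum) return(call("repeat-block-80", "discard", NA_integer_, fp2))
  call("none", "keep", NA_integer_, max(fp2, 0))
}

#' Apply chimera calls to a contig set
#'
#' Split calls yield fragments `[0, bp)` / `[bp, len)` with ids
#' `<parent>.1` / `<parent>.2`; fragments shorter than
#' `min_fragment_len` are dropped. Discard calls remove the contig.
#' Near-duplicate fragments are deliberately left for downstream
#' inclusion removal to absorb.
#'
#' @param contigs contig-set tibble.
#' @param calls tibble of calls, one per contig ([classify_self_chimera()]).
#' @param min_fragment_len minimum surviving fragment length.
#' @return the processed contig set.
#' @export
apply_chimera_calls <- function(contigs, calls, min_fragment_len = 200L) {
  out <- list()
  for (i in seq_len(nrow(contigs))) {
    ct <- contigs[i, ]
    cl <- calls[calls$contig_id == ct$id, ]
    if (!nrow(cl) || cl$action[1] == "keep") {
      out[[length(out) + 1L]] <- ct
    } else if (cl$action[1] == "split") {
      bp <- cl$breakpoint[1]
      len <- nchar(ct$seq)
      if (is.na(bp) || bp <= 0L || bp >= len) {
        stop("split breakpoint outside (0, len) for contig ", ct$id)
      }
      frag <- tibble(
        id = paste0(ct$id, c(".1", ".2")),
        seq = c(substr(ct$seq, 1L, bp), substr(ct$seq, bp + 1L, len)),
        locus = ct$locus, asm_depth = ct$asm_depth,
        source = "split-fragment", parent = ct$id)
      out[[length(out) + 1L]] <- frag[nchar(frag$seq) >= min_fragment_len, ]
    } # discard: drop
  }
  validate_contig_set(bind_rows(out))
}

#' Majority-allele consensus correction of one contig
#'
#' At every position with pileup depth of at least `min_depth`, the
#' allele carried by a strict majority of reads (a base, a deletion
#' starting there, or an insertion anchored after it) replaces the
#' consensus. Ties and mere pluralities leave the consensus unchanged,
#' and N never wins. Edits are applied right to left so recorded
#' positions refer to the input coordinate system.
#'
#' @param contig one-row contig-set tibble.
#' @param pileup `cp_pileup` for this contig ([build_pileup()]).
#' @param min_depth minimum read depth for a position to be correctable.
#' @return list with `contig` (corrected, `source = "corrected"` when
#'   edited) and `edits` (tibble `contig_id`, `position`, `kind`,
#'   `from_allele`, `to_allele`, `depth`, `support`).
#' @export
majority_correct <- function(contig, pileup, min_depth = 10L) {
  stopifnot(nrow(contig) == 1L, pileup$contig_id == contig$id)
  len <- pileup$len
  depth <- pileup_depth(pileup)
  cons <- strsplit(contig$seq, "", fixed = TRUE)[[1]]
  edits <- list()

  bases <- pileup$bases[c("A", "C", "G", "T"), , drop = FALSE]
  # only positions where a non-consensus allele could take a strict
  # majority need a look: majority base differing from the consensus, or
  # any deletion evidence
  top <- do.call(pmax, lapply(1:4, function(r) bases[r, ]))
  winner <- c("A", "C", "G", "T")[max.col(t(bases), ties.method = "first")]
  eligible <- which(depth >= min_depth &
                    ((top * 2L > depth & winner != cons) | pileup$delcov > 0L))
  for (p in eligible) {
    d <- depth[p]
    bc <- bases[, p]
    # candidate alleles: bases (not N) and deletions starting at p
    dels_here <- pileup$dels[pileup$dels$pos == p - 1L, ]
    alleles <- c(bc, if (nrow(dels_here))
      stats::setNames(dels_here$count, paste0("del", dels_here$len)))
    win <- which(alleles * 2L > d)
    if (!length(win)) next
    allele <- names(alleles)[win[1L]]
    support <- alleles[[win[1L]]]
    if (allele %in% c("A", "C", "G", "T")) {
      if (allele != cons[p]) {
        edits[[length(edits) + 1L]] <- tibble(
          contig_id = contig$id, position = p - 1L, kind = "substitution",
          from_allele = cons[p], to_allele = allele,
          depth = d, support = support)
      }
    } else {
      dl <- as.integer(sub("^del", "", allele))
      edits[[length(edits) + 1L]] <- tibble(
        contig_id = contig$id, position = p - 1L, kind = "deletion",
        from_allele = paste(cons[p:min(len, p + dl - 1L)], collapse = ""),
        to_allele = "", depth = d, support = support)
    }
  }

  # insertions: anchored after position p (0-based); junction coverage is
  # reads spanning the junction without an insertion plus those with one
  if (nrow(pileup$ins)) {
    ins_by_pos <- split(pileup$ins, pileup$ins$pos)
    for (ps in names(ins_by_pos)) {
      p0 <- as.integer(ps)                 # 0-based anchor
      grp <- ins_by_pos[[ps]]
      total <- pileup$jcov[p0 + 1L] + sum(grp$count)
      if (total < min_depth) next
      best <- grp[order(-grp$count, grp$seq), ][1L, ]
      if (best$count * 2L > total) {
        edits[[length(edits) + 1L]] <- tibble(
          contig_id = contig$id, position = p0, kind = "insertion",
          from_allele = "", to_allele = best$seq,
          depth = total, support = best$count)
      }
    }
  }

  if (!length(edits)) {
    return(list(contig = contig,
                edits = tibble(contig_id = character(), position = integer(),
                               kind = character(), from_allele = character(),
                               to_allele = character(), depth = integer(),
                               support = integer())))
  }
  ed <- bind_rows(edits) |> arrange(desc(.data$position), .data$kind)
  pieces <- cons
  for (i in seq_len(nrow(ed))) {
    e <- ed[i, ]
    p <- e$position + 1L
    if (e$kind == "substitution") {
      pieces[p] <- e$to_allele
    } else if (e$kind == "deletion") {
      dl <- nchar(e$from_allele)
      pieces <- pieces[-(p:(p + dl - 1L))]
    } else {
      pieces <- append(pieces, strsplit(e$to_allele, "")[[1]], after = p)
    }
  }
  newc <- contig
  newc$seq <- paste(pieces, collapse = "")
  newc$source <- "corrected"
  list(contig = newc, edits = arrange(ed, .data$position))
}

#' Two-pass consensus correction of a contig set
#'
#' Aligns reads, majority-corrects each contig, re-aligns against the
#' corrected contigs and corrects again. Reads that change alignment
#' location after the first pass are what the second pass exploits.
#'
#' @param contigs contig-set tibble.
#' @param reads read tibble ([read_fastq()] schema).
#' @param aligner function `(reads, contigs) -> alignments`; defaults to
#'   [map_reads_simple()]. An external SAM can be supplied by wrapping
#'   [read_sam()] output for pass 1 (pass 2 always needs a live aligner).
#' @param min_depth minimum depth for correction.
#' @return list: `contigs` (corrected set), `pass1_edits`, `pass2_edits`,
#'   `alignments` (final-pass alignments, reusable for expression and
#'   mapping-rate metrics).
#' @export
two_pass_correct <- function(contigs, reads, aligner = map_reads_simple,
                             min_depth = 10L) {
  run_pass <- function(cs, aln) {
    res <- purrr::map(seq_len(nrow(cs)), function(i) {
      majority_correct(cs[i, ], build_pileup(cs[i, ], aln), min_depth)
    })
    list(contigs = validate_contig_set(bind_rows(purrr::map(res, "contig"))),
         edits = bind_rows(purrr::map(res, "edits")))
  }
  aln1 <- aligner(reads, contigs)
  p1 <- run_pass(contigs, aln1)
  aln2 <- aligner(reads, p1$contigs)
  p2 <- run_pass(p1$contigs, aln2)
  final_aln <- if (nrow(p2$edits)) aligner(reads, p2$contigs) else aln2
  list(contigs = p2$contigs, pass1_edits = p1$edits, pass2_edits = p2$edits,
       alignments = final_aln)
}

# maximal terminal run (3' when tail = TRUE) of base `b` with purity floor
.terminal_run <- function(seq, b, tail, min_run, purity) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (tail) chars <- rev(chars)
  hits <- cumsum(chars == b)
  lens <- seq_along(chars)
  ok <- which(hits / lens >= purity & lens >= min_run & chars == b)
  if (!length(ok)) 0L else max(ok)
}

#' TSA-style contig cleaning
#'
#' Prepares contigs for transcriptome shotgun archive submission:
#' trims 3' polyA and 5' polyT tails (maximal terminal segment with
#' base purity at least `polya_purity` and length at least
#' `polya_min_run`), trims terminal Ns, splits at internal N runs of at
#' least `n_split_run`, and drops pieces shorter than `min_len`.
#'
#' @param contig one-row contig-set tibble.
#' @param polya_min_run minimum tail length to trigger trimming.
#' @param polya_purity minimum A (or T) fraction of the trimmed segment.
#' @param n_split_run internal N-run length that splits the contig.
#' @param min_len minimum surviving piece length.
#' @return contig-set tibble of surviving pieces (possibly empty); split
#'   pieces get `.1`, `.2`, ... id suffixes and `source = "split-fragment"`.
#' @export
tsa_clean <- function(contig, polya_min_run = 10L, polya_purity = 0.9,
                      n_split_run = 14L, min_len = 200L) {
  stopifnot(nrow(contig) == 1L)
  s <- contig$seq
  ra <- .terminal_run(s, "A", tail = TRUE, polya_min_run, polya_purity)
  if (ra > 0L) s <- substr(s, 1L, nchar(s) - ra)
  rt <- .terminal_run(s, "T", tail = FALSE, polya_min_run, polya_purity)
  if (rt > 0L) s <- substr(s, rt + 1L, nchar(s))
  s <- sub("^N+", "", sub("N+$", "", s))
  if (!nzchar(s)) return(contig[0, ])

  pieces <- strsplit(s, sprintf("N{%d,}", n_split_run))[[1]]
  pieces <- sub("^N+", "", sub("N+$", "", pieces))
  pieces <- pieces[nchar(pieces) >= min_len]
  if (!length(pieces)) return(contig[0, ])
  if (length(pieces) == 1L) {
    out <- contig
    out$seq <- pieces
    return(out)
  }
  tibble(id = paste0(contig$id, ".", seq_along(pieces)), seq = pieces,
         locus = contig$locus, asm_depth = contig$asm_depth,
         source = "split-fragment", parent = contig$id)
}

#' Clean a whole contig set for TSA submission
#' @inheritParams tsa_clean
#' @param contigs contig-set tibble.
#' @return cleaned contig set.
#' @export
tsa_clean_set <- function(contigs, polya_min_run = 10L, polya_purity = 0.9,
                          n_split_run = 14L, min_len = 200L) {
  validate_contig_set(bind_rows(purrr::map(
    seq_len(nrow(contigs)),
    function(i) tsa_clean(contigs[i, ], polya_min_run, polya_purity,
                          n_split_run, min_len))))
}
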