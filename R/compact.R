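#' Keep the best contig of each locus
#'
#' For assemblies whose headers carry locus information (see
#' [annotate_loci()]), sub-selects one contig per locus: the longest,
#' then the most covered (`asm_depth`), with the id as final ascending
#' tie-break. Contigs without a locus are their own singleton locus.
#'
#' @param contigs a contig-set tibble with a `locus` column.
#' @return the reduced contig set, one row per locus.
#' @export
choose_best_per_locus <- function(contigs) {
  cs <- contigs
  cs$locus <- dplyr::coalesce(cs$locus, cs$id)
  cs |>
    mutate(.len = nchar(.data$seq),
           .dep = dplyr::coalesce(.data$asm_depth, -Inf)) |>
    arrange(.data$locus, desc(.data$.len), desc(.data$.dep), .data$id) |>
    group_by(.data$locus) |>
    dplyr::slice_head(n = 1L) |>
    ungroup() |>
    select(-".len", -".dep")
}

# k-mer prefilter index: environment mapping word -> integer ids
.kmer_index_new <- function() new.env(parent = emptyenv(), hash = TRUE)

.kmer_index_add <- function(idx, seq, id, k = 31L, step = 1L) {
  for (w in unique(seq_kmers(seq, k, step))) {
    idx[[w]] <- c(idx[[w]], id)
  }
}

.kmer_index_query <- function(idx, seq, k = 31L, step = 10L) {
  words <- unique(c(seq_kmers(seq, k, step), seq_kmers(revcomp(seq), k, step)))
  hits <- unlist(lapply(words, function(w) idx[[w]]), use.names = FALSE)
  unique(hits)
}

#' Remove contigs included in longer ones
#'
#' Processes contigs by length descending (id ascending on ties); each
#' candidate is tested for containment against the already-kept contigs
#' only, and dropped when a kept contig absorbs it at the identity and
#' coverage thresholds. After this step no kept contig is contained in
#' another kept contig at the same thresholds.
#'
#' @param contigs a contig-set tibble.
#' @param min_identity containment identity floor.
#' @param min_short_cov minimum coverage of the shorter (candidate) contig.
#' @return list with `kept` (contig set) and `removed` (tibble `id`,
#'   `absorbed_by`, `identity`, `coverage`, `strand`).
#' @export
remove_included <- function(contigs, min_identity = 0.96,
                            min_short_cov = 0.99) {
  ord <- order(-nchar(contigs$seq), contigs$id, method = "radix")
  cs <- contigs[ord, ]
  keep <- logical(nrow(cs))
  removed <- list()
  idx <- .kmer_index_new()
  kept_ids <- integer(0)
  for (i in seq_len(nrow(cs))) {
    cand <- cs$seq[i]
    hit <- NULL
    cand_kept <- .kmer_index_query(idx, cand)
    # longest absorber first, deterministically
    cand_kept <- cand_kept[order(-nchar(cs$seq[cand_kept]), cs$id[cand_kept])]
    for (j in cand_kept) {
      cn <- containment(cand, cs$seq[j], min_identity, min_short_cov)
      if (!is.null(cn)) {
        hit <- mutate(cn, id = cs$id[i], absorbed_by = cs$id[j],
                      coverage = .data$short_coverage)
        break
      }
    }
    if (is.null(hit)) {
      keep[i] <- TRUE
      .kmer_index_add(idx, cand, i)
      kept_ids <- c(kept_ids, i)
    } else {
      removed[[length(removed) + 1L]] <- hit
    }
  }
  removed <- if (length(removed)) {
    bind_rows(removed) |>
      select("id", "absorbed_by", "identity", "coverage", "strand")
  } else {
    tibble(id = character(), absorbed_by = character(),
           identity = numeric(), coverage = numeric(), strand = character())
  }
  list(kept = cs[keep, ], removed = removed)
}

# word -> positions map of one sequence, for the overlap scan
.word_pos_env <- function(seq, k) {
  e <- new.env(parent = emptyenv(), hash = TRUE)
  words <- seq_kmers(seq, k)
  for (i in seq_along(words)) e[[words[i]]] <- c(e[[words[i]]], i)
  e
}

# best suffix(a)-prefix(b) overlap given a's word-position map
.best_overlap_idx <- function(aenv, a, b, min_len, min_identity, k = 21L) {
  la <- nchar(a); lb <- nchar(b)
  if (min(la, lb) <= min_len) return(0L)
  offs <- seq.int(0L, min(63L, lb - k), by = 7L)
  best <- 0L
  for (o in offs) {
    pos <- aenv[[substr(b, o + 1L, o + k)]]
    if (is.null(pos)) next
    for (pp in pos) {
      L <- la - pp + 1L + o
      if (L < min_len || L >= min(la, lb)) next
      mm <- hamming(substr(a, la - L + 1L, la), substr(b, 1L, L))
      if (1 - mm / L >= min_identity && L > best) best <- L
    }
  }
  best
}

#' Greedy suffix-prefix overlap merging
#'
#' Elongates contigs by merging pairs whose suffix-prefix overlap meets
#' the length and identity floors, best (longest) overlap first, with
#' the overlap consensus taken from the longer contig; iterated to a
#' fixpoint. Both orientations of the second contig are considered.
#' Inclusion removal should already have been applied. Merged contigs
#' carry `source = "merged"` and an id joining their parents with `|`.
#'
#' @param contigs a contig-set tibble.
#' @param min_overlap_len minimum overlap length in nt.
#' @param min_overlap_identity minimum overlap identity.
#' @return the merged contig set.
#' @export
overlap_merge <- function(contigs, min_overlap_len = 40L,
                          min_overlap_identity = 0.96) {
  cs <- contigs[order(contigs$id, method = "radix"), ]
  k <- 21L
  envs <- lapply(cs$seq, .word_pos_env, k = k)
  rcs <- revcomp(cs$seq)
  repeat {
    n <- nrow(cs)
    if (n < 2L) break
    best <- list(L = 0L)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        for (orient in c("+", "-")) {
          b <- if (orient == "+") cs$seq[j] else rcs[j]
          L <- .best_overlap_idx(envs[[i]], cs$seq[i], b, min_overlap_len,
                                 min_overlap_identity, k)
          if (L > best$L) best <- list(L = L, i = i, j = j, orient = orient)
        }
      }
    }
    if (best$L == 0L) break
    a <- cs$seq[best$i]
    b <- if (best$orient == "+") cs$seq[best$j] else rcs[best$j]
    la <- nchar(a); lb <- nchar(b); L <- best$L
    merged_seq <- if (la >= lb) paste0(a, substr(b, L + 1L, lb))
                  else paste0(substr(a, 1L, la - L), b)
    merged <- tibble(
      id = paste0(cs$id[best$i], "|", cs$id[best$j]),
      seq = merged_seq, locus = NA_character_, asm_depth = NA_real_,
      source = "merged", parent = NA_character_)
    keep <- setdiff(seq_len(n), c(best$i, best$j))
    cs <- bind_rows(cs[keep, ], merged)
    envs <- c(envs[keep], list(.word_pos_env(merged_seq, k)))
    rcs <- c(rcs[keep], revcomp(merged_seq))
    ord <- order(cs$id, method = "radix")
    cs <- cs[ord, ]; envs <- envs[ord]; rcs <- rcs[ord]
  }
  validate_contig_set(cs)
}

# longest-ORF protein of each contig (NA when no qualifying ORF)
.longest_orf_protein <- function(contigs, orf_min_len = 200L) {
  purrr::map_chr(contigs$seq, function(s) {
    orfs <- find_orfs(s, min_len = orf_min_len)
    if (!nrow(orfs)) NA_character_ else orfs$protein[[1]]
  })
}

#' Merge several contig sets (meta-assembly)
#'
#' Two-stage compaction of pooled per-sample contig sets. Stage 1 removes
#' cross-set nucleotide containments ([remove_included] semantics at
#' `nuc_identity`). Stage 2 clusters the survivors whose longest-ORF
#' translations align at `prot_identity` identity over at least 90% of
#' the shorter protein, keeping the longest nucleotide member of each
#' cluster; contigs lacking a qualifying ORF skip stage 2. Idempotent.
#'
#' @param contig_sets a list of contig-set tibbles (at least one).
#' @param nuc_identity nucleotide containment identity floor.
#' @param prot_identity protein clustering identity floor.
#' @param min_prot_cov minimum aligned fraction of the shorter protein.
#' @param orf_min_len minimum ORF length (nt) for stage 2 eligibility.
#' @return the merged contig set.
#' @export
meta_merge <- function(contig_sets, nuc_identity = 0.96,
                       prot_identity = 0.95, min_prot_cov = 0.9,
                       orf_min_len = 200L) {
  if (!length(contig_sets)) stop("meta_merge needs at least one contig set")
  pooled <- bind_rows(purrr::imap(contig_sets, function(cs, i) {
    cs$id <- if (anyDuplicated(unlist(purrr::map(contig_sets, "id"))))
      paste0("s", i, ":", cs$id) else cs$id
    cs
  }))
  pooled <- validate_contig_set(pooled)
  stage1 <- remove_included(pooled, nuc_identity, 0.99)$kept

  prots <- .longest_orf_protein(stage1, orf_min_len)
  has_orf <- !is.na(prots)
  coding <- stage1[has_orf, ]
  coding_prot <- prots[has_orf]
  ord <- order(-nchar(coding$seq), coding$id, method = "radix")
  coding <- coding[ord, ]; coding_prot <- coding_prot[ord]

  keep <- logical(nrow(coding))
  pidx <- .kmer_index_new()
  for (i in seq_len(nrow(coding))) {
    reps <- unique(unlist(lapply(
      unique(seq_kmers(coding_prot[i], 6L, 3L)),
      function(w) pidx[[w]]), use.names = FALSE))
    joined <- FALSE
    for (j in sort(as.integer(reps))) {
      pa <- coding_prot[j]; pb <- coding_prot[i]
      shorter <- min(nchar(pa), nchar(pb))
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(pb), Biostrings::AAString(pa), type = "local",
        substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
      cols <- nchar(as.character(Biostrings::pattern(aln)))
      if (cols == 0) next
      ident <- Biostrings::nmatch(aln) / cols
      cov <- min(IRanges::width(Biostrings::pattern(aln)@range),
                 IRanges::width(Biostrings::subject(aln)@range)) / shorter
      if (ident >= prot_identity && cov >= min_prot_cov) {
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      keep[i] <- TRUE
      for (w in unique(seq_kmers(coding_prot[i], 6L, 1L))) {
        pidx[[w]] <- c(pidx[[w]], i)
      }
    }
  }
  out <- bind_rows(coding[keep, ], stage1[!has_orf, ])
  validate_contig_set(out[order(out$id, method = "radix"), ])
}
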