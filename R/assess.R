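#' Contig length metrics
#'
#' N50 is the length of the contig at which the cumulative length
#' (contigs sorted longest first) first reaches half the total; L50 is
#' how many contigs that takes.
#'
#' @param contigs contig-set tibble (or an integer vector of lengths).
#' @return one-row tibble: `n_contigs`, `n50_nt`, `l50_count`, `sum_nt`,
#'   `median_len_nt`.
#' @export
contig_metrics <- function(contigs) {
  lens <- if (is.numeric(contigs)) as.integer(contigs)
          else contig_lengths(contigs)
  if (!length(lens)) stop("contig_metrics needs a non-empty contig set")
  s <- sort(lens, decreasing = TRUE)
  cum <- cumsum(as.numeric(s))
  i <- which(cum >= sum(as.numeric(s)) / 2)[1]
  tibble(n_contigs = length(lens), n50_nt = s[i], l50_count = i,
         sum_nt = sum(as.numeric(lens)), median_len_nt = stats::median(lens))
}

#' Read and pair mapping rates
#'
#' Percent of reads mapped and percent carrying the proper-pair flag,
#' over all records including unmapped ones. For single-end data the
#' properly-paired rate is `NA`.
#'
#' @param alignments alignment tibble including unmapped records.
#' @return one-row tibble `pct_mapped`, `pct_properly_paired`.
#' @export
mapping_rates <- function(alignments) {
  n <- nrow(alignments)
  if (!n) return(tibble(pct_mapped = NA_real_, pct_properly_paired = NA_real_))
  pm <- 100 * sum(alignments$mapped) / n
  pp <- if (any(isTRUE_vec(alignments$paired))) {
    100 * sum(isTRUE_vec(alignments$proper_pair)) / n
  } else {
    NA_real_
  }
  tibble(pct_mapped = pm, pct_properly_paired = pp)
}

# ---- best local nucleotide hits of queries against a contig set ----

.nt_contig_index <- function(contigs, k = 21L) {
  idx <- .kmer_index_new()
  for (i in seq_len(nrow(contigs))) .kmer_index_add(idx, contigs$seq[i], i, k)
  idx
}

# best hit of one query; returns NULL or list(contig_id, identity,
# coverage, strand, score, subject_start [0-based])
.nt_best_hit <- function(query, contigs, idx, k = 21L) {
  nq <- nchar(query)
  cand <- .kmer_index_query(idx, query, k, step = max(1L, nq %/% 20L))
  cand <- cand[order(contigs$id[cand])]
  best <- NULL
  for (j in cand) {
    subj <- contigs$seq[j]
    hit <- NULL
    p <- regexpr(query, subj, fixed = TRUE)
    if (p[1] != -1L) {
      hit <- list(contig_id = contigs$id[j], identity = 1, coverage = 1,
                  strand = "+", score = nq, subject_start = as.integer(p[1]) - 1L)
    } else {
      prc <- regexpr(revcomp(query), subj, fixed = TRUE)
      if (prc[1] != -1L) {
        hit <- list(contig_id = contigs$id[j], identity = 1, coverage = 1,
                    strand = "-", score = nq, subject_start = as.integer(prc[1]) - 1L)
      }
    }
    if (is.null(hit)) {
      for (strand in c("+", "-")) {
        q <- if (strand == "+") query else revcomp(query)
        aln <- Biostrings::pairwiseAlignment(
          q, subj, type = "local",
          substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
            match = 1, mismatch = -2, baseOnly = FALSE),
          gapOpening = 3, gapExtension = 2)
        cols <- nchar(as.character(Biostrings::pattern(aln)))
        if (cols == 0) next
        h <- list(contig_id = contigs$id[j],
                  identity = Biostrings::nmatch(aln) / cols,
                  coverage = IRanges::width(Biostrings::pattern(aln)@range) / nq,
                  strand = strand, score = Biostrings::score(aln),
                  subject_start = IRanges::start(Biostrings::subject(aln)@range) - 1L)
        if (is.null(hit) || h$score > hit$score) hit <- h
      }
    }
    if (!is.null(hit) && (is.null(best) || hit$score > best$score)) best <- hit
  }
  best
}

#' Link reference transcripts to contigs
#'
#' Keeps the single best local-alignment hit per transcript and emits a
#' link only when its query identity and query coverage both exceed the
#' floors (strictly, matching the "over 90%" convention).
#'
#' @param transcripts tibble with `id` and `seq` (reference transcripts).
#' @param contigs contig-set tibble.
#' @param min_identity,min_coverage strict lower bounds for a link.
#' @return tibble `transcript_id`, `contig_id`, `query_identity`,
#'   `query_coverage`, `strand`, `linked` (at most one row per
#'   transcript; unlinked transcripts have `linked = FALSE` and `NA`
#'   contig).
#' @export
link_transcripts <- function(transcripts, contigs, min_identity = 0.90,
                             min_coverage = 0.90) {
  idx <- .nt_contig_index(contigs)
  rows <- purrr::map(seq_len(nrow(transcripts)), function(i) {
    hit <- .nt_best_hit(transcripts$seq[i], contigs, idx)
    if (is.null(hit)) {
      return(tibble(transcript_id = transcripts$id[i],
                    contig_id = NA_character_, query_identity = NA_real_,
                    query_coverage = NA_real_, strand = NA_character_,
                    linked = FALSE))
    }
    ok <- hit$identity > min_identity && hit$coverage > min_coverage
    tibble(transcript_id = transcripts$id[i],
           contig_id = if (ok) hit$contig_id else NA_character_,
           query_identity = hit$identity, query_coverage = hit$coverage,
           strand = if (ok) hit$strand else NA_character_, linked = ok)
  })
  bind_rows(rows)
}

#' Gene-level summary of transcript links
#'
#' @param links output of [link_transcripts()].
#' @param gene_map tibble `transcript_id`, `gene_id`.
#' @return one-row tibble: `n_genes`, `n_genes_represented`,
#'   `n_multi_isoform_genes` (genes with two or more isoforms linked to
#'   distinct contigs).
#' @export
gene_representation <- function(links, gene_map) {
  lk <- left_join(links, gene_map, by = "transcript_id")
  per_gene <- lk |>
    dplyr::filter(.data$linked) |>
    group_by(.data$gene_id) |>
    summarise(n_contigs = dplyr::n_distinct(.data$contig_id),
              .groups = "drop")
  tibble(n_genes = dplyr::n_distinct(gene_map$gene_id),
         n_genes_represented = nrow(per_gene),
         n_multi_isoform_genes = sum(per_gene$n_contigs >= 2L))
}

# ---- protein reconstruction (translated search) ----

# split a frame translation at stops into searchable segments
.frame_segments <- function(seq) {
  n <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (f in 0:2) {
      ncod <- (n - f) %/% 3L
      if (ncod < 10L) next
      starts <- f + 1L + 3L * (seq_len(ncod) - 1L)
      aa <- Biostrings::GENETIC_CODE[substring(s, starts, starts + 2L)]
      aa[is.na(aa)] <- "X"
      tr <- paste(aa, collapse = "")
      segs <- strsplit(tr, "*", fixed = TRUE)[[1]]
      off <- 0L
      for (sg in segs) {
        if (nchar(sg) >= 10L) {
          out[[length(out) + 1L]] <- list(seq = sg, strand = strand,
                                          frame = f, aa_offset = off)
        }
        off <- off + nchar(sg) + 1L
      }
    }
  }
  out
}

#' Align reference proteins to contigs (translated search)
#'
#' Each contig is translated in six frames, frame translations are split
#' at stops, and each protein is locally aligned (BLOSUM62) to candidate
#' segments sharing peptide words. The best hit per (protein, contig)
#' pair is kept.
#'
#' @param proteins tibble `id`, `seq` (amino-acid sequences).
#' @param contigs contig-set tibble.
#' @return tibble `protein_id`, `contig_id`, `identity`,
#'   `protein_coverage` (on the protein/query length), `score`.
#' @export
align_proteins <- function(proteins, contigs) {
  seg_tab <- purrr::map(seq_len(nrow(contigs)),
                        function(i) .frame_segments(contigs$seq[i]))
  pidx <- .kmer_index_new()
  flat <- list()
  for (ci in seq_along(seg_tab)) {
    for (sg in seg_tab[[ci]]) {
      flat[[length(flat) + 1L]] <- c(sg, list(contig = ci))
      si <- length(flat)
      for (w in unique(seq_kmers(sg$seq, 5L, 2L))) pidx[[w]] <- c(pidx[[w]], si)
    }
  }
  rows <- list()
  for (p in seq_len(nrow(proteins))) {
    pseq <- proteins$seq[p]
    cand <- unique(unlist(lapply(unique(seq_kmers(pseq, 5L, 1L)),
                                 function(w) pidx[[w]]), use.names = FALSE))
    if (!length(cand)) next
    best_by_contig <- list()
    for (si in sort(cand)) {
      sg <- flat[[si]]
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(pseq), Biostrings::AAString(sg$seq),
        type = "local", substitutionMatrix = "BLOSUM62",
        gapOpening = 10, gapExtension = 0.5)
      cols <- nchar(as.character(Biostrings::pattern(aln)))
      if (cols == 0) next
      hit <- tibble(
        protein_id = proteins$id[p], contig_id = contigs$id[sg$contig],
        identity = Biostrings::nmatch(aln) / cols,
        protein_coverage = IRanges::width(Biostrings::pattern(aln)@range) /
          nchar(pseq),
        score = Biostrings::score(aln))
      key <- hit$contig_id
      if (is.null(best_by_contig[[key]]) ||
          hit$score > best_by_contig[[key]]$score) {
        best_by_contig[[key]] <- hit
      }
    }
    rows <- c(rows, best_by_contig)
  }
  if (!length(rows)) {
    return(tibble(protein_id = character(), contig_id = character(),
                  identity = numeric(), protein_coverage = numeric(),
                  score = numeric()))
  }
  bind_rows(rows)
}

#' Protein reconstruction summary (80/80 rule)
#'
#' A reference protein counts as reconstructed when some contig aligns
#' to it with identity and protein coverage both strictly over the
#' floors. Contig-side percentages come from per-contig distinct
#' reconstructed-protein counts.
#'
#' @param hits best-per-(protein, contig) hits ([align_proteins()]).
#' @param n_proteins total number of reference proteins.
#' @param n_contigs total number of contigs.
#' @param id_floor,cov_floor strict lower bounds ("over 80%").
#' @return one-row tibble: `n_proteins_reconstructed`,
#'   `pct_contigs_0_prot`, `pct_contigs_1_prot`, `pct_multi_prot`.
#' @export
protein_reconstruction <- function(hits, n_proteins, n_contigs,
                                   id_floor = 0.80, cov_floor = 0.80) {
  good <- dplyr::filter(hits, .data$identity > id_floor,
                        .data$protein_coverage > cov_floor)
  per_contig <- good |>
    group_by(.data$contig_id) |>
    summarise(n_prot = dplyr::n_distinct(.data$protein_id), .groups = "drop")
  n0 <- n_contigs - nrow(per_contig)
  tibble(
    n_proteins_reconstructed = dplyr::n_distinct(good$protein_id),
    pct_contigs_0_prot = if (n_contigs) 100 * n0 / n_contigs else NA_real_,
    pct_contigs_1_prot = if (n_contigs)
      100 * sum(per_contig$n_prot == 1L) / n_contigs else NA_real_,
    pct_multi_prot = if (n_contigs)
      100 * sum(per_contig$n_prot >= 2L) / n_contigs else NA_real_)
}

#' Exon retrieval, placement and order fidelity
#'
#' An exon is retrieved when it aligns somewhere in the contig set with
#' identity and query coverage both over 0.9; in the right contig when
#' its best placement lies on the contig its transcript links to; in the
#' right order when, among its transcript's exons placed on that contig,
#' its rank along the link strand equals its annotated rank. Also
#' reports the percentage of contigs placing exons of more than one gene
#' and the maximum number of genes per contig. Exons longer than any
#' contig simply count as not retrieved.
#'
#' @param exons tibble `transcript_id`, `exon_rank`, `seq`.
#' @param contigs contig-set tibble.
#' @param links transcript links ([link_transcripts()]); computed from
#'   `transcripts` when `NULL`.
#' @param transcripts optional transcript tibble used when `links` is `NULL`.
#' @param gene_map optional tibble `transcript_id`, `gene_id` for the
#'   multi-gene contig columns.
#' @param min_identity,min_coverage strict floors for an exon placement.
#' @return one-row tibble: `pct_exons_retrieved`,
#'   `pct_exons_right_contig`, `pct_exons_right_order`,
#'   `pct_contigs_multi_gene`, `max_genes_per_contig`.
#' @export
exon_fidelity <- function(exons, contigs, links = NULL, transcripts = NULL,
                          gene_map = NULL, min_identity = 0.90,
                          min_coverage = 0.90) {
  if (is.null(links)) {
    stopifnot(!is.null(transcripts))
    links <- link_transcripts(transcripts, contigs, min_identity, min_coverage)
  }
  idx <- .nt_contig_index(contigs)
  link_of <- stats::setNames(links$contig_id, links$transcript_id)
  place <- purrr::map(seq_len(nrow(exons)), function(i) {
    hit <- .nt_best_hit(exons$seq[i], contigs, idx)
    if (is.null(hit) || !(hit$identity > min_identity &&
                          hit$coverage > min_coverage)) {
      return(tibble(contig_id = NA_character_, pos = NA_integer_,
                    strand = NA_character_))
    }
    # ties (identical exons shared across isoform contigs) resolve in
    # favour of the contig the exon's transcript links to
    linked <- link_of[[exons$transcript_id[i]]]
    if (!is.null(linked) && !is.na(linked) && hit$contig_id != linked) {
      j <- which(contigs$id == linked)
      if (length(j)) {
        alt <- .nt_best_hit(exons$seq[i], contigs[j, ],
                            .nt_contig_index(contigs[j, ]))
        if (!is.null(alt) && alt$score >= hit$score &&
            alt$identity > min_identity && alt$coverage > min_coverage) {
          hit <- alt
          hit$contig_id <- linked
        }
      }
    }
    tibble(contig_id = hit$contig_id, pos = hit$subject_start,
           strand = hit$strand)
  })
  ex <- dplyr::bind_cols(exons[, c("transcript_id", "exon_rank")],
                         bind_rows(place))
  ex$retrieved <- !is.na(ex$contig_id)
  strand_of <- stats::setNames(links$strand, links$transcript_id)
  ex$right_contig <- ex$retrieved & !is.na(link_of[ex$transcript_id]) &
    ex$contig_id == link_of[ex$transcript_id]
  ex$right_contig[is.na(ex$right_contig)] <- FALSE

  ex$right_order <- FALSE
  for (tid in unique(ex$transcript_id)) {
    rowsel <- which(ex$transcript_id == tid & ex$right_contig)
    if (!length(rowsel)) next
    sub <- ex[rowsel, ]
    dirn <- if (!is.na(strand_of[tid]) && strand_of[tid] == "-") -1 else 1
    placed_rank <- rank(dirn * sub$pos, ties.method = "first")
    annot_rank <- rank(sub$exon_rank, ties.method = "first")
    ex$right_order[rowsel] <- placed_rank == annot_rank
  }

  n <- nrow(ex)
  multi <- tibble(pct_contigs_multi_gene = NA_real_,
                  max_genes_per_contig = NA_integer_)
  if (!is.null(gene_map)) {
    placed <- dplyr::filter(ex, .data$retrieved) |>
      left_join(gene_map, by = "transcript_id") |>
      group_by(.data$contig_id) |>
      summarise(n_genes = dplyr::n_distinct(.data$gene_id), .groups = "drop")
    multi <- tibble(
      pct_contigs_multi_gene = if (nrow(contigs))
        100 * sum(placed$n_genes > 1L) / nrow(contigs) else NA_real_,
      max_genes_per_contig = if (nrow(placed)) max(placed$n_genes) else 0L)
  }
  dplyr::bind_cols(
    tibble(pct_exons_retrieved = 100 * sum(ex$retrieved) / n,
           pct_exons_right_contig = 100 * sum(ex$right_contig) / n,
           pct_exons_right_order = 100 * sum(ex$right_order) / n),
    multi)
}

#' Structural defect rates of a contig set
#'
#' Read-only reuse of the compaction and correction classifiers:
#' percent of contigs contained in a longer one, percent with multiple
#' complete non-overlapping ORFs, and percent classified self-chimeric.
#'
#' @param contigs contig-set tibble.
#' @param orf_min_len minimum complete-ORF length (nt).
#' @return one-row tibble `pct_included`, `pct_multi_orf`, `pct_chimeric`.
#' @export
defect_rates <- function(contigs, orf_min_len = 200L) {
  n <- nrow(contigs)
  if (!n) {
    return(tibble(pct_included = 0, pct_multi_orf = 0, pct_chimeric = 0))
  }
  inc <- nrow(remove_included(contigs)$removed)
  morf <- sum(is_multi_orf(contigs, orf_min_len))
  chim <- sum(purrr::map_chr(seq_len(n), function(i)
    classify_self_chimera(contigs[i, ])$action) != "keep")
  tibble(pct_included = 100 * inc / n, pct_multi_orf = 100 * morf / n,
         pct_chimeric = 100 * chim / n)
}

#' Assess one assembly
#'
#' Computes the full metrics record for a contig set: length metrics,
#' defect rates, mapping rates (when alignments are given), protein
#' reconstruction (when a reference proteome is given), transcript
#' linking and exon fidelity (when reference transcripts / exon models
#' are given). Never modifies the contig set.
#'
#' @param contigs contig-set tibble.
#' @param alignments optional alignment tibble (reads mapped to these
#'   contigs, unmapped records included).
#' @param proteins optional reference protein tibble `id`, `seq`.
#' @param transcripts optional reference transcript tibble `id`, `seq`.
#' @param exons optional exon models `transcript_id`, `exon_rank`, `seq`.
#' @param gene_map optional `transcript_id`, `gene_id` map.
#' @param name assembly label used in reports.
#' @return a `cp_report` object (named list of metric fields).
#' @export
assess_assembly <- function(contigs, alignments = NULL, proteins = NULL,
                            transcripts = NULL, exons = NULL,
                            gene_map = NULL, name = "assembly") {
  met <- contig_metrics(contigs)
  def <- defect_rates(contigs)
  rep <- c(list(name = name), as.list(met), as.list(def))
  rep$pct_reads_mapped <- NA_real_
  rep$pct_properly_paired <- NA_real_
  if (!is.null(alignments)) {
    mr <- mapping_rates(alignments)
    rep$pct_reads_mapped <- mr$pct_mapped
    rep$pct_properly_paired <- mr$pct_properly_paired
  }
  rep$n_proteins_reconstructed <- NA_integer_
  rep$pct_contigs_0_prot <- NA_real_
  rep$pct_contigs_1_prot <- NA_real_
  rep$pct_multi_prot <- NA_real_
  if (!is.null(proteins)) {
    hits <- align_proteins(proteins, contigs)
    pr <- protein_reconstruction(hits, nrow(proteins), nrow(contigs))
    rep[names(pr)] <- as.list(pr)
  }
  rep$n_transcripts_linked <- NA_integer_
  rep$n_genes_represented <- NA_integer_
  rep$n_multi_isoform_genes <- NA_integer_
  links <- NULL
  if (!is.null(transcripts)) {
    links <- link_transcripts(transcripts, contigs)
    rep$n_transcripts_linked <- sum(links$linked)
    if (!is.null(gene_map)) {
      gr <- gene_representation(links, gene_map)
      rep$n_genes_represented <- gr$n_genes_represented
      rep$n_multi_isoform_genes <- gr$n_multi_isoform_genes
    }
  }
  rep$fidelity <- list(pct_exons_retrieved = NA_real_,
                       pct_exons_right_contig = NA_real_,
                       pct_exons_right_order = NA_real_,
                       pct_contigs_multi_gene = NA_real_,
                       max_genes_per_contig = NA_integer_)
  if (!is.null(exons) && !is.null(links)) {
    fid <- exon_fidelity(exons, contigs, links = links, gene_map = gene_map)
    rep$fidelity <- as.list(fid)
  }
  # external scores (not computed internally; import paths only)
  rep$transrate_score <- NA_real_
  rep$busco <- NA_real_
  structure(rep, class = "cp_report")
}

#' Write a metrics report as JSON
#'
#' Stable key order, all fields present, `NA` serialised as null;
#' re-readable with [read_report()].
#'
#' @param report a `cp_report` (or plain named list).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a metrics report from JSON
#' @param path JSON written by [write_report()].
#' @return a `cp_report` object.
#' @export
read_report <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "cp_report")
}

#' Compare several assemblies
#'
#' @param reports named list of `cp_report` objects.
#' @return tibble with one row per assembly and one column per scalar
#'   metric.
#' @export
compare_reports <- function(reports) {
  bind_rows(purrr::map(reports, function(r) {
    flat <- c(r[!purrr::map_lgl(r, is.list)],
              purrr::set_names(r$fidelity, paste0("fid_", names(r$fidelity))))
    as_tibble(flat)
  }))
}
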