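#' Fragment counts and FPKM per contig
#'
#' A fragment is a mapped read pair (counted once, on the shared contig
#' when both mates map there) or a mapped unpaired/orphan read (counted
#' once on its own contig). FPKM for a contig is
#' `fragments * 1e9 / (length_nt * total_mapped_fragments)`, and 0 when
#' no fragment maps anywhere. Fragment totals are conserved: the column
#' sums to the total mapped fragment count.
#'
#' @param alignments alignment tibble ([read_sam()] / [map_reads_simple()]
#'   schema).
#' @param contigs contig-set tibble; every contig gets a row even with
#'   zero fragments.
#' @return tibble `contig_id`, `length_nt`, `fragments`, `fpkm`.
#' @export
compute_fpkm <- function(alignments, contigs) {
  a <- dplyr::filter(alignments, .data$mapped)
  frags <- tibble(contig_id = character(0))
  if (nrow(a)) {
    paired <- isTRUE_vec(a$paired)
    pid <- sub("/[12]$", "", a$read_id)
    ap <- a[paired, ]; pidp <- pid[paired]
    pair_tab <- tibble(pair_id = pidp, contig_id = ap$contig_id) |>
      group_by(.data$pair_id) |>
      summarise(n_mates = n(),
                same = dplyr::n_distinct(.data$contig_id) == 1L,
                contig_1 = dplyr::first(.data$contig_id),
                contig_2 = dplyr::last(.data$contig_id), .groups = "drop")
    frag_contigs <- c(
      # both mates on one contig: one fragment there
      pair_tab$contig_1[pair_tab$n_mates == 2L & pair_tab$same],
      # discordant pair: two single fragments
      pair_tab$contig_1[pair_tab$n_mates == 2L & !pair_tab$same],
      pair_tab$contig_2[pair_tab$n_mates == 2L & !pair_tab$same],
      # orphan mate: one fragment
      pair_tab$contig_1[pair_tab$n_mates == 1L],
      # unpaired reads
      a$contig_id[!paired]
    )
    frags <- tibble(contig_id = frag_contigs)
  }
  counts <- frags |> dplyr::count(.data$contig_id, name = "fragments")
  total <- sum(counts$fragments)
  out <- tibble(contig_id = contigs$id, length_nt = nchar(contigs$seq)) |>
    left_join(counts, by = "contig_id") |>
    mutate(fragments = dplyr::coalesce(.data$fragments, 0L),
           fpkm = if (total == 0) 0
                  else .data$fragments * 1e9 / (.data$length_nt * total))
  out
}

#' Filter contigs on expression and length / coding potential
#'
#' Keeps a contig iff its FPKM is at least `fpkm_threshold` and it
#' passes the structural rule: length at least `min_len`, or, with
#' `coding_only`, a longest ORF of at least `orf_min_len` nt (a highly
#' expressed contig without a qualifying ORF is dropped from coding
#' sets).
#'
#' @param contigs contig-set tibble.
#' @param expression output of [compute_fpkm()] covering all contigs
#'   (a missing contig is an error).
#' @param fpkm_threshold FPKM floor (kept when `fpkm >= threshold`).
#' @param coding_only require a qualifying ORF instead of raw length.
#' @param min_len minimum contig length for non-coding-mode filtering.
#' @param orf_min_len minimum longest-ORF length for coding mode.
#' @return the filtered contig set.
#' @export
filter_contigs <- function(contigs, expression, fpkm_threshold = 1,
                           coding_only = FALSE, min_len = 200L,
                           orf_min_len = 200L) {
  miss <- setdiff(contigs$id, expression$contig_id)
  if (length(miss)) {
    stop("contig(s) missing from expression table: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  fpkm <- expression$fpkm[match(contigs$id, expression$contig_id)]
  keep_expr <- fpkm >= fpkm_threshold
  keep_struct <- if (coding_only) {
    purrr::map_lgl(contigs$seq, function(s) {
      orfs <- find_orfs(s, min_len = orf_min_len)
      nrow(orfs) > 0L
    })
  } else {
    nchar(contigs$seq) >= min_len
  }
  contigs[keep_expr & keep_struct, ]
}

#' Emit the eight canonical result sets
#'
#' Writes `transcripts_fpkm_<t>.fa` (all transcripts) and
#' `coding_fpkm_<t>.fa` (coding only) for FPKM thresholds 1, 3, 5 and
#' 10: always exactly eight FASTA files, nested within each series
#' (higher threshold is a subset of lower).
#'
#' @inheritParams filter_contigs
#' @param out_dir output directory (created if needed).
#' @param thresholds FPKM thresholds, default `c(1, 3, 5, 10)`.
#' @return invisibly, a tibble `file`, `set`, `fpkm_threshold`, `n_contigs`.
#' @export
emit_result_sets <- function(contigs, expression, out_dir,
                             thresholds = c(1, 3, 5, 10),
                             min_len = 200L, orf_min_len = 200L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  rows <- list()
  for (coding in c(FALSE, TRUE)) {
    for (t in thresholds) {
      fc <- filter_contigs(contigs, expression, fpkm_threshold = t,
                           coding_only = coding, min_len = min_len,
                           orf_min_len = orf_min_len)
      file <- file.path(out_dir, sprintf("%s_fpkm_%g.fa",
                                         if (coding) "coding" else "transcripts", t))
      write_fasta(fc, file)
      rows[[length(rows) + 1L]] <- tibble(
        file = file, set = if (coding) "coding" else "all",
        fpkm_threshold = t, n_contigs = nrow(fc))
    }
  }
  invisible(bind_rows(rows))
}
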