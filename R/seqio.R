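#' Read a FASTA file into a contig set
#'
#' Record order is preserved and sequences are uppercased (soft-masked
#' lowercase bases are folded). Ids are the header up to the first
#' whitespace. Duplicate ids and empty sequences are errors.
#'
#' @param path FASTA file.
#' @return a contig-set tibble (see [contig_set()]).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(ss))
  contig_set(id = ids, seq = as.character(ss))
}

#' Write a contig set to FASTA
#'
#' @param contigs a contig-set tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path) {
  ss <- Biostrings::DNAStringSet(contigs$seq)
  names(ss) <- contigs$id
  Biostrings::writeXStringSet(ss, path, format = "fasta", width = 70L)
  invisible(path)
}

#' Read reads from FASTQ
#'
#' Base qualities are read but not used downstream: pileup counting is
#' unweighted by design.
#'
#' @param path FASTQ file (optionally a second mate file via `path2`).
#' @param path2 optional mate FASTQ for paired-end data.
#' @return tibble with `read_id`, `seq`, and for paired input `pair_id`
#'   and `mate` (1 or 2).
#' @export
read_fastq <- function(path, path2 = NULL) {
  r1 <- Biostrings::readDNAStringSet(path, format = "fastq")
  ids <- sub("\\s.*$", "", names(r1))
  if (is.null(path2)) {
    return(tibble(read_id = ids, seq = toupper(as.character(r1)),
                  pair_id = NA_character_, mate = NA_integer_))
  }
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  ids2 <- sub("\\s.*$", "", names(r2))
  strip <- function(x) sub("/[12]$", "", x)
  bind_rows(
    tibble(read_id = paste0(strip(ids), "/1"), seq = toupper(as.character(r1)),
           pair_id = strip(ids), mate = 1L),
    tibble(read_id = paste0(strip(ids2), "/2"), seq = toupper(as.character(r2)),
           pair_id = strip(ids2), mate = 2L)
  )
}

# 4-line-per-record FASTQ writer used by the read simulator.
write_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$seq))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$seq, "\n+\n", qual), con)
  invisible(path)
}

#' Parse Oases-style contig headers
#'
#' Recognises the `Locus_<n>_Transcript_<i>/<m>_Confidence_<c>_Length_<L>`
#' dialect. The pattern is configurable; ids that do not match yield `NA`
#' fields and are treated downstream as singleton loci. Lenient: never
#' errors.
#'
#' @param ids character vector of contig ids.
#' @param pattern regex with four groups: locus number, transcript index,
#'   confidence, declared length.
#' @return tibble with `id`, `locus`, `confidence`, `declared_length`.
#' @export
parse_oases_header <- function(
    ids,
    pattern = "^Locus_([0-9]+)_Transcript_([0-9]+)/[0-9]+_Confidence_([0-9.]+)_Length_([0-9]+)$") {
  m <- regmatches(ids, regexec(pattern, ids))
  grab <- function(x, i) if (length(x) >= i + 1L) x[[i + 1L]] else NA_character_
  tibble(
    id = ids,
    locus = purrr::map_chr(m, function(x)
      if (length(x)) paste0("Locus_", x[[2L]]) else NA_character_),
    confidence = as.numeric(purrr::map_chr(m, grab, 3L)),
    declared_length = as.integer(purrr::map_chr(m, grab, 4L))
  )
}

#' Annotate contig loci from their headers
#'
#' Fills the `locus` column from [parse_oases_header()]; contigs whose id
#' does not match the dialect become their own locus.
#'
#' @inheritParams parse_oases_header
#' @param contigs a contig-set tibble.
#' @return the contig set with `locus` filled.
#' @export
annotate_loci <- function(contigs, pattern = NULL) {
  parsed <- if (is.null(pattern)) parse_oases_header(contigs$id)
            else parse_oases_header(contigs$id, pattern)
  contigs$locus <- dplyr::coalesce(parsed$locus, contigs$id)
  contigs
}

#' Read a SAM file into an alignment tibble
#'
#' SAM's 1-based POS is converted to the package-wide 0-based half-open
#' convention at this boundary. Unmapped records are retained with
#' `mapped = FALSE` so mapping-rate denominators are exact. A
#' CIGAR/sequence length mismatch is an error naming the record.
#'
#' @param path SAM (or BAM) file with a header.
#' @return tibble with one row per record: `read_id`, `contig_id`,
#'   `start` (0-based), `cigar`, `strand`, `mapped`, `paired`,
#'   `proper_pair`, `first_in_pair`, `seq`.
#' @export
read_sam <- function(path) {
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  x <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "strand", "seq")))[[1]]
  aln <- tibble(
    read_id = x$qname,
    contig_id = as.character(x$rname),
    start = as.integer(x$pos) - 1L,
    cigar = x$cigar,
    strand = as.character(x$strand),
    mapped = bitwAnd(x$flag, 4L) == 0L,
    paired = bitwAnd(x$flag, 1L) > 0L,
    proper_pair = bitwAnd(x$flag, 2L) > 0L,
    first_in_pair = bitwAnd(x$flag, 64L) > 0L,
    seq = as.character(x$seq)
  )
  aln$strand[!aln$mapped] <- NA_character_
  bad <- aln$mapped & !is.na(aln$cigar) &
    cigar_query_length(aln$cigar) != nchar(aln$seq)
  if (any(bad)) {
    stop("CIGAR/sequence length mismatch for record(s): ",
         paste(utils::head(aln$read_id[bad], 5L), collapse = ", "))
  }
  aln
}

# query bases consumed by a CIGAR string (M/I/S/=/X)
cigar_query_length <- function(cigar) {
  purrr::map_int(cigar, function(cg) {
    if (is.na(cg)) return(NA_integer_)
    ops <- cigar_ops(cg)
    sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
  })
}

# reference bases consumed by a CIGAR string (M/D/N/=/X)
cigar_ref_length <- function(cigar) {
  purrr::map_int(cigar, function(cg) {
    if (is.na(cg)) return(NA_integer_)
    ops <- cigar_ops(cg)
    sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
  })
}

cigar_ops <- function(cg) {
  lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
  ops <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1]]
  list(len = lens, op = ops)
}

#' Write an alignment tibble as SAM
#'
#' Inverse of [read_sam()] for records produced by this package; 0-based
#' starts are converted back to SAM's 1-based POS.
#'
#' @param alignments alignment tibble.
#' @param contigs contig set the alignments refer to (for `@SQ` lines).
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, contigs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               paste0("@SQ\tSN:", contigs$id, "\tLN:", nchar(contigs$seq))), con)
  a <- alignments
  flag <- ifelse(a$mapped, 0L, 4L) +
    ifelse(!is.na(a$strand) & a$strand == "-", 16L, 0L) +
    ifelse(isTRUE_vec(a$paired), 1L, 0L) +
    ifelse(isTRUE_vec(a$proper_pair), 2L, 0L) +
    ifelse(isTRUE_vec(a$first_in_pair), 64L, 0L) +
    ifelse(isTRUE_vec(a$paired) & !isTRUE_vec(a$first_in_pair), 128L, 0L)
  lines <- paste(a$read_id, flag,
                 ifelse(a$mapped, a$contig_id, "*"),
                 ifelse(a$mapped, a$start + 1L, 0L),
                 ifelse(a$mapped, 60L, 0L),
                 ifelse(a$mapped, a$cigar, "*"),
                 "*", 0L, 0L, a$seq, strrep("I", nchar(a$seq)),
                 sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Build a per-position pileup for one contig
#'
#' Tallies, per contig position, read-supported bases, deletions (keyed
#' by length at their starting position) and insertions (keyed by the
#' inserted string, anchored after the position). Soft-clipped read parts
#' contribute nothing. Depth at a position is the sum of base counts plus
#' reads deleting that position.
#'
#' @param contig one-row contig-set tibble (or a row subset with one row).
#' @param alignments alignment tibble; only mapped rows targeting this
#'   contig are used. An alignment overrunning the contig end is an error.
#' @return an object of class `cp_pileup`: list with `contig_id`, `len`,
#'   `bases` (5 x len count matrix, rows A,C,G,T,N), `delcov`, `jcov`,
#'   and tibbles `dels` (`pos`, `len`, `count`) and `ins`
#'   (`pos`, `seq`, `count`), all positions 0-based.
#' @export
build_pileup <- function(contig, alignments) {
  stopifnot(nrow(contig) == 1L)
  len <- nchar(contig$seq)
  a <- dplyr::filter(alignments, .data$mapped, .data$contig_id == contig$id)
  res <- pileup_cpp(len, as.integer(a$start), a$cigar, a$seq)
  rownames(res$bases) <- c("A", "C", "G", "T", "N")
  structure(list(
    contig_id = contig$id, len = len,
    bases = res$bases, delcov = res$delcov, jcov = res$jcov,
    dels = tibble(pos = res$del_pos, len = res$del_len, count = res$del_count),
    ins = tibble(pos = res$ins_pos, seq = res$ins_seq, count = res$ins_count)
  ), class = "cp_pileup")
}

#' Per-position depth of a pileup
#' @param pileup a `cp_pileup` object.
#' @return integer vector, one entry per contig position.
#' @export
pileup_depth <- function(pileup) {
  as.integer(colSums(pileup$bases) + pileup$delcov)
}
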