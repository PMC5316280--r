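.STOPS <- c("TAA", "TAG", "TGA")

# translate a vector of codons with the standard code; unknown -> X
.translate_codons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Find open reading frames in all six frames
#'
#' An ORF is either complete (ATG through a stop codon, stop included in
#' the interval) or open-ended at a contig edge (partial, flagged via
#' `complete5`/`complete3`). Any-stop-to-stop regions without an ATG and
#' away from the edges are not reported. Reverse-strand ORFs are
#' reported with forward-strand coordinates. Results are sorted by
#' nucleotide length descending.
#'
#' @param seq nucleotide string (or one-row contig-set tibble).
#' @param min_len minimum ORF length in nucleotides (stop codon
#'   included for complete ORFs). Default 200, the coding-transcript
#'   selection floor used throughout the pipeline.
#' @return tibble: `start`, `end` (0-based half-open, forward strand),
#'   `strand`, `frame` (0-2 on the reported strand), `complete5`,
#'   `complete3`, `nt_len`, `protein` (stop excluded).
#' @export
find_orfs <- function(seq, min_len = 200L) {
  if (is.data.frame(seq)) seq <- seq$seq[[1]]
  seq <- toupper(seq)
  n <- nchar(seq)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (f in 0:2) {
      ncod <- (n - f) %/% 3L
      if (ncod < 1L) next
      starts <- f + 1L + 3L * (seq_len(ncod) - 1L)
      codons <- substring(s, starts, starts + 2L)
      stops <- which(codons %in% .STOPS)
      seg_lo <- c(1L, stops + 1L)
      seg_hi <- c(stops, ncod)         # stop codon included in its segment
      seg_has_stop <- c(rep(TRUE, length(stops)), FALSE)
      for (g in seq_along(seg_lo)) {
        lo <- seg_lo[g]; hi <- seg_hi[g]
        if (lo > hi) next
        body_hi <- if (seg_has_stop[g]) hi - 1L else hi
        if (body_hi < lo) next
        atg <- which(codons[lo:body_hi] == "ATG")
        if (length(atg)) {
          c0 <- lo + atg[1L] - 1L
          complete5 <- TRUE
        } else if (lo == 1L) {
          c0 <- lo                      # open at the 5' contig edge
          complete5 <- FALSE
        } else {
          next
        }
        c1 <- hi
        complete3 <- seg_has_stop[g]
        nt_len <- (c1 - c0 + 1L) * 3L
        if (nt_len < min_len) next
        body <- codons[c0:(if (complete3) c1 - 1L else c1)]
        prot <- if (length(body)) .translate_codons(body) else ""
        st <- f + (c0 - 1L) * 3L        # 0-based on this strand
        en <- f + c1 * 3L
        if (strand == "-") { tmp <- st; st <- n - en; en <- n - tmp }
        res[[length(res) + 1L]] <- tibble(
          start = st, end = en, strand = strand, frame = f,
          complete5 = complete5, complete3 = complete3,
          nt_len = nt_len, protein = prot)
      }
    }
  }
  if (!length(res)) {
    return(tibble(start = integer(), end = integer(), strand = character(),
                  frame = integer(), complete5 = logical(),
                  complete3 = logical(), nt_len = integer(),
                  protein = character()))
  }
  bind_rows(res) |> arrange(desc(.data$nt_len), .data$start, .data$strand)
}

# greedy maximal set of mutually non-overlapping complete ORFs, longest first
.nonoverlapping_complete <- function(orfs, min_len) {
  comp <- dplyr::filter(orfs, .data$complete5, .data$complete3,
                        .data$nt_len >= min_len)
  if (!nrow(comp)) return(comp)
  comp <- arrange(comp, desc(.data$nt_len), .data$start)
  picked <- comp[0, ]
  for (i in seq_len(nrow(comp))) {
    o <- comp[i, ]
    if (!nrow(picked) ||
        all(o$end <= picked$start | o$start >= picked$end)) {
      picked <- bind_rows(picked, o)
    }
  }
  arrange(picked, .data$start)
}

#' Split multi-ORF (multi-transcript chimera) contigs
#'
#' A contig carrying two or more complete, mutually non-overlapping ORFs
#' is treated as a multi-transcript chimera and cut at the midpoint of
#' each inter-ORF gap, apportioning the intervening UTR sequence evenly;
#' each piece contains exactly one of those ORFs. Partial ORFs never
#' trigger splitting. Anything else passes through unchanged.
#'
#' @param contig one-row contig-set tibble.
#' @param orfs ORFs from [find_orfs()] on the same contig; found
#'   internally when `NULL`.
#' @param min_len minimum complete-ORF length (nt) to count.
#' @return contig-set tibble: either the input row or the split
#'   fragments (`source = "split-fragment"`, ids suffixed `.1`, `.2`, ...).
#' @export
split_multi_orf <- function(contig, orfs = NULL, min_len = 200L) {
  stopifnot(nrow(contig) == 1L)
  if (is.null(orfs)) orfs <- find_orfs(contig$seq, min_len = min_len)
  picked <- .nonoverlapping_complete(orfs, min_len)
  if (nrow(picked) < 2L) return(contig)
  n <- nchar(contig$seq)
  cuts <- (picked$end[-nrow(picked)] + picked$start[-1L]) %/% 2L
  lo <- c(0L, cuts); hi <- c(cuts, n)
  tibble(
    id = paste0(contig$id, ".", seq_along(lo)),
    seq = substring(contig$seq, lo + 1L, hi),
    locus = contig$locus, asm_depth = contig$asm_depth,
    source = "split-fragment", parent = contig$id)
}

#' Count of multi-ORF contigs
#'
#' @param contigs contig-set tibble.
#' @param min_len minimum complete-ORF length (nt).
#' @return logical vector: does each contig carry >= 2 complete,
#'   non-overlapping ORFs of at least `min_len`?
#' @export
is_multi_orf <- function(contigs, min_len = 200L) {
  purrr::map_lgl(contigs$seq, function(s) {
    nrow(.nonoverlapping_complete(find_orfs(s, min_len), min_len)) >= 2L
  })
}
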