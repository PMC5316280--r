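#' @keywords internal
"_PACKAGE"

#' @useDynLib contigpolish, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join row_number desc n
#' @importFrom tibble tibble as_tibble
NULL

# Complement lookup shared by revcomp helpers
.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement nucleotide strings
#'
#' Vectorised over its input; non-ACGT characters map to N.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between two equal-length strings (byte-wise, fast).
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(a) != charToRaw(b))
}

# All k-mer start positions of `kmer`-length words in `seq`, as character vector.
seq_kmers <- function(seq, k, step = 1L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq.int(1L, n - k + 1L, by = step)
  substring(seq, starts, starts + k - 1L)
}

#' Construct a contig set
#'
#' A contig set is a tibble with one row per contig: `id` (unique), `seq`
#' (uppercase nucleotides), optional Oases `locus`, optional assembler
#' depth `asm_depth`, a provenance `source` tag and, for split fragments,
#' the `parent` id.
#'
#' @param id character vector of unique contig ids.
#' @param seq character vector of nucleotide sequences.
#' @param locus optional locus keys (connected component of the assembly
#'   graph); `NA` means the contig is its own locus.
#' @param asm_depth optional assembler-reported coverage depth.
#' @param source provenance: one of `"original"`, `"split-fragment"`,
#'   `"merged"`, `"corrected"`.
#' @param parent parent contig id for split fragments.
#' @return a contig-set tibble.
#' @export
contig_set <- function(id = character(), seq = character(),
                       locus = NA_character_, asm_depth = NA_real_,
                       source = "original", parent = NA_character_) {
  seq <- toupper(seq)
  out <- tibble(
    id = as.character(id), seq = as.character(seq),
    locus = as.character(locus), asm_depth = as.numeric(asm_depth),
    source = as.character(source), parent = as.character(parent)
  )
  validate_contig_set(out)
}

validate_contig_set <- function(x) {
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  if (anyDuplicated(x$id)) {
    stop("duplicate contig id(s): ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "))
  }
  if (nrow(x) && any(!nzchar(x$seq))) {
    stop("empty sequence for contig(s): ",
         paste(x$id[!nzchar(x$seq)], collapse = ", "))
  }
  for (col in c("locus", "source", "parent")) {
    if (!col %in% names(x)) x[[col]] <- NA_character_
  }
  if (!"asm_depth" %in% names(x)) x$asm_depth <- NA_real_
  as_tibble(x)
}

#' Contig lengths
#' @param contigs a contig-set tibble.
#' @return integer vector of sequence lengths.
#' @export
contig_lengths <- function(contigs) nchar(contigs$seq)

# deterministic seed derivation for sub-tasks, kept below 2^31
derive_seed <- function(seed, salt) {
  (as.integer(seed) * 69069L + as.integer(salt)) %% 2147483587L
}
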