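---
title: "Polishing de novo transcriptome assemblies: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polishing de novo transcriptome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(contigpolish)
```

## The problem

De novo transcriptome assemblers (Trinity, Oases and their kin) produce
contig sets that represent the transcriptome well but carry systematic
defects: many redundant copies of complete or partial transcripts
(especially from multi-k assembly strategies), chimeric contigs
(self-chimeras that duplicate part of a transcript within one contig,
and multi-transcript chimeras that concatenate unrelated transcripts),
consensus base errors and small indels that break reading frames, polyA
tails, and lowly covered contigs that reflect transcriptional or
sequencing noise rather than genes. `contigpolish` implements the
post-assembly stages that repair these defects — compaction,
correction, expression filtering and quality assessment — as a tidy R
library plus a thin command-line wrapper, together with a seeded
synthetic-data generator so that every stage can be exercised and
verified without external datasets.

All user-facing functions take a data frame first and return tibbles.
A contig set is a tibble with columns `id`, `seq`, `locus`,
`asm_depth`, `source` and `parent`; alignments, pileups, expression
tables, truth tables and reports are likewise tabular, so the whole
pipeline composes with the pipe.

## Compaction

Redundancy is removed in three steps, in the order they run in
`run_polish()`:

1. **Best contig per locus** (`choose_best_per_locus()`). Assemblers
   that report the graph component ("locus") of each contig emit
   several alternative contigs per locus which are usually subsequences
   of one another. One contig per locus is kept, selected by length,
   then assembler-reported depth, then id. The selection key is
   lexicographic because no principled combined score of length and
   depth presents itself, and length dominates every downstream metric;
   the id tie-break makes the choice deterministic.
2. **Inclusion removal** (`remove_included()`). Contigs are processed
   longest first; a contig contained in an already-kept contig at
   ≥ 96% identity over ≥ 99% of its own length (both strands) is
   dropped. After this pass the inclusion rate of the kept set is zero
   by construction — re-running the removal finds nothing.
3. **Overlap merging** (`overlap_merge()`). A deliberately simplified
   stand-in for a full overlap-layout-consensus assembly step: pairs of
   contigs whose suffix–prefix overlap is at least 40 nt at ≥ 96%
   identity are merged greedily, longest overlap first, taking the
   overlap consensus from the longer contig, iterated to a fixpoint.
   This captures the gene-part-joining effect of a dedicated clustering
   assembler at a small fraction of its complexity; it does not attempt
   multi-way consensus. The greedy order plus deterministic tie-breaks
   make the fixpoint independent of input order.

`meta_merge()` extends compaction across independently assembled
sample sets: pooled nucleotide containment clustering first, then a
protein-level pass that clusters contigs whose longest-ORF translations
align at ≥ 95% identity over ≥ 90% of the shorter protein — catching
redundant contigs that differ by synonymous codon choices — keeping the
longest nucleotide member. Contigs without a qualifying ORF skip the
protein pass. The operation is idempotent.

## Correction

### Self-chimera detection

A contig is aligned against itself and its reverse complement
(`self_local_matches()`: k-mer diagonal seeding, run merging, exact end
extension; the trivial full-length identity diagonal is never
reported). Matches below 96% identity or shorter than 60 nt are
ignored — sub-60-nt repeats cannot drive the coverage rules on
realistically sized contigs. Two published rules then classify the
contig (`classify_self_chimera()`):

* **Rule (i)**: the longest self-match covers at least 60% of the
  contig (footprint = union of its two copies). The contig is split at
  the start of the downstream copy, keeping the 5'-most copy intact.
* **Rule (ii)**: greedily chosen non-overlapping match footprints
  cover at least 80% of the contig: the contig is only a repetition of
  a short block and is discarded.

Two interpretation choices deserve note, because the coverage
arithmetic is not fully specified by the rules themselves. First,
"covers" is read as the union footprint of a match's two copies
relative to contig length. Second, rule (i) applies only when the two
copies of the longest match are essentially disjoint (a tolerance of
max(10 nt, 5% of the match) absorbs chance single-base end
extensions): a longest match whose copies overlap each other is the
signature of tandem periodicity — the match between the array and
itself shifted by one unit — and such contigs fall through to rule
(ii), which correctly discards them. Without this distinction a
50-nt-unit tandem array would be "split" one unit in rather than
discarded.

Splitting emits fragments `<id>.1` / `<id>.2`; fragments shorter than
200 nt are dropped, and near-duplicate fragments (e.g. the two halves
of a perfect duplication) are deliberately left for the later
inclusion-removal pass to absorb.

### Consensus polishing

Reads are aligned to the contigs and tallied into per-position pileups
of bases, deletions (keyed by length at their start position) and
insertions (keyed by inserted string, anchored after a position). At
every position with **depth ≥ 10**, the allele carried by a **strict
majority** of reads replaces the consensus (`majority_correct()`).
Three conservative choices:

* Ties and mere pluralities leave the consensus unchanged — "most
  represented" is read as a strict majority, which avoids oscillation
  between passes.
* N never wins a vote; it is absence of evidence.
* An insertion is installed only when reads carrying that exact
  insertion strictly outnumber all junction-spanning reads without
  one.

Edits are applied right-to-left so recorded positions stay in input
coordinates. The whole step runs **twice** (`two_pass_correct()`):
after the first pass some reads change alignment location, and the
second pass exploits them; on synthetic data the second pass is almost
always silent, which is also the convergence check the tests use.

The bundled micro-mapper (`map_reads_simple()`) seeds with exact
21-mers, extends without gaps, and picks the placement with the fewest
mismatches (ties: contig id, then position). When the best ungapped
placement exceeds the mismatch budget, a single-pass rescue tries every
placement of one 1-nt insertion or deletion. This rescue is what lets
pileups carry the indel alleles that majority voting needs to repair
assembler frameshifts; a strictly ungapped mapper could never produce
deletion or insertion evidence. External SAM alignments
(`read_sam()`) are interchangeable with the internal mapper — the
internal one is meant for desk-scale work and testing, not
production-scale mapping.

### TSA cleaning

`tsa_clean()` applies archive-submission hygiene: trim the maximal 3'
terminal segment with ≥ 90% A content and ≥ 10 nt (and the symmetric
5' polyT), trim terminal Ns, split at internal runs of ≥ 14 Ns, and
drop pieces under 200 nt. The numeric knobs are package defaults
standing in for archive guidelines that are distributed as prose; all
are configurable. Adapter/vector screening is out of scope because it
requires an external contaminant database.

### Multi-ORF splitting

A contig with two or more complete, mutually non-overlapping ORFs of
≥ 200 nt is treated as a multi-transcript chimera and cut at the
midpoint of each inter-ORF gap (`split_multi_orf()`), apportioning the
intervening UTR evenly — a symmetric choice where no evidence favours
either side. Partial ORFs never trigger splitting: multi-ORF is
equated with multi-transcript chimerism, which implies separable
complete coding units. ORFs are ATG-initiated or open at contig edges
(`find_orfs()`, all six frames, standard code); any-stop-to-stop mode
is not used.

## Expression filtering and the eight result sets

A fragment is one mapped read pair (counted once, on the shared
contig) or one mapped orphan/single read. FPKM is
`fragments × 1e9 / (contig_length × total_mapped_fragments)`
(`compute_fpkm()`); fragment counts are conserved by construction.
Discordant pairs count once on each contig — a conservation-preserving
reading, since the counting rule for such pairs is underdetermined.
`filter_contigs()` keeps a contig when `FPKM ≥ threshold` (the
boundary is inclusive) and it passes the structural rule: raw length
≥ 200 nt, or, for the coding series, a longest ORF ≥ 200 nt — a
highly expressed contig without a qualifying ORF (e.g. an rRNA
fragment) is dropped from the coding sets. `emit_result_sets()` always
writes exactly eight FASTA files, `{all, coding} × FPKM {1, 3, 5, 10}`,
nested within each series by the monotonicity of the threshold.

## Quality assessment

`assess_assembly()` computes, read-only:

* contig metrics — N50 (length at which the cumulative sorted length
  first reaches half the total), L50, sum, median;
* defect rates — inclusions, multi-ORF contigs, self-chimeras — by
  running the compaction/correction classifiers in read-only mode;
* mapping rates over all reads including unmapped ones (properly
  paired is `NA` for single-end data);
* protein reconstruction — a reference protein counts when some contig
  aligns to it with identity and protein coverage both strictly over
  80% ("over" is read strictly), via a translated search: six-frame
  translations split at stops, local alignment under BLOSUM62;
* transcript linking — the best hit per reference transcript counts as
  a link when query identity and coverage both exceed 90%;
* exon fidelity — an exon is retrieved if it places anywhere at over
  90/90; in the right contig if its best placement is on the contig
  its transcript links to (score ties resolve in favour of the linked
  contig, so exons shared between isoforms do not spuriously fail); in
  the right order if its rank among its transcript's placed exons,
  along the link strand, equals its annotated rank. Rank agreement on
  a single strand is a declared reconstruction of the order check — no
  inversion tolerance is attempted.

Reports serialise to JSON with stable keys (`write_report()`), carry
explicit nulls for unavailable fields (external TransRate/BUSCO-style
scores are import-only and otherwise null), and have `tidy()`,
`glance()` and `autoplot()` methods.

## The synthetic-data generator

The generator stands in for real read sets and assemblies so the
pipeline is testable offline; all three functions are pure functions of
their parameters and seed.

* `gen_transcriptome()` plants complete ORFs (ATG…stop, occupying
  80–90% of the transcript; UTRs are kept modest so that chimera
  splitting leaves linkable pieces) in transcripts of 500–2500 nt cut
  into 2–8 exons of ≥ 60 nt; a fraction of genes (default 20%) carries
  a second, exon-skipping isoform. The default `orf_fraction = 1`
  models an mRNA-only reference; lowering it adds noncoding
  transcripts, with the caveat that kilobase-scale random sequence
  contains chance ORFs ≥ 200 nt at an appreciable rate, which the
  multi-ORF splitter may act on.
* `sim_reads()` draws per-transcript expression log-normally (sdlog 1
  by default — a generic stand-in for an empirical expression fit, not
  fitted to any dataset), places fragments uniformly (mean 250 nt,
  sd 25), and applies independent per-base substitution errors
  (default 1%). Indel sequencing errors are not simulated; length-1
  indel evidence reaches the pileup through consensus-indel
  constructions instead.
* `corrupt_assembly()` injects one defect class per affected
  transcript at fixed rounded rates: redundant copies (half truncated),
  extra 50–90% truncated copies, self-chimeras built to satisfy the
  60% footprint rule (cis or trans), multi-transcript chimeras of two
  ORF-bearing transcripts (cis or trans), 2–4 consensus substitutions
  plus an optional 1-nt indel, and 15–40 nt polyA tails. Truncation is
  injected as an extra truncated copy alongside the intact transcript
  (mirroring how assemblers emit partial alternatives); replacing the
  transcript with its truncation would make full-length recovery
  impossible by construction rather than by pipeline failure. Every
  contig carries exactly one truth record.

What the generator does **not** emulate: quality-score profiles,
coverage biases (GC, positional), intron retention / pre-mRNA,
sequence-sharing gene families, and contamination. Passing tests
therefore demonstrate the correctness of the rules and their
composition under controlled defects, not performance on real tissue
libraries — on real data the alignment-dependent steps inherit the
error profile of the chosen aligner.

## Pipeline order and checkpointing

`run_polish()` chains: best-per-locus → inclusion removal → overlap
merge → self-chimera split → two-pass consensus correction → multi-ORF
split → TSA clean → **second inclusion removal** → expression →
result sets → report. The second removal exists because chimera and
multi-ORF splitting create fragments that duplicate kept sequence;
running containment removal once more guarantees the published
invariant that the final inclusion rate is null. Each stage writes a
checkpoint (TSV of the contig state plus a done-marker); re-invocation
with `resume = TRUE` restarts after the last error-free step, a failing
stage leaves an error file named for the stage, and `write_only = TRUE`
writes the execution plan without running anything. `run_meta()` and
`run_assess()` follow the same conventions; `run_assess()` never
modifies its inputs.

The `exec/contigpolish` script exposes `simulate`, `polish`, `meta` and
`assess` subcommands over these functions; all scientific logic lives
in the package.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere inside the package; the
  SAM convention is converted exactly once, at the I/O boundary.
* Identity is matches over aligned columns, gaps counted; coverage is
  always computed on the query (the shorter/reference sequence).
* Alignment scoring for containment and linking is match +1, mismatch
  −2, gap opening 3, extension 2; protein alignment uses BLOSUM62 with
  gap 10/0.5. Self-alignment seeding uses 15-mers with a 120-nt
  seed-gap merge and a 100-occurrence low-complexity guard.
* Empty contig sets propagate as empty tibbles (eight empty result
  files, zero defect rates); `contig_metrics()` on an empty set is an
  error, as no N50 exists.
* All randomised components accept an explicit seed and derive
  sub-seeds below 2^31.

## Problem sizes

The bundled verification (tests and the acceptance script) runs at
desk scale, chosen so the full suite completes in minutes on one CPU:
transcriptomes of 100–200 transcripts (0.1–0.3 Mb), 20× simulated
coverage (~60k reads), 300-contig chimera panels, and oracle
cross-checks on 10–50-sequence fixtures (brute-force containment,
six-frame ORF scan, exhaustive 80/80 and 90/90 enumeration, cumulative
N50 walk). These sizes exercise every rule at full fidelity; scaling
to real assemblies is a matter of substituting an external aligner's
SAM for the internal mapper and is linear in the read count for
correction and quadratic (with k-mer prefilters) in contig count for
compaction.

## Known limitations

* The overlap merger is a greedy suffix–prefix joiner, not an OLC
  assembler; complex multi-way overlaps resolve pairwise.
* Consensus correction at positions below 10× stays untouched by
  design; low-expression transcripts retain their assembler errors.
* The multi-ORF splitter can split a noncoding contig that happens to
  contain two chance complete ORFs; with coding-dominated input this
  is rare, and the affected fragments are still absorbed by the final
  containment pass when redundant.
* Exon order checking tolerates no inversions and uses rank agreement
  only.
* Protein hits on contigs whose reading frame is interrupted by a stop
  are confined to one stop-free segment; heavily frameshifted contigs
  under-count reconstructed proteins (which is also what makes the
  metric sensitive to consensus errors, and is why correction improves
  it).
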