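#' Default polishing configuration
#'
#' All thresholds of the post-assembly pipeline in one list; every value
#' can be overridden by name in [run_polish()].
#'
#' @param ... overrides by name.
#' @return named list of parameters.
#' @export
polish_config <- function(...) {
  cfg <- list(
    best_per_locus = TRUE, oases_pattern = NULL,
    containment_identity = 0.96, containment_coverage = 0.99,
    merge = TRUE, min_overlap_len = 40L, min_overlap_identity = 0.96,
    self_min_identity = 0.96, self_min_match_len = 60L,
    chimera_cov_single = 0.60, chimera_cov_sum = 0.80,
    min_fragment_len = 200L,
    min_depth = 10L, mapper_k = 21L, mapper_max_mismatch = 3L,
    orf_min_len = 200L,
    polya_min_run = 10L, polya_purity = 0.9, n_split_run = 14L,
    min_len = 200L, fpkm_thresholds = c(1, 3, 5, 10),
    seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

# ---- checkpoint plumbing -------------------------------------------------

.save_contigs_tsv <- function(contigs, path) {
  utils::write.table(contigs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

.load_contigs_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(id = "character", seq = "character",
                                         locus = "character",
                                         asm_depth = "numeric",
                                         source = "character",
                                         parent = "character"),
                          na.strings = "NA")
  validate_contig_set(as_tibble(df))
}

#' Inspect the checkpoint state of a pipeline directory
#'
#' @param out_dir a [run_polish()] working directory.
#' @return tibble `step`, `status` (`done` / `failed` / `pending`).
#' @export
polish_state <- function(out_dir) {
  plan <- file.path(out_dir, "plan.json")
  if (!file.exists(plan)) stop("no pipeline plan under ", out_dir)
  steps <- jsonlite::read_json(plan, simplifyVector = TRUE)$steps
  status <- purrr::map_chr(steps, function(s) {
    if (file.exists(file.path(out_dir, "steps", paste0(s, ".done")))) "done"
    else if (file.exists(file.path(out_dir, "steps", paste0(s, ".error"))))
      "failed"
    else "pending"
  })
  tibble(step = steps, status = status)
}

#' Run the full post-assembly polishing pipeline
#'
#' Stage order: best-contig-per-locus (when locus headers are present),
#' inclusion removal, overlap merging, self-chimera splitting, two-pass
#' majority-allele consensus correction (when reads are supplied),
#' multi-ORF splitting, TSA cleaning, a second inclusion removal that
#' absorbs near-duplicate split fragments, expression quantification,
#' the eight FPKM result sets and the metrics report. Every stage writes
#' its output and a checkpoint marker under `out_dir/steps/`; with
#' `resume = TRUE` a re-invocation skips stages already done and
#' restarts after the last error-free step. A failing stage leaves a
#' `<step>.error` file naming the stage.
#'
#' @param assembly a contig-set tibble or FASTA path.
#' @param reads a read tibble ([read_fastq()]) or FASTQ path(s)
#'   (`c(R1)` or `c(R1, R2)`); optional, but required for consensus
#'   correction, mapping rates and informative FPKM filtering.
#' @param out_dir working/result directory.
#' @param config a [polish_config()] list.
#' @param resume resume from existing checkpoints instead of starting
#'   clean.
#' @param write_only write the execution plan and directories, run
#'   nothing (inspect/modify, then re-invoke to run).
#' @return invisibly, a list: `contigs` (final set), `expression`,
#'   `report`, `out_dir`, `result_sets`.
#' @export
run_polish <- function(assembly, reads = NULL, out_dir,
                       config = polish_config(), resume = FALSE,
                       write_only = FALSE) {
  if (is.character(assembly)) assembly <- read_fasta(assembly)
  if (is.character(reads)) {
    reads <- if (length(reads) == 2L) read_fastq(reads[1], reads[2])
             else read_fastq(reads)
  }
  dir.create(file.path(out_dir, "steps"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "result_sets"), showWarnings = FALSE)

  steps <- c("01_best_per_locus", "02_remove_included", "03_overlap_merge",
             "04_chimera", "05_consensus", "06_orf_split", "07_tsa_clean",
             "08_dedup", "09_expression", "10_result_sets", "11_report")
  jsonlite::write_json(list(tool = "polish", steps = steps,
                            config = config[order(names(config))]),
                       file.path(out_dir, "plan.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  if (write_only) {
    message("plan written to ", file.path(out_dir, "plan.json"),
            "; re-run without write_only to execute")
    return(invisible(list(out_dir = out_dir, plan = steps)))
  }
  if (!resume) {
    unlink(list.files(file.path(out_dir, "steps"), full.names = TRUE))
  }

  state <- new.env(parent = emptyenv())
  state$contigs <- assembly
  state$alignments <- NULL
  state$expression <- NULL

  ckpt_fa <- function(step) file.path(out_dir, "steps", paste0(step, ".tsv"))
  done <- function(step) file.path(out_dir, "steps", paste0(step, ".done"))

  run_step <- function(step, fn, save_contigs = TRUE) {
    if (resume && file.exists(done(step))) {
      if (save_contigs && file.exists(ckpt_fa(step))) {
        state$contigs <- .load_contigs_tsv(ckpt_fa(step))
      }
      return(invisible(NULL))
    }
    ok <- tryCatch({
      fn()
      TRUE
    }, error = function(e) {
      writeLines(conditionMessage(e),
                 file.path(out_dir, "steps", paste0(step, ".error")))
      stop("pipeline stage '", step, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    if (save_contigs) .save_contigs_tsv(state$contigs, ckpt_fa(step))
    file.create(done(step))
    invisible(NULL)
  }

  aligner <- function(rd, cs) {
    map_reads_simple(rd, cs, k = config$mapper_k,
                     max_mismatch = config$mapper_max_mismatch)
  }

  run_step("01_best_per_locus", function() {
    if (isTRUE(config$best_per_locus)) {
      cs <- annotate_loci(state$contigs, config$oases_pattern)
      state$contigs <- choose_best_per_locus(cs)
    }
  })
  run_step("02_remove_included", function() {
    state$contigs <- remove_included(state$contigs,
                                     config$containment_identity,
                                     config$containment_coverage)$kept
  })
  run_step("03_overlap_merge", function() {
    if (isTRUE(config$merge)) {
      state$contigs <- overlap_merge(state$contigs, config$min_overlap_len,
                                     config$min_overlap_identity)
    }
  })
  run_step("04_chimera", function() {
    calls <- bind_rows(purrr::map(seq_len(nrow(state$contigs)), function(i) {
      classify_self_chimera(state$contigs[i, ],
                            cov_single = config$chimera_cov_single,
                            cov_sum = config$chimera_cov_sum,
                            min_identity = config$self_min_identity)
    }))
    utils::write.table(calls, file.path(out_dir, "chimera_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    state$contigs <- apply_chimera_calls(state$contigs, calls,
                                         config$min_fragment_len)
  })
  run_step("05_consensus", function() {
    if (!is.null(reads)) {
      res <- two_pass_correct(state$contigs, reads, aligner,
                              config$min_depth)
      state$contigs <- res$contigs
      utils::write.table(bind_rows(p1 = res$pass1_edits, p2 = res$pass2_edits,
                                   .id = "pass"),
                         file.path(out_dir, "consensus_edits.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  })
  run_step("06_orf_split", function() {
    state$contigs <- validate_contig_set(bind_rows(purrr::map(
      seq_len(nrow(state$contigs)),
      function(i) split_multi_orf(state$contigs[i, ],
                                  min_len = config$orf_min_len))))
  })
  run_step("07_tsa_clean", function() {
    state$contigs <- tsa_clean_set(state$contigs, config$polya_min_run,
                                   config$polya_purity, config$n_split_run,
                                   config$min_len)
  })
  run_step("08_dedup", function() {
    state$contigs <- remove_included(state$contigs,
                                     config$containment_identity,
                                     config$containment_coverage)$kept
    write_fasta(state$contigs, file.path(out_dir, "contigs.fa"))
  })
  run_step("09_expression", function() {
    if (!is.null(reads)) {
      state$alignments <- aligner(reads, state$contigs)
      state$expression <- compute_fpkm(state$alignments, state$contigs)
    } else {
      state$expression <- tibble(contig_id = state$contigs$id,
                                 length_nt = nchar(state$contigs$seq),
                                 fragments = NA_integer_, fpkm = Inf)
    }
    utils::write.table(state$expression,
                       file.path(out_dir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }, save_contigs = FALSE)
  run_step("10_result_sets", function() {
    if (is.null(state$expression)) {
      state$expression <- .load_expression(out_dir, state$contigs)
    }
    state$result_sets <- emit_result_sets(
      state$contigs, state$expression, file.path(out_dir, "result_sets"),
      thresholds = config$fpkm_thresholds, min_len = config$min_len,
      orf_min_len = config$orf_min_len)
  }, save_contigs = FALSE)
  run_step("11_report", function() {
    state$report <- assess_assembly(state$contigs,
                                    alignments = state$alignments,
                                    name = basename(out_dir))
    write_report(state$report, file.path(out_dir, "report.json"))
  }, save_contigs = FALSE)

  invisible(list(contigs = state$contigs, expression = state$expression,
                 report = state$report, out_dir = out_dir,
                 result_sets = state$result_sets))
}

.load_expression <- function(out_dir, contigs) {
  p <- file.path(out_dir, "expression.tsv")
  if (file.exists(p)) {
    as_tibble(utils::read.table(p, sep = "\t", header = TRUE,
                                colClasses = c(contig_id = "character")))
  } else {
    tibble(contig_id = contigs$id, length_nt = nchar(contigs$seq),
           fragments = NA_integer_, fpkm = Inf)
  }
}

#' Merge several polished assemblies (meta-assembly)
#'
#' Loads the final contig set of each polishing run (or takes contig
#' sets directly), merges them with [meta_merge()], quantifies
#' expression when reads are given, and writes the eight result sets
#' plus a report.
#'
#' @param inputs list of [run_polish()] output directories or contig-set
#'   tibbles (typically two or more).
#' @param out_dir result directory.
#' @param reads optional read tibble or FASTQ path(s).
#' @param config a [polish_config()] list.
#' @return invisibly, list `contigs`, `expression`, `report`, `out_dir`.
#' @export
run_meta <- function(inputs, out_dir, reads = NULL,
                     config = polish_config()) {
  if (!length(inputs)) stop("run_meta needs at least one polished input")
  sets <- purrr::map(inputs, function(x) {
    if (is.character(x)) {
      fa <- file.path(x, "contigs.fa")
      if (!file.exists(fa)) stop("missing polished contig set: ", fa)
      read_fasta(fa)
    } else {
      validate_contig_set(x)
    }
  })
  if (is.character(reads)) {
    reads <- if (length(reads) == 2L) read_fastq(reads[1], reads[2])
             else read_fastq(reads)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  merged <- meta_merge(sets, nuc_identity = config$containment_identity,
                       orf_min_len = config$orf_min_len)
  write_fasta(merged, file.path(out_dir, "contigs.fa"))
  aln <- NULL
  expr <- if (!is.null(reads)) {
    aln <- map_reads_simple(reads, merged, k = config$mapper_k,
                            max_mismatch = config$mapper_max_mismatch)
    compute_fpkm(aln, merged)
  } else {
    tibble(contig_id = merged$id, length_nt = nchar(merged$seq),
           fragments = NA_integer_, fpkm = Inf)
  }
  emit_result_sets(merged, expr, file.path(out_dir, "result_sets"),
                   thresholds = config$fpkm_thresholds,
                   min_len = config$min_len,
                   orf_min_len = config$orf_min_len)
  report <- assess_assembly(merged, alignments = aln,
                            name = basename(out_dir))
  write_report(report, file.path(out_dir, "report.json"))
  invisible(list(contigs = merged, expression = expr, report = report,
                 out_dir = out_dir))
}

#' Assess one or more assemblies side by side
#'
#' Read-only: input contig sets are never modified. When reads are
#' given they are mapped to each assembly with the internal mapper to
#' produce mapping rates.
#'
#' @param assemblies named list of contig-set tibbles or FASTA paths.
#' @param out_dir report directory.
#' @param reads optional read tibble or FASTQ path(s).
#' @param proteins,transcripts optional reference tibbles (`id`, `seq`)
#'   or FASTA paths.
#' @param exons optional exon models (`transcript_id`, `exon_rank`,
#'   `seq`) or TSV path.
#' @param gene_map optional `transcript_id`/`gene_id` tibble or TSV path.
#' @param config a [polish_config()] list (mapper settings).
#' @return invisibly, list `reports` (one `cp_report` per assembly) and
#'   `comparison` (tibble).
#' @export
run_assess <- function(assemblies, out_dir, reads = NULL, proteins = NULL,
                       transcripts = NULL, exons = NULL, gene_map = NULL,
                       config = polish_config()) {
  if (!length(assemblies)) stop("run_assess needs at least one assembly")
  if (is.null(names(assemblies))) {
    names(assemblies) <- paste0("assembly_", seq_along(assemblies))
  }
  load_fa <- function(x) if (is.character(x)) read_fasta(x)
                         else validate_contig_set(x)
  load_tsv <- function(x) {
    if (is.character(x)) as_tibble(utils::read.table(x, sep = "\t",
                                                     header = TRUE))
    else x
  }
  if (is.character(reads)) {
    reads <- if (length(reads) == 2L) read_fastq(reads[1], reads[2])
             else read_fastq(reads)
  }
  if (is.character(proteins)) {
    pp <- read_fasta_aa(proteins)
    proteins <- pp
  }
  if (is.character(transcripts)) transcripts <- read_fasta(transcripts)
  exons <- if (!is.null(exons)) load_tsv(exons)
  gene_map <- if (!is.null(gene_map)) load_tsv(gene_map)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  reports <- purrr::imap(assemblies, function(a, nm) {
    cs <- load_fa(a)
    aln <- if (!is.null(reads)) {
      map_reads_simple(reads, cs, k = config$mapper_k,
                       max_mismatch = config$mapper_max_mismatch)
    }
    rep <- assess_assembly(cs, alignments = aln, proteins = proteins,
                           transcripts = transcripts, exons = exons,
                           gene_map = gene_map, name = nm)
    write_report(rep, file.path(out_dir, paste0("report_", nm, ".json")))
    rep
  })
  comparison <- compare_reports(reports)
  jsonlite::write_json(comparison, file.path(out_dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(list(reports = reports, comparison = comparison))
}

#' Read an amino-acid FASTA
#' @param path protein FASTA file.
#' @return tibble `id`, `seq`.
#' @export
read_fasta_aa <- function(path) {
  ss <- Biostrings::readAAStringSet(path, format = "fasta")
  tibble(id = sub("\\s.*$", "", names(ss)), seq = as.character(ss))
}
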