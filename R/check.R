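#' Check the strandedness of a paired-end RNA-seq library
#'
#' End-to-end pipeline: load the transcriptome (optionally attaching genome
#' strands from a GTF), build or load the k-mer index, sample read pairs,
#' classify each pair's orientation, tally, and produce a
#' [strandedness_report()] with a verdict. The GTF is optional: all
#' decisions are made in transcript (sense/antisense) space; without it
#' only the RSeQC per-pair code strings are unavailable.
#'
#' @param reads_1,reads_2 Paths to the mate-1 / mate-2 FASTQ files (plain
#'   or gzipped). Alternatively `reads_1` may be a `read_pairs` object
#'   (e.g. simulator output), in which case `reads_2` is ignored and no
#'   sampling is performed beyond `n_pairs`.
#' @param transcripts Transcriptome FASTA path or
#'   [Biostrings::DNAStringSet]; required unless `index` is given.
#' @param gtf Optional GTF path for genome strands (reporting only).
#' @param index Optional: a `kmer_index` object or the path of an index
#'   artifact from [save_index()]; skips rebuilding.
#' @param n_pairs Read pairs to sample (default 200000).
#' @param k K-mer size for index construction (default 31; ignored with a
#'   warning when a prebuilt index is supplied).
#' @param min_vote_frac Per-mate assignment threshold (see
#'   [assign_read()]).
#' @param thresholds Decision thresholds ([strand_thresholds()]).
#' @param sample_strategy,seed Pair sampling strategy (see
#'   [sample_pairs()]).
#' @param denominator Denominator for the stranded proportion (see
#'   [strandedness_report()]).
#' @param ci_level Confidence level for the reported interval.
#' @param out_prefix If non-`NULL`, write `<prefix>.tsv` and
#'   `<prefix>.json` ([write_report()]); with `audit = TRUE` also
#'   `<prefix>.audit.tsv`, the per-pair classification dump.
#' @param audit Write the per-pair audit table (off by default).
#' @param quiet Suppress stage progress messages (they go to standard
#'   error, so reports compose in shell pipelines).
#' @return A `strandedness` object. An error (not a verdict) is raised when
#'   no pair orientation can be determined at all.
#' @examples
#' tx <- make_transcriptome(20, c(300, 600), seed = 1)
#' sim <- simulate_pairs(tx, sim_spec(n_pairs = 2000, p = 1, seed = 2))
#' check_strandedness(sim, transcripts = tx, quiet = TRUE)
#' @export
check_strandedness <- function(reads_1, reads_2 = NULL, transcripts = NULL,
                               gtf = NULL, index = NULL, n_pairs = 200000,
                               k = 31, min_vote_frac = 0.25,
                               thresholds = strand_thresholds(),
                               sample_strategy = c("head", "reservoir"),
                               seed = NULL,
                               denominator = c("determined", "total"),
                               ci_level = 0.99, out_prefix = NULL,
                               audit = FALSE, quiet = FALSE) {
  sample_strategy <- match.arg(sample_strategy)
  denominator <- match.arg(denominator)
  note <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop("[", name, "] ", conditionMessage(e), call. = FALSE)
      }))
    note("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0)
    r
  }

  idx <- if (inherits(index, "kmer_index")) {
    if (!is.null(k) && as.integer(k) != index$k)
      warning("supplied index has k = ", index$k, "; ignoring k = ", k)
    index
  } else if (is.character(index)) {
    stage("load-index", load_index(index, k))
  } else {
    if (is.null(transcripts))
      stop("either 'transcripts' or 'index' must be supplied",
           call. = FALSE)
    stage("index", {
      tx <- as_transcriptome(transcripts)
      if (!is.null(gtf)) tx <- attach_gtf_strands(tx, gtf)
      build_index(tx, k)
    })
  }
  note("[index] k = %d, %d transcripts, %.0f k-mers",
       idx$k, idx$n_transcripts, idx$n_kmers)

  pairs <- if (inherits(reads_1, "read_pairs")) {
    if (length(reads_1) > n_pairs) reads_1[seq_len(n_pairs)] else reads_1
  } else {
    stage("sample", sample_pairs(reads_1, reads_2, n_pairs,
                                 sample_strategy, seed))
  }
  note("[sample] %d read pair(s)", length(pairs))

  calls <- stage("classify", classify_pairs(pairs, idx, min_vote_frac))
  counts <- tally(calls)
  note("[classify] FR %d, RF %d, FAILED %d, UNMAPPED %d",
       counts$n_fr, counts$n_rf, counts$n_failed, counts$n_unmapped)
  rep <- stage("report",
               strandedness_report(counts, thresholds, ci_level,
                                   denominator))
  if (!is.null(out_prefix)) {
    write_report(rep, out_prefix)
    if (audit)
      utils::write.table(calls, paste0(out_prefix, ".audit.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rep
}

#' Build and save a reusable index artifact
#'
#' Convenience wrapper: read the transcriptome, optionally attach GTF
#' strands, build the index and write it to disk for reuse via
#' `check_strandedness(index = )`.
#'
#' @inheritParams check_strandedness
#' @param out Output path for the index artifact.
#' @return Invisibly, the `kmer_index` (also saved to `out`).
#' @export
build_index_file <- function(transcripts, out, k = 31, gtf = NULL) {
  tx <- as_transcriptome(transcripts)
  if (!is.null(gtf)) tx <- attach_gtf_strands(tx, gtf)
  idx <- build_index(tx, k)
  save_index(idx, out)
  invisible(idx)
}
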