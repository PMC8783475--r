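#' Build a strand-aware k-mer voting index
#'
#' Indexes every sense-strand k-mer of the transcriptome (k-mers containing
#' `N` are skipped). Reverse-complement k-mers are not stored; queries probe
#' both orientations, which is what makes the index strand-aware: a read
#' whose forward k-mers match is sense, one whose reverse-complement k-mers
#' match is antisense.
#'
#' @param transcripts A transcriptome (FASTA path or
#'   [Biostrings::DNAStringSet] from [read_transcriptome()]).
#' @param k Odd k-mer size in `[11, 31]`; default 31 (k-mers are packed two
#'   bits per base into one 64-bit word, hence the 31 cap — the same cap and
#'   default as kallisto).
#' @return A `kmer_index` object (in-memory; see [save_index()] to persist).
#' @examples
#' tx <- Biostrings::DNAStringSet(c(tx1 = "ACGTACGTACGTACG"))
#' idx <- build_index(tx, k = 11)
#' idx
#' @export
build_index <- function(transcripts, k = 31) {
  tx <- as_transcriptome(transcripts)
  k <- as.integer(k)
  if (length(k) != 1 || is.na(k) || k < 11 || k > 31 || k %% 2 == 0)
    stop("k must be an odd integer in [11, 31]", call. = FALSE)
  res <- .build_index_cpp(as.character(tx), k)
  if (length(res$too_short))
    warning(length(res$too_short), " transcript(s) shorter than k = ", k,
            " contribute no k-mers")
  gs <- S4Vectors::mcols(tx)$genome_strand
  structure(list(ptr = res$ptr, k = k, tx_ids = names(tx),
                 genome_strand = gs, n_transcripts = length(tx),
                 n_kmers = res$n_kmers),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index: k = %d, %d transcript(s), %.0f distinct k-mer(s)\n",
              x$k, x$n_transcripts, x$n_kmers))
  invisible(x)
}

#' Assign a single read to the transcriptome
#'
#' Counts how many of the read's forward k-mers are present in the index
#' (sense votes) and how many of its reverse-complement k-mers are present
#' (antisense votes). With `m` k-mer positions in the read and
#' `v = max(votes)`, the read is `ASSIGNED` when `v >= min_vote_frac * m`
#' and the winning orientation strictly beats the other;
#' `AMBIGUOUS_STRAND` when both orientations reach the threshold and are
#' within one vote of each other (palindromic or low-complexity sequence
#' should not vote a strand); otherwise `UNMAPPED`. The transcript set is
#' the intersection of the id-sets of the winning orientation's matching
#' k-mers, falling back to their union (junction-spanning reads) when the
#' intersection is empty.
#'
#' @param seq A DNA string. Shorter than `k` yields `UNMAPPED` with zero
#'   votes.
#' @param index A `kmer_index` from [build_index()].
#' @param min_vote_frac Fraction of the read's k-mers that must match
#'   (default 0.25, tolerating roughly one substitution error per 100
#'   bases).
#' @return A list: `status` (`ASSIGNED`/`UNMAPPED`/`AMBIGUOUS_STRAND`),
#'   `orientation` (`SENSE`/`ANTISENSE` or `NA`), `transcripts` (ids),
#'   `votes_sense`, `votes_antisense`, `multi_transcript`.
#' @export
assign_read <- function(seq, index, min_vote_frac = 0.25) {
  stopifnot(inherits(index, "kmer_index"),
            is.character(seq), length(seq) == 1)
  a <- .assign_read_cpp(seq, index$ptr, min_vote_frac)
  list(
    status = c("UNMAPPED", "ASSIGNED", "AMBIGUOUS_STRAND")[a$status + 1L],
    orientation = if (a$orientation == 0) NA_character_
                  else c("SENSE", "ANTISENSE")[a$orientation],
    transcripts = index$tx_ids[a$transcripts],
    votes_sense = a$votes_sense,
    votes_antisense = a$votes_antisense,
    multi_transcript = a$multi)
}

#' Enumerate the k-mers stored in an index
#'
#' Intended for inspection and testing on small indexes; the full table of a
#' real transcriptome is large.
#'
#' @param index A `kmer_index`.
#' @return A data frame with columns `kmer` and `ids` (list of transcript
#'   ids per k-mer), sorted by k-mer.
#' @export
index_kmers <- function(index) {
  stopifnot(inherits(index, "kmer_index"))
  r <- .index_kmers_cpp(index$ptr)
  ids <- lapply(r$ids, function(i) index$tx_ids[i])
  o <- order(r$kmer)
  data.frame(kmer = r$kmer[o], ids = I(ids[o]), row.names = NULL)
}

#' Save / load a k-mer index
#'
#' The index is written as a flat binary artifact with a versioned header so
#' repeated runs on the same species can skip rebuilding. `k`, the
#' transcript ids and any genome strands travel with the artifact.
#'
#' @param index A `kmer_index`.
#' @param file Path for the index artifact.
#' @return `save_index`: invisibly, `file`. `load_index`: a `kmer_index`.
#' @export
save_index <- function(index, file) {
  stopifnot(inherits(index, "kmer_index"))
  .save_index_cpp(index$ptr, index$tx_ids, file)
  # the artifact stores k, ids and k-mers; genome strands (reporting sugar
  # only) are re-attached from the GTF when needed
  invisible(file)
}

#' @param k Optional; if supplied and different from the `k` stored in the
#'   artifact, the stored value wins with a warning.
#' @rdname save_index
#' @export
load_index <- function(file, k = NULL) {
  r <- .load_index_cpp(file)
  if (!is.null(k) && as.integer(k) != r$k)
    warning("index file stores k = ", r$k, "; ignoring k = ", k)
  structure(list(ptr = r$ptr, k = r$k, tx_ids = r$tx_ids,
                 genome_strand = rep(NA_character_, length(r$tx_ids)),
                 n_transcripts = length(r$tx_ids), n_kmers = r$n_kmers),
            class = "kmer_index")
}
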