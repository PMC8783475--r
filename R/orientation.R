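ORIENTATION_LEVELS <- c("FR", "RF", "FAILED", "UNMAPPED")

#' Classify read pairs into the FR/RF orientation space
#'
#' Both mates are assigned to the transcriptome independently (see
#' [assign_read()]) and the pair is classified by a decision table:
#' mate 1 sense + mate 2 antisense is `FR` (file 1 carries the original RNA);
#' the converse is `RF`. When only one mate is assigned, that mate decides
#' alone (mate 1 sense -> FR, mate 1 antisense -> RF, mate 2 sense -> RF,
#' mate 2 antisense -> FR) — discarding such pairs would bias libraries with
#' one weak mate. A pair is `FAILED` when both mates map with the same
#' orientation (discordant), when either mate is strand-ambiguous, or when
#' the mates' transcript sets are disjoint (likely chimeric); `UNMAPPED`
#' when neither mate is assigned.
#'
#' @param pairs A `read_pairs` object (from [sample_pairs()] or the
#'   simulator).
#' @param index A `kmer_index` built from the same transcriptome the reads
#'   come from.
#' @param min_vote_frac Per-mate assignment threshold; see [assign_read()].
#' @return An `orientation_calls` data frame: `name`, `call`
#'   (factor FR/RF/FAILED/UNMAPPED), `tx` (a representative transcript id
#'   shared by the mates, or `NA`), per-mate statuses, orientations and vote
#'   counts. Suitable as a per-pair audit dump via [utils::write.table()].
#' @export
classify_pairs <- function(pairs, index, min_vote_frac = 0.25) {
  stopifnot(inherits(pairs, "read_pairs"), inherits(index, "kmer_index"))
  r <- .classify_pairs_cpp(pairs$seq1, pairs$seq2, index$ptr, min_vote_frac)
  st <- c("UNMAPPED", "ASSIGNED", "AMBIGUOUS_STRAND")
  orient <- function(o) ifelse(o == 0, NA_character_,
                               c("SENSE", "ANTISENSE")[pmax(o, 1)])
  df <- data.frame(
    name = pairs$name,
    call = factor(ORIENTATION_LEVELS[r$call], levels = ORIENTATION_LEVELS),
    tx = index$tx_ids[r$tx],
    m1_status = st[r$m1_status + 1L],
    m1_orientation = orient(r$m1_orientation),
    m1_votes_sense = r$m1_votes_sense,
    m1_votes_antisense = r$m1_votes_antisense,
    m2_status = st[r$m2_status + 1L],
    m2_orientation = orient(r$m2_orientation),
    m2_votes_sense = r$m2_votes_sense,
    m2_votes_antisense = r$m2_votes_antisense,
    stringsAsFactors = FALSE)
  class(df) <- c("orientation_calls", "data.frame")
  df
}

#' @param seq1,seq2 Mate sequences of a single pair.
#' @rdname classify_pairs
#' @return `classify_pair`: a single string, one of `FR`, `RF`, `FAILED`,
#'   `UNMAPPED`.
#' @export
classify_pair <- function(seq1, seq2, index, min_vote_frac = 0.25) {
  p <- new_read_pairs("pair", seq1, seq2)
  as.character(classify_pairs(p, index, min_vote_frac)$call[1])
}

#' Tally orientation calls
#'
#' @param calls An `orientation_calls` data frame or a vector of call
#'   strings/factor (`FR`, `RF`, `FAILED`, `UNMAPPED`).
#' @return An `orientation_counts` list: `n_total`, `n_fr`, `n_rf`,
#'   `n_failed`, `n_unmapped` (the four categories always sum to
#'   `n_total`).
#' @export
tally <- function(calls) {
  v <- if (is.data.frame(calls)) calls$call else calls
  v <- factor(as.character(v), levels = ORIENTATION_LEVELS)
  if (anyNA(v))
    stop("invalid orientation call; expected FR, RF, FAILED or UNMAPPED",
         call. = FALSE)
  tab <- table(v)
  structure(list(n_total = length(v),
                 n_fr = as.integer(tab["FR"]),
                 n_rf = as.integer(tab["RF"]),
                 n_failed = as.integer(tab["FAILED"]),
                 n_unmapped = as.integer(tab["UNMAPPED"])),
            class = "orientation_counts")
}

#' @export
print.orientation_counts <- function(x, ...) {
  cat(sprintf(
    "orientation_counts: %d pair(s) (FR %d, RF %d, FAILED %d, UNMAPPED %d)\n",
    x$n_total, x$n_fr, x$n_rf, x$n_failed, x$n_unmapped))
  invisible(x)
}

#' RSeQC-style orientation code strings
#'
#' Translates an FR/RF call into the genome-space orientation codes used by
#' RSeQC's infer_experiment, given the genome strand of the assigned
#' transcript: FR on a `+` transcript is `"1++,2+-"`, on `-` it is
#' `"1--,2-+"`; RF correspondingly `"1+-,2++"` / `"1-+,2--"`. Summary
#' reporting aggregates FR as `"1++,1--,2+-,2-+"` and RF as
#' `"1+-,1-+,2++,2--"` (see [rseqc_layout_code()]). These strings are
#' reporting sugar: all decisions are made in transcript (sense/antisense)
#' space, so the GTF is optional.
#'
#' @param call Vector of calls (`FR`, `RF`, `FAILED`, `UNMAPPED`).
#' @param genome_strand Vector of `+`/`-` genome strands (`NA` allowed:
#'   code omitted, call still counted).
#' @return Character vector of code strings (`NA` where undefined).
#' @export
rseqc_code <- function(call, genome_strand) {
  call <- as.character(call)
  key <- paste0(call, genome_strand)
  codes <- c("FR+" = "1++,2+-", "FR-" = "1--,2-+",
             "RF+" = "1+-,2++", "RF-" = "1-+,2--")
  out <- unname(codes[key])
  out[!call %in% c("FR", "RF") | !genome_strand %in% c("+", "-")] <-
    NA_character_
  out
}

#' @param layout `"FR"` or `"RF"`.
#' @rdname rseqc_code
#' @export
rseqc_layout_code <- function(layout = c("FR", "RF")) {
  switch(match.arg(layout),
         FR = "1++,1--,2+-,2-+",
         RF = "1+-,1-+,2++,2--")
}
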