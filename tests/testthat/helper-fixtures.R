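# Shared fixtures and independent oracles, built in code at test time.

rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

toy_transcriptome <- function(n = 10, len_range = c(300, 2000), seed = 11) {
  make_transcriptome(n, len_range, seed = seed)
}

random_dna <- function(len, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Brute-force assignment oracle: scan every transcript and both strands for
# the read as an exact substring.  Independent of the k-mer voting path.
oracle_assign <- function(seq, transcriptome) {
  s <- as.character(transcriptome)
  ids <- names(transcriptome)
  hit_s <- ids[vapply(s, function(t) grepl(seq, t, fixed = TRUE), logical(1))]
  hit_a <- ids[vapply(s, function(t) grepl(rc(seq), t, fixed = TRUE),
                      logical(1))]
  if (length(hit_s) && length(hit_a))
    list(status = "AMBIGUOUS_STRAND", orientation = NA_character_,
         transcripts = character())
  else if (length(hit_s))
    list(status = "ASSIGNED", orientation = "SENSE", transcripts = hit_s)
  else if (length(hit_a))
    list(status = "ASSIGNED", orientation = "ANTISENSE",
         transcripts = hit_a)
  else
    list(status = "UNMAPPED", orientation = NA_character_,
         transcripts = character())
}

# Orientation oracle for a simulated pair at error 0: which strand of the
# named source transcript contains mate 1 as an exact substring?
oracle_pair_orientation <- function(seq1, tx_seq) {
  if (grepl(seq1, tx_seq, fixed = TRUE)) "FR"
  else if (grepl(rc(seq1), tx_seq, fixed = TRUE)) "RF"
  else NA_character_
}

write_tmp_fasta <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fa",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

counts_from <- function(n_fr, n_rf, n_failed = 0, n_unmapped = 0) {
  tally(rep(c("FR", "RF", "FAILED", "UNMAPPED"),
            c(n_fr, n_rf, n_failed, n_unmapped)))
}
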