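#' Simulation parameters for paired-end reads
#'
#' @param n_pairs Number of read pairs to emit (default 200000, the
#'   pipeline's default sample size).
#' @param read_len Read length in bases (default 100).
#' @param frag_len_mean,frag_len_sd Fragment length model, Normal truncated
#'   to `[read_len, transcript length]` (defaults 250 and 25 bases, typical
#'   Illumina values).
#' @param p Strandedness fraction in `[0.5, 1]`: the probability that a
#'   pair follows `layout` (1 = fully stranded, 0.5 = unstranded). Values
#'   below 0.5 are rejected — that is the mirrored case; set
#'   `layout = "RF"` instead.
#' @param layout `"FR"` or `"RF"`: which layout the stranded fraction
#'   follows.
#' @param error_rate Per-base substitution probability (default 0; no
#'   indels).
#' @param abundance `"lognormal"` (meanlog 0, sdlog 1 over transcripts;
#'   emulates realistic skewed expression) or `"uniform"` (analytic
#'   checks).
#' @param seed Integer seed; the full output is reproducible per seed.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_pairs = 200000, read_len = 100, frag_len_mean = 250,
                     frag_len_sd = 25, p = 1.0, layout = c("FR", "RF"),
                     error_rate = 0,
                     abundance = c("lognormal", "uniform"), seed = NULL) {
  layout <- match.arg(layout)
  abundance <- match.arg(abundance)
  if (p < 0.5 || p > 1)
    stop("p must be in [0.5, 1]; p < 0.5 is the mirrored layout - ",
         "set layout = \"RF\" instead", call. = FALSE)
  if (frag_len_mean < read_len)
    stop("frag_len_mean must be >= read_len", call. = FALSE)
  stopifnot(n_pairs >= 1, read_len >= 1, frag_len_sd >= 0,
            error_rate >= 0, error_rate < 1)
  structure(list(n_pairs = as.integer(n_pairs),
                 read_len = as.integer(read_len),
                 frag_len_mean = frag_len_mean, frag_len_sd = frag_len_sd,
                 p = p, layout = layout, error_rate = error_rate,
                 abundance = abundance, seed = seed),
            class = "sim_spec")
}

#' Generate a random synthetic transcriptome
#'
#' I.i.d. uniform-base sequences (expected GC 0.5), reproducible per seed.
#' Ids are `tx0001`, `tx0002`, ...
#'
#' @param n Number of transcripts.
#' @param len_range `c(min, max)` transcript length in bases (default
#'   500-3000).
#' @param seed Integer seed.
#' @param k Downstream index k-mer size checked against `len_range`
#'   (warning if transcripts could be too short to index; default 31).
#' @return A named [Biostrings::DNAStringSet].
#' @export
make_transcriptome <- function(n, len_range = c(500, 3000), seed = NULL,
                               k = 31) {
  stopifnot(n >= 1, length(len_range) == 2, len_range[1] >= 1,
            len_range[1] <= len_range[2])
  if (len_range[1] < k)
    warning("len_range minimum (", len_range[1], ") is below k = ", k,
            "; short transcripts will contribute no k-mers")
  with_seed(seed, {
    lens <- if (len_range[1] == len_range[2]) rep(len_range[1], n)
            else sample(len_range[1]:len_range[2], n, replace = TRUE)
    bases <- sample(c("A", "C", "G", "T"), sum(lens), replace = TRUE)
    seqs <- vapply(split(bases, rep(seq_len(n), lens)),
                   paste, "", collapse = "")
  })
  width <- max(4L, nchar(as.character(n)))
  out <- Biostrings::DNAStringSet(unname(seqs))
  names(out) <- sprintf("tx%0*d", width, seq_len(n))
  as_transcriptome(out)
}

# i.i.d. substitution errors at `rate`; substituted base always differs.
add_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  len <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), len, rate)
  for (j in which(n_err > 0)) {
    pos <- sample.int(len[j], n_err[j])
    for (p_ in pos) {
      old <- substr(seqs[j], p_, p_)
      new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      substr(seqs[j], p_, p_) <- new
    }
  }
  seqs
}

#' Simulate paired-end reads with controlled strandedness
#'
#' For each pair a transcript is drawn from the abundance model, a fragment
#' length from the truncated Normal model, and a start position uniformly;
#' with probability `p` the pair follows `spec$layout`, otherwise the
#' opposite layout. In an FR pair mate 1 is the fragment's 5' end on the
#' sense strand and mate 2 the reverse complement of its 3' end; an RF pair
#' swaps the mates. Ground truth (source transcript, orientation, fragment
#' start and length) is encoded in the read names
#' (`pair0000001|tx0001|FR|start|len`) and returned as a truth table.
#'
#' @param transcriptome A transcriptome (FASTA path or DNAStringSet).
#' @param spec A [sim_spec()].
#' @return A `sim_reads` object (also a `read_pairs`): `name`, `seq1`,
#'   `seq2`, plus `truth` (data frame) and `spec`. Write to disk with
#'   [write_fastq()] / [write_truth()].
#' @export
simulate_pairs <- function(transcriptome, spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  tx <- as_transcriptome(transcriptome)
  txs <- as.character(tx)
  txlen <- nchar(txs)
  rl <- spec$read_len
  usable <- which(txlen >= rl)
  if (length(usable) == 0)
    stop("every transcript is shorter than read_len = ", rl, call. = FALSE)
  n <- spec$n_pairs
  with_seed(spec$seed, {
    w <- switch(spec$abundance,
                uniform = rep(1, length(usable)),
                lognormal = stats::rlnorm(length(usable), 0, 1))
    i <- usable[sample.int(length(usable), n, replace = TRUE, prob = w)]
    fl <- round(stats::rnorm(n, spec$frag_len_mean, spec$frag_len_sd))
    fl <- pmax(rl, pmin(fl, txlen[i]))
    st <- 1L + as.integer(floor(stats::runif(n) * (txlen[i] - fl + 1)))
    primary <- stats::runif(n) < spec$p
    left <- substring(txs[i], st, st + rl - 1L)
    right <- revcomp_chr(substring(txs[i], st + fl - rl, st + fl - 1L))
    orient <- ifelse(xor(primary, spec$layout == "RF"), "FR", "RF")
    seq1 <- ifelse(orient == "FR", left, right)
    seq2 <- ifelse(orient == "FR", right, left)
    seq1 <- add_errors(seq1, spec$error_rate)
    seq2 <- add_errors(seq2, spec$error_rate)
  })
  name <- paste(sprintf("pair%07d", seq_len(n)), names(tx)[i], orient,
                st, fl, sep = "|")
  truth <- data.frame(name = name, transcript = names(tx)[i],
                      orientation = orient, start = st, frag_len = fl,
                      stringsAsFactors = FALSE)
  structure(list(name = name, seq1 = seq1, seq2 = seq2, truth = truth,
                 spec = spec),
            class = c("sim_reads", "read_pairs"))
}

#' Write a simulation truth table
#'
#' Sidecar TSV mirroring the truth already encoded in the read names.
#'
#' @param sim A `sim_reads` object (or anything with a `truth` data frame).
#' @param file Output TSV path.
#' @return Invisibly, `file`.
#' @export
write_truth <- function(sim, file) {
  stopifnot(!is.null(sim$truth))
  utils::write.table(sim$truth, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Mix two read-pair samples at a given ratio
#'
#' Draws `floor(ratio * total_pairs)` pairs without replacement from sample
#' A and the remainder from sample B, interleaved in random order. Mixing a
#' fully stranded sample (p = 1) with an unstranded one (p = 0.5) at ratio
#' `r` gives an expected percent stranded of `100 * (r + (1 - r) / 2)`.
#'
#' @param a,b `read_pairs` objects, or length-2 character vectors of FASTQ
#'   paths.
#' @param ratio Fraction of the output drawn from `a`, in `[0, 1]`.
#' @param total_pairs Total pairs emitted (default 200000).
#' @param seed Integer seed.
#' @return A `read_pairs` object.
#' @export
mix_samples <- function(a, b, ratio, total_pairs = 200000, seed = NULL) {
  stopifnot(ratio >= 0, ratio <= 1, total_pairs >= 1)
  a <- as_read_pairs(a)
  b <- as_read_pairs(b)
  n_a <- floor(ratio * total_pairs)
  n_b <- total_pairs - n_a
  if (length(a) < n_a)
    stop(sprintf("sample A has %d pair(s); %d requested (deficit %d)",
                 length(a), n_a, n_a - length(a)), call. = FALSE)
  if (length(b) < n_b)
    stop(sprintf("sample B has %d pair(s); %d requested (deficit %d)",
                 length(b), n_b, n_b - length(b)), call. = FALSE)
  with_seed(seed, {
    ia <- sample.int(length(a), n_a)
    ib <- sample.int(length(b), n_b)
    ord <- sample.int(total_pairs)
  })
  rp_concat(a[ia], b[ib])[ord]
}

#' Simulate genomic-DNA fragment pairs against a "+"-only reference
#'
#' Emulates the intergenic control for genomic-DNA contamination: a random
#' reference region is partitioned into fixed-size features that are all
#' assigned the `+` strand, and fragment pairs are drawn whose source
#' strand is a fair coin per pair. Genomic DNA carries no strand bias, so
#' running the standard pipeline on this input must report a stranded
#' proportion of ~50%.
#'
#' @param n_pairs Number of fragment pairs (default 200000).
#' @param region_len Length of the random reference region (default
#'   100000 bases).
#' @param feature_len Feature (chunk) size the region is partitioned into
#'   (default 1000 bases).
#' @param read_len,frag_len_mean,frag_len_sd As in [sim_spec()].
#' @param seed Integer seed.
#' @return A list: `reads` (a `read_pairs` with a `truth` data frame
#'   holding the per-pair source strand) and `transcriptome` (the
#'   "+"-strand-only feature set, ready for [build_index()]).
#' @export
simulate_gdna_pairs <- function(n_pairs = 200000, region_len = 100000,
                                feature_len = 1000, read_len = 100,
                                frag_len_mean = 250, frag_len_sd = 25,
                                seed = NULL) {
  stopifnot(region_len >= frag_len_mean, frag_len_mean >= read_len,
            feature_len >= 1)
  with_seed(seed, {
    region <- paste(sample(c("A", "C", "G", "T"), region_len,
                           replace = TRUE), collapse = "")
    n <- as.integer(n_pairs)
    fl <- round(stats::rnorm(n, frag_len_mean, frag_len_sd))
    fl <- pmax(read_len, pmin(fl, region_len))
    st <- 1L + as.integer(floor(stats::runif(n) * (region_len - fl + 1)))
    strand <- sample(c("+", "-"), n, replace = TRUE)
  })
  left <- substring(region, st, st + read_len - 1L)
  right <- revcomp_chr(substring(region, st + fl - read_len,
                                 st + fl - 1L))
  # '+' fragment: mate 1 is the 5' end on the reference strand; '-'
  # fragment: the fragment was read off the opposite strand, so the mates
  # swap (equivalent to an RF pair in reference coordinates)
  seq1 <- ifelse(strand == "+", left, right)
  seq2 <- ifelse(strand == "+", right, left)
  name <- paste(sprintf("gdna%07d", seq_len(n)), strand, st, fl,
                sep = "|")
  truth <- data.frame(name = name, strand = strand, start = st,
                      frag_len = fl, stringsAsFactors = FALSE)
  starts <- seq(1L, region_len, by = feature_len)
  feats <- substring(region, starts,
                     pmin(starts + feature_len - 1L, region_len))
  ref <- Biostrings::DNAStringSet(feats)
  names(ref) <- sprintf("igr%04d", seq_along(feats))
  ref <- as_transcriptome(ref)
  md <- S4Vectors::mcols(ref)
  md$genome_strand <- "+"
  S4Vectors::mcols(ref) <- md
  reads <- structure(list(name = name, seq1 = seq1, seq2 = seq2,
                          truth = truth),
                     class = c("sim_reads", "read_pairs"))
  list(reads = reads, transcriptome = ref)
}

#' Generate a grid of simulated samples on disk
#'
#' Writes FASTQ pairs (plus truth tables and the shared transcriptome
#' FASTA) for every combination of read count and strandedness mode —
#' the validation-study layout (read counts from 1000 to 2 million, each
#' as a stranded and an unstranded sample).
#'
#' @param out_dir Output directory (created if needed).
#' @param read_counts Read-pair counts to simulate.
#' @param transcriptome Optional transcriptome; a fresh 1000-transcript one
#'   is generated when `NULL`.
#' @param seed Base seed; each sample derives its own.
#' @param ... Further arguments passed to [sim_spec()] (e.g. `read_len`).
#' @return Invisibly, a data frame listing the files written.
#' @export
simulate_grid <- function(out_dir,
                          read_counts = c(1000L, 10000L, 100000L, 200000L,
                                          1000000L, 2000000L),
                          transcriptome = NULL, seed = 1, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(transcriptome))
    transcriptome <- make_transcriptome(1000, seed = seed)
  write_transcriptome(transcriptome, file.path(out_dir, "transcriptome.fa"))
  modes <- c(stranded = 1.0, unstranded = 0.5)
  out <- list()
  run <- 0L
  for (nc in read_counts) {
    for (m in names(modes)) {
      run <- run + 1L
      tag <- sprintf("%s_%d", m, nc)
      sim <- simulate_pairs(transcriptome,
                            sim_spec(n_pairs = nc, p = modes[[m]],
                                     seed = seed + run, ...))
      f1 <- file.path(out_dir, paste0(tag, "_1.fastq.gz"))
      f2 <- file.path(out_dir, paste0(tag, "_2.fastq.gz"))
      write_fastq(sim, f1, f2)
      write_truth(sim, file.path(out_dir, paste0(tag, "_truth.tsv")))
      out[[tag]] <- data.frame(sample = tag, n_pairs = nc,
                               p = modes[[m]], fastq_1 = f1, fastq_2 = f2)
    }
  }
  invisible(do.call(rbind, out))
}
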