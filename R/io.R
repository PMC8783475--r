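#' Read a transcriptome FASTA
#'
#' Reads sense-strand transcript sequences from a (possibly gzipped) FASTA
#' file. The id of each transcript is the first whitespace-delimited token of
#' its header line. Sequences are uppercased and any character outside
#' `{A,C,G,T,N}` is replaced by `N`.
#'
#' @param file Path to a FASTA file (plain or gzipped; multi-line records
#'   are fine).
#' @return A [Biostrings::DNAStringSet] named by transcript id, with metadata
#'   columns `gene_id` and `genome_strand` (both `NA` until
#'   [attach_gtf_strands()] is used).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">tx1 gene=g1", "acgtACGT"), fa)
#' read_transcriptome(fa)
#' @export
read_transcriptome <- function(file) {
  x <- tryCatch(
    Biostrings::readDNAStringSet(file, format = "fasta"),
    error = function(e) {
      stop("failed to read transcriptome FASTA '", file, "': ",
           conditionMessage(e), call. = FALSE)
    })
  if (length(x) == 0)
    stop("transcriptome FASTA '", file, "' contains no records",
         call. = FALSE)
  ids <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(ids)))
    stop("empty transcript id in '", file, "'", call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate transcript id(s) in '", file, "': ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  s <- toupper(as.character(x))
  n_bad <- sum(nchar(s)) - sum(nchar(gsub("[^ACGTN]", "", s)))
  if (n_bad > 0) {
    s <- gsub("[^ACGTN]", "N", s)
    message(n_bad, " non-ACGTN base(s) replaced by N")
  }
  if (any(!nzchar(s)))
    stop("zero-length sequence(s) in '", file, "'", call. = FALSE)
  out <- Biostrings::DNAStringSet(s)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    gene_id = NA_character_, genome_strand = NA_character_)
  out
}

# Normalize a transcriptome argument: path or DNAStringSet.
as_transcriptome <- function(x) {
  if (is.character(x) && length(x) == 1) return(read_transcriptome(x))
  if (!methods::is(x, "DNAStringSet"))
    stop("'transcripts' must be a FASTA path or a DNAStringSet", call. = FALSE)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("transcriptome sequences must be named", call. = FALSE)
  md <- S4Vectors::mcols(x)
  if (is.null(md) || !all(c("gene_id", "genome_strand") %in% names(md))) {
    S4Vectors::mcols(x) <- S4Vectors::DataFrame(
      gene_id = if (!is.null(md$gene_id)) md$gene_id else NA_character_,
      genome_strand = if (!is.null(md$genome_strand)) md$genome_strand
                      else NA_character_)
  }
  x
}

#' Attach genome strands from a GTF annotation
#'
#' Fills the `genome_strand` metadata column of a transcriptome from the
#' strand of `transcript` (or `exon`) features in a GTF file. Transcript ids
#' are matched after stripping a trailing `.<digits>` version, tolerating the
#' differing id dialects of Ensembl FASTA and GTF files. Transcripts absent
#' from the GTF keep an unset strand (with a warning giving the count); no
#' transcript is removed. The genome strand is reporting sugar only (RSeQC
#' orientation codes); verdicts never depend on it.
#'
#' @param transcripts A transcriptome from [read_transcriptome()] (or a FASTA
#'   path).
#' @param gtf Path to a GTF file (Ensembl dialect; `transcript_id`
#'   attributes required).
#' @return The transcriptome with `genome_strand` filled where known.
#' @export
attach_gtf_strands <- function(transcripts, gtf) {
  tx <- as_transcriptome(transcripts)
  g <- tryCatch(
    rtracklayer::import(gtf, format = "gtf"),
    error = function(e) {
      stop("failed to parse GTF '", gtf, "': ", conditionMessage(e),
           call. = FALSE)
    })
  md <- S4Vectors::mcols(g)
  if (!"transcript_id" %in% names(md))
    stop("GTF '", gtf, "' has no transcript_id attributes", call. = FALSE)
  keep <- !is.na(md$transcript_id)
  if ("type" %in% names(md) && any(md$type %in% c("transcript", "exon")))
    keep <- keep & md$type %in% c("transcript", "exon")
  tid <- strip_version(as.character(md$transcript_id[keep]))
  std <- as.character(BiocGenerics::strand(g))[keep]
  std[!std %in% c("+", "-")] <- NA_character_
  gid <- if ("gene_id" %in% names(md))
    as.character(md$gene_id[keep]) else rep(NA_character_, length(tid))

  first <- !duplicated(tid)
  smap <- std[first]
  gmap <- gid[first]
  names(smap) <- names(gmap) <- tid[first]
  # conflicting strands for one transcript id: keep the first, warn
  agg <- tapply(std, tid, function(z) length(unique(z[!is.na(z)])))
  if (any(agg > 1, na.rm = TRUE))
    warning(sum(agg > 1, na.rm = TRUE),
            " transcript id(s) with conflicting strands in GTF; first kept")

  key <- strip_version(names(tx))
  hit <- match(key, names(smap))
  miss <- sum(is.na(hit))
  if (miss > 0)
    warning(miss, " of ", length(tx),
            " transcript(s) absent from GTF; genome_strand left unset")
  md_tx <- S4Vectors::mcols(tx)
  md_tx$genome_strand <- ifelse(is.na(hit), md_tx$genome_strand,
                                unname(smap[hit]))
  fill_gene <- is.na(md_tx$gene_id) & !is.na(hit)
  md_tx$gene_id[fill_gene] <- unname(gmap[hit[fill_gene]])
  S4Vectors::mcols(tx) <- md_tx
  tx
}

# --- paired FASTQ ----------------------------------------------------------

read_fastq_file <- function(file) {
  tryCatch(
    Biostrings::readDNAStringSet(file, format = "fastq"),
    error = function(e) {
      stop("failed to read FASTQ '", file,
           "' (truncated or malformed record?): ", conditionMessage(e),
           call. = FALSE)
    })
}

# Pair name: first whitespace token of the header, then any trailing /1 /2
# mate suffix (Casava <1.8 dialect; the >=1.8 " 1:N:..." dialect is removed
# with the whitespace tail).
pair_name <- function(headers) sub("/[12]$", "", sub("\\s.*$", "", headers))

new_read_pairs <- function(name, seq1, seq2) {
  structure(list(name = name, seq1 = seq1, seq2 = seq2),
            class = "read_pairs")
}

#' Sample synchronized read pairs from two FASTQ files
#'
#' Reads both mates of a paired-end FASTQ file pair (plain or gzipped),
#' verifies that mate names agree record by record, and returns up to
#' `n_pairs` pairs: the first `n_pairs` in file order (`strategy = "head"`,
#' the default) or a uniform random subset reproducible per `seed`
#' (`strategy = "reservoir"`).
#'
#' @param fastq_1,fastq_2 Paths to the mate-1 and mate-2 FASTQ files.
#' @param n_pairs Number of pairs to sample (default 200000, the pipeline's
#'   default sample size). If fewer pairs are available, all are returned
#'   with a warning.
#' @param strategy `"head"` (first `n_pairs`, seed-independent) or
#'   `"reservoir"` (uniform random subset).
#' @param seed Integer seed for the `"reservoir"` strategy; ignored by
#'   `"head"`.
#' @return A `read_pairs` object: pair names (mate suffixes stripped) plus
#'   the two mate sequences.
#' @export
sample_pairs <- function(fastq_1, fastq_2, n_pairs = 200000,
                         strategy = c("head", "reservoir"), seed = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(n_pairs >= 1)
  r1 <- read_fastq_file(fastq_1)
  r2 <- read_fastq_file(fastq_2)
  if (length(r1) != length(r2))
    stop(sprintf("paired FASTQ files have unequal record counts: %d vs %d",
                 length(r1), length(r2)), call. = FALSE)
  n1 <- pair_name(names(r1))
  n2 <- pair_name(names(r2))
  bad <- which(n1 != n2)
  if (length(bad))
    stop(sprintf("mate name mismatch at record %d: '%s' vs '%s'",
                 bad[1], n1[bad[1]], n2[bad[1]]), call. = FALSE)
  avail <- length(r1)
  take <- min(n_pairs, avail)
  if (is.finite(n_pairs) && avail < n_pairs)
    warning(sprintf("fewer read pairs available (%d) than requested (%d)",
                    avail, n_pairs))
  idx <- if (strategy == "head") seq_len(take)
         else with_seed(seed, sort(sample.int(avail, take)))
  new_read_pairs(n1[idx], unname(as.character(r1[idx])),
                 unname(as.character(r2[idx])))
}

as_read_pairs <- function(x) {
  if (inherits(x, "read_pairs")) return(x)
  if (is.character(x) && length(x) == 2)
    return(sample_pairs(x[1], x[2], n_pairs = Inf))
  stop("expected a read_pairs object or a length-2 vector of FASTQ paths",
       call. = FALSE)
}

rp_concat <- function(a, b) {
  new_read_pairs(c(a$name, b$name), c(a$seq1, b$seq1), c(a$seq2, b$seq2))
}

#' @export
length.read_pairs <- function(x) length(x$name)

#' @export
`[.read_pairs` <- function(x, i) {
  new_read_pairs(x$name[i], x$seq1[i], x$seq2[i])
}

#' @export
print.read_pairs <- function(x, ...) {
  cat(sprintf("read_pairs: %d pair(s)\n", length(x)))
  if (length(x)) {
    k <- min(3L, length(x))
    for (i in seq_len(k))
      cat(sprintf("  %s  %s.. / %s..\n", x$name[i],
                  substr(x$seq1[i], 1, 20), substr(x$seq2[i], 1, 20)))
    if (length(x) > k) cat("  ...\n")
  }
  invisible(x)
}

open_out <- function(file) {
  if (grepl("\\.gz$", file)) gzfile(file, "wb") else file(file, "wb")
}

#' Write read pairs to a pair of FASTQ files
#'
#' Emits standard 4-line FASTQ records with a constant quality string
#' (`"I"`); qualities are never interpreted by this package. Files ending in
#' `.gz` are gzip-compressed.
#'
#' @param pairs A `read_pairs` (or simulated reads) object.
#' @param fastq_1,fastq_2 Output paths for mates 1 and 2.
#' @return Invisibly, `c(fastq_1, fastq_2)`.
#' @export
write_fastq <- function(pairs, fastq_1, fastq_2) {
  stopifnot(inherits(pairs, "read_pairs"))
  qual <- strrep("I", nchar(pairs$seq1))
  qual2 <- strrep("I", nchar(pairs$seq2))
  con <- open_out(fastq_1)
  writeLines(as.vector(rbind(paste0("@", pairs$name, "/1"),
                             pairs$seq1, "+", qual)), con)
  close(con)
  con <- open_out(fastq_2)
  writeLines(as.vector(rbind(paste0("@", pairs$name, "/2"),
                             pairs$seq2, "+", qual2)), con)
  close(con)
  invisible(c(fastq_1, fastq_2))
}

#' Write a transcriptome to FASTA
#'
#' @param transcripts A transcriptome ([Biostrings::DNAStringSet]).
#' @param file Output path (`.gz` for gzip).
#' @return Invisibly, `file`.
#' @export
write_transcriptome <- function(transcripts, file) {
  tx <- as_transcriptome(transcripts)
  Biostrings::writeXStringSet(
    tx, file, compress = grepl("\\.gz$", file), format = "fasta")
  invisible(file)
}
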