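# End-to-end orchestration through files on disk.

e2e_world <- local({
  tx <- make_transcriptome(50, c(400, 1200), seed = 101)
  fa <- tempfile(fileext = ".fa")
  write_transcriptome(tx, fa)
  list(tx = tx, fa = fa)
})

sim_to_files <- function(spec, env = parent.frame()) {
  sim <- simulate_pairs(e2e_world$tx, spec)
  f1 <- withr::local_tempfile(fileext = "_1.fastq.gz", .local_envir = env)
  f2 <- withr::local_tempfile(fileext = "_2.fastq.gz", .local_envir = env)
  write_fastq(sim, f1, f2)
  c(f1, f2)
}

test_that("a fully stranded FR library is called FR_STRANDED from FASTQ files", {
  fq <- sim_to_files(sim_spec(n_pairs = 5000, p = 1, seed = 103))
  rep <- check_strandedness(fq[1], fq[2], transcripts = e2e_world$fa,
                            n_pairs = 5000, quiet = TRUE)
  expect_identical(rep$verdict, "FR_STRANDED")
  expect_equal(rep$counts$n_rf, 0)
  expect_equal(rep$stranded_proportion, 1)
})

test_that("an RF library and an unstranded library get the right verdicts", {
  fq_rf <- sim_to_files(sim_spec(n_pairs = 4000, p = 1, layout = "RF",
                                 seed = 107))
  rep_rf <- check_strandedness(fq_rf[1], fq_rf[2],
                               transcripts = e2e_world$fa,
                               n_pairs = 4000, quiet = TRUE)
  expect_identical(rep_rf$verdict, "RF_STRANDED")
  fq_un <- sim_to_files(sim_spec(n_pairs = 20000, p = 0.5, seed = 109))
  rep_un <- check_strandedness(fq_un[1], fq_un[2],
                               transcripts = e2e_world$fa,
                               n_pairs = 20000, quiet = TRUE)
  expect_identical(rep_un$verdict, "UNSTRANDED")
})

test_that("reads from an unrelated transcriptome raise the undefined-proportion error", {
  other <- make_transcriptome(30, c(400, 900), seed = 113)
  sim <- simulate_pairs(other, sim_spec(n_pairs = 1000, p = 1, seed = 127))
  err <- tryCatch(
    check_strandedness(sim, transcripts = e2e_world$tx, quiet = TRUE),
    error = function(e) conditionMessage(e))
  expect_match(err, "undefined")
  expect_match(err, "aligned")
})

test_that("machine-readable outputs are written and end-to-end deterministic", {
  fq <- sim_to_files(sim_spec(n_pairs = 3000, p = 1, seed = 131))
  out1 <- withr::local_tempfile()
  out2 <- withr::local_tempfile()
  r1 <- check_strandedness(fq[1], fq[2], transcripts = e2e_world$fa,
                           n_pairs = 3000, out_prefix = out1, audit = TRUE,
                           quiet = TRUE)
  r2 <- check_strandedness(fq[1], fq[2], transcripts = e2e_world$fa,
                           n_pairs = 3000, out_prefix = out2, quiet = TRUE)
  expect_identical(readLines(paste0(out1, ".tsv")),
                   readLines(paste0(out2, ".tsv")))
  expect_identical(readLines(paste0(out1, ".json")),
                   readLines(paste0(out2, ".json")))
  js <- jsonlite::read_json(paste0(out1, ".json"))
  expect_equal(js$n_sampled, 3000)
  expect_identical(js$verdict, r1$verdict)
  audit <- read.delim(paste0(out1, ".audit.tsv"))
  expect_equal(nrow(audit), 3000)
  expect_true(all(c("name", "call", "m1_status", "m2_orientation") %in%
                  names(audit)))
})

test_that("a saved index reproduces in-memory classification and wins over the k flag", {
  idxf <- withr::local_tempfile(fileext = ".idx")
  build_index_file(e2e_world$fa, idxf, k = 31)
  sim <- simulate_pairs(e2e_world$tx, sim_spec(n_pairs = 2000, p = 0.8,
                                               seed = 137))
  mem <- check_strandedness(sim, transcripts = e2e_world$tx, quiet = TRUE)
  expect_warning(
    disk <- check_strandedness(sim, index = idxf, k = 21, quiet = TRUE),
    "ignoring k")
  expect_equal(disk$stranded_proportion, mem$stranded_proportion)
  expect_identical(disk$verdict, mem$verdict)
  expect_identical(as.data.frame(disk), as.data.frame(mem))
})

test_that("n_pairs caps in-memory read sets and GTF strands pass through", {
  sim <- simulate_pairs(e2e_world$tx, sim_spec(n_pairs = 1500, p = 1,
                                               seed = 139))
  rep <- check_strandedness(sim, transcripts = e2e_world$tx, n_pairs = 500,
                            quiet = TRUE)
  expect_equal(rep$counts$n_total, 500)
  # GTF: every transcript on "+", pipeline unaffected
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(sprintf(
    "chr1\tsim\ttranscript\t1\t100\t.\t+\t.\tgene_id \"g\"; transcript_id \"%s\";",
    names(e2e_world$tx)), gtf)
  rep2 <- check_strandedness(sim, transcripts = e2e_world$fa, gtf = gtf,
                             n_pairs = 500, quiet = TRUE)
  expect_identical(rep2$verdict, rep$verdict)
})

test_that("the shell entry points are installed and self-describing", {
  cli <- system.file("cli", package = "strandcheck")
  scripts <- c("check-strandedness.R", "build-index.R", "simulate-reads.R")
  expect_true(all(file.exists(file.path(cli, scripts))))
})
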