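test_that("make_transcriptome is reproducible, named and GC-balanced", {
  a <- make_transcriptome(1, c(100, 100), seed = 2)
  b <- make_transcriptome(1, c(100, 100), seed = 2)
  expect_identical(as.character(a), as.character(b))
  ids <- names(make_transcriptome(10, c(50, 60), seed = 1))
  expect_identical(ids, sprintf("tx%04d", 1:10))
  tx <- make_transcriptome(1000, c(500, 3000), seed = 3)
  freq <- Biostrings::alphabetFrequency(tx, collapse = TRUE)
  gc <- sum(freq[c("C", "G")]) / sum(freq[c("A", "C", "G", "T")])
  expect_gt(gc, 0.48)
  expect_lt(gc, 0.52)
  expect_warning(make_transcriptome(2, c(20, 40), seed = 1), "below k")
})

test_that("sim_spec validates its domain", {
  expect_error(sim_spec(p = 0.4), "layout")
  expect_error(sim_spec(p = 1.1))
  expect_error(sim_spec(frag_len_mean = 50, read_len = 100), "read_len")
  expect_silent(sim_spec(p = 0.5))
})

test_that("simulation is byte-reproducible per seed, including FASTQ output", {
  tx <- toy_transcriptome(10, c(400, 1200), seed = 7)
  s1 <- simulate_pairs(tx, sim_spec(n_pairs = 300, p = 0.8, seed = 13))
  s2 <- simulate_pairs(tx, sim_spec(n_pairs = 300, p = 0.8, seed = 13))
  expect_identical(s1$seq1, s2$seq1)
  expect_identical(s1$seq2, s2$seq2)
  expect_identical(s1$truth, s2$truth)
  f1a <- withr::local_tempfile(fileext = ".fastq")
  f2a <- withr::local_tempfile(fileext = ".fastq")
  f1b <- withr::local_tempfile(fileext = ".fastq")
  f2b <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(s1, f1a, f2a)
  write_fastq(s2, f1b, f2b)
  expect_identical(readLines(f1a), readLines(f1b))
  expect_identical(readLines(f2a), readLines(f2b))
})

test_that("truth orientations follow the strandedness parameter", {
  tx <- toy_transcriptome(10, c(400, 1200), seed = 7)
  n <- 20000
  sim <- simulate_pairs(tx, sim_spec(n_pairs = n, p = 0.5, seed = 19))
  n_fr <- sum(sim$truth$orientation == "FR")
  expect_lt(abs(n_fr - n / 2), 4 * sqrt(n * 0.25))  # binomial concentration
  pure <- simulate_pairs(tx, sim_spec(n_pairs = 1000, p = 1, seed = 20))
  expect_true(all(pure$truth$orientation == "FR"))
  rf <- simulate_pairs(tx, sim_spec(n_pairs = 1000, p = 1, layout = "RF",
                                    seed = 21))
  expect_true(all(rf$truth$orientation == "RF"))
})

test_that("truth in read names agrees with a substring-orientation oracle", {
  tx <- toy_transcriptome(8, c(400, 1200), seed = 23)
  txt <- as.character(tx)
  sim <- simulate_pairs(tx, sim_spec(n_pairs = 200, p = 0.6, seed = 29))
  fields <- strsplit(sim$name, "|", fixed = TRUE)
  for (i in seq_along(sim$name)) {
    src <- fields[[i]][2]
    named_orient <- fields[[i]][3]
    expect_identical(named_orient, sim$truth$orientation[i])
    expect_identical(oracle_pair_orientation(sim$seq1[i], txt[src]),
                     named_orient)
  }
})

test_that("the substitution error model hits the requested rate", {
  tx <- toy_transcriptome(5, c(400, 800), seed = 33)
  clean <- simulate_pairs(tx, sim_spec(n_pairs = 300, p = 1, seed = 37))
  noisy <- simulate_pairs(tx, sim_spec(n_pairs = 300, p = 1, seed = 37,
                                       error_rate = 0.02))
  expect_identical(clean$truth, noisy$truth)  # same fragments drawn
  mism <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, clean$seq1, noisy$seq1)
  rate <- sum(mism) / sum(nchar(clean$seq1))
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.03)
})

test_that("mix_samples respects the ratio, interleaves and fails on deficit", {
  tx <- toy_transcriptome(6, c(400, 900), seed = 41)
  a <- simulate_pairs(tx, sim_spec(n_pairs = 1500, p = 1, seed = 43))
  b <- simulate_pairs(tx, sim_spec(n_pairs = 1500, p = 0.5, seed = 47))
  b$name <- sub("^pair", "unstr", b$name)
  m <- mix_samples(a, b, ratio = 0.5, total_pairs = 2000, seed = 53)
  expect_equal(length(m), 2000)
  expect_equal(sum(startsWith(m$name, "pair")), 1000)
  expect_equal(sum(startsWith(m$name, "unstr")), 1000)
  pure <- mix_samples(a, b, ratio = 1, total_pairs = 1200, seed = 53)
  expect_true(all(startsWith(pure$name, "pair")))
  expect_error(mix_samples(a, b, ratio = 1, total_pairs = 2000, seed = 1),
               "deficit 500")
  m1 <- mix_samples(a, b, 0.3, 1000, seed = 59)
  m2 <- mix_samples(a, b, 0.3, 1000, seed = 59)
  expect_identical(m1, m2)
})

test_that("the gDNA control draws strands fairly against a '+'-only reference", {
  g1 <- simulate_gdna_pairs(n_pairs = 100, region_len = 20000, seed = 61)
  g2 <- simulate_gdna_pairs(n_pairs = 100, region_len = 20000, seed = 61)
  expect_identical(g1$reads$seq1, g2$reads$seq1)
  expect_identical(as.character(g1$transcriptome),
                   as.character(g2$transcriptome))
  expect_true(all(S4Vectors::mcols(g1$transcriptome)$genome_strand == "+"))
  n <- 20000
  g <- simulate_gdna_pairs(n_pairs = n, region_len = 50000, seed = 67)
  n_plus <- sum(g$reads$truth$strand == "+")
  expect_lt(abs(n_plus - n / 2), 4 * sqrt(n * 0.25))
})

test_that("simulate_grid writes the sample grid with truth sidecars", {
  dir <- withr::local_tempdir()
  tx <- toy_transcriptome(20, c(300, 600), seed = 71)
  manifest <- simulate_grid(dir, read_counts = c(100L, 200L),
                            transcriptome = tx, seed = 5)
  expect_true(file.exists(file.path(dir, "transcriptome.fa")))
  expect_equal(nrow(manifest), 4)  # 2 counts x {stranded, unstranded}
  expect_true(all(file.exists(manifest$fastq_1)))
  expect_true(all(file.exists(manifest$fastq_2)))
  p <- sample_pairs(manifest$fastq_1[1], manifest$fastq_2[1], 100)
  expect_equal(length(p), 100)
})
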