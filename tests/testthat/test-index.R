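test_that("the index stores exactly the sense k-mers of the transcripts", {
  tx <- Biostrings::DNAStringSet(c(tx1 = "ACGTACGTACGTAC"))  # length 14
  idx <- build_index(tx, k = 11)
  tab <- index_kmers(idx)
  expected <- substring("ACGTACGTACGTAC", 1:4, 11:14)
  expect_identical(tab$kmer, sort(expected))
  expect_true(all(vapply(tab$ids, identical, logical(1), "tx1")))
})

test_that("k-mers containing N are skipped and short transcripts warn", {
  tx <- Biostrings::DNAStringSet(c(tx1 = "ACGTACGTACGNACGTACGTACG",
                                   stub = "ACGTACGTAC"))  # length 10 < k
  expect_warning(idx <- build_index(tx, k = 11), "shorter than k")
  tab <- index_kmers(idx)
  expect_false(any(grepl("N", tab$kmer)))
  # the two N-free windows are both "ACGTACGTACG": one key survives
  expect_identical(tab$kmer, "ACGTACGTACG")
})

test_that("a k-mer shared by two transcripts maps to both ids", {
  shared <- strrep("ACGTTGCAGGA", 1)  # 11-mer
  tx <- Biostrings::DNAStringSet(c(
    tx1 = paste0("TTTTTTTTTTTT", shared),
    tx2 = paste0(shared, "GGGGGGGGGGGG")))
  idx <- build_index(tx, k = 11)
  tab <- index_kmers(idx)
  row <- tab[tab$kmer == shared, ]
  expect_identical(sort(row$ids[[1]]), c("tx1", "tx2"))
})

test_that("k outside the supported range is rejected", {
  tx <- Biostrings::DNAStringSet(c(tx1 = strrep("ACGT", 20)))
  expect_error(build_index(tx, k = 12), "odd")
  expect_error(build_index(tx, k = 9), "odd")
  expect_error(build_index(tx, k = 33), "odd")
  expect_error(build_index(Biostrings::DNAStringSet(c(t1 = "ACGT")), k = 11),
               "cannot build|length k")
})

test_that("exact substrings are assigned with the full vote count", {
  tx <- toy_transcriptome(3, c(200, 400), seed = 5)
  idx <- build_index(tx, k = 31)
  read <- substr(as.character(tx)[1], 10, 59)  # 50 bases => 20 k-mers
  a <- assign_read(read, idx)
  expect_identical(a$status, "ASSIGNED")
  expect_identical(a$orientation, "SENSE")
  expect_equal(a$votes_sense, 20)
  expect_identical(a$transcripts, names(tx)[1])
  b <- assign_read(rc(read), idx)
  expect_identical(b$status, "ASSIGNED")
  expect_identical(b$orientation, "ANTISENSE")
  expect_equal(b$votes_antisense, 20)
  expect_identical(b$transcripts, names(tx)[1])
})

test_that("degenerate reads are UNMAPPED, not errors", {
  tx <- toy_transcriptome(3, c(200, 400), seed = 5)
  idx <- build_index(tx, k = 31)
  n50 <- strrep("N", 50)
  a <- assign_read(n50, idx)
  expect_identical(a$status, "UNMAPPED")
  expect_equal(a$votes_sense + a$votes_antisense, 0)
  short <- assign_read("ACGT", idx)  # shorter than k
  expect_identical(short$status, "UNMAPPED")
  expect_equal(short$votes_sense, 0)
})

test_that("orientation is antisymmetric under reverse complement", {
  tx <- toy_transcriptome(5, c(300, 800), seed = 21)
  idx <- build_index(tx, k = 31)
  txt <- as.character(tx)
  reads <- withr::with_seed(99, c(
    vapply(1:20, function(i) {
      t <- sample(length(txt), 1)
      st <- sample(nchar(txt[t]) - 99, 1)
      substr(txt[t], st, st + 99)
    }, ""),
    vapply(1:10, function(i) random_dna(100), "")))
  for (r in reads) {
    a <- assign_read(r, idx)
    b <- assign_read(rc(r), idx)
    expect_equal(a$votes_sense, b$votes_antisense)
    expect_equal(a$votes_antisense, b$votes_sense)
    expect_identical(a$status, b$status)
    if (a$status == "ASSIGNED") {
      expect_identical(sort(a$transcripts), sort(b$transcripts))
      expect_identical(setdiff(c("SENSE", "ANTISENSE"), a$orientation),
                       b$orientation)
    }
  }
})

test_that("k-mer voting agrees with the brute-force substring oracle", {
  tx <- toy_transcriptome(10, c(300, 2000), seed = 31)
  idx <- build_index(tx, k = 31)
  txt <- as.character(tx)
  cases <- withr::with_seed(17, lapply(1:200, function(i) {
    t <- sample(length(txt), 1)
    len <- sample(31:120, 1)
    st <- sample(nchar(txt[t]) - len + 1, 1)
    r <- substr(txt[t], st, st + len - 1)
    if (runif(1) < 0.5) r <- rc(r)
    r
  }))
  for (r in cases) {
    got <- assign_read(r, idx)
    want <- oracle_assign(r, tx)
    expect_identical(got$status, want$status)
    if (want$status == "ASSIGNED") {
      expect_identical(got$orientation, want$orientation)
      expect_identical(sort(got$transcripts), sort(want$transcripts))
    }
  }
})

test_that("lowering min_vote_frac never unmaps an assigned read", {
  tx <- toy_transcriptome(5, c(300, 800), seed = 41)
  idx <- build_index(tx, k = 31)
  txt <- as.character(tx)
  reads <- withr::with_seed(123, vapply(1:50, function(i) {
    t <- sample(length(txt), 1)
    st <- sample(nchar(txt[t]) - 99, 1)
    r <- substr(txt[t], st, st + 99)
    # sprinkle substitutions to vary the vote counts
    n_mut <- sample(0:8, 1)
    for (p in sample(100, n_mut))
      substr(r, p, p) <- sample(c("A", "C", "G", "T"), 1)
    r
  }, ""))
  for (r in reads) {
    hi <- assign_read(r, idx, min_vote_frac = 0.5)
    lo <- assign_read(r, idx, min_vote_frac = 0.1)
    if (hi$status == "ASSIGNED") expect_false(lo$status == "UNMAPPED")
  }
})

test_that("index save/load round-trips classification; integrity is enforced", {
  tx <- toy_transcriptome(8, c(300, 900), seed = 51)
  idx <- build_index(tx, k = 31)
  f <- withr::local_tempfile(fileext = ".idx")
  save_index(idx, f)
  expect_warning(idx2 <- load_index(f, k = 21), "ignoring k")
  expect_equal(idx2$k, 31)
  expect_identical(idx2$tx_ids, idx$tx_ids)
  expect_equal(idx2$n_kmers, idx$n_kmers)
  sim <- simulate_pairs(tx, sim_spec(n_pairs = 500, p = 0.8, seed = 9))
  c1 <- classify_pairs(sim, idx)
  c2 <- classify_pairs(sim, idx2)
  expect_identical(c1, c2)
  # corrupt files fail loudly
  bad <- withr::local_tempfile(fileext = ".idx")
  writeLines("garbage", bad)
  expect_error(load_index(bad), "not a strandcheck index")
  trunc <- withr::local_tempfile(fileext = ".idx")
  raw_all <- readBin(f, "raw", n = file.info(f)$size)
  writeBin(raw_all[1:200], trunc)
  expect_error(load_index(trunc), "corrupt|truncated")
})
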