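write_fastq_text <- function(path, records) {
  writeLines(as.character(unlist(lapply(records, function(r) {
    c(paste0("@", r$name), r$seq, "+", strrep("I", nchar(r$seq)))
  }))), path)
}

test_that("stLFR dialect extracts barcodes and routes placeholders to discard", {
  r1 <- withr::local_tempfile(fileext = ".fq")
  r2 <- withr::local_tempfile(fileext = ".fq")
  write_fastq_text(r1, list(
    list(name = "read1#12_34_56/1", seq = "ACGTACGT"),
    list(name = "read2#0_0_0/1", seq = "ACGTACGA"),
    list(name = "read3/1", seq = "ACGTACGC")
  ))
  write_fastq_text(r2, list(
    list(name = "read1#12_34_56/2", seq = "TTGTACGT"),
    list(name = "read2#0_0_0/2", seq = "TTGTACGA"),
    list(name = "read3/2", seq = "TTGTACGC")
  ))
  expect_message(reads <- read_barcoded_fastq(r1, r2), "2 read pair")
  expect_equal(reads$barcode, c("12_34_56", NA, NA))
  expect_equal(reads$read_id, c("read1", "read2", "read3"))
  expect_equal(reads$seq1[1], "ACGTACGT")
  expect_equal(reads$seq2[3], "TTGTACGC")
})

test_that("unpaired records raise an error naming the read", {
  r1 <- withr::local_tempfile(fileext = ".fq")
  r2 <- withr::local_tempfile(fileext = ".fq")
  write_fastq_text(r1, list(list(name = "readA#1_1_1/1", seq = "ACGT")))
  write_fastq_text(r2, list(list(name = "readB#1_1_1/2", seq = "ACGT")))
  expect_error(read_barcoded_fastq(r1, r2), "readA")
  write_fastq_text(r2, list())
  expect_error(read_barcoded_fastq(r1, r2), "unpaired")
})

test_that("sidecar dialect looks barcodes up by read id", {
  r1 <- withr::local_tempfile(fileext = ".fq")
  r2 <- withr::local_tempfile(fileext = ".fq")
  write_fastq_text(r1, list(
    list(name = "rA/1", seq = "ACGT"), list(name = "rB/1", seq = "ACGA")
  ))
  write_fastq_text(r2, list(
    list(name = "rA/2", seq = "ACGT"), list(name = "rB/2", seq = "ACGA")
  ))
  sc <- tibble::tibble(read_id = "rA", barcode = "BC7")
  reads <- read_barcoded_fastq(r1, r2, dialect = "sidecar", sidecar = sc)
  expect_equal(reads$barcode, c("BC7", NA))
})

test_that("simulator FASTQ round-trips barcodes and sequences", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  write_linked_reads(sim, dir)
  back <- read_barcoded_fastq(
    file.path(dir, "reads_1.fq.gz"), file.path(dir, "reads_2.fq.gz")
  )
  orig <- dplyr::arrange(sim$reads, read_id)
  back <- dplyr::arrange(back, read_id)
  expect_equal(back$barcode, orig$barcode)
  expect_equal(back$seq1, orig$seq1)
  expect_equal(back$seq2, orig$seq2)
  truth_back <- read_truth(file.path(dir, "truth.tsv"))
  expect_equal(tibble::as_tibble(truth_back), tibble::as_tibble(sim$truth))
})

test_that("small-barcode filter is strict and conserves reads otherwise", {
  reads <- tibble::tibble(
    barcode = rep(c("b1", "b2"), c(5, 11)),
    read_id = sprintf("r%02d", 1:16),
    seq1 = strrep("A", 20), seq2 = strrep("C", 20)
  )
  kept <- filter_small_barcodes(reads, min_pairs = 10)
  expect_equal(unique(kept$barcode), "b2")
  expect_equal(nrow(kept), 11)
  expect_equal(sort(unique(filter_small_barcodes(reads, 0)$barcode)), c("b1", "b2"))
  prof <- tibble::tibble(barcode = c("a", "b"), n_pairs = c(10L, 11L))
  expect_equal(filter_small_barcodes(prof, 10)$barcode, "b")
})

test_that("profiles equal a brute-force per-barcode set computation", {
  sim <- small_sim()
  k <- 11L
  freq <- count_kmers(c(sim$reads$seq1, sim$reads$seq2), k)
  uniq <- select_unique_kmers(freq, 2, 30)
  profiles <- build_barcode_profiles(sim$reads, uniq)
  # set-algebra oracle on a handful of barcodes
  uset <- uniq$code
  for (b in head(profiles$barcode, 4)) {
    rs <- dplyr::filter(sim$reads, barcode == b)
    kms <- unlist(lapply(c(rs$seq1, rs$seq2), function(r) {
      canonicalize(substring(r, 1:(nchar(r) - k + 1), k:nchar(r)))
    }))
    expected <- sort(intersect(unique(encode_kmers(kms)), uset))
    got <- profiles$kmers[[match(b, profiles$barcode)]]
    expect_identical(got, expected)
    expect_equal(
      profiles$n_kmers[match(b, profiles$barcode)],
      length(unique(encode_kmers(kms)))
    )
  }
  expect_true(all(profiles$unique_fraction >= 0 & profiles$unique_fraction <= 1))
  # pair accounting matches the input
  expect_equal(sum(profiles$n_pairs), nrow(sim$reads))
})

test_that("profiles are invariant to input read order", {
  sim <- small_sim()
  freq <- count_kmers(c(sim$reads$seq1, sim$reads$seq2), 13)
  uniq <- select_unique_kmers(freq, 2, 30)
  p1 <- build_barcode_profiles(sim$reads, uniq)
  set.seed(9)
  p2 <- build_barcode_profiles(sim$reads[sample.int(nrow(sim$reads)), ], uniq)
  expect_identical(tibble::as_tibble(p1), tibble::as_tibble(p2))
})
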