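test_that("phred scores map to base-call accuracy", {
  expect_equal(phred_accuracy(20), 0.99)
  expect_equal(phred_accuracy(0), 0.0)
  expect_equal(phred_accuracy(30), 0.999)
  expect_error(phred_accuracy(-1), ">= 0")
})

test_that("sliding-window trimming matches the brute-force window scan", {
  # frozen oracle values
  expect_identical(oracle_trim_len(rep(30L, 30)), 30L)
  expect_identical(oracle_trim_len(rep(2L, 30)), 0L)
  expect_identical(oracle_trim_len(c(rep(30L, 16), rep(2L, 8))), 14L)

  cases <- list(rep(30L, 30),
                rep(2L, 30),
                c(rep(30L, 16), rep(2L, 8)),
                c(10L, 30L, 30L, 30L, 30L),    # low leading base, window ok
                c(30L, 30L),                   # shorter than window, good
                c(5L, 5L))                     # shorter than window, bad
  for (q in cases) {
    reads <- make_reads(strrep("A", length(q)), q)
    got <- trim_quality(reads)
    expect_identical(nchar(got$bases), oracle_trim_len(q))
    expect_identical(got$quals[[1]], q[seq_len(oracle_trim_len(q))])
  }
})

test_that("trimming always returns a prefix and never lengthens", {
  set.seed(101)
  for (i in 1:50) {
    L <- sample(1:60, 1)
    q <- sample(0:40, L, replace = TRUE)
    b <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
    got <- trim_quality(make_reads(b, q))
    expect_lte(nchar(got$bases), L)
    expect_identical(got$bases, substr(b, 1, nchar(got$bases)))
    expect_identical(nchar(got$bases), oracle_trim_len(q))
  }
})

test_that("malformed read records are rejected with the read id", {
  bad <- make_reads("ACGT", list(c(30L, 30L)))
  expect_error(trim_quality(bad), "r001")
})

test_that("insert extraction captures the leading group per pool type", {
  at <- extraction_rule("AT")
  expect_identical(extract_insert(paste0("ATATATATATAT", "CTCT", "AGAT"), at),
                   "ATATATATATAT")
  # maximal capture: 112-nt insert in a 120-nt read
  r112 <- paste0(strrep("AT", 56), "CTCT", "AGAT")
  expect_identical(nchar(r112), 120L)
  expect_identical(nchar(extract_insert(r112, at)), 112L)
  # below the 12-nt minimum
  expect_true(is.na(extract_insert(paste0("ATATATATATA", "CTCT", "AGAT"), at)))
  # alphabet mismatch
  expect_true(is.na(extract_insert(paste0(strrep("GC", 10), "CTCT", "AGAT"),
                                   at)))
  gc <- extraction_rule("GC")
  expect_identical(extract_insert(paste0(strrep("GC", 10), "CTCT", "AGAT"),
                                  gc), strrep("GC", 10))
})

test_that("extraction agrees with the explicit rightmost-split scan", {
  set.seed(202)
  rules <- list(AT = extraction_rule("AT"), GC = extraction_rule("GC"),
                ATGC = extraction_rule("ATGC"))
  for (i in 1:200) {
    rule <- rules[[sample(3, 1)]]
    ins_len <- sample(8:30, 1)
    ins <- paste(sample(rule$alphabet, ins_len, replace = TRUE),
                 collapse = "")
    tail_len <- sample(2:8, 1)
    tl <- paste(sample(c("C", "T"), tail_len, replace = TRUE), collapse = "")
    read <- paste0(ins, tl, if (runif(1) < 0.8) "AGAT" else "AGA")
    expect_identical(extract_insert(read, rule),
                     oracle_extract(read, rule$alphabet),
                     info = paste(rule$pool_type, read))
  }
})

test_that("structured reads obey extracted = read - tail - 4", {
  # the insert/tail boundary is unambiguous when the first tail base lies
  # outside the insert alphabet (otherwise greedy capture may legitimately
  # absorb surplus tail bases; the differential test above covers those)
  set.seed(303)
  for (i in 1:50) {
    rule <- extraction_rule(sample(c("AT", "GC"), 1))
    ins_len <- sample(12:100, 1)
    tail_len <- sample(4:10, 1)
    ins <- paste(sample(rule$alphabet, ins_len, replace = TRUE),
                 collapse = "")
    first <- if (rule$pool_type == "AT") "C" else "T"
    tl <- paste0(first, paste(sample(c("C", "T"), tail_len - 1L,
                                     replace = TRUE), collapse = ""))
    read <- paste0(ins, tl, "AGAT")
    got <- extract_insert(read, rule)
    expect_identical(nchar(got), nchar(read) - tail_len - 4L)
    # re-validate every output against the anchored pattern
    expect_true(grepl(rule$pattern, paste0(got, tl, "AGAT"), perl = TRUE))
  }
})

test_that("FASTQ write/read round-trips records exactly", {
  set.seed(404)
  n <- 100
  bases <- rand_seqs(n, 40)
  quals <- lapply(1:n, function(i) sample(0:41, 40, replace = TRUE))
  reads <- make_reads(bases, quals)
  f <- tempfile(fileext = ".fastq")
  write_fastq(reads, f)
  back <- read_fastq(f)
  expect_identical(back$read_id, reads$read_id)
  expect_identical(back$bases, reads$bases)
  expect_identical(unclass(back$quals), unclass(reads$quals),
                   ignore_attr = TRUE)
  # gzip round trip too
  fz <- tempfile(fileext = ".fastq.gz")
  write_fastq(reads, fz)
  expect_identical(read_fastq(fz)$bases, reads$bases)
})

test_that("empty and malformed FASTQ files are handled", {
  f <- tempfile(fileext = ".fastq")
  file.create(f)
  expect_identical(nrow(read_fastq(f)), 0L)
  writeLines(c("@r1", "ACGT", "+", "II"), f)      # short quality line
  expect_error(read_fastq(f), "length 2")
  writeLines(c("@r1", "ACGT", "+"), f)            # truncated record
  expect_error(read_fastq(f), "truncated")
})

test_that("extract_pool reports counts by category", {
  reads <- make_reads(
    c(paste0(strrep("AT", 10), "CTCT", "AGAT"),   # extractable
      strrep("G", 24),                            # no match
      strrep("A", 24)),                           # trimmed to empty
    list(rep(36L, 28), rep(36L, 24), rep(2L, 24)))
  res <- extract_pool(reads, "AT")
  expect_identical(res$report$total_reads, 3L)
  expect_identical(res$report$extracted, 1L)
  expect_identical(res$report$no_match, 1L)
  expect_identical(res$report$trimmed_to_empty, 1L)
  expect_identical(res$pool$seqs, strrep("AT", 10))
  expect_identical(res$source_read_id, "r001")
})
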