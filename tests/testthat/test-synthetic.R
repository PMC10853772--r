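test_that("pool generation is seeded and respects the bias", {
  p1 <- generate_pool(200, 0.7, "G", "GC", seed = 99)
  p2 <- generate_pool(200, 0.7, "G", "GC", seed = 99)
  expect_identical(p1$seqs, p2$seqs)
  expect_false(identical(p1$seqs, generate_pool(200, 0.7, "G", "GC",
                                                seed = 100)$seqs))
  big <- generate_pool(10000, 0.7, "G", "GC", seed = 101)
  s <- summarize_pool(big, "G")
  expect_lt(abs(s$f_bar - 0.7), 3 * sqrt(0.7 * 0.3 / s$total_nt))
  expect_error(generate_pool(10, 1.0, "A"), "strictly")
  near <- generate_pool(100, 0.999, "A", seed = 102)
  expect_gt(summarize_pool(near, "A")$f_bar, 0.99)
})

test_that("distinct seeds give homogeneous k-mer statistics", {
  a <- generate_pool(20000, 0.5, "A", seed = 7)
  b <- generate_pool(20000, 0.5, "A", seed = 8)
  ca <- kmer_symmetry(a, 4)$abundance
  cb <- kmer_symmetry(b, 4)$abundance
  keep <- ca + cb > 0
  # same generating distribution: homogeneity chi-square is unremarkable
  pval <- suppressWarnings(stats::chisq.test(rbind(ca[keep],
                                                   cb[keep]))$p.value)
  expect_gt(pval, 0.001)
})

test_that("the injector modulation stays a valid probability", {
  expect_error(inject_signatures(list(c(20, 0.95)), n = 10,
                                 period = list(p = 2, amplitude = 0.2,
                                               noise = 0), seed = 1),
               "outside")
  expect_error(inject_signatures(list(c(20, 1.2)), n = 10, seed = 1),
               "\\(0, 1\\)")
})

test_that("replication conserves strand count and grows mass", {
  p0 <- generate_pool(300, 0.7, "A", seed = 21)
  expect_identical(simulate_replication(p0, rounds = 0)$seqs, p0$seqs)
  p1 <- simulate_replication(p0, rounds = 5, seed = 22)
  expect_identical(length(p1$seqs), length(p0$seqs))
  expect_gte(sum(nchar(p1$seqs)), sum(nchar(p0$seqs)))
  lg <- attr(p1, "log")
  expect_identical(nrow(lg), 5L)
  expect_true(all(diff(lg$total_nt) >= 0))
  # determinism
  p1b <- simulate_replication(p0, rounds = 5, seed = 22)
  expect_identical(p1$seqs, p1b$seqs)
  # stacking-weighted annealing obeys the same conservation laws
  p1c <- simulate_replication(p0, rounds = 2, anneal_weighting = "stacking",
                              seed = 23)
  expect_identical(length(p1c$seqs), length(p0$seqs))
  expect_gte(sum(nchar(p1c$seqs)), sum(nchar(p0$seqs)))
})

test_that("replication homogenizes the pool average", {
  closer <- logical(6)
  for (s in 1:6) {
    p0 <- generate_pool(800, 0.7, "A", seed = 30 + s)
    f0 <- summarize_pool(p0, "A")$f_bar
    p1 <- simulate_replication(p0, rounds = 10, seed = 60 + s)
    f1 <- summarize_pool(p1, "A")$f_bar
    closer[s] <- abs(f1 - 0.5) < abs(f0 - 0.5)
  }
  expect_gte(sum(closer), 5)
})

test_that("extension retains head bias and inverts the appended segment", {
  p0 <- generate_pool(3000, 0.7, "A", seed = 71)
  p1 <- simulate_replication(p0, rounds = 1, seed = 72)
  ext <- p1$seqs[nchar(p1$seqs) > 12]
  expect_gt(length(ext), 500)
  m <- positional_fractions(pool(ext, "AT"), "A", min_support = 1)
  head_f <- with(m[m$position <= 12, ], weighted.mean(fraction, support))
  app_f <- with(m[m$position > 12, ], weighted.mean(fraction, support))
  n_head <- sum(m$support[m$position <= 12])
  expect_lt(abs(head_f - 0.7), 3 * sqrt(0.7 * 0.3 / n_head))
  # appended bases are complementary copies of biased-template prefixes;
  # annealing-site multiplicity correlates flanks, so the match to 1 - f
  # is approximate (documented): assert inversion plus a 0.05 band
  expect_lt(app_f, 0.5 - 3 * sqrt(0.25 / sum(m$support[m$position > 12])))
  expect_lt(abs(app_f - 0.3), 0.05)
})

test_that("emitted FASTQ round-trips through extraction", {
  p <- generate_pool(150, 0.6, "T", length = 20, seed = 81)
  f <- tempfile(fileext = ".fastq")
  emit_fastq(p, f)
  res <- extract_pool(f, "AT")
  expect_identical(res$report$extracted, 150L)
  expect_setequal(res$pool$seqs, p$seqs)
  expect_error(emit_fastq(p, f, tail = "CTA"), "CT")
})

test_that("the 120-nt capture window bounds recoverable insert length", {
  ins112 <- paste(rep(c("A", "T"), 56)[1:112], collapse = "")
  f <- tempfile(fileext = ".fastq")
  emit_fastq(pool(ins112, "AT"), f)
  reads <- read_fastq(f)
  expect_identical(nchar(reads$bases), 120L)
  res <- extract_pool(f, "AT")
  expect_identical(nchar(res$pool$seqs), 112L)
  # longer inserts lose the adapter to truncation and are left behind
  ins150 <- strrep("AT", 75)
  emit_fastq(pool(ins150, "AT"), f)
  res2 <- extract_pool(f, "AT")
  expect_identical(res2$report$extracted, 0L)
  expect_identical(res2$report$no_match, 1L)
})

test_that("degraded 3' tails are trimmed before extraction", {
  p <- pool(strrep("TA", 20), "AT")
  f <- tempfile(fileext = ".fastq")
  emit_fastq(p, f, decay_len = 10, decay_to = 2, degrade_frac = 1, seed = 5)
  reads <- read_fastq(f)
  trimmed <- trim_quality(reads)
  expect_lt(nchar(trimmed$bases), nchar(reads$bases))
})
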