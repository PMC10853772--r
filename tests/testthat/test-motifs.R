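test_that("zebraness counts alternating dimer steps", {
  expect_equal(zebraness(c("ATATAT", "AAAA", "AATT")), c(1, 0, 1 / 3))
  expect_error(zebraness("A"), "length >= 2")
  # exact invariances: reversal and complementation
  set.seed(211)
  s <- rand_seqs(30, 15)
  expect_equal(zebraness(s), zebraness(oracle_revcomp(s)))
  expect_equal(zebraness(s), zebraness(complement_seq(s)))
})

test_that("i.i.d. pools have zebraness 2 f (1 - f)", {
  for (f in c(0.5, 0.7)) {
    p <- generate_pool(4000, f, "T", length = 30, seed = round(100 * f))
    z <- mean(zebraness(p$seqs))
    se <- sqrt(0.25 / (4000 * 29))   # transition-level SE upper bound
    expect_lt(abs(z - 2 * f * (1 - f)), 5 * se)
  }
})

test_that("longest self-complementary region matches frozen examples", {
  # oracle-confirmed: rc("AT")=="AT", rc("AATT")=="AATT", homopolymer has none
  expect_identical(oracle_lcs_selfcomp("AT"), 2L)
  expect_identical(oracle_lcs_selfcomp("AAAA"), 0L)
  expect_identical(oracle_lcs_selfcomp("AATT"), 4L)
  expect_identical(oracle_lcs_selfcomp("GGGGCCCC"), 8L)
  expect_identical(longest_self_complementary(c("AT", "AAAA", "AATT",
                                                "GGGGCCCC")),
                   c(2L, 0L, 4L, 8L))
})

test_that("self-complementarity agrees with brute force on random sequences", {
  set.seed(222)
  seqs <- c(rand_seqs(60, 12, c("A", "T")), rand_seqs(60, 20))
  expect_identical(longest_self_complementary(seqs),
                   vapply(seqs, oracle_lcs_selfcomp, integer(1),
                          USE.NAMES = FALSE))
  expect_identical(longest_self_complementary(seqs, "foldback"),
                   vapply(seqs, oracle_foldback, integer(1),
                          USE.NAMES = FALSE))
  # exact invariances
  expect_identical(longest_self_complementary(seqs),
                   longest_self_complementary(oracle_revcomp(seqs)))
  expect_true(all(longest_self_complementary(seqs) <= nchar(seqs)))
  expect_identical(oracle_revcomp(oracle_revcomp(seqs)), seqs)
  expect_identical(revcomp(revcomp(seqs)), seqs)
})

test_that("planted hairpins score their full length", {
  set.seed(233)
  half <- rand_seqs(20, 15)
  hairpins <- paste0(half, oracle_revcomp(half))
  expect_identical(longest_self_complementary(hairpins),
                   rep(30L, 20))
  expect_identical(longest_self_complementary(hairpins, "foldback"),
                   rep(15L, 20))
})

test_that("selfcomp profiles compare pools against a matched reference", {
  set.seed(244)
  p <- pool(rand_seqs(120, 30, c("A", "T")), "AT")
  prof <- selfcomp_profile(p, seed = 1, min_support = 50)
  # a random pool against its own kind of reference: curves agree
  expect_lt(abs(prof$mean_selfcomp - prof$mean_selfcomp_ref), 3 *
              sqrt(2 * stats::var(longest_self_complementary(p$seqs)) / 120))
  # long zebra runs are self-complementary: pool exceeds reference
  zebra <- pool(rep(strrep("AT", 25), 60), "AT")
  zprof <- selfcomp_profile(zebra, seed = 1, min_support = 50)
  expect_gt(zprof$mean_selfcomp, zprof$mean_selfcomp_ref)
  expect_equal(zprof$mean_selfcomp, 50)
})

test_that("k-mer symmetry scores reverse-complement pairing of abundances", {
  # a pool closed under reverse complement is perfectly symmetric
  set.seed(255)
  half <- rand_seqs(40, 20)
  closed <- pool(c(half, oracle_revcomp(half)), "ATGC")
  expect_equal(kmer_symmetry(closed, 4)$symmetry_score, 0)
  # homopolymer pool: the only scored pair is maximally asymmetric
  mono <- pool(rep(strrep("A", 10), 5), "AT")
  ks <- kmer_symmetry(mono, 4)
  expect_equal(ks$symmetry_score, 1)
  expect_identical(ks$n_pairs_scored, 1L)
  expect_error(kmer_symmetry(mono, 0), "k must be")
  # involution on the key set
  expect_setequal(revcomp(names(ks$abundance)), names(ks$abundance))
})

test_that("replication lowers k-mer asymmetry of a biased pool", {
  lower <- logical(10)
  for (s in 1:10) {
    p0 <- generate_pool(400, 0.7, "A", seed = 300 + s)
    s0 <- kmer_symmetry(p0, 4)$symmetry_score
    p1 <- simulate_replication(p0, rounds = 6, seed = 400 + s)
    s1 <- kmer_symmetry(p1, 4)$symmetry_score
    lower[s] <- s1 < s0
  }
  expect_gte(sum(lower), 9)
})
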