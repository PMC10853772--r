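#' Zebraness of sequences
#'
#' Zebraness is the fraction of adjacent base pairs that alternate (XY or
#' YX dimer steps); its complement, the bulky fraction, counts homodimer
#' steps (XX, YY). For an i.i.d. binary pool with reference-base fraction f
#' the expected zebraness is 2 f (1 - f), so 0.5 marks the unbiased random
#' level. For quaternary sequences any adjacent unequal pair counts as
#' alternating.
#'
#' @param seqs Character vector of sequences, each of length >= 2.
#' @return Numeric vector of zebraness values in `[0, 1]`.
#' @examples
#' zebraness(c("ATATAT", "AAAA", "AATT"))
#' @export
zebraness <- function(seqs) {
  L <- nchar(seqs)
  if (any(L < 2)) stop("zebraness needs sequences of length >= 2")
  a <- substr(seqs, 1L, L - 1L)
  b <- substr(seqs, 2L, L)
  ca <- strsplit(a, "")
  cb <- strsplit(b, "")
  mapply(function(u, v) mean(u != v), ca, cb, USE.NAMES = FALSE)
}

#' Longest self-complementary region of sequences
#'
#' The default `"substring"` variant returns the length of the longest
#' contiguous substring of a sequence whose reverse complement also occurs
#' in the same sequence (equivalently, the longest common substring of the
#' sequence and its reverse complement). Overlapping self-hits are allowed:
#' a perfect alternating (zebra) run is its own reverse complement and
#' scores its full length. The stricter `"foldback"` variant returns the
#' longest hairpin stem: the maximal run of pairings s[i+t] ~ s[j-t] with
#' disjoint arms, i.e. the arm length of the best fold-back site.
#'
#' @param seqs Character vector of non-empty sequences.
#' @param variant `"substring"` (default) or `"foldback"`.
#' @return Integer vector of region lengths (nt); 0 when no complementary
#'   region exists.
#' @examples
#' longest_self_complementary(c("AT", "AAAA", "AATT", "GGGGCCCC"))
#' @export
longest_self_complementary <- function(seqs,
                                       variant = c("substring", "foldback")) {
  variant <- match.arg(variant)
  if (any(nchar(seqs) == 0L)) stop("sequences must be non-empty")
  if (variant == "substring") {
    .lcs_substring_len(seqs, revcomp(seqs))
  } else {
    .foldback_len(seqs)
  }
}

#' Zebraness profile by sequence length
#'
#' @param pool A [pool()] or character vector.
#' @param min_support Minimum sequences per length bin (default 50).
#' @return Data.frame with columns `length`, `mean_zebraness`, `support`.
#' @export
zebraness_profile <- function(pool, min_support = 50L) {
  pool <- as_pool(pool)
  seqs <- pool$seqs[nchar(pool$seqs) >= 2L]
  z <- zebraness(seqs)
  by_len <- split(z, nchar(seqs))
  supp <- lengths(by_len)
  keep <- supp >= min_support
  data.frame(length = as.integer(names(by_len)[keep]),
             mean_zebraness = vapply(by_len[keep], mean, numeric(1),
                                     USE.NAMES = FALSE),
             support = as.integer(supp[keep]))
}

#' Self-complementarity profile with a matched random reference
#'
#' Per-length mean of the longest self-complementary region for the pool,
#' together with the same curve for a random reference pool of identical
#' alphabet and length histogram generated with base fraction 0.50. The
#' reference provides the expected self-complementarity in the absence of
#' pool- or sequence-level patterns.
#'
#' @param pool A [pool()] or character vector.
#' @param seed Seed for the random reference pool (default 7001).
#' @param variant Passed to [longest_self_complementary()].
#' @param min_support Minimum sequences per length bin (default 50).
#' @return Data.frame with columns `length`, `mean_selfcomp`,
#'   `mean_selfcomp_ref`, `support`.
#' @export
selfcomp_profile <- function(pool, seed = 7001L,
                             variant = c("substring", "foldback"),
                             min_support = 50L) {
  pool <- as_pool(pool)
  variant <- match.arg(variant)
  lens <- nchar(pool$seqs)
  ref_seqs <- withr_seed(seed, random_pool_like(lens, pool$alphabet))
  sc <- longest_self_complementary(pool$seqs, variant)
  sc_ref <- longest_self_complementary(ref_seqs, variant)
  agg <- function(v, l) vapply(split(v, l), mean, numeric(1))
  by_len <- split(sc, lens)
  supp <- lengths(by_len)
  keep <- supp >= min_support
  m <- agg(sc, lens)[keep]
  mr <- agg(sc_ref, nchar(ref_seqs))[keep]
  data.frame(length = as.integer(names(m)), mean_selfcomp = unname(m),
             mean_selfcomp_ref = unname(mr), support = as.integer(supp[keep]))
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# random sequences with the given lengths over alphabet, all bases equiprobable
random_pool_like <- function(lens, alphabet) {
  total <- sum(lens)
  bases <- sample(alphabet, total, replace = TRUE)
  vapply(split(bases, rep.int(seq_along(lens), lens)),
         paste0, character(1), collapse = "", USE.NAMES = FALSE)
}

#' k-mer reverse-complement abundance symmetry
#'
#' Counts all overlapping k-mers of the pool and scores how similar the
#' abundances of reverse-complementary k-mer pairs are. The symmetry score
#' is the mean, over unordered pairs \{w, rc(w)\} with w != rc(w) and
#' nonzero total count, of |count(w) - count(rc(w))| / (count(w) +
#' count(rc(w))): 0 for a pool whose k-mer content is perfectly
#' reverse-complement symmetric, 1 for maximal asymmetry. Complementary
#' copying during templated replication drives this score down.
#'
#' @param pool A [pool()] or character vector; all sequences must be >= k.
#' @param k Motif length (default 4).
#' @return A list of class `"kmer_symmetry"`: `k`, `abundance` (named
#'   integer vector over all k-mers of the pool alphabet, lexicographic),
#'   `symmetry_score`, `n_pairs_scored`.
#' @export
kmer_symmetry <- function(pool, k = 4L) {
  if (k < 1L) stop("k must be >= 1")
  pool <- as_pool(pool)
  if (any(nchar(pool$seqs) < k)) stop("all sequences must be >= k nt")
  counts <- colSums(Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(pool$seqs), width = k))
  # restrict to k-mers over the pool alphabet
  kmers <- names(counts)
  in_alpha <- !grepl(sprintf("[^%s]", paste(pool$alphabet, collapse = "")),
                     kmers)
  counts <- counts[in_alpha]
  rc <- revcomp(names(counts))
  reps <- names(counts) < rc            # representative of each proper pair
  w <- names(counts)[reps]
  cw <- as.numeric(counts[w])
  crc <- as.numeric(counts[rc[reps]])
  tot <- cw + crc
  scored <- tot > 0
  score <- if (any(scored)) mean(abs(cw - crc)[scored] / tot[scored]) else NaN
  structure(list(k = as.integer(k),
                 abundance = counts[order(names(counts))],
                 symmetry_score = score,
                 n_pairs_scored = sum(scored)),
            class = "kmer_symmetry")
}
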