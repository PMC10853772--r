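#' Generate a biased random pool
#'
#' Draws `n` i.i.d. sequences of fixed length whose positions are
#' independent draws with probability `f` for the biased base (the
#' remaining probability is split equally over the rest of the alphabet).
#' This emulates the chemically synthesized starting pools: random 12-mers
#' over a binary (AT or GC) or quaternary alphabet with a stated
#' per-position base bias.
#'
#' @param n Number of sequences.
#' @param f Per-position probability of the biased base, in (0, 1).
#' @param biased_base The base favored by the bias (default `"A"`).
#' @param pool_type `"AT"`, `"GC"` or `"ATGC"`.
#' @param length Sequence length (default 12).
#' @param label Pool label.
#' @param seed RNG seed (default 1001).
#' @return A [pool()].
#' @examples
#' p <- generate_pool(100, f = 0.7, biased_base = "A", seed = 1)
#' @export
generate_pool <- function(n, f, biased_base = "A",
                          pool_type = c("AT", "GC", "ATGC"),
                          length = 12L, label = "", seed = 1001L) {
  pool_type <- match.arg(pool_type)
  if (!(f > 0 && f < 1)) stop("bias f must lie strictly in (0, 1)")
  alphabet <- strsplit(pool_type, "")[[1]]
  if (!biased_base %in% alphabet) {
    stop("biased_base '", biased_base, "' not in pool type ", pool_type)
  }
  probs <- stats::setNames(rep((1 - f) / (length(alphabet) - 1),
                               length(alphabet)), alphabet)
  probs[biased_base] <- f
  withr_seed(seed, {
    bases <- sample(alphabet, n * length, replace = TRUE, prob = probs)
    seqs <- vapply(split(bases, rep(seq_len(n), each = length)),
                   paste0, character(1), collapse = "", USE.NAMES = FALSE)
    pool(seqs, pool_type, label = label, validate = FALSE)
  })
}

#' Generate a pool with planted compositional signatures
#'
#' Ground-truth generator for parameter-recovery tests: sequences are drawn
#' from an explicit per-position probability profile for the reference
#' base, built from bias blocks (5'->3') and an optional sinusoidal
#' periodic modulation whose phase is randomized per sequence (integer
#' phases for integer periods, so the planted conditional-probability
#' amplitude has a closed form). Optional flip noise degrades the
#' modulation.
#'
#' @param blocks List of `c(length, bias)` pairs defining consecutive
#'   blocks of per-position probability of `ref_base`.
#' @param n Number of sequences.
#' @param period Optional `list(p = , amplitude = , noise = )`: period in
#'   nt, modulation amplitude on the probability scale, and per-position
#'   flip probability (binary alphabet only).
#' @param ref_base Base whose probability the profile describes.
#' @param pool_type `"AT"` or `"GC"`.
#' @param label Pool label.
#' @param seed RNG seed.
#' @return A [pool()] with attribute `"truth"` recording the planted
#'   ground-truth parameters.
#' @export
inject_signatures <- function(blocks, n, period = NULL, ref_base = "T",
                              pool_type = c("AT", "GC"), label = "",
                              seed = 1001L) {
  pool_type <- match.arg(pool_type)
  alphabet <- strsplit(pool_type, "")[[1]]
  stopifnot(ref_base %in% alphabet)
  other <- setdiff(alphabet, ref_base)
  prof <- unlist(lapply(blocks, function(b) rep(b[2], b[1])))
  if (any(prof <= 0 | prof >= 1)) stop("block biases must lie in (0, 1)")
  L <- length(prof)
  withr_seed(seed, {
    seqs <- character(n)
    for (s in seq_len(n)) {
      p <- prof
      if (!is.null(period)) {
        ph <- if (period$p == round(period$p)) {
          sample.int(period$p, 1L) - 1L
        } else stats::runif(1, 0, period$p)
        p <- p + period$amplitude * cospi(2 * (seq_len(L) + ph) / period$p)
        if (any(p < 0 | p > 1)) {
          stop("periodic modulation pushes probabilities outside [0, 1]")
        }
      }
      draw <- ifelse(stats::runif(L) < p, ref_base, other)
      if (!is.null(period) && !is.null(period$noise) && period$noise > 0) {
        flip <- stats::runif(L) < period$noise
        draw[flip] <- ifelse(draw[flip] == ref_base, other, ref_base)
      }
      seqs[s] <- paste(draw, collapse = "")
    }
    out <- pool(seqs, pool_type, label = label, validate = FALSE)
    attr(out, "truth") <- list(blocks = blocks, period = period,
                               ref_base = ref_base, seed = seed)
    out
  })
}

#' Toy templated-replication simulator
#'
#' Minimal mechanistic model of isothermal primer extension with strand
#' displacement. Each round, a fraction of the pool is sampled (without
#' replacement) as primers. A primer anneals where its 3'-terminal
#' `min_overlap` bases are exactly complementary to an internal site of
#' another sequence (the template) and is extended 5'->3' with the
#' complement of the template's remaining 5'-ward bases. Sequences of at
#' least `self_templation_min_length` nt may instead fold back: the same
#' 3'-terminal overlap anneals to a complementary site upstream within the
#' strand itself, and extension copies the strand's own 5' region.
#' Optionally, candidate annealing sites are weighted by the Boltzmann
#' factor of the stacking free energy of the full contiguous overlap
#' duplex. The strand count is conserved (nucleotides are only appended to
#' existing strands) and total mass is non-decreasing.
#'
#' The simulator is deliberately a qualitative toy: it produces the
#' mechanistic signatures of templated replication (pool-average
#' homogenization, retained 5' head bias, inverted bias in the appended
#' segment) without modeling enzyme kinetics.
#'
#' @param pool A [pool()].
#' @param rounds Number of replication rounds, >= 0.
#' @param min_overlap Required contiguous 3'-complementarity in nt
#'   (default 4).
#' @param extend_fraction Fraction of the pool sampled as primers per round
#'   (default 0.5).
#' @param anneal_weighting `"none"` (uniform over candidate sites) or
#'   `"stacking"` (Boltzmann-weighted by overlap stacking energy).
#' @param self_templation_min_length Minimum strand length for fold-back
#'   self-templation (default 24).
#' @param self_templation_prob Probability that an eligible strand
#'   self-templates instead of pool-templating (default 0.2).
#' @param max_candidates Candidate sites examined per primer under
#'   stacking weighting (default 30).
#' @param rt Thermal energy in kcal/mol for the Boltzmann weight
#'   (default 0.616, i.e. ~37 C).
#' @param seed RNG seed (default 2002).
#' @return The replicated [pool()], with attribute `"log"`: per-round
#'   data.frame of `round`, `primers`, `extended`, `self_templated`,
#'   `no_site`, `total_nt`.
#' @export
simulate_replication <- function(pool, rounds, min_overlap = 4L,
                                 extend_fraction = 0.5,
                                 anneal_weighting = c("none", "stacking"),
                                 self_templation_min_length = 24L,
                                 self_templation_prob = 0.2,
                                 max_candidates = 30L,
                                 rt = 0.616, seed = 2002L) {
  anneal_weighting <- match.arg(anneal_weighting)
  pool <- as_pool(pool)
  if (!length(pool$seqs)) stop("empty pool")
  stopifnot(rounds >= 0, min_overlap >= 1)
  w <- as.integer(min_overlap)
  seqs <- pool$seqs
  n <- length(seqs)
  log <- vector("list", rounds)
  nn <- if (anneal_weighting == "stacking") nn_table() else NULL
  withr_seed(seed, {
    for (r in seq_len(rounds)) {
      primers <- sample.int(n, ceiling(extend_fraction * n))
      lens <- nchar(seqs)
      suffix <- substr(seqs[primers], lens[primers] - w + 1L, lens[primers])
      key <- revcomp(suffix)
      # self-templation split
      eligible <- lens[primers] >= self_templation_min_length
      selfer <- eligible & stats::runif(length(primers)) < self_templation_prob
      n_self <- 0L; n_ext <- 0L; n_miss <- 0L
      # --- self-templation: anneal own 3' suffix upstream in the strand
      self_i <- integer(0); self_pos <- integer(0)
      for (ii in which(selfer)) {
        i <- primers[ii]
        prefix_region <- substr(seqs[i], 1L, nchar(seqs[i]) - w)
        hits <- gregexpr(key[ii], prefix_region, fixed = TRUE)[[1]]
        hits <- hits[hits >= 2L]
        if (length(hits) == 0L || hits[1] == -1L) { n_miss <- n_miss + 1L; next }
        self_i <- c(self_i, i)
        self_pos <- c(self_pos, if (length(hits) == 1L) hits else
          sample(hits, 1L))
      }
      if (length(self_i)) {
        seqs[self_i] <- paste0(seqs[self_i],
                               revcomp(substr(seqs[self_i], 1L,
                                              self_pos - 1L)))
        n_self <- length(self_i)
      }
      # --- pool templation, grouped by overlap key for vectorization
      pooler <- which(!selfer)
      occ <- kmer_occurrences(seqs, unique(key[pooler]))
      for (k in unique(key[pooler])) {
        grp <- primers[pooler[key[pooler] == k]]
        ok <- occ[[k]]
        if (is.null(ok) || nrow(ok) == 0L) { n_miss <- n_miss + length(grp); next }
        si <- ok$seq_idx; po <- ok$pos
        if (anneal_weighting == "none") {
          # uniform site choice; resample self-collisions, drop leftovers
          pick <- sample.int(length(si), length(grp), replace = TRUE)
          for (retry in 1:5) {
            bad <- si[pick] == grp
            if (!any(bad)) break
            pick[bad] <- sample.int(length(si), sum(bad), replace = TRUE)
          }
          usable <- si[pick] != grp
          n_miss <- n_miss + sum(!usable)
          g <- grp[usable]; pk <- pick[usable]
          seqs[g] <- paste0(seqs[g],
                            revcomp(substr(seqs[si[pk]], 1L, po[pk] - 1L)))
          n_ext <- n_ext + length(g)
        } else {
          for (i in grp) {
            cand <- which(si != i)
            if (!length(cand)) { n_miss <- n_miss + 1L; next }
            if (length(cand) > max_candidates) {
              cand <- sample(cand, max_candidates)
            }
            wts <- vapply(cand, function(ci) {
              ov <- overlap_extent(seqs[i], seqs[si[ci]], po[ci], w)
              exp(-stacking_score(ov, nn) / rt)
            }, numeric(1))
            pick <- cand[sample.int(length(cand), 1L, prob = wts)]
            seqs[i] <- paste0(seqs[i],
                              revcomp(substr(seqs[si[pick]], 1L,
                                             po[pick] - 1L)))
            n_ext <- n_ext + 1L
          }
        }
      }
      log[[r]] <- data.frame(round = r, primers = length(primers),
                             extended = n_ext, self_templated = n_self,
                             no_site = n_miss, total_nt = sum(nchar(seqs)))
    }
  })
  out <- pool(seqs, paste(pool$alphabet, collapse = ""),
              label = pool$label, validate = FALSE)
  out$alphabet <- pool$alphabet
  attr(out, "log") <- do.call(rbind, log)
  out
}

# positions (>= 2, so there is something 5'-ward to copy) of each key
# within each sequence; returns list(key -> data.frame(seq_idx, pos))
kmer_occurrences <- function(seqs, keys) {
  out <- vector("list", length(keys))
  names(out) <- keys
  for (k in keys) {
    m <- gregexpr(k, seqs, fixed = TRUE)
    idx <- rep.int(seq_along(seqs), vapply(m, function(v)
      sum(v != -1L), integer(1)))
    pos <- unlist(lapply(m, function(v) v[v != -1L]), use.names = FALSE)
    keep <- pos >= 2L
    out[[k]] <- data.frame(seq_idx = idx[keep], pos = pos[keep])
  }
  out
}

# the contiguous complementary overlap duplex (top strand) between the
# primer 3' end and a template site, extended 5'-ward beyond the seed
overlap_extent <- function(primer, template, pos, w, cap = 12L) {
  lp <- nchar(primer)
  ext <- 0L
  while (ext < cap - w &&
         lp - w - ext >= 1L && pos + w + ext <= nchar(template) &&
         substr(primer, lp - w - ext, lp - w - ext) ==
         complement_seq(substr(template, pos + w + ext, pos + w + ext))) {
    ext <- ext + 1L
  }
  substr(primer, lp - w - ext + 1L, lp)
}

#' Emit a pool as adapter-tagged FASTQ
#'
#' Writes each sequence as a sequencing-like read: insert + CT tail +
#' AGAT adapter, truncated at the configured read length. Qualities follow
#' a plateau with an optional linear 3' decay, and a configurable fraction
#' of reads get strongly degraded 3' tails (emulating declining quality
#' toward the read end).
#'
#' @param pool A [pool()].
#' @param path Output FASTQ path (`.gz` allowed).
#' @param tail 3' tail appended before the adapter; must match `[CT]{4,}`.
#' @param adapter Literal adapter (default `"AGAT"`).
#' @param read_length Maximum read length in nt (default 120).
#' @param plateau_q Plateau Phred score (default 36).
#' @param decay_len Length of the linear 3' quality decay in nt (default 0).
#' @param decay_to Phred score at the read end of the decay (default 2).
#' @param degrade_frac Fraction of reads whose final `decay_len` bases are
#'   set to `decay_to` outright (default 0).
#' @param seed RNG seed used for choosing degraded reads (default 3003).
#' @return `path`, invisibly; attribute `"n_records"` gives the read count.
#' @export
emit_fastq <- function(pool, path, tail = "CTCT", adapter = "AGAT",
                       read_length = 120L, plateau_q = 36L, decay_len = 0L,
                       decay_to = 2L, degrade_frac = 0, seed = 3003L) {
  pool <- as_pool(pool)
  if (!grepl("^[CT]{4,}$", tail)) stop("tail must match [CT]{4,}")
  full <- paste0(pool$seqs, tail, adapter)
  bases <- substr(full, 1L, read_length)
  n <- length(bases)
  withr_seed(seed, {
    degraded <- stats::runif(n) < degrade_frac
    quals <- lapply(seq_len(n), function(i) {
      L <- nchar(bases[i])
      q <- rep(as.integer(plateau_q), L)
      d <- min(decay_len, L)
      if (d > 0) {
        if (degraded[i]) {
          q[(L - d + 1L):L] <- as.integer(decay_to)
        } else {
          q[(L - d + 1L):L] <- as.integer(round(seq(plateau_q, decay_to,
                                                    length.out = d)))
        }
      }
      q
    })
    reads <- data.frame(read_id = sprintf("synth_%06d", seq_len(n)),
                        bases = bases, quals = I(quals))
    write_fastq(reads, path)
  })
  invisible(structure(path, n_records = n))
}
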