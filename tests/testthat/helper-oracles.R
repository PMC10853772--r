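# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the package's own implementation paths.

# sliding-window trimming: enumerate every window mean directly
oracle_trim_len <- function(q, window = 4L, min_mean_q = 20) {
  L <- length(q)
  if (L == 0L) return(0L)
  if (L < window) return(if (mean(q) >= min_mean_q) L else 0L)
  for (start in 1:(L - window + 1L)) {
    if (mean(q[start:(start + window - 1L)]) < min_mean_q) {
      return(start - 1L)
    }
  }
  L
}

# insert extraction as an explicit rightmost-split scan (greedy semantics):
# longest prefix over the class, >= 12, immediately followed by a
# [CT]{4,}AGAT lookahead
oracle_extract <- function(read, alphabet) {
  chars <- strsplit(read, "")[[1]]
  in_class <- chars %in% alphabet
  max_run <- if (all(in_class)) length(chars) else which(!in_class)[1] - 1L
  if (max_run < 12L) return(NA_character_)
  for (i in max_run:12L) {
    rest <- substr(read, i + 1L, nchar(read))
    if (grepl("^[CT]{4,}AGAT", rest)) {
      return(substr(read, 1L, i))
    }
  }
  NA_character_
}

oracle_revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# longest substring of s whose reverse complement occurs in s:
# enumerate all substrings, test occurrence with fixed-string grepl
oracle_lcs_selfcomp <- function(s) {
  L <- nchar(s)
  for (len in L:1) {
    for (start in 1:(L - len + 1L)) {
      sub <- substr(s, start, start + len - 1L)
      if (grepl(oracle_revcomp(sub), s, fixed = TRUE)) return(len)
    }
  }
  0L
}

# longest fold-back stem: try every (i, j) outer pair and walk inward
oracle_foldback <- function(s) {
  chars <- strsplit(s, "")[[1]]
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  L <- length(chars)
  best <- 0L
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (j <= i) next
      k <- 0L
      while (i + k < j - k + 1L &&
             !is.na(comp[chars[j - k]]) &&
             chars[i + k] == comp[chars[j - k]]) {
        k <- k + 1L
      }
      best <- max(best, k)
    }
  }
  best
}

# planted-periodicity conditional-probability excess at the planted period:
# closed-form mixture over the discrete phase of the modulation.
# For per-position P(ref) = f + a*cos(2*pi*(j+phi)/p), phi uniform on
# 0..p-1: E[P_i P_j] = f^2 + a^2 * mean_phi cos(..i..)cos(..j..); the
# conditional matrix row oscillation has amplitude 100*a^2*c_p/f with
# c_p = mean_phi cos(2*pi*d/p) coefficient: 1 for p = 2, 1/2 for p >= 3.
# The measured spectrum replaces each row's diagonal entry (which sits at
# the cosine's phase peak, cos(0) = 1) by the row mean, attenuating the
# least-squares amplitude by (1 - 2/N) at interior periods and (1 - 1/N)
# at the Nyquist period p = 2 (cosine-only design there).
oracle_injected_excess <- function(f, a, p, N = Inf) {
  phases <- 0:(p - 1)
  # c_p = coefficient of cos(2*pi*(i-j)/p) in E[cos_i cos_j], read off at
  # lag 0 (phase-averaged second moment)
  c_p <- mean(cospi(2 * (1 + phases) / p)^2)
  atten <- if (is.infinite(N)) 1 else if (p == 2) 1 - 1 / N else 1 - 2 / N
  100 * a^2 * c_p / f * atten
}

# random sequences of given length over an alphabet (test-local)
rand_seqs <- function(n, L, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, L, replace = TRUE), collapse = "")
  }, character(1))
}

make_reads <- function(bases, quals) {
  if (!is.list(quals)) quals <- list(quals)
  data.frame(read_id = sprintf("r%03d", seq_along(bases)),
             bases = bases, quals = I(quals))
}
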