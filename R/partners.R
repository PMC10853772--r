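#' Census of periodic partner motif classes
#'
#' Enumerates all k-mers over an alphabet and partitions them into
#' reverse-complement classes: a pair \{w, rc(w)\} with w != rc(w)
#' (pool-templating: the two motifs can template each other across
#' sequences) or a singleton \{w\} with rc(w) == w (self-templating: a run
#' of the motif is its own reverse complement). Motifs are taken as
#' written, without rotational identification. The class counts obey
#' `2 * n_pairs + n_self == |alphabet|^k`; odd k over a complementary
#' alphabet has no self-templating classes, while even k over \{A,T\}
#' has `2^(k/2)` of them.
#'
#' @param k Motif length, >= 1.
#' @param alphabet Character vector of bases (default `c("A", "T")`).
#' @param max_kmers Enumeration cap on `|alphabet|^k` (default 2^20).
#' @return A list of class `"partner_census"`: `k`, `alphabet`, `classes`
#'   (list of sorted character vectors, ordered by lexicographic
#'   representative), `n_pairs`, `n_self`.
#' @examples
#' census(3)           # the four 3-nt periodic partner classes over {A,T}
#' @export
census <- function(k, alphabet = c("A", "T"), max_kmers = 2^20) {
  stopifnot(k >= 1L)
  if (!setequal(alphabet, chartr("ACGT", "TGCA", alphabet))) {
    stop("alphabet must be closed under complementation (AT, GC or ATGC)")
  }
  n_kmers <- length(alphabet)^k
  if (n_kmers > max_kmers) {
    stop("|alphabet|^k = ", n_kmers, " exceeds the cap of ", max_kmers)
  }
  grid <- do.call(expand.grid,
                  c(rep(list(alphabet), k), stringsAsFactors = FALSE))
  kmers <- do.call(paste0, rev(grid))   # lexicographic order
  rc <- revcomp(kmers)
  reps <- sort(unique(pmin(kmers, rc)))   # lexicographic representative
  classes <- lapply(reps, function(r) sort(unique(c(r, revcomp(r)))))
  n_self <- sum(lengths(classes) == 1L)
  structure(list(k = as.integer(k), alphabet = alphabet, classes = classes,
                 n_pairs = length(classes) - n_self, n_self = n_self),
            class = "partner_census")
}

#' @export
print.partner_census <- function(x, ...) {
  cat(sprintf("partner_census k=%d over {%s}: %d pool-templating pairs, %d self-templating\n",
              x$k, paste(x$alphabet, collapse = ","), x$n_pairs, x$n_self))
  lab <- vapply(x$classes, paste, character(1), collapse = "/")
  cat(" ", paste(lab, collapse = "  "), "\n")
  invisible(x)
}

#' Fraction of sequences dominated by each periodic partner class
#'
#' Assigns a sequence to a motif class when, in some reading frame, more
#' than `threshold` of its frame-aligned k-mers belong to that class. A
#' perfect k-periodic repeat is constant within each frame (its k-mers at
#' positions 1, 1+k, 1+2k, ... are all the same motif), so repeats score 1
#' in their own frame, while unstructured sequences score near the class's
#' share of k-mer space in every frame. Phase-shifted classes of the same
#' repeat family tie at 1; ties are broken by census order (lexicographic
#' representative). Class fractions sum to at most 1; the remainder is
#' reported under `"unassigned"`.
#'
#' @param pool A [pool()] or character vector; sequences must be >= 2k nt.
#' @param k Motif length.
#' @param threshold Dominance threshold on the frame-aligned k-mer
#'   fraction (default 0.5, exceeded strictly).
#' @return Data.frame with columns `class` (motifs joined by "/") and
#'   `fraction`, including an `"unassigned"` row.
#' @export
periodic_fraction <- function(pool, k = 3L, threshold = 0.5) {
  pool <- as_pool(pool)
  cen <- census(k, pool$alphabet)
  seqs <- pool$seqs
  if (any(nchar(seqs) < 2L * k)) stop("all sequences must be >= 2k nt")
  labels <- vapply(cen$classes, paste, character(1), collapse = "/")
  class_of <- stats::setNames(rep(seq_along(labels), lengths(cen$classes)),
                              unlist(cen$classes))
  assign_one <- function(s) {
    n <- nchar(s)
    starts <- 1:(n - k + 1L)
    km <- substring(s, starts, starts + k - 1L)
    frame <- (starts - 1L) %% k
    cls <- class_of[km]
    score <- numeric(length(labels))
    for (r in unique(frame)) {
      fr <- cls[frame == r]
      tab <- tabulate(fr, nbins = length(labels)) / length(fr)
      score <- pmax(score, tab)
    }
    top <- which.max(score)          # ties: first in census order
    if (score[top] > threshold) labels[top] else "unassigned"
  }
  got <- vapply(seqs, assign_one, character(1), USE.NAMES = FALSE)
  frac <- table(factor(got, levels = c(labels, "unassigned"))) / length(seqs)
  data.frame(class = names(frac), fraction = as.numeric(frac),
             row.names = NULL)
}
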