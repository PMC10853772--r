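#' Construct a sequence pool
#'
#' A pool bundles a set of single-stranded DNA sequences (typically inserts
#' extracted from sequencing reads, or synthetic sequences) with its base
#' alphabet and a free-text time-point label such as `"A0_2h"`.
#'
#' @param seqs Character vector of sequences, 5'->3'.
#' @param alphabet Either a pool type (`"AT"`, `"GC"`, `"ATGC"`) or a
#'   character vector of allowed bases.
#' @param label Free-text label for the pool (e.g. sample and time point).
#' @param validate If `TRUE` (default), check every sequence against the
#'   alphabet. Disable only for large pools already known to conform.
#' @return An object of class `"dna_pool"`: a list with elements `seqs`,
#'   `alphabet` (character vector of bases) and `label`.
#' @examples
#' p <- pool(c("ATAT", "TTAA"), "AT", label = "demo")
#' length(p$seqs)
#' @export
pool <- function(seqs, alphabet = c("AT", "GC", "ATGC"), label = "",
                 validate = TRUE) {
  if (is.character(alphabet) && length(alphabet) == 1L &&
      alphabet %in% c("AT", "GC", "ATGC")) {
    alphabet <- strsplit(alphabet, "")[[1]]
  }
  alphabet <- toupper(alphabet)
  stopifnot(is.character(seqs), all(alphabet %in% c("A", "C", "G", "T")))
  if (validate && length(seqs)) {
    ok <- !grepl(sprintf("[^%s]", paste(alphabet, collapse = "")), seqs)
    if (!all(ok)) {
      stop("sequence(s) ", paste(utils::head(which(!ok), 3), collapse = ", "),
           " contain bases outside alphabet {",
           paste(alphabet, collapse = ","), "}")
    }
  }
  structure(list(seqs = seqs, alphabet = alphabet, label = label),
            class = "dna_pool")
}

#' @export
print.dna_pool <- function(x, ...) {
  cat(sprintf("dna_pool '%s': %d sequences over {%s}, lengths %s\n",
              x$label, length(x$seqs), paste(x$alphabet, collapse = ","),
              if (length(x$seqs)) {
                paste(range(nchar(x$seqs)), collapse = "-")
              } else "-"))
  invisible(x)
}

as_pool <- function(x, ...) {
  if (inherits(x, "dna_pool")) x else pool(x, ...)
}

#' Reverse complement of DNA sequences
#'
#' Thin vectorized wrapper around [Biostrings::reverseComplement()].
#' Reverse complementation is an involution: `revcomp(revcomp(x)) == x`.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp(c("AATT", "GATC", "ACGT"))
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Complement (same orientation) of DNA sequences
#' @param x Character vector of DNA sequences.
#' @return Character vector of complements read in the original direction.
#' @export
complement_seq <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

# base-frequency of one base across a character vector, nucleotide-weighted
count_base <- function(seqs, base) {
  if (!length(seqs)) return(0L)
  sum(Biostrings::letterFrequency(Biostrings::DNAStringSet(seqs), base))
}
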