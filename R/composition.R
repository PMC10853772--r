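#' Summarize a pool's composition
#'
#' The pool-average fraction `f_bar` of the reference base is
#' nucleotide-weighted: total count of the reference base divided by the
#' total number of nucleotides in the pool (not an unweighted mean over
#' sequences). For binary pools `f_bar(X) + f_bar(complement of X) = 1`.
#'
#' @param pool A [pool()] (or character vector of sequences).
#' @param ref_base Reference base, e.g. `"T"` for AT pools, `"C"` for GC.
#' @return A list of class `"pool_summary"`: `n_sequences`, `total_nt`,
#'   `f_bar`, `length_histogram` (named integer vector), `ref_base`, `label`.
#' @export
summarize_pool <- function(pool, ref_base) {
  pool <- as_pool(pool)
  if (!length(pool$seqs)) stop("empty pool: nothing to summarize")
  if (!ref_base %in% pool$alphabet) {
    stop("ref_base '", ref_base, "' is not in the pool alphabet {",
         paste(pool$alphabet, collapse = ","), "}")
  }
  lens <- nchar(pool$seqs)
  hist <- table(lens)
  out <- list(n_sequences = length(pool$seqs),
              total_nt = sum(lens),
              f_bar = count_base(pool$seqs, ref_base) / sum(lens),
              length_histogram = stats::setNames(as.integer(hist),
                                                 names(hist)),
              ref_base = ref_base,
              label = pool$label)
  class(out) <- "pool_summary"
  out
}

#' @export
print.pool_summary <- function(x, ...) {
  cat(sprintf("pool_summary '%s': n=%d, %d nt, f_bar(%s)=%.4f, lengths %s-%s\n",
              x$label, x$n_sequences, x$total_nt, x$ref_base, x$f_bar,
              names(x$length_histogram)[1],
              names(x$length_histogram)[length(x$length_histogram)]))
  invisible(x)
}

#' Length distribution of a pool
#'
#' @param pool A [pool()] or character vector.
#' @return Named integer vector: count of sequences per length.
#' @export
length_distribution <- function(pool) {
  pool <- as_pool(pool)
  h <- table(nchar(pool$seqs))
  stats::setNames(as.integer(h), names(h))
}

#' Positional nucleotide-fraction map
#'
#' For every sequence length L with at least `min_support` sequences, the
#' fraction of the reference base at each position i (1-based, 5'->3', the
#' direction of polymerase extension) is computed over the sequences of
#' exactly that length. Length bins below the support threshold are
#' suppressed, not zero-filled, to avoid noisy tails.
#'
#' @param pool A [pool()] or character vector.
#' @param ref_base Reference base.
#' @param min_support Minimum number of sequences per length bin (default 50).
#' @return A data.frame with columns `length`, `position`, `fraction`,
#'   `support`, plus an attribute `"suppressed_lengths"` listing length bins
#'   dropped for low support.
#' @export
positional_fractions <- function(pool, ref_base, min_support = 50L) {
  pool <- as_pool(pool)
  if (!length(pool$seqs)) stop("empty pool: no positional fractions")
  lens <- nchar(pool$seqs)
  by_len <- split(pool$seqs, lens)
  support <- lengths(by_len)
  keep <- support >= min_support
  suppressed <- as.integer(names(by_len)[!keep])
  res <- lapply(names(by_len)[keep], function(Lc) {
    L <- as.integer(Lc)
    seqs <- by_len[[Lc]]
    cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs),
                                      baseOnly = TRUE)
    frac <- cm[ref_base, ] / length(seqs)
    data.frame(length = L, position = seq_len(L), fraction = as.numeric(frac),
               support = length(seqs))
  })
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(length = integer(0), position = integer(0),
               fraction = numeric(0), support = integer(0))
  attr(out, "suppressed_lengths") <- suppressed
  attr(out, "ref_base") <- ref_base
  out
}

#' Write a positional fraction map as tidy TSV
#' @param map Output of [positional_fractions()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_fraction_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Heatmap of a positional fraction map
#'
#' Draws the length-stacked positional fraction map (position on x,
#' sequence length on y, fraction as fill), the layout used to visualize
#' how per-position bias evolves with length.
#'
#' @param map Output of [positional_fractions()].
#' @return A ggplot object.
#' @export
plot_fraction_map <- function(map) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  ggplot2::ggplot(map, ggplot2::aes(x = .data$position, y = .data$length,
                                    fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 0.5, low = "darkorange",
                                  mid = "white", high = "purple4",
                                  limits = c(0, 1)) +
    ggplot2::labs(x = "position (5'→3')", y = "sequence length (nt)",
                  fill = paste0("f_", attr(map, "ref_base")))
}
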