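#' Read a 4-line FASTQ file
#'
#' Parses plain or gzip-compressed FASTQ (strict 4-line records, Phred+33
#' quality encoding; no autodetection of other encodings). Malformed records
#' are rejected with a diagnostic naming the offending line.
#'
#' @param path Path to a `.fastq` or `.fastq.gz` file.
#' @return A data.frame with columns `read_id` (character), `bases`
#'   (character) and `quals` (list of integer Phred scores, one vector per
#'   read, same length as `bases`).
#' @seealso [write_fastq()], [trim_quality()], [extract_insert()]
#' @export
read_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  n <- length(lines)
  if (n == 0L) {
    return(data.frame(read_id = character(0), bases = character(0),
                      quals = I(list())))
  }
  if (n %% 4L != 0L) {
    stop("truncated FASTQ: ", n, " lines is not a multiple of 4 (record ",
         "starting at line ", 4L * (n %/% 4L) + 1L, " is incomplete)")
  }
  idx <- seq(1L, n, by = 4L)
  hdr <- lines[idx]
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  qstr <- lines[idx + 3L]
  bad <- which(substr(hdr, 1L, 1L) != "@")
  if (length(bad)) {
    stop("malformed FASTQ: line ", idx[bad[1]], " does not start with '@'")
  }
  bad <- which(substr(plus, 1L, 1L) != "+")
  if (length(bad)) {
    stop("malformed FASTQ: line ", idx[bad[1]] + 2L, " does not start with '+'")
  }
  bad <- which(nchar(qstr) != nchar(seqs))
  if (length(bad)) {
    stop("malformed FASTQ: quality at line ", idx[bad[1]] + 3L,
         " has length ", nchar(qstr[bad[1]]), " but sequence has length ",
         nchar(seqs[bad[1]]), " (read ", sub("^@", "", hdr[bad[1]]), ")")
  }
  ids <- sub("\\s.*$", "", sub("^@", "", hdr))
  quals <- lapply(qstr, function(q) as.integer(charToRaw(q)) - 33L)
  data.frame(read_id = ids, bases = toupper(seqs), quals = I(quals),
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads A data.frame as returned by [read_fastq()].
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  validate_reads(reads)
  qstr <- vapply(reads$quals,
                 function(q) rawToChar(as.raw(q + 33L)), character(1))
  out <- character(4L * nrow(reads))
  out[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", reads$read_id)
  out[c(FALSE, TRUE, FALSE, FALSE)] <- reads$bases
  out[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  out[c(FALSE, FALSE, FALSE, TRUE)] <- qstr
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

validate_reads <- function(reads) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "bases", "quals") %in% names(reads)))
  len_ok <- nchar(reads$bases) == lengths(reads$quals)
  if (!all(len_ok)) {
    stop("malformed read record(s): base/quality length mismatch for read(s) ",
         paste(utils::head(reads$read_id[!len_ok], 3), collapse = ", "))
  }
  invisible(TRUE)
}

#' Base-call accuracy implied by a Phred score
#'
#' A Phred score Q encodes the probability P of a wrong base call through
#' Q = -10 log10 P; the corresponding accuracy is 1 - P.
#'
#' @param q Integer Phred score(s), >= 0.
#' @return Accuracy `1 - 10^(-q/10)` in `[0, 1)`.
#' @examples
#' phred_accuracy(20)  # 0.99
#' @export
phred_accuracy <- function(q) {
  if (any(q < 0)) stop("Phred scores must be >= 0")
  1 - 10^(-q / 10)
}

#' Sliding-window quality trimming
#'
#' Scans 4-nt windows 5'->3' along each read and cuts the read at the start
#' of the first window whose mean Phred quality falls below `min_mean_q`
#' (the convention of the standard sliding-window trimmers). Reads shorter
#' than the window are judged by a single window over the whole read. The
#' result is always a (possibly empty) prefix of the input read.
#'
#' @param reads Data.frame of reads (see [read_fastq()]).
#' @param window Window width in nt (default 4).
#' @param min_mean_q Minimum mean Phred quality per window (default 20,
#'   i.e. at least 99% average base-call accuracy).
#' @return The reads data.frame with `bases`/`quals` trimmed.
#' @export
trim_quality <- function(reads, window = 4L, min_mean_q = 20) {
  stopifnot(window >= 1L)
  validate_reads(reads)
  keep <- vapply(reads$quals, trim_point, integer(1),
                 window = as.integer(window), min_mean_q = min_mean_q)
  reads$bases <- substr(reads$bases, 1L, keep)
  reads$quals <- I(mapply(function(q, k) q[seq_len(k)], reads$quals, keep,
                          SIMPLIFY = FALSE))
  reads
}

# prefix length retained for one quality vector
trim_point <- function(q, window, min_mean_q) {
  L <- length(q)
  if (L == 0L) return(0L)
  if (L < window) {
    return(if (mean(q) >= min_mean_q) L else 0L)
  }
  cs <- cumsum(c(0, q))
  means <- (cs[(window + 1L):(L + 1L)] - cs[1:(L - window + 1L)]) / window
  fail <- which(means < min_mean_q)
  if (!length(fail)) L else fail[1] - 1L
}

#' Insert-extraction rule for a pool type
#'
#' Returns the anchored, lookahead-guarded pattern used to capture the
#' leading insert of a read whose 3' end carries a pyrimidine (CT) tail of
#' at least 4 nt followed by the literal adapter AGAT. The insert class is
#' restricted to the pool alphabet, which simultaneously excludes
#' non-binary sequences from binary-pool analyses. Matching uses greedy
#' backtracking (PCRE), so the insert is the longest prefix compatible
#' with the tail lookahead.
#'
#' @param pool_type One of `"AT"`, `"GC"`, `"ATGC"`.
#' @return A list with `pool_type`, `pattern`, `alphabet`, `min_insert`.
#' @examples
#' extraction_rule("AT")$pattern
#' @export
extraction_rule <- function(pool_type = c("AT", "GC", "ATGC")) {
  pool_type <- match.arg(pool_type)
  pattern <- switch(pool_type,
    AT   = "(^[AT]{12,})(?=([CT]{4,}AGAT))",
    GC   = "(^[CG]{12,})(?=([CT]{4,}AGAT))",
    ATGC = "(^[ATGC]{12,})(?=([CT]{4,}AGAT))")
  list(pool_type = pool_type, pattern = pattern,
       alphabet = strsplit(switch(pool_type, AT = "AT", GC = "GC",
                                  ATGC = "ATGC"), "")[[1]],
       min_insert = 12L)
}

#' Extract inserts from trimmed reads
#'
#' Applies the pool-type extraction pattern to each read; reads without a
#' match are excluded from downstream statistics (a normal outcome, counted
#' in the run report).
#'
#' @param bases Character vector of (already quality-trimmed) read sequences.
#' @param rule An extraction rule from [extraction_rule()].
#' @return Character vector of the same length: the captured insert, or
#'   `NA` where the read does not match.
#' @export
extract_insert <- function(bases, rule = extraction_rule("AT")) {
  m <- regexpr(rule$pattern, bases, perl = TRUE)
  len <- attr(m, "capture.length")[, 1L]
  out <- rep(NA_character_, length(bases))
  hit <- m != -1L
  out[hit] <- substr(bases[hit], 1L, len[hit])
  out
}

#' Trim and extract a FASTQ file into an insert pool
#'
#' Full preprocessing step: sliding-window quality trimming followed by
#' insert extraction, with a machine-readable run report.
#'
#' @param input Either a FASTQ path or a reads data.frame.
#' @param pool_type `"AT"`, `"GC"` or `"ATGC"`.
#' @param window,min_mean_q Trimming parameters, see [trim_quality()].
#' @param label Label attached to the resulting pool.
#' @return A list with `pool` (a [pool()] of inserts), `source_read_id`
#'   (character, read of origin per insert) and `report` (list with
#'   `total_reads`, `trimmed_to_empty`, `no_match`, `extracted`, `rule`).
#' @export
extract_pool <- function(input, pool_type = c("AT", "GC", "ATGC"),
                         window = 4L, min_mean_q = 20, label = "") {
  pool_type <- match.arg(pool_type)
  reads <- if (is.character(input)) read_fastq(input) else input
  rule <- extraction_rule(pool_type)
  total <- nrow(reads)
  trimmed <- trim_quality(reads, window = window, min_mean_q = min_mean_q)
  empty <- nchar(trimmed$bases) == 0L
  ins <- extract_insert(trimmed$bases, rule)
  hit <- !is.na(ins)
  report <- list(total_reads = total,
                 trimmed_to_empty = sum(empty),
                 no_match = sum(!hit & !empty),
                 extracted = sum(hit),
                 rule = rule$pattern,
                 pool_type = pool_type,
                 window = as.integer(window),
                 min_mean_q = min_mean_q)
  list(pool = pool(ins[hit], pool_type, label = label, validate = FALSE),
       source_read_id = trimmed$read_id[hit],
       report = report)
}
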