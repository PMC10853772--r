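#' Nearest-neighbor stacking free-energy table
#'
#' Loads a table of duplex dimer-step stacking free energies (ΔG°37,
#' kcal/mol). The embedded default is the unified nearest-neighbor
#' parameter set for DNA; a step label like `AT/TA` denotes top strand
#' 5'-AT-3' paired with bottom strand 3'-TA-5'. All ten unique
#' Watson-Crick steps must be present and negative (stabilizing).
#' Terminal/initiation penalties are deliberately excluded: the zebra vs
#' bulky comparison uses step energies only.
#'
#' @param path Optional path to an alternative TSV with columns
#'   `step`, `dG_kcal_per_mol` (and optionally `source`).
#' @return A named numeric vector of 10 step energies, with an attribute
#'   `"source"`.
#' @export
nn_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nn_unified_dG37.tsv",
                        package = "poolscape", mustWork = TRUE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("step", "dG_kcal_per_mol") %in% names(df)))
  tab <- stats::setNames(df$dG_kcal_per_mol, df$step)
  needed <- c("AA/TT", "AT/TA", "TA/AT", "CA/GT", "GT/CA", "CT/GA",
              "GA/CT", "CG/GC", "GC/CG", "GG/CC")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("nearest-neighbor table missing step(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(tab >= 0)) stop("stacking step energies must be negative")
  attr(tab, "source") <- if ("source" %in% names(df)) df$source[1] else path
  tab
}

# map an arbitrary top-strand dimer to its canonical table label:
# a step read from the other strand has the same energy, so XY and rc(XY)
# share one entry.
step_label <- function(dimer) {
  canon <- c("AA/TT", "AT/TA", "TA/AT", "CA/GT", "GT/CA", "CT/GA",
             "GA/CT", "CG/GC", "GC/CG", "GG/CC")
  first <- substr(canon, 1, 2)
  idx <- match(dimer, first)
  alt <- match(revcomp(dimer), first)
  out <- canon[ifelse(is.na(idx), alt, idx)]
  if (anyNA(out)) stop("no nearest-neighbor step for dimer(s): ",
                       paste(dimer[is.na(out)], collapse = ", "))
  out
}

#' Stacking free energy of a sequence's full duplex
#'
#' Sums the nearest-neighbor step energies over all adjacent base pairs of
#' the duplex formed by a sequence and its full complement. By duplex
#' symmetry the score is invariant under reverse complementation of the
#' input.
#'
#' @param seqs Character vector of ACGT sequences, each >= 2 nt.
#' @param table A table from [nn_table()].
#' @return Numeric vector of stacking free energies (kcal/mol, negative).
#' @examples
#' stacking_score("AA")    # single AA/TT step
#' @export
stacking_score <- function(seqs, table = nn_table()) {
  if (any(grepl("[^ACGT]", seqs))) stop("sequences must be over ACGT")
  L <- nchar(seqs)
  if (any(L < 2)) stop("stacking needs sequences of length >= 2")
  vapply(seqs, function(s) {
    n <- nchar(s)
    dimers <- substring(s, 1:(n - 1), 2:n)
    sum(table[step_label(dimers)])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Zebra vs bulky motif stacking energies
#'
#' Compares the stacking free energy of alternating (zebra: XY, YX) and
#' homodimer (bulky: XX, YY) dimer steps for the AT and GC base pairs. The
#' zebra energy is the mean of the two heterodimer steps, the bulky energy
#' is the homodimer step, and `delta` is the zebra minus bulky difference:
#' a positive delta means alternating steps stack more weakly than
#' homodimer steps (the AT case), a negative delta the opposite (GC). The
#' motif type with the weaker (less stabilizing) stacking is the one whose
#' duplexes separate most easily, hence the one enriched among fast
#' replicators.
#'
#' @param table A table from [nn_table()].
#' @return A list of class `"motif_energy_report"` with full-precision
#'   elements `dG_zebra_AT`, `dG_bulky_AT`, `dG_zebra_GC`, `dG_bulky_GC`,
#'   `delta_AT`, `delta_GC` (kcal/mol). Values are rounded (2 decimals)
#'   only when printed or exported via [report_motif_energies()].
#' @export
motif_energies <- function(table = nn_table()) {
  z_at <- (table[["AT/TA"]] + table[["TA/AT"]]) / 2
  b_at <- table[["AA/TT"]]
  z_gc <- (table[["GC/CG"]] + table[["CG/GC"]]) / 2
  b_gc <- table[["GG/CC"]]
  structure(list(dG_zebra_AT = z_at, dG_bulky_AT = b_at,
                 dG_zebra_GC = z_gc, dG_bulky_GC = b_gc,
                 delta_AT = z_at - b_at, delta_GC = z_gc - b_gc),
            class = "motif_energy_report")
}

#' Rounded motif-energy report
#' @param report Output of [motif_energies()].
#' @param digits Decimals for reporting (default 2).
#' @return Named numeric vector rounded for reporting.
#' @export
report_motif_energies <- function(report = motif_energies(), digits = 2) {
  round(unlist(report), digits)
}

#' @export
print.motif_energy_report <- function(x, ...) {
  v <- report_motif_energies(x)
  cat("Stacking free energies (kcal/mol, duplex dimer steps):\n")
  cat(sprintf("  AT: zebra %.2f  bulky %.2f  delta(zebra-bulky) %+.2f\n",
              v["dG_zebra_AT"], v["dG_bulky_AT"], v["delta_AT"]))
  cat(sprintf("  GC: zebra %.2f  bulky %.2f  delta(zebra-bulky) %+.2f\n",
              v["dG_zebra_GC"], v["dG_bulky_GC"], v["delta_GC"]))
  invisible(x)
}
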