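#' Default pipeline configuration
#'
#' Assembles the parameter blocks of a full analysis run. Either an input
#' source (`fastq` path or `inserts` path with one sequence per line) or a
#' `synthetic` block (arguments to [generate_pool()]) must be supplied.
#'
#' @param pool_type `"AT"`, `"GC"` or `"ATGC"`.
#' @param ref_base Reference base for composition/periodicity analyses;
#'   defaults to the pyrimidine of the pool type (`T` for AT/ATGC, `C` for GC).
#' @param fastq,inserts Optional input paths (mutually exclusive with
#'   `synthetic`).
#' @param synthetic Optional list of [generate_pool()] arguments.
#' @param time_label Free-text time-point label.
#' @param out_dir Output directory.
#' @param window,min_mean_q Trimming parameters.
#' @param min_support Per-length support threshold.
#' @param L Analysis length for the conditional matrix (default 50).
#' @param periods Probed periods (default `seq(2, 10, by = 0.1)`).
#' @param k Motif length for partner/symmetry analyses (default 4 for
#'   symmetry, 3 for the partner census).
#' @param selfcomp_seed Seed for the self-complementarity reference pool.
#' @return A named list (class `"run_config"`).
#' @export
run_config <- function(pool_type = c("AT", "GC", "ATGC"), ref_base = NULL,
                       fastq = NULL, inserts = NULL, synthetic = NULL,
                       time_label = "t0", out_dir = "poolscape_run",
                       window = 4L, min_mean_q = 20, min_support = 50L,
                       L = 50L, periods = seq(2, 10, by = 0.1), k = 4L,
                       selfcomp_seed = 7001L) {
  pool_type <- match.arg(pool_type)
  if (is.null(ref_base)) ref_base <- if (pool_type == "GC") "C" else "T"
  inputs <- c(!is.null(fastq), !is.null(inserts), !is.null(synthetic))
  if (sum(inputs) != 1L) {
    stop("exactly one of fastq, inserts or synthetic must be given")
  }
  for (p in c(fastq, inserts)) {
    if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  structure(list(pool_type = pool_type, ref_base = ref_base, fastq = fastq,
                 inserts = inserts, synthetic = synthetic,
                 time_label = time_label, out_dir = out_dir,
                 window = as.integer(window), min_mean_q = min_mean_q,
                 min_support = as.integer(min_support), L = as.integer(L),
                 periods = periods, k = as.integer(k),
                 selfcomp_seed = as.integer(selfcomp_seed)),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read YAML configs")
  }
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Orchestrates extraction -> composition -> periodicity -> motifs ->
#' thermodynamics/partner census into one reproducible run with a
#' deterministic directory layout and a manifest recording versions, seeds
#' and parameters. Outputs are byte-stable across reruns of the same
#' configuration.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list (`"report_bundle"`) with the output directory,
#'   the manifest, and the in-memory pool summary.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outfile <- function(x) file.path(config$out_dir, x)
  wjson <- function(x, f) jsonlite::write_json(
    x, outfile(f), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # --- input acquisition
  if (!is.null(config$fastq)) {
    ex <- extract_pool(config$fastq, config$pool_type, config$window,
                       config$min_mean_q, label = config$time_label)
    p <- ex$pool
    wjson(ex$report, "extraction_report.json")
  } else if (!is.null(config$inserts)) {
    p <- pool(readLines(config$inserts), config$pool_type,
              label = config$time_label)
  } else {
    p <- do.call(generate_pool,
                 c(config$synthetic, list(pool_type = config$pool_type,
                                          label = config$time_label)))
  }
  if (!length(p$seqs)) stop("pipeline input produced an empty pool")

  # --- composition
  summ <- summarize_pool(p, config$ref_base)
  wjson(list(label = summ$label, ref_base = summ$ref_base,
             n_sequences = summ$n_sequences, total_nt = summ$total_nt,
             f_bar = summ$f_bar,
             length_histogram = as.list(summ$length_histogram)),
        "pool_summary.json")
  fmap <- positional_fractions(p, config$ref_base, config$min_support)
  write_fraction_map(fmap, outfile(sprintf("fraction_map_%s.tsv",
                                           config$ref_base)))

  # --- periodicity (only when the analysis length has support)
  n_L <- sum(nchar(p$seqs) == config$L)
  spectrum_file <- NULL
  if (n_L >= config$min_support) {
    cm <- conditional_matrix(p, config$ref_base, config$L,
                             config$min_support)
    sp <- amplitude_spectrum(cm, config$periods)
    spectrum_file <- "spectrum.tsv"
    write_spectrum(sp, outfile(spectrum_file), L = config$L)
    det <- detect_periods(sp)
    wjson(list(baseline = attr(sp, "baseline"),
               detected = det), "detected_periods.json")
  }

  # --- motifs
  zp <- zebraness_profile(p, config$min_support)
  utils::write.table(zp, outfile("zebraness.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  scp <- selfcomp_profile(p, seed = config$selfcomp_seed,
                          min_support = config$min_support)
  utils::write.table(scp, outfile("selfcomp.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ks <- kmer_symmetry(p, config$k)
  wjson(list(k = ks$k, symmetry_score = ks$symmetry_score,
             n_pairs_scored = ks$n_pairs_scored,
             abundance = as.list(ks$abundance)), "kmer_symmetry.json")

  # --- thermo & partners (pool-independent references)
  wjson(as.list(report_motif_energies()), "thermo.json")
  cen <- census(3L, p$alphabet)
  wjson(list(k = cen$k, n_pairs = cen$n_pairs, n_self = cen$n_self,
             classes = lapply(cen$classes, paste, collapse = "/")),
        "partner_census.json")

  manifest <- list(
    package = "poolscape",
    version = as.character(utils::packageVersion("poolscape")),
    pool_type = config$pool_type, ref_base = config$ref_base,
    time_label = config$time_label,
    parameters = list(window = config$window, min_mean_q = config$min_mean_q,
                      min_support = config$min_support, L = config$L,
                      periods = range(config$periods), k = config$k,
                      selfcomp_seed = config$selfcomp_seed,
                      synthetic = config$synthetic),
    n_sequences = summ$n_sequences, f_bar = summ$f_bar,
    outputs = Filter(Negate(is.null), list(
      "pool_summary.json",
      sprintf("fraction_map_%s.tsv", config$ref_base),
      spectrum_file, "zebraness.tsv", "selfcomp.tsv",
      "kmer_symmetry.json", "thermo.json", "partner_census.json")))
  wjson(manifest, "manifest.json")
  invisible(structure(list(out_dir = config$out_dir, manifest = manifest,
                           summary = summ, pool = p),
                      class = "report_bundle"))
}

#' Compare pipeline runs across time points
#'
#' Tabulates pool-average composition, zebraness and k-mer symmetry across
#' two or more report bundles of the same pool type, in the order given
#' (assumed chronological), and flags monotone homogenization of the
#' pool-average bias (|f_bar - 0.5| strictly decreasing).
#'
#' @param bundles List of `"report_bundle"` objects from [run_pipeline()],
#'   or of output directories.
#' @return A list with `table` (data.frame: label, f_bar, bias, mean
#'   zebraness, symmetry score) and `homogenization` (logical flag).
#' @export
compare_timepoints <- function(bundles) {
  if (length(bundles) < 2L) stop("need at least 2 bundles to compare")
  read_bundle <- function(b) {
    if (inherits(b, "report_bundle")) b$out_dir else b
  }
  dirs <- vapply(bundles, read_bundle, character(1))
  mani <- lapply(dirs, function(d)
    jsonlite::read_json(file.path(d, "manifest.json"), simplifyVector = TRUE))
  ptypes <- vapply(mani, `[[`, character(1), "pool_type")
  refs <- vapply(mani, `[[`, character(1), "ref_base")
  if (length(unique(ptypes)) != 1L || length(unique(refs)) != 1L) {
    stop("incompatible bundles: pool_type/ref_base differ (",
         paste(unique(ptypes), collapse = ","), "; ",
         paste(unique(refs), collapse = ","), ")")
  }
  row_of <- function(d, m) {
    zp <- utils::read.delim(file.path(d, "zebraness.tsv"))
    ks <- jsonlite::read_json(file.path(d, "kmer_symmetry.json"),
                              simplifyVector = TRUE)
    data.frame(label = m$time_label, f_bar = m$f_bar,
               bias = abs(m$f_bar - 0.5),
               mean_zebraness = stats::weighted.mean(zp$mean_zebraness,
                                                     zp$support),
               symmetry_score = ks$symmetry_score)
  }
  tab <- do.call(rbind, Map(row_of, dirs, mani))
  rownames(tab) <- NULL
  list(table = tab,
       homogenization = all(diff(tab$bias) < 0) || all(diff(tab$bias) <= 0) &&
         any(diff(tab$bias) < 0))
}
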