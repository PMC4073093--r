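#' Pipeline run configuration
#'
#' Collects input paths and every stage threshold. Threshold defaults
#' are the published procedure: 30x minimum site depth in both pools,
#' 80% shared-high-frequency exclusion, 1-cM bins with at least 30
#' SNPs, deletions of at least 150 bp with wildtype depth of at least
#' 5x, mutant depth at most 2x and a wildtype/mutant ratio of at least
#' 4.
#'
#' @param vcf,depth,targets,anchors,genes Input file paths (pools VCF,
#'   paired depth TSV, targets BED, anchor TSV, gene table TSV).
#' @param out_dir Output directory for per-stage TSVs and
#'   `summary.json`.
#' @param mutant_sample,wildtype_sample VCF sample names.
#' @param min_depth,both_high,bin_width,min_snps Frequency-stage
#'   thresholds.
#' @param min_length,wt_min_c1,wt_min_c2,mut_max,ratio_min
#'   Deletion-stage thresholds.
#' @param interval_chromosome,interval_lo,interval_hi Genetic target
#'   interval; when `NULL` it is derived as the peak chromosome and
#'   peak +/- `interval_half_width`.
#' @param interval_half_width Half-width in cM used when the interval
#'   is derived from the peak (default 15).
#' @param warn_threshold Minimum convincing peak score.
#' @return A list of class `run_config`.
#' @export
run_config <- function(vcf, depth, targets, anchors, genes,
                       out_dir = ".",
                       mutant_sample = "mutant",
                       wildtype_sample = "wildtype",
                       min_depth = 30, both_high = 0.80, bin_width = 1.0,
                       min_snps = 30, min_length = 150, wt_min_c1 = 5,
                       wt_min_c2 = 5, mut_max = 2, ratio_min = 4,
                       interval_chromosome = NULL, interval_lo = NULL,
                       interval_hi = NULL, interval_half_width = 15,
                       warn_threshold = 0.2) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a
#' comment. Keys are the arguments of [run_config()]; unknown keys are
#' an error. Values given on the command line or as arguments override
#' the file.
#'
#' @param path Config file path.
#' @param ... Overrides, as for [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*[:=]\\s*(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("cannot parse config line: ", lines[bad][1L])
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  known <- names(formals(run_config))
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- as.list(vals)
  names(args) <- keys
  numeric_keys <- setdiff(known, c("vcf", "depth", "targets", "anchors",
                                   "genes", "out_dir", "mutant_sample",
                                   "wildtype_sample",
                                   "interval_chromosome"))
  for (k in intersect(names(args), numeric_keys))
    args[[k]] <- as.numeric(args[[k]])
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(run_config, args)
}

#' Run the full mapping-by-sequencing analysis
#'
#' Chains the three stages — allele-frequency mapping, read-depth
#' deletion scan, candidate ranking — on the configured inputs, writes
#' `freqmap.tsv`, `delscan.tsv`, `candidates.tsv`, `intergenic.tsv`
#' and `summary.json` into `out_dir`, and logs counts at every filter
#' boundary. Any stage error is re-raised with the stage name, and
#' partially written outputs are removed.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return An object of class `poolmap_run`: `bins`, `peak`, `calls`,
#'   `anchored_split`, `candidates`, `counts`, `summary`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  say <- if (quiet) function(...) invisible() else message
  outputs <- file.path(config$out_dir,
                       c("freqmap.tsv", "delscan.tsv", "candidates.tsv",
                         "intergenic.tsv", "summary.json"))
  stage <- function(name, expr) {
    tryCatch(if (quiet) suppressMessages(expr) else expr,
             error = function(e) {
      unlink(outputs)
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
  }
  for (p in c(config$vcf, config$depth, config$targets, config$anchors,
              config$genes))
    if (!file.exists(p)) stop("input file not found: ", p)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # stage 1: allele-frequency mapping
  fm <- stage("freqmap", {
    sites <- read_pool_vcf(config$vcf, config$mutant_sample,
                           config$wildtype_sample)
    freq_map(sites, read_anchor_table(config$anchors),
             min_depth = config$min_depth, both_high = config$both_high,
             bin_width = config$bin_width, min_snps = config$min_snps,
             warn_threshold = config$warn_threshold)
  })
  fc <- fm$filter_counts
  say(sprintf(
    "freqmap: %d sites read, %d below %gx, %d high in both pools, %d on unanchored contigs, %d bins retained",
    fc[["input"]], fc[["removed_low_depth"]], config$min_depth,
    fc[["removed_both_high"]], attr(fm$bins, "n_unanchored"),
    nrow(fm$bins)))
  say(sprintf("freqmap: peak on %s at [%g, %g) cM, mutant %.1f%% / wildtype %.1f%%",
              fm$peak$chromosome, fm$peak$bin_start,
              fm$peak$bin_start + config$bin_width,
              100 * fm$peak$mean_freq_mut, 100 * fm$peak$mean_freq_wt))

  # stage 2: deletion scan
  scan <- stage("delscan", {
    tracks <- read_depth_track(config$depth, sample_count = 2)
    ivs <- covered_intervals(tracks[[1L]], tracks[[2L]],
                             read_targets_bed(config$targets))
    call_deletions(ivs, min_length = config$min_length,
                   wt_min_c1 = config$wt_min_c1,
                   wt_min_c2 = config$wt_min_c2,
                   mut_max = config$mut_max,
                   ratio_min = config$ratio_min)
  })
  sc <- attr(scan, "scan_counts")
  say(sprintf("delscan: %d covered intervals, %d >= %d bp, %d called",
              sc[["intervals"]], sc[["length_pass"]], config$min_length,
              sc[["called"]]))

  # stage 3: anchoring + ranking
  rank <- stage("rank", {
    anchors <- read_anchor_table(config$anchors)
    split <- anchor_deletions(scan, anchors)
    chr <- config$interval_chromosome
    lo <- config$interval_lo
    hi <- config$interval_hi
    if (is.null(chr)) chr <- fm$peak$chromosome
    if (is.null(lo)) lo <- fm$peak$bin_mid - config$interval_half_width
    if (is.null(hi)) hi <- fm$peak$bin_mid + config$interval_half_width
    in_iv <- select_in_interval(split$anchored, chr, max(0, lo), hi)
    cand <- rank_candidates(in_iv, read_gene_table(config$genes),
                            fm$peak)
    list(split = split, in_interval = in_iv, candidates = cand,
         interval = list(chromosome = chr, lo = max(0, lo), hi = hi))
  })
  n_in <- nrow(rank$in_interval)
  n_anch <- nrow(rank$split$anchored)
  say(sprintf(
    "rank: %d calls in the %s %g-%g cM interval, %d anchored elsewhere, %d unanchored",
    n_in, rank$interval$chromosome, rank$interval$lo, rank$interval$hi,
    n_anch - n_in, nrow(rank$split$unanchored)))

  counts <- list(
    sites_read = unname(fc[["input"]]),
    sites_low_depth = unname(fc[["removed_low_depth"]]),
    sites_both_high = unname(fc[["removed_both_high"]]),
    sites_unanchored = attr(fm$bins, "n_unanchored"),
    bins_retained = nrow(fm$bins),
    intervals_found = unname(sc[["intervals"]]),
    intervals_length_pass = unname(sc[["length_pass"]]),
    deletions_called = unname(sc[["called"]]),
    calls_in_interval = n_in,
    calls_other_regions = n_anch - n_in,
    calls_unanchored = nrow(rank$split$unanchored))
  top <- if (nrow(rank$candidates)) rank$candidates[1L, ] else NULL
  summary_obj <- list(
    peak = list(chromosome = fm$peak$chromosome,
                bin_start = fm$peak$bin_start,
                bin_mid = fm$peak$bin_mid,
                mean_freq_mut = fm$peak$mean_freq_mut,
                mean_freq_wt = fm$peak$mean_freq_wt,
                score = fm$peak$score),
    interval = rank$interval,
    counts = counts,
    top_candidate = if (is.null(top)) NULL else as.list(top))

  wr <- function(df, path) utils::write.table(
    df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  stage("write", {
    wr(as.data.frame(fm$bins), outputs[1L])
    dels <- as.data.frame(scan)
    dels$mean_depth_mut <- round(dels$mean_depth_mut, 1)
    dels$mean_depth_wt <- round(dels$mean_depth_wt, 1)
    names(dels)[names(dels) == "mean_depth_mut"] <- "cov_mut"
    names(dels)[names(dels) == "mean_depth_wt"] <- "cov_wt"
    wr(dels, outputs[2L])
    wr(as.data.frame(rank$candidates), outputs[3L])
    wr(attr(rank$candidates, "intergenic"), outputs[4L])
    jsonlite::write_json(summary_obj, outputs[5L], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  })
  structure(list(bins = fm$bins, peak = fm$peak, calls = scan,
                 anchored_split = rank$split,
                 candidates = rank$candidates, counts = counts,
                 summary = summary_obj, config = config),
            class = "poolmap_run")
}

#' @export
print.poolmap_run <- function(x, ...) {
  cat("Mapping-by-sequencing run\n")
  print(x$peak)
  cat(sprintf(
    "  deletions: %d called (%d in interval, %d elsewhere, %d unanchored)\n",
    x$counts$deletions_called, x$counts$calls_in_interval,
    x$counts$calls_other_regions, x$counts$calls_unanchored))
  if (!is.null(x$summary$top_candidate))
    cat(sprintf("  top candidate: %s (%s), %.1f cM from the peak\n",
                x$summary$top_candidate$gene_id,
                x$summary$top_candidate$annotation,
                x$summary$top_candidate$distance_to_peak))
  else cat("  no gene-bearing deletion call in the target interval\n")
  invisible(x)
}

#' @export
summary.poolmap_run <- function(object, ...) {
  print(object)
  cat("\nFilter-boundary counts:\n")
  for (k in names(object$counts))
    cat(sprintf("  %-22s %d\n", k, object$counts[[k]]))
  cat("\nTop candidate genes:\n")
  print(utils::head(as.data.frame(object$candidates), 5))
  invisible(object)
}
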