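#' Per-pool allele frequency at one site
#'
#' The frequency of the mutant (alternate) allele: reads supporting the
#' alternate allele divided by all reads at the site in that pool. The
#' convention assumes the reference is the wildtype outcross parent, so
#' the VCF alternate allele is the mutant-linked allele.
#'
#' @param sites A `pool_sites` data frame (or any data frame with the
#'   ref/alt depth columns).
#' @param pool `"mutant"` or `"wildtype"`.
#' @return Numeric vector of frequencies; `NaN` where the pool has zero
#'   depth (such sites are removed by the coverage filter upstream).
#' @export
site_frequency <- function(sites, pool = c("mutant", "wildtype")) {
  pool <- match.arg(pool)
  if (pool == "mutant") sites$alt_mut / (sites$ref_mut + sites$alt_mut)
  else sites$alt_wt / (sites$ref_wt + sites$alt_wt)
}

#' Coverage and shared-high-frequency site filters
#'
#' Retains sites with total depth of at least `min_depth` in both pools,
#' then removes sites whose alternate-allele frequency is at least
#' `both_high` in both pools (such sites reflect variants between the
#' mutant background and the reference rather than segregating markers).
#'
#' @param sites `pool_sites` data frame.
#' @param min_depth Minimum per-pool total depth (default 30).
#' @param both_high Frequency threshold applied to both pools jointly
#'   (default 0.80, inclusive).
#' @return Filtered `pool_sites`; attribute `filter_counts` records how
#'   many sites each rule removed.
#' @export
filter_sites <- function(sites, min_depth = 30, both_high = 0.80) {
  tot_mut <- sites$ref_mut + sites$alt_mut
  tot_wt <- sites$ref_wt + sites$alt_wt
  deep <- tot_mut >= min_depth & tot_wt >= min_depth
  kept <- sites[deep, , drop = FALSE]
  f_mut <- site_frequency(kept, "mutant")
  f_wt <- site_frequency(kept, "wildtype")
  shared_high <- f_mut >= both_high & f_wt >= both_high
  out <- kept[!shared_high, , drop = FALSE]
  attr(out, "filter_counts") <- c(
    input = nrow(sites),
    removed_low_depth = sum(!deep),
    removed_both_high = sum(shared_high),
    retained = nrow(out))
  class(out) <- c("pool_sites", "data.frame")
  out
}

#' Average pool allele frequencies in centimorgan bins
#'
#' Each site inherits the (chromosome, cM) anchor of its contig; sites
#' on unanchored contigs are excluded and counted. Bins are half-open
#' `[k, k + width)` centimorgan; bins holding fewer than `min_snps`
#' sites are dropped. Bin means are unweighted arithmetic means over
#' sites.
#'
#' @param sites Filtered `pool_sites`.
#' @param anchors Anchor table ([read_anchor_table()]).
#' @param bin_width Bin width in centimorgan (default 1).
#' @param min_snps Minimum sites per retained bin (default 30).
#' @return Data frame of class `poolmap_freqmap` with columns
#'   `chromosome`, `bin_start`, `n_snps`, `mean_freq_mut`,
#'   `mean_freq_wt`, `score`; attribute `n_unanchored` counts excluded
#'   sites, `n_bins_dropped` the bins below `min_snps`.
#' @export
bin_frequencies <- function(sites, anchors, bin_width = 1.0,
                            min_snps = 30) {
  idx <- match(sites$contig, anchors$contig)
  n_unanchored <- sum(is.na(idx))
  if (n_unanchored > 0)
    message("bin_frequencies: ", n_unanchored,
            " site(s) on unanchored contigs excluded")
  sites <- sites[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  chrom <- anchors$chromosome[idx]
  bin_start <- floor(anchors$cm[idx] / bin_width) * bin_width
  f_mut <- site_frequency(sites, "mutant")
  f_wt <- site_frequency(sites, "wildtype")
  key <- paste(chrom, bin_start, sep = "\r")
  agg <- function(v) vapply(split(v, key), mean, numeric(1))
  n <- vapply(split(f_mut, key), length, integer(1))
  out <- data.frame(
    chromosome = vapply(strsplit(names(n), "\r"), `[`, character(1), 1L),
    bin_start = as.numeric(vapply(strsplit(names(n), "\r"), `[`,
                                  character(1), 2L)),
    n_snps = as.integer(n),
    mean_freq_mut = unname(agg(f_mut)),
    mean_freq_wt = unname(agg(f_wt)),
    stringsAsFactors = FALSE)
  dropped <- out$n_snps < min_snps
  out <- out[!dropped, , drop = FALSE]
  out <- out[order(out$chromosome, out$bin_start), , drop = FALSE]
  rownames(out) <- NULL
  out$score <- out$mean_freq_mut - out$mean_freq_wt
  attr(out, "n_unanchored") <- n_unanchored
  attr(out, "n_bins_dropped") <- sum(dropped)
  attr(out, "bin_width") <- bin_width
  class(out) <- c("poolmap_freqmap", "data.frame")
  out
}

#' Call the allele-frequency peak
#'
#' The causal-locus bin is the bin maximising the frequency difference
#' `mean_freq_mut - mean_freq_wt`; under the pool-genetics model this
#' score is maximal at the causal locus and is robust to a heterozygote
#' mis-phenotyped into the mutant bulk. Ties are broken by chromosome
#' order, then by lower bin start.
#'
#' @param bins A `poolmap_freqmap` ([bin_frequencies()]).
#' @param n_best Number of top-scoring bins to attach for diagnostics.
#' @param warn_threshold Warn when the best score is below this value
#'   (default 0.2), indicating no convincing peak.
#' @return A list of class `peak_call` with `chromosome`, `bin_start`,
#'   `bin_mid`, `mean_freq_mut`, `mean_freq_wt`, `score` and a
#'   `best_bins` data frame.
#' @export
detect_peak <- function(bins, n_best = 5, warn_threshold = 0.2) {
  if (nrow(bins) == 0L)
    stop("no bins available: cannot call a peak")
  width <- attr(bins, "bin_width")
  if (is.null(width)) width <- 1.0
  ord <- order(-bins$score, bins$chromosome, bins$bin_start)
  top <- bins[ord[1L], ]
  if (top$score < warn_threshold)
    warning(sprintf(
      "max bin score %.3f < %.2f: no convincing allele-frequency peak",
      top$score, warn_threshold))
  structure(list(
    chromosome = top$chromosome,
    bin_start = top$bin_start,
    bin_mid = top$bin_start + width / 2,
    mean_freq_mut = top$mean_freq_mut,
    mean_freq_wt = top$mean_freq_wt,
    score = top$score,
    best_bins = utils::head(bins[ord, ], n_best)),
    class = "peak_call")
}

#' @export
print.peak_call <- function(x, ...) {
  cat("Allele-frequency peak\n")
  cat(sprintf("  chromosome %s, bin [%g, %g) cM\n", x$chromosome,
              x$bin_start, 2 * x$bin_mid - x$bin_start))
  cat(sprintf("  mutant pool %.1f%%, wildtype pool %.1f%%, score %.3f\n",
              100 * x$mean_freq_mut, 100 * x$mean_freq_wt, x$score))
  invisible(x)
}

#' @export
print.poolmap_freqmap <- function(x, ...) {
  cat(sprintf("Binned pool allele frequencies: %d bin(s) on %d chromosome(s)\n",
              nrow(x), length(unique(x$chromosome))))
  NextMethod()
}

#' Plot binned pool allele frequencies along the genetic map
#'
#' @param x A `poolmap_freqmap`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.poolmap_freqmap <- function(x, ...) {
  chroms <- unique(x$chromosome)
  offs <- c(0, cumsum(vapply(chroms, function(ch)
    max(x$bin_start[x$chromosome == ch]) + 5, numeric(1))))
  pos <- x$bin_start + offs[match(x$chromosome, chroms)]
  graphics::plot(pos, x$mean_freq_mut, col = "red", pch = 16, cex = 0.5,
                 ylim = c(0, 1), xlab = "genetic position (cM, concatenated)",
                 ylab = "alternate-allele frequency", ...)
  graphics::points(pos, x$mean_freq_wt, col = "black", pch = 16, cex = 0.5)
  graphics::legend("topleft", legend = c("mutant pool", "wildtype pool"),
                   col = c("red", "black"), pch = 16, bty = "n")
  invisible(x)
}

#' Allele-frequency mapping stage
#'
#' Convenience wrapper chaining [filter_sites()], [bin_frequencies()]
#' and [detect_peak()].
#'
#' @param sites `pool_sites` (from [read_pool_vcf()] or the simulator).
#' @param anchors Anchor table.
#' @inheritParams filter_sites
#' @inheritParams bin_frequencies
#' @inheritParams detect_peak
#' @return List with `bins` (`poolmap_freqmap`) and `peak` (`peak_call`).
#' @export
freq_map <- function(sites, anchors, min_depth = 30, both_high = 0.80,
                     bin_width = 1.0, min_snps = 30,
                     warn_threshold = 0.2) {
  kept <- filter_sites(sites, min_depth = min_depth,
                       both_high = both_high)
  bins <- bin_frequencies(kept, anchors, bin_width = bin_width,
                          min_snps = min_snps)
  peak <- detect_peak(bins, warn_threshold = warn_threshold)
  list(bins = bins, peak = peak,
       filter_counts = attr(kept, "filter_counts"))
}
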